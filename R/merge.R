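#' Construct a merge fixture
#'
#' Bundles the inputs of [merge_by_core()]: a core alignment holding one
#' representative per family, the per-family sub-alignments, and the map
#' from family label to representative id. The representative's ungapped
#' sequence must be identical in the core and in its sub-alignment.
#'
#' @param core An [msa] of the family representatives only.
#' @param subs Named list (family label -> [msa]) of sub-alignments, each
#'   containing its representative.
#' @param representative_of Named character vector, family label ->
#'   representative sequence id.
#' @return A `merge_fixture` list.
#' @export
merge_fixture <- function(core, subs, representative_of) {
  if (ncol(core) < 1L || nrow(core) < 1L) stop("empty core alignment")
  fams <- names(subs)
  if (is.null(fams) || anyDuplicated(fams))
    stop("sub-alignments must be uniquely named by family label")
  if (!all(fams %in% names(representative_of)))
    stop("missing representative for: ",
         paste(setdiff(fams, names(representative_of)), collapse = ", "))
  for (f in fams) {
    rep_id <- representative_of[[f]]
    if (!rep_id %in% rownames(core))
      stop("representative ", rep_id, " absent from core")
    if (!rep_id %in% rownames(subs[[f]]))
      stop("representative ", rep_id, " absent from sub-alignment ", f)
    ungap <- function(s) gsub("-", "", s, fixed = TRUE)
    if (ungap(msa_strings(core)[[rep_id]]) !=
        ungap(msa_strings(subs[[f]])[[rep_id]]))
      stop("representative sequence mismatch between core and sub for ", f)
  }
  structure(list(core = core, subs = subs,
                 representative_of = representative_of[fams]),
            class = "merge_fixture")
}

#' Merge family sub-alignments over a core alignment of representatives
#'
#' The sequence-side of a structure-guided superfamily alignment protocol:
#' each family's sub-alignment is threaded onto the core alignment of the
#' family representatives, which acts as the guide. Sub-alignment columns
#' in which the family representative carries a residue land in that
#' residue's core column; columns where the representative is gapped
#' (insertions relative to the representative) become family-private insert
#' columns in which every other family carries gaps. Insert blocks are
#' attached immediately after the core column of the preceding
#' representative residue (left-anchored; leading insertions anchor before
#' core column 1); blocks from different families at the same anchor follow
#' the family input order. Within each family the residue correspondences
#' of the sub-alignment are preserved exactly, and across representatives
#' those of the core are preserved exactly.
#'
#' @param fixture A [merge_fixture].
#' @return A list with `alignment` (the merged [msa]; rows grouped by
#'   family in input order), `provenance` (character vector, one entry per
#'   merged column: `"core:<k>"` or `"insert:<family>:<anchor>:<i>"`), and
#'   `annotation` (a [family_annotation] for the merged rows).
#' @export
merge_by_core <- function(fixture) {
  stopifnot(inherits(fixture, "merge_fixture"))
  core <- unclass(fixture$core)
  fams <- names(fixture$subs)
  n_core <- ncol(core)

  # For each family: map every sub column to a core column (>=1) or to an
  # insert slot (anchor a in 0..n_core, position within the family's block).
  col_maps <- list()   # per family: data.frame(sub_col, kind, core_col/anchor, pos)
  insert_widths <- matrix(0L, nrow = length(fams), ncol = n_core + 1L,
                          dimnames = list(fams, NULL))  # col a+1 = anchor a
  for (f in fams) {
    rep_id <- fixture$representative_of[[f]]
    sub <- unclass(fixture$subs[[f]])
    rep_sub <- sub[rep_id, ]
    rep_core <- core[rep_id, ]
    res_to_core <- which(rep_core != GAP)        # residue index -> core column
    sub_res_idx <- cumsum(rep_sub != GAP)        # per sub column, last residue seen
    is_res <- rep_sub != GAP
    kind <- ifelse(is_res, "core", "insert")
    target <- integer(ncol(sub))
    anchor <- integer(ncol(sub))
    pos <- integer(ncol(sub))
    target[is_res] <- res_to_core[sub_res_idx[is_res]]
    # insertion anchor: core column of preceding representative residue (0 if none)
    prev_res <- sub_res_idx[!is_res]
    anchor[!is_res] <- ifelse(prev_res == 0L, 0L, res_to_core[pmax(prev_res, 1L)])
    # position within the anchor's block, in sub-column order
    if (any(!is_res)) {
      a <- anchor[!is_res]
      pos[!is_res] <- stats::ave(seq_along(a), a, FUN = seq_along)
      w <- tapply(a, a, length)
      insert_widths[f, as.integer(names(w)) + 1L] <- as.integer(w)
    }
    col_maps[[f]] <- list(kind = kind, target = target,
                          anchor = anchor, pos = pos)
  }

  # Lay out merged columns: anchor-0 inserts, then for each core column k:
  # core:k followed by inserts anchored at k; families in input order.
  prov <- character()
  slot_of <- new.env(parent = emptyenv())  # "f:anchor:pos" -> merged col
  add_inserts <- function(a) {
    for (f in fams) {
      w <- insert_widths[f, a + 1L]
      if (w > 0L) for (i in seq_len(w)) {
        prov[[length(prov) + 1L]] <<- paste0("insert:", f, ":", a, ":", i)
        assign(paste0(f, ":", a, ":", i), length(prov), envir = slot_of)
      }
    }
  }
  core_slot <- integer(n_core)
  add_inserts(0L)
  for (k in seq_len(n_core)) {
    prov[[length(prov) + 1L]] <- paste0("core:", k)
    core_slot[k] <- length(prov)
    add_inserts(k)
  }
  n_merged <- length(prov)

  ids <- character()
  labels <- character()
  rows <- list()
  for (f in fams) {
    sub <- unclass(fixture$subs[[f]])
    cm <- col_maps[[f]]
    dest <- integer(ncol(sub))
    dest[cm$kind == "core"] <- core_slot[cm$target[cm$kind == "core"]]
    ins <- which(cm$kind == "insert")
    for (j in ins)
      dest[j] <- get(paste0(f, ":", cm$anchor[j], ":", cm$pos[j]),
                     envir = slot_of)
    for (id in rownames(sub)) {
      r <- rep(GAP, n_merged)
      r[dest] <- sub[id, ]
      rows[[id]] <- r
      ids <- c(ids, id)
      labels <- c(labels, f)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  aln <- structure(m, class = c("msa", "matrix", "array"))
  list(alignment = aln, provenance = prov,
       annotation = family_annotation(ids, labels))
}
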