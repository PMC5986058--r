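#' Synthetic-alignment configuration
#'
#' Describes a multi-family alignment with planted column roles:
#'
#' * conserved columns — one residue across the whole alignment, each
#'   sequence deviating independently with probability `deviation_rate`;
#' * exception columns — one majority residue in all families but one,
#'   which carries its own residue (the pattern of an invariant position
#'   substituted in a single family);
#' * FSP columns — a per-family residue map (at least 2 distinct
#'   residues), each sequence deviating with probability `deviation_rate`;
#' * background columns — i.i.d. draws from `background_distribution`.
#'
#' Gaps are inserted per cell with probability `gap_rate`; with
#' `gap_protect = TRUE` (default) planted columns stay gap-free so that
#' recovery tests isolate the statistics from gap masking.
#'
#' @param n_families,seqs_per_family,n_columns Alignment dimensions.
#' @param conserved Data frame with columns `column`, `residue`,
#'   `deviation_rate` (may be `NULL`).
#' @param exceptions Data frame with columns `column`, `majority_residue`,
#'   `deviating_family` (label), `deviating_residue` (may be `NULL`).
#' @param fsp List of lists, each with `column`, `residues` (character
#'   vector named by family label, >= 2 distinct values), `deviation_rate`
#'   (may be `NULL`).
#' @param background_distribution Named probability vector over the 20
#'   residues (default uniform, the maximum-entropy and hence hardest null
#'   for false conservation).
#' @param gap_rate Per-cell gap probability (default 0).
#' @param gap_protect Keep planted columns gap-free (default `TRUE`).
#' @param seed Integer seed.
#' @return A `synth_config` list. Family labels are `"F1"`, ..., ids
#'   `"F<i>_s<j>"`.
#' @export
synth_config <- function(n_families, seqs_per_family, n_columns,
                         conserved = NULL, exceptions = NULL, fsp = NULL,
                         background_distribution = NULL,
                         gap_rate = 0, gap_protect = TRUE, seed = 1L) {
  if (is.null(background_distribution))
    background_distribution <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(abs(sum(background_distribution) - 1) < 1e-9,
            n_families >= 1, seqs_per_family >= 1, n_columns >= 1,
            gap_rate >= 0, gap_rate < 1)
  fam_labels <- paste0("F", seq_len(n_families))
  planted <- c(if (!is.null(conserved)) conserved$column,
               if (!is.null(exceptions)) exceptions$column,
               vapply(fsp, `[[`, numeric(1), "column"))
  if (anyDuplicated(planted)) stop("overlapping planted columns")
  if (length(planted) && any(planted < 1 | planted > n_columns))
    stop("planted column out of range")
  for (p in fsp) {
    if (!all(fam_labels %in% names(p$residues)))
      stop("fsp residue map must cover all families")
    if (length(unique(p$residues)) < 2L)
      stop("fsp residue map must assign >= 2 distinct residues")
  }
  if (!is.null(exceptions) &&
      !all(exceptions$deviating_family %in% fam_labels))
    stop("unknown deviating_family in exceptions")
  structure(list(n_families = as.integer(n_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 n_columns = as.integer(n_columns),
                 conserved = conserved, exceptions = exceptions, fsp = fsp,
                 background_distribution = background_distribution,
                 gap_rate = gap_rate, gap_protect = gap_protect,
                 seed = as.integer(seed),
                 family_labels = fam_labels),
            class = "synth_config")
}

#' Randomly planted synthetic configuration
#'
#' Convenience constructor: samples disjoint planted columns and their
#' residues from the seeded RNG, then delegates to [synth_config()]. FSP
#' columns get distinct residues across families (all-distinct when
#' `n_families <= 20`).
#'
#' @inheritParams synth_config
#' @param n_conserved,n_fsp,n_exception Numbers of planted columns.
#' @param conserved_deviation,fsp_deviation Per-sequence deviation rates.
#' @return A `synth_config`.
#' @export
sample_synth_config <- function(n_families, seqs_per_family, n_columns,
                                n_conserved = 0L, n_fsp = 0L,
                                n_exception = 0L,
                                conserved_deviation = 0.01,
                                fsp_deviation = 0.05,
                                gap_rate = 0, gap_protect = TRUE,
                                seed = 1L) {
  n_planted <- n_conserved + n_fsp + n_exception
  stopifnot(n_planted <= n_columns)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  cols <- sample.int(n_columns, n_planted)
  fam_labels <- paste0("F", seq_len(n_families))
  i <- 0L
  conserved <- NULL
  if (n_conserved > 0L) {
    conserved <- data.frame(column = cols[i + seq_len(n_conserved)],
                            residue = sample(AA20, n_conserved, replace = TRUE),
                            deviation_rate = conserved_deviation)
    i <- i + n_conserved
  }
  fsp <- NULL
  if (n_fsp > 0L) {
    fsp <- lapply(seq_len(n_fsp), function(k) {
      resid <- if (n_families <= 20L) sample(AA20, n_families)
               else sample(AA20, n_families, replace = TRUE)
      list(column = cols[i + k],
           residues = setNames(resid, fam_labels),
           deviation_rate = fsp_deviation)
    })
    i <- i + n_fsp
  }
  exceptions <- NULL
  if (n_exception > 0L) {
    maj <- sample(AA20, n_exception, replace = TRUE)
    dev <- vapply(maj, function(r) sample(setdiff(AA20, r), 1L), character(1))
    exceptions <- data.frame(column = cols[i + seq_len(n_exception)],
                             majority_residue = maj,
                             deviating_family = sample(fam_labels,
                                                       n_exception,
                                                       replace = TRUE),
                             deviating_residue = dev)
  }
  synth_config(n_families, seqs_per_family, n_columns,
               conserved = conserved, exceptions = exceptions, fsp = fsp,
               gap_rate = gap_rate, gap_protect = gap_protect, seed = seed)
}

#' Generate a synthetic alignment with planted ground truth
#'
#' Draws an alignment from a [synth_config]: planted columns carry their
#' designated residues (with the configured per-sequence deviation rates;
#' deviations are uniform over the 19 other residues), background columns
#' are i.i.d. from the background distribution, and gaps are overlaid per
#' cell at `gap_rate` (sparing planted columns when `gap_protect` is on).
#' Deterministic given the config's seed.
#'
#' @param config A [synth_config].
#' @return A list with `alignment` (an [msa]), `annotation` (a
#'   [family_annotation]) and `truth` (a data frame with one row per
#'   column: `column`, `role` in `{conserved, exception, fsp,
#'   background}`, `planted` — the planted residue, comma-joined
#'   per-family residues for FSP columns, `""` for background). The config
#'   is attached to `truth` as attribute `"config"`.
#' @export
generate_alignment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  nf <- config$n_families
  ns <- config$seqs_per_family
  nc <- config$n_columns
  n <- nf * ns
  fam <- rep(config$family_labels, each = ns)
  ids <- paste0(fam, "_s", formatC(rep(seq_len(ns), nf), width = 3, flag = "0"))

  m <- matrix("", nrow = n, ncol = nc)
  role <- rep("background", nc)
  planted_desc <- rep("", nc)
  bg <- config$background_distribution

  for (k in seq_len(nrow(config$conserved %||% data.frame()))) {
    j <- config$conserved$column[k]
    r <- config$conserved$residue[k]
    rate <- config$conserved$deviation_rate[k]
    col <- rep(r, n)
    flip <- stats::runif(n) < rate
    if (any(flip)) col[flip] <- sample(setdiff(AA20, r), sum(flip), replace = TRUE)
    m[, j] <- col
    role[j] <- "conserved"
    planted_desc[j] <- r
  }
  for (p in config$fsp %||% list()) {
    j <- p$column
    col <- p$residues[fam]
    flip <- stats::runif(n) < p$deviation_rate
    for (i in which(flip)) col[i] <- sample(setdiff(AA20, col[i]), 1L)
    m[, j] <- col
    role[j] <- "fsp"
    planted_desc[j] <- paste(p$residues[config$family_labels], collapse = ",")
  }
  for (k in seq_len(nrow(config$exceptions %||% data.frame()))) {
    j <- config$exceptions$column[k]
    devfam <- config$exceptions$deviating_family[k]
    col <- ifelse(fam == devfam,
                  config$exceptions$deviating_residue[k],
                  config$exceptions$majority_residue[k])
    m[, j] <- col
    role[j] <- "exception"
    planted_desc[j] <- paste0(config$exceptions$majority_residue[k], "/",
                              devfam, ":",
                              config$exceptions$deviating_residue[k])
  }
  bgcols <- which(role == "background")
  if (length(bgcols))
    m[, bgcols] <- sample(names(bg), n * length(bgcols), replace = TRUE,
                          prob = bg)
  if (config$gap_rate > 0) {
    gappable <- if (config$gap_protect) bgcols else seq_len(nc)
    if (length(gappable)) {
      sub <- m[, gappable, drop = FALSE]
      sub[stats::runif(length(sub)) < config$gap_rate] <- GAP
      m[, gappable] <- sub
    }
  }
  aln <- msa(ids, apply(m, 1L, paste, collapse = ""))
  truth <- data.frame(column = seq_len(nc), role = role,
                      planted = planted_desc, stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  list(alignment = aln,
       annotation = family_annotation(ids, fam),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random merge fixture with known expected width
#'
#' Builds a core alignment of `n_families` representatives (with random
#' gaps so that representatives differ in which core columns they occupy)
#' and one sub-alignment per family, then plants insertion blocks —
#' sub-alignment columns gapped in the representative — at the requested
#' anchors. Used to exercise [merge_by_core()] against a known expected
#' merged width (`core_length + sum of insertion widths`).
#'
#' @param n_families Number of families/representatives.
#' @param core_length Number of core columns.
#' @param insertions Data frame with columns `family` (label `"F<i>"` or
#'   index), `anchor` (core column 0..core_length after which the block
#'   sits) and `width`; may be `NULL`.
#' @param seqs_per_family Sequences per sub-alignment (>= 1; the
#'   representative included).
#' @param core_gap_rate Probability that a representative is gapped at a
#'   core column (default 0.15; columns are re-drawn so every core column
#'   keeps >= 1 residue and every representative >= 1 residue).
#' @param seed Integer seed.
#' @return A list with `fixture` (a [merge_fixture]) and
#'   `expected_width`.
#' @export
generate_merge_fixture <- function(n_families, core_length,
                                   insertions = NULL,
                                   seqs_per_family = 3L,
                                   core_gap_rate = 0.15, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fam_labels <- paste0("F", seq_len(n_families))
  if (!is.null(insertions)) {
    if (is.numeric(insertions$family))
      insertions$family <- fam_labels[insertions$family]
    if (!all(insertions$family %in% fam_labels)) stop("unknown family in insertions")
    if (any(insertions$anchor < 0L | insertions$anchor > core_length))
      stop("insertion anchor out of range")
    if (any(insertions$width < 1L)) stop("insertion width must be >= 1")
  }
  # core occupancy: representative i has a residue at core column j or a gap
  repeat {
    occ <- matrix(stats::runif(n_families * core_length) >= core_gap_rate,
                  nrow = n_families)
    if (all(rowSums(occ) >= 1L) && all(colSums(occ) >= 1L)) break
  }
  core_m <- matrix(GAP, n_families, core_length)
  core_m[occ] <- sample(AA20, sum(occ), replace = TRUE)
  rep_ids <- paste0(fam_labels, "_rep")
  core <- msa(rep_ids, apply(core_m, 1L, paste, collapse = ""))

  subs <- list()
  for (i in seq_len(n_families)) {
    f <- fam_labels[i]
    rep_res <- core_m[i, core_m[i, ] != GAP]     # ungapped representative
    L <- length(rep_res)
    # sub columns: one per representative residue, plus insertion blocks
    ins_f <- if (is.null(insertions)) NULL
             else insertions[insertions$family == f, , drop = FALSE]
    # anchors in representative-residue coordinates: insertion after core
    # column a goes after the last representative residue at column <= a
    res_cols <- which(core_m[i, ] != GAP)
    blocks <- list()
    if (!is.null(ins_f) && nrow(ins_f)) for (k in seq_len(nrow(ins_f))) {
      after_res <- sum(res_cols <= ins_f$anchor[k])
      blocks[[length(blocks) + 1L]] <- c(after = after_res,
                                         width = ins_f$width[k])
    }
    # build sub representative row: residues with '-' at insert columns
    sub_cols <- as.list(seq_len(L))
    # insert markers: 0 denotes an insert column
    for (bl in blocks) {
      pos <- bl[["after"]]
      at <- which(vapply(sub_cols, function(x) !identical(x, 0L) &&
                                               x <= pos, logical(1)))
      idx <- if (length(at)) max(at) else 0L
      sub_cols <- append(sub_cols, rep(list(0L), bl[["width"]]), after = idx)
    }
    sub_cols <- unlist(sub_cols)
    rep_row <- ifelse(sub_cols == 0L, GAP, rep_res[pmax(sub_cols, 1L)])
    n_sub_cols <- length(sub_cols)
    rows <- matrix(sample(AA20, max(0L, seqs_per_family - 1L) * n_sub_cols,
                          replace = TRUE),
                   ncol = n_sub_cols)
    # sprinkle gaps into member rows so induced pairs differ from the rep
    if (nrow(rows)) {
      gm <- stats::runif(length(rows)) < 0.1
      rows[gm] <- GAP
    }
    smat <- rbind(rep_row, rows)
    ids <- c(rep_ids[i],
             if (seqs_per_family > 1L)
               paste0(f, "_m", seq_len(seqs_per_family - 1L)))
    subs[[f]] <- msa(ids, apply(smat, 1L, paste, collapse = ""))
  }
  fixture <- merge_fixture(core, subs, setNames(rep_ids, fam_labels))
  expected <- core_length +
    if (is.null(insertions)) 0L else sum(insertions$width)
  list(fixture = fixture, expected_width = as.integer(expected))
}
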