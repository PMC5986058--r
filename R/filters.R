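#' Filter configuration
#'
#' Thresholds for per-family sequence-set cleaning: redundancy removal at a
#' pairwise-identity threshold, and outlier removal relative to the family
#' representative by average substitution score (bits per aligned column)
#' and ungapped-length difference, plus a hard cap on family size.
#'
#' Defaults follow common practice for assembling a superfamily set from
#' database hits: collapse pairs at or above 95% identity, drop sequences
#' scoring under 0.5 bits per column against the representative or
#' differing from it in length by more than 20%, and keep at most 1000
#' sequences per family.
#'
#' @param identity_threshold Fraction in (0, 1]; pairs at or above it are
#'   redundant.
#' @param min_bits_per_column Minimum mean substitution score (bits) against
#'   the representative.
#' @param max_length_diff Maximum tolerated relative ungapped-length
#'   difference from the representative.
#' @param max_seqs_per_family Cap on retained sequences per family.
#' @param substitution_matrix_name Name of the half-bit substitution matrix
#'   (a Biostrings data set).
#' @return A `filter_config` list.
#' @export
filter_config <- function(identity_threshold = 0.95,
                          min_bits_per_column = 0.5,
                          max_length_diff = 0.20,
                          max_seqs_per_family = 1000L,
                          substitution_matrix_name = "BLOSUM62") {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_bits_per_column > 0, max_length_diff > 0,
            max_seqs_per_family >= 1)
  structure(list(identity_threshold = identity_threshold,
                 min_bits_per_column = min_bits_per_column,
                 max_length_diff = max_length_diff,
                 max_seqs_per_family = as.integer(max_seqs_per_family),
                 substitution_matrix_name = substitution_matrix_name),
            class = "filter_config")
}

new_filter_report <- function(retained_ids, removed, config) {
  if (is.null(removed) || nrow(removed) == 0L)
    removed <- data.frame(id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  structure(list(retained_ids = retained_ids, removed = removed,
                 config_used = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report: ", length(x$retained_ids), " retained, ",
      nrow(x$removed), " removed\n", sep = "")
  if (nrow(x$removed)) print(x$removed, row.names = FALSE)
  invisible(x)
}

# Rows of one family as an msa restricted to the given ids, rep first.
family_rows <- function(alignment, ids, representative_id) {
  if (!representative_id %in% ids)
    stop("representative not among family sequences: ", representative_id)
  ids <- c(representative_id, setdiff(ids, representative_id))
  structure(unclass(alignment)[ids, , drop = FALSE],
            class = c("msa", "matrix", "array"))
}

#' Remove redundant sequences within a family
#'
#' Greedy sweep in input order, representative first: a sequence is removed
#' iff its [pairwise_identity()] with some already-retained sequence is at
#' or above `identity_threshold`. Deterministic and idempotent; the
#' representative is always retained.
#'
#' @param alignment An [msa] holding the family's rows (it may hold more;
#'   `ids` selects the family).
#' @param representative_id Identifier of the family representative.
#' @param config A [filter_config].
#' @param ids Ids to sweep; defaults to all rows of `alignment`.
#' @return A `filter_report` with `retained_ids`, a `removed` data frame
#'   (`id`, `reason` of the form `"redundant_with:<id>"`), and the config.
#' @export
redundancy_filter <- function(alignment, representative_id,
                              config = filter_config(),
                              ids = rownames(alignment)) {
  fam <- family_rows(alignment, ids, representative_id)
  strs <- msa_strings(fam)
  retained <- character()
  removed_id <- character()
  removed_reason <- character()
  for (id in names(strs)) {
    dup <- NULL
    for (kept in retained) {
      if (pairwise_identity(strs[[id]], strs[[kept]]) >=
          config$identity_threshold) {
        dup <- kept
        break
      }
    }
    if (is.null(dup)) retained <- c(retained, id)
    else {
      removed_id <- c(removed_id, id)
      removed_reason <- c(removed_reason, paste0("redundant_with:", dup))
    }
  }
  new_filter_report(retained,
                    data.frame(id = removed_id, reason = removed_reason,
                               stringsAsFactors = FALSE),
                    config)
}

#' Remove outlier sequences relative to the family representative
#'
#' A sequence is removed iff its [bits_per_column()] against the
#' representative falls below `min_bits_per_column`, or its ungapped length
#' differs from the representative's by more than `max_length_diff`
#' (strictly more; a boundary-exact difference is retained). If more than
#' `max_seqs_per_family` sequences then remain, only the first
#' `max_seqs_per_family` (input order, representative first) are kept and
#' the rest are removed with reason `over_cap`.
#'
#' @inheritParams redundancy_filter
#' @return A `filter_report`; removal reasons are
#'   `"low_bits_per_column:<value>"`, `"length_diff:<fraction>"` or
#'   `"over_cap"`.
#' @export
outlier_filter <- function(alignment, representative_id,
                           config = filter_config(),
                           ids = rownames(alignment)) {
  fam <- family_rows(alignment, ids, representative_id)
  strs <- msa_strings(fam)
  mat <- blosum_matrix(config$substitution_matrix_name)
  rep_str <- strs[[representative_id]]
  rep_len <- sum(strsplit(rep_str, "")[[1L]] != GAP)
  if (rep_len == 0L) stop("representative has zero residues")
  retained <- representative_id
  removed_id <- character()
  removed_reason <- character()
  for (id in setdiff(names(strs), representative_id)) {
    bpc <- bits_per_column(strs[[id]], rep_str, mat)
    len <- sum(strsplit(strs[[id]], "")[[1L]] != GAP)
    ldiff <- abs(len - rep_len) / rep_len
    if (bpc < config$min_bits_per_column) {
      removed_id <- c(removed_id, id)
      removed_reason <- c(removed_reason,
                          paste0("low_bits_per_column:", format(bpc)))
    } else if (ldiff > config$max_length_diff) {
      removed_id <- c(removed_id, id)
      removed_reason <- c(removed_reason,
                          paste0("length_diff:", format(ldiff)))
    } else {
      retained <- c(retained, id)
    }
  }
  if (length(retained) > config$max_seqs_per_family) {
    capped <- retained[-seq_len(config$max_seqs_per_family)]
    retained <- retained[seq_len(config$max_seqs_per_family)]
    removed_id <- c(removed_id, capped)
    removed_reason <- c(removed_reason, rep("over_cap", length(capped)))
  }
  new_filter_report(retained,
                    data.frame(id = removed_id, reason = removed_reason,
                               stringsAsFactors = FALSE),
                    config)
}

#' Clean one family's sequence set
#'
#' Applies [outlier_filter()] then [redundancy_filter()] (redundancy among
#' discarded outliers is irrelevant) and combines the reports.
#'
#' @inheritParams redundancy_filter
#' @return A `filter_report` over both stages.
#' @export
filter_family_set <- function(alignment, representative_id,
                              config = filter_config(),
                              ids = rownames(alignment)) {
  out <- outlier_filter(alignment, representative_id, config, ids)
  red <- redundancy_filter(alignment, representative_id, config,
                           out$retained_ids)
  new_filter_report(red$retained_ids, rbind(out$removed, red$removed), config)
}
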