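#' Scan configuration
#'
#' Thresholds and permutation settings for column classification.
#'
#' @param conserved_min_freq Minimum whole-alignment consensus frequency
#'   for a `conserved` call (default 0.98: near-invariance rather than
#'   strict invariance, since superfamilies of thousands of sequences carry
#'   occasional database or alignment noise even at truly invariant sites).
#' @param exception_max_families Maximum number of families allowed to
#'   deviate in a `conserved_with_exceptions` call (default 1, the pattern
#'   of an invariant position substituted in a single family).
#' @param fsp_min_within_family_consensus Minimum within-family consensus
#'   frequency for a family to count as conserved at a column (default 0.9).
#' @param fsp_min_distinct_consensi Minimum number of distinct
#'   within-family consensus residues for an FSP call (default 2).
#' @param gap_mask_threshold Columns with gap-plus-ambiguity fraction above
#'   this are masked (default 0.5); family-correlated gaps are indel
#'   signal, not residue-specificity signal.
#' @param n_permutations Number of label permutations B (default 1000;
#'   at least 99 so p-values can resolve q <= 0.05).
#' @param fdr_q Benjamini-Hochberg FDR level for FSP significance
#'   (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A `scan_config` list.
#' @export
scan_config <- function(conserved_min_freq = 0.98,
                        exception_max_families = 1L,
                        fsp_min_within_family_consensus = 0.90,
                        fsp_min_distinct_consensi = 2L,
                        gap_mask_threshold = 0.50,
                        n_permutations = 1000L,
                        fdr_q = 0.05,
                        seed = 1L) {
  stopifnot(conserved_min_freq > 0, conserved_min_freq <= 1,
            fsp_min_within_family_consensus > 0,
            fsp_min_within_family_consensus <= 1,
            gap_mask_threshold > 0, gap_mask_threshold <= 1,
            fdr_q > 0, fdr_q <= 1)
  if (n_permutations < 99L)
    stop("n_permutations must be >= 99 (p-value resolution too coarse)")
  structure(list(conserved_min_freq = conserved_min_freq,
                 exception_max_families = as.integer(exception_max_families),
                 fsp_min_within_family_consensus = fsp_min_within_family_consensus,
                 fsp_min_distinct_consensi = as.integer(fsp_min_distinct_consensi),
                 gap_mask_threshold = gap_mask_threshold,
                 n_permutations = as.integer(n_permutations),
                 fdr_q = fdr_q,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Residue profile of one alignment column
#'
#' Overall and per-family residue counts for a column. Gaps and the
#' ambiguity codes `B`/`Z`/`X` are excluded from the counts but included
#' in `gap_fraction`; `n_effective` is the number of counted observations.
#'
#' @param alignment An [msa].
#' @param annotation A [family_annotation] covering all rows.
#' @param column 1-based column index.
#' @return A `column_profile` list with `column`, `counts` (named integer
#'   vector), `per_family_counts` (named list of named integer vectors,
#'   one per family in annotation order), `gap_fraction` and `n_effective`.
#' @export
column_profile <- function(alignment, annotation, column) {
  m <- unclass(alignment)
  column <- as.integer(column)
  if (column < 1L || column > ncol(m)) stop("column out of range")
  if (!all(rownames(m) %in% names(annotation)))
    stop("annotation does not cover all alignment sequences")
  v <- m[, column]
  fam <- unclass(annotation)[rownames(m)]
  eff <- v %in% AA20
  counts <- table(v[eff])
  counts <- setNames(as.integer(counts), names(counts))
  pfc <- lapply(families(annotation), function(f) {
    tf <- table(v[eff & fam == f])
    setNames(as.integer(tf), names(tf))
  })
  names(pfc) <- families(annotation)
  structure(list(column = column, counts = counts,
                 per_family_counts = pfc,
                 gap_fraction = sum(!eff) / length(v),
                 n_effective = sum(eff)),
            class = "column_profile")
}

#' Whole-alignment conservation of a column
#'
#' Frequency of the most common residue among the column's effective
#' (non-gap, non-ambiguous) observations. Ties are broken alphabetically
#' for the reported consensus.
#'
#' @param profile A [column_profile] with `n_effective >= 1`.
#' @return The conservation fraction, with the consensus residue as the
#'   `"consensus"` attribute.
#' @export
conservation_score <- function(profile) {
  if (profile$n_effective < 1L)
    stop("conservation undefined for an all-gap column (mask it)")
  counts <- profile$counts[order(names(profile$counts))]
  k <- which.max(counts)
  structure(counts[[k]] / profile$n_effective, consensus = names(counts)[k])
}

# entropy (base 2) of a count vector
entropy2 <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Mutual information between residue identity and family label
#'
#' Plug-in (maximum-likelihood) mutual information, in bits, between the
#' residue observed at a column and the family of the sequence carrying
#' it, over the column's effective observations:
#' `MI = H(residue) + H(family) - H(residue, family)`. The normalised
#' variant is `MI / min(H(residue), H(family))`, defined as 0 when either
#' marginal entropy is 0. This is the package's family-specificity
#' statistic.
#'
#' @param profile A [column_profile] with observations in at least two
#'   families.
#' @return A list with `mi` (bits) and `nmi` (in `[0, 1]`).
#' @export
mutual_information <- function(profile) {
  pfc <- profile$per_family_counts[vapply(profile$per_family_counts,
                                          function(x) sum(x) > 0L, logical(1))]
  if (length(pfc) < 2L)
    stop("mutual information requires observations in >= 2 families")
  res_levels <- sort(unique(unlist(lapply(pfc, names))))
  joint <- vapply(pfc, function(x) {
    out <- setNames(integer(length(res_levels)), res_levels)
    out[names(x)] <- x
    out
  }, integer(length(res_levels)))
  joint <- matrix(joint, nrow = length(res_levels))
  h_res <- entropy2(rowSums(joint))
  h_fam <- entropy2(colSums(joint))
  h_joint <- entropy2(as.vector(joint))
  mi <- max(0, h_res + h_fam - h_joint)
  nmi <- if (min(h_res, h_fam) <= 0) 0 else mi / min(h_res, h_fam)
  list(mi = mi, nmi = nmi)
}

# Integer coding of an alignment for the fast permutation loop:
# residue codes 1..20, NA for gaps/ambiguity.
code_alignment <- function(alignment) {
  m <- unclass(alignment)
  codes <- match(m, AA20)
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}

# MI in bits from residue codes (1..20) and family codes (1..nf) at one
# column; h_res may be precomputed (residue marginal is permutation-fixed).
mi_from_codes <- function(res, fam, nf, h_res = entropy2(tabulate(res, 20L))) {
  joint <- tabulate((fam - 1L) * 20L + res, nbins = 20L * nf)
  h_fam <- entropy2(tabulate(fam, nf))
  max(0, h_res + h_fam - entropy2(joint))
}

#' Permutation significance of per-column mutual information
#'
#' Tests each column's residue-family mutual information against the null
#' of no association by permuting family labels across sequences. One
#' permutation is drawn per iteration and applied to all columns, which
#' preserves the joint (inter-column) structure of the null. The p-value
#' is `(1 + #\{b : MI_b >= MI_obs\}) / (B + 1)`; the z-score is
#' `(MI_obs - mean_b) / sd_b` (0 if `sd_b` is 0). Deterministic given the
#' configured seed; the permutation RNG stream is local to the call.
#'
#' @param alignment An [msa].
#' @param annotation A [family_annotation] with >= 2 families.
#' @param config A [scan_config] (uses `n_permutations` and `seed`).
#' @param columns Columns to test (default all).
#' @return A data frame with `column`, `mi` (observed, bits), `p_value`,
#'   `z_score`.
#' @export
permutation_significance <- function(alignment, annotation,
                                     config = scan_config(),
                                     columns = seq_len(ncol(alignment))) {
  if (length(families(annotation)) < 2L) stop("need >= 2 families")
  B <- config$n_permutations
  codes <- code_alignment(alignment)
  fam_all <- match(unclass(annotation)[rownames(codes)], families(annotation))
  nf <- length(families(annotation))
  n <- nrow(codes)
  cols <- as.integer(columns)

  obs_idx <- lapply(cols, function(j) which(!is.na(codes[, j])))
  res <- lapply(seq_along(cols), function(i) codes[obs_idx[[i]], cols[i]])
  h_res <- vapply(res, function(r) entropy2(tabulate(r, 20L)), numeric(1))
  mi_obs <- vapply(seq_along(cols), function(i) {
    if (length(res[[i]]) == 0L) return(NA_real_)
    f <- fam_all[obs_idx[[i]]]
    if (length(unique(f)) < 2L) return(NA_real_)
    mi_from_codes(res[[i]], f, nf, h_res[i])
  }, numeric(1))

  ge_count <- integer(length(cols))
  s1 <- numeric(length(cols))
  s2 <- numeric(length(cols))
  testable <- which(!is.na(mi_obs))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  for (b in seq_len(B)) {
    fam_b <- fam_all[sample.int(n)]
    for (i in testable) {
      mib <- mi_from_codes(res[[i]], fam_b[obs_idx[[i]]], nf, h_res[i])
      if (mib >= mi_obs[i] - 1e-12) ge_count[i] <- ge_count[i] + 1L
      s1[i] <- s1[i] + mib
      s2[i] <- s2[i] + mib * mib
    }
  }
  p <- rep(NA_real_, length(cols))
  z <- rep(NA_real_, length(cols))
  p[testable] <- (1 + ge_count[testable]) / (B + 1)
  mu <- s1 / B
  sdv <- sqrt(pmax(0, s2 / B - mu^2) * B / max(1, B - 1))
  z[testable] <- ifelse(sdv[testable] > 0,
                        (mi_obs[testable] - mu[testable]) / sdv[testable], 0)
  data.frame(column = cols, mi = mi_obs, p_value = p, z_score = z)
}

#' Classify alignment columns
#'
#' The end-point of the position analysis: every column receives exactly
#' one class.
#'
#' * `masked` — gap-plus-ambiguity fraction above `gap_mask_threshold`.
#' * `conserved` — whole-alignment consensus frequency at or above
#'   `conserved_min_freq` (the near-invariant pattern of catalytic-core
#'   residues).
#' * `conserved_with_exceptions` — the whole-alignment consensus is the
#'   within-family consensus (at frequency >= `fsp_min_within_family_consensus`)
#'   in all but at most `exception_max_families` families; the deviating
#'   families are listed.
#' * `fsp` — family-specific position: Benjamini-Hochberg `q_value <=
#'   fdr_q` for the permutation-tested mutual information, at least
#'   `fsp_min_distinct_consensi` distinct within-family consensus residues,
#'   and at least 2 families conserved at the column.
#' * `variable` — everything else.
#'
#' BH q-values are computed across all non-masked columns' permutation
#' p-values.
#'
#' @param alignment An [msa].
#' @param annotation A [family_annotation] with >= 2 families.
#' @param config A [scan_config].
#' @param numberings Optional named list of [ref_numbering] objects (one
#'   per family, the family representative) used to attach
#'   reference-numbered residue labels per family.
#' @return A data frame, one row per column: `column`, `class`,
#'   `consensus`, `conservation`, `mi`, `nmi`, `p_value`, `q_value`,
#'   `z_score`, `exception_families` (comma-separated), `gap_fraction`,
#'   plus one `ref_<family>` label column per entry of `numberings`. The
#'   `scan_config` used is attached as attribute `"config"` and the
#'   statistic name as attribute `"statistic"`.
#' @export
classify_positions <- function(alignment, annotation, config = scan_config(),
                               numberings = NULL) {
  m <- unclass(alignment)
  n_col <- ncol(m)
  fams <- families(annotation)
  if (length(fams) < 2L) stop("need >= 2 families")
  profiles <- lapply(seq_len(n_col), column_profile,
                     alignment = alignment, annotation = annotation)
  gapfrac <- vapply(profiles, `[[`, numeric(1), "gap_fraction")
  masked <- gapfrac > config$gap_mask_threshold |
    vapply(profiles, `[[`, integer(1), "n_effective") == 0L

  perm <- permutation_significance(alignment, annotation, config,
                                   columns = which(!masked))
  p_value <- q_value <- z_score <- mi <- nmi <- rep(NA_real_, n_col)
  p_value[perm$column] <- perm$p_value
  z_score[perm$column] <- perm$z_score
  mi[perm$column] <- perm$mi
  ok <- !masked & !is.na(p_value)
  q_value[ok] <- stats::p.adjust(p_value[ok], method = "BH")

  cls <- character(n_col)
  consensus <- rep(NA_character_, n_col)
  conservation <- rep(NA_real_, n_col)
  exceptions <- rep("", n_col)

  for (j in seq_len(n_col)) {
    pr <- profiles[[j]]
    if (masked[j]) {
      cls[j] <- "masked"
      next
    }
    cons <- conservation_score(pr)
    conservation[j] <- as.numeric(cons)
    consensus[j] <- attr(cons, "consensus")
    if (!is.na(mi[j])) {
      mival <- tryCatch(mutual_information(pr), error = function(e) NULL)
      if (!is.null(mival)) nmi[j] <- mival$nmi
    }
    # within-family consensus residue and frequency
    fam_cons <- rep(NA_character_, length(fams))
    fam_freq <- rep(NA_real_, length(fams))
    for (i in seq_along(fams)) {
      cf <- pr$per_family_counts[[fams[i]]]
      if (length(cf) && sum(cf) > 0L) {
        cf <- cf[order(names(cf))]
        k <- which.max(cf)
        fam_cons[i] <- names(cf)[k]
        fam_freq[i] <- cf[[k]] / sum(cf)
      }
    }
    strong <- !is.na(fam_freq) &
      fam_freq >= config$fsp_min_within_family_consensus
    agreeing <- strong & !is.na(fam_cons) & fam_cons == consensus[j]
    if (conservation[j] >= config$conserved_min_freq) {
      cls[j] <- "conserved"
    } else if (sum(agreeing) >= length(fams) - config$exception_max_families) {
      cls[j] <- "conserved_with_exceptions"
      exceptions[j] <- paste(fams[!agreeing], collapse = ",")
    } else if (!is.na(q_value[j]) && q_value[j] <= config$fdr_q &&
               length(unique(fam_cons[strong])) >= config$fsp_min_distinct_consensi &&
               sum(strong) >= 2L) {
      cls[j] <- "fsp"
    } else {
      cls[j] <- "variable"
    }
  }

  out <- data.frame(column = seq_len(n_col), class = cls,
                    consensus = consensus, conservation = conservation,
                    mi = mi, nmi = nmi, p_value = p_value,
                    q_value = q_value, z_score = z_score,
                    exception_families = exceptions,
                    gap_fraction = gapfrac,
                    stringsAsFactors = FALSE)
  if (!is.null(numberings)) {
    for (f in names(numberings)) {
      out[[paste0("ref_", f)]] <-
        map_column_to_reference(alignment, numberings[[f]], out$column)
    }
  }
  attr(out, "config") <- config
  attr(out, "statistic") <-
    "plug-in residue-family mutual information, label-permutation null, BH FDR"
  out
}
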