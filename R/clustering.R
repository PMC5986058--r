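# Pairwise identity matrix over all rows of an alignment (symmetric).
identity_matrix <- function(alignment) {
  m <- unclass(alignment)
  n <- nrow(m)
  std <- matrix(m %in% AA20, nrow = n)
  D <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    D[i, i] <- 1
    if (i < n) for (j in (i + 1L):n) {
      ok <- std[i, ] & std[j, ]
      v <- if (!any(ok)) 0 else sum(m[i, ok] == m[j, ok]) / sum(ok)
      D[i, j] <- v
      D[j, i] <- v
    }
  }
  D
}

# Per-group, per-column max residue frequency and consensus over effective
# (non-gap, non-ambiguous) observations; cols = non-masked columns only.
group_column_stats <- function(m, members, cols) {
  sub <- m[members, cols, drop = FALSE]
  maxfreq <- rep(NA_real_, length(cols))
  consensus <- rep(NA_character_, length(cols))
  for (j in seq_along(cols)) {
    v <- sub[, j]
    v <- v[v %in% AA20]
    if (length(v)) {
      tab <- table(v)
      # alphabetical tie-break: table() sorts names, which.max takes first
      k <- which.max(tab)
      maxfreq[j] <- tab[[k]] / length(v)
      consensus[j] <- names(tab)[k]
    }
  }
  list(maxfreq = maxfreq, consensus = consensus)
}

# W, B, Q for a given partition (integer vector of group codes).
partition_objective <- function(m, groups, cols) {
  gl <- sort(unique(groups))
  stats <- lapply(gl, function(g)
    group_column_stats(m, which(groups == g), cols))
  W <- mean(unlist(lapply(stats, `[[`, "maxfreq")), na.rm = TRUE)
  if (length(gl) < 2L) {
    B <- 0
  } else {
    cons <- do.call(rbind, lapply(stats, `[[`, "consensus"))
    agree <- rep(NA_real_, length(cols))
    pairs <- utils::combn(length(gl), 2L)
    for (j in seq_along(cols)) {
      cj <- cons[, j]
      eq <- cj[pairs[1L, ]] == cj[pairs[2L, ]]
      agree[j] <- mean(eq, na.rm = TRUE)
    }
    B <- mean(agree, na.rm = TRUE)
    if (is.nan(B)) B <- 0
  }
  c(W = W, B = B, Q = W - B)
}

# Merge groups below min_size into the nearest group by mean distance.
enforce_min_size <- function(groups, dist_mat, min_size) {
  repeat {
    sizes <- table(groups)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) <= 1L) break
    g <- small[order(sizes[small])][1L]
    mem <- which(groups == g)
    others <- setdiff(names(sizes), g)
    dmean <- vapply(others, function(h)
      mean(dist_mat[mem, groups == h, drop = FALSE]), numeric(1))
    groups[mem] <- others[which.min(dmean)]
  }
  groups
}

#' Partition sequences into specificity groups
#'
#' When no family annotation is available, infers specificity groups by
#' average-linkage hierarchical clustering on the distance
#' `1 - pairwise_identity`, scanning a range of group counts `k` and
#' keeping the partition that maximises the objective `Q(k) = W(k) - B(k)`:
#' `W` is within-group conservation (the mean, over groups and non-masked
#' columns, of the most frequent residue's within-group frequency) and `B`
#' is between-group similarity (the mean, over non-masked columns, of the
#' fraction of group pairs whose group-consensus residues agree). Maximal
#' `Q` thus rewards groups that are internally conserved yet mutually
#' divergent. Ties are broken towards smaller `k`; groups smaller than
#' `min_group_size` are merged into their nearest group (smallest mean
#' distance) before scoring. Deterministic given the input order.
#'
#' Columns whose gap-plus-ambiguity fraction exceeds `gap_mask_threshold`
#' are ignored by the objective.
#'
#' @param alignment An [msa] with at least 2 sequences.
#' @param k_range Integer vector of candidate group counts (subset of
#'   `1..n_sequences`; `k = 1` is only sensible for degenerate inputs).
#' @param min_group_size Minimum group size before scoring (default 2:
#'   singleton families cannot exhibit conservation).
#' @param gap_mask_threshold Columns gappier than this are excluded from
#'   the objective (default 0.5).
#' @return A `clustering_result` list: `annotation` (a
#'   [family_annotation], groups labelled `"G1"`, `"G2"`, ... in order of
#'   first appearance), `k`, `objective_value`, and `objective_trace` (a
#'   data frame of `k`, `W`, `B`, `Q` over the scanned range).
#' @export
cluster_specificity_groups <- function(alignment, k_range,
                                       min_group_size = 2L,
                                       gap_mask_threshold = 0.5) {
  m <- unclass(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L | k_range > n)) stop("k_range outside [1, n_sequences]")
  gapfrac <- colMeans(matrix(!(m %in% AA20), nrow = n))
  cols <- which(gapfrac <= gap_mask_threshold)
  if (!length(cols)) stop("all columns masked")
  S <- identity_matrix(alignment)
  if (max(1 - S[upper.tri(S)]) == 0 && !(1L %in% k_range))
    stop("no separable structure: all sequences identical")
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  trace <- data.frame(k = integer(), W = double(), B = double(), Q = double())
  best <- NULL
  for (k in k_range) {
    groups <- stats::cutree(hc, k = k)
    groups <- enforce_min_size(groups, 1 - S, min_group_size)
    obj <- partition_objective(m, groups, cols)
    trace <- rbind(trace, data.frame(k = k, W = obj[["W"]],
                                     B = obj[["B"]], Q = obj[["Q"]]))
    if (is.null(best) || obj[["Q"]] > best$Q + 1e-12) {
      best <- list(k = k, groups = groups, Q = obj[["Q"]])
    }
  }
  labels <- paste0("G", match(best$groups, unique(best$groups)))
  ann <- family_annotation(rownames(m), labels)
  structure(list(annotation = ann, k = best$k,
                 objective_value = best$Q, objective_trace = trace),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("Specificity clustering: k = ", x$k, ", Q = ",
      format(x$objective_value, digits = 4), "\n", sep = "")
  print(x$objective_trace, row.names = FALSE)
  invisible(x)
}
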