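# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force mutual information (bits) by the double summation
# sum_{a,f} p(a,f) log2( p(a,f) / (p(a) p(f)) ) over a joint count matrix
# (rows = residues, cols = families).
brute_force_mi <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  pa <- rowSums(p)
  pf <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log2(p[i, j] / (pa[i] * pf[j]))
  }
  unname(mi)
}

# Residue-index correspondences induced between two rows of an alignment:
# the set of (i-th residue of a, j-th residue of b) pairs that share a
# column. Returned as a character vector "i:j" for set comparison.
induced_correspondences <- function(row_a, row_b) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  paste0(ia[both], ":", ib[both])
}

# All within-family correspondence sets of an alignment, keyed by id pair.
all_pair_correspondences <- function(strings) {
  ids <- names(strings)
  out <- list()
  if (length(ids) < 2) return(out)
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    key <- paste(ids[i], ids[j], sep = "|")
    out[[key]] <- induced_correspondences(strings[[ids[i]]],
                                          strings[[ids[j]]])
  }
  out
}

# A family-structured alignment for clustering tests: a share of globally
# conserved columns plus family-diagnostic columns, tuned to give roughly
# 0.85 within-family and 0.25 between-family identity.
make_clusterable_alignment <- function(n_families = 3, seqs_per_family = 12,
                                       n_columns = 120,
                                       frac_conserved = 0.25,
                                       conserved_dev = 0.05,
                                       fsp_dev = 0.078, seed = 1) {
  n_cons <- round(frac_conserved * n_columns)
  cfg <- fspscan::synth_config(
    n_families, seqs_per_family, n_columns,
    conserved = data.frame(
      column = seq_len(n_cons),
      residue = rep(c("A", "D", "K", "G", "R"), length.out = n_cons),
      deviation_rate = conserved_dev),
    fsp = lapply((n_cons + 1):n_columns, function(j) {
      set.seed(seed * 100003L + j)
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      list(column = j,
           residues = stats::setNames(sample(aa, n_families),
                                      paste0("F", seq_len(n_families))),
           deviation_rate = fsp_dev)
    }),
    seed = seed)
  fspscan::generate_alignment(cfg)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
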