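two_family_alignment <- function(cols) {
  # cols: list of per-sequence residue vectors, one entry per column
  n <- length(cols[[1]])
  seqs <- vapply(seq_len(n), function(i)
    paste(vapply(cols, `[`, character(1), i), collapse = ""), character(1))
  msa(paste0("s", seq_len(n)), seqs)
}

test_that("column profiles count residues per family, excluding gaps and ambiguity", {
  aln <- two_family_alignment(list(c("K", "K", "K", "K"),
                                   c("H", "H", "F", "F"),
                                   c("K", "-", "X", "K")))
  ann <- family_annotation(paste0("s", 1:4), c("A", "A", "B", "B"))
  p1 <- column_profile(aln, ann, 1)
  expect_equal(p1$counts, c(K = 4L))
  expect_equal(p1$gap_fraction, 0)
  p2 <- column_profile(aln, ann, 2)
  expect_equal(p2$per_family_counts, list(A = c(H = 2L), B = c(F = 2L)))
  p3 <- column_profile(aln, ann, 3)
  expect_equal(p3$counts, c(K = 2L))
  expect_equal(p3$gap_fraction, 0.5)
  expect_equal(p3$n_effective, 2L)
  expect_error(column_profile(aln, ann, 9), "out of range")
})

test_that("conservation score is the top residue frequency, ties alphabetical", {
  aln <- two_family_alignment(list(c("K", "K", "K", "K"),
                                   c("H", "H", "F", "F")))
  ann <- family_annotation(paste0("s", 1:4), c("A", "A", "B", "B"))
  s1 <- conservation_score(column_profile(aln, ann, 1))
  expect_equal(as.numeric(s1), 1.0)
  s2 <- conservation_score(column_profile(aln, ann, 2))
  expect_equal(as.numeric(s2), 0.5)
  expect_equal(attr(s2, "consensus"), "F")  # alphabetical tie-break
  # the near-invariant pattern: 14 of 15 -> 0.933...
  aln3 <- msa(paste0("s", 1:15),
              c(rep("R", 14), "V"))
  ann3 <- family_annotation(paste0("s", 1:15),
                            rep(c("A", "B", "C"), each = 5))
  expect_equal(as.numeric(conservation_score(column_profile(aln3, ann3, 1))),
               14 / 15)
})

test_that("mutual information matches analytic values and the brute-force oracle", {
  aln <- two_family_alignment(list(c("K", "K", "K", "K"),
                                   c("H", "H", "F", "F")))
  ann <- family_annotation(paste0("s", 1:4), c("A", "A", "B", "B"))
  inv <- mutual_information(column_profile(aln, ann, 1))
  expect_equal(inv$mi, 0)
  expect_equal(inv$nmi, 0)
  diag <- mutual_information(column_profile(aln, ann, 2))
  expect_equal(diag$mi, 1.0)   # equal groups, disjoint residues
  expect_equal(diag$nmi, 1.0)

  # H:8/Y:2 vs F:9/L:1 against the independent double summation
  aln2 <- msa(paste0("s", 1:20),
              c(rep("H", 8), rep("Y", 2), rep("F", 9), "L"))
  ann2 <- family_annotation(paste0("s", 1:20), rep(c("A", "B"), each = 10))
  mi <- mutual_information(column_profile(aln2, ann2, 1))$mi
  joint <- cbind(A = c(H = 8, Y = 2, F = 0, L = 0),
                 B = c(H = 0, Y = 0, F = 9, L = 1))
  expect_equal(mi, brute_force_mi(joint), tolerance = 1e-12)

  expect_error(mutual_information(
    column_profile(aln, family_annotation(paste0("s", 1:4), rep("A", 4)), 1)),
    ">= 2 families")
})

test_that("MI is bounded by both marginal entropies on random profiles", {
  set.seed(21)
  aa <- strsplit("ACDEFG", "")[[1]]
  for (rep in 1:50) {
    nf <- sample(2:4, 1)
    per_fam <- sample(3:8, 1)
    res <- sample(aa, nf * per_fam, replace = TRUE)
    aln <- msa(paste0("s", seq_along(res)), res)
    ann <- family_annotation(paste0("s", seq_along(res)),
                             rep(paste0("F", 1:nf), each = per_fam))
    pr <- column_profile(aln, ann, 1)
    v <- mutual_information(pr)
    h_res <- -sum((pr$counts / sum(pr$counts)) *
                    log2(pr$counts / sum(pr$counts)))
    fam_tot <- vapply(pr$per_family_counts, sum, integer(1))
    pf <- fam_tot[fam_tot > 0] / sum(fam_tot)
    h_fam <- -sum(pf * log2(pf))
    expect_gte(v$mi, -1e-12)
    expect_lte(v$mi, min(h_res, h_fam) + 1e-9)
  }
})

test_that("permutation test: diagnostic column at the floor, invariant at 1", {
  # 10 vs 10, disjoint residues, B = 999 -> p = 1/1000
  aln <- msa(paste0("s", 1:20),
             paste0(c(rep("H", 10), rep("F", 10)),
                    "K"))  # col 1 diagnostic, col 2 invariant
  ann <- family_annotation(paste0("s", 1:20), rep(c("A", "B"), each = 10))
  res <- permutation_significance(aln, ann,
                                  scan_config(n_permutations = 999, seed = 5))
  expect_equal(res$p_value[1], 1 / 1000)
  expect_equal(res$p_value[2], 1.0)
  expect_equal(res$mi[2], 0)
  expect_equal(res$z_score[2], 0)
  expect_error(permutation_significance(aln, ann,
                                        scan_config(n_permutations = 50)),
               "99")
})

test_that("permutation p-values are calibrated under a uniform null", {
  cfg <- synth_config(2, 25, 120, seed = 31)
  sim <- generate_alignment(cfg)
  res <- permutation_significance(sim$alignment, sim$annotation,
                                  scan_config(n_permutations = 199, seed = 8))
  frac <- mean(res$p_value < 0.05)
  # P(p < 0.05) = 9/200 at this resolution; 3 binomial SDs over 120 columns
  expect_lt(abs(frac - 9 / 200), 3 * sqrt(0.045 * 0.955 / 120))
  expect_identical(res,
                   permutation_significance(sim$alignment, sim$annotation,
                                            scan_config(n_permutations = 199,
                                                        seed = 8)))
})

test_that("classification reproduces the canonical column patterns", {
  # 15 families; col 1 invariant K; col 2 consensus R with one V family;
  # col 3 family-specific among first three families.
  nf <- 15; ns <- 4
  fam <- rep(paste0("F", 1:nf), each = ns)
  ids <- paste0(fam, "_", rep(1:ns, nf))
  col1 <- rep("K", nf * ns)
  col2 <- ifelse(fam == "F7", "V", "R")
  fsp_map <- setNames(rep(c("H", "A", "S"), length.out = nf), paste0("F", 1:nf))
  col3 <- fsp_map[fam]
  aln <- msa(ids, paste0(col1, col2, col3))
  ann <- family_annotation(ids, fam)
  cl <- classify_positions(aln, ann,
                           scan_config(n_permutations = 199, seed = 2))
  expect_equal(cl$class[1], "conserved")
  expect_equal(cl$class[2], "conserved_with_exceptions")
  expect_equal(cl$exception_families[2], "F7")
  expect_equal(cl$class[3], "fsp")
  expect_true(all(cl$q_value >= cl$p_value - 1e-12, na.rm = TRUE))
})

test_that("masking, BH monotonicity and the class partition hold", {
  cfg <- sample_synth_config(3, 15, 60, n_conserved = 2, n_fsp = 2,
                             gap_rate = 0.05, seed = 17)
  sim <- generate_alignment(cfg)
  # force one heavily gapped column
  m <- unclass(sim$alignment)
  m[1:40, 5] <- "-"
  aln <- msa(rownames(m), apply(m, 1, paste, collapse = ""))
  cl <- classify_positions(aln, sim$annotation,
                           scan_config(n_permutations = 199, seed = 3))
  expect_equal(cl$class[5], "masked")
  expect_true(all(cl$class %in% c("conserved", "conserved_with_exceptions",
                                  "fsp", "variable", "masked")))
  expect_identical(cl$class == "masked",
                   cl$gap_fraction > 0.5 | is.na(cl$conservation))
  ok <- !is.na(cl$p_value)
  ord <- order(cl$p_value[ok])
  expect_true(all(diff(cl$q_value[ok][ord]) >= -1e-12))
  expect_true(all(cl$p_value[ok] >= 1 / 200))
})
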