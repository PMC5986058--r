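report_fixture <- function() {
  nf <- 3; ns <- 5
  fam <- rep(paste0("F", 1:nf), each = ns)
  ids <- paste0(fam, "_", rep(1:ns, nf))
  # col1 conserved D; col2 family-specific; col3 background-ish; the F3
  # representative is gapped at the FSP column
  col1 <- rep("D", nf * ns)
  col2 <- setNames(c("H", "A", "S"), paste0("F", 1:nf))[fam]
  col2[ids == "F3_1"] <- "-"
  set.seed(44)
  col3 <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], nf * ns,
                 replace = TRUE)
  aln <- msa(ids, paste0(col1, col2, col3))
  ann <- family_annotation(ids, fam)
  numberings <- list(F1 = ref_numbering("F1_1", 10),
                     F2 = ref_numbering("F2_1", 100),
                     F3 = ref_numbering("F3_1", 7))
  list(aln = aln, ann = ann, numberings = numberings)
}

test_that("family table reports reference-numbered residues, N/A at gaps", {
  fx <- report_fixture()
  cl <- classify_positions(fx$aln, fx$ann,
                           scan_config(n_permutations = 199, seed = 6),
                           numberings = fx$numberings)
  expect_equal(cl$class[1], "conserved")
  expect_equal(cl$class[2], "fsp")
  tab <- build_family_table(cl, fx$aln, fx$ann, fx$numberings)
  expect_equal(tab$family, c("F1", "F2", "F3"))
  # conserved column first: planted D at reference residue 10/100/7
  expect_equal(tab$c1, c("D10", "D100", "D7"))
  # representative of F3 is gapped at the FSP column
  expect_equal(tab$c2, c("H11", "A101", "N/A"))
  expect_equal(unname(attr(tab, "position_class")),
               c("conserved", "fsp"))
  expect_error(build_family_table(cl, fx$aln, fx$ann,
                                  fx$numberings[c("F1", "F2")]),
               "F3")
})

test_that("a classification with no FSPs yields a conserved-only table", {
  nf <- 2; ns <- 4
  fam <- rep(c("F1", "F2"), each = ns)
  ids <- paste0(fam, "_", rep(1:ns, nf))
  aln <- msa(ids, rep("KD", nf * ns))
  ann <- family_annotation(ids, fam)
  numberings <- list(F1 = ref_numbering("F1_1"), F2 = ref_numbering("F2_1"))
  cl <- classify_positions(aln, ann, scan_config(n_permutations = 199,
                                                 seed = 1),
                           numberings = numberings)
  tab <- build_family_table(cl, aln, ann, numberings)
  expect_equal(unname(attr(tab, "position_class")),
               rep("conserved", 2))
})

test_that("run_scan orchestrates stages, fails fast, and is byte-deterministic", {
  expect_error(run_scan(), "alignment or a merge fixture")
  expect_error(run_scan(alignment = msa("a", "MK"), filter = filter_config()),
               "family annotation")

  cfg <- sample_synth_config(3, 12, 60, n_conserved = 2, n_fsp = 2,
                             n_exception = 1, gap_rate = 0.02, seed = 23)
  sim <- generate_alignment(cfg)
  numberings <- setNames(lapply(families(sim$annotation), function(f)
    ref_numbering(paste0(f, "_s001"))), families(sim$annotation))
  sc <- scan_config(n_permutations = 299, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- run_scan(sim$alignment, sim$annotation, sc, numberings,
                 out_dir = d1)
  b2 <- run_scan(sim$alignment, sim$annotation, sc, numberings,
                 out_dir = d2)
  for (f in c("positions.tsv", "families.tsv", "family_table.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(all(attr(b1$family_table, "position_class") %in%
                    c("conserved", "conserved_with_exceptions", "fsp")))
  expect_equal(b1$provenance$statistic, attr(b1$classifications, "statistic"))

  # clustering stage engages when no annotation is supplied
  sim2 <- make_clusterable_alignment(n_families = 2, seqs_per_family = 8,
                                     n_columns = 80, seed = 2)
  b3 <- run_scan(sim2$alignment, annotation = NULL,
                 config = scan_config(n_permutations = 199, seed = 4),
                 cluster_k_range = 2:4)
  expect_equal(length(families(b3$annotation)), 2L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(unclass(b3$annotation),
                                         unclass(sim2$annotation)), 1.0)
})

test_that("the filter stage cleans families before scanning", {
  ids <- c("F1_rep", "F1_dup", "F1_ok", "F2_rep", "F2_alien")
  seqs <- c("MKADLMKADL", "MKADLMKADL", "MKVDLMKVDL",
            "MRTDLMRTDL", "WWWWWWWWWW")
  aln <- msa(ids, seqs)
  ann <- family_annotation(ids, c("F1", "F1", "F1", "F2", "F2"))
  b <- run_scan(aln, ann, scan_config(n_permutations = 199, seed = 5),
                filter = filter_config(),
                representatives = c(F1 = "F1_rep", F2 = "F2_rep"))
  expect_equal(rownames(b$alignment), c("F1_rep", "F1_ok", "F2_rep"))
  expect_equal(b$filter_reports$F1$removed$id, "F1_dup")
  expect_match(b$filter_reports$F2$removed$reason, "low_bits_per_column")
})
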