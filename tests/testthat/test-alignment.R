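test_that("aligned FASTA round-trips and is validated on read", {
  path <- write_lines_tmp(c(">s1 some description", "MK-A", ">s2", "mkya"),
                          ".fasta")
  aln <- read_alignment(path)
  expect_s3_class(aln, "msa")
  expect_equal(rownames(aln), c("s1", "s2"))
  expect_equal(n_columns(aln), 4L)
  expect_equal(unname(msa_strings(aln)), c("MK-A", "MKYA"))  # upper-cased

  out <- tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(msa_strings(read_alignment(out)), msa_strings(aln))

  ragged <- write_lines_tmp(c(">s1", "MKA", ">s2", "MKYA"), ".fasta")
  expect_error(read_alignment(ragged), "ragged alignment at s1")
  empty <- write_lines_tmp(character(), ".fasta")
  expect_error(read_alignment(empty), "no records")
  dup <- write_lines_tmp(c(">s1", "MKA", ">s1", "MKA"), ".fasta")
  expect_error(read_alignment(dup), "duplicate")
})

test_that("msa constructor enforces the alphabet and normalises gaps", {
  expect_error(msa("s1", "MKO1"), "illegal characters")
  aln <- msa(c("a", "b"), c("mk.a", "MKXA"))
  expect_equal(unname(msa_strings(aln)), c("MK-A", "MKXA"))
})

test_that("family annotation TSV is strict by default and ordered by appearance", {
  aln <- msa(c("s1", "s2", "s3", "s4"),
             c("MKAA", "MKAV", "MRAA", "MRAV"))
  path <- write_lines_tmp(c("s1\tfamA", "s2\tfamB", "s3\tfamA", "s4\tfamB"),
                          ".tsv")
  ann <- read_family_annotation(path, aln)
  expect_equal(families(ann), c("famA", "famB"))
  expect_equal(unname(unclass(ann)[c("s1", "s4")]), c("famA", "famB"))

  dup <- write_lines_tmp(c("s1\tfamA", "s1\tfamB", "s2\tfamB",
                           "s3\tfamA", "s4\tfamB"), ".tsv")
  expect_error(read_family_annotation(dup, aln), "duplicate annotation")

  partial <- write_lines_tmp(c("s1\tfamA", "s2\tfamB", "s3\tfamA"), ".tsv")
  expect_error(read_family_annotation(partial, aln), "s4")
  lenient <- read_family_annotation(partial, aln, strict = FALSE)
  expect_equal(unname(unclass(lenient)["s4"]), "unassigned")

  unknown <- write_lines_tmp(c("s1\tfamA", "s2\tfamB", "s3\tfamA",
                               "s4\tfamB", "s9\tfamA"), ".tsv")
  expect_error(read_family_annotation(unknown, aln), "s9")
})

test_that("pairwise identity counts matches over mutually ungapped columns", {
  expect_equal(pairwise_identity("MKAA", "MKAA"), 1.0)
  # gap column dropped from the denominator: 3/3
  expect_equal(pairwise_identity("MKAA", "MKA-"), 1.0)
  expect_equal(pairwise_identity("MKAA", "MRAV"), 0.5)
  # ambiguity codes are missing data on either side
  expect_equal(pairwise_identity("MKXA", "MKAA"), 1.0)
  expect_equal(pairwise_identity("----", "MKAA"), 0)
  expect_error(pairwise_identity("MKA", "MKAA"), "unequal")
})

test_that("pairwise identity is symmetric and 1 iff shared columns agree", {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_equal(pairwise_identity("MK-A", "MKY-"), 1.0)  # shared cols agree
})

test_that("bits per column averages BLOSUM62 half-bits over shared columns", {
  expect_equal(bits_per_column("AAAA", "AAAA"), 2.0)  # A:A = 4 half-bits
  expect_equal(bits_per_column("AAAA", "AA--"), 2.0)  # reduced denominator
  expect_identical(bits_per_column("AA--", "--AA"), -Inf)
  # symmetric for a symmetric matrix
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
  b <- paste(sample(aa, 40, replace = TRUE), collapse = "")
  expect_equal(bits_per_column(a, b), bits_per_column(b, a))
})

test_that("reference numbering maps columns to residue labels, N/A at gaps", {
  aln <- msa(c("r", "s"), c("M-KT", "MAKT"))
  num <- ref_numbering("r", 1)
  expect_equal(map_column_to_reference(aln, num, 3), "K2")
  expect_equal(map_column_to_reference(aln, num, 2), "N/A")
  aln2 <- msa(c("r", "s"), c("MKT", "MKT"))
  expect_equal(map_column_to_reference(aln2, ref_numbering("r", 197), 1),
               "M197")
  expect_error(map_column_to_reference(aln, num, 5), "out of range")
  expect_error(map_column_to_reference(aln, ref_numbering("zz"), 1),
               "not in alignment")
})

test_that("mapping every column enumerates reference residues exactly once", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
  for (rep in 1:10) {
    row <- sample(aa, 40, replace = TRUE)
    if (!any(row != "-")) row[1] <- "M"
    aln <- msa(c("r", "pad"),
               c(paste(row, collapse = ""),
                 paste(rep("A", 40), collapse = "")))
    start <- sample(1:300, 1)
    labs <- map_column_to_reference(aln, ref_numbering("r", start), 1:40)
    got <- labs[labs != "N/A"]
    nums <- as.integer(sub("^[A-Z]", "", got))
    expect_equal(nums, seq(start, start + sum(row != "-") - 1L))
    expect_false(anyDuplicated(got) > 0)
  }
})
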