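#' Construct a multiple alignment object
#'
#' A multiple alignment is a rectangular set of aligned residue strings over
#' the alphabet of the 20 standard amino acids, the gap character `-` and
#' the ambiguity codes `B`/`Z`/`X`. Internally it is stored as a character
#' matrix (one row per sequence, one column per alignment column) with the
#' sequence identifiers as row names.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths),
#'   parallel to `ids`. Lower case is accepted and upper-cased; `.` is
#'   accepted as a gap alias and normalised to `-`.
#' @return An object of class `msa`: a character matrix with row names.
#' @examples
#' aln <- msa(c("s1", "s2"), c("MK-A", "MKYA"))
#' n_columns(aln)
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) < 1L) stop("no records")
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    # name the row deviating from the modal length (ties: longer wins,
    # since a single truncated record is the common corruption)
    tab <- table(lens)
    modal <- as.integer(names(tab)[order(-tab, -as.integer(names(tab)))][1L])
    bad <- ids[lens != modal][1L]
    stop("ragged alignment at ", bad)
  }
  if (lens[1L] < 1L) stop("alignment has zero columns")
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, NULL))
  illegal <- setdiff(unique(as.vector(m)), ALPHABET)
  if (length(illegal))
    stop("illegal characters in alignment: ", paste(illegal, collapse = ", "))
  structure(m, class = c("msa", "matrix", "array"))
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple alignment: ", nrow(x), " sequences x ", ncol(x),
      " columns\n", sep = "")
  show_n <- min(6L, nrow(x))
  s <- msa_strings(x)[seq_len(show_n)]
  s <- ifelse(nchar(s) > 60, paste0(substr(s, 1, 57), "..."), s)
  for (i in seq_len(show_n))
    cat(format(rownames(x)[i], width = 15), s[i], "\n")
  if (nrow(x) > show_n) cat("  ... ", nrow(x) - show_n, " more\n", sep = "")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln An `msa` object.
#' @return Integer column count.
#' @export
n_columns <- function(aln) ncol(aln)

#' Aligned sequences as strings
#' @param aln An `msa` object.
#' @return Named character vector of aligned rows.
#' @export
msa_strings <- function(aln) {
  setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file and validates it as a rectangular
#' alignment. Record order is preserved. Sequence descriptions after the
#' first whitespace are dropped from the identifiers.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [msa] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  msa(ids, as.character(ss))
}

#' Write an alignment to aligned FASTA
#' @param aln An [msa] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(msa_strings(aln))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a family annotation
#'
#' Maps every sequence identifier to exactly one family (specificity-group)
#' label. Family order is the order of first appearance.
#'
#' @param ids Character vector of sequence identifiers.
#' @param labels Character vector of family labels, parallel to `ids`.
#' @return An object of class `family_annotation`: a named character vector
#'   (`names` = sequence ids) with a `families` attribute listing distinct
#'   labels in order of first appearance.
#' @export
family_annotation <- function(ids, labels) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) != length(labels)) stop("ids and labels lengths differ")
  if (anyDuplicated(ids))
    stop("duplicate annotation for: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- setNames(labels, ids)
  attr(out, "families") <- unique(labels)
  class(out) <- "family_annotation"
  out
}

#' @export
print.family_annotation <- function(x, ...) {
  fam <- attr(x, "families")
  cat("Family annotation: ", length(x), " sequences in ", length(fam),
      " families\n", sep = "")
  print(table(factor(unclass(x), levels = fam)))
  invisible(x)
}

#' Families of an annotation
#' @param annotation A [family_annotation] object.
#' @return Character vector of family labels in order of first appearance.
#' @export
families <- function(annotation) attr(annotation, "families")

#' Read a family annotation TSV
#'
#' Reads a two-column tab-separated file (`seq_id<TAB>family`, no header)
#' and checks it against an alignment. In strict mode (the default) every
#' alignment sequence must be annotated; in lenient mode missing sequences
#' are assigned to a family `"unassigned"`.
#'
#' @param path Path to the TSV file.
#' @param alignment The [msa] the annotation refers to.
#' @param strict If `TRUE` (default), error when an alignment id is missing
#'   from the file.
#' @return A [family_annotation] covering all alignment ids, in alignment
#'   row order.
#' @export
read_family_annotation <- function(path, alignment, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("annotation file must have two tab-separated columns")
  ids <- df[[1L]]
  labels <- df[[2L]]
  if (anyDuplicated(ids))
    stop("duplicate annotation for: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(ids, rownames(alignment))
  if (length(unknown))
    stop("annotated ids absent from alignment: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(rownames(alignment), ids)
  if (length(missing)) {
    if (strict)
      stop("alignment ids missing from annotation: ",
           paste(missing, collapse = ", "))
    ids <- c(ids, missing)
    labels <- c(labels, rep("unassigned", length(missing)))
  }
  ord <- match(rownames(alignment), ids)
  family_annotation(ids[ord], labels[ord])
}

#' Write a family annotation TSV
#' @param annotation A [family_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_annotation <- function(annotation, path) {
  utils::write.table(data.frame(id = names(annotation),
                                family = unclass(annotation)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Residue characters split into a vector if given as a single string.
as_residue_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1L]]
  else toupper(as.character(x))
}

#' Pairwise sequence identity on an induced alignment
#'
#' Identity between two rows of the same alignment: the fraction of
#' matching positions among columns where both rows carry a standard
#' residue. Gaps and the ambiguity codes `B`/`Z`/`X` are treated as missing
#' and excluded from both numerator and denominator. Returns 0 when the two
#' rows share no scorable column.
#'
#' @param row_a,row_b Aligned residue strings (or character vectors) of
#'   equal length.
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("MKAA", "MRAV")  # 2 matches / 4 shared columns = 0.5
#' @export
pairwise_identity <- function(row_a, row_b) {
  a <- as_residue_vector(row_a)
  b <- as_residue_vector(row_b)
  if (length(a) != length(b)) stop("rows have unequal lengths")
  ok <- a %in% AA20 & b %in% AA20
  if (!any(ok)) return(0)
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Average substitution score per aligned column, in bits
#'
#' Mean substitution-matrix score over columns where both rows are non-gap,
#' converted from half-bit matrix units to bits (score / 2). Used as the
#' outlier-filter criterion against a family representative. With no shared
#' non-gap column the score is undefined and `-Inf` is returned, which
#' fails any positive threshold.
#'
#' @param row_a,row_b Aligned residue strings of equal length.
#' @param matrix Substitution matrix in half-bit units with residues as
#'   dimnames (default the BLOSUM62 matrix shipped with Biostrings).
#' @return Mean score in bits, or `-Inf` if no column is scorable.
#' @examples
#' bits_per_column("AAAA", "AA--")  # BLOSUM62 A:A = 4 half-bits -> 2 bits
#' @export
bits_per_column <- function(row_a, row_b, matrix = blosum_matrix("BLOSUM62")) {
  a <- as_residue_vector(row_a)
  b <- as_residue_vector(row_b)
  if (length(a) != length(b)) stop("rows have unequal lengths")
  ok <- a != GAP & b != GAP
  if (!any(ok)) return(-Inf)
  a <- a[ok]
  b <- b[ok]
  absent <- unique(c(setdiff(a, rownames(matrix)), setdiff(b, colnames(matrix))))
  if (length(absent))
    stop("residues absent from substitution matrix: ",
         paste(absent, collapse = ", "))
  mean(matrix[cbind(a, b)]) / 2
}

#' Reference residue numbering
#'
#' Ties alignment columns to the residue numbers of a chosen reference
#' sequence (typically the family representative with a solved structure),
#' so that reported positions read like `"K199"`. `start_number` is the
#' residue number of the reference row's first non-gap character.
#'
#' @param seq_id Identifier of the reference sequence.
#' @param start_number Integer residue number of its first residue
#'   (default 1; set to the construct's true numbering to match PDB
#'   numbering).
#' @return An object of class `ref_numbering`.
#' @export
ref_numbering <- function(seq_id, start_number = 1L) {
  structure(list(seq_id = as.character(seq_id),
                 start_number = as.integer(start_number)),
            class = "ref_numbering")
}

#' Map an alignment column to a reference residue label
#'
#' Returns the one-letter residue of the reference row at the column,
#' suffixed with its residue number (count of non-gap characters up to and
#' including the column, offset by `start_number - 1`), e.g. `"K199"`. A
#' gap in the reference row at that column yields `"N/A"`.
#'
#' @param alignment An [msa] containing the reference sequence.
#' @param numbering A [ref_numbering].
#' @param column 1-based column index (may be a vector).
#' @return Character vector of residue labels or `"N/A"`.
#' @examples
#' aln <- msa(c("r", "s"), c("M-KT", "MAKT"))
#' map_column_to_reference(aln, ref_numbering("r"), 1:4)
#' @export
map_column_to_reference <- function(alignment, numbering, column) {
  if (!numbering$seq_id %in% rownames(alignment))
    stop("reference sequence not in alignment: ", numbering$seq_id)
  column <- as.integer(column)
  if (any(column < 1L | column > ncol(alignment)))
    stop("column out of range")
  row <- unclass(alignment)[numbering$seq_id, ]
  nongap <- row != GAP
  resnum <- cumsum(nongap) + numbering$start_number - 1L
  ifelse(nongap[column],
         paste0(row[column], resnum[column]),
         "N/A")
}
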