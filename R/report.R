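#' Family-by-position report table
#'
#' Renders the classification into a family x position table in the style
#' of a superfamily summary: one row per family, one column per reported
#' position — conserved-type positions (classes `conserved` and
#' `conserved_with_exceptions`, in column order) first, then FSPs ordered
#' by descending permutation z-score. Cells hold the reference-numbered
#' residue label of the family representative at that column (e.g.
#' `"K199"`), or `"N/A"` where the representative is gapped.
#'
#' @param classifications Output of [classify_positions()].
#' @param alignment The classified [msa].
#' @param annotation Its [family_annotation].
#' @param numberings Named list (family label -> [ref_numbering] of that
#'   family's representative); one entry per family.
#' @return A data frame with `family` and `representative` columns followed
#'   by one column per reported position, named `c<column>` with the
#'   alignment column index; attribute `"position_class"` gives each
#'   reported position's class.
#' @export
build_family_table <- function(classifications, alignment, annotation,
                               numberings) {
  fams <- families(annotation)
  missing <- setdiff(fams, names(numberings))
  if (length(missing))
    stop("no representative numbering for family: ",
         paste(missing, collapse = ", "))
  cons <- classifications[classifications$class %in%
                            c("conserved", "conserved_with_exceptions"), ,
                          drop = FALSE]
  cons <- cons[order(cons$column), , drop = FALSE]
  fsp <- classifications[classifications$class == "fsp", , drop = FALSE]
  fsp <- fsp[order(-fsp$z_score, fsp$column), , drop = FALSE]
  sel <- rbind(cons, fsp)
  out <- data.frame(family = fams,
                    representative = vapply(fams, function(f)
                      numberings[[f]]$seq_id, character(1)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sel))) {
    j <- sel$column[i]
    out[[paste0("c", j)]] <- vapply(fams, function(f)
      map_column_to_reference(alignment, numberings[[f]], j), character(1))
  }
  attr(out, "position_class") <- setNames(sel$class, paste0("c", sel$column))
  rownames(out) <- NULL
  out
}

#' Run the full position-analysis pipeline
#'
#' Orchestrates the analysis over a prepared superfamily alignment:
#' optional per-family set cleaning, optional merge of family
#' sub-alignments over a core guide, specificity-group clustering when no
#' annotation is supplied, column classification, and reporting. Inputs
#' are validated before any computation starts. Fully deterministic given
#' the configuration (including its seed).
#'
#' @param alignment An [msa] (the superfamily alignment), or `NULL` when
#'   `merge` is supplied.
#' @param annotation A [family_annotation], or `NULL` to infer specificity
#'   groups by [cluster_specificity_groups()].
#' @param config A [scan_config].
#' @param numberings Optional named list of [ref_numbering] per family;
#'   required for the family table.
#' @param merge Optional [merge_fixture]; when given, the superfamily
#'   alignment and annotation are produced by [merge_by_core()] first.
#' @param filter Optional [filter_config]; when given together with an
#'   annotation and `representatives` (named character vector, family ->
#'   representative id), each family's rows are cleaned with
#'   [filter_family_set()] before scanning.
#' @param representatives Named character vector used by the filter stage.
#' @param cluster_k_range Candidate group counts for the clustering stage
#'   (default `2:10`), used only when `annotation` is `NULL`.
#' @param out_dir Optional directory; when given, `positions.tsv`,
#'   `families.tsv` and (if `numberings` is supplied) `family_table.tsv`
#'   are written there.
#' @return A `scan_result_bundle` list: `classifications`, `family_table`
#'   (or `NULL`), `alignment`, `annotation`, `filter_reports` (or `NULL`),
#'   and `provenance` (config echo, statistic name, package version).
#' @export
run_scan <- function(alignment = NULL, annotation = NULL,
                     config = scan_config(), numberings = NULL,
                     merge = NULL, filter = NULL, representatives = NULL,
                     cluster_k_range = 2:10, out_dir = NULL) {
  # fail-fast validation before any computation
  if (is.null(alignment) && is.null(merge))
    stop("either an alignment or a merge fixture is required")
  if (!is.null(merge) && !inherits(merge, "merge_fixture"))
    stop("merge must be a merge_fixture")
  if (!is.null(filter) && (is.null(annotation) && is.null(merge)))
    stop("the filter stage needs a family annotation")
  if (!is.null(filter) && is.null(representatives))
    stop("the filter stage needs per-family representatives")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (!is.null(merge)) {
    merged <- merge_by_core(merge)
    alignment <- merged$alignment
    annotation <- merged$annotation
  }
  filter_reports <- NULL
  if (!is.null(filter)) {
    fams <- families(annotation)
    keep <- character()
    filter_reports <- list()
    for (f in fams) {
      ids <- names(annotation)[unclass(annotation) == f]
      rep_id <- representatives[[f]]
      if (is.null(rep_id)) stop("no representative for family ", f)
      rpt <- filter_family_set(alignment, rep_id, filter, ids)
      filter_reports[[f]] <- rpt
      keep <- c(keep, rpt$retained_ids)
    }
    alignment <- structure(unclass(alignment)[keep, , drop = FALSE],
                           class = c("msa", "matrix", "array"))
    annotation <- family_annotation(keep, unclass(annotation)[keep])
  }
  clustering <- NULL
  if (is.null(annotation)) {
    clustering <- cluster_specificity_groups(
      alignment, cluster_k_range,
      gap_mask_threshold = config$gap_mask_threshold)
    annotation <- clustering$annotation
  }
  classifications <- classify_positions(alignment, annotation, config,
                                        numberings)
  family_table <- if (!is.null(numberings))
    build_family_table(classifications, alignment, annotation, numberings)
  bundle <- structure(list(
    classifications = classifications,
    family_table = family_table,
    alignment = alignment,
    annotation = annotation,
    clustering = clustering,
    filter_reports = filter_reports,
    provenance = list(config = unclass(config),
                      statistic = attr(classifications, "statistic"),
                      package_version =
                        as.character(utils::packageVersion("fspscan")))),
    class = "scan_result_bundle")
  if (!is.null(out_dir)) {
    write_positions_tsv(classifications,
                        file.path(out_dir, "positions.tsv"))
    write_family_annotation(annotation, file.path(out_dir, "families.tsv"))
    if (!is.null(family_table))
      utils::write.table(family_table,
                         file.path(out_dir, "family_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}

#' @export
print.scan_result_bundle <- function(x, ...) {
  tab <- table(x$classifications$class)
  cat("Position scan over", nrow(x$classifications), "columns:\n")
  print(tab)
  cat("Statistic:", x$provenance$statistic, "\n")
  invisible(x)
}

#' Write the per-column classification table as TSV
#'
#' One row per alignment column with class, consensus, conservation,
#' mutual information (and its normalised form), permutation p, BH q,
#' z-score, exception families and any reference-numbered labels.
#' Numeric columns are written with full precision so that repeated runs
#' can be compared byte-for-byte.
#'
#' @param classifications Output of [classify_positions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions_tsv <- function(classifications, path) {
  df <- classifications
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
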