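#' Classify an alignment and write the per-column artifacts
#'
#' End-to-end classification step: reads (or takes) a grouped alignment,
#' classifies every column, and writes `calls.tsv` (one row per column with
#' status, divergence type and serialized blocks), `census.json`, and a
#' `manifest.json` recording input checksums and parameters so that any run
#' can be reproduced. Outputs are deterministic: the same inputs produce
#' byte-identical files.
#'
#' @param fasta_path,group_map_path input paths (ignored when `aln` given).
#' @param aln optionally an already-built [grouped_alignment].
#' @param out_dir output directory (created if needed).
#' @param params an [entropy_params] object.
#' @return Invisibly, a list with the `divergence_calls` object (`fit`),
#'   the alignment and the written file paths.
#' @export
run_classify <- function(fasta_path = NULL, group_map_path = NULL,
                         aln = NULL, out_dir, params = entropy_params()) {
  if (is.null(aln)) {
    if (is.null(fasta_path) || is.null(group_map_path))
      stop("give either aln or both fasta_path and group_map_path",
           call. = FALSE)
    aln <- read_alignment(fasta_path, group_map_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- classify_alignment(aln, params)
  calls_path <- file.path(out_dir, "calls.tsv")
  census_path <- file.path(out_dir, "census.json")
  manifest_path <- file.path(out_dir, "manifest.json")
  utils::write.table(as.data.frame(fit), calls_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(status = as.list(fit$census),
         divergence = as.list(fit$divergence_census),
         n_columns = fit$n_columns,
         n_sequences = fit$n_sequences,
         groups = fit$groups),
    census_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inputs <- list()
  if (!is.null(fasta_path))
    inputs$fasta <- unname(tools::md5sum(fasta_path))
  if (!is.null(group_map_path))
    inputs$group_map <- unname(tools::md5sum(group_map_path))
  jsonlite::write_json(
    list(inputs = inputs,
         params = unclass(params),
         package = "paraldiv",
         version = as.character(utils::packageVersion("paraldiv"))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, alignment = aln,
                 files = c(calls = calls_path, census = census_path,
                           manifest = manifest_path)))
}

#' Compute and write the pattern census
#'
#' Produces `pattern_census.tsv` (`pattern`, `observed`, `expected`,
#' `significant`, bracket notation) and `pattern_census.json`. Expected
#' counts are included when the alignment is supplied.
#'
#' @param fit a `divergence_calls` object (e.g. from [run_classify()]).
#' @param out_dir output directory.
#' @param family_alpha family-wise alpha.
#' @param aln optional [grouped_alignment] for expected counts.
#' @return Invisibly, the `pattern_census` object plus file paths.
#' @export
run_patterns <- function(fit, out_dir, family_alpha = 0.1, aln = NULL) {
  if (!inherits(fit, "divergence_calls"))
    stop("dependency error: run_patterns needs the column calls from ",
         "run_classify / classify_alignment", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cen <- pattern_census(fit, family_alpha, aln)
  tab <- data.frame(pattern = names(cen$observed),
                    observed = as.integer(cen$observed),
                    expected = if (!is.null(cen$expected))
                      round(unname(cen$expected[names(cen$observed)]), 4)
                      else NA_real_,
                    significant = names(cen$observed) %in% cen$significant,
                    stringsAsFactors = FALSE)
  tsv_path <- file.path(out_dir, "pattern_census.tsv")
  json_path <- file.path(out_dir, "pattern_census.json")
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_nongap_columns = cen$n_nongap_columns,
         n_possible_patterns = cen$n_possible_patterns,
         significance_threshold = cen$significance_threshold,
         family_alpha = cen$family_alpha,
         observed = as.list(cen$observed),
         significant = cen$significant),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(census = cen,
                 files = c(tsv = tsv_path, json = json_path)))
}

#' Map pattern columns onto a reference protein and report region fractions
#'
#' Writes per-residue pattern annotations for a reference sequence
#' (`residue_annotations.tsv`: residue number, column, status, divergence,
#' pattern -- suitable for colouring a structure in a molecular viewer) and,
#' when a region and pattern are given, a region-enrichment report with the
#' fractions as integer ratios and percentages.
#'
#' @param fit a `divergence_calls` object.
#' @param aln the classified [grouped_alignment].
#' @param reference_id reference sequence id.
#' @param out_dir output directory.
#' @param offset residue-numbering offset for the reference.
#' @param region_columns optional integer vector of region columns.
#' @param pattern optional [conservation_pattern] for the region report.
#' @return Invisibly, list with the `column_residue_map`, the enrichment
#'   report (or NULL) and file paths.
#' @export
run_map <- function(fit, aln, reference_id, out_dir, offset = 0L,
                    region_columns = NULL, pattern = NULL) {
  stopifnot(inherits(fit, "divergence_calls"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- build_column_residue_map(aln, reference_id, offset)
  calls_df <- as.data.frame(fit)
  ann <- merge(map$pairs, calls_df, by = "column")
  ann <- ann[order(ann$residue_number),
             c("residue_number", "residue_letter", "column", "status",
               "divergence", "pattern")]
  ann_path <- file.path(out_dir, "residue_annotations.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(annotations = ann_path)
  report <- NULL
  if (!is.null(region_columns) && !is.null(pattern)) {
    report <- region_enrichment(fit, region_columns, pattern)
    report_path <- file.path(out_dir, "region_report.json")
    jsonlite::write_json(
      list(pattern = format(pattern),
           region = sprintf("%d/%d", report$region_count,
                            report$region_size),
           region_percent = round(100 * report$fraction_in_region, 1),
           overall = sprintf("%d/%d", report$overall_count,
                             report$n_nongap_columns),
           overall_percent = round(100 * report$fraction_overall, 1)),
      report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, report = report_path)
  }
  invisible(list(map = map, report = report, files = files))
}

#' Generate a synthetic alignment run on disk
#'
#' Writes the aligned FASTA, the group-map TSV and the planted ground truth
#' (`truth.tsv`) for a [simulation_spec].
#'
#' @param spec a [simulation_spec].
#' @param out_dir output directory.
#' @param params the [entropy_params] the plans target.
#' @return Invisibly, the `generate_alignment()` result plus file paths.
#' @export
run_simulate <- function(spec, out_dir, params = entropy_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_alignment(spec, params)
  fasta_path <- file.path(out_dir, "alignment.fasta")
  map_path <- file.path(out_dir, "groups.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_alignment(gen$alignment, fasta_path, map_path)
  utils::write.table(gen$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gen, list(files = c(fasta = fasta_path, groups = map_path,
                                  truth = truth_path))))
}
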