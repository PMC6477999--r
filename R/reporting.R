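#' Run the filtration pipeline over a simulated/exported data directory
#'
#' Expects the layout written by [simulate_to_dir()]: per proband
#' `<id>_variants.tsv`, optional `<id>.ped` and `<id>_carriers.tsv`.
#' Writes one per-case TSV report (variant, votes, hypotheses,
#' segregation, final class) and a JSON run summary with stage counts
#' and the detection rate.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created if needed).
#' @param config a [filter_config()].
#' @return The run summary list, invisibly.
#' @export
run_filter_pipeline <- function(in_dir, out_dir,
                                config = filter_config()) {
  var_files <- list.files(in_dir, pattern = "_variants\\.tsv$",
                          full.names = TRUE)
  if (!length(var_files))
    stop("no *_variants.tsv files found in ", in_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (vf in var_files) {
    id <- sub("_variants\\.tsv$", "", basename(vf))
    variants <- read_annotated_table(vf, proband_id = id)
    ped_path <- file.path(in_dir, paste0(id, ".ped"))
    car_path <- file.path(in_dir, paste0(id, "_carriers.tsv"))
    ped <- if (file.exists(ped_path)) read_ped(ped_path)
    carriers <- if (file.exists(car_path)) read_carrier_table(car_path)
    cr <- run_case(variants, config, ped = ped, carriers = carriers,
                   proband_id = id)
    results[[id]] <- cr
    write_case_report(cr, file.path(out_dir,
                                    paste0(id, "_report.tsv")))
  }
  summary <- summarize_cases(results)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Write a per-case TSV report
#'
#' @param case_result a [run_case()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(case_result, path) {
  cols <- c("variant_id", "gene", "transcript", "exon", "hgvs_c",
            "hgvs_p", "clinvar_class", "clinvar_id", "votes",
            "hypotheses", "segregation", "final_class")
  surv <- case_result$survivors
  out <- surv[, intersect(cols, names(surv)), drop = FALSE]
  for (j in seq_along(out)) {
    v <- as.character(out[[j]]); v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Phenotype reporting: frequency tables and cohort summary
#'
#' Writes ungrouped, age-band and ancestry frequency tables as TSV and
#' a cohort summary JSON.
#'
#' @param cohort cohort data frame (or path to a phenotype TSV).
#' @param out_dir output directory (created if needed).
#' @param feature_codes features to tabulate (default: all).
#' @return List of the tables and the summary, invisibly.
#' @export
run_phenotype_report <- function(cohort, out_dir,
                                 feature_codes = NULL) {
  if (is.character(cohort)) cohort <- read_phenotype_table(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(feature_codes)) feature_codes <- cohort_features(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    overall = frequency_table(cohort, feature_codes, "none"),
    by_age_band = frequency_table(cohort, feature_codes, "age_band"),
    by_ancestry = frequency_table(cohort, feature_codes, "ancestry"))
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]],
                       file.path(out_dir, paste0("features_", nm,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- cohort_summary(cohort)
  jsonlite::write_json(summary,
                       file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tabs, list(summary = summary)))
}

#' Write the packaged study fixture to a directory
#'
#' Exports the deterministic study fixture in the same file layout as
#' [simulate_to_dir()], so the file-based pipeline entry points can be
#' exercised on it.
#'
#' @param out_dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_fixture <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fix <- study_fixture()
  for (id in unique(fix$variants$proband_id)) {
    sub <- fix$variants[fix$variants$proband_id == id, , drop = FALSE]
    write_annotated_table(sub, file.path(out_dir,
                                         paste0(id, "_variants.tsv")))
    if (!is.null(fix$pedigrees[[id]])) {
      write_ped(fix$pedigrees[[id]],
                file.path(out_dir, paste0(id, ".ped")))
      cc <- fix$carriers[fix$carriers$variant_id %in% sub$variant_id, ,
                         drop = FALSE]
      utils::write.table(cc,
                         file.path(out_dir, paste0(id,
                                                   "_carriers.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_phenotype_table(fix$cohort,
                        file.path(out_dir, "cohort_phenotypes.tsv"))
  invisible(out_dir)
}
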