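#' Reconcile consensus-passing variants with ClinVar and segregation
#'
#' A consensus vote is necessary but not sufficient: archived assertions
#' and family evidence can overturn it. The precedence is fixed:
#' \enumerate{
#'   \item a ClinVar benign / likely benign assertion excludes the
#'     variant outright (`EXCLUDED_BENIGN`);
#'   \item otherwise a `FAILS_TO_SEGREGATE` call excludes it
#'     (`EXCLUDED_NON_SEGREGATING`);
#'   \item otherwise ClinVar pathogenic / likely pathogenic confirms it
#'     (`PATHOGENIC_KNOWN`) — segregation need not be informative;
#'   \item otherwise supportive segregation (`SEGREGATES`, `DE_NOVO`,
#'     `POSSIBLE_GERMLINE_MOSAICISM`) upgrades an unreported variant to
#'     `PATHOGENIC_NOVEL`;
#'   \item otherwise the variant remains a `VUS`.
#' }
#'
#' @param clinvar_class vector over the ClinVar vocabulary.
#' @param segregation vector of segregation labels (see
#'   [assess_segregation()]); NA treated as `UNINFORMATIVE`.
#' @return Character vector of final classes.
#' @export
reconcile <- function(clinvar_class, segregation) {
  segregation[is.na(segregation)] <- "UNINFORMATIVE"
  clinvar_class[is.na(clinvar_class)] <- "not_reported"
  out <- character(length(clinvar_class))
  benign <- clinvar_class %in% c("benign", "likely_benign")
  patho  <- clinvar_class %in% c("pathogenic", "likely_pathogenic")
  support <- segregation %in% c("SEGREGATES", "DE_NOVO",
                                "POSSIBLE_GERMLINE_MOSAICISM")
  fails <- segregation == "FAILS_TO_SEGREGATE"
  out[] <- "VUS"
  out[support] <- "PATHOGENIC_NOVEL"
  out[patho] <- "PATHOGENIC_KNOWN"
  out[!benign & fails] <- "EXCLUDED_NON_SEGREGATING"
  out[benign] <- "EXCLUDED_BENIGN"
  out
}

#' Run the full prioritization pipeline for one proband
#'
#' Stages, in order: population-frequency filter, attribute filter
#' (zygosity / function / location), dual-hypothesis consensus vote,
#' ClinVar + segregation reconciliation. Protein-truncating variants
#' whose 19-slot profile is entirely missing can never reach a vote
#' cutoff; they are reported in `vote_ineligible` rather than silently
#' dropped.
#'
#' @param variants canonical variant table for one proband.
#' @param config a [filter_config()].
#' @param ped optional pedigree for the proband's family.
#' @param carriers optional carrier-status table.
#' @param proband_id id stamped on the result (defaults to the table's).
#' @return A `case_result` list: `proband_id`, `stage_counts` (input,
#'   post_maf, post_attribute, post_vote, final), `survivors` (variant
#'   table with votes, hypotheses, segregation, final_class),
#'   `vote_ineligible`.
#' @export
run_case <- function(variants, config = filter_config(),
                     ped = NULL, carriers = NULL, proband_id = NULL) {
  validate_variants(variants, config$registry)
  if (is.null(proband_id)) {
    ids <- unique(stats::na.omit(variants$proband_id))
    proband_id <- if (length(ids) == 1L) ids else NA_character_
  }
  s_input <- nrow(variants)
  v1 <- filter_by_maf(variants, config)
  v2 <- filter_by_attributes(v1, config)
  ineligible <- v2[vote_count(v2, config$registry) == 0L &
                     rowSums(!is.na(as.matrix(
                       v2[, config$registry$tool_id, drop = FALSE]))) == 0L, ,
                   drop = FALSE]
  v3 <- apply_hypotheses(v2, config)

  seg_label <- rep(NA_character_, nrow(v3))
  seg_support <- vector("list", nrow(v3))
  if (!is.null(ped) && nrow(v3) > 0L) {
    if (is.null(carriers))
      carriers <- data.frame(member_id = character(0),
                             variant_id = character(0),
                             carrier = character(0))
    for (i in seq_len(nrow(v3))) {
      seg <- assess_segregation(ped, carriers, v3$variant_id[i])
      seg_label[i] <- seg$label
      seg_support[[i]] <- seg$supporting
    }
  }
  v3$segregation <- if (nrow(v3)) ifelse(is.na(seg_label),
                                         "UNINFORMATIVE", seg_label)
                    else character(0)
  v3$final_class <- reconcile(v3$clinvar_class, v3$segregation)
  final <- v3[startsWith(v3$final_class, "PATHOGENIC") |
                v3$final_class == "VUS", , drop = FALSE]
  structure(list(
    proband_id = proband_id,
    stage_counts = c(input = s_input, post_maf = nrow(v1),
                     post_attribute = nrow(v2), post_vote = nrow(v3),
                     final = nrow(final)),
    survivors = v3,
    vote_ineligible = ineligible
  ), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat("Case", x$proband_id, "- stage counts:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  if (nrow(x$survivors)) {
    cols <- c("variant_id", "gene", "hgvs_c", "votes", "hypotheses",
              "segregation", "final_class")
    print(x$survivors[, intersect(cols, names(x$survivors))],
          row.names = FALSE)
  } else cat("  no surviving variants\n")
  invisible(x)
}

#' Run the pipeline across a multi-proband variant table
#'
#' @param variants canonical variant table with a `proband_id` column.
#' @param config a [filter_config()].
#' @param pedigrees optional named list of pedigrees, keyed by proband id.
#' @param carriers optional carrier-status table shared by all families.
#' @return Named list of `case_result`, one per proband.
#' @export
run_cases <- function(variants, config = filter_config(),
                      pedigrees = NULL, carriers = NULL) {
  ids <- unique(variants$proband_id)
  out <- lapply(ids, function(id) {
    run_case(variants[variants$proband_id %in% id, , drop = FALSE],
             config,
             ped = pedigrees[[id]], carriers = carriers,
             proband_id = id)
  })
  names(out) <- ids
  out
}

#' Molecular detection rate over a set of cases
#'
#' @param case_results list of `case_result` objects.
#' @return List: `positive` (cases with at least one final PATHOGENIC_*
#'   variant), `n`, `fraction`, `percent` (one-decimal string, see
#'   [format_percent()]).
#' @export
detection_rate <- function(case_results) {
  if (length(case_results) == 0L)
    stop("detection_rate() needs at least one case", call. = FALSE)
  pos <- vapply(case_results, function(cr)
    any(startsWith(cr$survivors$final_class, "PATHOGENIC")), logical(1))
  k <- sum(pos); n <- length(case_results)
  list(positive = k, n = n, fraction = k / n,
       percent = format_percent(k, n))
}

#' Summarize a set of case results
#'
#' @param case_results list of `case_result` objects.
#' @return List with aggregate stage counts, per-class survivor counts,
#'   and the detection rate; serializable to JSON.
#' @export
summarize_cases <- function(case_results) {
  stage <- Reduce(`+`, lapply(case_results, `[[`, "stage_counts"))
  surv <- do.call(rbind, lapply(case_results, `[[`, "survivors"))
  rate <- detection_rate(case_results)
  list(
    n_cases = length(case_results),
    stage_counts = as.list(stage),
    final_class_counts = as.list(table(surv$final_class)),
    detection = list(positive = rate$positive, n = rate$n,
                     fraction = rate$fraction, percent = rate$percent)
  )
}
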