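#' Percent formatting used throughout the reports
#'
#' One decimal place with round-half-even (banker's) rounding, so
#' 5/16 prints as "31.2%" and 17/26 as "65.4%". The trailing ".0" is
#' always retained.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return Character vector like "31.2%".
#' @export
format_percent <- function(numerator, denominator) {
  if (any(denominator <= 0))
    stop("format_percent(): denominator must be positive", call. = FALSE)
  paste0(sprintf("%.1f", round_half_even(100 * numerator / denominator, 1L)),
         "%")
}

#' Round half to even at a given number of decimals
#'
#' Explicit banker's rounding with a small tolerance against binary
#' floating-point representation of decimal fractions.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_even <- function(x, digits = 1L) {
  s <- 10^digits
  y <- x * s
  f <- floor(y)
  rem <- y - f
  tol <- 1e-9
  up <- rem > 0.5 + tol
  half <- abs(rem - 0.5) <= tol
  out <- f
  out[up] <- f[up] + 1
  odd <- (f %% 2) != 0
  out[half & odd] <- f[half & odd] + 1
  out / s
}

#' The packaged phenotype feature dictionary
#'
#' Maps standardized feature codes to human-readable labels and a broad
#' category. The `cardiovascular` category defines the feature set used
#' for the "any cardiovascular abnormality" summary.
#'
#' @return Data frame: `code`, `label`, `category`.
#' @export
feature_dictionary <- function() {
  path <- system.file("extdata", "feature_dictionary.tsv",
                      package = "panelvote", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.meta_columns <- c("patient_id", "sex", "age_months", "ancestry",
                   "proband_flag", "gene_result")
.ancestries <- c("black_african", "mixed", "caucasian", "indian")

#' Feature columns of a cohort table
#' @param cohort cohort data frame.
#' @return Character vector of feature codes present in the table.
#' @export
cohort_features <- function(cohort) setdiff(names(cohort), .meta_columns)

#' Validate a phenotype cohort table
#'
#' @param cohort data frame: metadata columns (`patient_id`, `sex`,
#'   `age_months`, `ancestry`, `proband_flag`, `gene_result`) plus one
#'   column per feature code with values 1 (present) / 0 (absent) /
#'   NA (unknown).
#' @param dictionary feature dictionary (defaults to the packaged one).
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort, dictionary = feature_dictionary()) {
  miss <- setdiff(.meta_columns, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(cohort_features(cohort), dictionary$code)
  if (length(unknown))
    stop("unknown feature code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(!is.na(cohort$age_months) & cohort$age_months < 0))
    stop("negative age_months", call. = FALSE)
  bad <- setdiff(unique(cohort$ancestry), c(.ancestries, NA))
  if (length(bad))
    stop("invalid ancestry value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (f in cohort_features(cohort)) {
    v <- cohort[[f]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("feature column '", f, "' must be 1/0/NA", call. = FALSE)
  }
  invisible(cohort)
}

#' Read a phenotype cohort TSV
#'
#' One row per patient; feature columns coded 1/0/NA.
#' @param path TSV path.
#' @param dictionary feature dictionary.
#' @return Validated cohort data frame.
#' @export
read_phenotype_table <- function(path, dictionary = feature_dictionary()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort(cohort, dictionary)
  cohort
}

#' Write a phenotype cohort TSV
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Assign the reporting age band
#'
#' Bands follow the cohort reporting convention: newborn (under
#' 2 months), infant (2-12 months inclusive), child (over 12 months up
#' to 12 years), adult (over 18 years). Ages between 12 and 18 years
#' fall outside the reported bands and are flagged "unbanded".
#'
#' @param age_months numeric vector of ages in months (>= 0).
#' @return Character vector over {"newborn", "infant_2_12m",
#'   "child_1_12y", "adult_over_18y", "unbanded"}.
#' @export
assign_age_band <- function(age_months) {
  if (any(!is.na(age_months) & age_months < 0))
    stop("negative age", call. = FALSE)
  out <- rep(NA_character_, length(age_months))
  out[age_months < 2] <- "newborn"
  out[age_months >= 2 & age_months <= 12] <- "infant_2_12m"
  out[age_months > 12 & age_months <= 144] <- "child_1_12y"
  out[age_months > 144 & age_months <= 216] <- "unbanded"
  out[age_months > 216] <- "adult_over_18y"
  out
}

.age_band_levels <- c("newborn", "infant_2_12m", "child_1_12y",
                      "adult_over_18y", "unbanded")

#' Feature frequency table, optionally stratified
#'
#' For each requested feature and group: the number of patients with the
#' feature present, absent, and unknown, the group size, and the percent
#' present-of-group (recomputed from counts, never stored).
#'
#' @param cohort validated cohort data frame.
#' @param feature_codes features to tabulate (default: all).
#' @param group_by "none", "age_band" or "ancestry".
#' @param dictionary feature dictionary.
#' @return Data frame: `feature`, `group`, `n_group`, `n_present`,
#'   `n_absent`, `n_unknown`, `percent_value`, `percent`.
#' @export
frequency_table <- function(cohort, feature_codes = cohort_features(cohort),
                            group_by = c("none", "age_band", "ancestry"),
                            dictionary = feature_dictionary()) {
  group_by <- match.arg(group_by)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  validate_cohort(cohort, dictionary)
  bad <- setdiff(feature_codes, cohort_features(cohort))
  if (length(bad))
    stop("feature(s) not in cohort: ", paste(bad, collapse = ", "),
         call. = FALSE)
  grp <- switch(group_by,
                none = rep("all", nrow(cohort)),
                age_band = assign_age_band(cohort$age_months),
                ancestry = cohort$ancestry)
  lev <- switch(group_by,
                none = "all",
                age_band = intersect(.age_band_levels, unique(grp)),
                ancestry = intersect(.ancestries, unique(grp)))
  rows <- list()
  for (f in feature_codes) for (g in lev) {
    v <- cohort[[f]][grp == g]
    n <- length(v)
    np <- sum(v == 1, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, group = g, n_group = n, n_present = np,
      n_absent = sum(v == 0, na.rm = TRUE), n_unknown = sum(is.na(v)),
      percent_value = round_half_even(100 * np / n, 1L),
      percent = format_percent(np, n),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Any-cardiovascular-abnormality indicator
#'
#' Derived per patient from the feature dictionary's `cardiovascular`
#' category: 1 if any such feature is present, else 0 (patients with
#' only unknown cardiovascular features get 0; counts are conservative).
#'
#' @param cohort validated cohort data frame.
#' @param dictionary feature dictionary.
#' @return Integer vector of length `nrow(cohort)`.
#' @export
any_cardiovascular <- function(cohort, dictionary = feature_dictionary()) {
  feats <- intersect(dictionary$code[dictionary$category ==
                                       "cardiovascular"],
                     cohort_features(cohort))
  if (!length(feats)) return(integer(nrow(cohort)))
  as.integer(rowSums(cohort[, feats, drop = FALSE] == 1,
                     na.rm = TRUE) > 0)
}

#' Cohort demographic summary
#'
#' @param cohort validated cohort data frame.
#' @return List: `n`, `n_probands`, `median_age_months`,
#'   `median_age_years`, `sex_counts`, `sex_ratio` (male:female,
#'   one-decimal quotient), `ancestry` (count and percent per group).
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  sexes <- table(factor(cohort$sex, levels = c("male", "female")))
  anc <- table(factor(cohort$ancestry, levels = .ancestries))
  anc_tab <- data.frame(
    ancestry = names(anc), n = as.integer(anc),
    percent = format_percent(as.integer(anc), nrow(cohort)),
    stringsAsFactors = FALSE)
  ratio <- if (sexes[["female"]] > 0)
    round_half_even(sexes[["male"]] / sexes[["female"]], 1L) else NA_real_
  list(
    n = nrow(cohort),
    n_probands = sum(cohort$proband_flag, na.rm = TRUE),
    median_age_months = stats::median(cohort$age_months, na.rm = TRUE),
    median_age_years = round_half_even(
      stats::median(cohort$age_months, na.rm = TRUE) / 12, 1L),
    sex_counts = as.list(sexes),
    sex_ratio = ratio,
    ancestry = anc_tab
  )
}

#' Genotype-phenotype cross-tabulation
#'
#' Restricted to mutation-positive patients (`gene_result` not NA/"none");
#' per gene: number of patients, mean age at diagnosis in years (one
#' decimal), and count + percent per requested feature.
#'
#' @param cohort validated cohort data frame.
#' @param feature_codes features to tabulate (default: all).
#' @return List: `genes` (data frame gene / n / mean_age_years) and
#'   `features` (data frame gene / feature / n_present / percent).
#' @export
genotype_phenotype_table <- function(cohort,
                                     feature_codes = cohort_features(cohort)) {
  pos <- cohort[!is.na(cohort$gene_result) &
                  cohort$gene_result != "none", , drop = FALSE]
  if (nrow(pos) == 0L)
    stop("no mutation-positive patients in cohort", call. = FALSE)
  genes <- sort(unique(pos$gene_result))
  gene_tab <- do.call(rbind, lapply(genes, function(g) {
    sub <- pos[pos$gene_result == g, , drop = FALSE]
    data.frame(gene = g, n = nrow(sub),
               mean_age_years = round_half_even(
                 mean(sub$age_months) / 12, 1L),
               stringsAsFactors = FALSE)
  }))
  feat_tab <- do.call(rbind, lapply(genes, function(g) {
    sub <- pos[pos$gene_result == g, , drop = FALSE]
    do.call(rbind, lapply(feature_codes, function(f) {
      np <- sum(sub[[f]] == 1, na.rm = TRUE)
      data.frame(gene = g, feature = f, n_present = np,
                 percent = format_percent(np, nrow(sub)),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(genes = gene_tab, features = feat_tab)
}
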