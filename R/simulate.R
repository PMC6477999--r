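#' Simulation configuration
#'
#' Defines the composition of synthetic per-proband variant sets and the
#' synthetic phenotype cohort. Defaults mirror the study conditions the
#' pipeline was built for: 16 genotyped probands, a 26-patient
#' phenotype cohort with feature prevalences taken from the cohort
#' tables, and per-case variant classes with separable vote-count and
#' allele-frequency profiles. Background-variant counts per case are not
#' constrained by any published value and are freely configurable.
#'
#' Variant classes generated per case:
#' \describe{
#'   \item{common}{MAF in `[0.01, 0.5]` in both populations; removed by
#'     the rarity filter.}
#'   \item{rare_benign}{rare or unrecorded MAF, vote count below the
#'     panel cutoff.}
#'   \item{planted_pathogenic}{panel-gene heterozygous missense, MAFs
#'     absent, vote count at or above the free cutoff; paired with
#'     either a ClinVar pathogenic assertion or a supportive pedigree,
#'     so the full pipeline must recover it.}
#'   \item{clinvar_benign_decoy}{passes the vote stage but carries a
#'     ClinVar benign assertion.}
#'   \item{nonpanel_decoy}{vote count in `[panel_cutoff, free_cutoff)`
#'     on a non-panel gene; passes neither hypothesis.}
#'   \item{nonsegregating_decoy}{vote-passing VUS whose carrier pattern
#'     contradicts the disease in the family.}
#' }
#'
#' @param seed integer master seed; each case derives its own stream.
#' @param n_cases number of probands to simulate.
#' @param n_common,n_rare_benign,n_planted_pathogenic per-case counts.
#' @param n_clinvar_benign_decoys,n_nonpanel_decoys,n_nonsegregating_decoys
#'   per-case decoy counts.
#' @param vote_range named list of `c(lo, hi)` integer vote-count ranges
#'   per class.
#' @param missing_rate probability that a non-deleterious predictor slot
#'   is missing rather than benign.
#' @param n_patients phenotype cohort size.
#' @param feature_prevalence named numeric vector of per-feature
#'   Bernoulli prevalences (defaults: the cohort's printed prevalences).
#' @param ancestry_probs,age_band_probs categorical sampling weights.
#' @param male_prob probability of male sex.
#' @param scenario_weights pedigree scenario mix (proband_only,
#'   trio_de_novo, familial_segregating, mosaic_half_sibs).
#' @return List with class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 16L,
                              n_common = 30L,
                              n_rare_benign = 10L,
                              n_planted_pathogenic = 1L,
                              n_clinvar_benign_decoys = 1L,
                              n_nonpanel_decoys = 2L,
                              n_nonsegregating_decoys = 0L,
                              vote_range = list(
                                common = c(0L, 4L),
                                rare_benign = c(0L, 4L),
                                planted_pathogenic = c(17L, 19L),
                                clinvar_benign_decoy = c(10L, 16L),
                                nonpanel_decoy = c(5L, 9L),
                                nonsegregating_decoy = c(10L, 16L)),
                              missing_rate = 0.1,
                              n_patients = 26L,
                              feature_prevalence = NULL,
                              ancestry_probs = c(black_african = 8/26,
                                                 mixed = 14/26,
                                                 caucasian = 2/26,
                                                 indian = 2/26),
                              age_band_probs = c(newborn = 1/26,
                                                 infant_2_12m = 4/26,
                                                 child_1_12y = 15/26,
                                                 adult_over_18y = 6/26),
                              male_prob = 15/26,
                              scenario_weights = c(proband_only = 0.4,
                                                   trio_de_novo = 0.2,
                                                   familial_segregating = 0.3,
                                                   mosaic_half_sibs = 0.1)) {
  if (any(c(n_cases, n_common, n_rare_benign, n_planted_pathogenic,
            n_clinvar_benign_decoys, n_nonpanel_decoys,
            n_nonsegregating_decoys, n_patients) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (is.null(feature_prevalence))
    feature_prevalence <- default_cohort_prevalence()
  if (any(feature_prevalence < 0 | feature_prevalence > 1))
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    n_common = as.integer(n_common),
    n_rare_benign = as.integer(n_rare_benign),
    n_planted_pathogenic = as.integer(n_planted_pathogenic),
    n_clinvar_benign_decoys = as.integer(n_clinvar_benign_decoys),
    n_nonpanel_decoys = as.integer(n_nonpanel_decoys),
    n_nonsegregating_decoys = as.integer(n_nonsegregating_decoys),
    vote_range = vote_range, missing_rate = missing_rate,
    n_patients = as.integer(n_patients),
    feature_prevalence = feature_prevalence,
    ancestry_probs = ancestry_probs, age_band_probs = age_band_probs,
    male_prob = male_prob, scenario_weights = scenario_weights
  ), class = "simulation_config")
}

#' Default per-feature prevalences of the synthetic cohort
#'
#' Cohort-level prevalences of the standardized features (fractions of
#' 26), as tabulated for the reference cohort.
#' @return Named numeric vector.
#' @export
default_cohort_prevalence <- function() {
  c(macrocephaly = 3/26, tall_prominent_forehead = 12/26,
    coarse_face = 8/26, elongated_face = 12/26,
    widely_spaced_eyes = 8/26, epicanthic_folds = 17/26,
    ptosis = 13/26, low_set_ears = 15/26,
    depressed_nasal_root = 18/26, prominent_nasolabial_folds = 4/26,
    high_wide_vermilion = 15/26, short_neck = 12/26,
    webbed_neck = 5/26, short_stature = 21/26,
    pulmonary_valve_stenosis = 9/26, hypertrophic_cardiomyopathy = 5/26,
    left_axis_deviation = 6/26, walked_by_18_months = 16/26,
    speech_delay = 13/26, typical_facial_features = 20/26)
}

.panel_intervals <- function() {
  path <- system.file("extdata", "panel_exons_synthetic.bed",
                      package = "panelvote", mustWork = TRUE)
  bed <- utils::read.table(path, comment.char = "#",
                           col.names = c("chrom", "start", "end", "gene"),
                           stringsAsFactors = FALSE)
  bed
}

# Benign tokens used when a categorical tool votes not-deleterious.
.benign_token <- c(
  SIFT = "T", Polyphen2_HVAR = "B", Polyphen2_HDIV = "B",
  MutationTaster = "N", MutationAssessor = "L", LRT = "N",
  FATHMM = "T", MetaSVM = "T", MetaLR = "T", PROVEAN = "N",
  `fathmm-MKL` = "N")

#' Build a 19-slot prediction profile with a given deleterious count
#'
#' Deterministically given the RNG state: `n_deleterious` tools are
#' drawn at random and given a deleterious token / above-threshold
#' score; the rest receive a benign token / below-threshold score, or
#' are missing with probability `missing_rate`.
#'
#' @param n_deleterious target vote count in `[0, 19]`.
#' @param registry predictor registry.
#' @param missing_rate per-slot missingness among non-deleterious tools.
#' @return Named character vector of 19 raw values (NA = missing).
#' @export
simulate_profile <- function(n_deleterious, registry = tool_registry(),
                             missing_rate = 0) {
  stopifnot(n_deleterious >= 0, n_deleterious <= 19)
  del <- sample(registry$tool_id, n_deleterious)
  out <- stats::setNames(rep(NA_character_, nrow(registry)),
                         registry$tool_id)
  for (i in seq_len(nrow(registry))) {
    id <- registry$tool_id[i]
    hit <- id %in% del
    if (registry$kind[i] == "categorical") {
      tokens <- strsplit(registry$deleterious_tokens[i], ",")[[1]]
      out[id] <- if (hit) tokens[1] else .benign_token[[id]]
    } else {
      thr <- registry$threshold[i]
      out[id] <- format(if (hit) thr + abs(thr) * 0.5 + 1
                        else max(0, thr - abs(thr) * 0.5 - 0.1),
                        scientific = FALSE)
    }
    if (!hit && stats::runif(1) < missing_rate) out[id] <- NA_character_
  }
  out
}

.draw_votes <- function(range) {
  if (range[1] == range[2]) range[1]
  else sample(seq(range[1], range[2]), 1L)
}

.blank_row <- function(registry) {
  row <- stats::setNames(
    as.list(rep(NA_character_, length(variant_columns(registry)))),
    variant_columns(registry))
  row
}

.simulated_variant <- function(class, config, registry, bed, idx,
                               proband_id) {
  row <- .blank_row(registry)
  on_panel <- class != "nonpanel_decoy"
  if (on_panel) {
    g <- bed[sample(nrow(bed), 1L), ]
    row$gene <- g$gene
    row$chrom <- g$chrom
    row$pos <- as.character(sample(seq(g$start + 1L, g$end), 1L))
  } else {
    row$gene <- sample(c("TTN", "OBSCN", "MUC16", "SYNE1"), 1L)
    row$chrom <- "chr2"
    row$pos <- as.character(sample(1e6:2e6, 1L))
  }
  alleles <- sample(c("A", "C", "G", "T"), 2L)
  row$ref <- alleles[1]; row$alt <- alleles[2]
  row$function_class <- "missense"
  row$location_class <- "exonic"
  row$zygosity <- "heterozygous"
  row$proband_id <- proband_id
  row$variant_id <- sprintf("%s:%s:%s>%s:%s", row$chrom, row$pos,
                            row$ref, row$alt, idx)
  votes <- .draw_votes(config$vote_range[[class]])
  if (class == "common") {
    row$maf_1000g <- format(stats::runif(1, 0.01, 0.5), scientific = FALSE)
    row$maf_exomes <- format(stats::runif(1, 0.01, 0.5), scientific = FALSE)
    row$clinvar_class <- "not_reported"
  } else if (class == "rare_benign") {
    if (stats::runif(1) < 0.5)
      row$maf_exomes <- format(stats::runif(1, 0, 0.009),
                               scientific = FALSE)
    row$clinvar_class <- "not_reported"
  } else if (class == "clinvar_benign_decoy") {
    row$clinvar_class <- "benign"
    row$clinvar_id <- as.character(sample(1e5, 1L))
  } else if (class == "nonsegregating_decoy") {
    row$clinvar_class <- "VUS"
  } else {
    row$clinvar_class <- "not_reported"
  }
  profile <- simulate_profile(votes, registry, config$missing_rate)
  for (id in registry$tool_id) row[[id]] <- profile[[id]]
  c(row, list(.class = class))
}

.scenario_pedigree <- function(scenario, proband_id, fam_id,
                               planted_ids, decoy_ids) {
  mem <- function(id, fa, mo, sex, aff)
    data.frame(family_id = fam_id, member_id = id, father_id = fa,
               mother_id = mo, sex = sex, affected = aff,
               stringsAsFactors = FALSE)
  fa <- paste0(fam_id, "_FA"); mo <- paste0(fam_id, "_MO")
  ped <- switch(scenario,
    proband_only = rbind(
      mem(fa, NA, NA, "male", "no"), mem(mo, NA, NA, "female", "no"),
      mem(proband_id, fa, mo, "male", "yes")),
    trio_de_novo = rbind(
      mem(fa, NA, NA, "male", "no"), mem(mo, NA, NA, "female", "no"),
      mem(proband_id, fa, mo, "male", "yes")),
    familial_segregating = rbind(
      mem(fa, NA, NA, "male", "no"), mem(mo, NA, NA, "female", "yes"),
      mem(proband_id, fa, mo, "male", "yes")),
    mosaic_half_sibs = rbind(
      mem(fa, NA, NA, "male", "no"), mem(mo, NA, NA, "female", "no"),
      mem(paste0(fam_id, "_MO2"), NA, NA, "female", "no"),
      mem(proband_id, fa, mo, "male", "yes"),
      mem(paste0(fam_id, "_SIB"), fa, paste0(fam_id, "_MO2"), "male",
          "yes")),
    stop("unknown pedigree scenario: ", scenario, call. = FALSE))
  call_row <- function(member, variant, status)
    data.frame(member_id = member, variant_id = variant,
               carrier = status, stringsAsFactors = FALSE)
  carriers <- list()
  for (v in planted_ids) {
    carriers[[length(carriers) + 1L]] <- switch(scenario,
      proband_only = call_row(proband_id, v, "carrier"),
      trio_de_novo = rbind(call_row(proband_id, v, "carrier"),
                           call_row(fa, v, "non_carrier"),
                           call_row(mo, v, "non_carrier")),
      familial_segregating = rbind(call_row(proband_id, v, "carrier"),
                                   call_row(mo, v, "carrier"),
                                   call_row(fa, v, "non_carrier")),
      mosaic_half_sibs = rbind(call_row(proband_id, v, "carrier"),
                               call_row(paste0(fam_id, "_SIB"), v,
                                        "carrier"),
                               call_row(fa, v, "non_carrier")))
  }
  for (v in decoy_ids) {
    # unaffected father typed as a carrier contradicts dominant
    # segregation for the decoy variant in every scenario
    carriers[[length(carriers) + 1L]] <-
      rbind(call_row(proband_id, v, "carrier"),
            call_row(fa, v, "carrier"))
  }
  list(ped = ped,
       carriers = if (length(carriers)) do.call(rbind, carriers)
                  else data.frame(member_id = character(0),
                                  variant_id = character(0),
                                  carrier = character(0)))
}

#' Generate one synthetic case (variants + pedigree + carrier calls)
#'
#' Reproducible per case: the RNG stream is seeded from
#' `config$seed + 7919 * case_index`, so cases can be regenerated
#' independently. Planted pathogenic variants are guaranteed
#' recoverable by construction: under an uninformative pedigree
#' scenario they carry a ClinVar pathogenic assertion, otherwise the
#' pedigree supports segregation (or de novo / mosaic recurrence).
#'
#' @param config a [simulation_config()].
#' @param case_index 1-based case number.
#' @return List: `proband_id`, `variants` (canonical table), `ped`,
#'   `carriers`, `truth` (variant_id and simulated class), `scenario`.
#' @export
generate_case <- function(config, case_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed((config$seed + 7919L * as.integer(case_index)) %%
             .Machine$integer.max)
  registry <- tool_registry()
  bed <- .panel_intervals()
  proband_id <- sprintf("SIM%03d", case_index)
  fam_id <- paste0("FAM", proband_id)
  scenario <- sample(names(config$scenario_weights), 1L,
                     prob = config$scenario_weights)

  classes <- c(rep("common", config$n_common),
               rep("rare_benign", config$n_rare_benign),
               rep("planted_pathogenic", config$n_planted_pathogenic),
               rep("clinvar_benign_decoy", config$n_clinvar_benign_decoys),
               rep("nonpanel_decoy", config$n_nonpanel_decoys),
               rep("nonsegregating_decoy",
                   config$n_nonsegregating_decoys))
  rows <- lapply(seq_along(classes), function(i)
    .simulated_variant(classes[i], config, registry, bed, i, proband_id))
  truth <- data.frame(
    variant_id = vapply(rows, function(r) r$variant_id, ""),
    class = vapply(rows, function(r) r$.class, ""),
    stringsAsFactors = FALSE)

  planted <- truth$variant_id[truth$class == "planted_pathogenic"]
  decoys <- truth$variant_id[truth$class == "nonsegregating_decoy"]
  fam <- .scenario_pedigree(scenario, proband_id, fam_id, planted, decoys)

  # guarantee recoverability of planted variants (see Details)
  for (i in seq_along(rows)) {
    if (rows[[i]]$.class == "planted_pathogenic" &&
        scenario == "proband_only") {
      rows[[i]]$clinvar_class <- "pathogenic"
      rows[[i]]$clinvar_id <- as.character(sample(1e5, 1L))
    }
    rows[[i]]$.class <- NULL
  }
  variants <- if (length(rows))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  else as.data.frame(stats::setNames(
    rep(list(character(0)), length(variant_columns(registry))),
    variant_columns(registry)), check.names = FALSE)
  variants <- canonical_variants(variants, registry = registry,
                                 source = proband_id)
  list(proband_id = proband_id, variants = variants, ped = fam$ped,
       carriers = fam$carriers, truth = truth, scenario = scenario)
}

#' Generate a set of synthetic cases
#'
#' @param config a [simulation_config()].
#' @return Named list of [generate_case()] results, one per case.
#' @export
generate_cases <- function(config) {
  out <- lapply(seq_len(config$n_cases), function(i)
    generate_case(config, i))
  names(out) <- vapply(out, `[[`, "", "proband_id")
  out
}

#' Generate a synthetic phenotype cohort
#'
#' Features are sampled independently per patient from the configured
#' prevalence map; ancestry, sex and age band from categorical
#' distributions, with ages uniform within the band.
#'
#' @param config a [simulation_config()].
#' @return Cohort data frame (see [validate_cohort()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  n <- config$n_patients
  prev <- config$feature_prevalence
  if (n == 0L) {
    cohort <- data.frame(patient_id = character(0), sex = character(0),
                         age_months = numeric(0), ancestry = character(0),
                         proband_flag = logical(0),
                         gene_result = character(0))
    for (f in names(prev)) cohort[[f]] <- integer(0)
    return(cohort)
  }
  band <- sample(names(config$age_band_probs), n, replace = TRUE,
                 prob = config$age_band_probs)
  age <- vapply(band, function(b) switch(b,
    newborn = stats::runif(1, 0, 2),
    infant_2_12m = stats::runif(1, 2, 12),
    child_1_12y = stats::runif(1, 12.01, 144),
    adult_over_18y = stats::runif(1, 216.01, 620)), numeric(1))
  cohort <- data.frame(
    patient_id = sprintf("SIMPT%03d", seq_len(n)),
    sex = ifelse(stats::runif(n) < config$male_prob, "male", "female"),
    age_months = round(age, 1),
    ancestry = sample(names(config$ancestry_probs), n, replace = TRUE,
                      prob = config$ancestry_probs),
    proband_flag = TRUE,
    gene_result = NA_character_,
    stringsAsFactors = FALSE)
  for (f in names(prev))
    cohort[[f]] <- stats::rbinom(n, 1L, prev[[f]])
  validate_cohort(cohort)
  cohort
}

#' Write a simulated data set to disk
#'
#' Writes the canonical annotated TSV, PED and carrier TSV per case,
#' the phenotype TSV, and a manifest JSON (seed, file list, md5 sums).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cases <- generate_cases(config)
  files <- character(0)
  for (cs in cases) {
    base <- file.path(out_dir, cs$proband_id)
    write_annotated_table(cs$variants, paste0(base, "_variants.tsv"))
    write_ped(cs$ped, paste0(base, ".ped"))
    utils::write.table(cs$carriers, paste0(base, "_carriers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, paste0(base, "_variants.tsv"), paste0(base, ".ped"),
               paste0(base, "_carriers.tsv"))
  }
  cohort <- generate_cohort(config)
  coh_path <- file.path(out_dir, "cohort_phenotypes.tsv")
  write_phenotype_table(cohort, coh_path)
  files <- c(files, coh_path)
  manifest <- list(
    seed = config$seed,
    n_cases = config$n_cases,
    n_patients = config$n_patients,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
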