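#' Deterministic study fixture: cohort, variant sets, pedigrees
#'
#' Reconstructs, from printed summary values, a desk-scale data set
#' emulating the reference cohort: 26 phenotyped patients (ancestry
#' 8 black African / 14 mixed / 2 Caucasian / 2 Indian; 15 males /
#' 11 females; one newborn, four infants, fifteen children, six adults)
#' and 16 genotyped probands. Seven variants carry vote-passing
#' prediction profiles: the five reported pathogenic variants (two with
#' ClinVar pathogenic assertions, three novel with supportive
#' segregation — one via germline-mosaicism recurrence in half-brothers)
#' plus two CBL decoys (one ClinVar-benign, one VUS that fails to
#' segregate in a large dominant family). Each proband additionally
#' carries background variants that fail the frequency, attribute or
#' vote filters.
#'
#' Only marginal counts are published; the per-patient co-occurrence of
#' features is an unconstrained choice of this fixture. Genomic
#' positions of the two CBL decoy variants are synthetic placeholders
#' inside the CBL locus (the source tables do not print them).
#'
#' @return List: `variants` (canonical table, all probands),
#'   `pedigrees` (named list by proband), `carriers`, `cohort`,
#'   `truth` (expected final class per vote-passing variant).
#' @export
study_fixture <- function() {
  registry <- tool_registry()
  fam <- .fixture_pedigrees()
  list(variants = .fixture_variants(registry),
       pedigrees = fam$peds,
       carriers = fam$carriers,
       cohort = fixture_cohort(),
       truth = .fixture_truth())
}

.fixture_profile <- function(n_deleterious, registry) {
  # deterministic: first n tools in registry order vote deleterious
  out <- stats::setNames(rep(NA_character_, 19L), registry$tool_id)
  for (i in seq_len(19L)) {
    id <- registry$tool_id[i]
    hit <- i <= n_deleterious
    if (registry$kind[i] == "categorical") {
      tokens <- strsplit(registry$deleterious_tokens[i], ",")[[1]]
      out[id] <- if (hit) tokens[1] else .benign_token[[id]]
    } else {
      thr <- registry$threshold[i]
      out[id] <- format(if (hit) thr + abs(thr) * 0.5 + 1
                        else max(0, thr - abs(thr) * 0.5 - 0.1),
                        scientific = FALSE)
    }
  }
  out
}

.fixture_panel_variants <- function() {
  # the seven vote-passing variants; CBL decoy positions are synthetic
  data.frame(
    proband_id = c("SA05", "SA04", "SA06", "SA07", "SA08",
                   "SA01", "SA02"),
    chrom = c("chr15", "chr15", "chr11", "chr12", "chr12",
              "chr11", "chr11"),
    pos = c(66729181L, 66727484L, 119170290L, 112926890L, 112926876L,
            119155899L, 119158562L),
    ref = c("A", "A", "T", "A", "C", "C", "C"),
    alt = c("G", "C", "G", "G", "T", "T", "T"),
    gene = c("MAP2K1", "MAP2K1", "CBL", "PTPN11", "PTPN11",
             "CBL", "CBL"),
    transcript = c("NM_002755.3", "NM_002755.3", "NM_005188.3",
                   "NM_002834.3", "NM_002834.3", "NM_005188.3",
                   "NM_005188.3"),
    exon = c(3L, 2L, 16L, 13L, 13L, 12L, 13L),
    hgvs_c = c("c.389A>G", "c.200A>C", "c.2520T>G", "c.1510A>G",
               "c.1496C>T", "c.1858C>T", "c.2345C>T"),
    hgvs_p = c("p.Tyr130Cys", "p.Asp67Ala", "p.Cys840Trp",
               "p.Met504Val", "p.Ser499Phe", "p.Leu620Phe",
               "p.Pro782Leu"),
    clinvar_class = c("pathogenic", "not_reported", "not_reported",
                      "pathogenic", "not_reported", "benign", "VUS"),
    clinvar_id = c("13351", NA, NA, "40562", NA, "254071", "254072"),
    votes = c(17L, 16L, 15L, 18L, 17L, 12L, 11L),
    stringsAsFactors = FALSE)
}

.fixture_variants <- function(registry = tool_registry()) {
  probands <- sprintf("SA%02d", 1:16)
  pv <- .fixture_panel_variants()
  bed <- .panel_intervals()
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  base_row <- function(proband, gene, chrom, pos, ref, alt,
                       function_class = "missense",
                       location_class = "exonic",
                       zygosity = "heterozygous",
                       maf_1000g = NA, maf_exomes = NA,
                       clinvar_class = "not_reported",
                       clinvar_id = NA, transcript = NA, exon = NA,
                       hgvs_c = NA, hgvs_p = NA, votes = 0L,
                       all_missing = FALSE) {
    row <- .blank_row(registry)
    row$proband_id <- proband
    row$chrom <- chrom; row$pos <- as.character(pos)
    row$ref <- ref; row$alt <- alt; row$gene <- gene
    row$transcript <- as.character(transcript)
    row$exon <- as.character(exon)
    row$hgvs_c <- as.character(hgvs_c)
    row$hgvs_p <- as.character(hgvs_p)
    row$function_class <- function_class
    row$location_class <- location_class
    row$zygosity <- zygosity
    row$maf_1000g <- as.character(maf_1000g)
    row$maf_exomes <- as.character(maf_exomes)
    row$clinvar_class <- clinvar_class
    row$clinvar_id <- as.character(clinvar_id)
    if (!all_missing) {
      profile <- .fixture_profile(votes, registry)
      for (id in registry$tool_id) row[[id]] <- profile[[id]]
    }
    row$variant_id <- sprintf("%s:%s:%s>%s", chrom, pos, ref, alt)
    row
  }

  for (k in seq_along(probands)) {
    p <- probands[k]
    # three common background variants (fail the MAF filter)
    for (j in 1:3) {
      g <- bed[((k + j) %% nrow(bed)) + 1L, ]
      add(base_row(p, g$gene, g$chrom, g$start + 100L * j + k,
                   ref = "G", alt = "A",
                   maf_1000g = 0.02 + 0.01 * j, maf_exomes = 0.05,
                   votes = 1L))
    }
    # one rare benign missense (passes MAF, fails the vote stage)
    g <- bed[(k %% nrow(bed)) + 1L, ]
    add(base_row(p, g$gene, g$chrom, g$start + 5000L + k, "C", "G",
                 maf_exomes = 0.004, votes = 2L))
    # one rare synonymous variant (removed by the attribute filter)
    g <- bed[((k + 3L) %% nrow(bed)) + 1L, ]
    add(base_row(p, g$gene, g$chrom, g$start + 6000L + k, "T", "C",
                 function_class = "synonymous", maf_exomes = 0.001,
                 votes = 0L))
    # one frameshift with an all-missing profile (vote-ineligible)
    g <- bed[((k + 5L) %% nrow(bed)) + 1L, ]
    add(base_row(p, g$gene, g$chrom, g$start + 7000L + k, "A", "AT",
                 function_class = "frameshift", all_missing = TRUE))
    # one non-panel decoy: votes between the two cutoffs
    add(base_row(p, "TTN", "chr2", 179400000L + k, "T", "C",
                 votes = 7L))
    # the proband's vote-passing panel variant, if any
    i <- which(pv$proband_id == p)
    if (length(i)) {
      v <- pv[i, ]
      add(base_row(p, v$gene, v$chrom, v$pos, v$ref, v$alt,
                   transcript = v$transcript, exon = v$exon,
                   hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p,
                   clinvar_class = v$clinvar_class,
                   clinvar_id = v$clinvar_id, votes = v$votes))
    }
  }
  raw <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  canonical_variants(raw, registry = registry, source = "study_fixture")
}

.fixture_pedigrees <- function() {
  pv <- .fixture_panel_variants()
  vid <- stats::setNames(
    sprintf("%s:%d:%s>%s", pv$chrom, pv$pos, pv$ref, pv$alt),
    pv$proband_id)
  mem <- function(fam, id, fa, mo, sex, aff)
    data.frame(family_id = fam, member_id = id, father_id = fa,
               mother_id = mo, sex = sex, affected = aff,
               stringsAsFactors = FALSE)
  cc <- function(member, variant, status)
    data.frame(member_id = member, variant_id = variant,
               carrier = status, stringsAsFactors = FALSE)
  peds <- list(); carriers <- list()
  # proband-only families (ClinVar-resolved or benign-decoy probands)
  for (p in c("SA01", "SA05", "SA07")) {
    fam <- paste0("F", p)
    peds[[p]] <- rbind(
      mem(fam, paste0(fam, "_FA"), NA, NA, "male", "unknown"),
      mem(fam, paste0(fam, "_MO"), NA, NA, "female", "unknown"),
      mem(fam, p, paste0(fam, "_FA"), paste0(fam, "_MO"), "male",
          "yes"))
    carriers[[p]] <- cc(p, vid[[p]], "carrier")
  }
  # familial segregating: affected carrier mother, unaffected
  # non-carrier father, affected carrier proband
  for (p in c("SA06", "SA08")) {
    fam <- paste0("F", p)
    peds[[p]] <- rbind(
      mem(fam, paste0(fam, "_FA"), NA, NA, "male", "no"),
      mem(fam, paste0(fam, "_MO"), NA, NA, "female", "yes"),
      mem(fam, p, paste0(fam, "_FA"), paste0(fam, "_MO"), "male",
          "yes"))
    carriers[[p]] <- rbind(cc(p, vid[[p]], "carrier"),
                           cc(paste0(fam, "_MO"), vid[[p]], "carrier"),
                           cc(paste0(fam, "_FA"), vid[[p]],
                              "non_carrier"))
  }
  # germline-mosaicism family: two affected carrier half-brothers,
  # shared unaffected father typed non-carrier
  fam <- "FSA04"
  peds[["SA04"]] <- rbind(
    mem(fam, "FSA04_FA", NA, NA, "male", "no"),
    mem(fam, "FSA04_MO1", NA, NA, "female", "no"),
    mem(fam, "FSA04_MO2", NA, NA, "female", "no"),
    mem(fam, "SA04", "FSA04_FA", "FSA04_MO1", "male", "yes"),
    mem(fam, "FSA04_HB", "FSA04_FA", "FSA04_MO2", "male", "yes"))
  carriers[["SA04"]] <- rbind(
    cc("SA04", vid[["SA04"]], "carrier"),
    cc("FSA04_HB", vid[["SA04"]], "carrier"),
    cc("FSA04_FA", vid[["SA04"]], "non_carrier"),
    cc("FSA04_MO1", vid[["SA04"]], "non_carrier"))
  # large dominant family: an affected aunt does not carry the VUS
  fam <- "FSA02"
  peds[["SA02"]] <- rbind(
    mem(fam, "FSA02_GM", NA, NA, "female", "yes"),
    mem(fam, "FSA02_GF", NA, NA, "male", "no"),
    mem(fam, "FSA02_MO", "FSA02_GF", "FSA02_GM", "female", "yes"),
    mem(fam, "FSA02_AU", "FSA02_GF", "FSA02_GM", "female", "yes"),
    mem(fam, "FSA02_FA", NA, NA, "male", "no"),
    mem(fam, "SA02", "FSA02_FA", "FSA02_MO", "male", "yes"))
  carriers[["SA02"]] <- rbind(
    cc("SA02", vid[["SA02"]], "carrier"),
    cc("FSA02_MO", vid[["SA02"]], "carrier"),
    cc("FSA02_GM", vid[["SA02"]], "carrier"),
    cc("FSA02_AU", vid[["SA02"]], "non_carrier"))
  list(peds = peds, carriers = do.call(rbind, unname(carriers)))
}

.fixture_truth <- function() {
  pv <- .fixture_panel_variants()
  data.frame(
    proband_id = pv$proband_id,
    variant_id = sprintf("%s:%d:%s>%s", pv$chrom, pv$pos, pv$ref,
                         pv$alt),
    expected_class = c("PATHOGENIC_KNOWN", "PATHOGENIC_NOVEL",
                       "PATHOGENIC_NOVEL", "PATHOGENIC_KNOWN",
                       "PATHOGENIC_NOVEL", "EXCLUDED_BENIGN",
                       "EXCLUDED_NON_SEGREGATING"),
    expected_segregation = c("UNINFORMATIVE",
                             "POSSIBLE_GERMLINE_MOSAICISM",
                             "SEGREGATES", "UNINFORMATIVE",
                             "SEGREGATES", "UNINFORMATIVE",
                             "FAILS_TO_SEGREGATE"),
    stringsAsFactors = FALSE)
}

#' The fixture's 26-patient phenotype cohort
#'
#' Hand-encoded so that every audited marginal count (feature by age
#' band and by ancestry, ancestry shares, sex split, developmental and
#' cardiac counts) is reproduced exactly; per-patient feature
#' co-occurrence is a fixture choice.
#'
#' @return Validated cohort data frame of 26 patients.
#' @export
fixture_cohort <- function() {
  id <- sprintf("SA%02d", 1:26)
  males <- c(1, 2, 4, 5, 6, 7, 8, 9, 10, 11, 12, 21, 22, 25, 26)
  age <- c(1, 3, 6, 12, 12, 17, 20, 72, 24, 30, 36, 42, 48, 48, 60, 84,
           96, 108, 120, 144, 228, 276, 336, 408, 540, 612)
  ancestry <- rep("mixed", 26)
  ancestry[c(1, 2, 3, 6, 7, 8, 9, 21)] <- "black_african"
  ancestry[c(19, 25)] <- "caucasian"
  ancestry[c(20, 26)] <- "indian"
  gene <- rep(NA_character_, 26)
  gene[c(4, 5)] <- "MAP2K1"; gene[6] <- "CBL"
  gene[c(7, 8)] <- "PTPN11"
  cohort <- data.frame(
    patient_id = id,
    sex = ifelse(seq_len(26) %in% males, "male", "female"),
    age_months = age,
    ancestry = ancestry,
    proband_flag = seq_len(26) <= 16,
    gene_result = gene,
    stringsAsFactors = FALSE)
  present <- list(
    macrocephaly = c(1, 2, 3),
    tall_prominent_forehead = c(1, 2, 3, 6:13, 21),
    coarse_face = c(5, 14, 15, 21:25),
    elongated_face = c(1, 2, 6:11, 21:24),
    widely_spaced_eyes = c(2, 4, 5, 6, 10, 11, 12, 20),
    epicanthic_folds = c(1, 2, 3, 4, 6:14, 20, 22, 23, 24),
    ptosis = c(2, 3, 4, 6:15),
    low_set_ears = c(1, 2, 4, 6:13, 19, 22, 23, 26),
    depressed_nasal_root = c(2, 3, 4, 6:17, 21, 22, 23),
    prominent_nasolabial_folds = c(18, 19, 25, 26),
    high_wide_vermilion = c(2, 3, 6:16, 21, 22),
    short_neck = c(4, 5, 6:13, 21, 22),
    webbed_neck = c(2, 6, 7, 19, 22),
    short_stature = c(1:9, 11:18, 20, 22, 23, 26),
    pulmonary_valve_stenosis = c(4, 8, 9, 10, 11, 21, 22, 23, 24),
    hypertrophic_cardiomyopathy = c(7, 12, 13, 25, 26),
    left_axis_deviation = c(4, 8, 9, 10, 21, 25),
    aortic_valve_stenosis = 7,
    mitral_valve_incompetence = 7,
    coarctation_of_aorta = 6,
    bicuspid_aortic_valve = 6,
    septal_defect = c(14, 15),
    walked_by_18_months = c(6, 8:18, 21, 23, 25, 26),
    unable_to_walk_after_24_months = c(2, 7, 19, 20, 22, 24),
    speech_delay = c(4, 5, 9:19),
    motor_delay = c(4, 5, 7),
    mild_intellectual_disability = c(4, 5),
    learning_difficulties = c(4, 5),
    typical_facial_features = setdiff(1:26, 6),
    suggestive_facial_features = 6,
    pectus_deformity = c(4, 5),
    family_history_definite_ns = c(4, 7, 8),
    cryptorchidism = c(4, 8),
    strabismus = 4,
    curly_hair = c(5, 6, 8),
    bleeding_diathesis = c(7, 8))
  for (f in names(present)) {
    v <- integer(26)
    v[present[[f]]] <- 1L
    cohort[[f]] <- v
  }
  validate_cohort(cohort)
  cohort
}

#' Audit the study fixture against the printed summary values
#'
#' Recomputes every encoded marginal count from the fixture and
#' compares it with the published value: detection statistics are NOT
#' audited here (they require running the pipeline; see
#' [run_cases()]), only cohort composition and feature counts.
#'
#' @param fixture a [study_fixture()] result (built if missing).
#' @return Data frame of checks (`check`, `expected`, `observed`,
#'   `pass`); attribute `ok` is TRUE iff all pass.
#' @export
audit_study_fixture <- function(fixture = study_fixture()) {
  coh <- fixture$cohort
  n <- nrow(coh)
  any_cv <- any_cardiovascular(coh) == 1L
  black <- coh$ancestry == "black_african"
  checks <- rbind(
    data.frame(check = "cohort size", expected = 26, observed = n),
    data.frame(check = "genotyped probands", expected = 16,
               observed = sum(coh$proband_flag)),
    data.frame(check = "males", expected = 15,
               observed = sum(coh$sex == "male")),
    data.frame(check = "females", expected = 11,
               observed = sum(coh$sex == "female")),
    data.frame(check = "black African", expected = 8,
               observed = sum(black)),
    data.frame(check = "mixed ancestry", expected = 14,
               observed = sum(coh$ancestry == "mixed")),
    data.frame(check = "Caucasian", expected = 2,
               observed = sum(coh$ancestry == "caucasian")),
    data.frame(check = "Indian", expected = 2,
               observed = sum(coh$ancestry == "indian")),
    data.frame(check = "median age (months)", expected = 54,
               observed = stats::median(coh$age_months)),
    data.frame(check = "pulmonary valve stenosis", expected = 9,
               observed = sum(coh$pulmonary_valve_stenosis)),
    data.frame(check = "hypertrophic cardiomyopathy", expected = 5,
               observed = sum(coh$hypertrophic_cardiomyopathy)),
    data.frame(check = "left axis deviation", expected = 6,
               observed = sum(coh$left_axis_deviation)),
    data.frame(check = "any cardiovascular abnormality", expected = 17,
               observed = sum(any_cv)),
    data.frame(check = "walked by 18 months", expected = 16,
               observed = sum(coh$walked_by_18_months)),
    data.frame(check = "speech delay", expected = 13,
               observed = sum(coh$speech_delay)),
    data.frame(check = "black African ptosis", expected = 6,
               observed = sum(coh$ptosis[black])),
    data.frame(check = "black African epicanthic folds", expected = 7,
               observed = sum(coh$epicanthic_folds[black])),
    data.frame(check = "vote-passing fixture variants", expected = 7,
               observed = sum(vote_count(fixture$variants) >= 10)))
  checks$pass <- checks$expected == checks$observed
  attr(checks, "ok") <- all(checks$pass)
  checks
}
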