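test_that("percent formatting rounds half to even at one decimal", {
  expect_identical(format_percent(5, 16), "31.2%")
  expect_identical(format_percent(17, 26), "65.4%")
  expect_identical(format_percent(13, 26), "50.0%")
  expect_identical(format_percent(0, 4), "0.0%")
  expect_identical(format_percent(1, 8), "12.5%")   # exact half, even
  expect_identical(format_percent(3, 8), "37.5%")
  expect_error(format_percent(1, 0), "denominator")
})

test_that("age bands partition ages as reported, flagging the 12-18y gap", {
  expect_identical(assign_age_band(1), "newborn")
  expect_identical(assign_age_band(2), "infant_2_12m")
  expect_identical(assign_age_band(6), "infant_2_12m")
  expect_identical(assign_age_band(12), "infant_2_12m")
  expect_identical(assign_age_band(13), "child_1_12y")
  expect_identical(assign_age_band(144), "child_1_12y")
  expect_identical(assign_age_band(15 * 12), "unbanded")
  expect_identical(assign_age_band(217), "adult_over_18y")
  expect_error(assign_age_band(-1), "negative")
})

test_that("frequency table counts partition each group and percents recompute", {
  coh <- fixture_cohort()
  tab <- frequency_table(coh, c("ptosis", "webbed_neck"), "ancestry")
  expect_true(all(tab$n_present + tab$n_absent + tab$n_unknown ==
                    tab$n_group))
  expect_identical(sum(tab$n_group[tab$feature == "ptosis"]), nrow(coh))
  black_pt <- tab[tab$feature == "ptosis" &
                    tab$group == "black_african", ]
  expect_identical(black_pt$n_present, 6L)
  expect_identical(black_pt$percent, "75.0%")
  # order invariance under cohort permutation
  set.seed(5)
  perm <- coh[sample(nrow(coh)), ]
  expect_identical(frequency_table(perm, c("ptosis", "webbed_neck"),
                                   "ancestry"), tab)
  # absent-everywhere feature
  coh$broad_thorax <- 0L
  t0 <- frequency_table(coh, "broad_thorax", "none")
  expect_identical(t0$percent, "0.0%")
  expect_error(frequency_table(coh[0, ], "ptosis"), "empty")
  expect_error(frequency_table(coh, "not_a_feature"), "not_a_feature")
})

test_that("cohort summary reproduces demographics", {
  s <- cohort_summary(fixture_cohort())
  expect_identical(s$n, 26L)
  expect_identical(s$sex_counts$male, 15L)
  expect_identical(s$sex_counts$female, 11L)
  expect_identical(s$median_age_years, 4.5)
  anc <- s$ancestry
  expect_identical(anc$percent[anc$ancestry == "mixed"], "53.8%")
  expect_identical(anc$percent[anc$ancestry == "black_african"],
                   "30.8%")
  one <- fixture_cohort()[3, ]
  s1 <- cohort_summary(one)
  expect_identical(
    s1$ancestry$percent[s1$ancestry$ancestry == "black_african"],
    "100.0%")
  expect_identical(cohort_summary(data.frame(
    patient_id = "x", sex = "male", age_months = c(12, 24, 36),
    ancestry = "mixed", proband_flag = TRUE,
    gene_result = NA))$median_age_months, 24)
})

test_that("genotype-phenotype table reports per-gene n and mean ages", {
  gp <- genotype_phenotype_table(fixture_cohort())
  genes <- gp$genes
  expect_identical(genes$n[genes$gene == "MAP2K1"], 2L)
  expect_identical(genes$mean_age_years[genes$gene == "MAP2K1"], 1.0)
  expect_identical(genes$mean_age_years[genes$gene == "CBL"], 1.4)
  ss <- gp$features[gp$features$feature == "short_stature", ]
  expect_true(all(ss$percent == "100.0%"))
  coh <- fixture_cohort()
  coh$gene_result <- NA_character_
  expect_error(genotype_phenotype_table(coh), "mutation-positive")
})

test_that("diagnostic scoring combines major and minor criteria", {
  crit <- read_criteria()
  blank <- fixture_cohort()[1, ]
  feats <- cohort_features(blank)
  blank[feats] <- 0L
  expect_identical(van_der_burgt_score(blank, crit)$diagnosis,
                   "not_definite")
  # typical facies + one other major criterion
  a <- blank; a$typical_facial_features <- 1L
  a$pulmonary_valve_stenosis <- 1L
  expect_identical(van_der_burgt_score(a, crit)$diagnosis,
                   "definite_NS")
  # typical facies alone is insufficient
  f <- blank; f$typical_facial_features <- 1L
  expect_identical(van_der_burgt_score(f, crit)$diagnosis,
                   "not_definite")
  # suggestive facies + two non-facial majors
  b <- blank; b$suggestive_facial_features <- 1L
  b$short_stature <- 1L; b$pectus_deformity <- 1L
  expect_identical(van_der_burgt_score(b, crit)$diagnosis,
                   "definite_NS")
  # suggestive facies + only one major: not definite
  c1 <- blank; c1$suggestive_facial_features <- 1L
  c1$short_stature <- 1L
  expect_identical(van_der_burgt_score(c1, crit)$diagnosis,
                   "not_definite")
})

test_that("scoring is monotone: adding features never withdraws a diagnosis", {
  crit <- read_criteria()
  base <- fixture_cohort()[1, ]
  feats <- cohort_features(base)
  base[feats] <- 0L
  base$suggestive_facial_features <- 1L
  base$height_below_p10 <- 1L
  base$broad_thorax <- 1L
  base$family_history_suggestive_ns <- 1L  # facies B + 3 minor
  expect_identical(van_der_burgt_score(base, crit)$diagnosis,
                   "definite_NS")
  for (f in c("short_stature", "typical_facial_features",
              "pectus_deformity", "pulmonary_valve_stenosis")) {
    up <- base
    up[[f]] <- 1L
    expect_identical(van_der_burgt_score(up, crit)$diagnosis,
                     "definite_NS", info = f)
  }
})

test_that("criteria referencing unknown feature codes are rejected", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("criteria:",
               "  - id: facies",
               "    A:",
               "      any_of: [made_up_code]"), tmp)
  expect_error(read_criteria(tmp), "made_up_code")
})

test_that("phenotype TSV round-trips and rejects unknown codes", {
  coh <- fixture_cohort()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_table(coh, tmp)
  back <- read_phenotype_table(tmp)
  expect_identical(back$ptosis, coh$ptosis)
  expect_identical(back$ancestry, coh$ancestry)
  bad <- coh
  names(bad)[names(bad) == "ptosis"] <- "eyelid_droop"
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_table(bad, tmp2)
  expect_error(read_phenotype_table(tmp2), "eyelid_droop")
})
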