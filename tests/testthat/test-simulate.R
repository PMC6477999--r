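test_that("identical config and seed reproduce cases exactly", {
  cfg <- simulation_config(seed = 42, n_cases = 2)
  a <- generate_case(cfg, 1)
  b <- generate_case(cfg, 1)
  expect_identical(a, b)
  # and a different case index gives different variants
  c2 <- generate_case(cfg, 2)
  expect_false(identical(a$variants$variant_id, c2$variants$variant_id))
})

test_that("simulated variant classes have the constructed properties", {
  cfg <- simulation_config(seed = 9, n_nonsegregating_decoys = 1)
  cs <- generate_case(cfg, 1)
  v <- cs$variants
  votes <- vote_count(v)
  cls <- cs$truth$class[match(v$variant_id, cs$truth$variant_id)]
  expect_true(all(v$maf_1000g[cls == "common"] >= 0.01))
  expect_true(all(votes[cls == "planted_pathogenic"] >= 10))
  expect_true(all(is.na(v$maf_1000g[cls == "planted_pathogenic"])))
  expect_true(all(v$gene[cls == "planted_pathogenic"] %in%
                    default_gene_panel()))
  expect_true(all(v$zygosity[cls == "planted_pathogenic"] ==
                    "heterozygous"))
  expect_true(all(votes[cls == "rare_benign"] < 5))
  expect_true(all(v$clinvar_class[cls == "clinvar_benign_decoy"] ==
                    "benign"))
  expect_true(all(votes[cls == "clinvar_benign_decoy"] >= 10))
  np <- cls == "nonpanel_decoy"
  expect_true(all(votes[np] >= 5 & votes[np] < 10))
  expect_true(all(!(v$gene[np] %in% default_gene_panel())))
})

test_that("planted variants are recovered and decoys excluded end to end", {
  for (seed in c(3, 17)) {
    cfg <- simulation_config(seed = seed, n_cases = 2,
                             n_nonsegregating_decoys = 1)
    for (cs in generate_cases(cfg)) {
      cr <- run_case(cs$variants, filter_config(), cs$ped, cs$carriers)
      surv <- cr$survivors
      planted <- cs$truth$variant_id[cs$truth$class ==
                                       "planted_pathogenic"]
      got <- surv$final_class[match(planted, surv$variant_id)]
      expect_true(all(startsWith(got, "PATHOGENIC")), info = seed)
      benign <- cs$truth$variant_id[cs$truth$class ==
                                      "clinvar_benign_decoy"]
      expect_true(all(surv$final_class[surv$variant_id %in% benign] ==
                        "EXCLUDED_BENIGN"))
      failing <- cs$truth$variant_id[cs$truth$class ==
                                       "nonsegregating_decoy"]
      expect_true(all(surv$final_class[surv$variant_id %in% failing] ==
                        "EXCLUDED_NON_SEGREGATING"))
    }
  }
})

test_that("zero counts give empty outputs, invalid configs error", {
  cfg <- simulation_config(seed = 1, n_common = 0, n_rare_benign = 0,
                           n_planted_pathogenic = 0,
                           n_clinvar_benign_decoys = 0,
                           n_nonpanel_decoys = 0)
  cs <- generate_case(cfg, 1)
  expect_identical(nrow(cs$variants), 0L)
  expect_identical(nrow(generate_cohort(
    simulation_config(seed = 1, n_patients = 0))), 0L)
  expect_error(simulation_config(n_cases = -1), "counts")
  expect_error(simulation_config(feature_prevalence = c(ptosis = 1.2)),
               "prevalences")
})

test_that("cohort feature frequencies track the prevalence map", {
  cfg <- simulation_config(seed = 8, n_patients = 2000,
                           feature_prevalence = c(ptosis = 0.654,
                                                  webbed_neck = 1.0))
  coh <- generate_cohort(cfg)
  expect_true(all(coh$webbed_neck == 1L))
  p_hat <- mean(coh$ptosis)
  se <- sqrt(0.654 * (1 - 0.654) / 2000)
  expect_lt(abs(p_hat - 0.654), 3 * se)
})

test_that("simulate_to_dir writes a deterministic, hash-stable data set", {
  cfg <- simulation_config(seed = 12, n_cases = 2, n_common = 5,
                           n_rare_benign = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_to_dir(cfg, d1)
  m2 <- simulate_to_dir(cfg, d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  expect_true("manifest.json" %in% f1)
  for (f in setdiff(f1, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  man <- jsonlite::read_json(m1)
  expect_identical(length(man$files), length(f1) - 1L)
})
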