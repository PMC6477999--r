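test_that("MAF filter: every present frequency must be rare (oracle: rule table)", {
  cfg <- filter_config()
  cases <- list(
    list(g = 0.2,   e = NA,    keep = FALSE),  # common in 1000g
    list(g = NA,    e = NA,    keep = TRUE),   # unrecorded -> retained
    list(g = 0.005, e = 0.02,  keep = FALSE),  # rare in one, common in other
    list(g = 0.005, e = 0.001, keep = TRUE),
    list(g = NA,    e = 0.009, keep = TRUE),
    list(g = 0.01,  e = NA,    keep = FALSE))  # boundary: not < 0.01
  for (cs in cases) {
    v <- make_variant(maf_1000g = cs$g, maf_exomes = cs$e)
    expect_identical(nrow(filter_by_maf(v, cfg)) == 1L, cs$keep,
                     info = paste(cs$g, cs$e))
  }
})

test_that("attribute filter enforces zygosity, function and location sets", {
  cfg <- filter_config()
  keep <- make_variant()  # heterozygous exonic missense
  expect_identical(nrow(filter_by_attributes(keep, cfg)), 1L)
  expect_identical(nrow(filter_by_attributes(
    make_variant(function_class = "synonymous"), cfg)), 0L)
  expect_identical(nrow(filter_by_attributes(
    make_variant(zygosity = "homozygous"), cfg)), 0L)
  expect_identical(nrow(filter_by_attributes(
    make_variant(location_class = "intronic"), cfg)), 0L)
  expect_identical(nrow(filter_by_attributes(
    make_variant(function_class = "frameshift",
                 location_class = "splicing",
                 all_missing = TRUE), cfg)), 1L)
})

test_that("free hypothesis passes at >= 10 votes, panel at >= 5 within panel", {
  cfg <- filter_config()
  expect_true(select_free_hypothesis(make_variant(votes = 10L), cfg))
  expect_false(select_free_hypothesis(make_variant(votes = 9L), cfg))
  expect_true(select_free_hypothesis(make_variant(votes = 19L), cfg))
  expect_true(select_panel_hypothesis(make_variant(votes = 5L), cfg))
  expect_false(select_panel_hypothesis(make_variant(votes = 4L), cfg))
  expect_false(select_panel_hypothesis(
    make_variant(gene = "TTN", votes = 19L), cfg))
})

test_that("hypothesis union tags provenance and respects the mode", {
  v <- make_variants(
    make_variant(votes = 12L),                 # free + panel
    make_variant(votes = 6L),                  # panel only
    make_variant(gene = "TTN", votes = 7L),    # neither (non-panel)
    make_variant(gene = "TTN", votes = 12L))   # free only
  got <- apply_hypotheses(v, filter_config())
  expect_identical(got$hypotheses, c("free,panel", "panel", "free"))
  expect_identical(
    nrow(apply_hypotheses(v, filter_config(hypothesis_mode = "free_only"))),
    2L)
  expect_identical(
    nrow(apply_hypotheses(v, filter_config(hypothesis_mode = "panel_only"))),
    2L)
})

test_that("free-hypothesis pass implies panel-hypothesis pass on panel genes", {
  cfg <- filter_config()
  for (votes in c(10L, 12L, 19L)) {
    v <- make_variant(votes = votes)
    expect_true(select_panel_hypothesis(v, cfg))
  }
})

test_that("filters are idempotent and commute", {
  set.seed(7)
  pool <- do.call(make_variants, lapply(1:30, function(i) {
    make_variant(
      pos = 1000L + i,
      gene = sample(c(default_gene_panel(), "TTN"), 1),
      function_class = sample(c("missense", "synonymous"), 1),
      zygosity = sample(c("heterozygous", "homozygous"), 1),
      maf_1000g = sample(c(NA, 0.001, 0.2), 1),
      maf_exomes = sample(c(NA, 0.005, 0.05), 1),
      votes = sample(0:19, 1))
  }))
  cfg <- filter_config()
  a <- filter_by_maf(pool, cfg)
  expect_identical(filter_by_maf(a, cfg), a)
  b <- filter_by_attributes(pool, cfg)
  expect_identical(filter_by_attributes(b, cfg), b)
  ab <- filter_by_attributes(filter_by_maf(pool, cfg), cfg)
  ba <- filter_by_maf(filter_by_attributes(pool, cfg), cfg)
  expect_identical(ab, ba)
})

test_that("configuration invariants are enforced", {
  expect_error(filter_config(maf_threshold = 0), "maf_threshold")
  expect_error(filter_config(free_cutoff = 4, panel_cutoff = 5),
               "panel_cutoff")
  expect_error(filter_config(free_cutoff = 20), "19")
})
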