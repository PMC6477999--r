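vid <- "chr1:100:A>G"

test_that("typed contradictions dominate: affected non-carrier or unaffected carrier", {
  ped <- make_trio()
  cc <- carrier_rows(c("PB1", "F1_FA"), vid, c("carrier", "carrier"))
  got <- assess_segregation(ped, cc, vid)
  expect_identical(got$label, "FAILS_TO_SEGREGATE")
  expect_true("F1_FA" %in% got$supporting)

  # multigeneration dominant family with a typed affected non-carrier
  ped2 <- data.frame(
    family_id = "F2",
    member_id = c("GM", "GF", "MO", "AU", "FA", "PB"),
    father_id = c(NA, NA, "GF", "GF", NA, "FA"),
    mother_id = c(NA, NA, "GM", "GM", NA, "MO"),
    sex = c("female", "male", "female", "female", "male", "male"),
    affected = c("yes", "no", "yes", "yes", "no", "yes"),
    stringsAsFactors = FALSE)
  cc2 <- carrier_rows(c("PB", "MO", "GM", "AU"), vid,
                      c("carrier", "carrier", "carrier", "non_carrier"))
  expect_identical(assess_segregation(ped2, cc2, vid)$label,
                   "FAILS_TO_SEGREGATE")
})

test_that("affected carrier half-siblings with non-carrier shared parent suggest mosaicism", {
  ped <- data.frame(
    family_id = "F3",
    member_id = c("FA", "MO1", "MO2", "PB", "HB"),
    father_id = c(NA, NA, NA, "FA", "FA"),
    mother_id = c(NA, NA, NA, "MO1", "MO2"),
    sex = c("male", "female", "female", "male", "male"),
    affected = c("no", "no", "no", "yes", "yes"),
    stringsAsFactors = FALSE)
  cc <- carrier_rows(c("PB", "HB", "FA"), vid,
                     c("carrier", "carrier", "non_carrier"))
  got <- assess_segregation(ped, cc, vid)
  expect_identical(got$label, "POSSIBLE_GERMLINE_MOSAICISM")
  expect_setequal(got$supporting, c("PB", "HB", "FA"))
  # untyped shared parent: no mosaicism claim, and no contradiction
  cc2 <- carrier_rows(c("PB", "HB"), vid, c("carrier", "carrier"))
  expect_identical(assess_segregation(ped, cc2, vid)$label,
                   "SEGREGATES")
})

test_that("single affected carrier with typed non-carrier parents is de novo", {
  ped <- make_trio()
  cc <- carrier_rows(c("PB1", "F1_FA", "F1_MO"), vid,
                     c("carrier", "non_carrier", "non_carrier"))
  expect_identical(assess_segregation(ped, cc, vid)$label, "DE_NOVO")
})

test_that("consistent typed members co-segregate; lone carrier is uninformative", {
  ped <- make_trio(mother_aff = "yes")
  cc <- carrier_rows(c("PB1", "F1_MO", "F1_FA"), vid,
                     c("carrier", "carrier", "non_carrier"))
  expect_identical(assess_segregation(ped, cc, vid)$label, "SEGREGATES")

  cc2 <- carrier_rows("PB1", vid, "carrier")
  expect_identical(assess_segregation(make_trio(father_aff = "unknown",
                                                mother_aff = "unknown"),
                                      cc2, vid)$label,
                   "UNINFORMATIVE")
  # untested variant id: nothing typed
  expect_identical(assess_segregation(ped, cc, "chr9:1:A>T")$label,
                   "UNINFORMATIVE")
})

test_that("structural pedigree errors are caught", {
  ped <- make_trio()
  ped$father_id[3] <- "GHOST"
  expect_error(validate_pedigree(ped), "dangling")
  loop <- data.frame(family_id = "F", member_id = c("A", "B"),
                     father_id = c("B", "A"), mother_id = c(NA, NA),
                     sex = "male", affected = "yes",
                     stringsAsFactors = FALSE)
  expect_error(validate_pedigree(loop), "cyclic")
})

test_that("PED + carrier tables round-trip through their file formats", {
  ped <- make_trio(mother_aff = "yes")
  tmp <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, tmp)
  back <- read_ped(tmp)
  rownames(back) <- rownames(ped) <- NULL
  expect_identical(back, ped)

  cc <- carrier_rows(c("PB1", "F1_MO"), vid, c("carrier", "untyped"))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cc, tmp2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_identical(read_carrier_table(tmp2), cc)
  writeLines(c("member_id\tvariant_id\tcarrier",
               "X\tv\tmaybe"), tmp2)
  expect_error(read_carrier_table(tmp2), "maybe")
})
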