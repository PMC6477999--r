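write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("reader maps sentinel cells to absent and preserves rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- make_variants(make_variant(pos = 100), make_variant(pos = 200),
                     make_variant(pos = 300, maf_1000g = 0.005))
  write_annotated_table(v, tmp)
  back <- read_annotated_table(tmp)
  expect_identical(nrow(back), 3L)
  expect_true(is.na(back$maf_1000g[1]))
  expect_identical(back$maf_1000g[3], 0.005)
  expect_identical(back$.row, 1:3)
})

test_that("canonical TSV round-trips field-identically", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- make_variants(
    make_variant(votes = 12L, maf_exomes = 0.001,
                 clinvar_class = "VUS", clinvar_id = "99"),
    make_variant(gene = "CBL", chrom = "chr11", pos = 119170290L,
                 ref = "T", alt = "G", votes = 3L),
    make_variant(function_class = "frameshift", all_missing = TRUE))
  write_annotated_table(v, tmp)
  back <- read_annotated_table(tmp)
  cols <- variant_columns()
  expect_identical(back[, cols], v[, cols])
  # idempotent under a second round trip
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_table(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("column_map binds foreign headers; schema errors name columns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(Chr = "chr12", Start = "112926890", Ref = "A",
                   Alt = "G", Gene.refGene = "PTPN11",
                   ExonicFunc = "missense", Func.refGene = "exonic",
                   Otherinfo = "heterozygous", check.names = FALSE)
  write_tsv_fixture(df, tmp)
  got <- read_annotated_table(tmp, column_map = c(
    chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt",
    gene = "Gene.refGene", function_class = "ExonicFunc",
    location_class = "Func.refGene", zygosity = "Otherinfo"))
  expect_identical(got$gene, "PTPN11")
  expect_identical(got$pos, 112926890L)
  expect_true(all(is.na(got$SIFT)))

  # missing mandatory column is reported by name
  df2 <- df; df2$Ref <- NULL
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(df2, tmp2)
  expect_error(read_annotated_table(tmp2), "ref")
})

test_that("malformed coordinates raise row-level errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- make_variants(make_variant(), make_variant(pos = 500))
  write_annotated_table(v, tmp)
  lines <- readLines(tmp)
  lines[3] <- sub("\t500\t", "\tnotanumber\t", lines[3], fixed = TRUE)
  writeLines(lines, tmp)
  expect_error(read_annotated_table(tmp), "row.*2|2")
})

test_that("a reported-variant row parses with its locus and ClinVar id", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  fix <- study_fixture()
  sub <- fix$variants[fix$variants$variant_id ==
                        "chr12:112926890:A>G", , drop = FALSE]
  write_annotated_table(sub, tmp)
  got <- read_annotated_table(tmp)
  expect_identical(got$gene, "PTPN11")
  expect_identical(got$exon, 13L)
  expect_identical(got$hgvs_c, "c.1510A>G")
  expect_identical(got$clinvar_id, "40562")
  expect_identical(got$clinvar_class, "pathogenic")
})

test_that("VCF reader agrees with the TSV reader through INFO keys", {
  skip_if_not_installed("vcfR")
  v <- make_variants(
    make_variant(votes = 11L, clinvar_class = "VUS"),
    make_variant(gene = "SOS1", chrom = "chr2", pos = 39250000L,
                 ref = "G", alt = "T", votes = 2L, maf_1000g = 0.3))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  reg <- tool_registry()
  info_keys <- c("gene", "function_class", "location_class", "zygosity",
                 "maf_1000g", "maf_exomes", "clinvar_class")
  safe <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"x\">",
                   safe(c(info_keys, reg$tool_id))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(v)), function(i) {
    kv <- vapply(c(info_keys, reg$tool_id), function(k) {
      val <- v[[k]][i]
      if (is.na(val)) NA_character_
      else paste0(safe(k), "=", val)
    }, "")
    paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".",
          paste(stats::na.omit(kv), collapse = ";"), sep = "\t")
  }, "")
  writeLines(c(hdr, body), tmp)
  cmap <- stats::setNames(safe(c(info_keys, reg$tool_id)),
                          c(info_keys, reg$tool_id))
  got <- read_annotated_vcf(tmp, column_map = cmap)
  expect_identical(got$gene, v$gene)
  expect_identical(got$pos, v$pos)
  expect_identical(vote_count(got), vote_count(v))
  expect_identical(got$maf_1000g, v$maf_1000g)
})
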