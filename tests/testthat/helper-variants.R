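# Builders for small in-code fixtures.

# A single canonical variant row with a profile of `votes` deleterious
# calls (first `votes` registry tools), remaining slots benign, or all
# slots missing if all_missing = TRUE.
make_variant <- function(gene = "PTPN11", chrom = "chr12",
                         pos = 112926890L, ref = "A", alt = "G",
                         function_class = "missense",
                         location_class = "exonic",
                         zygosity = "heterozygous",
                         maf_1000g = NA, maf_exomes = NA,
                         clinvar_class = "not_reported",
                         clinvar_id = NA,
                         votes = 0L, all_missing = FALSE,
                         proband_id = "PB1") {
  registry <- tool_registry()
  row <- stats::setNames(
    as.list(rep(NA_character_, length(variant_columns(registry)))),
    variant_columns(registry))
  row$proband_id <- proband_id
  row$chrom <- chrom; row$pos <- as.character(pos)
  row$ref <- ref; row$alt <- alt; row$gene <- gene
  row$function_class <- function_class
  row$location_class <- location_class
  row$zygosity <- zygosity
  row$maf_1000g <- as.character(maf_1000g)
  row$maf_exomes <- as.character(maf_exomes)
  row$clinvar_class <- clinvar_class
  row$clinvar_id <- as.character(clinvar_id)
  if (!all_missing) {
    for (i in seq_len(nrow(registry))) {
      id <- registry$tool_id[i]
      hit <- i <= votes
      if (registry$kind[i] == "categorical") {
        tok <- strsplit(registry$deleterious_tokens[i], ",")[[1]][1]
        row[[id]] <- if (hit) tok else "N"
      } else {
        thr <- registry$threshold[i]
        row[[id]] <- as.character(if (hit) thr + 1 else thr / 2 - 0.01)
      }
    }
  }
  canonical_variants(
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE),
    registry = registry, source = "helper")
}

make_variants <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$.row <- seq_len(nrow(out))
  out
}

# A trio pedigree builder.
make_trio <- function(proband = "PB1", fam = "F1",
                      father_aff = "no", mother_aff = "no",
                      proband_aff = "yes") {
  data.frame(
    family_id = fam,
    member_id = c(paste0(fam, "_FA"), paste0(fam, "_MO"), proband),
    father_id = c(NA, NA, paste0(fam, "_FA")),
    mother_id = c(NA, NA, paste0(fam, "_MO")),
    sex = c("male", "female", "male"),
    affected = c(father_aff, mother_aff, proband_aff),
    stringsAsFactors = FALSE)
}

carrier_rows <- function(members, variant_id, statuses) {
  data.frame(member_id = members, variant_id = variant_id,
             carrier = statuses, stringsAsFactors = FALSE)
}
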