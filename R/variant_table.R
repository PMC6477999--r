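#' Default 14-gene Noonan syndrome panel
#'
#' Gene symbols covered by the targeted amplicon panel used for
#' RASopathy diagnostics: Ras-family GTPases and modulators/transducers
#' of Ras/MAPK signaling.
#'
#' @return Character vector of 14 gene symbols.
#' @export
default_gene_panel <- function() {
  c("A2ML1", "BRAF", "CBL", "HRAS", "KRAS", "MAP2K1", "MAP2K2",
    "NRAS", "PTPN11", "RAF1", "RIT1", "SHOC2", "SOS1", "SPRED1")
}

#' Canonical column names of an annotated variant table
#'
#' @param registry a registry from [tool_registry()].
#' @return Character vector: mandatory descriptive columns followed by
#'   the 19 predictor columns.
#' @export
variant_columns <- function(registry = tool_registry()) {
  c("proband_id", "variant_id", "chrom", "pos", "ref", "alt",
    "gene", "transcript", "exon", "hgvs_c", "hgvs_p",
    "function_class", "location_class", "zygosity",
    "maf_1000g", "maf_exomes", "clinvar_class", "clinvar_id",
    registry$tool_id)
}

.function_classes <- c("missense", "nonsense", "frameshift", "splice",
                       "synonymous", "other")
.location_classes <- c("exonic", "splicing", "intronic", "UTR",
                       "intergenic")
.zygosity_levels  <- c("heterozygous", "homozygous", "unknown")
.clinvar_classes  <- c("pathogenic", "likely_pathogenic", "VUS",
                       "likely_benign", "benign", "not_reported")

#' Validate an annotated variant table
#'
#' Checks column completeness, coordinate sanity (pos >= 1), allele
#' strings over A/C/G/T, controlled vocabularies, and allele-frequency
#' ranges. Used by the readers and before every pipeline run.
#'
#' @param variants data frame in canonical layout.
#' @param registry a registry from [tool_registry()].
#' @return The table, invisibly, on success; error otherwise.
#' @export
validate_variants <- function(variants, registry = tool_registry()) {
  need <- variant_columns(registry)
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("annotated variant table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(variants) == 0L) return(invisible(variants))
  bad_pos <- which(is.na(variants$pos) | variants$pos < 1)
  if (length(bad_pos))
    stop("malformed coordinate (pos must be >= 1) at row(s): ",
         paste(bad_pos, collapse = ", "), call. = FALSE)
  ok_allele <- function(x) grepl("^[ACGT]+$", x)
  bad_allele <- which(!ok_allele(variants$ref) | !ok_allele(variants$alt))
  if (length(bad_allele))
    stop("malformed ref/alt allele at row(s): ",
         paste(bad_allele, collapse = ", "), call. = FALSE)
  chk_vocab <- function(col, levels) {
    bad <- which(!is.na(variants[[col]]) & !(variants[[col]] %in% levels))
    if (length(bad))
      stop("invalid ", col, " value(s) at row(s): ",
           paste(bad, collapse = ", "), " (allowed: ",
           paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  chk_vocab("function_class", .function_classes)
  chk_vocab("location_class", .location_classes)
  chk_vocab("zygosity", .zygosity_levels)
  chk_vocab("clinvar_class", .clinvar_classes)
  for (col in c("maf_1000g", "maf_exomes")) {
    v <- variants[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop(col, " outside [0,1] at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(variants)
}

#' Read an annotated variant table (ANNOVAR-multianno-style TSV)
#'
#' One variant per row, tab-separated, header line; "." and empty cells
#' denote absent values. Arbitrary header names are bound to the
#' canonical fields through `column_map` (canonical name -> header name);
#' unmapped canonical-named headers are picked up directly, predictor
#' columns case-insensitively.
#'
#' @param path path to the TSV file.
#' @param column_map optional named character vector/list, canonical
#'   field -> actual header name.
#' @param registry a registry from [tool_registry()].
#' @param proband_id optional id stamped on all rows lacking one.
#' @return Validated data frame in canonical layout with a `.row`
#'   column preserving source line order for logging.
#' @export
read_annotated_table <- function(path, column_map = NULL,
                                 registry = tool_registry(),
                                 proband_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c(NA, "NA"))
  canonical_variants(raw, column_map = column_map, registry = registry,
                     proband_id = proband_id, source = path)
}

#' Coerce a raw annotation data frame into the canonical layout
#'
#' Workhorse behind [read_annotated_table()] and the VCF reader.
#' @param raw data frame of character columns as read from file.
#' @inheritParams read_annotated_table
#' @param source label used in error messages.
#' @return Validated canonical variant table.
#' @export
canonical_variants <- function(raw, column_map = NULL,
                               registry = tool_registry(),
                               proband_id = NULL, source = "input") {
  column_map <- as.list(column_map)
  hdr <- names(raw)
  pick <- function(canon) {
    if (!is.null(column_map[[canon]])) {
      j <- match(column_map[[canon]], hdr)
      if (is.na(j))
        stop(source, ": column_map binds '", canon, "' to missing header '",
             column_map[[canon]], "'", call. = FALSE)
      return(raw[[j]])
    }
    j <- match(tolower(canon), tolower(hdr))
    if (is.na(j)) return(NULL)
    raw[[j]]
  }
  blank2na <- function(x) {
    x <- as.character(x)
    x[x == "." | is.na(x) | !nzchar(trimws(x))] <- NA_character_
    x
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  mandatory <- c("chrom", "pos", "ref", "alt", "gene", "function_class",
                 "location_class", "zygosity")
  optional  <- c("proband_id", "variant_id", "transcript", "exon",
                 "hgvs_c", "hgvs_p", "maf_1000g", "maf_exomes",
                 "clinvar_class", "clinvar_id")
  miss <- character(0)
  for (canon in c(mandatory, optional)) {
    col <- pick(canon)
    if (is.null(col)) {
      if (canon %in% mandatory) miss <- c(miss, canon)
      col <- rep(NA_character_, nrow(raw))
    }
    out[[canon]] <- blank2na(col)
  }
  if (length(miss))
    stop(source, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (id in registry$tool_id) {
    col <- pick(id)
    if (is.null(col)) col <- rep(NA_character_, nrow(raw))
    out[[id]] <- blank2na(col)
  }
  # typed fields
  pos <- suppressWarnings(as.integer(out$pos))
  bad <- which(is.na(pos) & !is.na(out$pos))
  if (length(bad))
    stop(source, ": malformed coordinate at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out$pos <- pos
  out$exon <- suppressWarnings(as.integer(out$exon))
  for (col in c("maf_1000g", "maf_exomes"))
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  out$clinvar_class[is.na(out$clinvar_class)] <- "not_reported"
  if (!is.null(proband_id))
    out$proband_id[is.na(out$proband_id)] <- proband_id
  if (all(is.na(out$variant_id)))
    out$variant_id <- sprintf("%s:%d:%s>%s", out$chrom, out$pos,
                              out$ref, out$alt)
  out <- out[, variant_columns(registry)]
  out$.row <- seq_len(nrow(out))
  validate_variants(out, registry)
  out
}

#' Write an annotated variant table in the canonical TSV dialect
#'
#' Absent values are written as "."; re-reading with
#' [read_annotated_table()] reproduces field-identical records.
#'
#' @param variants canonical variant table.
#' @param path output path.
#' @param registry a registry from [tool_registry()].
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(variants, path,
                                  registry = tool_registry()) {
  validate_variants(variants, registry)
  out <- variants[, variant_columns(registry)]
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read annotated variants from a VCF file
#'
#' Fixed VCF fields supply coordinates and alleles; every other canonical
#' field is taken from an INFO key through the same column map used by
#' the TSV reader (canonical field -> INFO key). Requires the `vcfR`
#' package.
#'
#' @param path path to a VCF v4.x file (uncompressed or bgzipped).
#' @inheritParams read_annotated_table
#' @return Validated canonical variant table.
#' @export
read_annotated_vcf <- function(path, column_map = NULL,
                               registry = tool_registry(),
                               proband_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_annotated_vcf() requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info <- vcfR::INFO2df(vcf)
  raw <- data.frame(chrom = fix$CHROM, pos = fix$POS,
                    ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in names(info)) raw[[k]] <- as.character(info[[k]])
  canonical_variants(raw, column_map = column_map, registry = registry,
                     proband_id = proband_id, source = path)
}
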