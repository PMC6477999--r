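#' Filtration configuration
#'
#' Bundles every threshold of the prioritization procedure. The two vote
#' cutoffs implement the dual selection hypotheses: the "free" hypothesis
#' keeps any variant called deleterious by at least `free_cutoff` of the
#' 19 predictors; the "panel" hypothesis keeps variants in the configured
#' gene panel called deleterious by at least `panel_cutoff` tools. The
#' default mode runs both and keeps the union, tagging each survivor with
#' the hypothesis(es) that fired.
#'
#' @param maf_threshold population-frequency cutoff; variants with any
#'   present MAF at or above it are removed (default 0.01).
#' @param free_cutoff vote cutoff of the panel-free hypothesis (default 10).
#' @param panel_cutoff vote cutoff of the panel-restricted hypothesis
#'   (default 5).
#' @param panel character vector of panel gene symbols.
#' @param hypothesis_mode one of "union", "free_only", "panel_only".
#' @param retained_function_classes,retained_location_classes,required_zygosity
#'   attribute filters; defaults follow a dominant, protein-altering model.
#' @param registry predictor registry used for vote counting.
#' @return A list with class `"filter_config"`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          free_cutoff = 10L,
                          panel_cutoff = 5L,
                          panel = default_gene_panel(),
                          hypothesis_mode = c("union", "free_only",
                                              "panel_only"),
                          retained_function_classes = c("missense",
                              "nonsense", "frameshift", "splice"),
                          retained_location_classes = c("exonic",
                              "splicing"),
                          required_zygosity = "heterozygous",
                          registry = tool_registry()) {
  hypothesis_mode <- match.arg(hypothesis_mode)
  if (!(maf_threshold > 0 && maf_threshold < 1))
    stop("maf_threshold must lie in (0, 1)", call. = FALSE)
  free_cutoff <- as.integer(free_cutoff)
  panel_cutoff <- as.integer(panel_cutoff)
  if (!(panel_cutoff >= 1L && panel_cutoff <= free_cutoff &&
        free_cutoff <= 19L))
    stop("need 1 <= panel_cutoff <= free_cutoff <= 19", call. = FALSE)
  structure(list(
    maf_threshold = maf_threshold,
    free_cutoff = free_cutoff,
    panel_cutoff = panel_cutoff,
    panel = panel,
    hypothesis_mode = hypothesis_mode,
    retained_function_classes = retained_function_classes,
    retained_location_classes = retained_location_classes,
    required_zygosity = required_zygosity,
    registry = registry
  ), class = "filter_config")
}

#' Rarity filter on population allele frequencies
#'
#' A variant is retained iff every *present* MAF field is below the
#' threshold; variants with all MAF fields absent are retained (absence
#' of a population record is evidence of rarity, not of commonness).
#'
#' @param variants canonical variant table.
#' @param config a [filter_config()].
#' @return The retained subset.
#' @export
filter_by_maf <- function(variants, config = filter_config()) {
  keep_one <- function(maf) is.na(maf) | maf < config$maf_threshold
  variants[keep_one(variants$maf_1000g) & keep_one(variants$maf_exomes), ,
           drop = FALSE]
}

#' Attribute filter on zygosity, function and location
#'
#' @inheritParams filter_by_maf
#' @return Variants whose zygosity, function class and location class
#'   all belong to the configured retained sets.
#' @export
filter_by_attributes <- function(variants, config = filter_config()) {
  keep <- variants$zygosity %in% config$required_zygosity &
    variants$function_class %in% config$retained_function_classes &
    variants$location_class %in% config$retained_location_classes
  keep[is.na(keep)] <- FALSE
  variants[keep, , drop = FALSE]
}

#' Dual-hypothesis consensus vote selection
#'
#' @inheritParams filter_by_maf
#' @return Logical vectors: does each variant pass the panel-free vote
#'   cutoff / the panel-restricted cutoff?
#' @name hypotheses
NULL

#' @rdname hypotheses
#' @export
select_free_hypothesis <- function(variants, config = filter_config()) {
  vote_count(variants, config$registry) >= config$free_cutoff
}

#' @rdname hypotheses
#' @export
select_panel_hypothesis <- function(variants, config = filter_config()) {
  variants$gene %in% config$panel &
    vote_count(variants, config$registry) >= config$panel_cutoff
}

#' Apply the configured hypothesis mode
#'
#' Annotates each variant with its vote count and per-hypothesis result
#' and retains variants passing the mode ("union": either hypothesis).
#'
#' @inheritParams filter_by_maf
#' @return Retained subset with columns `votes`, `pass_free`,
#'   `pass_panel`, `hypotheses` (comma-joined provenance tag).
#' @export
apply_hypotheses <- function(variants, config = filter_config()) {
  variants$votes <- vote_count(variants, config$registry)
  variants$pass_free <- variants$votes >= config$free_cutoff
  variants$pass_panel <- variants$gene %in% config$panel &
    variants$votes >= config$panel_cutoff
  keep <- switch(config$hypothesis_mode,
                 union = variants$pass_free | variants$pass_panel,
                 free_only = variants$pass_free,
                 panel_only = variants$pass_panel)
  out <- variants[keep, , drop = FALSE]
  tag <- function(f, p) paste(c(if (f) "free", if (p) "panel"),
                              collapse = ",")
  out$hypotheses <- mapply(tag, out$pass_free, out$pass_panel,
                           USE.NAMES = FALSE)
  if (nrow(out) == 0L) out$hypotheses <- character(0)
  out
}
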