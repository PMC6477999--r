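#' The 19-predictor registry
#'
#' The prioritization pipeline consumes precomputed functional predictions
#' from 19 dbNSFP-style tools attached during annotation. Eleven tools emit
#' categorical calls (e.g. SIFT "D"/"T"), eight emit numeric scores only.
#' Each registry row records how a tool's raw output is binarized into a
#' deleterious vote: categorical tools via a set of deleterious tokens,
#' score tools via a threshold plus direction.
#'
#' Score thresholds are configurable conventions, not properties of the
#' voting procedure itself; the shipped defaults are widely used cutoffs
#' (e.g. CADD phred >= 20, DANN >= 0.96). Override them via the
#' `thresholds` argument.
#'
#' @param thresholds optional named numeric vector overriding score-tool
#'   thresholds, names matched case-insensitively against tool ids.
#' @return A data frame with one row per tool: `tool_id`, `kind`
#'   ("categorical" or "score"), `deleterious_tokens` (comma-separated,
#'   categorical only), `threshold` and `direction` (score only).
#' @examples
#' reg <- tool_registry()
#' nrow(reg)  # 19
#' tool_registry(thresholds = c(CADD = 15))
#' @export
tool_registry <- function(thresholds = NULL) {
  reg <- data.frame(
    tool_id = c(
      "SIFT", "Polyphen2_HVAR", "Polyphen2_HDIV", "MutationTaster",
      "MutationAssessor", "LRT", "FATHMM", "MetaSVM", "MetaLR",
      "PROVEAN", "fathmm-MKL",
      "GERP++", "PhyloP", "VEST3", "DANN", "CADD",
      "integrated_fitCons", "SiPhy_29way", "phastCons"
    ),
    kind = c(rep("categorical", 11L), rep("score", 8L)),
    deleterious_tokens = c(
      "D",        # SIFT: D = deleterious
      "D", "D",   # Polyphen2 HVAR / HDIV: D = probably damaging
      "A,D",      # MutationTaster: A = disease causing automatic
      "H,M",      # MutationAssessor: high / medium functional impact
      "D",        # LRT
      "D",        # FATHMM
      "D", "D",   # MetaSVM / MetaLR
      "D",        # PROVEAN
      "D",        # fathmm-MKL coding
      rep(NA_character_, 8L)
    ),
    threshold = c(
      rep(NA_real_, 11L),
      4.4,    # GERP++ RS
      1.6,    # PhyloP vertebrate
      0.5,    # VEST3
      0.96,   # DANN
      20,     # CADD phred
      0.7,    # integrated fitCons
      12.17,  # SiPhy 29-way logOdds
      0.8     # phastCons
    ),
    direction = c(rep(NA_character_, 11L), rep("ge", 8L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(thresholds)) {
    if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
      stop("`thresholds` must be a named numeric vector", call. = FALSE)
    idx <- match(tolower(names(thresholds)), tolower(reg$tool_id))
    if (anyNA(idx))
      stop("unknown tool id(s) in `thresholds`: ",
           paste(names(thresholds)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    if (any(reg$kind[idx] != "score"))
      stop("threshold override given for categorical tool(s): ",
           paste(names(thresholds)[reg$kind[idx] != "score"], collapse = ", "),
           call. = FALSE)
    reg$threshold[idx] <- as.numeric(thresholds)
  }
  stopifnot(!anyDuplicated(reg$tool_id), nrow(reg) == 19L)
  reg
}

#' Tool ids of the 19-predictor registry
#' @param registry a registry from [tool_registry()].
#' @return Character vector of the 19 tool identifiers, in registry order.
#' @export
tool_ids <- function(registry = tool_registry()) registry$tool_id

#' Resolve a tool name to its registry id, case-insensitively
#'
#' Annotation exports vary in capitalization ("Fathmm-MKL", "PhastCons").
#' @param name character vector of tool names as found in a table header.
#' @param registry a registry from [tool_registry()].
#' @return The canonical tool id(s); error on names that resolve nowhere.
#' @export
resolve_tool_id <- function(name, registry = tool_registry()) {
  idx <- match(tolower(name), tolower(registry$tool_id))
  if (anyNA(idx))
    stop("unknown predictor tool(s): ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  registry$tool_id[idx]
}

#' Binarize one predictor output into a vote
#'
#' Categorical tools vote DELETERIOUS iff the token is in the tool's
#' deleterious set; score tools iff the score satisfies the configured
#' threshold and direction. Absent values (NA, ".", "") vote MISSING.
#'
#' @param tool_id one registry tool id.
#' @param raw_value a category token, a numeric score (or its string
#'   form), or NA/"."/"" for absent. Vectorized over `raw_value`.
#' @param registry a registry from [tool_registry()].
#' @return Character vector over {"DELETERIOUS", "NOT_DELETERIOUS",
#'   "MISSING"}.
#' @examples
#' binarize_prediction("SIFT", c("D", "T", NA))
#' binarize_prediction("CADD", c(35, 12.5))
#' @export
binarize_prediction <- function(tool_id, raw_value,
                                registry = tool_registry()) {
  stopifnot(length(tool_id) == 1L)
  row <- registry[match(tolower(tool_id), tolower(registry$tool_id)), ]
  if (nrow(row) != 1L || is.na(row$tool_id))
    stop("unknown predictor tool: ", tool_id, call. = FALSE)
  raw <- as.character(raw_value)
  absent <- is.na(raw) | raw == "." | !nzchar(trimws(raw))
  out <- rep("MISSING", length(raw))
  present <- !absent
  if (!any(present)) return(out)
  if (row$kind == "categorical") {
    tokens <- strsplit(row$deleterious_tokens, ",", fixed = TRUE)[[1]]
    out[present] <- ifelse(trimws(raw[present]) %in% tokens,
                           "DELETERIOUS", "NOT_DELETERIOUS")
  } else {
    score <- suppressWarnings(as.numeric(raw[present]))
    if (anyNA(score))
      stop("non-numeric score for score-kind tool '", row$tool_id, "': ",
           paste(unique(raw[present][is.na(score)]), collapse = ", "),
           call. = FALSE)
    hit <- switch(row$direction,
                  ge = score >= row$threshold,
                  le = score <= row$threshold,
                  stop("bad direction in registry: ", row$direction))
    out[present] <- ifelse(hit, "DELETERIOUS", "NOT_DELETERIOUS")
  }
  out
}

#' Count deleterious votes for each variant
#'
#' Applies [binarize_prediction()] across the 19 predictor columns of an
#' annotated variant table and counts DELETERIOUS calls per row. MISSING
#' and NOT_DELETERIOUS both contribute zero: the vote cutoffs downstream
#' are absolute tool counts, not fractions of non-missing tools.
#'
#' @param variants annotated variant table (see [read_annotated_table()]);
#'   must carry all 19 predictor columns.
#' @param registry a registry from [tool_registry()].
#' @return Integer vector in `[0, 19]`, one count per row.
#' @export
vote_count <- function(variants, registry = tool_registry()) {
  ids <- registry$tool_id
  missing_cols <- setdiff(ids, names(variants))
  if (length(missing_cols))
    stop("variant table lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(variants) == 0L) return(integer(0))
  votes <- vapply(ids, function(id) {
    binarize_prediction(id, variants[[id]], registry) == "DELETERIOUS"
  }, logical(nrow(variants)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  as.integer(rowSums(votes))
}

#' Full vote matrix (one column per predictor)
#'
#' @inheritParams vote_count
#' @return Character matrix `nrow(variants)` x 19 over the vote vocabulary.
#' @export
vote_matrix <- function(variants, registry = tool_registry()) {
  ids <- registry$tool_id
  out <- sapply(ids, function(id)
    binarize_prediction(id, variants[[id]], registry))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(variants),
                                       dimnames = list(NULL, ids))
  out
}
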