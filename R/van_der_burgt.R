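#' Load a Van der Burgt criteria table
#'
#' The diagnostic scoring system lists six criteria, each with a major
#' (A) and a minor (B) definition; a diagnosis of definite Noonan
#' syndrome combines counts of satisfied A and B items. The table ships
#' as an editable YAML file mapping each definition to standardized
#' feature codes: a definition is satisfied when any (`any_of`) or all
#' (`all_of`) of its codes are present in the patient record.
#'
#' @param path YAML file; defaults to the packaged transcription of the
#'   scoring system.
#' @param dictionary feature dictionary used to check the referenced
#'   codes.
#' @return List of criterion definitions with class
#'   `"vdb_criteria"`.
#' @export
read_criteria <- function(path = system.file("extdata",
                            "van_der_burgt_criteria.yaml",
                            package = "panelvote", mustWork = TRUE),
                          dictionary = feature_dictionary()) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$criteria) || !length(spec$criteria))
    stop("criteria file has no 'criteria' section", call. = FALSE)
  codes <- unlist(lapply(spec$criteria, function(cr)
    c(cr$A$any_of, cr$A$all_of, cr$B$any_of, cr$B$all_of)))
  unknown <- setdiff(codes, dictionary$code)
  if (length(unknown))
    stop("criteria reference unknown feature code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ids <- vapply(spec$criteria, `[[`, "", "id")
  if (!"facies" %in% ids)
    stop("criteria must include a 'facies' criterion", call. = FALSE)
  structure(spec$criteria, class = "vdb_criteria")
}

.definition_satisfied <- function(def, present) {
  if (is.null(def)) return(FALSE)
  if (!is.null(def$all_of)) return(all(def$all_of %in% present))
  if (!is.null(def$any_of)) return(any(def$any_of %in% present))
  FALSE
}

#' Van der Burgt diagnostic score for one patient record
#'
#' Evaluates every criterion on the patient's present features (unknown
#' or absent features never satisfy a definition). A satisfied major (A)
#' definition also counts as satisfying the minor (B) definition of the
#' same criterion, so that strengthening a manifestation can never
#' withdraw a diagnosis. Definite Noonan syndrome requires:
#' typical facies (facies A) plus one other A or two other B; or
#' suggestive facies (facies B) plus two other A or three other B.
#'
#' @param record one cohort row, or a named vector/list of feature
#'   values (1/0/NA).
#' @param criteria a [read_criteria()] table.
#' @return List: `diagnosis` ("definite_NS" or "not_definite"),
#'   `satisfied` data frame (criterion, level).
#' @export
van_der_burgt_score <- function(record, criteria = read_criteria()) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  vals <- unlist(record[setdiff(names(record), .meta_columns)])
  present <- names(vals)[!is.na(vals) & vals == 1]

  ids <- vapply(criteria, `[[`, "", "id")
  a_hit <- vapply(criteria, function(cr)
    .definition_satisfied(cr$A, present), logical(1))
  b_hit <- vapply(criteria, function(cr)
    .definition_satisfied(cr$B, present), logical(1)) | a_hit

  fi <- which(ids == "facies")
  facies_a <- a_hit[fi]; facies_b <- b_hit[fi]
  n_a <- sum(a_hit[-fi]); n_b <- sum(b_hit[-fi])
  definite <- (facies_a && (n_a >= 1L || n_b >= 2L)) ||
    (facies_b && (n_a >= 2L || n_b >= 3L))

  sat <- data.frame(
    criterion = ids,
    level = ifelse(a_hit, "A", ifelse(b_hit, "B", "none")),
    stringsAsFactors = FALSE)
  list(diagnosis = if (definite) "definite_NS" else "not_definite",
       satisfied = sat[sat$level != "none", , drop = FALSE])
}
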