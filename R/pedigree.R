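#' Read a 6-column PED pedigree file
#'
#' Standard whitespace-separated PED layout: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, other = unknown),
#' affection (2 = affected, 1 = unaffected, other = unknown). "0" or "."
#' parent ids mean founder.
#'
#' @param path PED file path.
#' @return Data frame: `family_id`, `member_id`, `father_id`,
#'   `mother_id` (NA for founders), `sex` ("male"/"female"/"unknown"),
#'   `affected` ("yes"/"no"/"unknown").
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("family_id", "member_id",
                                         "father_id", "mother_id",
                                         "sex", "affected"))
  raw$father_id[raw$father_id %in% c("0", ".")] <- NA_character_
  raw$mother_id[raw$mother_id %in% c("0", ".")] <- NA_character_
  raw$sex <- c(`1` = "male", `2` = "female")[raw$sex]
  raw$sex[is.na(raw$sex)] <- "unknown"
  raw$affected <- c(`2` = "yes", `1` = "no")[raw$affected]
  raw$affected[is.na(raw$affected)] <- "unknown"
  validate_pedigree(raw)
  raw
}

#' Write a pedigree in PED format
#' @param ped pedigree data frame (see [read_ped()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  enc <- data.frame(
    ped$family_id, ped$member_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(male = "1", female = "2", unknown = "0")[ped$sex],
    c(yes = "2", no = "1", unknown = "0")[ped$affected])
  utils::write.table(enc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Structural validation of a pedigree
#'
#' Parent references must resolve within the pedigree (or be absent) and
#' no member may be its own ancestor.
#'
#' @param ped pedigree data frame.
#' @return `ped`, invisibly; error on dangling parent or cycle.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "member_id", "father_id", "mother_id",
            "sex", "affected")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop("pedigree lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ped$member_id))
    stop("duplicate member id(s) in pedigree", call. = FALSE)
  parents <- c(ped$father_id, ped$mother_id)
  dangling <- setdiff(parents[!is.na(parents)], ped$member_id)
  if (length(dangling))
    stop("dangling parent reference(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  # cycle check by repeated ancestor expansion
  for (m in ped$member_id) {
    seen <- character(0)
    frontier <- m
    while (length(frontier)) {
      i <- match(frontier, ped$member_id)
      frontier <- stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
      frontier <- setdiff(frontier, seen)
      if (m %in% frontier)
        stop("cyclic pedigree: ", m, " is its own ancestor",
             call. = FALSE)
      seen <- union(seen, frontier)
    }
  }
  invisible(ped)
}

#' Read a carrier-status table
#'
#' TSV with columns `member_id`, `variant_id`, `carrier` over
#' {carrier, non_carrier, untyped}; one row per screened member and
#' variant.
#'
#' @param path TSV path.
#' @return Data frame of carrier calls.
#' @export
read_carrier_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("member_id", "variant_id", "carrier")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("carrier table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tab$carrier),
                 c("carrier", "non_carrier", "untyped"))
  if (length(bad))
    stop("invalid carrier status value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Classify segregation of a variant through a family
#'
#' Applies, in order, a fixed rule cascade over the typed members
#' (typed = carrier status resolved to carrier or non_carrier):
#' \enumerate{
#'   \item any typed affected non-carrier, or typed unaffected carrier,
#'     contradicts co-segregation: `FAILS_TO_SEGREGATE`;
#'   \item two or more affected carrier (half-)siblings whose shared
#'     typed parent(s) are non-carriers indicate recurrence from an
#'     untransmitting parent: `POSSIBLE_GERMLINE_MOSAICISM`;
#'   \item exactly one affected carrier whose parents are both typed
#'     non-carriers: `DE_NOVO`;
#'   \item at least two typed members, every typed affected member a
#'     carrier and every typed unaffected member a non-carrier:
#'     `SEGREGATES`;
#'   \item otherwise `UNINFORMATIVE`.
#' }
#' The cascade assumes full penetrance of a dominant allele; unknown
#' affection never triggers a rule.
#'
#' @param ped pedigree data frame (see [read_ped()]).
#' @param carriers carrier-status table (see [read_carrier_table()]).
#' @param variant_id the variant whose carrier calls to use.
#' @return List with `label` and `supporting` (member ids driving the
#'   classification).
#' @export
assess_segregation <- function(ped, carriers, variant_id) {
  validate_pedigree(ped)
  cc <- carriers[carriers$variant_id == variant_id, , drop = FALSE]
  status <- cc$carrier[match(ped$member_id, cc$member_id)]
  status[is.na(status)] <- "untyped"
  typed <- status %in% c("carrier", "non_carrier")
  if (!any(typed))
    return(list(label = "UNINFORMATIVE", supporting = character(0)))

  aff <- ped$affected == "yes"
  unaff <- ped$affected == "no"
  is_car <- status == "carrier"
  is_non <- status == "non_carrier"

  conflict <- (typed & aff & is_non) | (typed & unaff & is_car)
  if (any(conflict))
    return(list(label = "FAILS_TO_SEGREGATE",
                supporting = ped$member_id[conflict]))

  ac <- which(aff & is_car)  # affected carriers
  if (length(ac) >= 2L) {
    for (i in utils::head(seq_along(ac), -1L)) for (j in seq_along(ac)) {
      if (j <= i) next
      a <- ac[i]; b <- ac[j]
      shared <- intersect(
        stats::na.omit(c(ped$father_id[a], ped$mother_id[a])),
        stats::na.omit(c(ped$father_id[b], ped$mother_id[b])))
      if (!length(shared)) next
      ps <- status[match(shared, ped$member_id)]
      if (any(ps %in% c("carrier", "non_carrier")) && all(
        ps[ps %in% c("carrier", "non_carrier")] == "non_carrier"))
        return(list(label = "POSSIBLE_GERMLINE_MOSAICISM",
                    supporting = c(ped$member_id[c(a, b)], shared)))
    }
  }

  if (length(ac) == 1L) {
    pid <- c(ped$father_id[ac], ped$mother_id[ac])
    if (!anyNA(pid)) {
      ps <- status[match(pid, ped$member_id)]
      if (all(ps == "non_carrier"))
        return(list(label = "DE_NOVO",
                    supporting = c(ped$member_id[ac], pid)))
    }
  }

  if (sum(typed) >= 2L &&
      all(is_car[typed & aff]) && all(is_non[typed & unaff]) &&
      any(typed & aff & is_car))
    return(list(label = "SEGREGATES",
                supporting = ped$member_id[typed & (aff | unaff)]))

  list(label = "UNINFORMATIVE", supporting = character(0))
}
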