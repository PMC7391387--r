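#' Case registry: eligibility filtering and deduplication
#'
#' A case registry is a data frame with one row per suspected hip-fracture
#' report. Required columns:
#' \describe{
#'   \item{case_id}{opaque record identifier (character).}
#'   \item{person_key}{opaque identifier of the individual, used for
#'     deduplication; record linkage is assumed done upstream.}
#'   \item{age}{completed years at the fracture event.}
#'   \item{sex}{`"male"` or `"female"`.}
#'   \item{event_date}{`Date` of the fracture.}
#'   \item{site_code}{proximal-femur ICD-10 site: `"S72.0"`, `"S72.1"`,
#'     `"S72.2"`, or `"unspecified"` (allowed only with
#'     `radiograph_confirmed = TRUE`).}
#'   \item{energy}{`"low"` (fall from standing height or less — the
#'     osteoporosis-relevant mechanism) or `"high"`.}
#'   \item{resident}{logical; permanent residence in the catchment area.}
#'   \item{pathological}{logical; fracture attributable to malignancy.}
#'   \item{source}{ascertainment pathway: `"inpatient"`, `"outpatient"`,
#'     `"primary_care"`, `"coroner"` or `"community"`.}
#'   \item{radiograph_confirmed}{logical.}
#' }
#'
#' @name registry
NULL

SITE_LEVELS <- c("S72.0", "S72.1", "S72.2", "unspecified")
SOURCE_LEVELS <- c("inpatient", "outpatient", "primary_care", "coroner",
                   "community")

REQUIRED_CASE_COLS <- c("case_id", "person_key", "age", "sex", "event_date",
                        "site_code", "energy", "resident", "pathological",
                        "source", "radiograph_confirmed")

#' Validate a case registry data frame
#'
#' Checks column presence and types, coerces `event_date` to `Date`, and
#' enforces the structural invariants (non-negative ages; `unspecified`
#' site codes only for radiograph-confirmed cases).
#'
#' @param cases data frame of suspected cases (see [registry]).
#' @return The validated data frame (invisibly usable), with `event_date`
#'   as `Date`.
#' @export
validate_cases <- function(cases) {
  miss <- setdiff(REQUIRED_CASE_COLS, names(cases))
  if (length(miss)) {
    stop("case registry: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cases$event_date <- as.Date(cases$event_date)
  ok_age <- !is.na(cases$age) & cases$age >= 0
  bad_site <- cases$site_code == "unspecified" &
    !isTRUE_vec(cases$radiograph_confirmed)
  if (any(bad_site, na.rm = TRUE)) {
    stop("case registry: site_code 'unspecified' requires ",
         "radiograph_confirmed = TRUE (case ",
         cases$case_id[which(bad_site)[1]], ")", call. = FALSE)
  }
  unknown_site <- !is.na(cases$site_code) & !cases$site_code %in% SITE_LEVELS
  if (any(unknown_site)) {
    stop("case registry: unknown site_code ",
         cases$site_code[which(unknown_site)[1]], call. = FALSE)
  }
  if (any(!ok_age & !is.na(cases$age))) {
    stop("case registry: negative age (case ",
         cases$case_id[which(!ok_age & !is.na(cases$age))[1]], ")",
         call. = FALSE)
  }
  cases
}

isTRUE_vec <- function(x) !is.na(x) & x

new_filter_report <- function(n_input, steps, removed) {
  structure(list(n_input = n_input,
                 n_after_each_filter = steps,
                 n_eligible = if (nrow(steps)) steps$remaining[nrow(steps)] else n_input,
                 removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$n_input, "record(s) in,", x$n_eligible,
      "eligible\n")
  if (nrow(x$n_after_each_filter)) {
    print(x$n_after_each_filter, row.names = FALSE)
  }
  invisible(x)
}

#' Apply the eligibility filters of a low-energy hip-fracture study
#'
#' Reduces raw multi-source reports to countable cases. Filters run in the
#' fixed order window, residence, age, energy, pathological, so every
#' removed record carries a single primary reason. (Any order yields the
#' same surviving set; order only affects reason attribution.) Records with
#' a missing sex or age are removed first with reason `"malformed"`.
#'
#' @param cases case registry data frame (see [registry]).
#' @param window length-2 `Date` vector (inclusive study window).
#' @param min_age minimum age in completed years (default 40).
#' @return A list with `cases` (the eligible subset) and `report`
#'   (a `filter_report`: input count, count remaining after each filter,
#'   and a `removed` data frame of `case_id`, `reason`).
#' @examples
#' fx <- make_district_fixture()
#' out <- apply_eligibility_filters(fx$cases, fx$window)
#' out$report
#' @export
apply_eligibility_filters <- function(cases, window, min_age = 40) {
  window <- as.Date(window)
  if (length(window) != 2 || anyNA(window) || window[1] > window[2]) {
    stop("window must be two ordered dates", call. = FALSE)
  }
  if (min_age < 0) stop("min_age must be >= 0", call. = FALSE)
  if (nrow(cases) == 0) {
    steps <- data.frame(filter = character(), remaining = integer())
    return(list(cases = cases,
                report = new_filter_report(0L, steps,
                                           data.frame(case_id = character(),
                                                      reason = character()))))
  }
  cases <- validate_cases(cases)

  removed <- list()
  steps <- list()
  keep <- rep(TRUE, nrow(cases))

  drop <- function(bad, reason) {
    bad <- bad & keep
    if (any(bad)) {
      removed[[length(removed) + 1]] <<-
        data.frame(case_id = cases$case_id[bad], reason = reason)
    }
    keep <<- keep & !bad
    steps[[length(steps) + 1]] <<-
      data.frame(filter = reason, remaining = sum(keep))
  }

  drop(is.na(cases$sex) | is.na(cases$age) | is.na(cases$event_date),
       "malformed")
  drop(cases$event_date < window[1] | cases$event_date > window[2], "window")
  drop(!isTRUE_vec(cases$resident), "residence")
  drop(cases$age < min_age, "age")
  drop(cases$energy != "low", "energy")
  drop(isTRUE_vec(cases$pathological), "pathological")

  steps <- do.call(rbind, steps)
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(case_id = character(), reason = character())
  list(cases = cases[keep, , drop = FALSE],
       report = new_filter_report(nrow(cases), steps, removed))
}

#' Collapse repeat reports of the same fracture
#'
#' Within the observation window, repeat admissions or reports for the same
#' fracture site in the same individual count once: for each
#' `(person_key, site_code)` group only the earliest `event_date` record is
#' retained. Ties on date prefer the radiograph-confirmed record, then the
#' lexicographically smallest `case_id`. Distinct sites in one person are
#' distinct fractures and are all retained.
#'
#' @param cases case registry data frame.
#' @return A list with `cases` (deduplicated) and `report`
#'   (a `filter_report` whose removals carry reason `"duplicate"`).
#' @export
deduplicate <- function(cases) {
  if (nrow(cases) == 0) {
    steps <- data.frame(filter = "duplicate", remaining = 0L)
    return(list(cases = cases,
                report = new_filter_report(0L, steps,
                                           data.frame(case_id = character(),
                                                      reason = character()))))
  }
  cases <- validate_cases(cases)
  grp <- paste(cases$person_key, cases$site_code, sep = "\r")
  # order so the record to keep sorts first within each group
  ord <- order(grp, cases$event_date, !isTRUE_vec(cases$radiograph_confirmed),
               cases$case_id)
  first <- !duplicated(grp[ord])
  keep_ids <- cases$case_id[ord][first]
  keep <- cases$case_id %in% keep_ids
  removed <- if (any(!keep)) {
    data.frame(case_id = cases$case_id[!keep], reason = "duplicate")
  } else {
    data.frame(case_id = character(), reason = character())
  }
  steps <- data.frame(filter = "duplicate", remaining = sum(keep))
  list(cases = cases[keep, , drop = FALSE],
       report = new_filter_report(nrow(cases), steps, removed))
}
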