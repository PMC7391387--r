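#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' For an observed count `k` over `E` person-years, the exact two-sided
#' interval on the rate is built from chi-square quantiles:
#' \deqn{lo = \chi^2_{\alpha/2, 2k} / (2E), \quad
#'       hi = \chi^2_{1-\alpha/2, 2k+2} / (2E),}
#' with `lo = 0` when `k = 0`. The interval guarantees at least
#' `1 - alpha` coverage for any true Poisson mean, at the price of mild
#' conservatism for small counts. Returned per 100,000 person-years.
#'
#' @param k non-negative integer event count (vectorised).
#' @param E person-years at risk, > 0 (vectorised).
#' @param alpha two-sided non-coverage level (default 0.05).
#' @return A data frame with columns `lo`, `hi` (rates per 100,000).
#' @examples
#' poisson_exact_ci(2, 7480)   # ~ (3, 97) per 100,000 after rounding
#' @export
poisson_exact_ci <- function(k, E, alpha = 0.05) {
  if (any(E <= 0)) stop("nonpositive exposure", call. = FALSE)
  if (any(k < 0) || any(k != trunc(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  lo <- ifelse(k == 0, 0, stats::qchisq(alpha / 2, 2 * k) / 2) / E * 1e5
  hi <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2 / E * 1e5
  data.frame(lo = lo, hi = hi)
}

#' Age/sex-specific incidence with exact confidence intervals
#'
#' Tallies eligible cases into the population table's bands and computes
#' per-band rates per 100,000 person-years with exact Poisson intervals.
#' Person-years are the census headcount times the 1-year window; no
#' mid-year adjustment is applied.
#'
#' @param cases eligible case registry (after [apply_eligibility_filters]
#'   and [deduplicate]).
#' @param pop population band table: columns `sex`, `age_lo`, `age_hi`,
#'   `count`.
#' @param alpha confidence level complement (default 0.05).
#' @return A data frame with one row per band: `sex`, `age_lo`, `age_hi`,
#'   `population`, `events`, `rate_per_100k`, `ci_lo`, `ci_hi` (all
#'   unrounded; use [round_display] for table-style formatting).
#' @export
band_incidence <- function(cases, pop, alpha = 0.05) {
  validate_bands(pop, "population table")
  if (!"count" %in% names(pop)) {
    stop("population table: missing column count", call. = FALSE)
  }
  if (any(pop$count < 0)) stop("population counts must be >= 0", call. = FALSE)
  idx <- band_match(cases$sex, cases$age, pop)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("case %s (sex %s, age %s) falls in no population band",
                 cases$case_id[bad], cases$sex[bad], cases$age[bad]),
         call. = FALSE)
  }
  k <- tabulate(idx, nbins = nrow(pop))
  E <- pop$count
  rate <- ifelse(E > 0, 1e5 * k / E, ifelse(k == 0, 0, NA_real_))
  if (anyNA(rate)) {
    stop("events observed in a band with zero population", call. = FALSE)
  }
  ci <- data.frame(lo = numeric(nrow(pop)), hi = numeric(nrow(pop)))
  pos <- E > 0
  if (any(pos)) ci[pos, ] <- poisson_exact_ci(k[pos], E[pos], alpha)
  out <- data.frame(sex = pop$sex, age_lo = pop$age_lo, age_hi = pop$age_hi,
                    population = E, events = k,
                    rate_per_100k = rate, ci_lo = ci$lo, ci_hi = ci$hi)
  out[order(out$sex, out$age_lo), ]
}

#' Crude incidence by sex and the female/male rate ratio
#'
#' @inheritParams band_incidence
#' @param min_age lower age cut for the denominator and numerator
#'   (default 40).
#' @return A list with `rate_f`, `rate_m` (per 100,000, unrounded),
#'   `ratio` (female/male, computed on unrounded rates; `NA` with a
#'   warning when the male denominator is zero), and the underlying
#'   `events` / `person_years` per sex.
#' @export
crude_incidence <- function(cases, pop, min_age = 40) {
  validate_bands(pop, "population table")
  keep_band <- pop$age_lo >= min_age
  keep_case <- cases$age >= min_age
  ev <- function(s) sum(cases$sex[keep_case] == s)
  py <- function(s) sum(pop$count[keep_band & pop$sex == s])
  kf <- ev("female"); km <- ev("male")
  Ef <- py("female"); Em <- py("male")
  rate_f <- if (Ef > 0) 1e5 * kf / Ef else NA_real_
  rate_m <- if (Em > 0) 1e5 * km / Em else NA_real_
  ratio <- if (!is.na(rate_m) && rate_m > 0) rate_f / rate_m else {
    warning("female/male ratio undefined (zero male rate or population)")
    NA_real_
  }
  list(rate_f = rate_f, rate_m = rate_m, ratio = ratio,
       events = c(female = kf, male = km),
       person_years = c(female = Ef, male = Em))
}

#' Ascertainment-source breakdown of eligible cases
#'
#' Counts cases by the care pathway through which they were identified.
#' Counts are primary; the unrounded fraction is kept alongside the
#' integer-rounded percent so display rounding never propagates.
#'
#' @param cases eligible case registry.
#' @return A data frame with one row per source (all five levels always
#'   present): `source`, `count`, `fraction`, `percent`.
#' @export
ascertainment_breakdown <- function(cases) {
  unknown <- !cases$source %in% SOURCE_LEVELS
  if (any(unknown)) {
    stop("unknown ascertainment source: ",
         cases$source[which(unknown)[1]], call. = FALSE)
  }
  n <- nrow(cases)
  counts <- table(factor(cases$source, levels = SOURCE_LEVELS))
  frac <- if (n > 0) as.numeric(counts) / n else rep(0, length(counts))
  data.frame(source = SOURCE_LEVELS,
             count = as.integer(counts),
             fraction = frac,
             percent = round_display(100 * frac))
}
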