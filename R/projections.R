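#' Project fracture counts onto population pyramids
#'
#' Applies fixed age/sex-specific rates to population pyramids per calendar
#' year: the expected count for a year and sex is the sum over bands at or
#' above `min_age` of rate times persons. Rates are held constant over
#' calendar time (the standard stable-incidence assumption of demographic
#' burden projections); catchment-to-national scaling is expressed simply
#' by supplying national pyramids.
#'
#' @param rates rate table: `sex`, `age_lo`, `age_hi`, `rate` (events per
#'   person-year).
#' @param pyramids long-format pyramid table: `calendar_year`, `sex`,
#'   `age_lo`, `age_hi`, `persons`.
#' @param min_age lower age cut for the projection (default 50).
#' @param outcome label for the output rows (default `"hip"`).
#' @return A data frame: `calendar_year`, `sex`, `outcome`,
#'   `expected_count` (unrounded).
#' @export
project_counts <- function(rates, pyramids, min_age = 50, outcome = "hip") {
  validate_bands(rates, "rate table")
  req <- c("calendar_year", "sex", "age_lo", "age_hi", "persons")
  miss <- setdiff(req, names(pyramids))
  if (length(miss)) stop("pyramid table: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(pyramids$persons < 0)) stop("persons must be >= 0", call. = FALSE)
  py <- pyramids[pyramids$age_lo >= min_age, , drop = FALSE]
  j <- band_join(py, rates, "rate table")
  py$expected <- py$persons * rates$rate[j]
  agg <- stats::aggregate(expected ~ calendar_year + sex, data = py, FUN = sum)
  out <- data.frame(calendar_year = agg$calendar_year, sex = agg$sex,
                    outcome = outcome, expected_count = agg$expected)
  out[order(out$calendar_year, out$sex), ]
}

#' Parametric uncertainty band around a projected count
#'
#' Poisson draws around the expected count; reports the 2.5 and 97.5
#' percentile counts. Deterministic under a fixed seed. The source study
#' style of projection reports point estimates only; this band quantifies
#' pure Poisson counting noise, not demographic or rate uncertainty.
#'
#' @param expected_count non-negative expected count (single value, or a
#'   `ProjectionResult`-style data frame row subset via
#'   `$expected_count`).
#' @param n_draws number of draws (>= 100).
#' @param seed integer RNG seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
uncertainty_bands <- function(expected_count, n_draws = 10000, seed = 1) {
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  if (expected_count < 0) stop("expected_count must be >= 0", call. = FALSE)
  draws <- with_seed(seed, stats::rpois(n_draws, expected_count))
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 1)
  c(lo = q[1], hi = q[2])
}

# Evaluate `expr` under a temporary RNG state; restores (or removes) the
# global .Random.seed afterwards so no package function leaks RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
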