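#' Piecewise-constant hazard schedules
#'
#' A hazard schedule holds a per-year event rate that is constant between
#' consecutive age knots, the resolution at which registry and mortality
#' data arrive (5-year bands). Keeping hazards piecewise constant makes
#' every survival and probability integral closed form — no quadrature
#' error anywhere in the probability chain.
#'
#' @param sex `"male"` or `"female"`.
#' @param knots strictly increasing ages; the schedule covers
#'   `[knots[1], knots[n]]` and the last knot is the terminal age
#'   (absorbing truncation: everyone dead or censored there).
#' @param hazard per-year rates, one per interval (`length(knots) - 1`),
#'   all finite and non-negative.
#' @return An object of class `hazard_schedule`.
#' @export
hazard_schedule <- function(sex, knots, hazard) {
  stopifnot(length(knots) >= 2, length(hazard) == length(knots) - 1)
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing",
                                  call. = FALSE)
  if (any(!is.finite(hazard)) || any(hazard < 0)) {
    stop("hazards must be finite and >= 0", call. = FALSE)
  }
  structure(list(sex = sex, knots = as.numeric(knots),
                 hazard = as.numeric(hazard),
                 terminal_age = knots[length(knots)]),
            class = "hazard_schedule")
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat("Piecewise-constant hazard schedule (", x$sex, "), ",
      length(x$hazard), " interval(s) on [", x$knots[1], ", ",
      x$terminal_age, "]\n", sep = "")
  invisible(x)
}

#' Build a hazard schedule from a banded rate table
#'
#' Band rates become the constant hazard on each band; the open terminal
#' band's rate extends to `terminal_age`; below the first band the hazard
#' is 0 (the schedule supports ages from 0).
#'
#' @param rt rate table: columns `sex`, `age_lo`, `age_hi`, `rate`
#'   (events per person-year).
#' @param sex which sex to extract.
#' @param terminal_age absorbing truncation age (default 110).
#' @return A `hazard_schedule`.
#' @examples
#' rt <- data.frame(sex = "female", age_lo = 40, age_hi = NA, rate = 0.01)
#' schedule_from_rate_table(rt, "female")
#' @export
schedule_from_rate_table <- function(rt, sex, terminal_age = 110) {
  validate_bands(rt, "rate table")
  if (!"rate" %in% names(rt)) stop("rate table: missing column rate",
                                   call. = FALSE)
  b <- rt[rt$sex == sex, ]
  if (nrow(b) == 0) stop("rate table: no bands for sex ", sex, call. = FALSE)
  if (any(!is.finite(b$rate)) || any(b$rate < 0)) {
    stop("rate table: rates must be finite and >= 0", call. = FALSE)
  }
  b <- b[order(b$age_lo), ]
  last_hi <- b$age_hi[nrow(b)]
  if (!is.na(last_hi) && last_hi > terminal_age ||
      terminal_age <= b$age_lo[nrow(b)]) {
    stop("terminal_age must exceed the last band start", call. = FALSE)
  }
  knots <- c(b$age_lo, terminal_age)
  hazard <- b$rate
  if (b$age_lo[1] > 0) {       # hazard 0 below the first band
    knots <- c(0, knots)
    hazard <- c(0, hazard)
  }
  # a closed last band whose upper bound is below terminal_age keeps its
  # own rate up to its bound and would leave a gap beyond it; extend the
  # last band's rate to terminal_age (same convention as the open band)
  hazard_schedule(sex, knots, hazard)
}

# Integrated hazard over [from, to] for one schedule (closed form).
cumulative_hazard <- function(schedule, from, to) {
  k <- schedule$knots
  if (from < k[1] || to > k[length(k)]) {
    stop("age outside schedule support [", k[1], ", ", k[length(k)], "]",
         call. = FALSE)
  }
  lo <- pmax(k[-length(k)], from)
  hi <- pmin(k[-1], to)
  sum(schedule$hazard * pmax(hi - lo, 0))
}

#' Event-free survival between two ages
#'
#' Probability of remaining alive and event-free from `from_age` to
#' `to_age`: `exp(-integral of (h_d + h_e))`, computed segment by segment
#' in closed form.
#'
#' @param schedule_death all-cause mortality `hazard_schedule`.
#' @param schedule_event event (fracture) `hazard_schedule`, or `NULL` for
#'   plain survival.
#' @param from_age,to_age ages with `from_age <= to_age`, inside both
#'   schedules' support.
#' @return A probability in (0, 1].
#' @examples
#' s <- hazard_schedule("female", c(0, 110), 0.05)
#' e <- hazard_schedule("female", c(0, 110), 0.01)
#' survival(s, e, 60, 70)  # exp(-0.6)
#' @export
survival <- function(schedule_death, schedule_event = NULL, from_age, to_age) {
  if (from_age > to_age) stop("from_age must be <= to_age", call. = FALSE)
  ch <- cumulative_hazard(schedule_death, from_age, to_age)
  if (!is.null(schedule_event)) {
    ch <- ch + cumulative_hazard(schedule_event, from_age, to_age)
  }
  exp(-ch)
}
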