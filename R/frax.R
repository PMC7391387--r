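#' Risk profile: a multiplicative relative risk on the fracture hazard
#'
#' A deliberately minimal stand-in for a clinical-risk-factor model: the
#' supplied relative risk scales the fracture hazard at every age. The full
#' multi-factor machinery with age-varying coefficients used by calibrated
#' national tools is proprietary and out of scope; a single multiplier
#' (e.g. ~1.8 for a prior fragility fracture) captures the mechanics.
#'
#' @param relative_risk positive multiplicative factor on the fracture
#'   hazard (default 1 = population average).
#' @param label free-text description.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(relative_risk = 1, label = "population average") {
  if (!is.numeric(relative_risk) || length(relative_risk) != 1 ||
      !is.finite(relative_risk) || relative_risk <= 0) {
    stop("relative_risk must be a single positive number", call. = FALSE)
  }
  structure(list(relative_risk = relative_risk, label = label),
            class = "risk_profile")
}

#' Impute major-osteoporotic-fracture rates from hip rates
#'
#' In settings with reliable hip-fracture surveillance but no direct data
#' on clinical spine, forearm and humerus fractures, MOF incidence is
#' imputed band-wise as hip rate times an age/sex-specific MOF/hip ratio
#' (the ratios observed in well-characterised Scandinavian registers are
#' conventionally assumed transferable). Ratios must be >= 1 since MOF
#' includes hip.
#'
#' @param hip rate table (`sex`, `age_lo`, `age_hi`, `rate`); any rate
#'   units, preserved in the output.
#' @param rho ratio table (`sex`, `age_lo`, `age_hi`, `rho`) covering the
#'   same bands.
#' @return A rate table of MOF rates on the same bands and units.
#' @export
impute_mof_incidence <- function(hip, rho) {
  validate_bands(hip, "hip rate table")
  validate_bands(rho, "ratio table")
  if (!"rate" %in% names(hip)) stop("hip table: missing column rate",
                                    call. = FALSE)
  if (!"rho" %in% names(rho)) stop("ratio table: missing column rho",
                                   call. = FALSE)
  if (any(rho$rho < 1)) {
    stop("MOF/hip ratios must be >= 1 (MOF includes hip)", call. = FALSE)
  }
  j <- band_join(hip, rho, "ratio table")
  out <- hip
  out$rate <- hip$rate * rho$rho[j]
  out
}

# Shared closed-form integrator. Walks the merged knot grid of the two
# schedules over [start_age, start_age + horizon]; within a segment of
# constant hazards (f, d) entered with event-free mass S0, the first-event
# probability contribution is S0 * f/(f+d) * (1 - exp(-(f+d)*dt)), death
# first analogously with d/(f+d).
integrate_first_event <- function(schedule_fracture, schedule_death,
                                  start_age, horizon, rr) {
  end_age <- start_age + horizon
  cuts <- sort(unique(c(schedule_fracture$knots, schedule_death$knots,
                        start_age, end_age)))
  cuts <- cuts[cuts >= start_age & cuts <= end_age]
  S0 <- 1
  p_frac <- 0
  p_death <- 0
  n_seg <- 0L
  haz_at <- function(s, a) {
    i <- findInterval(a, s$knots, rightmost.closed = TRUE)
    s$hazard[min(max(i, 1L), length(s$hazard))]
  }
  if (length(cuts) >= 2) {
    for (i in seq_len(length(cuts) - 1)) {
      a <- cuts[i]; b <- cuts[i + 1]
      dt <- b - a
      if (dt <= 0) next
      f <- rr * haz_at(schedule_fracture, a)
      d <- haz_at(schedule_death, a)
      tot <- f + d
      if (tot > 0) {
        gone <- S0 * (1 - exp(-tot * dt))
        p_frac <- p_frac + gone * f / tot
        p_death <- p_death + gone * d / tot
        S0 <- S0 * exp(-tot * dt)
      }
      n_seg <- n_seg + 1L
    }
  }
  list(p_fracture = p_frac, p_death_first = p_death, p_event_free = S0,
       n_segments = n_seg)
}

new_probability_result <- function(sex, start_age, horizon, outcome, rr,
                                   parts) {
  structure(list(sex = sex, start_age = start_age, horizon = horizon,
                 outcome = outcome, relative_risk = rr,
                 probability = parts$p_fracture,
                 p_death_first = parts$p_death_first,
                 p_event_free = parts$p_event_free,
                 n_segments = parts$n_segments,
                 notes = "all-cause mortality; no post-fracture excess mortality modelled"),
            class = "probability_result")
}

#' @export
print.probability_result <- function(x, ...) {
  cat(sprintf("%s fracture probability: %s, age %g, horizon %s, RR %g\n",
              x$outcome, x$sex, x$start_age,
              if (is.numeric(x$horizon)) paste0(x$horizon, "y") else x$horizon,
              x$relative_risk))
  cat(sprintf("  P(fracture) = %.5f  (death first %.5f, event-free %.5f)\n",
              x$probability, x$p_death_first, x$p_event_free))
  invisible(x)
}

#' Fracture probability over a horizon under competing risk of death
#'
#' Probability of a first fracture within `horizon_years` of `start_age`,
#' integrating the (relative-risk-scaled) fracture hazard against joint
#' fracture/death survival:
#' \deqn{P = \int_0^T RR\,h_f(a+t)\,
#'   e^{-\int_0^t (RR\,h_f + h_d)\,du}\, dt,}
#' evaluated exactly segment by segment on the piecewise-constant hazards.
#' First fracture is the absorbing event; death beforehand removes the
#' individual from risk.
#'
#' @param schedule_fracture fracture `hazard_schedule`.
#' @param schedule_death all-cause mortality `hazard_schedule` (same sex).
#' @param start_age age at assessment.
#' @param horizon_years horizon length (10 for the conventional 10-year
#'   probability); `start_age + horizon_years` must not exceed the
#'   terminal age.
#' @param profile a [risk_profile] (default RR 1).
#' @param outcome label stored in the result (`"hip"` or `"MOF"`).
#' @return A `probability_result`: `probability`, the complementary
#'   `p_death_first` and `p_event_free` masses (the three sum to 1), and
#'   the number of closed-form segments used.
#' @examples
#' f <- hazard_schedule("female", c(0, 110), 0.01)
#' d <- hazard_schedule("female", c(0, 110), 0.05)
#' fracture_probability(f, d, 70, 10)  # (0.01/0.06) * (1 - exp(-0.6))
#' @export
fracture_probability <- function(schedule_fracture, schedule_death,
                                 start_age, horizon_years,
                                 profile = risk_profile(),
                                 outcome = "hip") {
  if (horizon_years < 0) stop("horizon must be >= 0", call. = FALSE)
  if (!identical(schedule_fracture$sex, schedule_death$sex)) {
    stop("fracture and death schedules must be for the same sex",
         call. = FALSE)
  }
  end_age <- start_age + horizon_years
  for (s in list(schedule_fracture, schedule_death)) {
    if (start_age < s$knots[1] || end_age > s$terminal_age) {
      stop("hazards undefined over [", start_age, ", ", end_age, "]",
           call. = FALSE)
    }
  }
  parts <- integrate_first_event(schedule_fracture, schedule_death,
                                 start_age, horizon_years,
                                 profile$relative_risk)
  new_probability_result(schedule_fracture$sex, start_age, horizon_years,
                         outcome, profile$relative_risk, parts)
}

#' Remaining lifetime fracture probability
#'
#' The same first-event integral with the horizon extended to the terminal
#' age of the schedules — the probability of ever sustaining the fracture
#' between `start_age` and the end of life, accounting for mortality.
#'
#' @inheritParams fracture_probability
#' @return A `probability_result` with `horizon = "lifetime"`.
#' @export
lifetime_probability <- function(schedule_fracture, schedule_death,
                                 start_age, profile = risk_profile(),
                                 outcome = "hip") {
  terminal <- min(schedule_fracture$terminal_age,
                  schedule_death$terminal_age)
  if (start_age >= terminal) stop("start_age must be below the terminal age",
                                  call. = FALSE)
  res <- fracture_probability(schedule_fracture, schedule_death, start_age,
                              terminal - start_age, profile, outcome)
  res$horizon <- "lifetime"
  res
}

#' Hip and MOF probability table over ages and sexes
#'
#' Convenience wrapper producing, for each requested age and each sex
#' present in the inputs, the hip and the (ratio-imputed) MOF fracture
#' probability over a common horizon.
#'
#' @param hip hip rate table (`rate` in events per person-year).
#' @param rho MOF/hip ratio table covering the same bands.
#' @param mortality all-cause mortality rate table (per person-year).
#' @param ages start ages to evaluate.
#' @param horizon years, or `"lifetime"`.
#' @param profile a [risk_profile].
#' @param terminal_age schedule truncation age (default 110).
#' @return A data frame: `sex`, `age`, `outcome`, `horizon`, `rr`,
#'   `probability` (full precision) and `probability_pct` (one decimal).
#' @export
probability_table <- function(hip, rho, mortality, ages, horizon = 10,
                              profile = risk_profile(), terminal_age = 110) {
  mof <- impute_mof_incidence(hip, rho)
  sexes <- intersect(SEX_LEVELS, unique(hip$sex))
  rows <- list()
  for (s in sexes) {
    sd <- schedule_from_rate_table(mortality, s, terminal_age)
    sf_hip <- schedule_from_rate_table(hip, s, terminal_age)
    sf_mof <- schedule_from_rate_table(mof, s, terminal_age)
    for (age in ages) {
      for (out in c("hip", "MOF")) {
        sf <- if (out == "hip") sf_hip else sf_mof
        res <- if (identical(horizon, "lifetime")) {
          lifetime_probability(sf, sd, age, profile, out)
        } else {
          fracture_probability(sf, sd, age, horizon, profile, out)
        }
        rows[[length(rows) + 1]] <- data.frame(
          sex = s, age = age, outcome = out,
          horizon = if (identical(horizon, "lifetime")) "lifetime"
                    else as.character(horizon),
          rr = profile$relative_risk,
          probability = res$probability,
          probability_pct = round(100 * res$probability, 1))
      }
    }
  }
  do.call(rbind, rows)
}
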