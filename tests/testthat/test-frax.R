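district_rate_tables <- function() {
  ch <- district_chain()
  inc <- ch$incidence
  hip <- data.frame(sex = inc$sex, age_lo = inc$age_lo, age_hi = inc$age_hi,
                    rate = inc$rate_per_100k / 1e5)
  bands <- hip[, c("sex", "age_lo", "age_hi")]
  mort <- rbind(
    simulate_mortality("gompertz", list(a = 4e-5, b = 0.090),
                       bands[bands$sex == "male", ]),
    simulate_mortality("gompertz", list(a = 2e-5, b = 0.095),
                       bands[bands$sex == "female", ]))
  list(hip = hip, mort = mort, bands = bands)
}

test_that("MOF imputation is band-wise multiplication", {
  hip <- data.frame(sex = "female", age_lo = 65, age_hi = 70, rate = 630e-5)
  rho <- data.frame(sex = "female", age_lo = 65, age_hi = 70, rho = 4)
  expect_equal(impute_mof_incidence(hip, rho)$rate, 2520e-5)

  rts <- district_rate_tables()
  rho1 <- rts$bands; rho1$rho <- 1
  expect_equal(impute_mof_incidence(rts$hip, rho1)$rate, rts$hip$rate)

  set.seed(21)
  rhoR <- rts$bands; rhoR$rho <- runif(nrow(rhoR), 1, 8)
  got <- impute_mof_incidence(rts$hip, rhoR)
  # element-wise spreadsheet oracle via an independent merge
  m <- merge(rts$hip, rhoR, by = c("sex", "age_lo"))
  m <- m[order(m$sex, m$age_lo), ]
  g <- got[order(got$sex, got$age_lo), ]
  expect_equal(g$rate, m$rate * m$rho, tolerance = 1e-12)

  expect_error(impute_mof_incidence(rts$hip, rhoR[-1, ]), "cover")
  bad <- rhoR; bad$rho[3] <- 0.5
  expect_error(impute_mof_incidence(rts$hip, bad), ">= 1")
})

test_that("fracture probability matches hand-checkable closed forms", {
  f <- const_schedule(0.01)
  d <- const_schedule(0.05)
  res <- fracture_probability(f, d, 70, 10)
  expect_equal(res$probability, (0.01 / 0.06) * (1 - exp(-0.6)),
               tolerance = 1e-12)
  # no competing risk: pure exponential
  z <- const_schedule(0)
  expect_equal(fracture_probability(f, z, 70, 10)$probability,
               1 - exp(-0.1), tolerance = 1e-12)
  # with RR folded into the no-mortality limit, equality is exact
  expect_equal(fracture_probability(f, z, 50, 20,
                                    risk_profile(2.5))$probability,
               1 - exp(-2.5 * 0.01 * 20), tolerance = 1e-12)
  expect_error(fracture_probability(f, d, 70, -1), "horizon")
  expect_error(fracture_probability(f, d, 105, 10), "undefined")
})

test_that("fracture + death-first + event-free mass is conserved", {
  rts <- district_rate_tables()
  for (s in c("male", "female")) {
    sf <- schedule_from_rate_table(rts$hip, s)
    sd <- schedule_from_rate_table(rts$mort, s)
    for (age in c(50, 67.5, 80)) {
      res <- fracture_probability(sf, sd, age, 10, risk_profile(1.85))
      expect_lt(abs(res$probability + res$p_death_first +
                    res$p_event_free - 1), 1e-12)
    }
  }
})

test_that("closed-form integration agrees with the discrete-time Markov and refinement oracles", {
  rts <- district_rate_tables()
  sf <- schedule_from_rate_table(rts$hip, "female")
  sd <- schedule_from_rate_table(rts$mort, "female")
  for (cfg in list(list(age = 70, rr = 1), list(age = 55, rr = 2))) {
    res <- fracture_probability(sf, sd, cfg$age, 10, risk_profile(cfg$rr))
    mk <- oracle_markov(sf, sd, cfg$age, 10, cfg$rr, dt = 1e-4)
    expect_close(res$probability, mk$p_fracture, tol = 1e-6)
    expect_close(res$p_death_first, mk$p_death_first, tol = 1e-6)
    expect_close(res$p_event_free, mk$p_event_free, tol = 1e-6)
    expect_close(res$probability,
                 oracle_refine(sf, sd, cfg$age, 10, cfg$rr), tol = 1e-10)
  }
})

test_that("probability is monotone in horizon, RR and the hazards; sub-multiplicative in RR", {
  rts <- district_rate_tables()
  sf <- schedule_from_rate_table(rts$hip, "male")
  sd <- schedule_from_rate_table(rts$mort, "male")
  p <- function(...) fracture_probability(...)$probability
  p5 <- p(sf, sd, 60, 5); p10 <- p(sf, sd, 60, 10); p20 <- p(sf, sd, 60, 20)
  expect_true(p5 < p10 && p10 < p20)
  p_rr1 <- p(sf, sd, 60, 10); p_rr2 <- p(sf, sd, 60, 10, risk_profile(2))
  expect_gt(p_rr2, p_rr1)
  expect_lt(p_rr2, 2 * p_rr1)  # sub-multiplicativity under competing risk
  # uniform 10% rate increase raises every probability
  up <- rts$hip; up$rate <- up$rate * 1.1
  expect_gt(p(schedule_from_rate_table(up, "male"), sd, 60, 10), p_rr1)
  # higher mortality lowers fracture probability
  mort_up <- rts$mort; mort_up$rate <- mort_up$rate * 2
  expect_lt(p(sf, schedule_from_rate_table(mort_up, "male"), 60, 10), p_rr1)
})

test_that("lifetime probability is the same integral run to the terminal age", {
  f <- const_schedule(0.002)
  d <- const_schedule(0.02)
  res <- lifetime_probability(f, d, 50)
  expect_equal(res$probability, (0.002 / 0.022) * (1 - exp(-1.32)),
               tolerance = 1e-12)
  expect_identical(res$horizon, "lifetime")
  z <- const_schedule(0)
  expect_equal(lifetime_probability(z, d, 50)$probability, 0)

  rts <- district_rate_tables()
  sf <- schedule_from_rate_table(rts$hip, "female")
  sd <- schedule_from_rate_table(rts$mort, "female")
  lt <- lifetime_probability(sf, sd, 50)
  expect_gt(lt$probability, 0); expect_lt(lt$probability, 1)
  expect_close(lt$probability, oracle_refine(sf, sd, 50, 60), tol = 1e-10)
  expect_equal(lt$probability,
               fracture_probability(sf, sd, 50, 60)$probability)
})

test_that("probability tables have the right shape and respect rho >= 1 dominance", {
  rts <- district_rate_tables()
  rho <- rts$bands; rho$rho <- 3.5
  pt <- probability_table(rts$hip, rho, rts$mort, ages = c(50, 60, 70, 80))
  expect_equal(nrow(pt), 16)  # 2 outcomes x 2 sexes x 4 ages
  expect_true(all(pt$probability >= 0 & pt$probability <= 1))

  set.seed(33)
  for (draw in 1:20) {
    rhoR <- rts$bands; rhoR$rho <- runif(nrow(rhoR), 1, 10)
    ptR <- probability_table(rts$hip, rhoR, rts$mort, ages = c(55, 75))
    wide <- reshape(ptR[c("sex", "age", "outcome", "probability")],
                    idvar = c("sex", "age"), timevar = "outcome",
                    direction = "wide")
    expect_true(all(wide$probability.MOF >= wide$probability.hip))
  }
})
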