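test_that("exact Poisson interval matches its chi-square closed form and printed examples", {
  # printed-table examples
  expect_equal(round_display(unlist(poisson_exact_ci(2, 7480))),
               c(lo = 3, hi = 97))
  expect_equal(round_display(poisson_exact_ci(8, 5536)$hi), 285)
  # zero-count band: lower bound 0, upper from -log(alpha/2) events
  ci0 <- poisson_exact_ci(0, 1e5)
  expect_equal(ci0$lo, 0)
  expect_equal(ci0$hi, -log(0.025), tolerance = 1e-10)  # 3.6889 per 100k
  # errors
  expect_error(poisson_exact_ci(2, 0), "exposure")
  expect_error(poisson_exact_ci(2.5, 100), "integer")
  expect_error(poisson_exact_ci(2, 100, alpha = 1.2), "alpha")
})

test_that("interval coverage is at least nominal over a small lambda grid", {
  # smoke-scale version of the full coverage run in test-acceptance.R
  set.seed(7)
  for (lam in c(0.5, 10)) {
    k <- rpois(2000, lam)
    ci <- poisson_exact_ci(k, E = 1)
    covered <- ci$lo <= lam * 1e5 & lam * 1e5 <= ci$hi
    expect_gte(mean(covered), 0.95 - 2 * sqrt(0.05 * 0.95 / 2000))
  }
})

test_that("band incidence reproduces the printed district table (documented exceptions aside)", {
  ch <- district_chain()
  inc <- ch$incidence
  tab <- printed_table1()
  key <- function(d) paste(d$sex, d$age_lo)
  inc <- inc[match(key(tab), key(inc)), ]

  expect_equal(inc$events, tab$events)
  expect_equal(inc$population, tab$population)
  expect_equal(unname(tapply(inc$events, inc$sex, sum)),
               c(female = 88, male = 52), ignore_attr = TRUE)

  disp_rate <- round_display(inc$rate_per_100k)
  ok <- !tab$rate_double_rounded
  expect_equal(disp_rate[ok], tab$printed_rate[ok])
  # the two double-rounded cells print one high; single rounding gives
  expect_equal(disp_rate[!ok], c(469, 543))

  # CI pairs: the printed interval method is not identifiable; exact
  # Poisson reproduces these ten pairs under the display rule
  match_ci <- round_display(inc$ci_lo) == tab$printed_lo &
    round_display(inc$ci_hi) == tab$printed_hi
  matching <- paste(tab$sex, tab$age_lo)[match_ci]
  expect_setequal(matching,
                  c("male 40", "male 45", "male 50", "male 60", "male 65",
                    "male 70", "male 80", "female 40", "female 45",
                    "female 55"))
})

test_that("crude rates and the female/male ratio come out of the fixture totals", {
  ch <- district_chain()
  cr <- crude_incidence(ch$eligible, ch$fx$population, min_age = 40)
  expect_equal(round_display(cr$rate_f), 240)
  expect_equal(round_display(cr$rate_m), 159)
  # ratio computed on unrounded rates; oracle straight from the totals
  expect_equal(cr$ratio, (88 / 36600) / (52 / 32784), tolerance = 1e-12)
  expect_equal(unname(cr$person_years), c(36600, 32784))
})

test_that("crude ratio recovers a known 2:1 truth from simulated registries", {
  bands <- age_bands(c("male", "female"), seq(40, 90, 5))
  pop <- bands; pop$count <- 1e5 / 11   # 1e5 person-years per sex
  rates <- bands
  rates$rate <- ifelse(rates$sex == "female", 300e-5, 150e-5)
  truth <- synthetic_truth(rates, decoys = c(energy = 0, residence = 0,
                                             pathological = 0, window = 0))
  ratios <- vapply(1:50, function(s) {
    cs <- simulate_registry(truth, pop, seed = 1000 + s)
    crude_incidence(cs, pop, min_age = 40)$ratio
  }, numeric(1))
  # E[k_f] = 300, E[k_m] = 150; MC error of the mean ratio over 50 reps
  # is ~0.03, plus ~1% Jensen bias in 1/k_m
  expect_close(mean(ratios), 2.0, tol = 0.12)
})

test_that("rates are invariant to splitting a band and recombining", {
  ch <- district_chain()
  pop <- ch$fx$population
  # split every closed female band at its midpoint; allocate people evenly
  f <- pop[pop$sex == "female" & !is.na(pop$age_hi), ]
  halves <- rbind(
    transform(f, age_hi = (age_lo + age_hi) / 2, count = count / 2),
    transform(f, age_lo = (age_lo + age_hi) / 2, count = count / 2))
  split_pop <- rbind(pop[pop$sex == "male" | is.na(pop$age_hi), ], halves)
  inc_split <- band_incidence(ch$eligible, split_pop)
  inc_orig <- band_incidence(ch$eligible, pop)
  for (s in c("male", "female")) {
    combined <- with(inc_split[inc_split$sex == s, ],
                     1e5 * sum(events) / sum(population))
    orig <- with(inc_orig[inc_orig$sex == s, ],
                 1e5 * sum(events) / sum(population))
    expect_equal(combined, orig, tolerance = 1e-12)
  }
})

test_that("cases outside all bands and overlapping bands are errors", {
  ch <- district_chain()
  young <- ch$eligible[1, ]; young$age <- 30; young$case_id <- "OOB"
  expect_error(band_incidence(rbind(ch$eligible, young), ch$fx$population),
               "OOB")
  overlap <- rbind(ch$fx$population,
                   data.frame(sex = "female", age_lo = 42, age_hi = 44,
                              count = 10))
  expect_error(band_incidence(ch$eligible, overlap), "band")
})

test_that("ascertainment breakdown partitions the eligible cases", {
  ch <- district_chain()
  br <- ascertainment_breakdown(ch$eligible)
  expect_equal(sum(br$count), nrow(ch$eligible))
  expect_equal(br$count[br$source == "inpatient"], 47)
  expect_equal(br$count[br$source == "community"], 15)
  expect_equal(sum(br$fraction), 1)

  one <- ch$eligible; one$source <- "coroner"
  br1 <- ascertainment_breakdown(one)
  expect_equal(br1$percent[br1$source == "coroner"], 100)
  expect_equal(sum(br1$percent), 100)

  bad <- ch$eligible; bad$source[1] <- "hearsay"
  expect_error(ascertainment_breakdown(bad), "hearsay")
})
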