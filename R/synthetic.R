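#' Ground truth for a synthetic fracture registry
#'
#' Bundles everything [simulate_registry] needs: true band rates, the
#' care-pathway mix, how many ineligible decoy records of each category to
#' plant, and the observation window.
#'
#' @param rates band table `sex`, `age_lo`, `age_hi`, `rate` (fractures
#'   per person-year).
#' @param source_probs named probabilities over the five ascertainment
#'   sources, summing to 1. Default mirrors a care setting where only a
#'   third of hip-fracture patients are hospitalised.
#' @param decoys named counts of ineligible records to plant, by the
#'   filter that must remove them.
#' @param window length-2 `Date` observation window.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(rates,
                            source_probs = c(inpatient = 0.336,
                                             outpatient = 0.264,
                                             primary_care = 0.293,
                                             coroner = 0,
                                             community = 0.107),
                            decoys = c(energy = 4, residence = 3,
                                       pathological = 2, window = 3),
                            window = as.Date(c("2016-04-01", "2017-03-31"))) {
  validate_bands(rates, "truth rate table")
  if (any(rates$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!setequal(names(source_probs), SOURCE_LEVELS)) {
    stop("source_probs must name exactly: ",
         paste(SOURCE_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(source_probs) - 1) > 1e-9) {
    stop("source_probs must sum to 1", call. = FALSE)
  }
  structure(list(rates = rates,
                 source_probs = source_probs[SOURCE_LEVELS],
                 decoys = decoys, window = as.Date(window)),
            class = "synthetic_truth")
}

# uniform integer age inside a band; open bands span 10 years
band_ages <- function(lo, hi, n) {
  top <- if (is.na(hi)) lo + 9 else hi - 1
  if (n == 0) integer(0) else sample(seq(lo, top), n, replace = TRUE)
}

random_dates <- function(window, n) {
  days <- as.integer(window[2] - window[1])
  window[1] + sample.int(days + 1, n, replace = TRUE) - 1
}

make_case_rows <- function(n, prefix, sex, age, date, source,
                           radiograph = TRUE) {
  if (n == 0) {
    out <- make_case_rows(1, prefix, "female", 70,
                          as.Date("2016-07-01"), "inpatient")
    return(out[0, ])
  }
  data.frame(case_id = sprintf("%s%04d", prefix, seq_len(n)),
             person_key = sprintf("P-%s%04d", prefix, seq_len(n)),
             age = age, sex = sex, event_date = date,
             site_code = sample(c("S72.0", "S72.1", "S72.2"), n,
                                replace = TRUE),
             energy = "low", resident = TRUE, pathological = FALSE,
             source = source, radiograph_confirmed = radiograph,
             decoy = NA_character_)
}

# Decoy records each violate exactly one eligibility criterion, labelled in
# the hidden `decoy` column so tests can assert exact filter behaviour.
make_decoys <- function(decoys, window) {
  n <- sum(decoys)
  if (n == 0) return(NULL)
  kind <- rep(names(decoys), times = decoys)
  d <- make_case_rows(n, "D", sex = rep(c("male", "female"), length.out = n),
                      age = 60 + seq_len(n),
                      date = random_dates(window, n),
                      source = rep(SOURCE_LEVELS, length.out = n))
  d$decoy <- kind
  d$energy[kind == "energy"] <- "high"
  d$resident[kind == "residence"] <- FALSE
  d$pathological[kind == "pathological"] <- TRUE
  d$event_date[kind == "window"] <- window[2] + seq_len(sum(kind == "window")) * 30
  d
}

#' Simulate a one-year multi-source fracture registry
#'
#' Per population band, the event count is Poisson with mean rate times
#' persons; each event gets a uniform age within its band, a uniform date
#' in the window, and an ascertainment source drawn from the truth's
#' care-pathway mix. The ineligible decoys from the truth are appended.
#' Fully reproducible under `seed`; no global RNG state leaks.
#'
#' @param truth a [synthetic_truth].
#' @param pop population band table (`sex`, `age_lo`, `age_hi`, `count`)
#'   covered by the truth's rates.
#' @param seed integer seed.
#' @return A case registry data frame (with the extra hidden `decoy`
#'   column, `NA` for genuine cases).
#' @export
simulate_registry <- function(truth, pop, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_bands(pop, "population table")
  j <- band_join(pop, truth$rates, "truth rate table")
  with_seed(seed, {
    ks <- stats::rpois(nrow(pop), truth$rates$rate[j] * pop$count)
    n <- sum(ks)
    age <- integer(0); sex <- character(0)
    for (i in seq_len(nrow(pop))) {
      if (ks[i] == 0) next
      age <- c(age, band_ages(pop$age_lo[i], pop$age_hi[i], ks[i]))
      sex <- c(sex, rep(pop$sex[i], ks[i]))
    }
    cases <- make_case_rows(
      n, "S", sex = sex, age = age,
      date = random_dates(truth$window, n),
      source = sample(SOURCE_LEVELS, n, replace = TRUE,
                      prob = truth$source_probs))
    rbind(cases, make_decoys(truth$decoys, truth$window))
  })
}

#' Synthetic all-cause mortality rate table
#'
#' Constant or Gompertz (exponentially age-increasing) hazard evaluated at
#' each band's midpoint; the open terminal band is evaluated at its lower
#' bound plus 5 years.
#'
#' @param model `"constant"` or `"gompertz"`.
#' @param params for `"constant"`: `list(rate = )`; for `"gompertz"`:
#'   `list(a = , b = )` giving hazard `a * exp(b * age)` (`a` > 0 is the
#'   hazard extrapolated to age 0, `b` the log-slope per year of age —
#'   ~0.09/yr is typical of adult human mortality).
#' @param bands band table (`sex`, `age_lo`, `age_hi`).
#' @return A rate table on the given bands (`rate` per person-year).
#' @export
simulate_mortality <- function(model = c("constant", "gompertz"), params,
                               bands) {
  model <- match.arg(model)
  validate_bands(bands, "mortality bands")
  mid <- ifelse(is.na(bands$age_hi), bands$age_lo + 5,
                (bands$age_lo + bands$age_hi) / 2)
  rate <- switch(model,
    constant = {
      if (is.null(params$rate) || params$rate < 0) {
        stop("constant model needs params$rate >= 0", call. = FALSE)
      }
      rep(params$rate, nrow(bands))
    },
    gompertz = {
      if (is.null(params$a) || is.null(params$b) || params$a <= 0) {
        stop("gompertz model needs params$a > 0 and params$b", call. = FALSE)
      }
      params$a * exp(params$b * mid)
    })
  data.frame(sex = bands$sex, age_lo = bands$age_lo, age_hi = bands$age_hi,
             rate = rate)
}

# Printed one-year district surveillance table this package uses as its
# worked example: population at risk and hip-fracture counts by sex and
# 5-year band, ages 40+ (terminal band open at 90).
district_table <- function() {
  lo <- seq(40, 90, 5)
  data.frame(
    sex = rep(c("male", "female"), each = 11),
    age_lo = rep(lo, 2),
    age_hi = rep(c(seq(45, 90, 5), NA), 2),
    count = c(7480, 6312, 5984, 4984, 3552, 1704, 1104, 912, 480, 216, 56,
              7760, 6768, 6632, 5536, 3968, 2064, 1344, 1208, 752, 400, 168),
    events = c(2, 3, 2, 5, 6, 8, 6, 7, 7, 5, 1,
               1, 4, 4, 8, 7, 13, 9, 12, 13, 11, 6))
}

#' Deterministic district registry fixture
#'
#' Reconstructs, record by record, a one-year hip-fracture registry for a
#' district catchment of 69,384 residents aged 40+ (32,784 men, 36,600
#' women) from its published surveillance counts: 140 eligible low-energy
#' hip fractures (52 men, 88 women) distributed over 5-year bands, with
#' care-pathway labels allocated to the published pathway counts —
#' 47 inpatient, 37 outpatient, 41 primary care, 15 community-identified
#' (the two non-hospital shares are printed only as rounded percentages;
#' 37/41 is the integer split consistent with the total) — plus 12
#' labelled decoy records (4 high-energy, 3 non-resident, 2 pathological,
#' 3 outside the window) that the eligibility filters must remove.
#'
#' Ages within bands, event dates and site codes are drawn once from a
#' fixed internal seed, so the fixture is byte-stable across calls and
#' machines.
#'
#' @return A list: `cases` (registry data frame, 152 rows incl. decoys),
#'   `population` (band table with `count`), `window` (the 1-year study
#'   window).
#' @examples
#' fx <- make_district_fixture()
#' nrow(fx$cases)                     # 152 = 140 eligible + 12 decoys
#' sum(fx$population$count)           # 69384
#' @export
make_district_fixture <- function() {
  tab <- district_table()
  window <- as.Date(c("2016-04-01", "2017-03-31"))
  with_seed(20160401, {
    n <- sum(tab$events)
    age <- integer(0); sex <- character(0)
    for (i in seq_len(nrow(tab))) {
      if (tab$events[i] == 0) next
      age <- c(age, band_ages(tab$age_lo[i], tab$age_hi[i], tab$events[i]))
      sex <- c(sex, rep(tab$sex[i], tab$events[i]))
    }
    sources <- sample(rep(c("inpatient", "outpatient", "primary_care",
                            "community"), c(47, 37, 41, 15)))
    cases <- make_case_rows(n, "C", sex = sex, age = age,
                            date = random_dates(window, n),
                            source = sources,
                            radiograph = sample(c(TRUE, FALSE), n,
                                                replace = TRUE,
                                                prob = c(0.89, 0.11)))
    # ~11% of records arrived without a usable site code; those were
    # retrieved radiographs, so unspecified implies radiograph-confirmed
    unspec <- which(cases$radiograph_confirmed)[seq_len(15)]
    cases$site_code[unspec] <- "unspecified"
    cases <- rbind(cases,
                   make_decoys(c(energy = 4, residence = 3,
                                 pathological = 2, window = 3), window))
    pop <- tab[, c("sex", "age_lo", "age_hi", "count")]
    list(cases = cases, population = pop, window = window)
  })
}
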