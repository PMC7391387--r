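#' Age/sex band tables
#'
#' Most inputs to this package are "band tables": data frames with one row
#' per sex and 5-year (or otherwise contiguous) age band, carrying a value
#' column (a population count, an event rate, or a ratio). A band covers
#' ages `[age_lo, age_hi)`; the terminal open band (e.g. 90+) has
#' `age_hi = NA`.
#'
#' @param sex character vector of `"male"` / `"female"`.
#' @param age_lo integer lower bounds (inclusive).
#' @param age_hi integer upper bounds (exclusive), `NA` for the open
#'   terminal band.
#' @return A data frame with columns `sex`, `age_lo`, `age_hi`.
#' @examples
#' age_bands("female", seq(40, 90, 5))
#' @export
age_bands <- function(sex, age_lo, age_hi = NULL) {
  if (is.null(age_hi)) {
    age_hi <- c(age_lo[-1], NA_real_)
  }
  df <- expand.grid(age_lo = as.numeric(age_lo), sex = sex,
                    stringsAsFactors = FALSE)
  df$age_hi <- rep(as.numeric(age_hi), times = length(sex))
  df[, c("sex", "age_lo", "age_hi")]
}

SEX_LEVELS <- c("male", "female")

# Validate the band structure of a table: per sex, bands must be disjoint
# and contiguous from the minimum age, with at most one open terminal band.
validate_bands <- function(tab, what = "band table") {
  req <- c("sex", "age_lo", "age_hi")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!all(tab$sex %in% SEX_LEVELS)) {
    stop(sprintf("%s: sex must be one of %s", what,
                 paste(SEX_LEVELS, collapse = "/")), call. = FALSE)
  }
  for (s in unique(tab$sex)) {
    b <- tab[tab$sex == s, ]
    b <- b[order(b$age_lo), ]
    if (anyDuplicated(b$age_lo)) {
      stop(sprintf("%s: overlapping bands for sex %s", what, s),
           call. = FALSE)
    }
    closed <- !is.na(b$age_hi)
    if (any(b$age_lo[closed] >= b$age_hi[closed])) {
      stop(sprintf("%s: age_lo must be < age_hi (sex %s)", what, s),
           call. = FALSE)
    }
    if (sum(!closed) > 1) {
      stop(sprintf("%s: more than one open band for sex %s", what, s),
           call. = FALSE)
    }
    if (nrow(b) > 1) {
      hi <- b$age_hi[-nrow(b)]
      lo <- b$age_lo[-1]
      if (anyNA(hi)) {
        stop(sprintf("%s: open band must be terminal (sex %s)", what, s),
             call. = FALSE)
      }
      if (any(hi != lo)) {
        stop(sprintf("%s: gap or overlap between bands for sex %s", what, s),
             call. = FALSE)
      }
    }
  }
  invisible(tab)
}

# Index of the band containing each (sex, age); NA when no band covers it.
band_match <- function(sex, age, bands) {
  idx <- rep(NA_integer_, length(sex))
  for (s in unique(bands$sex)) {
    rows <- which(bands$sex == s)
    b <- bands[rows, ]
    ord <- order(b$age_lo)
    b <- b[ord, ]
    sel <- which(sex == s)
    if (!length(sel)) next
    j <- findInterval(age[sel], b$age_lo)
    ok <- j >= 1
    # closed bands exclude their upper bound
    hi <- b$age_hi[pmax(j, 1)]
    ok <- ok & (is.na(hi) | age[sel] < hi)
    idx[sel[ok]] <- rows[ord][j[ok]]
  }
  idx
}

# Join two band tables on (sex, age_lo, age_hi); errors if `x` has bands
# `y` does not cover.
band_join <- function(x, y, what = "band table") {
  key <- function(t) paste(t$sex, t$age_lo, ifelse(is.na(t$age_hi), "open", t$age_hi))
  j <- match(key(x), key(y))
  if (anyNA(j)) {
    bad <- key(x)[is.na(j)]
    stop(sprintf("%s does not cover band(s): %s", what,
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  j
}

#' Round for display the way incidence tables are printed
#'
#' Values of at least 1 round half-up to an integer; values below 1 keep one
#' decimal (so a lower confidence bound of 0.326 per 100,000 prints as 0.3).
#' Internal computation in this package is never rounded; this helper is a
#' formatting concern only.
#'
#' @param x numeric vector.
#' @return numeric vector rounded under the display rule.
#' @export
round_display <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 1, floor(x + 0.5), floor(x * 10 + 0.5) / 10))
}
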