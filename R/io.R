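#' Read a CSV against a column schema
#'
#' Thin wrapper over [utils::read.csv] that checks required columns,
#' coerces them to declared types, and flags (but preserves) unknown
#' columns. Handles CRLF and LF files identically.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   one of `"character"`, `"integer"`, `"numeric"`, `"logical"`,
#'   `"date"`.
#' @param quiet suppress the row/column log message.
#' @return The validated data frame.
#' @export
read_table <- function(path, schema, quiet = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    x <- df[[col]]
    coerced <- switch(schema[[col]],
      character = as.character(x),
      integer   = suppressWarnings(as.integer(x)),
      numeric   = suppressWarnings(as.numeric(x)),
      logical   = as.logical(x),
      date      = as.Date(x),
      stop("unknown schema type ", schema[[col]], call. = FALSE))
    bad <- which(is.na(coerced) & !is.na(x) & x != "")
    if (length(bad)) {
      stop(sprintf("%s: cannot parse column %s at row %d (value '%s')",
                   path, col, bad[1], x[bad[1]]), call. = FALSE)
    }
    df[[col]] <- coerced
  }
  extra <- setdiff(names(df), names(schema))
  if (!quiet) {
    message(sprintf("read %s: %d row(s), %d column(s)%s", path, nrow(df),
                    ncol(df),
                    if (length(extra))
                      paste0(" (unknown column(s) preserved: ",
                             paste(extra, collapse = ", "), ")")
                    else ""))
  }
  df
}

CASES_SCHEMA <- c(case_id = "character", person_key = "character",
                  age = "numeric", sex = "character",
                  event_date = "date", site_code = "character",
                  energy = "character", resident = "logical",
                  pathological = "logical", source = "character",
                  radiograph_confirmed = "logical")

#' @rdname read_table
#' @export
read_cases_csv <- function(path) {
  validate_cases(read_table(path, CASES_SCHEMA))
}

#' @rdname read_table
#' @export
read_population_csv <- function(path) {
  df <- read_table(path, c(sex = "character", age_lo = "numeric",
                           age_hi = "numeric", count = "numeric"))
  validate_bands(df, path)
  df
}

#' Read a banded rate CSV, normalising units to per person-year
#'
#' The file carries `sex`, `age_lo`, `age_hi`, `rate` and a `units` column
#' that is either `per_100k` or `per_person_year`.
#'
#' @param path file path.
#' @return Rate table with `rate` in events per person-year.
#' @export
read_rate_csv <- function(path) {
  df <- read_table(path, c(sex = "character", age_lo = "numeric",
                           age_hi = "numeric", rate = "numeric",
                           units = "character"))
  validate_bands(df, path)
  bad <- !df$units %in% c("per_100k", "per_person_year")
  if (any(bad)) stop(path, ": units must be per_100k or per_person_year",
                     call. = FALSE)
  df$rate <- ifelse(df$units == "per_100k", df$rate / 1e5, df$rate)
  df$units <- NULL
  df
}

#' @rdname read_table
#' @export
read_ratio_csv <- function(path) {
  df <- read_table(path, c(sex = "character", age_lo = "numeric",
                           age_hi = "numeric", rho = "numeric"))
  validate_bands(df, path)
  df
}

#' @rdname read_table
#' @export
read_pyramid_csv <- function(path) {
  read_table(path, c(calendar_year = "integer", sex = "character",
                     age_lo = "numeric", age_hi = "numeric",
                     persons = "numeric"))
}

#' Write a filter report to CSV
#'
#' Writes two files: `<stem>_steps.csv` (`filter`, `remaining`) and
#' `<stem>_removals.csv` (`case_id`, `reason`).
#'
#' @param report a `filter_report`.
#' @param stem output path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_filter_report <- function(report, stem) {
  p1 <- paste0(stem, "_steps.csv")
  p2 <- paste0(stem, "_removals.csv")
  utils::write.csv(report$n_after_each_filter, p1, row.names = FALSE)
  utils::write.csv(report$removed, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Pipeline configuration
#'
#' Defaults follow the surveillance-study conventions: `alpha` 0.05,
#' registry `min_age` 40, projection `min_age` 50, `terminal_age` 110.
#' Values in a YAML-style `key: value` config file are overridden by
#' arguments supplied here (CLI flags take precedence over file values).
#'
#' @param cases,population,mortality,ratios,pyramids input CSV paths
#'   (later stages are skipped when their inputs are `NULL`).
#' @param out_dir output directory.
#' @param alpha,min_age,projection_min_age,terminal_age,seed,rr,horizon
#'   numeric settings.
#' @param window_start,window_end ISO dates bounding the study window;
#'   default is the range of the case dates.
#' @param config_file optional path to a `key: value` file.
#' @return A `run_config` list.
#' @export
run_config <- function(cases = NULL, population = NULL, mortality = NULL,
                       ratios = NULL, pyramids = NULL, out_dir = "hipfrax_out",
                       alpha = NULL, min_age = NULL, projection_min_age = NULL,
                       terminal_age = NULL, seed = NULL, rr = NULL,
                       horizon = NULL, window_start = NULL, window_end = NULL,
                       config_file = NULL) {
  defaults <- list(alpha = 0.05, min_age = 40, projection_min_age = 50,
                   terminal_age = 110, seed = 1, rr = 1, horizon = 10)
  file_vals <- list()
  if (!is.null(config_file)) file_vals <- read_kv_config(config_file)
  supplied <- list(cases = cases, population = population,
                   mortality = mortality, ratios = ratios,
                   pyramids = pyramids, out_dir = out_dir, alpha = alpha,
                   min_age = min_age, projection_min_age = projection_min_age,
                   terminal_age = terminal_age, seed = seed, rr = rr,
                   horizon = horizon, window_start = window_start,
                   window_end = window_end)
  cfg <- defaults
  for (nm in names(file_vals)) cfg[[nm]] <- file_vals[[nm]]
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) cfg[[nm]] <- supplied[[nm]]
  }
  applied <- setdiff(names(defaults), c(names(file_vals),
                                        names(Filter(Negate(is.null),
                                                     supplied))))
  if (length(applied)) {
    message("defaults applied: ",
            paste(sprintf("%s=%s", applied, unlist(defaults[applied])),
                  collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("config: cannot parse line '", ln, "'",
                             call. = FALSE)
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full analysis pipeline
#'
#' Registry filtering and deduplication, then incidence estimation, then
#' fracture probabilities (when mortality and ratio tables are supplied),
#' then burden projection (when pyramids are supplied). Each stage writes
#' its CSV to `out_dir`; a `manifest.json` records the configuration,
#' input checksums, stage outputs and package version. Inputs are never
#' modified; identical inputs yield identical outputs.
#'
#' @param config a [run_config].
#' @return The output directory path, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }

  stage <- "registry"
  wrap({
    if (is.null(config$cases) || is.null(config$population)) {
      stop("cases and population inputs are required")
    }
    cases <- read_cases_csv(config$cases)
    pop <- read_population_csv(config$population)
    window <- range(cases$event_date)
    if (!is.null(config$window_start)) {
      window <- as.Date(c(config$window_start, config$window_end))
    }
    flt <- apply_eligibility_filters(cases, window, config$min_age)
    ded <- deduplicate(flt$cases)
    eligible <- ded$cases
    emit(eligible[, REQUIRED_CASE_COLS], "eligible_cases.csv")
    emit(rbind(flt$report$removed, ded$report$removed), "removals.csv")
  })

  stage <- "incidence"
  wrap({
    inc <- band_incidence(eligible, pop, config$alpha)
    disp <- inc
    disp[c("rate_per_100k", "ci_lo", "ci_hi")] <-
      lapply(disp[c("rate_per_100k", "ci_lo", "ci_hi")], round_display)
    emit(disp, "incidence.csv")
    src <- ascertainment_breakdown(eligible)
    emit(src, "ascertainment.csv")
  })

  have_frax <- !is.null(config$mortality) && !is.null(config$ratios)
  if (have_frax) {
    stage <- "frax"
    wrap({
      mort <- read_rate_csv(config$mortality)
      rho <- read_ratio_csv(config$ratios)
      hip <- inc[, c("sex", "age_lo", "age_hi")]
      hip$rate <- inc$rate_per_100k / 1e5
      ages <- seq(50, 90, 10)
      pt <- probability_table(hip, rho, mort, ages, config$horizon,
                              risk_profile(config$rr),
                              terminal_age = config$terminal_age)
      emit(pt, "probabilities.csv")
    })
  } else if (!is.null(config$ratios) || !is.null(config$mortality)) {
    stop("pipeline stage 'frax' failed: both mortality and ratios are ",
         "required for probability output", call. = FALSE)
  }

  if (!is.null(config$pyramids)) {
    stage <- "projections"
    wrap({
      pyr <- read_pyramid_csv(config$pyramids)
      hip <- inc[, c("sex", "age_lo", "age_hi")]
      hip$rate <- inc$rate_per_100k / 1e5
      proj <- project_counts(hip, pyr, config$projection_min_age)
      emit(proj, "projections.csv")
    })
  }

  stage <- "manifest"
  wrap({
    ins <- Filter(Negate(is.null),
                  config[c("cases", "population", "mortality", "ratios",
                           "pyramids")])
    manifest <- list(
      package = "hipfrax",
      version = as.character(utils::packageVersion("hipfrax")),
      config = config[setdiff(names(config), "out_dir")],
      inputs = lapply(ins, function(p) list(path = p,
                                            md5 = unname(tools::md5sum(p)))),
      outputs = outputs)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  })
  invisible(config$out_dir)
}
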