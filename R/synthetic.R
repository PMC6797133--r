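#' Configuration for the synthetic-data generator
#'
#' Defines the covariate distributions and true extinction model from
#' which synthetic resurvey data sets and occurrence databases are drawn.
#' Defaults emulate the published conditions of a rare-orchid database
#' audit: a 205-record resurvey set with sizes 1-1084 individuals,
#' revisit intervals of 1-29 years, and montane elevations; and a
#' 2415-record occurrence database split into a low-size/low-elevation
#' region and a larger/higher region, overall mean size near 25, years
#' since observation spanning 1-115 with mean near 15, and elevations
#' 234-1851 m. Extinction outcomes are Bernoulli draws from the logistic
#' model with `true_coefficients` (extinction-coded: positive values
#' increase extinction probability).
#'
#' Sizes are truncated log-normal rounded to integers (`meanlog`,
#' `sdlog`, truncation to `[1, max]`); resurvey years are integer-uniform
#' on `[min, max]`; database years are rounded log-normal clamped to
#' `[min, max]` (occurrence records skew strongly toward recent
#' observations); elevations are continuous-uniform.
#'
#' @param true_coefficients numeric length 4: intercept, log-size, years,
#'   elevation effects on the extinction log-odds.
#' @param n_resurvey,n_database record counts.
#' @param resurvey list of distributions: `size = list(meanlog, sdlog,
#'   max)`, `years = list(min, max)`, `elevation = list(min, max)`.
#' @param database list with `groups` (named list of per-group `weight`,
#'   `size`, `elevation` specs) and `years = list(meanlog, sdlog, min,
#'   max)`.
#' @param seed base RNG seed; covariates, outcomes, and group labels draw
#'   from substreams derived from it, so the generator is reproducible.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    true_coefficients = c(0.93, -0.70, 0.12, -0.0018),
    n_resurvey = 205,
    n_database = 2415,
    resurvey = list(
      size = list(meanlog = 2.5, sdlog = 1.3, max = 1084),
      years = list(min = 1, max = 29),
      elevation = list(min = 250, max = 1900)),
    database = list(
      groups = list(
        oregon = list(weight = 1258 / 2415,
                      size = list(meanlog = 1.82, sdlog = 1.2, max = 1859),
                      elevation = list(min = 234, max = 1280)),
        california = list(weight = 1157 / 2415,
                          size = list(meanlog = 2.655, sdlog = 1.4, max = 1859),
                          elevation = list(min = 787, max = 1851))),
      years = list(meanlog = 2.35, sdlog = 0.9, min = 1, max = 115)),
    seed = 1) {
  stopifnot(length(true_coefficients) == 4, n_resurvey >= 0, n_database >= 0)
  check_dist <- function(d, what) {
    if (!is.null(d$min) && !is.null(d$max) && d$min > d$max) {
      stop(sprintf("inconsistent bounds for %s: min > max", what),
           call. = FALSE)
    }
    if (!is.null(d$sdlog) && d$sdlog < 0) {
      stop(sprintf("negative sdlog for %s", what), call. = FALSE)
    }
  }
  check_dist(resurvey$size, "resurvey size")
  check_dist(resurvey$years, "resurvey years")
  check_dist(resurvey$elevation, "resurvey elevation")
  check_dist(database$years, "database years")
  for (g in names(database$groups)) {
    check_dist(database$groups[[g]]$size, paste(g, "size"))
    check_dist(database$groups[[g]]$elevation, paste(g, "elevation"))
  }
  w <- vapply(database$groups, `[[`, numeric(1), "weight")
  if (length(w) && abs(sum(w) - 1) > 1e-8) {
    stop("database group weights must sum to 1", call. = FALSE)
  }
  structure(list(true_coefficients = true_coefficients,
                 n_resurvey = n_resurvey, n_database = n_database,
                 resurvey = resurvey, database = database, seed = seed),
            class = "generator_config")
}

# substream offsets keep covariate, outcome, and group draws independent
SUBSTREAM <- c(resurvey_covariates = 101L, resurvey_outcomes = 211L,
               database_covariates = 307L, database_groups = 401L)

substream_seed <- function(config, stream) {
  (config$seed + SUBSTREAM[[stream]]) %% .Machine$integer.max
}

draw_sizes <- function(spec, n) {
  pmin(pmax(1, round(stats::rlnorm(n, spec$meanlog, spec$sdlog))), spec$max)
}

#' Draw covariate rows from a generator configuration
#'
#' Samples `(size, years, elevation)` rows from the resurvey-side
#' distributions of `config`: sizes are rounded truncated log-normal
#' draws (always >= 1), years integer-uniform, elevations uniform.
#'
#' @param config a [generator_config()].
#' @param n number of rows.
#' @param seed optional seed; defaults to the config's covariate
#'   substream.
#' @return `data.frame` with columns `size`, `years`, `elevation_m`.
#' @export
sample_covariates <- function(config, n,
                              seed = substream_seed(config,
                                                    "resurvey_covariates")) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  rs <- config$resurvey
  data.frame(
    size = draw_sizes(rs$size, n),
    years = rs$years$min +
      sample.int(rs$years$max - rs$years$min + 1L, n, replace = TRUE) - 1L,
    elevation_m = stats::runif(n, rs$elevation$min, rs$elevation$max))
}

# extinction probability under the generator's true model
true_extinction_probability <- function(config, size, years, elevation_m) {
  b <- config$true_coefficients
  stats::plogis(b[1] + b[2] * log(size) + b[3] * years + b[4] * elevation_m)
}

#' Generate a synthetic resurvey data set
#'
#' Covariates come from [sample_covariates()]; each record's fate is a
#' Bernoulli draw with extinction probability given by the inverse-logit
#' of the true linear predictor. Extinct records get `final_size = 0`;
#' extant records get a log-normal final size.
#'
#' @param config a [generator_config()].
#' @return canonical resurvey records (see [read_resurvey_table()]).
#' @export
generate_resurvey_dataset <- function(config) {
  n <- config$n_resurvey
  cov <- sample_covariates(config, n)
  set.seed(substream_seed(config, "resurvey_outcomes"))
  p_ext <- true_extinction_probability(config, cov$size, cov$years,
                                       cov$elevation_m)
  extinct <- stats::rbinom(n, 1, p_ext)
  final <- ifelse(extinct == 1, 0, draw_sizes(config$resurvey$size, n))
  data.frame(
    record_id = sprintf("R%04d", seq_len(n)),
    elevation_m = cov$elevation_m,
    years_between = cov$years,
    initial_size = cov$size,
    final_size = final,
    extinct = extinct,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic occurrence database
#'
#' Group labels are drawn first with the configured weights; sizes and
#' elevations then come from the group-specific distributions and years
#' since observation from the shared database years distribution. No
#' extinction outcome is attached: database records are the prediction
#' targets, and their true expected extant count is available from
#' [true_expected_extant()].
#'
#' @param config a [generator_config()].
#' @return canonical occurrence records (see [read_occurrence_table()]).
#' @export
generate_database <- function(config) {
  n <- config$n_database
  if (n == 0L) {
    return(data.frame(record_id = character(0), size = integer(0),
                      elevation_m = numeric(0), years_since = numeric(0),
                      group = character(0), already_extinct = logical(0),
                      stringsAsFactors = FALSE))
  }
  gspec <- config$database$groups
  set.seed(substream_seed(config, "database_groups"))
  grp <- sample(names(gspec), n, replace = TRUE,
                prob = vapply(gspec, `[[`, numeric(1), "weight"))
  set.seed(substream_seed(config, "database_covariates"))
  size <- integer(n)
  elev <- numeric(n)
  for (g in names(gspec)) {
    k <- grp == g
    size[k] <- draw_sizes(gspec[[g]]$size, sum(k))
    elev[k] <- stats::runif(sum(k), gspec[[g]]$elevation$min,
                            gspec[[g]]$elevation$max)
  }
  ys <- config$database$years
  years <- pmin(pmax(ys$min, round(stats::rlnorm(n, ys$meanlog, ys$sdlog))),
                ys$max)
  data.frame(
    record_id = sprintf("D%05d", seq_len(n)),
    size = size,
    elevation_m = elev,
    years_since = years,
    group = grp,
    already_extinct = FALSE,
    stringsAsFactors = FALSE)
}

#' True expected extant count of a generated database
#'
#' The analytic expectation under the generator's own coefficients: the
#' sum over records of one minus the true extinction probability. Used to
#' check coverage of the bootstrap interval against a known truth.
#'
#' @param config the [generator_config()] that produced `records`.
#' @param records occurrence records.
#' @return the expected extant count (real).
#' @export
true_expected_extant <- function(config, records) {
  sum(1 - true_extinction_probability(config, records$size,
                                      records$years_since,
                                      records$elevation_m))
}
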