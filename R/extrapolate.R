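#' Expected number of extant populations under a fitted model
#'
#' Each database record's persistence probability is one minus its
#' predicted extinction probability; the expected extant count is the sum
#' of the persistence probabilities over all records.
#'
#' @param fit a converged `extinction_fit` (or [fit_from_coefficients()]).
#' @param records filtered occurrence records (`size >= 1`).
#' @return list with `point` (the expected extant count, a real number in
#'   `[0, N]`) and `survival` (the per-record persistence probabilities).
#' @export
point_extant_estimate <- function(fit, records) {
  if (nrow(records) == 0L) {
    return(list(point = 0, survival = numeric(0)))
  }
  if (any(records$size < 1)) {
    bad <- records$record_id[records$size < 1]
    stop("record(s) with size < 1 passed to extrapolation: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  surv <- 1 - predict_extinction(fit, records$size, records$years_since,
                                 records$elevation_m)
  list(point = sum(surv), survival = surv)
}

#' Settings for the coefficient bootstrap
#'
#' @param n_reps bootstrap iterations (default 10000).
#' @param confidence_level central coverage of the percentile interval
#'   (default 0.95).
#' @param seed RNG seed for the resampling stream; `NULL` leaves the RNG
#'   state untouched.
#' @param nonconvergence_policy what to do when a resample's fit does not
#'   converge (separation in the resample): `"redraw"` draws a fresh
#'   resample (up to `max_redraws` per iteration), `"skip"` records the
#'   iteration as missing.
#' @param max_redraws redraw cap per iteration under the redraw policy.
#' @return a `bootstrap_settings` list.
#' @export
bootstrap_settings <- function(n_reps = 10000, confidence_level = 0.95,
                               seed = NULL,
                               nonconvergence_policy = c("redraw", "skip"),
                               max_redraws = 100) {
  stopifnot(n_reps >= 1, confidence_level > 0, confidence_level < 1,
            max_redraws >= 1)
  structure(list(n_reps = as.integer(n_reps),
                 confidence_level = confidence_level,
                 seed = seed,
                 nonconvergence_policy = match.arg(nonconvergence_policy),
                 max_redraws = as.integer(max_redraws)),
            class = "bootstrap_settings")
}

#' Bootstrap the extrapolated extant count
#'
#' The empirical coefficient bootstrap: at each iteration, draw as many
#' resurvey records as the data set holds with replacement, refit the
#' logistic model, and propagate the coefficient draw through the database
#' predictions to an extant-count sum. The percentile interval is taken
#' from the empirical quantiles of the iteration sums (linear
#' interpolation between order statistics); the point estimate comes from
#' the fit on the original, un-resampled resurvey data. Extinction-rate
#' bounds are the monotone transform `rate = 1 - sum / N` of the count
#' quantiles.
#'
#' Resample indices are drawn iteration by iteration from a single RNG
#' stream seeded by `settings$seed`, so results are reproducible.
#'
#' @param resurvey resurvey records (the model-building data).
#' @param database filtered occurrence records to extrapolate over.
#' @param terms a [model_terms()] set (typically the BIC-selected one).
#' @param settings a [bootstrap_settings()] object.
#' @return an `extrapolation` object; see Details for fields.
#' @details Fields of the result: `point_extant`, `lower_q`, `upper_q`
#'   (count scale), `extinction_rate` with `rate_lower`/`rate_upper`,
#'   `per_record_survival`, `n_database`, `n_effective_reps`, `sums` (all
#'   retained iteration sums), `coef_draws` (iterations x coefficients),
#'   `fit` (original-data fit), and `settings`.
#' @export
bootstrap_extrapolation <- function(resurvey, database, terms,
                                    settings = bootstrap_settings()) {
  terms <- as_model_terms(terms)
  fit0 <- fit_logistic(resurvey, terms)
  if (!fit0$converged) {
    stop("model does not converge on the original resurvey data",
         call. = FALSE)
  }
  pe <- point_extant_estimate(fit0, database)
  N <- nrow(database)

  y <- as.integer(resurvey$extinct)
  X <- design_matrix(resurvey$initial_size, resurvey$years_between,
                     resurvey$elevation_m, terms)
  Xdb <- design_matrix(database$size, database$years_since,
                       database$elevation_m, terms)
  n <- length(y)

  if (!is.null(settings$seed)) set.seed(settings$seed)
  reps <- settings$n_reps
  sums <- rep(NA_real_, reps)
  draws <- matrix(NA_real_, reps, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  redraws_used <- 0L
  for (r in seq_len(reps)) {
    for (attempt in seq_len(
           if (settings$nonconvergence_policy == "redraw")
             settings$max_redraws else 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(fit_logistic_xy(X[idx, , drop = FALSE], y[idx],
                                    terms, se = FALSE),
                    error = function(e) NULL)
      if (!is.null(f) && f$converged) break
      f <- NULL
      redraws_used <- redraws_used + 1L
    }
    if (is.null(f)) next   # skip policy, or redraw cap exhausted
    draws[r, ] <- f$coefficients
    sums[r] <- N - sum(stats::plogis(drop(Xdb %*% f$coefficients)))
  }

  ok <- !is.na(sums)
  if (sum(ok) < 0.5 * reps) {
    stop(sprintf(
      "bootstrap unreliable: only %d of %d iterations converged",
      sum(ok), reps), call. = FALSE)
  }
  alpha <- 1 - settings$confidence_level
  qs <- stats::quantile(sums[ok], c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)

  structure(list(
    point_extant = pe$point,
    lower_q = qs[1], upper_q = qs[2],
    extinction_rate = 1 - pe$point / N,
    rate_lower = 1 - qs[2] / N,
    rate_upper = 1 - qs[1] / N,
    per_record_survival = pe$survival,
    n_database = N,
    n_effective_reps = sum(ok),
    redraws_used = redraws_used,
    sums = sums[ok],
    coef_draws = draws[ok, , drop = FALSE],
    fit = fit0,
    terms = terms,
    settings = settings
  ), class = "extrapolation")
}

#' @export
print.extrapolation <- function(x, ...) {
  cat(sprintf(
    "Extrapolated extant populations: %.0f of %d (%.0f%% extinction rate)\n",
    x$point_extant, x$n_database, 100 * x$extinction_rate))
  cat(sprintf("%d%% bootstrap quantiles: %.0f-%.0f extant (rate %.0f%%-%.0f%%), %d iterations\n",
              round(100 * x$settings$confidence_level), x$lower_q, x$upper_q,
              100 * x$rate_lower, 100 * x$rate_upper, x$n_effective_reps))
  invisible(x)
}

#' Per-group extinction-rate summaries
#'
#' Splits the database by its group label (e.g. state or region) and
#' reports, per group: record count, point expected extant count and
#' extinction rate from the original fit, and bootstrap bounds obtained by
#' applying the one shared set of coefficient draws group-wise. Unlabelled
#' records are collected under `"ungrouped"`. Group point estimates sum
#' exactly to the overall point estimate.
#'
#' @param result an `extrapolation` from [bootstrap_extrapolation()].
#' @param records the same filtered database the extrapolation used.
#' @return `data.frame` with one row per group and an `overall` row.
#' @export
summarize_by_group <- function(result, records) {
  stopifnot(inherits(result, "extrapolation"),
            nrow(records) == result$n_database)
  grp <- if ("group" %in% names(records)) records$group
         else rep(NA_character_, nrow(records))
  grp[is.na(grp) | !nzchar(grp)] <- "ungrouped"
  alpha <- 1 - result$settings$confidence_level
  draws <- result$coef_draws

  one_group <- function(keep, label) {
    ng <- sum(keep)
    Xg <- design_matrix(records$size[keep], records$years_since[keep],
                        records$elevation_m[keep], result$terms)
    # extant sums per coefficient draw, restricted to the group
    sums_g <- ng - rowSums(stats::plogis(draws %*% t(Xg)))
    qs <- stats::quantile(sums_g, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE, type = 7)
    point_g <- sum(result$per_record_survival[keep])
    data.frame(group = label, n = ng,
               point_extant = point_g,
               extant_lower = qs[1], extant_upper = qs[2],
               extinction_rate = 1 - point_g / ng,
               rate_lower = 1 - qs[2] / ng,
               rate_upper = 1 - qs[1] / ng,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    one_group(grp == g, g)
  }))
  overall <- data.frame(group = "overall", n = result$n_database,
                        point_extant = result$point_extant,
                        extant_lower = result$lower_q,
                        extant_upper = result$upper_q,
                        extinction_rate = result$extinction_rate,
                        rate_lower = result$rate_lower,
                        rate_upper = result$rate_upper,
                        stringsAsFactors = FALSE)
  rbind(out, overall)
}

#' Covariate summary of an occurrence database
#'
#' Minimum, maximum, mean, and a normal-approximation 95% half-width
#' `1.96 * sd / sqrt(N)` per covariate.
#'
#' @param records occurrence records (nonempty).
#' @param vars covariate columns to summarise.
#' @return `data.frame` with one row per covariate.
#' @export
covariate_summary <- function(records,
                              vars = c("size", "years_since", "elevation_m")) {
  stopifnot(nrow(records) >= 1)
  vars <- intersect(vars, names(records))
  do.call(rbind, lapply(vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, n = length(x), min = min(x), max = max(x),
               mean = mean(x),
               ci95_half_width = 1.96 * stats::sd(x) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  }))
}
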