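MAIN_EFFECTS <- c("SIZE", "YEARS", "ELEV")
ALL_TERMS <- c("SIZE", "YEARS", "ELEV",
               "SIZE:YEARS", "SIZE:ELEV", "YEARS:ELEV",
               "SIZE:YEARS:ELEV")

#' Define a candidate set of model terms
#'
#' A term set names the predictors of one candidate logistic extinction
#' model; the intercept is always included. Main effects are `SIZE`
#' (natural log of initial population size), `YEARS` (years between
#' surveys), and `ELEV` (elevation in metres); interactions are written
#' with `:` and are products of their parents' columns. Marginality is
#' enforced: an interaction may appear only when all of its parent main
#' effects do.
#'
#' @param terms character vector drawn from
#'   `c("SIZE","YEARS","ELEV","SIZE:YEARS","SIZE:ELEV","YEARS:ELEV","SIZE:YEARS:ELEV")`;
#'   empty for the intercept-only model.
#' @return a `model_terms` object (ordered character vector).
#' @export
model_terms <- function(terms = character(0)) {
  terms <- unique(as.character(terms))
  unknown <- setdiff(terms, ALL_TERMS)
  if (length(unknown)) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (tm in terms) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parents) > 1L && !all(parents %in% terms)) {
      stop(sprintf("marginality violated: '%s' requires main effect(s) %s",
                   tm, paste(setdiff(parents, terms), collapse = ", ")),
           call. = FALSE)
    }
  }
  terms <- ALL_TERMS[ALL_TERMS %in% terms]   # canonical order
  structure(terms, class = "model_terms")
}

#' @export
print.model_terms <- function(x, ...) {
  cat("model terms: ~ 1",
      if (length(x)) paste("+", paste(unclass(x), collapse = " + ")), "\n")
  invisible(x)
}

# design matrix for given covariates; first column is the intercept
design_matrix <- function(size, years, elevation_m, terms) {
  if (any(size < 1)) {
    stop("population size must be >= 1 (log transform undefined below 1)",
         call. = FALSE)
  }
  n <- max(length(size), length(years), length(elevation_m))
  base <- list(SIZE = rep_len(log(size), n),
               YEARS = rep_len(as.numeric(years), n),
               ELEV = rep_len(as.numeric(elevation_m), n))
  cols <- lapply(unclass(terms), function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, base[parts])
  })
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(cols)) {
    X <- cbind(X, do.call(cbind, cols))
    colnames(X) <- c("(Intercept)", unclass(terms))
  }
  X
}

#' Build design rows for the logistic extinction model
#'
#' One row per resurvey record: `SIZE` is the natural logarithm of the
#' initial population size (defined because sizes are >= 1), `YEARS` and
#' `ELEV` are carried in raw units, interaction columns are exact products
#' of their parent columns, and `y` is the extinction indicator
#' (1 = extinct at the most recent visit).
#'
#' @param records resurvey records (canonical columns).
#' @param terms a [model_terms()] set.
#' @return `data.frame` with the requested predictor columns plus `y`.
#' @export
build_design <- function(records, terms = model_terms(MAIN_EFFECTS)) {
  terms <- as_model_terms(terms)
  X <- design_matrix(records$initial_size, records$years_between,
                     records$elevation_m, terms)
  out <- as.data.frame(X[, -1, drop = FALSE])
  out$y <- as.integer(records$extinct)
  out
}

as_model_terms <- function(terms) {
  if (inherits(terms, "model_terms")) terms else model_terms(terms)
}

#' Bayes information criterion
#'
#' `BIC = k * ln(n) - 2 * logLik`; smaller is more parsimonious.
#'
#' @param log_likelihood log-likelihood at the maximum.
#' @param k number of estimated parameters.
#' @param n number of records.
#' @return the BIC value.
#' @export
bic <- function(log_likelihood, k, n) {
  stopifnot(n >= 1, k >= 1)
  k * log(n) - 2 * log_likelihood
}

#' Fit the binomial logistic extinction model
#'
#' Maximum-likelihood fit of the logit model
#' \deqn{\log(p/(1-p)) = \beta_0 + \sum_j \beta_j x_j}
#' with `y = 1` meaning the population was extinct at the most recent
#' visit. Fitting uses iteratively reweighted least squares
#' (`stats::glm.fit`, iteration cap 100); standard errors come from the
#' observed information matrix at the MLE. The `converged` flag requires
#' the scaled score norm (largest component of the per-observation
#' log-likelihood gradient, with covariate columns scaled to unit maximum)
#' to fall below `1e-8`; complete or quasi-complete separation therefore
#' surfaces as `converged = FALSE` with diagnostics, never as silently
#' huge coefficients.
#'
#' @param records resurvey records, or a design built by [build_design()].
#' @param terms a [model_terms()] set.
#' @return an `extinction_fit` with elements `coefficients`,
#'   `std_errors`, `z_scores`, `p_values`, `log_likelihood`, `bic`, `n`,
#'   `k`, `converged`, `terms`, `vcov`, and `diagnostics`.
#' @export
fit_logistic <- function(records, terms = model_terms(MAIN_EFFECTS)) {
  terms <- as_model_terms(terms)
  if ("y" %in% names(records)) {
    y <- as.integer(records$y)
    X <- cbind(`(Intercept)` = 1,
               as.matrix(records[, unclass(terms), drop = FALSE]))
  } else {
    y <- as.integer(records$extinct)
    X <- design_matrix(records$initial_size, records$years_between,
                       records$elevation_m, terms)
  }
  fit_logistic_xy(X, y, terms)
}

fit_logistic_xy <- function(X, y, terms, se = TRUE) {
  n <- length(y)
  k <- ncol(X)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes (extinct and extant) are required to fit",
         call. = FALSE)
  }
  if (n <= k) {
    stop(sprintf("need more records (%d) than parameters (%d)", n, k),
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  p <- fit$fitted.values
  score <- drop(crossprod(X, y - p))
  # per-observation gradient with covariates scaled to unit maximum, so the
  # tolerance is meaningful regardless of covariate units or sample size
  col_scale <- pmax(apply(abs(X), 2, max), 1)
  score_norm <- max(abs(score) / col_scale) / n
  separated <- any(p < 1e-10 | p > 1 - 1e-10) || any(abs(beta) > 25)
  converged <- isTRUE(fit$converged) && score_norm < 1e-8 && !separated

  ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  if (se && converged) {
    info <- crossprod(X * sqrt(p * (1 - p)))   # observed information
    vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(vc)) {
      converged <- FALSE
      ses <- rep(NA_real_, k)
    } else {
      dimnames(vc) <- list(colnames(X), colnames(X))
      ses <- sqrt(diag(vc))
    }
  } else {
    vc <- NULL
    ses <- rep(NA_real_, k)
  }
  z <- beta / ses
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    std_errors = stats::setNames(ses, colnames(X)),
    z_scores = stats::setNames(z, colnames(X)),
    p_values = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    log_likelihood = ll,
    bic = bic(ll, k, n),
    n = n, k = k,
    converged = converged,
    terms = terms,
    vcov = vc,
    diagnostics = list(score_norm = score_norm,
                       irls_converged = isTRUE(fit$converged),
                       separation_suspected = separated,
                       iterations = fit$iter)
  ), class = "extinction_fit")
}

#' @export
print.extinction_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Binomial logistic extinction model (n = %d, k = %d)\n",
              x$n, x$k))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors,
                    z = x$z_scores, p = x$p_values)
  print(round(tab, digits))
  cat(sprintf("logLik %.3f  BIC %.3f  converged: %s\n",
              x$log_likelihood, x$bic, x$converged))
  invisible(x)
}

#' Construct a fit object from fixed coefficients
#'
#' Wraps a known coefficient vector (for example a published table of
#' estimates, or a synthetic generator's true coefficients) so it can be
#' used wherever a fitted model is expected, e.g. in
#' [predict_extinction()] and [point_extant_estimate()].
#'
#' @param coefficients named or unnamed numeric vector: intercept first,
#'   then one value per term in `terms`' canonical order.
#' @param terms a [model_terms()] set.
#' @return an `extinction_fit` with `converged = TRUE` and no
#'   standard errors.
#' @export
fit_from_coefficients <- function(coefficients,
                                  terms = model_terms(MAIN_EFFECTS)) {
  terms <- as_model_terms(terms)
  k <- length(terms) + 1L
  if (length(coefficients) != k) {
    stop(sprintf("expected %d coefficients (intercept + %d term(s))",
                 k, length(terms)), call. = FALSE)
  }
  nms <- c("(Intercept)", unclass(terms))
  structure(list(
    coefficients = stats::setNames(as.numeric(coefficients), nms),
    std_errors = stats::setNames(rep(NA_real_, k), nms),
    z_scores = stats::setNames(rep(NA_real_, k), nms),
    p_values = stats::setNames(rep(NA_real_, k), nms),
    log_likelihood = NA_real_, bic = NA_real_,
    n = NA_integer_, k = k, converged = TRUE, terms = terms,
    vcov = NULL,
    diagnostics = list(source = "fixed coefficients")
  ), class = "extinction_fit")
}

#' Enumerate candidate term sets
#'
#' Every term set over the three predictors that satisfies marginality,
#' from the intercept-only model up to the full model with all three main
#' effects, the three two-way interactions, and the three-way interaction.
#' Order is deterministic: by parameter count, then lexicographically.
#'
#' @return list of [model_terms()] objects.
#' @export
enumerate_candidate_models <- function() {
  out <- list()
  mains <- MAIN_EFFECTS
  for (mi in 0:7) {
    m <- mains[bitwAnd(mi, c(1L, 2L, 4L)) > 0]
    inter <- ALL_TERMS[-(1:3)]
    allowed <- inter[vapply(inter, function(tm) {
      all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% m)
    }, logical(1))]
    for (ii in 0:(2^length(allowed) - 1)) {
      sel <- allowed[bitwAnd(ii, 2^(seq_along(allowed) - 1)) > 0]
      out[[length(out) + 1L]] <- model_terms(c(m, sel))
    }
  }
  key <- vapply(out, function(tm) paste(unclass(tm), collapse = ","),
                character(1))
  ord <- order(lengths(out), key)
  out[ord]
}

#' Select the most parsimonious extinction model by BIC
#'
#' Fits every candidate term set and returns the converged candidate with
#' the smallest BIC; exact ties break toward fewer parameters. A ranking
#' table over all candidates (terms, k, logLik, BIC, delta BIC,
#' convergence) is attached for reporting.
#'
#' @param records resurvey records.
#' @param candidates list of [model_terms()] sets; defaults to
#'   [enumerate_candidate_models()].
#' @return a `model_selection`: list with `terms`, `fit`, and `ranking`.
#' @export
select_model <- function(records, candidates = enumerate_candidate_models()) {
  fits <- lapply(candidates, function(tm) {
    tryCatch(fit_logistic(records, tm), error = function(e) e)
  })
  ok <- vapply(fits, inherits, logical(1), "extinction_fit")
  ranking <- data.frame(
    terms = vapply(candidates, function(tm) {
      if (length(tm)) paste(unclass(tm), collapse = "+") else "(intercept)"
    }, character(1)),
    k = lengths(candidates) + 1L,
    logLik = ifelse(ok, vapply(fits, function(f) {
      if (inherits(f, "extinction_fit")) f$log_likelihood else NA_real_
    }, numeric(1)), NA_real_),
    BIC = vapply(fits, function(f) {
      if (inherits(f, "extinction_fit")) f$bic else NA_real_
    }, numeric(1)),
    converged = vapply(fits, function(f) {
      inherits(f, "extinction_fit") && f$converged
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  best <- select_best(ranking)
  if (is.na(best)) {
    stop("no candidate model converged; diagnostics: ",
         paste(utils::capture.output(utils::str(fits, max.level = 1)),
               collapse = " "), call. = FALSE)
  }
  ranking$delta_BIC <- ranking$BIC - ranking$BIC[best]
  ord <- order(ranking$BIC)
  structure(list(terms = candidates[[best]], fit = fits[[best]],
                 ranking = ranking[ord, , drop = FALSE]),
            class = "model_selection")
}

# row index of the selected model in a ranking table: smallest BIC among
# converged candidates, exact ties broken toward smaller k
select_best <- function(ranking) {
  elig <- which(ranking$converged & is.finite(ranking$BIC))
  if (!length(elig)) return(NA_integer_)
  elig[order(ranking$BIC[elig], ranking$k[elig])][1]
}

#' @export
print.model_selection <- function(x, ...) {
  cat("BIC model selection over", nrow(x$ranking), "candidate term sets\n")
  cat("selected:", x$ranking$terms[x$ranking$delta_BIC == 0][1], "\n\n")
  print(utils::head(x$ranking, 8), row.names = FALSE)
  invisible(x)
}

#' Predict extinction probability for one or more populations
#'
#' Evaluates the inverse-logit of the fitted linear predictor with
#' `SIZE = ln(size)`. Values are clamped away from exactly 0 and 1 so the
#' result is strictly inside (0, 1).
#'
#' @param fit a converged `extinction_fit`.
#' @param size population size(s), >= 1.
#' @param years years between surveys (resurvey data) or since the last
#'   observation (database records).
#' @param elevation_m elevation(s) in metres.
#' @return vector of extinction probabilities in (0, 1).
#' @export
predict_extinction <- function(fit, size, years, elevation_m) {
  if (!inherits(fit, "extinction_fit")) {
    stop("'fit' must be an extinction_fit", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("refusing to predict from a non-converged fit", call. = FALSE)
  }
  X <- design_matrix(size, years, elevation_m, fit$terms)
  p <- stats::plogis(drop(X %*% fit$coefficients))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
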