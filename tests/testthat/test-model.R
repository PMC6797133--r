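test_that("design rows log-transform size and form exact interaction products", {
  rec <- data.frame(record_id = "x", elevation_m = 1000, years_between = 10,
                    initial_size = 100L, extinct = 1L)
  d <- build_design(rec, model_terms(c("SIZE", "YEARS", "ELEV",
                                       "SIZE:YEARS", "SIZE:ELEV",
                                       "YEARS:ELEV", "SIZE:YEARS:ELEV")))
  expect_equal(d$SIZE, log(100))
  expect_equal(d$YEARS, 10)
  expect_equal(d$ELEV, 1000)
  expect_identical(d$`SIZE:ELEV`, d$SIZE * d$ELEV)  # = 4605.17...
  expect_identical(d$`SIZE:YEARS:ELEV`, d$SIZE * d$YEARS * d$ELEV)
  expect_identical(d$y, 1L)

  rec$initial_size <- 1L
  expect_equal(build_design(rec, model_terms("SIZE"))$SIZE, 0)
  rec$initial_size <- 0L
  expect_error(build_design(rec, model_terms("SIZE")), "log transform")
})

test_that("term sets enforce marginality and match the brute-force lattice", {
  expect_error(model_terms("SIZE:YEARS"), "marginality")
  expect_error(model_terms(c("SIZE", "SIZE:YEARS:ELEV")), "marginality")
  expect_error(model_terms("BOGUS"), "unknown")

  cands <- enumerate_candidate_models()
  keys <- sort(vapply(cands, function(tm) {
    paste(sort(unclass(tm)), collapse = ",")
  }, character(1)))
  expect_identical(keys, brute_force_candidate_keys())
  expect_true("" %in% keys)                       # intercept-only
  expect_true(paste(sort(c("SIZE", "YEARS", "ELEV", "SIZE:YEARS",
                           "SIZE:ELEV", "YEARS:ELEV", "SIZE:YEARS:ELEV")),
                    collapse = ",") %in% keys)    # full model
  # deterministic order: parameter count never decreases
  expect_true(!is.unsorted(lengths(cands)))
})

test_that("BIC follows k*ln(n) - 2*logLik", {
  expect_equal(bic(0, 1, 1), 0)
  expect_equal(bic(-100, 4, 205), 4 * log(205) + 200)
  # linear in k at fixed likelihood and n
  expect_equal(bic(-10, 6, 50) - bic(-10, 3, 50), 3 * log(50))
  expect_error(bic(0, 0, 10))

  rs <- generate_resurvey_dataset(generator_config(seed = 5))
  fit <- fit_logistic(rs)
  expect_equal(fit$bic, fit$k * log(fit$n) - 2 * fit$log_likelihood)
  expect_equal(fit$z_scores, fit$coefficients / fit$std_errors)
})

test_that("intercept-only fit equals the logit of the sample extinction fraction", {
  rec <- data.frame(record_id = as.character(1:6), elevation_m = 500,
                    years_between = 5, initial_size = 10L,
                    extinct = rep(c(1L, 0L), 3))
  fit <- fit_logistic(rec, model_terms())
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)

  rec205 <- data.frame(record_id = as.character(1:205), elevation_m = 500,
                       years_between = 5, initial_size = 10L,
                       extinct = rep(c(1L, 0L), c(70, 135)))
  fit205 <- fit_logistic(rec205, model_terms())
  expect_equal(unname(fit205$coefficients), log(70 / 135), tolerance = 1e-8)
})

test_that("one-predictor MLE agrees with a dense grid-search oracle", {
  x <- c(0, 0, 1, 1, 2, 2, 3, 3)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  rec <- data.frame(record_id = as.character(1:8), elevation_m = 500,
                    years_between = x, initial_size = 10L, extinct = y)
  fit <- fit_logistic(rec, model_terms("YEARS"))
  oracle <- grid_mle(x, y, step = 0.02)
  expect_equal(unname(fit$coefficients[1]), oracle[1], tolerance = 0.02)
  expect_equal(unname(fit$coefficients[2]), oracle[2], tolerance = 0.02)
})

test_that("score equations hold at the MLE and fits are order-invariant", {
  rs <- generate_resurvey_dataset(generator_config(seed = 11))
  tm <- model_terms(c("SIZE", "YEARS", "ELEV"))
  fit <- fit_logistic(rs, tm)
  expect_true(fit$converged)
  expect_lt(fit$diagnostics$score_norm, 1e-8)

  perm <- rs[sample.int(nrow(rs)), ]
  fit2 <- fit_logistic(perm, tm)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-7)
  expect_equal(fit$log_likelihood, fit2$log_likelihood, tolerance = 1e-9)
})

test_that("degenerate inputs surface as structured errors, not numbers", {
  rec <- data.frame(record_id = as.character(1:10), elevation_m = 500,
                    years_between = 1:10, initial_size = 10L,
                    extinct = rep(1L, 10))
  expect_error(fit_logistic(rec, model_terms("YEARS")), "both outcome classes")

  few <- data.frame(record_id = as.character(1:3), elevation_m = c(1, 2, 3),
                    years_between = c(1, 2, 3), initial_size = c(1L, 2L, 3L),
                    extinct = c(0L, 1L, 0L))
  expect_error(
    fit_logistic(few, model_terms(c("SIZE", "YEARS", "ELEV"))),
    "more records")
})

test_that("complete separation is flagged instead of silently returned", {
  rec <- data.frame(record_id = as.character(1:12), elevation_m = 500,
                    years_between = c(1:6, 11:16), initial_size = 10L,
                    extinct = rep(c(0L, 1L), c(6, 6)))
  fit <- fit_logistic(rec, model_terms("YEARS"))
  expect_false(fit$converged)
  expect_true(fit$diagnostics$separation_suspected ||
                fit$diagnostics$score_norm >= 1e-8)
  expect_error(predict_extinction(fit, 10, 5, 500), "non-converged")
})

test_that("BIC selection prefers the generating main-effects model and breaks ties toward parsimony", {
  cfg <- generator_config(seed = 30, n_resurvey = 5000)
  rs <- generate_resurvey_dataset(cfg)
  sel <- select_model(rs)
  expect_identical(unclass(sel$terms), c("SIZE", "YEARS", "ELEV"))
  expect_true(all(sel$ranking$delta_BIC >= 0))
  expect_identical(nrow(sel$ranking), 26L)

  # exact-tie rule, exercised on a synthetic ranking table
  ranking <- data.frame(terms = c("a", "b", "c"), k = c(4L, 2L, 3L),
                        logLik = 0, BIC = c(100, 100, 101),
                        converged = TRUE)
  expect_identical(extantr:::select_best(ranking), 2L)
  ranking$converged <- c(FALSE, FALSE, TRUE)
  expect_identical(extantr:::select_best(ranking), 3L)
})

test_that("parameters are recovered within 3 SE on large synthetic data", {
  cfg <- generator_config(seed = 77, n_resurvey = 5000)
  rs <- generate_resurvey_dataset(cfg)
  fit <- fit_logistic(rs, model_terms(c("SIZE", "YEARS", "ELEV")))
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - cfg$true_coefficients) <
                    3 * fit$std_errors))
})

test_that("predicted extinction probability evaluates the inverse-logit closed form", {
  tm <- model_terms(c("SIZE", "YEARS", "ELEV"))
  flat <- fit_from_coefficients(c(0, 0, 0, 0), tm)
  expect_equal(predict_extinction(flat, c(1, 50, 900), c(0, 10, 99),
                                  c(200, 800, 1800)),
               rep(0.5, 3))

  ref <- fit_from_coefficients(c(0.93, -0.70, 0.12, -0.0018), tm)
  expect_equal(predict_extinction(ref, 100, 10, 1000),
               plogis(0.93 - 0.70 * log(100) + 0.12 * 10 - 0.0018 * 1000))
  expect_equal(round(predict_extinction(ref, 100, 10, 1000), 4), 0.0525)
  expect_error(predict_extinction(ref, 0, 10, 1000), ">= 1")
})

test_that("predictions are monotone in each covariate as its coefficient sign dictates", {
  tm <- model_terms(c("SIZE", "YEARS", "ELEV"))
  ref <- fit_from_coefficients(c(0.93, -0.70, 0.12, -0.0018), tm)
  sizes <- c(1, 2, 5, 10, 50, 100, 500, 1084)
  years <- c(1, 5, 10, 20, 29)
  elevs <- seq(200, 2000, by = 200)
  for (yy in years) for (ee in elevs) {
    expect_true(all(diff(predict_extinction(ref, sizes, yy, ee)) < 0))
  }
  for (ss in sizes) for (ee in elevs) {
    expect_true(all(diff(predict_extinction(ref, ss, years, ee)) > 0))
  }
  for (ss in sizes) for (yy in years) {
    expect_true(all(diff(predict_extinction(ref, ss, yy, elevs)) < 0))
  }
  # probabilities stay strictly inside (0, 1) even at extremes
  p <- predict_extinction(ref, c(1, 1e6), c(115, 1), c(200, 2000))
  expect_true(all(p > 0 & p < 1))
})
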