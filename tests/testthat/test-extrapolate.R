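test_that("expected extant count sums per-record persistence probabilities", {
  # two records with extinction probabilities 0.2 and 0.5 -> 1.3 extant
  tm <- model_terms("YEARS")
  fit <- fit_from_coefficients(c(qlogis(0.2), qlogis(0.5) - qlogis(0.2)), tm)
  rec <- data.frame(record_id = c("a", "b"), size = c(10L, 10L),
                    elevation_m = 500, years_since = c(0, 1))
  pe <- point_extant_estimate(fit, rec)
  expect_equal(pe$point, 1.3)
  expect_equal(pe$survival, c(0.8, 0.5))

  expect_equal(point_extant_estimate(fit, rec[0, ])$point, 0)
  rec$size[1] <- 0L
  expect_error(point_extant_estimate(fit, rec), "a")
})

test_that("extant count stays within [0, N] and survival within (0, 1) for any coefficients", {
  cfg <- generator_config(seed = 3, n_database = 400)
  db <- generate_database(cfg)
  tm <- model_terms(c("SIZE", "YEARS", "ELEV"))
  set.seed(8)
  for (i in 1:20) {
    beta <- rnorm(4, 0, c(5, 2, 0.5, 0.01))
    pe <- point_extant_estimate(fit_from_coefficients(beta, tm), db)
    expect_true(pe$point >= 0 && pe$point <= nrow(db))
    expect_true(all(pe$survival > 0 & pe$survival < 1))
  }
})

test_that("bootstrap settings are validated", {
  expect_error(bootstrap_settings(n_reps = 0))
  expect_error(bootstrap_settings(confidence_level = 1))
  s <- bootstrap_settings(n_reps = 50, seed = 9, nonconvergence_policy = "skip")
  expect_identical(s$n_reps, 50L)
  expect_identical(s$nonconvergence_policy, "skip")
})

test_that("the coefficient bootstrap is reproducible and its quantiles are ordered", {
  cfg <- generator_config(seed = 12, n_database = 300)
  rs <- generate_resurvey_dataset(cfg)
  db <- generate_database(cfg)
  tm <- model_terms(c("SIZE", "YEARS", "ELEV"))

  ex1 <- bootstrap_extrapolation(rs, db, tm,
                                 bootstrap_settings(n_reps = 200, seed = 21))
  ex2 <- bootstrap_extrapolation(rs, db, tm,
                                 bootstrap_settings(n_reps = 200, seed = 21))
  expect_identical(ex1$sums, ex2$sums)            # bit-identical
  expect_identical(ex1$coef_draws, ex2$coef_draws)

  expect_lte(ex1$lower_q, ex1$upper_q)
  expect_gte(ex1$lower_q, min(ex1$sums))
  expect_lte(ex1$upper_q, max(ex1$sums))
  expect_true(ex1$point_extant >= 0 && ex1$point_extant <= nrow(db))
  expect_true(ex1$extinction_rate >= 0 && ex1$extinction_rate <= 1)
  # rate bounds are the monotone transform of the count bounds
  expect_equal(ex1$rate_lower, 1 - ex1$upper_q / nrow(db))
  expect_equal(ex1$rate_upper, 1 - ex1$lower_q / nrow(db))

  # a single iteration gives degenerate quantiles equal to its sum
  ex3 <- bootstrap_extrapolation(rs, db, tm,
                                 bootstrap_settings(n_reps = 1, seed = 4))
  expect_equal(ex3$lower_q, ex3$upper_q)
  expect_equal(ex3$lower_q, ex3$sums[1])
})

test_that("an empty database collapses the bootstrap to zero spread", {
  cfg <- generator_config(seed = 12, n_database = 0)
  rs <- generate_resurvey_dataset(cfg)
  db <- generate_database(cfg)
  ex <- bootstrap_extrapolation(rs, db, model_terms(c("SIZE", "YEARS", "ELEV")),
                                bootstrap_settings(n_reps = 20, seed = 2))
  expect_equal(ex$point_extant, 0)
  expect_equal(ex$lower_q, 0)
  expect_equal(ex$upper_q, 0)
})

test_that("bootstrap refuses a model that fails on the original data", {
  rec <- data.frame(record_id = as.character(1:12), elevation_m = 500,
                    years_between = c(1:6, 11:16), initial_size = 10L,
                    extinct = rep(c(0L, 1L), c(6, 6)))  # separated
  db <- toy_occurrences()
  expect_error(
    bootstrap_extrapolation(rec, db, model_terms("YEARS"),
                            bootstrap_settings(n_reps = 5, seed = 1)),
    "does not converge")
})

test_that("group summaries decompose the overall estimate exactly", {
  cfg <- generator_config(seed = 19, n_database = 500)
  rs <- generate_resurvey_dataset(cfg)
  db <- generate_database(cfg)
  ex <- bootstrap_extrapolation(rs, db, model_terms(c("SIZE", "YEARS", "ELEV")),
                                bootstrap_settings(n_reps = 150, seed = 6))
  tab <- summarize_by_group(ex, db)
  grp <- tab[tab$group != "overall", ]
  overall <- tab[tab$group == "overall", ]

  expect_equal(sum(grp$point_extant), overall$point_extant)
  expect_equal(sum(grp$n), overall$n)
  # record-weighted group rates average to the overall rate
  expect_equal(sum(grp$n * grp$extinction_rate) / overall$n,
               overall$extinction_rate)
  expect_true(all(grp$rate_lower <= grp$rate_upper))

  # a single-group database reproduces the overall extrapolation
  db1 <- db
  db1$group <- "only"
  ex1 <- bootstrap_extrapolation(rs, db1, model_terms(c("SIZE", "YEARS", "ELEV")),
                                 bootstrap_settings(n_reps = 150, seed = 6))
  tab1 <- summarize_by_group(ex1, db1)
  expect_equal(tab1$point_extant[tab1$group == "only"],
               tab1$point_extant[tab1$group == "overall"])
  expect_equal(tab1$extant_lower[tab1$group == "only"],
               tab1$extant_lower[tab1$group == "overall"])

  # unlabelled records are collected under an explicit bucket
  db2 <- db
  db2$group[1:10] <- NA
  ex2 <- bootstrap_extrapolation(rs, db2, model_terms(c("SIZE", "YEARS", "ELEV")),
                                 bootstrap_settings(n_reps = 50, seed = 6))
  expect_true("ungrouped" %in% summarize_by_group(ex2, db2)$group)
})

test_that("the low-size low-elevation group shows the higher extinction rate", {
  cfg <- generator_config(seed = 23)
  rs <- generate_resurvey_dataset(cfg)
  db <- generate_database(cfg)
  ex <- bootstrap_extrapolation(rs, db, model_terms(c("SIZE", "YEARS", "ELEV")),
                                bootstrap_settings(n_reps = 100, seed = 14))
  tab <- summarize_by_group(ex, db)
  expect_gt(tab$extinction_rate[tab$group == "oregon"],
            tab$extinction_rate[tab$group == "california"])
})

test_that("covariate summaries report min, max, mean, and CI half-width", {
  rec <- data.frame(size = c(1L, 3L), years_since = c(7, 7),
                    elevation_m = c(100, 300))
  cs <- covariate_summary(rec)
  sz <- cs[cs$variable == "size", ]
  expect_equal(c(sz$min, sz$max, sz$mean), c(1, 3, 2))
  expect_equal(sz$ci95_half_width, 1.96 * sd(c(1, 3)) / sqrt(2))
  expect_equal(cs$ci95_half_width[cs$variable == "years_since"], 0)
})
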