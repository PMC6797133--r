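# Independent oracles used across tests; these never call the code paths
# they are checking.

# all marginality-respecting term sets by brute force over the 2^7 subsets
brute_force_candidate_keys <- function() {
  all_terms <- c("SIZE", "YEARS", "ELEV", "SIZE:YEARS", "SIZE:ELEV",
                 "YEARS:ELEV", "SIZE:YEARS:ELEV")
  keys <- character(0)
  for (mask in 0:(2^7 - 1)) {
    sel <- all_terms[bitwAnd(mask, 2^(0:6)) > 0]
    ok <- TRUE
    for (tm in sel) {
      parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (length(parents) > 1 && !all(parents %in% sel)) ok <- FALSE
    }
    if (ok) keys <- c(keys, paste(sort(sel), collapse = ","))
  }
  sort(keys)
}

# log-likelihood of a one-predictor logistic model, for the grid oracle
grid_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# dense grid search for the one-predictor MLE over a fixed window
grid_mle <- function(x, y, lo = -5, hi = 5, step = 0.02) {
  b0s <- seq(lo, hi, by = step)
  b1s <- seq(lo, hi, by = step)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (b1 in b1s) {
    ll <- vapply(b0s, grid_loglik, numeric(1), b1 = b1, x = x, y = y)
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best <- c(b0s[i], b1)
    }
  }
  best
}

# a tiny well-formed resurvey data frame for fixture writing
toy_resurvey <- function() {
  data.frame(
    record_id = c("a", "b", "c", "d", "e", "f"),
    elevation_m = c(500, 800, 1200, 600, 950, 1500),
    years_between = c(5, 12, 3, 20, 8, 15),
    initial_size = c(10, 200, 3, 50, 1, 400),
    final_size = c(0, 210, 0, 55, 0, 380),
    extinct = c(1L, 0L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

toy_occurrences <- function() {
  data.frame(
    record_id = sprintf("o%02d", 1:6),
    size = c(1L, 25L, 400L, 3L, 60L, 9L),
    elevation_m = c(300, 700, 1500, 450, 1100, 900),
    years_since = c(2, 10, 30, 60, 5, 16),
    group = c("west", "west", "east", "west", "east", "east"),
    already_extinct = FALSE,
    stringsAsFactors = FALSE)
}
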