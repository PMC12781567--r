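# Step/turn metrics, HMM likelihood, decoding and immersion validation.

test_that("great-circle steps match the haversine closed form", {
  # 1 degree of longitude on the equator with R = 6371 km
  tk <- data.frame(time = as.POSIXct("2022-01-01", tz = "UTC") + c(0, 600, 1200),
                   lat = c(0, 0, 0), lon = c(0, 1, 2))
  s <- track_steps_angles(tk)
  expect_equal(s$step, rep(6371 * pi / 180, 2), tolerance = 1e-6)
  # collinear equally spaced fixes turn by zero
  expect_equal(s$turn[2], 0, tolerance = 1e-9)
  expect_true(is.na(s$turn[1]))
})

test_that("a stationary bird yields zero steps and missing turns", {
  tk <- data.frame(time = as.POSIXct("2022-01-01", tz = "UTC") + (0:3) * 600,
                   lat = rep(-54, 4), lon = rep(-38, 4))
  s <- track_steps_angles(tk)
  expect_equal(s$step, rep(0, 3))
  expect_true(all(is.na(s$turn)))
  expect_error(track_steps_angles(tk[1:2, ]), "at least 3")
})

test_that("forward likelihood and Viterbi agree with exhaustive enumeration", {
  p <- toy_hmm_params()
  set.seed(99)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    sim <- simulate_hmm_series(n, p, seed = 100 + i)
    en <- enumerate_paths(p, sim$series)
    expect_equal(forward_loglik(p, sim$series), en$loglik, tolerance = 1e-10)
    expect_identical(as.integer(decode_states(p, sim$series)), en$best_path)
  }
})

test_that("the likelihood is invariant under state relabeling", {
  p <- toy_hmm_params()
  sim <- simulate_hmm_series(50, p, seed = 7)
  perm <- c(2, 3, 1)
  p2 <- hmm_params(tpm = p$tpm[perm, perm], step_mean = p$step_mean[perm],
                   step_sd = p$step_sd[perm], turn_mean = p$turn_mean[perm],
                   turn_kappa = p$turn_kappa[perm])
  expect_equal(forward_loglik(p, sim$series), forward_loglik(p2, sim$series),
               tolerance = 1e-8)
})

test_that("a straight track under high concentration decodes as commuting", {
  p <- hmm_params(tpm = matrix(1 / 3, 3, 3), step_mean = c(0.1, 3, 8),
                  step_sd = c(0.08, 1.5, 3), turn_kappa = c(0.5, 1, 50))
  s <- structure(data.frame(step = rep(8, 20), turn = c(NA, rep(0, 19))),
                 class = c("step_series", "data.frame"))
  expect_true(all(decode_states(p, s) == "commute"))
})

test_that("fitting recovers well-separated parameters and nests the 1-state model", {
  p <- toy_hmm_params()
  sim <- simulate_hmm_series(600, p, seed = 12)
  fit <- fit_hmm(sim$series, n_starts = 6, seed = 2)
  expect_lt(max(abs(fit$params$step_mean - p$step_mean) / p$step_mean), 0.15)
  # returned fit has the best likelihood over starts, and decoding is accurate
  expect_gt(mean(as.integer(decode_states(fit, sim$series)) == sim$states), 0.9)

  # degenerate single-state data: the 3-state fit nests the 1-state fit and
  # gains only chance structure (a tiny per-observation improvement), unlike
  # the large per-observation gain on genuinely 3-state data
  set.seed(3)
  one <- structure(
    data.frame(step = rgamma(300, shape = 4, rate = 2),
               turn = c(NA, albaflap:::rvm(299, 0, 1))),
    class = c("step_series", "data.frame"))
  fit1 <- suppressWarnings(fit_hmm(one, n_starts = 6, seed = 4))
  # independent 1-state reference: ML gamma + von Mises fit
  nll1 <- function(par) {
    -sum(dgamma(one$step, shape = exp(par[1]), rate = exp(par[2]), log = TRUE)) -
      sum(albaflap:::ldvm(one$turn[-1], par[3], exp(par[4])))
  }
  ref <- optim(c(log(4), log(2), 0, 0), nll1)
  gain_flat <- (fit1$loglik - (-ref$value)) / nrow(one)
  expect_gte(gain_flat, -1e-6)   # nesting: 3 states can never fit worse
  expect_lt(gain_flat, 0.1)      # ... and no real state structure was found
  # contrast: on the 3-state series above, the same gain is large
  nll3 <- function(par) {
    -sum(dgamma(sim$series$step, shape = exp(par[1]), rate = exp(par[2]),
                log = TRUE)) -
      sum(albaflap:::ldvm(sim$series$turn[-1], par[3], exp(par[4])))
  }
  ref3 <- optim(c(log(2), log(1), 0, 0), nll3)
  gain_struct <- (fit$loglik - (-ref3$value)) / nrow(sim$series)
  expect_gt(gain_struct, 0.5)
})

test_that("pooled series contribute independent likelihood terms", {
  p <- toy_hmm_params()
  a <- simulate_hmm_series(30, p, seed = 1)$series
  b <- simulate_hmm_series(40, p, seed = 2)$series
  expect_equal(forward_loglik(p, list(a, b)),
               forward_loglik(p, a) + forward_loglik(p, b), tolerance = 1e-10)
})

test_that("immersion agreement is exact for tiling and zero for all-dry logs", {
  start <- as.POSIXct("2022-01-01", tz = "UTC")
  states <- factor(c(rep("rest", 5), rep("commute", 5)),
                   levels = albaflap:::state_labels)
  ts <- start + (0:9) * 600
  imm <- data.frame(bird_id = "b01", start = start + (0:4) * 600,
                    end = start + (1:5) * 600, state = "wet")
  expect_equal(validate_against_immersion(states, ts, imm), 1.0)
  dry <- data.frame(bird_id = "b01", start = start, end = start + 3000,
                    state = "dry")
  expect_equal(validate_against_immersion(states, ts, dry), 0.0)
  # wet records shorter than 6 s are ignored
  tiny <- data.frame(bird_id = "b01", start = start + 100,
                     end = start + 103, state = "wet")
  expect_equal(validate_against_immersion(states, ts, tiny), 0.0)
  # no rest intervals: undefined
  fly <- factor(rep("commute", 10), levels = albaflap:::state_labels)
  expect_message(res <- validate_against_immersion(fly, ts, imm))
  expect_true(is.na(res))
})
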