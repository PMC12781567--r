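# Synthetic-data generator: contracts and statistical structure.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  bad_tpm <- rbind(c(0.5, 0.5, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  expect_error(sim_config(state_tpm = bad_tpm), "row-stochastic")
  expect_error(sim_config(flap_amp = 0.1, noise_sd = 0.15), "exceed noise_sd")
  expect_error(sim_config(flap_freq = 13, accel_rate = 25), "Nyquist")
})

test_that("an absorbing chain keeps all steps in the start state's distribution", {
  cfg <- sim_config(seed = 3, trip_hours = 84, state_tpm = diag(3))
  tr <- gen_track(cfg, seed = 3, start_state = 3L)
  expect_true(all(tr$truth$states == "commute"))
  # and starting from rest, all steps stay tiny
  tr2 <- gen_track(cfg, seed = 4, start_state = 1L)
  expect_true(all(tr2$truth$states == "rest"))
  expect_lt(mean(tr2$truth$steps), 0.2)
})

test_that("per-state empirical step means match the configured gamma means", {
  cfg <- sim_config(seed = 5, trip_hours = 84, state_tpm = diag(3))
  for (k in 1:3) {
    tr <- gen_track(cfg, seed = 10 + k, start_state = k)
    expect_equal(length(tr$truth$steps), 504)
    expect_lt(abs(mean(tr$truth$steps) - cfg$step_means[k]) / cfg$step_means[k],
              0.1)
  }
})

test_that("tracks are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, trip_hours = 12)
  a <- gen_track(cfg, seed = 21)
  b <- gen_track(cfg, seed = 21)
  expect_identical(a, b)
  c_ <- gen_track(cfg, seed = 22)
  expect_false(identical(a$track$lat, c_$track$lat))
})

test_that("simulated steps and turns match their generating distributions", {
  cfg <- sim_config(seed = 1, trip_hours = 170, state_tpm = diag(3))
  gp <- albaflap:::gamma_pars(cfg$step_means, cfg$step_sds)
  for (k in 1:3) {
    tr <- gen_track(cfg, seed = 30 + k, start_state = k)
    steps <- tr$truth$steps[1:1000]
    ks <- suppressWarnings(
      stats::ks.test(steps, "pgamma", shape = gp$shape[k], rate = gp$rate[k]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("accel traces honor the length contract and flap-free case", {
  cfg <- sim_config(seed = 2, trip_hours = 1)
  states <- factor(rep("commute", 6), levels = albaflap:::state_labels)
  acc <- gen_accel_trace(states, cfg, seed = 7, flap_rate = 0)
  expect_equal(nrow(acc$trace), 1 * 3600 * 25)
  expect_length(acc$flap_times, 0)
  expect_equal(sum(acc$hourly$flaps), 0)
  # baseline near 1 g
  expect_lt(abs(mean(acc$trace$az) - 1), 0.02)
})

test_that("rest intervals contain no flaps and hourly truth sums match", {
  cfg <- sim_config(seed = 2, trip_hours = 3)
  states <- factor(c(rep("rest", 6), rep("commute", 6), rep("rest", 6)),
                   levels = albaflap:::state_labels)
  acc <- gen_accel_trace(states, cfg, seed = 8, flap_rate = 800)
  expect_true(all(acc$flap_times >= 3600 & acc$flap_times < 7200))
  expect_equal(sum(acc$hourly$flaps), length(acc$flap_times))
})

test_that("a planted 30-beat bout yields 30 true peaks", {
  z <- rep(1, 25 * 30)
  res <- add_flap_bursts(z, 2 + (0:29) / 3, flap_freq = 3, flap_amp = 1.2,
                         rate = 25)
  expect_length(res$flap_times, 30)
  expect_true(all(diff(res$flap_times) > 0))
})

test_that("constant environment fields reproduce exactly and swell is clamped", {
  g <- constant_grid(u = 3, v = 4, swell = 2)
  ws <- wind_speed_dir(as.vector(g$u10), as.vector(g$v10))
  expect_true(all(abs(ws$speed - 18) < 1e-12)) # 5 m/s * 3.6
  expect_true(all(g$swh == 2))
  g2 <- gen_env_grid(env_grid_spec(n_hours = 4, swell_mean = 0.1,
                                   swell_sd = 2), seed = 3)
  expect_true(all(g2$swh >= 0))
})

test_that("generated swell is statistically independent of windspeed", {
  # short spatial/temporal correlation scales so the 10k sampled cells carry
  # many effective degrees of freedom
  g <- gen_env_grid(env_grid_spec(lat_range = c(-62, -46),
                                  lon_range = c(-46, -30), res = 0.25,
                                  n_hours = 8, smooth = 2, ar = 0.3),
                    seed = 11)
  speed <- sqrt(g$u10^2 + g$v10^2)
  set.seed(1)
  idx <- sample(length(speed), 10000)
  expect_lt(abs(cor(speed[idx], g$swh[idx])), 0.2)
})

test_that("cohort streams are seeded, linked and truth-consistent", {
  cfg <- sim_config(seed = 4, n_birds = 2, trip_hours = 6,
                    immersion_flip_error = 0)
  co <- gen_cohort(cfg)
  co2 <- gen_cohort(cfg)
  expect_identical(co$gps, co2$gps)
  expect_identical(co$truth[["b01"]]$flap_times, co2$truth[["b01"]]$flap_times)
  cfg_b <- sim_config(seed = 5, n_birds = 2, trip_hours = 6)
  co3 <- gen_cohort(cfg_b)
  expect_false(identical(co$truth[["b01"]]$flap_times,
                         co3$truth[["b01"]]$flap_times))
  # flip-error 0: wet intervals exactly tile the rest states
  for (b in c("b01", "b02")) {
    wet_starts <- co$immersion$start[co$immersion$bird_id == b]
    rest_starts <- co$gps$time[co$gps$bird_id == b][which(co$truth[[b]]$states == "rest")]
    expect_identical(sort(as.numeric(wet_starts)), sort(as.numeric(rest_starts)))
  }
})

test_that("a flat response yields hourly counts with the configured mean", {
  cfg <- sim_config(seed = 6, n_birds = 4, trip_hours = 48,
                    response_coefs = c(log(800), 0, 0))
  co <- gen_cohort(cfg)
  # evaluate the mean rate over fully-flight hours (where the target applies)
  tot_flaps <- 0; tot_hours <- 0
  for (b in names(co$accel)) {
    st <- co$truth[[b]]$states
    full_flight <- vapply(seq_len(48), function(h) {
      iv <- ((h - 1) * 6 + 1):(h * 6)
      all(st[iv] != "rest")
    }, logical(1))
    tot_flaps <- tot_flaps + sum(co$truth[[b]]$hourly_flaps$flaps[full_flight])
    tot_hours <- tot_hours + sum(full_flight)
  }
  expect_gt(tot_hours, 50)
  expect_lt(abs(tot_flaps / tot_hours - 800) / 800, 0.05)
})

test_that("hourly-table counts recover the generating response coefficients", {
  cfg <- sim_config(seed = 8)
  tab <- gen_hourly_table(cfg, n_birds = 40, hours_per_bird = 50, seed = 13,
                          bird_sd = 0)
  fit <- MASS::glm.nb(flaps ~ windspeed + swell_height, data = tab)
  est <- coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  expect_true(all(abs(est - cfg$response_coefs) <= 2 * se))
})
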