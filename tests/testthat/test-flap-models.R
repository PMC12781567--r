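# AICc arithmetic, model selection, KDE masking, the reduction statistic,
# conditional profiles and down-sampling robustness.

fake_fit <- function(id, aicc, n = 500) {
  structure(list(id = id, label = id, aicc = aicc, edf = 5, loglik = NA,
                 n = n, r2 = 0.2, dev_expl = 0.2), class = "flap_fit")
}

test_that("AICc follows its defining formula and limits", {
  expect_equal(aicc(-100, 0, 100), 200)
  expect_equal(aicc(-100, 5, 100), 200 + 10 + 2 * 5 * 6 / 94)  # 210.6383...
  expect_equal(aicc(-100, 5, 100), 210.6383, tolerance = 1e-4)
  expect_lt(abs(aicc(-50, 5, 1e6) - (2 * 50 + 10)), 0.01)       # -> AIC
  expect_error(aicc(-10, 5, 6), "n > edf")
})

test_that("Akaike weights are uniform under ties and decisive at dAICc 20", {
  fits <- lapply(MODEL_IDS <- c("0", "I", "II", "III", "IV", "V"),
                 fake_fit, aicc = 100)
  tab <- model_selection_table(fits)
  expect_equal(tab$weight, rep(1 / 6, 6))
  expect_equal(sum(tab$weight), 1)
  fits2 <- c(lapply(c("0", "I", "II", "III", "IV"), fake_fit, aicc = 120),
             list(fake_fit("V", 100)))
  tab2 <- model_selection_table(fits2)
  expect_equal(tab2$Model[1], "V")
  expect_gt(tab2$weight[1], 0.999)
  expect_true(all(diff(tab2$AICc) >= 0))
  # mismatched row sets are rejected
  expect_error(model_selection_table(list(fake_fit("0", 1, n = 10),
                                          fake_fit("I", 2, n = 20))),
               "identical row")
})

test_that("a wind-only response ranks the wind family above the swell family", {
  cfg <- sim_config(seed = 1, response_coefs = c(log(800), -0.05, 0))
  tab <- gen_hourly_table(cfg, n_birds = 25, hours_per_bird = 24, seed = 31)
  fits <- fit_model_set(tab, ids = c("I", "II"))
  expect_gt(fits[["I"]]$dev_expl, fits[["II"]]$dev_expl)
  expect_lt(fits[["I"]]$aicc, fits[["II"]]$aicc)
})

test_that("permuting the covariate destroys the fit", {
  cfg <- sim_config(seed = 1, response_coefs = c(log(800), -0.05, 0))
  tab <- gen_hourly_table(cfg, n_birds = 25, hours_per_bird = 24, seed = 32)
  base <- fit_flap_model(tab, "I")$r2
  set.seed(33)
  worse <- vapply(1:20, function(i) {
    perm <- tab
    perm$windspeed <- sample(perm$windspeed)
    fit_flap_model(perm, "I")$r2
  }, numeric(1))
  expect_gte(mean(worse < base), 0.95)
})

test_that("the 99% KDE mask keeps the observed cloud and drops far points", {
  set.seed(21)
  x1 <- rnorm(1000); x2 <- rnorm(1000)
  m <- kde_mask_99(x1, x2)
  expect_gte(mean(kde_inside(m, x1, x2)), 0.98)
  expect_false(kde_inside(m, 10 * max(abs(x1)), 0))
  expect_error(kde_mask_99(rep(1, 200), rnorm(200)), "zero-variance")
})

test_that("the reduction statistic reproduces published per-species values", {
  # printed 95th/5th quantile pairs of predicted flap rates, flaps/hour
  pairs <- data.frame(
    species = c("black-browed", "grey-headed", "wandering", "black-footed",
                "laysan"),
    max_rate = c(1549, 1952, 1512, 1043, 1429),
    min_rate = c(167.5, 160.0, 116.4, 68.71, 129.9),
    reduction = c(89.19, 91.80, 92.30, 93.41, 90.91))
  for (i in seq_len(nrow(pairs)))
    expect_equal(percent_reduction(pairs$max_rate[i], pairs$min_rate[i]),
                 pairs$reduction[i])
})

test_that("flap reduction is scale-invariant and zero for a flat surface", {
  set.seed(4)
  v <- rgamma(200, 3, 1 / 200)
  r1 <- flap_reduction(v)
  r2 <- flap_reduction(7 * v)
  expect_equal(r1$reduction_pct, r2$reduction_pct)
  expect_equal(flap_reduction(rep(100, 50))$reduction_pct, 0)
  expect_lte(r1$min_rate, r1$max_rate)
  expect_error(flap_reduction(1:5), ">= 20")
})

test_that("model V surfaces recover a monotone response and profile consistently", {
  cfg <- sim_config(seed = 2, response_coefs = c(log(1200), -0.05, -0.3))
  tab <- gen_hourly_table(cfg, n_birds = 30, hours_per_bird = 30, seed = 41)
  fit <- fit_flap_model(tab, "V")
  prof <- conditional_profile(fit, vary = "windspeed", n = 50)
  # monotone-decreasing truth: decreasing over the central 80% of support
  mid <- prof$fit[seq(6, 45)]
  expect_true(all(diff(mid) < 0))
  expect_true(all(prof$lower <= prof$fit & prof$fit <= prof$upper))
  # profile agrees with the prediction surface at the held mean
  surf <- prediction_surface(fit, n_grid = 101)
  j <- which.min(abs(surf$x2 - mean(tab$swell_height)))
  i <- which.min(abs(surf$x1 - prof$windspeed[25]))
  expect_lt(abs(surf$pred[i, j] - prof$fit[25]) / prof$fit[25], 0.05)
})

test_that("down-sampled refits are reproducible and use 18 distinct birds", {
  cfg <- sim_config(seed = 3)
  tab <- gen_hourly_table(cfg, n_birds = 24, hours_per_bird = 25, seed = 51)
  r1 <- downsample_robustness(tab, n_birds = 18, ratio = c(12, 6), reps = 3,
                              seed = 9, n_grid = 12)
  r2 <- downsample_robustness(tab, n_birds = 18, ratio = c(12, 6), reps = 3,
                              seed = 9, n_grid = 12)
  expect_identical(r1$lower, r2$lower)
  expect_identical(r1$upper, r2$upper)
  for (r in 1:3) expect_length(unique(r1$birds_used[r, ]), 18)
  expect_true(all(r1$lower <= r1$upper + 1e-9))
  expect_error(downsample_robustness(tab[tab$stage == "incubation", ],
                                     reps = 1), "too few birds")
})
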