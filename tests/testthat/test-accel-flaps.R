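# LULU filtering, animal-frame rotation and flap detection.

test_that("LULU operators remove isolated impulses of unit width", {
  expect_equal(lulu_floor(c(0, 0, 5, 0, 0), 1), rep(0, 5))
  expect_equal(lulu_ceil(c(0, 0, -5, 0, 0), 1), rep(0, 5))
  # and leave wide structure alone
  expect_equal(lulu_floor(c(0, 5, 5, 5, 0), 1), c(0, 5, 5, 5, 0))
})

test_that("LULU operators agree with their definition on random sequences", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(10:60, 1))
    n <- sample(1:4, 1)
    if (length(x) <= 2 * n) next
    expect_equal(lulu_floor(x, n), lulu_floor_ref(x, n))
    expect_equal(lulu_ceil(x, n), lulu_ceil_ref(x, n))
  }
})

test_that("monotone sequences are fixed points of both operators", {
  # brute force over all monotone 0/1 sequences of length <= 8
  for (len in 5:8) {
    for (k in 0:len) {
      up <- c(rep(0, len - k), rep(1, k))
      dn <- rev(up)
      for (n in 1:2) {
        expect_equal(lulu_floor(up, n), up)
        expect_equal(lulu_ceil(up, n), up)
        expect_equal(lulu_floor(dn, n), dn)
        expect_equal(lulu_ceil(dn, n), dn)
      }
    }
  }
})

test_that("LULU compositions are idempotent and bracket the identity", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(50:512, 1))
    n <- sample(1:5, 1)
    for (comp in c("LU", "UL")) {
      s1 <- lulu_smooth(x, n, comp)
      expect_equal(lulu_smooth(s1, n, comp), s1, tolerance = 1e-12)
    }
    expect_true(all(lulu_floor(x, n) <= x + 1e-12))
    expect_true(all(lulu_ceil(x, n) >= x - 1e-12))
  }
})

test_that("an already-level trace rotates by less than a degree", {
  tr <- noise_trace(minutes = 2, seed = 3)
  rot <- rotate_to_animal_frame(tr)
  R <- attr(rot, "rotation")
  angle <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("a known 15-degree pitch is recovered within a degree", {
  tr <- noise_trace(minutes = 3, seed = 4)
  th <- 15 * pi / 180
  # pitch about the y axis: mix x and z
  ax2 <- cos(th) * tr$ax + sin(th) * tr$az
  az2 <- -sin(th) * tr$ax + cos(th) * tr$az
  tilted <- accel_trace(tr$time, ax2, tr$ay, az2, attr(tr, "rate"))
  rot <- rotate_to_animal_frame(tilted)
  R <- attr(rot, "rotation")
  angle <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(abs(angle - 15), 1)
  # and the low-pass mean of the rotated heave is ~1 g
  expect_lt(abs(mean(rot$az) - 1), 0.02)
})

test_that("rotation preserves the per-sample vector norm", {
  tr <- noise_trace(minutes = 2, seed = 5)
  tilted <- accel_trace(tr$time, tr$ax + 0.2, tr$ay, tr$az, attr(tr, "rate"))
  rot <- rotate_to_animal_frame(tilted)
  n0 <- sqrt(tilted$ax^2 + tilted$ay^2 + tilted$az^2)
  n1 <- sqrt(rot$ax^2 + rot$ay^2 + rot$az^2)
  expect_lt(max(abs(n0 - n1)), 1e-9)
})

test_that("planted spikes are detected exactly at high SNR", {
  set.seed(11)
  rate <- 25
  n <- 25 * 120
  z <- 1 + rnorm(n, 0, 0.15)
  res <- add_flap_bursts(z, seq(5, 110, length.out = 30), 3, 1.2, rate)
  tr <- accel_trace((seq_len(n) - 1) / rate, rnorm(n, 0, 0.15),
                    rnorm(n, 0, 0.15), res$z, rate)
  ev <- detect_flaps(tr, flap_config(threshold = 0.5))
  expect_equal(length(ev$peak_times), 30)
  # every detection within two samples of a planted peak (noise can shift
  # the residual maximum by a sample)
  expect_true(all(vapply(ev$peak_times, function(t)
    min(abs(res$flap_times - t)) <= 2 / rate + 1e-12, logical(1))))
})

test_that("a threshold above the residual maximum yields zero events", {
  tr <- noise_trace(minutes = 2, seed = 6)
  ev <- detect_flaps(tr, flap_config(threshold = 50))
  expect_length(ev$peak_times, 0)
})

test_that("the refractory gap keeps the taller of two close spikes", {
  rate <- 25
  n <- 25 * 70
  z <- rep(1, n)
  ci1 <- round(30 * rate) + 1      # t = 30.00, amplitude 1.0
  ci2 <- round(30.12 * rate) + 1   # t = 30.12, amplitude 1.4 (taller)
  z[ci1] <- z[ci1] + 1.0
  z[ci2] <- z[ci2] + 1.4
  tr <- accel_trace((seq_len(n) - 1) / rate, rep(0, n), rep(0, n), z, rate)
  ev <- detect_flaps(tr, flap_config(lulu_window = 4, threshold = 0.5,
                                     refractory = 0.2))
  expect_equal(length(ev$peak_times), 1)
  expect_equal(ev$peak_times, (ci2 - 1) / rate, tolerance = 1e-9)
})

test_that("raising the threshold never adds events", {
  cfg <- sim_config(seed = 2, trip_hours = 1)
  states <- factor(rep("commute", 6), levels = albaflap:::state_labels)
  acc <- gen_accel_trace(states, cfg, seed = 17, flap_rate = 600)
  prev <- Inf
  for (thr in c(0.3, 0.5, 0.7, 0.9, 1.1)) {
    k <- length(detect_flaps(acc$trace, flap_config(threshold = thr))$peak_times)
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("hourly counts follow the half-open clock-hour convention", {
  start <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC")
  ev <- structure(list(peak_times = c(10, 3599.99, 3600, 5400),
                       peak_heights = rep(1, 4), start_time = start,
                       duration = 7200), class = "flap_events")
  counts <- flaps_per_hour(ev)
  expect_equal(counts$flaps, c(2L, 2L))     # boundary peak in the later hour
  expect_equal(sum(counts$flaps), 4L)       # conservation
})

test_that("decimation to 25 Hz preserves the slow signal", {
  rate <- 75
  n <- 75 * 120
  t <- (seq_len(n) - 1) / rate
  z <- 1 + 0.5 * sin(2 * pi * 0.5 * t)  # 0.5 Hz, well under the 10 Hz cutoff
  tr <- accel_trace(t, rep(0, n), rep(0, n), z, rate)
  dn <- downsample_accel(tr, 3L)
  expect_equal(attr(dn, "rate"), 25)
  expect_equal(nrow(dn), ceiling(n / 3))
  mid <- 100:(nrow(dn) - 100)
  expect_lt(max(abs(dn$az[mid] - (1 + 0.5 * sin(2 * pi * 0.5 * dn$time[mid])))),
            0.01)
})

test_that("accel CSV reading round-trips a trace", {
  tr <- noise_trace(minutes = 1, seed = 8)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    timestamp = as.numeric(attr(tr, "start_time")) + tr$time,
    ax = tr$ax, ay = tr$ay, az = tr$az), path, row.names = FALSE)
  back <- read_accel_csv(path, rate = 25)
  expect_equal(back$az, tr$az, tolerance = 1e-8)
  expect_equal(attr(back, "rate"), 25)
  unlink(path)
})
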