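# Synthetic biologging cohort generator.
#
# Emulates the four input streams of an albatross flap-rate study -- 25 Hz
# tri-axial acceleration, 10-min GPS fixes, 3-s-resolution leg-mounted
# immersion logs, and hourly gridded wind/swell fields -- together with the
# ground truth (true behavioural states, true wingbeat instants, true hourly
# flap counts, true flap-rate response coefficients) that downstream recovery
# tests compare against. Everything is reproducible bit-for-bit under a seed.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe a
#' breeding-season foraging trip: 25 Hz acceleration with ~3 Hz wingbeats of
#' 1.2 g amplitude over a 0.15 g noise floor, 10-min GPS fixes driven by a
#' 3-state (rest / forage / commute) Markov chain with gamma step lengths and
#' von Mises turns, and a log-linear true flap-rate response
#' `exp(b0 + b1 * windspeed_kmh + b2 * swell_m)` used to modulate flapping.
#'
#' @param seed base integer seed; per-stream seeds are derived from it.
#' @param n_birds number of individuals in the cohort.
#' @param trip_hours trip duration in hours per bird.
#' @param accel_rate accelerometer sampling rate in Hz.
#' @param gps_interval GPS interval in minutes.
#' @param flap_freq wingbeat frequency in Hz (must be below Nyquist).
#' @param flap_amp wingbeat spike amplitude in g (must exceed `noise_sd`).
#' @param noise_sd accelerometer noise standard deviation in g.
#' @param state_tpm 3x3 row-stochastic transition matrix over
#'   (rest, forage, commute), one transition per 10-min interval.
#' @param step_means,step_sds per-state gamma step-length mean/sd in km per
#'   10 min, ordered rest < forage < commute.
#' @param turn_concentrations per-state von Mises concentration of turns.
#' @param response_coefs numeric length 3: intercept (log flaps/hour), slope
#'   per km/h windspeed, slope per m swell height of the true response.
#' @param flaps_per_bout wingbeats per flapping bout; bouts are placed as a
#'   Poisson process in flight states with intensity chosen so the expected
#'   hourly flap count matches the true response.
#' @param undulation_amp amplitude (g) of the 0.1--0.3 Hz soaring undulation
#'   superimposed on the heave baseline.
#' @param immersion_flip_error probability that a 10-min interval's wet/dry
#'   classification is recorded flipped in the immersion log.
#' @param colony colony position, named vector `c(lat = , lon = )`.
#' @param start_time trip start (POSIXct, UTC), aligned to a clock hour.
#' @param env_grid_spec environment-grid specification, see [env_grid_spec()].
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_birds = 5L,
                       trip_hours = 48,
                       accel_rate = 25,
                       gps_interval = 10,
                       flap_freq = 3.0,
                       flap_amp = 1.2,
                       noise_sd = 0.15,
                       state_tpm = rbind(c(0.85, 0.10, 0.05),
                                         c(0.10, 0.80, 0.10),
                                         c(0.05, 0.10, 0.85)),
                       step_means = c(0.1, 3, 8),
                       step_sds = c(0.08, 1.5, 3),
                       turn_concentrations = c(0.5, 1, 15),
                       response_coefs = c(log(1500), -0.04, -0.25),
                       flaps_per_bout = 10,
                       undulation_amp = 0.08,
                       immersion_flip_error = 0.02,
                       colony = c(lat = -54.0, lon = -38.05),
                       start_time = as.POSIXct("2022-01-01 00:00:00", tz = "UTC"),
                       env_grid_spec = NULL) {
  stopifnot(is.matrix(state_tpm), all(dim(state_tpm) == c(3, 3)))
  if (any(state_tpm < 0) || any(abs(rowSums(state_tpm) - 1) > 1e-12))
    stop("state_tpm must be row-stochastic (rows summing to 1 within 1e-12)")
  if (flap_amp <= noise_sd)
    stop("flap_amp must exceed noise_sd")
  if (flap_freq >= accel_rate / 2)
    stop("flap_freq must be below the Nyquist frequency accel_rate/2")
  stopifnot(length(step_means) == 3, length(step_sds) == 3,
            all(step_means > 0), all(step_sds > 0),
            length(turn_concentrations) == 3, all(turn_concentrations >= 0),
            length(response_coefs) == 3, trip_hours > 0, n_birds >= 1)
  if (is.null(env_grid_spec))
    env_grid_spec <- albaflap::env_grid_spec(
      lat_range = colony["lat"] + c(-8, 8),
      lon_range = colony["lon"] + c(-8, 8),
      n_hours = ceiling(trip_hours) + 1,
      start_time = start_time)
  structure(list(
    seed = as.integer(seed), n_birds = as.integer(n_birds),
    trip_hours = trip_hours, accel_rate = accel_rate,
    gps_interval = gps_interval, flap_freq = flap_freq,
    flap_amp = flap_amp, noise_sd = noise_sd, state_tpm = state_tpm,
    step_means = step_means, step_sds = step_sds,
    turn_concentrations = turn_concentrations,
    response_coefs = response_coefs, flaps_per_bout = flaps_per_bout,
    undulation_amp = undulation_amp,
    immersion_flip_error = immersion_flip_error,
    colony = colony, start_time = start_time,
    env_grid_spec = env_grid_spec), class = "sim_config")
}

state_labels <- c("rest", "forage", "commute")

#' Simulate one foraging track with known states
#'
#' Positions at the GPS interval are produced by a 3-state Markov chain with
#' per-state gamma step lengths and von Mises turn angles; the heading in the
#' final 20% of the trip is reflected toward the colony so trips end where
#' they started ("complete trips"). The generating state sequence is returned
#' as ground truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this track.
#' @param bird_id identifier stored in the track.
#' @param start_state initial state index (1 = rest, 2 = forage,
#'   3 = commute); trips leave the colony commuting by default.
#' @return list with `track` (data.frame: bird_id, time, lat, lon) and
#'   `truth` (list: states factor, steps km, turns rad).
#' @export
gen_track <- function(config, seed = config$seed, bird_id = "b01",
                      start_state = 3L) {
  if (any(abs(rowSums(config$state_tpm) - 1) > 1e-12))
    stop("non-stochastic transition matrix")
  set.seed(seed)
  n_int <- as.integer(round(config$trip_hours * 60 / config$gps_interval))
  states <- integer(n_int)
  states[1] <- start_state
  for (i in seq_len(n_int - 1))
    states[i + 1] <- sample.int(3, 1, prob = config$state_tpm[states[i], ])
  gp <- gamma_pars(config$step_means, config$step_sds)
  steps <- rgamma(n_int, shape = gp$shape[states], rate = gp$rate[states])
  turns <- vapply(config$turn_concentrations[states],
                  function(k) rvm(1, 0, k), numeric(1))
  lat <- numeric(n_int + 1); lon <- numeric(n_int + 1)
  lat[1] <- config$colony[["lat"]]; lon[1] <- config$colony[["lon"]]
  heading <- runif(1, 0, 360)
  homeward_from <- ceiling(0.8 * n_int)
  for (i in seq_len(n_int)) {
    if (i > homeward_from) {
      # reflect the walk toward the colony for the final 20% of the trip
      to_colony <- geosphere::bearing(c(lon[i], lat[i]),
                                      c(config$colony[["lon"]], config$colony[["lat"]]))
      heading <- to_colony + turns[i] * 180 / pi
    } else {
      heading <- heading + turns[i] * 180 / pi
    }
    p <- geosphere::destPoint(c(lon[i], lat[i]), wrap_360(heading),
                              steps[i] * 1000, r = EARTH_RADIUS_M)
    lon[i + 1] <- p[1, 1]; lat[i + 1] <- p[1, 2]
  }
  time <- config$start_time + (0:n_int) * config$gps_interval * 60
  list(
    track = data.frame(bird_id = bird_id, time = time, lat = lat, lon = lon,
                       stringsAsFactors = FALSE),
    truth = list(states = factor(state_labels[states], levels = state_labels),
                 steps = steps, turns = turns))
}

#' Add wingbeat pulses to a heave signal
#'
#' Superimposes one raised-cosine pulse (width one wingbeat period, peak at
#' the flap instant) per flap time onto a heave vector sampled at `rate` Hz.
#'
#' @param z heave vector (g).
#' @param flap_times flap peak instants in seconds from the first sample.
#' @param flap_freq wingbeat frequency in Hz.
#' @param flap_amp pulse amplitude in g.
#' @param rate sampling rate in Hz.
#' @return list with the modified vector `z` and `flap_times` snapped to the
#'   sample grid (strictly increasing, deduplicated).
#' @export
add_flap_bursts <- function(z, flap_times, flap_freq, flap_amp, rate) {
  n <- length(z)
  if (length(flap_times) == 0)
    return(list(z = z, flap_times = numeric(0)))
  ci <- unique(pmin(pmax(round(flap_times * rate) + 1L, 1L), n))
  # pulse half-width: a quarter wingbeat period, so spikes are narrower than
  # the beat period as in real heave traces
  w <- max(1L, floor(rate / (4 * flap_freq)))
  off <- -w:w
  idx <- rep(ci, each = length(off)) + rep(off, times = length(ci))
  val <- flap_amp * cos(2 * pi * flap_freq * rep(off, times = length(ci)) / rate) *
    (abs(rep(off, times = length(ci))) <= w)
  ok <- idx >= 1L & idx <= n
  agg <- rowsum(val[ok], idx[ok])
  at <- as.integer(rownames(agg))
  z[at] <- z[at] + agg[, 1]
  list(z = z, flap_times = sort((ci - 1L) / rate))
}

#' Simulate a tri-axial acceleration trace for a known state sequence
#'
#' The heave (z) axis is a 1 g baseline plus Gaussian noise plus a
#' low-frequency soaring undulation; during flight states, flapping bouts are
#' placed as a Poisson process whose intensity tracks a per-hour target flap
#' rate, each bout a short burst of raised-cosine spikes at the wingbeat
#' frequency. True flap peak instants are returned as ground truth.
#'
#' @param states factor/character vector of per-10-min-interval states
#'   (`rest`, `forage`, `commute`).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param flap_rate target flap rate(s) in flaps/hour: a single value or one
#'   per clock hour of the trace. Zero gives a flap-free trace.
#' @return list with `trace` (an [accel_trace()]), `flap_times` (s from trace
#'   start), and `hourly` (data.frame hour/flaps of true counts, one row per
#'   clock hour).
#' @export
gen_accel_trace <- function(states, config, seed = config$seed,
                            flap_rate = 800) {
  if (config$flap_freq >= config$accel_rate / 2)
    stop("flap_freq must be below the Nyquist frequency accel_rate/2")
  set.seed(seed)
  rate <- config$accel_rate
  int_s <- config$gps_interval * 60
  n_int <- length(states)
  dur <- n_int * int_s
  n <- as.integer(dur * rate)
  t <- (seq_len(n) - 1) / rate
  und_freq <- runif(1, 0.1, 0.3)
  z <- 1 + rnorm(n, 0, config$noise_sd) +
    config$undulation_amp * sin(2 * pi * und_freq * t + runif(1, 0, 2 * pi))
  st <- as.character(states)
  n_hours <- ceiling(dur / 3600)
  rates <- rep_len(flap_rate, n_hours)
  flap_times <- numeric(0)
  fpb <- config$flaps_per_bout
  bout_dur <- fpb / config$flap_freq
  for (i in seq_len(n_int)) {
    if (!st[i] %in% c("forage", "commute")) next
    t0 <- (i - 1) * int_s
    lambda <- rates[min(n_hours, floor(t0 / 3600) + 1)]
    if (lambda <= 0) next
    # non-overlapping bouts as a renewal process (exponential gaps + bout
    # duration), with the gap rate inflated so the expected bout count per
    # unit time still equals lambda / flaps_per_bout
    nu <- lambda / fpb / 3600
    if (nu * bout_dur >= 0.95) nu <- 0.95 / bout_dur # cap the duty cycle
    nu_gap <- nu / (1 - nu * bout_dur)
    pos <- rexp(1, nu_gap)
    while (pos + bout_dur <= int_s) {
      ft <- t0 + pos + (seq_len(fpb) - 1) / config$flap_freq
      flap_times <- c(flap_times, ft)
      pos <- pos + bout_dur + rexp(1, nu_gap)
    }
  }
  res <- add_flap_bursts(z, flap_times, config$flap_freq, config$flap_amp, rate)
  trace <- accel_trace(time = t,
                       ax = rnorm(n, 0, config$noise_sd),
                       ay = rnorm(n, 0, config$noise_sd),
                       az = res$z, rate = rate,
                       start_time = config$start_time)
  hour <- floor(res$flap_times / 3600)
  counts <- tabulate(hour + 1L, nbins = n_hours)
  list(trace = trace, flap_times = res$flap_times,
       hourly = data.frame(hour = config$start_time + 3600 * (seq_len(n_hours) - 1),
                           flaps = counts))
}

#' Environment-grid specification
#'
#' Describes the spatial extent, resolution and statistical structure of the
#' synthetic hourly wind/swell fields. Anomalies are spatially smoothed white
#' noise evolving as an AR(1) process across hours; the swell field is drawn
#' independently of the wind components, mirroring swell generated by distant
#' weather systems rather than local wind.
#'
#' @param lat_range,lon_range extent in degrees.
#' @param res grid resolution in degrees.
#' @param n_hours number of hourly fields.
#' @param start_time POSIXct (UTC) of the first field.
#' @param u_mean,v_mean mean 10 m wind components in m/s.
#' @param wind_sd anomaly standard deviation of each wind component (m/s).
#' @param swell_mean,swell_sd mean/anomaly-sd of significant swell height (m);
#'   the field is clamped at 0.
#' @param swell_dir_mean mean swell origin direction in degrees.
#' @param smooth spatial smoothing scale in grid cells.
#' @param ar hourly AR(1) coefficient of the anomalies.
#' @param constant optional list `(u, v, swell, swell_dir)` producing constant
#'   fields (useful for exact-extraction tests).
#' @return object of class `env_grid_spec`.
#' @export
env_grid_spec <- function(lat_range = c(-62, -46), lon_range = c(-46, -30),
                          res = 0.5, n_hours = 49,
                          start_time = as.POSIXct("2022-01-01 00:00:00", tz = "UTC"),
                          u_mean = 8, v_mean = 1, wind_sd = 2.5,
                          swell_mean = 2.5, swell_sd = 0.7,
                          swell_dir_mean = 270, smooth = 4, ar = 0.9,
                          constant = NULL) {
  if (res <= 0) stop("grid resolution must be positive")
  structure(list(lat_range = lat_range, lon_range = lon_range, res = res,
                 n_hours = n_hours, start_time = start_time,
                 u_mean = u_mean, v_mean = v_mean, wind_sd = wind_sd,
                 swell_mean = swell_mean, swell_sd = swell_sd,
                 swell_dir_mean = swell_dir_mean, smooth = smooth, ar = ar,
                 constant = constant), class = "env_grid_spec")
}

# Gaussian spatial smoother for an L x M matrix, scale in cells.
smooth2d <- function(m, scale) {
  k <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(i - j, sd = scale))
    d / rowSums(d)
  }
  k(nrow(m)) %*% m %*% t(k(ncol(m)))
}

#' Generate a synthetic hourly wind/swell grid
#'
#' Smooth Gaussian-process-like hourly fields for the 10 m wind components,
#' significant swell height (clamped at 0) and swell direction. Swell is
#' statistically independent of wind by construction.
#'
#' @param spec an [env_grid_spec()].
#' @param seed integer seed.
#' @return an [env_grid()].
#' @export
gen_env_grid <- function(spec, seed = 1L) {
  if (spec$res <= 0) stop("grid resolution must be positive")
  set.seed(seed)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$res)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$res)
  L <- length(lat); M <- length(lon); H <- spec$n_hours
  time <- spec$start_time + 3600 * (seq_len(H) - 1)
  if (!is.null(spec$constant)) {
    cc <- spec$constant
    mk <- function(v) array(v, dim = c(H, L, M))
    return(env_grid(time, lat, lon, u10 = mk(cc$u), v10 = mk(cc$v),
                    swh = mk(cc$swell), swd = mk(cc$swell_dir %||% 270)))
  }
  anom_field <- function() {
    a <- array(0, dim = c(H, L, M))
    e <- smooth2d(matrix(rnorm(L * M), L, M), spec$smooth)
    e <- e / sd(e)
    a[1, , ] <- e
    for (h in seq_len(H - 1)) {
      innov <- smooth2d(matrix(rnorm(L * M), L, M), spec$smooth)
      innov <- innov / sd(innov)
      a[h + 1, , ] <- spec$ar * a[h, , ] + sqrt(1 - spec$ar^2) * innov
    }
    a
  }
  u10 <- spec$u_mean + spec$wind_sd * anom_field()
  v10 <- spec$v_mean + spec$wind_sd * anom_field()
  swh <- pmax(spec$swell_mean + spec$swell_sd * anom_field(), 0)
  swd <- wrap_360(spec$swell_dir_mean + 40 * anom_field())
  env_grid(time, lat, lon, u10 = u10, v10 = v10, swh = swh, swd = swd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Links all generators: one environment grid, then per bird a track with
#' true states, an acceleration trace whose bout intensity follows the true
#' log-linear flap-rate response evaluated at the bird's hourly position, and
#' an immersion log marking rest intervals wet (with a configurable flip-error
#' rate; wet/dry records are at least 6 s long at 3 s resolution).
#'
#' @param config a [sim_config()].
#' @return list with `gps` (all birds' fixes), `accel` (per-bird traces),
#'   `immersion` (wet/dry intervals), `env` (the [env_grid()]), and `truth`
#'   (per-bird states, flap times, true hourly flaps and rates, plus the
#'   generating response coefficients).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- gen_env_grid(config$env_grid_spec, derive_seed(config$seed, 1))
  gps <- list(); accel <- list(); immersion <- list(); truth <- list()
  n_hours <- ceiling(config$trip_hours)
  for (b in seq_len(config$n_birds)) {
    id <- sprintf("b%02d", b)
    tr <- gen_track(config, derive_seed(config$seed, 100 + b), bird_id = id)
    # true response evaluated at the top-of-hour position
    hr_time <- config$start_time + 3600 * (0:(n_hours - 1))
    hi <- match(hr_time, tr$track$time)
    env <- extract_env(grid, tr$track$lat[hi], tr$track$lon[hi], hr_time)
    lambda <- exp(config$response_coefs[1] +
                  config$response_coefs[2] * env$windspeed +
                  config$response_coefs[3] * env$swell_height)
    lambda[is.na(lambda)] <- exp(config$response_coefs[1])
    acc <- gen_accel_trace(tr$truth$states, config,
                           seed = derive_seed(config$seed, 200 + b),
                           flap_rate = lambda)
    # immersion log: rest intervals wet, flipped with the configured error rate
    set.seed(derive_seed(config$seed, 300 + b))
    int_s <- config$gps_interval * 60
    n_int <- length(tr$truth$states)
    wet <- tr$truth$states == "rest"
    flip <- runif(n_int) < config$immersion_flip_error
    wet <- xor(wet, flip)
    imm <- if (any(wet)) {
      starts <- config$start_time + (which(wet) - 1) * int_s
      data.frame(bird_id = id, start = starts, end = starts + int_s,
                 state = "wet", stringsAsFactors = FALSE)
    } else NULL
    gps[[id]] <- tr$track
    accel[[id]] <- acc$trace
    immersion[[id]] <- imm
    truth[[id]] <- list(states = tr$truth$states,
                        flap_times = acc$flap_times,
                        hourly_flaps = acc$hourly,
                        hourly_rate = lambda)
  }
  list(gps = do.call(rbind, gps),
       accel = accel,
       immersion = do.call(rbind, immersion),
       env = grid,
       truth = c(truth, list(response_coefs = config$response_coefs)))
}

#' Generate an hourly modeling table directly from the true response
#'
#' Bypasses the per-sample acceleration synthesis and draws hourly flap
#' counts straight from the log-linear true response with a per-bird random
#' intercept and negative binomial noise. This is the fast path for
#' model-recovery simulations; [gen_cohort()] is the full-stream path.
#'
#' @param config a [sim_config()] (supplies `response_coefs`).
#' @param n_birds,hours_per_bird table dimensions.
#' @param seed integer seed.
#' @param bird_sd standard deviation of the per-bird log-scale intercept.
#' @param nb_size negative binomial size (dispersion) of hourly counts.
#' @param wind_mean,wind_sd gamma moments of windspeed (km/h).
#' @param swell_mean,swell_sd gamma moments of swell height (m).
#' @param brood_guard_fraction fraction of birds labelled brood-guard.
#' @return data.frame with columns bird_id, hour, windspeed, swell_height,
#'   BWA, BSA, flaps, stage, complete_trip.
#' @export
gen_hourly_table <- function(config, n_birds = 40, hours_per_bird = 50,
                             seed = config$seed, bird_sd = 0.15, nb_size = 5,
                             wind_mean = 25, wind_sd = 10,
                             swell_mean = 2.5, swell_sd = 0.9,
                             brood_guard_fraction = 2 / 3) {
  set.seed(seed)
  n <- n_birds * hours_per_bird
  bird <- factor(rep(sprintf("b%02d", seq_len(n_birds)), each = hours_per_bird))
  u <- rnorm(n_birds, 0, bird_sd)[as.integer(bird)]
  gw <- gamma_pars(wind_mean, wind_sd)
  gs <- gamma_pars(swell_mean, swell_sd)
  wind <- rgamma(n, gw$shape, gw$rate)
  swell <- rgamma(n, gs$shape, gs$rate)
  mu <- exp(config$response_coefs[1] + u +
            config$response_coefs[2] * wind +
            config$response_coefs[3] * swell)
  stage <- rep(ifelse(seq_len(n_birds) <= round(brood_guard_fraction * n_birds),
                      "brood-guard", "incubation"), each = hours_per_bird)
  data.frame(bird_id = bird,
             hour = rep(seq_len(hours_per_bird), times = n_birds),
             windspeed = wind, swell_height = swell,
             BWA = runif(n, 0, 180), BSA = runif(n, 0, 180),
             flaps = rnbinom(n, size = nb_size, mu = mu),
             stage = stage, complete_trip = TRUE,
             stringsAsFactors = FALSE)
}
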