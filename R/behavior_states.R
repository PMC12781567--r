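# Movement-state segmentation.
#
# A 3-state hidden Markov model on 10-min step lengths (gamma emissions) and
# turn angles (von Mises emissions) segments tracks into resting-on-water,
# foraging and commuting; the latter two are grouped as "flight" downstream.
# Fitting maximizes the forward-algorithm log-likelihood directly over
# multiple seeded random starts; decoding is Viterbi. The forward and Viterbi
# recursions run in compiled code and are cross-checked in tests against
# exhaustive path enumeration.

STEP_FLOOR_KM <- 0.001 # 1 m floor replacing exact-zero steps in the gamma

#' Step lengths and turn angles from a 10-min track
#'
#' Steps are great-circle (haversine, R = 6371 km) distances between
#' consecutive fixes; turns are the signed change in initial bearing between
#' consecutive steps, wrapped to (-pi, pi]. The first turn (and any turn
#' adjacent to a missing fix or zero-length step) is missing.
#'
#' @param track data.frame with columns `time`, `lat`, `lon` on a uniform
#'   10-min grid (missing fixes as NA), at least 3 fixes.
#' @return data.frame of class `step_series` with columns `step` (km) and
#'   `turn` (radians); `turn[1]` is structurally NA so there is one fewer
#'   turn than steps.
#' @export
track_steps_angles <- function(track) {
  if (nrow(track) < 3) stop("track_steps_angles requires at least 3 fixes")
  n <- nrow(track) - 1
  p <- cbind(track$lon, track$lat)
  step <- geosphere::distHaversine(p[-(n + 1), , drop = FALSE],
                                   p[-1, , drop = FALSE], r = EARTH_RADIUS_M) / 1000
  brg <- geosphere::bearing(p[-(n + 1), , drop = FALSE], p[-1, , drop = FALSE])
  turn <- c(NA_real_, wrap_pi(diff(brg) * pi / 180))
  turn[c(FALSE, step[-n] < STEP_FLOOR_KM / 2) | step < STEP_FLOOR_KM / 2] <- NA_real_
  structure(data.frame(step = step, turn = turn),
            class = c("step_series", "data.frame"))
}

#' HMM parameter set
#'
#' @param tpm 3x3 row-stochastic transition matrix (rows sum to 1 within
#'   1e-10), states ordered rest < forage < commute by mean step length.
#' @param step_mean,step_sd per-state gamma step-length mean/sd in km (> 0).
#' @param turn_mean per-state von Mises mean direction (radians).
#' @param turn_kappa per-state von Mises concentration (>= 0).
#' @param delta initial state distribution; defaults to the stationary
#'   distribution of `tpm`.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(tpm, step_mean, step_sd, turn_mean = c(0, 0, 0),
                       turn_kappa, delta = NULL) {
  stopifnot(is.matrix(tpm), all(dim(tpm) == c(3, 3)))
  if (any(tpm < 0) || any(abs(rowSums(tpm) - 1) > 1e-10))
    stop("tpm rows must sum to 1 within 1e-10")
  stopifnot(all(step_mean > 0), all(step_sd > 0), all(turn_kappa >= 0),
            length(step_mean) == 3, length(step_sd) == 3,
            length(turn_mean) == 3, length(turn_kappa) == 3)
  if (is.null(delta)) delta <- stationary_dist(tpm)
  structure(list(tpm = tpm, step_mean = step_mean, step_sd = step_sd,
                 turn_mean = turn_mean, turn_kappa = turn_kappa,
                 delta = delta), class = "hmm_params")
}

# stationary distribution of a stochastic matrix (left eigenvector)
stationary_dist <- function(tpm) {
  e <- eigen(t(tpm))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

# T x 3 matrix of log emission densities; missing components contribute 0
emission_logdens <- function(params, series) {
  step <- pmax(series$step, STEP_FLOOR_KM)
  n <- length(step)
  ld <- matrix(0, n, 3)
  for (k in 1:3) {
    gp <- gamma_pars(params$step_mean[k], params$step_sd[k])
    ls <- dgamma(step, shape = gp$shape, rate = gp$rate, log = TRUE)
    ls[is.na(ls)] <- 0
    lt <- rep(0, n)
    ok <- !is.na(series$turn)
    lt[ok] <- ldvm(series$turn[ok], params$turn_mean[k], params$turn_kappa[k])
    ld[, k] <- ls + lt
  }
  ld
}

as_series_list <- function(series) {
  if (inherits(series, "step_series") || (is.data.frame(series) && !is.null(series$step)))
    list(series) else series
}

#' Forward-algorithm log-likelihood
#'
#' Scaled forward recursion; for a list of series (pooled birds) the
#' log-likelihoods sum and the chain does not bridge trips.
#'
#' @param params an [hmm_params()].
#' @param series a `step_series` or list of them.
#' @return total log-likelihood.
#' @export
forward_loglik <- function(params, series) {
  sum(vapply(as_series_list(series), function(s) {
    .hmm_forward_cpp(emission_logdens(params, s), params$tpm, params$delta)
  }, numeric(1)))
}

# unconstrained working vector <-> hmm_params; tpm off-diagonals are
# multinomial logits relative to the diagonal entry, column-major order
pars_to_vec <- function(p) {
  off <- log(sweep(p$tpm, 1, diag(p$tpm), "/"))
  c(off[!diag(3) == 1], log(p$step_mean), log(p$step_sd),
    p$turn_mean, log(p$turn_kappa))
}

vec_to_pars <- function(v) {
  m <- matrix(0, 3, 3)
  m[!diag(3) == 1] <- v[1:6]
  tpm <- exp(m)
  tpm <- tpm / rowSums(tpm)
  hmm_params(tpm = tpm, step_mean = exp(v[7:9]), step_sd = exp(v[10:12]),
             turn_mean = wrap_pi(v[13:15]), turn_kappa = exp(v[16:18]))
}

# order states by mean step length: rest < forage < commute
relabel_by_step <- function(p) {
  o <- order(p$step_mean)
  hmm_params(tpm = p$tpm[o, o], step_mean = p$step_mean[o],
             step_sd = p$step_sd[o], turn_mean = p$turn_mean[o],
             turn_kappa = p$turn_kappa[o])
}

#' Fit the 3-state movement HMM
#'
#' Maximizes the pooled forward log-likelihood by quasi-Newton optimization
#' from `n_starts` seeded random initializations around moment-based guesses,
#' returning the best converged fit with states relabeled so mean step length
#' orders rest < forage < commute. The initial distribution is tied to the
#' stationary distribution of the transition matrix.
#'
#' @param series a `step_series` or list of them (pooled across birds); at
#'   least 100 intervals in total.
#' @param n_starts number of random starts.
#' @param seed integer seed for the starts.
#' @return object of class `hmm_fit`: list with `params` ([hmm_params()]),
#'   `loglik`, `n_starts`, `convergence` (per-start optim codes).
#' @export
fit_hmm <- function(series, n_starts = 25, seed = 1L) {
  sl <- as_series_list(series)
  n_tot <- sum(vapply(sl, nrow, integer(1)))
  if (n_tot < 100) stop("fit_hmm requires at least 100 intervals")
  steps <- pmax(unlist(lapply(sl, `[[`, "step")), STEP_FLOOR_KM)
  steps <- steps[!is.na(steps)]
  base_means <- as.numeric(quantile(steps, c(0.15, 0.5, 0.9)))
  base_means <- pmax(base_means, STEP_FLOOR_KM * c(1, 2, 4)) * c(1, 1.001, 1.002)
  negll <- function(v) {
    p <- try(vec_to_pars(v), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    # guard against likelihood spikes: no emission component may collapse
    # onto single observations (sd below the 1 m step floor) or become a
    # near-point mass on the circle
    if (any(p$step_sd < STEP_FLOOR_KM) || any(p$turn_kappa > 1e3) ||
        any(p$step_mean > 1e4)) return(1e10)
    ll <- try(suppressWarnings(forward_loglik(p, sl)), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  best <- NULL; best_val <- Inf; codes <- integer(0)
  for (s in seq_len(n_starts)) {
    init <- hmm_params(
      tpm = matrix(rep(1 / 3, 9), 3) * 0 + (diag(3) * 0.6 + 0.2 / 1.5),
      step_mean = base_means * exp(rnorm(3, 0, 0.4)),
      step_sd = base_means * runif(3, 0.4, 1.2),
      turn_mean = c(0, 0, 0),
      turn_kappa = exp(rnorm(3, 0, 1)))
    v0 <- pars_to_vec(init)
    fit <- try(optim(v0, negll, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-9)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    codes <- c(codes, fit$convergence)
    if (fit$value < best_val) { best_val <- fit$value; best <- fit }
  }
  if (is.null(best) || best_val >= 1e9)
    stop("fit_hmm: optimizer failed to converge on all starts (",
         n_starts, " starts; convergence codes: ",
         paste(codes, collapse = ","), ")")
  params <- relabel_by_step(vec_to_pars(best$par))
  structure(list(params = params, loglik = -best_val, n_starts = n_starts,
                 convergence = codes), class = "hmm_fit")
}

#' Viterbi state decoding
#'
#' Most-probable state path under the fitted model; ties break toward the
#' lower state index (rest < forage < commute).
#'
#' @param params an [hmm_params()] or `hmm_fit`.
#' @param series a `step_series`.
#' @return factor of per-interval labels in (rest, forage, commute), with a
#'   logical attribute-free helper column available via
#'   `decoded %in% c("forage", "commute")` for the flight flag.
#' @export
decode_states <- function(params, series) {
  if (inherits(params, "hmm_fit")) params <- params$params
  ld <- emission_logdens(params, series)
  path <- .hmm_viterbi_cpp(ld, params$tpm, params$delta)
  factor(state_labels[path], levels = state_labels)
}

#' Validate HMM resting calls against an immersion log
#'
#' A 10-min interval is GLS-on-water when any wet record of duration >= 6 s
#' overlaps it. Returns the fraction of HMM-rest intervals that are also
#' GLS-on-water (the agreement statistic).
#'
#' @param states factor of decoded per-interval labels.
#' @param interval_start POSIXct starts of the intervals.
#' @param immersion data.frame with `start`, `end` (POSIXct) and `state`
#'   (`"wet"`/`"dry"`); only wet records matter.
#' @param interval_sec interval length in seconds.
#' @return agreement fraction in [0, 1]; NA (with a message) when there are
#'   no HMM-rest intervals.
#' @export
validate_against_immersion <- function(states, interval_start, immersion,
                                       interval_sec = 600) {
  stopifnot(length(states) == length(interval_start))
  rest <- which(states == "rest")
  if (length(rest) == 0) {
    message("no HMM-rest intervals; agreement undefined")
    return(NA_real_)
  }
  wet <- immersion[immersion$state == "wet" &
                   as.numeric(immersion$end) - as.numeric(immersion$start) >= 6, ,
                   drop = FALSE]
  if (nrow(wet) == 0) return(0)
  s <- as.numeric(interval_start[rest]); e <- s + interval_sec
  ws <- as.numeric(wet$start); we <- as.numeric(wet$end)
  on_water <- vapply(seq_along(s), function(i) any(ws < e[i] & we > s[i]), logical(1))
  mean(on_water)
}

#' Brute-force HMM likelihood and best path by path enumeration
#'
#' Sums the joint likelihood over all `3^T` state paths (and returns the
#' argmax path). Exponential in the series length; intended as an
#' independent oracle for short series only.
#'
#' @param params an [hmm_params()].
#' @param series a short `step_series` (length <= 10).
#' @return list with `loglik` and `best_path` (integer states).
#' @export
enumerate_paths <- function(params, series) {
  n <- nrow(series)
  stopifnot(n <= 10)
  ld <- emission_logdens(params, series)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(st) {
    v <- log(params$delta[st[1]]) + ld[1, st[1]]
    if (n > 1) for (t in 2:n)
      v <- v + log(params$tpm[st[t - 1], st[t]]) + ld[t, st[t]]
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = as.integer(paths[which.max(lp), ]))
}

#' Read a GPS CSV (bird_id, timestamp, lat, lon)
#' @param path file path.
#' @return data.frame with POSIXct `time`.
#' @export
read_gps_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(bird_id = d$bird_id,
             time = as.POSIXct(d$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
             lat = d$lat, lon = d$lon, stringsAsFactors = FALSE)
}

#' Read an immersion CSV (bird_id, start, end, state)
#' @param path file path.
#' @return data.frame with POSIXct `start`/`end`.
#' @export
read_immersion_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  fmt <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")
  data.frame(bird_id = d$bird_id,
             start = as.POSIXct(d$start, tz = "UTC", tryFormats = fmt),
             end = as.POSIXct(d$end, tz = "UTC", tryFormats = fmt),
             state = d$state, stringsAsFactors = FALSE)
}

#' Write decoded states as CSV
#' @param states factor of labels; @param times interval starts;
#' @param bird_id id; @param path output file.
#' @return the path, invisibly.
#' @export
write_states_csv <- function(states, times, bird_id, path) {
  write.csv(data.frame(bird_id = bird_id,
                       timestamp = format(times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                       state = as.character(states)),
            path, row.names = FALSE)
  invisible(path)
}
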