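# Wing-flap counting from the heave axis.
#
# Individual wingbeats appear as impulsive spikes on the dorsoventral (z,
# "heave") axis of a bird-borne accelerometer. The detector (i) rigidly
# rotates the trace into the animal frame to absorb small tag-placement
# errors, (ii) removes impulses with a LULU nonlinear smoother so the
# residual isolates the flap spikes, and (iii) keeps residual peaks above a
# threshold subject to a refractory gap, greedily in descending height.

#' Construct an acceleration trace
#'
#' @param time sample times in seconds from trace start (uniform).
#' @param ax,ay,az acceleration in g (z is the heave axis).
#' @param rate sampling rate in Hz.
#' @param start_time POSIXct (UTC) of the first sample.
#' @return data.frame of class `accel_trace` with attributes `rate` and
#'   `start_time`.
#' @export
accel_trace <- function(time, ax, ay, az, rate,
                        start_time = as.POSIXct("2022-01-01 00:00:00", tz = "UTC")) {
  stopifnot(length(time) == length(ax), length(ax) == length(ay),
            length(ay) == length(az), rate > 0)
  n <- length(time)
  if (n > 1) {
    # O(1)-ish uniformity check: overall span plus a subsample of gaps
    if (abs((time[n] - time[1]) / (n - 1) - 1 / rate) > 1e-6)
      stop("accel_trace requires uniform sampling at the stated rate (jitter <= 1e-6 s)")
    i <- unique(pmax(2L, as.integer(seq(2, n, length.out = min(n, 2000)))))
    if (any(abs((time[i] - time[i - 1L]) - 1 / rate) > 1e-6))
      stop("accel_trace requires uniform sampling at the stated rate (jitter <= 1e-6 s)")
  }
  structure(list(time = time, ax = ax, ay = ay, az = az),
            row.names = c(NA_integer_, -length(time)),
            rate = rate, start_time = start_time,
            class = c("accel_trace", "data.frame"))
}

accel_rate <- function(trace) attr(trace, "rate")
accel_start <- function(trace) attr(trace, "start_time")

#' LULU floor operator L_n
#'
#' `L_n(x)_i = max_{j in [i-n, i]} min_{k in [j, j+n]} x_k`. Removes upward
#' impulses of width at most `n` while preserving edges. The finite sequence
#' is evaluated as on its constant extension (end values replicated), which
#' keeps monotone sequences exact fixed points at the boundaries.
#'
#' @param x numeric sequence of length > 2n.
#' @param n operator half-width in samples (>= 1).
#' @return filtered sequence, same length.
#' @export
lulu_floor <- function(x, n) {
  stopifnot(n >= 1, length(x) > 2 * n)
  .lulu_floor_cpp(as.numeric(x), as.integer(n))
}

#' LULU ceiling operator U_n
#'
#' The dual of [lulu_floor()] with min and max exchanged; removes downward
#' impulses of width at most `n`.
#'
#' @inheritParams lulu_floor
#' @return filtered sequence, same length.
#' @export
lulu_ceil <- function(x, n) {
  stopifnot(n >= 1, length(x) > 2 * n)
  .lulu_ceil_cpp(as.numeric(x), as.integer(n))
}

#' Composed LULU smoother
#'
#' @param x numeric sequence.
#' @param n operator half-width in samples.
#' @param composition `"LU"` applies L after U (`L(U(x))`), `"UL"` the
#'   reverse. Both are idempotent.
#' @return smoothed sequence.
#' @export
lulu_smooth <- function(x, n, composition = c("LU", "UL")) {
  composition <- match.arg(composition)
  if (composition == "LU") lulu_floor(lulu_ceil(x, n), n)
  else lulu_ceil(lulu_floor(x, n), n)
}

#' Flap-detection configuration
#'
#' @param lulu_window LULU operator half-width in samples. The window must
#'   sit strictly between the spike width and the inter-beat valley width:
#'   wide enough that a wingbeat impulse is removed by the smoother (and so
#'   survives in the residual), narrow enough that the valleys between
#'   consecutive beats of a bout are not filled in. The default 4 (0.16 s at
#'   25 Hz) does both for ~2--4-sample spikes at ~3 Hz wingbeats.
#' @param composition `"LU"` (default) applies the floor after the ceiling,
#'   `L(U(x))`; its residual is non-positive at noise maxima, which keeps
#'   the false-peak rate low. `"UL"` is the dual (see [lulu_smooth()]).
#' @param threshold residual peak height in g; the default 0.5 sits midway
#'   between a 0.15 g noise floor and a 1.2 g wingbeat spike.
#' @param refractory minimum inter-peak separation in seconds; must be at
#'   least one sample. The default 0.15 s is under half a wingbeat at 3 Hz.
#' @return object of class `flap_config`.
#' @export
flap_config <- function(lulu_window = 4, composition = "LU",
                        threshold = 0.5, refractory = 0.15) {
  stopifnot(lulu_window >= 1, threshold > 0, refractory > 0,
            composition %in% c("LU", "UL"))
  structure(list(lulu_window = as.integer(lulu_window),
                 composition = composition, threshold = threshold,
                 refractory = refractory), class = "flap_config")
}

# low-pass by centred moving average over a window of `sec` seconds
# (cumsum implementation; NA at the edges where the window is incomplete)
lowpass_mean <- function(x, rate, sec = 2) {
  n <- length(x)
  h <- max(1L, as.integer(round(sec * rate / 2)))
  w <- 2L * h + 1L
  if (n < w) return(rep(mean(x), n))
  cs <- c(0, cumsum(x))
  out <- rep(NA_real_, n)
  i <- (h + 1L):(n - h)
  out[i] <- (cs[i + h + 1L] - cs[i - h]) / w
  out
}

# Rodrigues rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(1 + c_) < 1e-12) return(diag(c(1, -1, -1))) # antipodal: 180 deg about x
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Rotate a trace into the animal frame
#'
#' Estimates a single rigid rotation from quiescent segments (the
#' lowest-variance decile of 10 s windows) such that the low-pass mean
#' acceleration vector maps onto (0, 0, 1 g), absorbing small tag placement
#' errors. If no quiescent segment is found, warns and uses the global
#' low-pass mean.
#'
#' @param trace an [accel_trace()] with at least 60 s of data.
#' @return rotated [accel_trace()], with the 3x3 rotation matrix attached as
#'   attribute `rotation`.
#' @export
rotate_to_animal_frame <- function(trace) {
  rate <- accel_rate(trace)
  n <- nrow(trace)
  if (n < 60 * rate) stop("rotate_to_animal_frame requires >= 60 s of data")
  lp <- cbind(lowpass_mean(trace$ax, rate), lowpass_mean(trace$ay, rate),
              lowpass_mean(trace$az, rate))
  win <- as.integer(10 * rate)
  n_win <- n %/% win
  g0 <- NULL
  if (n_win >= 2) {
    idx <- rep(seq_len(n_win), each = win)
    vtot <- vapply(seq_len(n_win), function(k) {
      s <- ((k - 1) * win + 1):(k * win)
      var(trace$ax[s]) + var(trace$ay[s]) + var(trace$az[s])
    }, numeric(1))
    quiet <- which(vtot <= quantile(vtot, 0.1))
    sel <- which(idx %in% quiet)
    m <- colMeans(lp[sel, , drop = FALSE], na.rm = TRUE)
    if (all(is.finite(m)) && sqrt(sum(m^2)) > 0.5) g0 <- m
  }
  if (is.null(g0)) {
    warning("no quiescent segment found; using the global low-pass mean")
    g0 <- colMeans(lp, na.rm = TRUE)
  }
  R <- rotation_between(g0, c(0, 0, 1))
  rot <- cbind(trace$ax, trace$ay, trace$az) %*% t(R)
  out <- accel_trace(trace$time, rot[, 1], rot[, 2], rot[, 3], rate,
                     accel_start(trace))
  attr(out, "rotation") <- R
  out
}

# local maxima above a threshold; plateau peaks resolve to their first sample
local_maxima <- function(x, threshold) {
  n <- length(x)
  if (n < 2) return(integer(0))
  prev <- c(-Inf, x[-n])
  nxt <- c(x[-1], -Inf)
  which(x > threshold & x > prev & x >= nxt)
}

#' Detect individual wing flaps
#'
#' Computes the residual of the heave axis against its LULU-smoothed
#' baseline, finds residual local maxima above the threshold, and accepts
#' them greedily in descending height subject to the refractory gap.
#'
#' @param trace a rotated [accel_trace()].
#' @param config a [flap_config()].
#' @return object of class `flap_events`: list with `peak_times` (seconds
#'   from trace start, strictly increasing), `peak_heights` (g), `start_time`
#'   and `duration` (s).
#' @export
detect_flaps <- function(trace, config = flap_config()) {
  rate <- accel_rate(trace)
  if (config$refractory < 1 / rate)
    stop("refractory must be at least one sample interval")
  resid <- trace$az - lulu_smooth(trace$az, config$lulu_window, config$composition)
  cand <- local_maxima(resid, config$threshold)
  if (length(cand) == 0) {
    return(structure(list(peak_times = numeric(0), peak_heights = numeric(0),
                          start_time = accel_start(trace),
                          duration = nrow(trace) / rate),
                     class = "flap_events"))
  }
  h <- resid[cand]
  ord <- order(h, decreasing = TRUE)
  tms <- trace$time[cand][ord]
  keep <- .greedy_refractory_cpp(tms, config$refractory)
  kept <- sort(tms[keep])
  structure(list(peak_times = kept,
                 peak_heights = resid[cand][ord][keep][order(tms[keep])],
                 start_time = accel_start(trace),
                 duration = nrow(trace) / rate),
            class = "flap_events")
}

#' Sum flap events into hourly counts
#'
#' Counts peaks per UTC clock hour with the half-open convention
#' `[hour, hour + 1)`: a peak exactly on a boundary belongs to the later
#' hour. Hours are the same clock hours as the environment grid.
#'
#' @param events a `flap_events` object (see [detect_flaps()]).
#' @param hours POSIXct vector of clock-hour starts to count into; defaults
#'   to the hours spanned by the events' trace.
#' @return data.frame with columns `hour` (POSIXct) and `flaps` (integer);
#'   counts sum to the total number of peaks inside the hour range.
#' @export
flaps_per_hour <- function(events, hours = NULL) {
  stopifnot(inherits(events, "flap_events"))
  if (is.null(hours)) {
    first <- as.POSIXct(trunc(events$start_time, "hours"))
    n_h <- ceiling(as.numeric(difftime(events$start_time + events$duration,
                                       first, units = "hours")))
    hours <- first + 3600 * (seq_len(max(1, n_h)) - 1)
  }
  abs_t <- as.numeric(events$start_time) + events$peak_times
  idx <- findInterval(abs_t, as.numeric(hours))
  in_range <- idx >= 1 & abs_t < as.numeric(hours[length(hours)]) + 3600
  counts <- tabulate(idx[in_range], nbins = length(hours))
  data.frame(hour = hours, flaps = as.integer(counts))
}

#' Downsample a 75 Hz trace to 25 Hz
#'
#' Applies a 10 Hz low-pass (4th-order Butterworth, zero-phase) to each axis
#' as anti-alias protection, then keeps every `factor`-th sample.
#'
#' @param trace an [accel_trace()].
#' @param factor integer decimation factor (3 for 75 to 25 Hz).
#' @return decimated [accel_trace()].
#' @export
downsample_accel <- function(trace, factor = 3L) {
  rate <- accel_rate(trace)
  new_rate <- rate / factor
  bf <- signal::butter(4, 10 / (rate / 2), type = "low")
  keep <- seq(1, nrow(trace), by = factor)
  f <- function(x) signal::filtfilt(bf, x)[keep]
  accel_trace(time = (seq_along(keep) - 1) / new_rate,
              ax = f(trace$ax), ay = f(trace$ay), az = f(trace$az),
              rate = new_rate, start_time = accel_start(trace))
}

#' Read an acceleration CSV
#'
#' Expects columns `timestamp` (ISO-8601 or epoch seconds), `ax`, `ay`, `az`
#' in g.
#'
#' @param path file path.
#' @param rate sampling rate in Hz; inferred from timestamps if omitted.
#' @return an [accel_trace()].
#' @export
read_accel_csv <- function(path, rate = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ts <- d$timestamp
  abs_t <- if (is.numeric(ts)) as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
           else as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  rel <- as.numeric(abs_t) - as.numeric(abs_t[1])
  if (is.null(rate)) rate <- round(1 / median(diff(rel)))
  accel_trace(time = (seq_along(rel) - 1) / rate, ax = d$ax, ay = d$ay,
              az = d$az, rate = rate, start_time = abs_t[1])
}

#' Write hourly flap counts as CSV
#'
#' @param counts data.frame from [flaps_per_hour()].
#' @param bird_id bird identifier.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_flap_csv <- function(counts, bird_id, path) {
  out <- data.frame(bird_id = bird_id,
                    hour = format(counts$hour, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    flaps = counts$flaps)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
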