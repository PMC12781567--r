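# Track-environment synchronization.
#
# Interpolates raw GPS to the 10-min grid, extracts hourly wind and swell at
# the bird's top-of-hour position by bilinear interpolation, converts the u/v
# wind components into speed (km/h) and a meteorological coming-from
# direction, folds bird-relative wind and swell angles onto [0, 180] (0 =
# traveling with the flow, 180 = against it), and assembles the hourly
# modeling table restricted to hours of continuous flight.

#' Hourly environment grid container
#'
#' @param time POSIXct vector of clock hours (UTC).
#' @param lat,lon regular coordinate vectors (degrees, increasing).
#' @param u10,v10 10 m wind components in m/s, arrays `[time, lat, lon]`.
#' @param swh significant height of total swell in m (>= 0).
#' @param swd mean swell direction in degrees `[0, 360)`, same convention as
#'   wind (coming-from) unless flipped at extraction.
#' @return object of class `env_grid`.
#' @export
env_grid <- function(time, lat, lon, u10, v10, swh, swd) {
  dims <- c(length(time), length(lat), length(lon))
  for (a in list(u10, v10, swh, swd))
    stopifnot(identical(dim(a), dims))
  stopifnot(!is.unsorted(lat), !is.unsorted(lon), all(swh >= 0, na.rm = TRUE))
  structure(list(time = time, lat = lat, lon = lon, u10 = u10, v10 = v10,
                 swh = swh, swd = swd), class = "env_grid")
}

#' Interpolate a raw GPS track onto a uniform grid
#'
#' Linear interpolation of lat/lon onto a uniform grid at `interval` minutes;
#' grid points falling inside a gap between fixes longer than `max_gap_min`
#' are left missing rather than bridged.
#'
#' @param track data.frame with `time` (POSIXct, ordered), `lat`, `lon`.
#' @param interval grid interval in minutes.
#' @param max_gap_min largest bridgeable gap in minutes.
#' @return data.frame `time`, `lat`, `lon` on the uniform grid (NA inside
#'   long gaps), plus `bird_id` if present in the input.
#' @export
interpolate_track <- function(track, interval = 10, max_gap_min = 60) {
  if (is.unsorted(as.numeric(track$time)))
    stop("track timestamps must be time-ordered")
  t0 <- as.numeric(track$time)
  step <- interval * 60
  grid <- seq(ceiling(t0[1] / step) * step, floor(t0[length(t0)] / step) * step,
              by = step)
  la <- approx(t0, track$lat, xout = grid)$y
  lo <- approx(t0, track$lon, xout = grid)$y
  if (length(t0) > 1) {
    gaps <- which(diff(t0) > max_gap_min * 60)
    for (g in gaps) {
      inside <- grid > t0[g] & grid < t0[g + 1]
      la[inside] <- NA; lo[inside] <- NA
    }
  }
  out <- data.frame(time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                    lat = la, lon = lo)
  if (!is.null(track$bird_id)) out$bird_id <- track$bird_id[1]
  out
}

#' Wind speed and direction from u/v components
#'
#' Speed in km/h; direction is the meteorological coming-from convention:
#' `wind_from = (270 - atan2(v, u) * 180/pi) mod 360`, so (0, -5) is a
#' northerly (from the north) and (-5, 0) an easterly.
#'
#' @param u,v 10 m wind components in m/s.
#' @return data.frame with `speed` (km/h) and `wind_from` (degrees).
#' @export
wind_speed_dir <- function(u, v) {
  data.frame(speed = 3.6 * sqrt(u^2 + v^2),
             wind_from = wrap_360(270 - atan2(v, u) * 180 / pi))
}

#' Bird-relative flow angle folded onto [0, 180]
#'
#' Folds the angle between the bird's travel bearing and the direction the
#' flow travels toward. `origin_dir` is the coming-from direction (the
#' meteorological convention for wind and, by default, swell): 0 is a direct
#' tailwind / traveling with the swell, 180 a direct headwind / against it.
#'
#' @param bearing travel bearing in degrees.
#' @param origin_dir coming-from direction of the flow in degrees.
#' @param origin_convention if `FALSE`, `origin_dir` is already the
#'   going-toward direction (some gridded swell products); no 180 flip.
#' @return folded angle in degrees `[0, 180]`.
#' @export
relative_angle <- function(bearing, origin_dir, origin_convention = TRUE) {
  toward <- if (origin_convention) wrap_360(origin_dir + 180) else wrap_360(origin_dir)
  d <- abs(wrap_360(bearing) - toward) %% 360
  pmin(d, 360 - d)
}

# bilinear interpolation of one [time, lat, lon] array at fixed hour index
bilinear_at <- function(a, hi, lat_grid, lon_grid, lat, lon) {
  i <- findInterval(lat, lat_grid, rightmost.closed = TRUE)
  j <- findInterval(lon, lon_grid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lat_grid) - 1L)
  j <- pmin(pmax(j, 1L), length(lon_grid) - 1L)
  fy <- (lat - lat_grid[i]) / (lat_grid[i + 1] - lat_grid[i])
  fx <- (lon - lon_grid[j]) / (lon_grid[j + 1] - lon_grid[j])
  a11 <- a[cbind(hi, i, j)];     a12 <- a[cbind(hi, i, j + 1)]
  a21 <- a[cbind(hi, i + 1, j)]; a22 <- a[cbind(hi, i + 1, j + 1)]
  (1 - fy) * ((1 - fx) * a11 + fx * a12) + fy * ((1 - fx) * a21 + fx * a22)
}

#' Extract wind and swell at positions and hours
#'
#' Bilinear interpolation in space at the exact hourly field (the grid is
#' hourly; no temporal interpolation). Swell direction interpolates on its
#' sine/cosine to respect circularity. Positions outside the grid extent
#' yield missing values with a warning.
#'
#' @param grid an [env_grid()].
#' @param lat,lon positions (degrees).
#' @param hour POSIXct clock hours, matching the grid's time index.
#' @param swell_origin_convention is the grid's swell direction a coming-from
#'   direction (like wind)? Stored on the result for downstream angle use.
#' @return data.frame with `windspeed` (km/h), `wind_from` (deg),
#'   `swell_height` (m), `swell_dir` (deg).
#' @export
extract_env <- function(grid, lat, lon, hour, swell_origin_convention = TRUE) {
  hi <- match(floor(as.numeric(hour) / 3600) * 3600, as.numeric(grid$time))
  outside <- is.na(lat) | is.na(lon) |
    lat < min(grid$lat) | lat > max(grid$lat) |
    lon < min(grid$lon) | lon > max(grid$lon) | is.na(hi)
  if (any(outside & !is.na(lat)))
    warning(sum(outside & !is.na(lat)), " position(s) outside the grid extent or time index; returning NA")
  hi2 <- ifelse(outside, 1L, hi)
  la2 <- ifelse(outside, grid$lat[1], lat)
  lo2 <- ifelse(outside, grid$lon[1], lon)
  u <- bilinear_at(grid$u10, hi2, grid$lat, grid$lon, la2, lo2)
  v <- bilinear_at(grid$v10, hi2, grid$lat, grid$lon, la2, lo2)
  sh <- bilinear_at(grid$swh, hi2, grid$lat, grid$lon, la2, lo2)
  sdir <- wrap_360(atan2(
    bilinear_at(sin(grid$swd * pi / 180), hi2, grid$lat, grid$lon, la2, lo2),
    bilinear_at(cos(grid$swd * pi / 180), hi2, grid$lat, grid$lon, la2, lo2)
  ) * 180 / pi)
  ws <- wind_speed_dir(u, v)
  out <- data.frame(windspeed = ws$speed, wind_from = ws$wind_from,
                    swell_height = sh, swell_dir = sdir)
  out[outside, ] <- NA
  attr(out, "swell_origin_convention") <- swell_origin_convention
  out
}

#' Build the hourly modeling table for one bird
#'
#' One row per bird-hour of continuous flight: hours containing at least one
#' rest-decoded 10-min interval are dropped. The bird's bearing is the
#' initial great-circle bearing from its top-of-hour position to the next
#' hour's position; bird-wind and bird-swell angles attach via
#' [relative_angle()].
#'
#' @param states decoded per-interval labels (factor) aligned with
#'   `track` intervals.
#' @param events `flap_events` for the bird (see [detect_flaps()]).
#' @param track interpolated 10-min track (`time`, `lat`, `lon`).
#' @param grid an [env_grid()].
#' @param bird_id identifier for the rows.
#' @param stage breeding stage label (`"incubation"` or `"brood-guard"`).
#' @param complete_trip did the trip end back at the colony?
#' @param swell_origin_convention see [extract_env()].
#' @return data.frame of hourly records: bird_id, hour, lat, lon, bearing,
#'   flaps, windspeed, wind_from, swell_height, swell_dir, BWA, BSA, stage,
#'   complete_trip.
#' @export
hourly_aggregate <- function(states, events, track, grid, bird_id = "b01",
                             stage = "incubation", complete_trip = TRUE,
                             swell_origin_convention = TRUE) {
  tt <- as.numeric(track$time)
  hours_all <- seq(as.POSIXct(trunc(track$time[1], "hours")),
                   as.POSIXct(trunc(track$time[nrow(track)] - 1, "hours")),
                   by = 3600)
  if (length(hours_all) == 0) {
    warning("no overlapping hours between streams; empty table")
    return(NULL)
  }
  hnum <- as.numeric(hours_all)
  # intervals [t_i, t_{i+1}) labelled by states[i]
  int_start <- tt[-length(tt)]
  rest_int <- int_start[as.character(states) == "rest"]
  has_rest <- vapply(hnum, function(h) any(rest_int < h + 3600 & rest_int + 600 > h),
                     logical(1))
  # top-of-hour positions (linear in time between the 10-min fixes)
  pos_lat <- approx(tt, track$lat, xout = hnum)$y
  pos_lon <- approx(tt, track$lon, xout = hnum)$y
  nxt_lat <- approx(tt, track$lat, xout = hnum + 3600)$y
  nxt_lon <- approx(tt, track$lon, xout = hnum + 3600)$y
  bearing <- rep(NA_real_, length(hnum))
  ok <- !is.na(pos_lat) & !is.na(nxt_lat)
  if (any(ok))
    bearing[ok] <- wrap_360(geosphere::bearing(cbind(pos_lon[ok], pos_lat[ok]),
                                               cbind(nxt_lon[ok], nxt_lat[ok])))
  env <- extract_env(grid, pos_lat, pos_lon, hours_all,
                     swell_origin_convention = swell_origin_convention)
  flaps <- flaps_per_hour(events, hours_all)$flaps
  out <- data.frame(bird_id = bird_id, hour = hours_all,
                    lat = pos_lat, lon = pos_lon, bearing = bearing,
                    flaps = flaps,
                    windspeed = env$windspeed, wind_from = env$wind_from,
                    swell_height = env$swell_height, swell_dir = env$swell_dir,
                    BWA = relative_angle(bearing, env$wind_from),
                    BSA = relative_angle(bearing, env$swell_dir,
                                         origin_convention = swell_origin_convention),
                    stage = stage, complete_trip = complete_trip,
                    stringsAsFactors = FALSE)
  dropped <- sum(has_rest)
  out <- out[!has_rest & !is.na(pos_lat), , drop = FALSE]
  attr(out, "dropped_rest_hours") <- dropped
  out
}

#' Read an environment grid from long-format CSV
#'
#' Plain-text interchange for the hourly gridded fields: one row per
#' (time, lat, lon) cell with columns `time`, `lat`, `lon`, `u10`, `v10`,
#' `swh`, `swd` (variable names configurable). The grid must be regular.
#'
#' @param path file path.
#' @param vars named character vector mapping the internal names
#'   (u10, v10, swh, swd) to the file's column names.
#' @return an [env_grid()].
#' @export
read_env_csv <- function(path, vars = c(u10 = "u10", v10 = "v10",
                                        swh = "swh", swd = "swd")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  time <- sort(unique(as.POSIXct(d$time, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))))
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  ti <- match(as.POSIXct(d$time, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")), time)
  li <- match(d$lat, lat); lj <- match(d$lon, lon)
  mk <- function(col) {
    a <- array(NA_real_, dim = c(length(time), length(lat), length(lon)))
    a[cbind(ti, li, lj)] <- d[[col]]
    a
  }
  env_grid(time, lat, lon, u10 = mk(vars[["u10"]]), v10 = mk(vars[["v10"]]),
           swh = mk(vars[["swh"]]), swd = mk(vars[["swd"]]))
}

#' Write an environment grid as long-format CSV
#' @param grid an [env_grid()]; @param path output file.
#' @return the path, invisibly.
#' @export
write_env_csv <- function(grid, path) {
  g <- expand.grid(ti = seq_along(grid$time), li = seq_along(grid$lat),
                   lj = seq_along(grid$lon))
  idx <- as.matrix(g)
  out <- data.frame(time = format(grid$time[g$ti], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    lat = grid$lat[g$li], lon = grid$lon[g$lj],
                    u10 = grid$u10[idx], v10 = grid$v10[idx],
                    swh = grid$swh[idx], swd = grid$swd[idx])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a deposited hourly modeling table from CSV
#'
#' Direct entry into the modeling stage for deposited hourly summaries of
#' flap rates and wind/wave conditions. Requires columns bird_id, hour,
#' windspeed, swell_height, BWA, BSA, flaps; stage and complete_trip are
#' optional.
#'
#' @param path file path.
#' @return hourly-record data.frame.
#' @export
read_hourly_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "hour", "windspeed", "swell_height", "BWA", "BSA", "flaps")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("hourly table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"stage" %in% names(d)) d$stage <- "incubation"
  if (!"complete_trip" %in% names(d)) d$complete_trip <- TRUE
  d$bird_id <- factor(d$bird_id)
  d
}

#' Write an hourly modeling table as CSV
#' @param table hourly-record data.frame; @param path output file.
#' @return the path, invisibly.
#' @export
write_hourly_table <- function(table, path) {
  t2 <- table
  if (inherits(t2$hour, "POSIXct"))
    t2$hour <- format(t2$hour, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(t2, path, row.names = FALSE)
  invisible(path)
}
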