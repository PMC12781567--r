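# Shared angular and circular-distribution helpers.
# Conventions: bearings in degrees clockwise from true north; turn angles in
# radians wrapped to (-pi, pi]; positions WGS-84 lat/lon; earth radius 6371 km.

EARTH_RADIUS_M <- 6371000

#' Wrap an angle in radians to (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return wrapped angles.
#' @keywords internal
wrap_pi <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  # %% maps exact pi to -pi; keep the (-pi, pi] convention
  out[out == -pi] <- pi
  out
}

#' Wrap an angle in degrees to [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_360 <- function(x) x %% 360

#' von Mises log-density
#'
#' Log-density of the von Mises distribution, numerically stable for large
#' concentration through the exponentially scaled Bessel function.
#'
#' @param x angles in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0).
#' @return log-density values.
#' @keywords internal
ldvm <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return draws in (-pi, pi].
#' @keywords internal
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(wrap_pi(runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out + mu)
}

# gamma shape/rate from mean and sd
gamma_pars <- function(mean, sd) {
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Azimuthal equal-area projection about a reference point
#'
#' Lambert azimuthal equal-area projection, returning planar coordinates in
#' kilometres. Distance-true near the reference point and area-preserving
#' everywhere, which is what kernel home-range estimates need.
#'
#' @param lat,lon positions in degrees.
#' @param lat0,lon0 projection centre in degrees (e.g. the colony).
#' @return data.frame with columns `x`, `y` in km.
#' @export
project_azeq <- function(lat, lon, lat0, lon0) {
  R <- EARTH_RADIUS_M / 1000
  phi <- lat * pi / 180; phi0 <- lat0 * pi / 180
  dl <- ((lon - lon0 + 180) %% 360 - 180) * pi / 180
  kden <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  k <- sqrt(2 / kden)
  data.frame(
    x = R * k * cos(phi) * sin(dl),
    y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  )
}

#' Inverse azimuthal equal-area projection
#'
#' @param x,y planar coordinates in km as produced by [project_azeq()].
#' @param lat0,lon0 projection centre in degrees.
#' @return data.frame with columns `lat`, `lon` in degrees.
#' @export
unproject_azeq <- function(x, y, lat0, lon0) {
  R <- EARTH_RADIUS_M / 1000
  phi0 <- lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ <- 2 * asin(pmin(1, rho / (2 * R)))
  lat <- ifelse(rho < 1e-12, lat0,
    asin(cos(c_) * sin(phi0) + y * sin(c_) * cos(phi0) / rho) * 180 / pi)
  lon <- ifelse(rho < 1e-12, lon0,
    lon0 + atan2(x * sin(c_), rho * cos(phi0) * cos(c_) - y * sin(phi0) * sin(c_)) * 180 / pi)
  data.frame(lat = lat, lon = ((lon + 180) %% 360) - 180)
}

# derive a reproducible per-stream seed from a base seed, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
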