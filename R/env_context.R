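# Wind/swell availability and use.
#
# Foraging-area utilization distributions (95% KDE on an equal-area
# projection about the colony), monthly wind/swell climatologies inside
# them, tercile categorization of windspeed and swell height from balanced
# cross-basin subsets, and per-species proportions of time in each wind and
# swell category.

#' 95% kernel utilization region of pooled foraging tracks
#'
#' Projects fixes with a Lambert azimuthal equal-area projection centred on
#' the colony, estimates a 2-D Gaussian KDE with an href-style reference
#' bandwidth, and keeps the smallest set of grid cells holding 95% of the
#' estimated mass.
#'
#' @param lat,lon pooled fixes of complete trips for one species
#'   (>= 500 fixes).
#' @param colony named vector `c(lat = , lon = )`, the projection centre.
#' @param prob utilization mass (default 0.95).
#' @param n_grid KDE grid cells per axis.
#' @return object of class `foraging_kde`: grid vectors `x`, `y` (km),
#'   density matrix `dens`, logical `inside`, `area_km2`, enclosed `mass`,
#'   `bandwidth` (km), `colony`, and the density `threshold`.
#' @export
foraging_kde_95 <- function(lat, lon, colony, prob = 0.95, n_grid = 120) {
  ok <- !is.na(lat) & !is.na(lon)
  lat <- lat[ok]; lon <- lon[ok]
  stopifnot(length(lat) >= 500)
  p <- project_azeq(lat, lon, colony[["lat"]], colony[["lon"]])
  if (sd(p$x) < 1e-9 || sd(p$y) < 1e-9)
    stop("foraging_kde_95: degenerate fixes (no spatial spread)")
  n <- length(p$x)
  # href-style reference bandwidth (ad hoc bivariate normal reference)
  h <- sqrt(0.5 * (var(p$x) + var(p$y))) * n^(-1 / 6)
  pad <- 3 * h
  gx <- seq(min(p$x) - pad, max(p$x) + pad, length.out = n_grid)
  gy <- seq(min(p$y) - pad, max(p$y) + pad, length.out = n_grid)
  dx1 <- dnorm(outer(gx, p$x, "-") / h)
  dy1 <- dnorm(outer(gy, p$y, "-") / h)
  dens <- (dx1 %*% t(dy1)) / (n * h^2) # [x, y]
  cell <- diff(gx)[1] * diff(gy)[1]
  mass_cell <- dens * cell
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass_cell[ord])
  total <- sum(mass_cell)
  k <- which(cum >= prob * total)[1]
  threshold <- dens[ord[k]]
  inside <- dens >= threshold
  structure(list(x = gx, y = gy, dens = dens, inside = inside,
                 area_km2 = sum(inside) * cell,
                 mass = sum(mass_cell[inside]) / total,
                 bandwidth = h, threshold = threshold, colony = colony,
                 points = p), class = "foraging_kde")
}

#' Is a lat/lon position inside a foraging KDE region?
#' @param kde a [foraging_kde_95()] result; @param lat,lon positions.
#' @return logical vector (nearest-grid-cell lookup).
#' @export
kde_region_contains <- function(kde, lat, lon) {
  p <- project_azeq(lat, lon, kde$colony[["lat"]], kde$colony[["lon"]])
  i <- pmin(pmax(findInterval(p$x, kde$x), 1L), length(kde$x))
  j <- pmin(pmax(findInterval(p$y, kde$y), 1L), length(kde$y))
  out <- kde$inside[cbind(i, j)]
  out[p$x < min(kde$x) | p$x > max(kde$x) |
      p$y < min(kde$y) | p$y > max(kde$y)] <- FALSE
  out
}

#' Monthly wind/swell climatology inside a foraging region
#'
#' Area-weighted (cosine-latitude) mean of monthly gridded windspeed and
#' swell height over cells whose centres fall inside the KDE region,
#' averaged across years per calendar month. Cells with missing data (e.g.
#' sea ice) are excluded.
#'
#' @param kde a [foraging_kde_95()] result.
#' @param monthly data.frame with columns `year`, `month`, `lat`, `lon`,
#'   `windspeed` (units as supplied), `swell_height` (m); NA allowed.
#' @return data.frame with 12 rows: `month`, `windspeed`, `swell_height`
#'   (multi-year monthly means inside the region).
#' @export
monthly_env_in_kde <- function(kde, monthly) {
  cells <- unique(monthly[, c("lat", "lon")])
  inside <- kde_region_contains(kde, cells$lat, cells$lon)
  if (!any(inside)) stop("monthly_env_in_kde: no grid cells inside the region")
  keep <- merge(monthly, cbind(cells[inside, , drop = FALSE], .in = TRUE),
                by = c("lat", "lon"))
  keep$w <- cos(keep$lat * pi / 180)
  agg <- function(v) {
    ok <- !is.na(keep[[v]])
    s <- tapply(keep[[v]][ok] * keep$w[ok],
                list(keep$month[ok], keep$year[ok]), sum)
    w <- tapply(keep$w[ok], list(keep$month[ok], keep$year[ok]), sum)
    rowMeans(s / w, na.rm = TRUE)
  }
  ws <- agg("windspeed"); sh <- agg("swell_height")
  data.frame(month = as.integer(names(ws)), windspeed = as.numeric(ws),
             swell_height = as.numeric(sh))
}

#' Tercile thresholds of windspeed and swell from a balanced subset
#'
#' Draws `n_per_basin` individuals with complete trips from each ocean
#' basin, balanced as evenly as possible across the species within each
#' basin (remainders distributed deterministically in species order), then
#' takes the 1/3 and 2/3 quantiles of the pooled windspeed and swell-height
#' distributions of the subset.
#'
#' @param table hourly records across species with columns `bird_id`,
#'   `species`, `basin`, `complete_trip`, `windspeed`, `swell_height`.
#' @param n_per_basin individuals sampled per basin.
#' @param seed integer seed.
#' @return object of class `category_thresholds`: `wind_t1`, `wind_t2`
#'   (km/h), `swell_t1`, `swell_t2` (m), and `birds` (the subset ids).
#' @export
category_thresholds <- function(table, n_per_basin = 34, seed = 1L) {
  d <- table[table$complete_trip, , drop = FALSE]
  set.seed(seed)
  chosen <- character(0)
  for (bas in unique(d$basin)) {
    sp <- unique(d$species[d$basin == bas])
    base <- n_per_basin %/% length(sp)
    extra <- n_per_basin %% length(sp)
    quota <- stats::setNames(rep(base, length(sp)), sort(sp))
    if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
    for (s in names(quota)) {
      ids <- unique(d$bird_id[d$basin == bas & d$species == s])
      if (length(ids) < quota[[s]])
        stop("species ", s, " has too few complete-trip birds (",
             length(ids), " < ", quota[[s]], ")")
      chosen <- c(chosen, sample(as.character(ids), quota[[s]]))
    }
  }
  sub <- d[as.character(d$bird_id) %in% chosen, , drop = FALSE]
  qw <- quantile(sub$windspeed, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  qs <- quantile(sub$swell_height, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  if (qw[1] >= qw[2] || qs[1] >= qs[2])
    stop("degenerate thresholds: t1 >= t2 (all-equal or near-constant input)")
  structure(list(wind_t1 = qw[1], wind_t2 = qw[2],
                 swell_t1 = qs[1], swell_t2 = qs[2], birds = chosen),
            class = "category_thresholds")
}

classify_magnitude <- function(x, t1, t2) {
  cut(x, breaks = c(-Inf, t1, t2, Inf), labels = c("low", "med", "high"),
      right = FALSE)
}

classify_angle <- function(a, labels, breaks = c(60, 120)) {
  cut(a, breaks = c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

#' Proportions of time in wind and swell categories
#'
#' Classifies each hour by windspeed and swell tercile (intervals closed on
#' the left at the thresholds) and by folded relative angle (default 60/120
#' degree boundaries: tail/with `[0, 60)`, cross/across `[60, 120)`,
#' head/against `[120, 180]`), computes per-bird proportions, then averages
#' across birds.
#'
#' @param records hourly records for one species: `bird_id`, `windspeed`,
#'   `swell_height`, `BWA`, `BSA`.
#' @param thresholds a [category_thresholds()].
#' @param angle_breaks category boundaries on the 0--180 scale.
#' @return list of named proportion vectors: `wind_magnitude`
#'   (low/med/high), `swell_magnitude`, `wind_angle` (tail/cross/head),
#'   `swell_angle` (with/across/against); each sums to 1.
#' @export
condition_proportions <- function(records, thresholds, angle_breaks = c(60, 120)) {
  per_bird <- function(cls) {
    tab <- table(factor(as.character(records$bird_id)), cls)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    colMeans(tab / rowSums(tab))
  }
  list(
    wind_magnitude = per_bird(classify_magnitude(records$windspeed,
                                                 thresholds$wind_t1, thresholds$wind_t2)),
    swell_magnitude = per_bird(classify_magnitude(records$swell_height,
                                                  thresholds$swell_t1, thresholds$swell_t2)),
    wind_angle = per_bird(classify_angle(records$BWA, c("tail", "cross", "head"),
                                         angle_breaks)),
    swell_angle = per_bird(classify_angle(records$BSA, c("with", "across", "against"),
                                          angle_breaks)))
}
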