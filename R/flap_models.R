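# Flap-rate models against wind and swell.
#
# Six candidate generalized additive models of hourly flap counts per
# species, compared by small-sample-corrected AIC on a common (ML) likelihood:
#   0   intercept only
#   I   s(windspeed)
#   II  s(swell_height)
#   III te(windspeed, BWA)
#   IV  te(swell_height, BSA)
#   V   te(windspeed, swell_height)
# every model carrying a random-effect smooth for bird identity. Prediction
# surfaces are trimmed to the 99% kernel-density region of the observed
# covariate space before the flap-reduction statistic (95th vs 5th quantile
# of masked predictions) is computed.

MODEL_IDS <- c("0", "I", "II", "III", "IV", "V")

model_terms <- function(id, k_marginal = 5, k_tensor = c(5, 5)) {
  switch(id,
    "0"   = "1",
    "I"   = sprintf("s(windspeed, k = %d)", k_marginal),
    "II"  = sprintf("s(swell_height, k = %d)", k_marginal),
    "III" = sprintf("te(windspeed, BWA, k = c(%d, %d))", k_tensor[1], k_tensor[2]),
    "IV"  = sprintf("te(swell_height, BSA, k = c(%d, %d))", k_tensor[1], k_tensor[2]),
    "V"   = sprintf("te(windspeed, swell_height, k = c(%d, %d))", k_tensor[1], k_tensor[2]),
    stop("unknown model id: ", id))
}

model_covars <- function(id) {
  switch(id, "0" = character(0), "I" = "windspeed", "II" = "swell_height",
         "III" = c("windspeed", "BWA"), "IV" = c("swell_height", "BSA"),
         "V" = c("windspeed", "swell_height"))
}

model_label <- function(id) {
  switch(id, "0" = "Null", "I" = "Windspeed", "II" = "Swell height",
         "III" = "Windspeed, BWA", "IV" = "Swell height, BSA",
         "V" = "Windspeed, Swell height")
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2 edf + 2 edf (edf + 1) / (n - edf - 1)`, with the
#' effective degrees of freedom playing the role of the parameter count.
#'
#' @param loglik model log-likelihood.
#' @param edf effective degrees of freedom (n > edf + 1 required).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, edf, n) {
  if (n <= edf + 1) stop("aicc requires n > edf + 1")
  -2 * loglik + 2 * edf + 2 * edf * (edf + 1) / (n - edf - 1)
}

#' Fit one flap-rate model
#'
#' Penalized-spline additive model of hourly flap counts with a log link and
#' an overdispersed count family (negative binomial by default), fitted by
#' ML smoothness selection so that AICc comparisons across the candidate set
#' share a likelihood definition. Every model includes a random-intercept
#' smooth for bird identity.
#'
#' @param table hourly-record data.frame (one species): needs `flaps`,
#'   `bird_id`, and the covariates of the chosen model; at least 200 rows
#'   and 5 birds.
#' @param id model id, one of `"0","I","II","III","IV","V"`.
#' @param family `"nb"` (negative binomial) or `"poisson"`.
#' @param k_marginal basis dimension of marginal smooths.
#' @param k_tensor basis dimensions of tensor-product smooths.
#' @param min_rows,min_birds precondition thresholds (lowered only for
#'   small simulation studies).
#' @return object of class `flap_fit`: list with the mgcv fit (`gam`),
#'   `id`, `label`, `aicc`, `edf`, `loglik`, `n`, `r2` (squared correlation
#'   of fitted and observed), `dev_expl`.
#' @export
fit_flap_model <- function(table, id, family = c("nb", "poisson"),
                           k_marginal = 5, k_tensor = c(5, 5),
                           min_rows = 200, min_birds = 5) {
  family <- match.arg(family)
  id <- match.arg(as.character(id), MODEL_IDS)
  stopifnot(nrow(table) >= min_rows,
            length(unique(table$bird_id)) >= min_birds)
  d <- table
  d$bird_id <- factor(d$bird_id)
  for (cv in model_covars(id))
    if (any(is.na(d[[cv]]))) d <- d[!is.na(d[[cv]]), , drop = FALSE]
  fam <- if (family == "nb") mgcv::nb() else stats::poisson()
  rhs <- paste(model_terms(id, k_marginal, k_tensor),
               '+ s(bird_id, bs = "re")')
  form <- stats::as.formula(paste("flaps ~", rhs))
  fit <- try(mgcv::gam(form, family = fam, data = d, method = "ML"),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("fit_flap_model: model ", id, " (", model_label(id), ") failed: ",
         attr(fit, "condition")$message)
  ll <- as.numeric(logLik(fit))
  # trace of the influence matrix, plus the estimated NB dispersion
  edf <- sum(fit$edf) + if (family == "nb") 1 else 0
  n <- nrow(d)
  structure(list(gam = fit, id = id, label = model_label(id),
                 aicc = aicc(ll, edf, n), edf = edf, loglik = ll, n = n,
                 r2 = stats::cor(fitted(fit), d$flaps)^2,
                 dev_expl = summary(fit)$dev.expl,
                 data = d),
            class = "flap_fit")
}

#' Fit the full candidate set
#'
#' @param table hourly-record data.frame for one species.
#' @param ids model ids to fit (default all six).
#' @param ... passed to [fit_flap_model()].
#' @return named list of `flap_fit` objects.
#' @export
fit_model_set <- function(table, ids = MODEL_IDS, ...) {
  fits <- lapply(ids, function(i) fit_flap_model(table, i, ...))
  names(fits) <- ids
  fits
}

#' Model-selection table with delta-AICc and Akaike weights
#'
#' @param fits list of `flap_fit` objects fitted to identical rows.
#' @return data.frame (ranked by AICc) with columns Model, Term, AICc,
#'   dAICc, df, weight, R2, DE; weights sum to 1.
#' @export
model_selection_table <- function(fits) {
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    stop("model_selection_table: fits are not on identical row sets")
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  d <- a - min(a)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(Model = vapply(fits, `[[`, character(1), "id"),
                    Term = vapply(fits, `[[`, character(1), "label"),
                    AICc = a, dAICc = d,
                    df = vapply(fits, `[[`, numeric(1), "edf"),
                    weight = w,
                    R2 = vapply(fits, `[[`, numeric(1), "r2"),
                    DE = vapply(fits, `[[`, numeric(1), "dev_expl"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  out
}

#' 99% kernel-density mask over a 2-D covariate space
#'
#' Gaussian-product KDE with normal-reference bandwidths; the retained
#' region is the set where the estimated density is at least the 1st
#' percentile of its values at the observed points, so at least ~99% of the
#' observations fall inside (>= 98% guaranteed up to ties).
#'
#' @param x1,x2 observed covariate values (>= 100 points).
#' @param prob mass parameter (default 0.99).
#' @return object of class `kde_mask`: fields `x1`, `x2`, `h1`, `h2`,
#'   `threshold`; use [kde_inside()] to evaluate it.
#' @export
kde_mask_99 <- function(x1, x2, prob = 0.99) {
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  stopifnot(length(x1) >= 100)
  if (sd(x1) == 0 || sd(x2) == 0)
    stop("kde_mask_99: zero-variance dimension")
  h1 <- stats::bw.nrd(x1); h2 <- stats::bw.nrd(x2)
  obj <- structure(list(x1 = x1, x2 = x2, h1 = h1, h2 = h2, prob = prob,
                        threshold = NA_real_), class = "kde_mask")
  f_obs <- kde_density(obj, x1, x2)
  obj$threshold <- as.numeric(quantile(f_obs, 1 - prob, type = 7))
  obj
}

#' Evaluate the product-kernel density of a [kde_mask_99()] object
#' @param mask a `kde_mask`; @param x1,x2 evaluation points.
#' @return density values.
#' @export
kde_density <- function(mask, x1, x2) {
  n <- length(mask$x1)
  out <- numeric(length(x1))
  # evaluate in blocks to bound the size of the outer-product matrices
  for (s in seq(1, length(x1), by = 1000)) {
    e <- min(length(x1), s + 999)
    d1 <- dnorm(outer(x1[s:e], mask$x1, "-") / mask$h1)
    d2 <- dnorm(outer(x2[s:e], mask$x2, "-") / mask$h2)
    out[s:e] <- rowSums(d1 * d2) / (n * mask$h1 * mask$h2)
  }
  out
}

#' Is a point inside the kernel-density region?
#' @param mask a `kde_mask`; @param x1,x2 points to test.
#' @return logical vector.
#' @export
kde_inside <- function(mask, x1, x2) {
  kde_density(mask, x1, x2) >= mask$threshold
}

#' Predicted flap-rate surface over a masked covariate grid
#'
#' Predicts on a regular grid over the observed covariate ranges with the
#' bird random effect excluded (population level) and attaches the 99% KDE
#' mask of the observed points.
#'
#' @param fit a `flap_fit` (typically Model V).
#' @param n_grid grid cells per axis.
#' @param mask optional precomputed `kde_mask`; built from the fit's data
#'   otherwise.
#' @return object of class `prediction_surface`: `x1`, `x2` (grid vectors),
#'   `var_names`, `pred` (matrix), `inside` (logical matrix).
#' @export
prediction_surface <- function(fit, n_grid = 40, mask = NULL) {
  vars <- model_covars(fit$id)
  stopifnot(length(vars) == 2)
  d <- fit$data
  x1 <- seq(min(d[[vars[1]]]), max(d[[vars[1]]]), length.out = n_grid)
  x2 <- seq(min(d[[vars[2]]]), max(d[[vars[2]]]), length.out = n_grid)
  if (is.null(mask)) mask <- kde_mask_99(d[[vars[1]]], d[[vars[2]]])
  g <- expand.grid(x1 = x1, x2 = x2)
  nd <- data.frame(g$x1, g$x2, d$bird_id[1])
  names(nd) <- c(vars, "bird_id")
  pr <- predict(fit$gam, newdata = nd, type = "response",
                exclude = "s(bird_id)", newdata.guaranteed = TRUE)
  inside <- matrix(kde_inside(mask, g$x1, g$x2), n_grid, n_grid)
  structure(list(x1 = x1, x2 = x2, var_names = vars,
                 pred = matrix(as.numeric(pr), n_grid, n_grid),
                 inside = inside, mask = mask),
            class = "prediction_surface")
}

#' Percent reduction from a maximum to a minimum rate
#'
#' `100 * (max - min) / max`, reported to 2 decimals: the reduction in
#' flapping from the high-flap corner of the condition space to the
#' low-flap corner.
#'
#' @param max_rate,min_rate flap rates (flaps/hour), `min_rate <= max_rate`.
#' @return percent reduction, rounded to 2 decimals.
#' @export
percent_reduction <- function(max_rate, min_rate) {
  if (max_rate == 0) return(0)
  round(100 * (max_rate - min_rate) / max_rate, 2)
}

#' Flap-reduction statistic over a masked prediction surface
#'
#' The maximum is the 95th and the minimum the 5th linear-interpolation
#' quantile of the predictions over masked grid cells (equal cell weights);
#' the reduction is their percent difference relative to the maximum.
#'
#' @param surface a [prediction_surface()], or a numeric vector of masked
#'   predictions.
#' @param min_cells minimum number of masked cells required.
#' @return object of class `reduction_result`: `max_rate`, `min_rate`,
#'   `reduction_pct`, `n_cells`.
#' @export
flap_reduction <- function(surface, min_cells = 20) {
  preds <- if (inherits(surface, "prediction_surface"))
    surface$pred[surface$inside] else as.numeric(surface)
  if (length(preds) < min_cells)
    stop("flap_reduction requires >= ", min_cells, " masked cells")
  qs <- quantile(preds, c(0.95, 0.05), type = 7, names = FALSE)
  structure(list(max_rate = qs[1], min_rate = qs[2],
                 reduction_pct = percent_reduction(qs[1], qs[2]),
                 n_cells = length(preds)), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("Flap reduction: %.2f%% (max %.4g -> min %.4g flaps/hour, %d cells)\n",
              x$reduction_pct, x$max_rate, x$min_rate, x$n_cells))
  invisible(x)
}

#' Conditional profile of a two-covariate model
#'
#' Predictions along one covariate with the other held at its mean observed
#' value, random effect at the population level, with pointwise 95%
#' intervals from the coefficient covariance (response scale via the link).
#'
#' @param fit a `flap_fit` with a two-covariate smooth (Model III, IV or V).
#' @param vary which covariate varies (name or index).
#' @param n profile length.
#' @return data.frame with the varying covariate, `fit`, `lower`, `upper`,
#'   plus attribute `held` naming the fixed covariate and its value.
#' @export
conditional_profile <- function(fit, vary = 1, n = 100) {
  vars <- model_covars(fit$id)
  stopifnot(length(vars) == 2)
  if (is.character(vary)) vary <- match(vary, vars)
  free <- vars[vary]; held <- vars[-vary]
  d <- fit$data
  xs <- seq(min(d[[free]]), max(d[[free]]), length.out = n)
  held_at <- mean(d[[held]])
  nd <- data.frame(xs, held_at, d$bird_id[1])
  names(nd) <- c(free, held, "bird_id")
  pr <- predict(fit$gam, newdata = nd, type = "link", se.fit = TRUE,
                exclude = "s(bird_id)", newdata.guaranteed = TRUE)
  inv <- fit$gam$family$linkinv
  out <- data.frame(x = xs, fit = inv(pr$fit),
                    lower = inv(pr$fit - 1.96 * pr$se.fit),
                    upper = inv(pr$fit + 1.96 * pr$se.fit))
  names(out)[1] <- free
  attr(out, "held") <- stats::setNames(held_at, held)
  out
}

#' Down-sampling robustness of the wind-by-swell model
#'
#' Refits Model V `reps` times on subsets of `n_birds` individuals drawn
#' without replacement with a fixed brood-guard:incubation ratio, predicting
#' each refit on a common masked grid, and reports per-cell quantile
#' envelopes of the predicted surfaces.
#'
#' @param table hourly-record data.frame with a `stage` column.
#' @param n_birds individuals per replicate.
#' @param ratio integer vector `c(brood_guard, incubation)` summing to
#'   `n_birds`.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param n_grid grid cells per axis.
#' @param probs envelope quantiles.
#' @param ... passed to [fit_flap_model()].
#' @return list with `x1`, `x2`, `inside`, `lower`, `upper` (envelope
#'   matrices), `surfaces` (per-rep masked prediction matrices) and
#'   `birds_used` (reps x n_birds matrix of ids).
#' @export
downsample_robustness <- function(table, n_birds = 18, ratio = c(12, 6),
                                  reps = 100, seed = 1L, n_grid = 25,
                                  probs = c(0.05, 0.95), ...) {
  stopifnot(sum(ratio) == n_birds)
  bg <- unique(as.character(table$bird_id[table$stage == "brood-guard"]))
  inc <- unique(as.character(table$bird_id[table$stage == "incubation"]))
  if (length(bg) < ratio[1] || length(inc) < ratio[2])
    stop("too few birds in a stage: need ", ratio[1], " brood-guard and ",
         ratio[2], " incubation, have ", length(bg), " and ", length(inc))
  mask <- kde_mask_99(table$windspeed, table$swell_height)
  x1 <- seq(min(table$windspeed), max(table$windspeed), length.out = n_grid)
  x2 <- seq(min(table$swell_height), max(table$swell_height), length.out = n_grid)
  g <- expand.grid(x1 = x1, x2 = x2)
  inside <- matrix(kde_inside(mask, g$x1, g$x2), n_grid, n_grid)
  set.seed(seed)
  surfaces <- vector("list", reps)
  birds_used <- matrix(NA_character_, reps, n_birds)
  for (r in seq_len(reps)) {
    ids <- c(sample(bg, ratio[1]), sample(inc, ratio[2]))
    birds_used[r, ] <- ids
    sub <- table[table$bird_id %in% ids, , drop = FALSE]
    sub$bird_id <- droplevels(factor(sub$bird_id))
    fit <- fit_flap_model(sub, "V", min_rows = 1, min_birds = 1, ...)
    nd <- data.frame(windspeed = g$x1, swell_height = g$x2,
                     bird_id = sub$bird_id[1])
    pr <- predict(fit$gam, newdata = nd, type = "response",
                  exclude = "s(bird_id)", newdata.guaranteed = TRUE)
    surfaces[[r]] <- matrix(as.numeric(pr), n_grid, n_grid)
  }
  arr <- simplify2array(surfaces)
  list(x1 = x1, x2 = x2, inside = inside,
       lower = apply(arr, c(1, 2), quantile, probs = probs[1]),
       upper = apply(arr, c(1, 2), quantile, probs = probs[2]),
       surfaces = surfaces, birds_used = birds_used)
}

#' Write a model-selection table as CSV
#' @param tab data.frame from [model_selection_table()]; @param path output.
#' @return the path, invisibly.
#' @export
write_selection_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a prediction surface as gridded CSV
#' @param surface a [prediction_surface()]; @param path output file.
#' @return the path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  g <- expand.grid(i = seq_along(surface$x1), j = seq_along(surface$x2))
  out <- data.frame(surface$x1[g$i], surface$x2[g$j],
                    pred = surface$pred[cbind(g$i, g$j)],
                    inside = surface$inside[cbind(g$i, g$j)])
  names(out)[1:2] <- surface$var_names
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
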