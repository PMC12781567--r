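# End-to-end orchestration: accel -> states -> sync -> models -> context.
#
# A pipeline run takes a config (R list or YAML file), executes the stages
# in order on either a synthetic cohort or file inputs, writes every
# artifact as CSV into a run directory together with a manifest recording
# the config hash and seeds, and returns the result bundle invisibly.
# Reruns with the same config are identical.

#' Pipeline configuration
#'
#' @param simulate if TRUE the input streams come from [gen_cohort()] with
#'   `sim`; otherwise `paths` must point at CSV inputs.
#' @param sim a [sim_config()] (synthetic runs).
#' @param paths named list of input paths: `gps`, `accel` (directory or
#'   vector), `immersion` (optional), `env` (long-format grid CSV).
#' @param flap a [flap_config()].
#' @param hmm list with `n_starts` and `seed`.
#' @param model list with `family`, `k_marginal`, `k_tensor`,
#'   `kde_prob`, `quantiles`, `n_grid`, and fit preconditions `min_rows`,
#'   `min_birds`.
#' @param context list with `n_per_basin` and `angle_breaks`.
#' @param seed global seed.
#' @param out_dir run directory for artifacts (created if missing).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            paths = list(),
                            flap = flap_config(),
                            hmm = list(n_starts = 25, seed = 1L),
                            model = list(family = "nb", k_marginal = 5,
                                         k_tensor = c(5, 5), kde_prob = 0.99,
                                         quantiles = c(0.05, 0.95), n_grid = 40,
                                         min_rows = 200, min_birds = 5),
                            context = list(n_per_basin = 34,
                                           angle_breaks = c(60, 120)),
                            seed = 1L, out_dir = tempfile("albaflap_run_")) {
  if (!simulate) {
    needed <- c("gps", "accel", "env")
    miss <- setdiff(needed, names(paths))
    if (length(miss))
      stop("pipeline_config: missing input paths: ", paste(miss, collapse = ", "))
    for (p in unlist(paths[needed]))
      if (!file.exists(p)) stop("pipeline_config: input path does not exist: ", p)
  }
  structure(list(simulate = simulate, sim = sim, paths = paths, flap = flap,
                 hmm = hmm, model = model, context = context,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the `sim`
#' and `flap` blocks onto [sim_config()] / [flap_config()] arguments.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  flap <- if (!is.null(y$flap)) do.call(flap_config, y$flap) else flap_config()
  args <- y[setdiff(names(y), c("sim", "flap"))]
  do.call(pipeline_config, c(list(sim = sim, flap = flap), args))
}

#' Run the full pipeline
#'
#' Stages in order: flap detection per bird, pooled HMM fit and per-bird
#' decoding, hourly aggregation against the environment grid, the
#' six-model selection, the masked Model V surface and flap-reduction
#' statistic, and the condition-category context summaries. Every artifact
#' is written under `config$out_dir`; the manifest records the config hash
#' and seed so identical configs give identical runs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `hourly`, `states`, `hmm_fit`, `selection`,
#'   `fits`, `surface`, `reduction`, `immersion_agreement`, `proportions`,
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)

  # ---- inputs -------------------------------------------------------------
  if (config$simulate) {
    say("simulating cohort (", config$sim$n_birds, " birds)")
    cohort <- gen_cohort(config$sim)
    gps <- cohort$gps; accel <- cohort$accel
    immersion <- cohort$immersion; grid <- cohort$env
  } else {
    gps <- read_gps_csv(config$paths$gps)
    apaths <- config$paths$accel
    if (length(apaths) == 1 && dir.exists(apaths))
      apaths <- list.files(apaths, pattern = "\\.csv$", full.names = TRUE)
    accel <- lapply(apaths, read_accel_csv)
    names(accel) <- sub("\\.csv$", "", basename(apaths))
    immersion <- if (!is.null(config$paths$immersion))
      read_immersion_csv(config$paths$immersion) else NULL
    grid <- read_env_csv(config$paths$env)
  }
  birds <- unique(gps$bird_id)
  # streams must cover the same birds
  if (!all(birds %in% names(accel)))
    stop("stage accel: no acceleration stream for bird ",
         setdiff(birds, names(accel))[1])

  # ---- stage 1: flap detection --------------------------------------------
  say("stage accel: detecting flaps")
  events <- lapply(birds, function(b) {
    tr <- tryCatch(rotate_to_animal_frame(accel[[b]]),
                   error = function(e) stop("stage accel, bird ", b, ": ",
                                            conditionMessage(e)))
    detect_flaps(tr, config$flap)
  })
  names(events) <- birds

  # ---- stage 2: behavioural states ----------------------------------------
  say("stage states: fitting 3-state HMM (", config$hmm$n_starts, " starts)")
  tracks <- lapply(birds, function(b) {
    tr <- gps[gps$bird_id == b, , drop = FALSE]
    interpolate_track(tr)
  })
  names(tracks) <- birds
  series <- lapply(tracks, track_steps_angles)
  hfit <- fit_hmm(series, n_starts = config$hmm$n_starts,
                  seed = config$hmm$seed)
  states <- lapply(series, function(s) decode_states(hfit, s))

  # immersion validation where logs exist
  agree <- NA_real_
  if (!is.null(immersion)) {
    per_bird <- vapply(birds, function(b) {
      imm <- immersion[immersion$bird_id == b, , drop = FALSE]
      if (nrow(imm) == 0) return(c(NA_real_, 0))
      st <- states[[b]]
      ts <- tracks[[b]]$time[-nrow(tracks[[b]])]
      n_rest <- sum(st == "rest")
      if (n_rest == 0) return(c(NA_real_, 0))
      c(suppressMessages(validate_against_immersion(st, ts, imm)), n_rest)
    }, numeric(2))
    w <- per_bird[2, ]
    ok <- !is.na(per_bird[1, ]) & w > 0
    if (any(ok)) agree <- sum(per_bird[1, ok] * w[ok]) / sum(w[ok])
  }

  # ---- stage 3: hourly sync ------------------------------------------------
  say("stage sync: hourly aggregation")
  hourly <- do.call(rbind, lapply(birds, function(b) {
    h <- hourly_aggregate(states[[b]], events[[b]], tracks[[b]], grid,
                          bird_id = b)
    logf("bird %s: %d flight hours, %d rest hours dropped", b,
         if (is.null(h)) 0L else nrow(h), attr(h, "dropped_rest_hours") %||% 0L)
    h
  }))
  hourly <- hourly[!is.na(hourly$windspeed) & !is.na(hourly$BWA), , drop = FALSE]
  hourly$bird_id <- factor(hourly$bird_id)

  # ---- stage 4: models -----------------------------------------------------
  say("stage model: fitting the six-model set")
  m <- config$model
  fits <- fit_model_set(hourly, family = m$family, k_marginal = m$k_marginal,
                        k_tensor = m$k_tensor, min_rows = m$min_rows,
                        min_birds = m$min_birds)
  selection <- model_selection_table(fits)
  surface <- prediction_surface(fits[["V"]], n_grid = m$n_grid,
                                mask = kde_mask_99(hourly$windspeed,
                                                   hourly$swell_height,
                                                   prob = m$kde_prob))
  reduction <- flap_reduction(surface)

  # ---- stage 5: context ----------------------------------------------------
  say("stage context: condition categories")
  ctx <- config$context
  ctx_tab <- hourly
  ctx_tab$species <- "synthetic"; ctx_tab$basin <- "synthetic"
  n_birds_ct <- length(unique(ctx_tab$bird_id))
  thresholds <- category_thresholds(ctx_tab,
                                    n_per_basin = min(ctx$n_per_basin, n_birds_ct),
                                    seed = config$seed)
  proportions <- condition_proportions(ctx_tab, thresholds,
                                       angle_breaks = ctx$angle_breaks)

  # ---- artifacts -----------------------------------------------------------
  write_hourly_table(hourly, file.path(config$out_dir, "hourly_table.csv"))
  st_df <- do.call(rbind, lapply(birds, function(b)
    data.frame(bird_id = b,
               timestamp = format(tracks[[b]]$time[-nrow(tracks[[b]])],
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               state = as.character(states[[b]]))))
  write.csv(st_df, file.path(config$out_dir, "states.csv"), row.names = FALSE)
  write_selection_csv(selection, file.path(config$out_dir, "model_selection.csv"))
  write_surface_csv(surface, file.path(config$out_dir, "surface.csv"))
  write.csv(data.frame(max_rate = reduction$max_rate,
                       min_rate = reduction$min_rate,
                       reduction_pct = reduction$reduction_pct),
            file.path(config$out_dir, "reduction.csv"), row.names = FALSE)
  write.csv(data.frame(classification = rep(names(proportions),
                                            each = 3),
                       category = unlist(lapply(proportions, names)),
                       proportion = unlist(proportions, use.names = FALSE)),
            file.path(config$out_dir, "proportions.csv"), row.names = FALSE)

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   hmm_seed = config$hmm$seed, n_birds = length(birds),
                   n_hourly_rows = nrow(hourly),
                   package_version = as.character(utils::packageVersion("albaflap")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(hourly = hourly, states = states, hmm_fit = hfit,
                 selection = selection, fits = fits, surface = surface,
                 reduction = reduction, immersion_agreement = agree,
                 proportions = proportions, manifest = manifest,
                 out_dir = config$out_dir))
}

# stable hash of the config: serialize canonically to yaml, md5 the bytes
config_hash <- function(config) {
  drop_fn <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && all(nzchar(names(x))))
        x <- x[order(names(x))]
      return(lapply(x, drop_fn))
    }
    if (is.function(x)) return(NULL)
    if (inherits(x, "POSIXt")) return(format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    x
  }
  cl <- unclass(config)
  cl$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(drop_fn(cl), tmp)
  unname(tools::md5sum(tmp))
}
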