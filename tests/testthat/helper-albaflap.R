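# Shared fixtures, all built in code.

# simulate a step/turn series directly from known HMM parameters
simulate_hmm_series <- function(n, params, seed) {
  set.seed(seed)
  st <- integer(n)
  st[1] <- sample(1:3, 1, prob = params$delta)
  for (i in seq_len(n - 1))
    st[i + 1] <- sample(1:3, 1, prob = params$tpm[st[i], ])
  gp <- albaflap:::gamma_pars(params$step_mean, params$step_sd)
  step <- rgamma(n, gp$shape[st], gp$rate[st])
  turn <- c(NA_real_, vapply(st[-1], function(k)
    albaflap:::rvm(1, params$turn_mean[k], params$turn_kappa[k]), numeric(1)))
  list(series = structure(data.frame(step = step, turn = turn),
                          class = c("step_series", "data.frame")),
       states = st)
}

# well-separated 3-state truth used across HMM tests
toy_hmm_params <- function() {
  hmm_params(tpm = rbind(c(0.80, 0.10, 0.10),
                         c(0.15, 0.70, 0.15),
                         c(0.10, 0.10, 0.80)),
             step_mean = c(0.1, 3, 8), step_sd = c(0.08, 1.5, 3),
             turn_mean = c(0, 0, 0), turn_kappa = c(0.5, 1, 10))
}

# a level accel trace of pure noise (no flaps)
noise_trace <- function(minutes = 2, rate = 25, noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  n <- minutes * 60 * rate
  accel_trace(time = (seq_len(n) - 1) / rate,
              ax = rnorm(n, 0, noise_sd), ay = rnorm(n, 0, noise_sd),
              az = 1 + rnorm(n, 0, noise_sd), rate = rate)
}

# reference (definition-level) LULU operators for oracle checks, evaluated
# on the constant extension of the sequence
lulu_floor_ref <- function(x, n) {
  T_ <- length(x)
  p <- c(rep(x[1], n), x, rep(x[T_], n)) # x[i] lives at p[i + n]
  vapply(seq_len(T_), function(i) {
    c_ <- i + n
    max(vapply((c_ - n):c_, function(j) min(p[j:(j + n)]), numeric(1)))
  }, numeric(1))
}
lulu_ceil_ref <- function(x, n) {
  T_ <- length(x)
  p <- c(rep(x[1], n), x, rep(x[T_], n))
  vapply(seq_len(T_), function(i) {
    c_ <- i + n
    min(vapply((c_ - n):c_, function(j) max(p[j:(j + n)]), numeric(1)))
  }, numeric(1))
}

# small constant-field grid for extraction tests
constant_grid <- function(u = 3, v = 4, swell = 2, swell_dir = 270,
                          n_hours = 6) {
  gen_env_grid(env_grid_spec(lat_range = c(-56, -52), lon_range = c(-40, -36),
                             res = 1, n_hours = n_hours,
                             constant = list(u = u, v = v, swell = swell,
                                             swell_dir = swell_dir)),
               seed = 1)
}
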