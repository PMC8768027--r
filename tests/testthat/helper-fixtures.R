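# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

# The default 533-measurement cohort at the default seed, with its feature
# table; several tests share it, so build it once.
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- generator_config(seed = 42)
    recs <- simulate_dataset(cfg)
    feats <- build_feature_table(recs)
    .fixtures$cohort <- list(config = cfg, recordings = recs, features = feats)
  }
  .fixtures$cohort
}

# A small cohort for structural / determinism tests.
small_config <- function(seed = 7L) {
  generator_config(
    n_patients = 6, n_measurements = 40, n_outliers = 6,
    n_outlier_patients = 3, seed = seed
  )
}

# Quiet generator: no noise, no tremor, no amplitude jitter, no fade.
quiet_config <- function(...) {
  generator_config(
    noise_sd = 0, twitch_jitter_sd = 0, tremor_max = 0,
    fade_distribution_params = list(mean = 1, sd = 1e-9), ...
  )
}

# Build a synthetic envelope with raised-cosine bursts at given peak times.
burst_envelope <- function(peak_times, amplitudes, n = 80, width = 3) {
  t <- seq_len(n) - 1
  v <- numeric(n)
  for (i in seq_along(peak_times)) {
    u <- (t - peak_times[i]) / width
    v <- v + amplitudes[i] * ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
  }
  structure(tibble::tibble(t = t, v = v),
            class = c("tof_envelope", class(tibble::tibble())))
}

# A labelled toy feature table with a known separable structure, for fast
# model/eval tests that do not need the full generator.
toy_feature_table <- function(n = 120, n_pos = 12, seed = 1) {
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed, {
    y <- rep(c(1L, 0L), c(n_pos, n - n_pos))
    x1 <- rnorm(n) + 2.5 * y
    x2 <- rnorm(n) - 1.5 * y
    tibble::tibble(f_a = x1, f_b = x2, f_c = rnorm(n),
                   label = ifelse(y == 1, "outlier", "normal"))
  })
}
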