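# Shared fixtures. Everything is generated in code; moderately expensive
# objects are built once per test run and memoised here.

noise_off <- function() growth_noise_params(pink_noise_rms = 0,
                                            measurement_noise_sd = 0)

# a default 300-cell cohort and its fit, shared by several spectral tests
.fixture_env <- new.env(parent = emptyenv())

default_fit <- function(seed = 101) {
  key <- paste0("fit", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- generate_cohort(cohort_config(n_cells = 300, seed = seed))
    .fixture_env[[key]] <- list(cohort = coh, fit = rhythm_fit(coh))
  }
  .fixture_env[[key]]
}

# small deterministic detection table: k cells drifting linearly
drifting_detections <- function(k = 4, n_frames = 30, step = 0.6, seed = 7) {
  set.seed(seed)
  x0 <- runif(k, 30, 220); y0 <- runif(k, 30, 220)
  vx <- runif(k, -step, step); vy <- runif(k, -step, step)
  do.call(rbind, lapply(0:(n_frames - 1), function(f)
    data.frame(frame = f, x = x0 + vx * f, y = y0 + vy * f,
               quality = 1, truth = seq_len(k))))
}
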