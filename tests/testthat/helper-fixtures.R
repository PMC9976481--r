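# In-code fixtures and independent oracles used across test files.

# detection tibble from explicit vectors
make_detections <- function(t, s, replicate = 1L, treatment = "test") {
  tibble::tibble(replicate = as.integer(replicate), treatment = treatment,
                 t = as.integer(t), s = as.numeric(s))
}

# random multi-replicate detection table
random_detections <- function(n_rows = 200, t_max = 30, n_reps = 3) {
  make_detections(
    t = sample.int(t_max, n_rows, replace = TRUE),
    s = stats::rnorm(n_rows, 0, 50),
    replicate = sample.int(n_reps, n_rows, replace = TRUE)
  )
}

# brute-force windowed MSD oracle: double loop over times and detections
msd_oracle <- function(data, times, window) {
  vapply(times, function(t0) {
    acc <- 0; n <- 0L
    for (i in seq_len(nrow(data))) {
      if (abs(data$t[i] - t0) <= window) {
        acc <- acc + data$s[i]^2
        n <- n + 1L
      }
    }
    if (n == 0) NA_real_ else acc / n
  }, numeric(1))
}

# noiseless/noisy continuous two-segment MSD series
two_slope_series <- function(b1 = 5.73, b2 = 3.09, bp = 246, t = 30:480,
                             intercept = 100, noise_sd = 0) {
  msd <- intercept + ifelse(t <= bp, b1 * t, b1 * bp + b2 * (t - bp))
  if (noise_sd > 0) msd <- msd + stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(t = t, msd = msd, n_detections = 100L)
}

# host table fixture
make_hosts <- function(s, parasitized = FALSE, first_discovery = NA_integer_,
                       total_visit = 0, replicate = 1L) {
  n <- length(s)
  tibble::tibble(
    replicate = as.integer(rep_len(replicate, n)), treatment = "test",
    host_id = seq_len(n), patch_id = seq_len(n), s = as.numeric(s),
    first_discovery = as.integer(rep_len(first_discovery, n)),
    total_visit = as.numeric(rep_len(total_visit, n)),
    parasitized = rep_len(parasitized, n)
  )
}
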