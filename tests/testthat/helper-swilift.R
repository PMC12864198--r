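# Deterministic config: no noise anywhere in the rating model.
noise_free_config <- function(n = 2, betaW = 0.01, betaV = -0.5,
                              beta0 = 300, seed = 1) {
  swi_config(
    n_participants = n, seed = seed,
    rating_model = list(
      residual_sd = 0, beta0_sd = 0, betaW_sd = 0, betaV_sd = 0,
      betaV_condition_sd = 0, condition_deltas = c(real = 0, virtual = 0),
      beta0_mean = beta0, betaW_mean = betaW, betaV_mean = betaV
    )
  )
}

noiseless_kinematics <- function(...) {
  swi_config(kinematic_model = list(position_noise_sd_mm = 0), ...)
}

# Exhaustive-scan oracle for reach segmentation: check every candidate
# start index directly against the run definition.
brute_reach <- function(speed, thr = 50, k = 3) {
  n <- length(speed)
  starts <- which(vapply(seq_len(n - k + 1),
                         function(i) all(speed[i:(i + k - 1)] > thr),
                         logical(1)))
  if (length(starts) == 0) return(c(NA_integer_, NA_integer_))
  onset <- starts[1]
  cand <- which(vapply(seq_len(n - k + 1),
                       function(i) all(speed[i:(i + k - 1)] < thr),
                       logical(1)))
  cand <- cand[cand > onset]
  c(onset, if (length(cand) == 0) NA_integer_ else cand[1])
}

# Exhaustive-scan oracle for lift segmentation.
brute_lift <- function(hand, object, z, thr = 50, k = 3) {
  first_run <- function(v) {
    ok <- which(vapply(seq_len(length(v) - k + 1),
                       function(i) all(v[i:(i + k - 1)] > thr),
                       logical(1)))
    if (length(ok) == 0) NA_integer_ else ok[1]
  }
  h0 <- first_run(hand); o0 <- first_run(object)
  if (is.na(h0) || is.na(o0)) return(c(NA_integer_, NA_integer_))
  onset <- max(h0, o0)
  idx <- onset:length(z)
  c(onset, idx[which.max(z[idx])])
}

# Random piecewise-smooth speed series for segmentation property tests.
random_speed_series <- function(n = 60) {
  base <- cumsum(rnorm(n, 0, 25))
  pmax(base - min(base) + runif(1, -20, 40), 0)
}
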