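#' Configuration for a synthetic size-weight illusion lifting study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe a
#' counterbalanced two-condition (real / virtual) study with 25 participants,
#' 90 Hz tracking, and 5 washout + 32 test lifts per condition block.
#'
#' @section Rating model:
#' Heaviness ratings follow the same linear structure the SWI analysis fits:
#' `rating = beta0_i + betaW_i * total_mass_g + betaV_ic * volume_cm3 + eps`,
#' with `eps ~ N(0, residual_sd)`. Participant coefficients are drawn once
#' per participant: `beta0_i ~ N(beta0_mean, beta0_sd)`,
#' `betaW_i ~ N(betaW_mean, betaW_sd)`. The volume slope has a shared
#' participant deviation `u_i ~ N(0, betaV_sd)` plus a condition-specific
#' deviation `w_ic ~ N(0, betaV_condition_sd)`:
#' `betaV_ic = betaV_mean + condition_deltas[c] + u_i + w_ic`.
#' With `betaW_mean = 1` (ratings on a "perceived grams" scale) the implied
#' illusion score `-betaV/betaW` averages 0.20 g/cm3 in the real condition
#' and 0.15 in the virtual one, a 0.05 g/cm3 paired difference whose
#' standardised size is about d_z = 0.42 under the default noise terms.
#' Ratings are floored at `1e-6`: the magnitude-estimation scale is open but
#' strictly positive (larger numbers mean heavier).
#'
#' @section Kinematic model:
#' Each trial is a still period, a minimum-jerk reach of
#' `reach_amplitude_mm` over the condition's `reach_duration_s`, a grasp
#' pause, a minimum-jerk lift of `lift_height_mm` over `lift_duration_s`, a
#' `hold_duration_s` hold, and a minimum-jerk replace. Durations are scaled
#' by lognormal tempo factors: a shared participant factor
#' (`participant_tempo_sd`), a participant-by-condition factor
#' (`participant_condition_tempo_sd`), and a per-trial factor
#' (`trial_tempo_sd`). Default reach durations (0.60 s real, 0.67 s
#' virtual) put peak reach velocity near 0.94 vs 0.84 m/s, i.e. a 0.10 m/s
#' slowing in the virtual condition; lift parameters are condition-neutral.
#' Isotropic Gaussian tracker noise (`position_noise_sd_mm`) is added per
#' sample and axis.
#'
#' @section Presence model:
#' Each participant has a latent presence level
#' `latent_i = latent_mean + assoc_slope * u_i + N(0, latent_sd)`, where
#' `u_i` is the participant's shared volume-slope deviation; the positive
#' default `assoc_slope` makes stronger illusions (more negative `u_i`)
#' co-occur with lower presence. Six questionnaire items are generated as
#' `round(latent_i + N(0, item_sd))` clamped to 1..7.
#'
#' @param n_participants Number of participants (>= 2).
#' @param seed Integer seed governing all randomness; stage-specific
#'   sub-seeds are derived from it.
#' @param sampling_rate_hz Tracker sampling rate in Hz.
#' @param hold_duration_s Hold time at the top of the lift, seconds.
#' @param rating_model,kinematic_model,presence_model Named lists overriding
#'   individual defaults documented above (partial lists are merged).
#' @param counterbalance If `TRUE`, odd-numbered participants do the real
#'   condition first and even-numbered the virtual condition first.
#' @return An object of class `swi_config` (a named list).
#' @examples
#' cfg <- swi_config(n_participants = 4, seed = 42,
#'                   rating_model = list(residual_sd = 0))
#' cfg$rating_model$residual_sd
#' @export
swi_config <- function(n_participants = 25,
                       seed = 1,
                       sampling_rate_hz = 90,
                       hold_duration_s = 2,
                       rating_model = list(),
                       kinematic_model = list(),
                       presence_model = list(),
                       counterbalance = TRUE) {
  rating_defaults <- list(
    beta0_mean = 50, beta0_sd = 30,
    betaW_mean = 1.0, betaW_sd = 0.1,
    betaV_mean = -0.20, betaV_sd = 0.06,
    betaV_condition_sd = 0.08,
    condition_deltas = c(real = 0, virtual = 0.05),
    residual_sd = 30,
    rating_floor = 1e-6
  )
  kinematic_defaults <- list(
    reach_amplitude_mm = 300,
    reach_duration_s = c(real = 0.60, virtual = 0.67),
    lift_height_mm = 100,
    lift_duration_s = 0.5,
    pre_still_s = 0.3,
    grasp_pause_s = 0.2,
    replace_duration_s = 0.4,
    post_still_s = 0.2,
    position_noise_sd_mm = 0.5,
    participant_tempo_sd = 0.10,
    participant_condition_tempo_sd = 0.065,
    trial_tempo_sd = 0.05
  )
  presence_defaults <- list(
    latent_mean = 4.8, latent_sd = 0.8,
    assoc_slope = 20, item_sd = 0.8
  )

  cfg <- list(
    n_participants = n_participants,
    seed = seed,
    sampling_rate_hz = sampling_rate_hz,
    hold_duration_s = hold_duration_s,
    rating_model = merge_model(rating_defaults, rating_model),
    kinematic_model = merge_model(kinematic_defaults, kinematic_model),
    presence_model = merge_model(presence_defaults, presence_model),
    counterbalance = isTRUE(counterbalance)
  )
  class(cfg) <- "swi_config"
  validate_config(cfg)
  cfg
}

merge_model <- function(defaults, user) {
  if (length(user) == 0) return(defaults)
  if (is.null(names(user)) || any(names(user) == "")) {
    stop("model overrides must be a fully named list")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  defaults
}

validate_config <- function(cfg) {
  stopifnot(
    "n_participants must be >= 2" = cfg$n_participants >= 2,
    "seed must be a finite number" = is.finite(cfg$seed),
    "sampling_rate_hz must be > 0" = cfg$sampling_rate_hz > 0,
    "hold_duration_s must be >= 0" = cfg$hold_duration_s >= 0
  )
  rm <- cfg$rating_model
  if (rm$residual_sd < 0) stop("residual_sd must be >= 0")
  if (rm$beta0_sd < 0 || rm$betaW_sd < 0 || rm$betaV_sd < 0 ||
      rm$betaV_condition_sd < 0) {
    stop("between-participant coefficient sds must be >= 0")
  }
  if (!all(c("real", "virtual") %in% names(rm$condition_deltas))) {
    stop("condition_deltas must name both 'real' and 'virtual'")
  }
  km <- cfg$kinematic_model
  if (!all(c("real", "virtual") %in% names(km$reach_duration_s))) {
    stop("reach_duration_s must name both 'real' and 'virtual'")
  }
  if (any(km$reach_duration_s <= 0) || km$lift_duration_s <= 0) {
    stop("movement durations must be positive")
  }
  if (km$reach_amplitude_mm <= 0 || km$lift_height_mm <= 0) {
    stop("movement amplitudes must be positive")
  }
  if (km$position_noise_sd_mm < 0) stop("position_noise_sd_mm must be >= 0")
  invisible(cfg)
}

#' @export
print.swi_config <- function(x, ...) {
  cat("swi_config:", x$n_participants, "participants, seed", x$seed, "\n")
  cat("  sampling:", x$sampling_rate_hz, "Hz; hold:", x$hold_duration_s, "s\n")
  cat("  rating model: betaW", x$rating_model$betaW_mean,
      "| betaV", x$rating_model$betaV_mean,
      "| residual sd", x$rating_model$residual_sd, "\n")
  cat("  implied mean SWI (real):",
      -x$rating_model$betaV_mean / x$rating_model$betaW_mean, "g/cm3\n")
  invisible(x)
}

# Derive a stage-specific sub-seed from the master seed, kept within the
# 32-bit integer range expected by set.seed().
sub_seed <- function(seed, stage) {
  offsets <- c(participants = 1L, ratings = 2L, streams = 3L, presence = 4L)
  if (!stage %in% names(offsets)) stop("unknown rng stage: ", stage)
  as.integer((as.numeric(seed) + 9973 * as.numeric(offsets[[stage]])) %%
               2147483647)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation stages do not leak global state.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
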