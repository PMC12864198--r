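#' Draw per-participant generative parameters
#'
#' Samples each participant's rating-model coefficients and movement tempo
#' factors from the population distributions in the config (see
#' [swi_config()] for the model). Drawn once per study so that ratings,
#' tracker streams, and presence responses share the same participant.
#'
#' @param config A [swi_config()] object.
#' @return A data frame with one row per participant: rating coefficients
#'   (`beta0`, `betaW`, `betaV_real`, `betaV_virtual`, shared volume-slope
#'   deviation `u`), and lognormal tempo factors (`tempo`, `tempo_real`,
#'   `tempo_virtual`).
#' @export
draw_participants <- function(config) {
  stopifnot(inherits(config, "swi_config"))
  rm <- config$rating_model
  km <- config$kinematic_model
  n <- config$n_participants
  with_rng(sub_seed(config$seed, "participants"), {
    u <- rnorm(n, 0, rm$betaV_sd)
    data.frame(
      participant_id = seq_len(n),
      beta0 = rnorm(n, rm$beta0_mean, rm$beta0_sd),
      betaW = rnorm(n, rm$betaW_mean, rm$betaW_sd),
      u = u,
      betaV_real = rm$betaV_mean + rm$condition_deltas[["real"]] + u +
        rnorm(n, 0, rm$betaV_condition_sd),
      betaV_virtual = rm$betaV_mean + rm$condition_deltas[["virtual"]] + u +
        rnorm(n, 0, rm$betaV_condition_sd),
      tempo = exp(rnorm(n, 0, km$participant_tempo_sd)),
      tempo_real = exp(rnorm(n, 0, km$participant_condition_tempo_sd)),
      tempo_virtual = exp(rnorm(n, 0, km$participant_condition_tempo_sd))
    )
  })
}

#' Simulate heaviness ratings for a trial schedule
#'
#' Generates magnitude-estimation heaviness ratings from the linear model
#' `rating = beta0_i + betaW_i * total_mass + betaV_ic * volume + eps`
#' with `eps ~ N(0, residual_sd)`. Mass is the total lifted mass (base plus
#' tracker) in grams; volume is the cylinder volume in cm3. Ratings are
#' floored at the configured positive minimum because the magnitude
#' estimation scale admits only positive numbers.
#'
#' @param config A [swi_config()] object.
#' @param schedule Trial slots from [make_schedule()].
#' @param objects Object table from [swi_object_set()].
#' @param participants Optional participant draw from [draw_participants()];
#'   drawn from `config` if omitted.
#' @return `schedule` with a `rating` column appended.
#' @examples
#' cfg <- swi_config(n_participants = 2, rating_model = list(
#'   residual_sd = 0, beta0_sd = 0, betaW_sd = 0, betaV_sd = 0,
#'   betaV_condition_sd = 0, condition_deltas = c(real = 0, virtual = 0)))
#' head(simulate_ratings(cfg, make_schedule(cfg), swi_object_set()))
#' @export
simulate_ratings <- function(config, schedule = make_schedule(config),
                             objects = swi_object_set(),
                             participants = draw_participants(config)) {
  stopifnot(inherits(config, "swi_config"))
  rm <- config$rating_model
  if (rm$residual_sd < 0) stop("residual_sd must be >= 0")
  obj <- object_lookup(schedule$object, objects)
  pidx <- match(schedule$participant_id, participants$participant_id)
  betaV <- ifelse(schedule$condition == "real",
                  participants$betaV_real[pidx],
                  participants$betaV_virtual[pidx])
  mu <- participants$beta0[pidx] +
    participants$betaW[pidx] * obj$total_mass_g +
    betaV * obj$volume_cm3
  eps <- with_rng(sub_seed(config$seed, "ratings"),
                  rnorm(nrow(schedule), 0, rm$residual_sd))
  out <- schedule
  out$rating <- pmax(mu + eps, rm$rating_floor)
  out
}

# Minimum-jerk unit displacement profile on normalised time tau in [0, 1].
minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' Simulate one trial's wrist and object tracker streams
#'
#' Builds a noiseless trial timeline -- still start, minimum-jerk reach of
#' the wrist towards the object, grasp pause, minimum-jerk vertical lift of
#' wrist and object together, hold, minimum-jerk replace -- sampled at the
#' configured rate, then adds isotropic Gaussian position noise per axis.
#' The object does not move until lift onset, and the wrist peak reach
#' speed is the minimum-jerk value `1.875 * amplitude / duration` at the
#' temporal midpoint of the reach.
#'
#' @param config A [swi_config()] object.
#' @param condition `"real"` or `"virtual"` (selects the reach duration).
#' @param tempo Multiplicative factor applied to all movement durations
#'   (participant/trial tempo; > 0).
#' @param trial_id Identifier copied into the output.
#' @return A data frame with columns `trial_id`, `time_s`, `wrist_x_mm`,
#'   `wrist_y_mm`, `wrist_z_mm`, `obj_x_mm`, `obj_y_mm`, `obj_z_mm`.
#' @examples
#' s <- simulate_stream(swi_config(kinematic_model =
#'   list(position_noise_sd_mm = 0)), "real")
#' max(diff(s$wrist_x_mm)) * 90  # approx peak reach speed, mm/s
#' @export
simulate_stream <- function(config, condition = c("real", "virtual"),
                            tempo = 1, trial_id = "trial") {
  stopifnot(inherits(config, "swi_config"))
  condition <- match.arg(condition)
  if (!is.finite(tempo) || tempo <= 0) stop("tempo must be positive")
  km <- config$kinematic_model
  fs <- config$sampling_rate_hz

  t_reach <- km$reach_duration_s[[condition]] * tempo
  t_lift <- km$lift_duration_s * tempo
  t_replace <- km$replace_duration_s * tempo
  if (t_reach <= 0 || t_lift <= 0) stop("movement durations must be positive")

  # phase boundaries (s)
  b1 <- km$pre_still_s
  b2 <- b1 + t_reach
  b3 <- b2 + km$grasp_pause_s
  b4 <- b3 + t_lift
  b5 <- b4 + config$hold_duration_s
  b6 <- b5 + t_replace
  total <- b6 + km$post_still_s

  time_s <- seq(0, total, by = 1 / fs)
  n <- length(time_s)
  A <- km$reach_amplitude_mm
  h <- km$lift_height_mm

  wrist_x <- A * minjerk((time_s - b1) / t_reach)
  z_lift <- h * minjerk((time_s - b3) / t_lift) -
    h * minjerk((time_s - b5) / t_replace)
  wrist_z <- z_lift
  obj_z <- z_lift
  # object is parked at the reach endpoint and untouched during the reach
  obj_x <- rep(A, n)

  out <- data.frame(
    trial_id = trial_id,
    time_s = time_s,
    wrist_x_mm = wrist_x, wrist_y_mm = 0, wrist_z_mm = wrist_z,
    obj_x_mm = obj_x, obj_y_mm = 0, obj_z_mm = obj_z
  )
  sd_n <- km$position_noise_sd_mm
  if (sd_n > 0) {
    noise <- matrix(rnorm(n * 6, 0, sd_n), n, 6)
    out[, 3:8] <- out[, 3:8] + noise
  }
  out
}

#' Simulate presence questionnaire responses
#'
#' Draws each participant's six presence items from a latent-normal model
#' with unit-spaced cutpoints: item = round(latent + noise) clamped to the
#' 1..7 response scale. The latent presence level is linearly associated
#' with the participant's shared volume-slope deviation `u`, so presence
#' and illusion strength can be made to covary (see [swi_config()]).
#'
#' @param config A [swi_config()] object.
#' @param participants Participant draw from [draw_participants()].
#' @return A data frame with `participant_id` and `item1`..`item6`.
#' @export
simulate_presence <- function(config,
                              participants = draw_participants(config)) {
  stopifnot(inherits(config, "swi_config"))
  pm <- config$presence_model
  n <- nrow(participants)
  with_rng(sub_seed(config$seed, "presence"), {
    latent <- pm$latent_mean + pm$assoc_slope * participants$u +
      rnorm(n, 0, pm$latent_sd)
    items <- matrix(
      pmin(pmax(round(rep(latent, each = 6) + rnorm(6 * n, 0, pm$item_sd)),
                1), 7),
      nrow = n, ncol = 6, byrow = TRUE
    )
    out <- data.frame(participant_id = participants$participant_id)
    colnames(items) <- paste0("item", 1:6)
    cbind(out, as.data.frame(items))
  })
}

#' Simulate a complete study dataset
#'
#' Runs the full generator: schedule, participant draw, heaviness ratings,
#' presence responses, and (optionally) per-trial tracker streams. All
#' randomness derives from `config$seed` via fixed stage offsets, so the
#' same config yields an identical dataset.
#'
#' @param config A [swi_config()] object.
#' @param streams Which trials get tracker streams: `"test"` (default;
#'   washout lifts are never analysed kinematically), `"all"`, or `"none"`.
#' @return A list of class `swi_study` with elements `config`, `objects`,
#'   `schedule`, `participants`, `ratings`, `presence`, and `streams` (a
#'   single long data frame, or `NULL`). Stream `trial_id`s are
#'   `"p<participant>_<condition>_t<trial_index>"`.
#' @examples
#' study <- simulate_study(swi_config(n_participants = 2), streams = "none")
#' nrow(study$ratings)  # 2 participants x 2 conditions x 37 lifts
#' @export
simulate_study <- function(config = swi_config(),
                           streams = c("test", "all", "none")) {
  streams <- match.arg(streams)
  schedule <- make_schedule(config)
  objects <- swi_object_set()
  participants <- draw_participants(config)
  ratings <- simulate_ratings(config, schedule, objects, participants)
  presence <- simulate_presence(config, participants)

  stream_df <- NULL
  if (streams != "none") {
    slots <- if (streams == "test") schedule[schedule$phase == "test", ]
             else schedule
    km <- config$kinematic_model
    stream_df <- with_rng(sub_seed(config$seed, "streams"), {
      pieces <- vector("list", nrow(slots))
      for (i in seq_len(nrow(slots))) {
        s <- slots[i, ]
        p <- participants[participants$participant_id == s$participant_id, ]
        cond_tempo <- if (s$condition == "real") p$tempo_real
                      else p$tempo_virtual
        tempo <- p$tempo * cond_tempo *
          exp(rnorm(1, 0, km$trial_tempo_sd))
        pieces[[i]] <- simulate_stream(
          config, s$condition, tempo = tempo,
          trial_id = sprintf("p%d_%s_t%d", s$participant_id, s$condition,
                             s$trial_index)
        )
      }
      do.call(rbind, pieces)
    })
  }

  structure(
    list(config = config, objects = objects, schedule = schedule,
         participants = participants, ratings = ratings,
         presence = presence, streams = stream_df),
    class = "swi_study"
  )
}

#' Write a simulated study to CSV files
#'
#' Writes `ratings.csv` (participant_id, condition, object, trial_index,
#' phase, rating), `presence.csv` (participant_id, item1..item6),
#' `streams.csv` (trial_id, time_s, wrist/object xyz in mm; only if streams
#' were simulated), and `config.txt` (flat key: value lines).
#'
#' @param study A `swi_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "swi_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ratings = file.path(dir, "ratings.csv"),
    presence = file.path(dir, "presence.csv"),
    config = file.path(dir, "config.txt")
  )
  ratings <- study$ratings[, c("participant_id", "condition", "object",
                               "trial_index", "phase", "rating")]
  utils::write.csv(ratings, paths[["ratings"]], row.names = FALSE)
  utils::write.csv(study$presence, paths[["presence"]], row.names = FALSE)
  writeLines(flatten_config(study$config), paths[["config"]])
  if (!is.null(study$streams)) {
    paths <- c(paths, streams = file.path(dir, "streams.csv"))
    utils::write.csv(study$streams, paths[["streams"]], row.names = FALSE)
  }
  invisible(paths)
}

flatten_config <- function(cfg, prefix = "") {
  out <- character(0)
  for (nm in setdiff(names(cfg), NULL)) {
    val <- cfg[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(val)) {
      out <- c(out, flatten_config(val, paste0(key, ".")))
    } else if (!is.null(names(val)) && length(val) > 1) {
      out <- c(out, paste0(key, ".", names(val), ": ", val))
    } else {
      out <- c(out, paste0(key, ": ", paste(val, collapse = ", ")))
    }
  }
  out
}
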