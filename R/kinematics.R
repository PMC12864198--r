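#' Dual-pass zero-phase Butterworth low-pass filter
#'
#' Smooths a signal with a Butterworth low-pass filter applied forward and
#' then backward, the standard zero-phase-lag smoothing for motion-capture
#' position data. Each pass is a 2nd-order filter by default, giving a
#' 4th-order-equivalent magnitude response; no cutoff correction is applied
#' for the double pass. Edges are padded by point reflection about the end
#' samples (pad length 3 x order per pass) to suppress start-up transients.
#'
#' @param x Numeric vector to filter.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param order Butterworth order per pass.
#' @return Filtered vector, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 90)
#' x <- sin(2 * pi * t) + sin(2 * pi * 30 * t)
#' sm <- butter_lowpass(x, fs = 90, cutoff = 10)
#' @export
butter_lowpass <- function(x, fs, cutoff = 10, order = 2) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist rate (fs/2)")
  }
  if (anyNA(x)) stop("input contains missing values")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- 3L * order
  n <- length(x)
  if (n <= pad + 1) stop("series too short for edge padding")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  # each pass starts from steady state at the first padded sample, so a
  # constant signal passes through exactly and edge transients stay small
  one_pass <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], order),
                              init.y = rep(v[1], order)))
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter all position channels of a tracker stream
#'
#' Applies [butter_lowpass()] to every wrist and object position axis of a
#' stream, per trial. The sampling rate is taken from the median time step.
#'
#' @param stream Stream data frame (columns `trial_id`, `time_s`,
#'   `wrist_x_mm`..`obj_z_mm`), possibly holding several trials.
#' @param cutoff,order Passed to [butter_lowpass()].
#' @return The stream with position columns replaced by filtered values.
#' @export
lowpass_dual_pass <- function(stream, cutoff = 10, order = 2) {
  check_stream_columns(stream)
  pos_cols <- stream_position_cols()
  pieces <- split(stream, stream$trial_id)
  pieces <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$time_s), , drop = FALSE]
    fs <- 1 / stats::median(diff(tr$time_s))
    for (cl in pos_cols) tr[[cl]] <- butter_lowpass(tr[[cl]], fs, cutoff,
                                                    order)
    tr
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

stream_position_cols <- function() {
  c("wrist_x_mm", "wrist_y_mm", "wrist_z_mm",
    "obj_x_mm", "obj_y_mm", "obj_z_mm")
}

check_stream_columns <- function(stream) {
  need <- c("trial_id", "time_s", stream_position_cols())
  missing <- setdiff(need, names(stream))
  if (length(missing) > 0) {
    stop("stream is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Differentiate position with respect to time
#'
#' Central differences in the interior, one-sided differences at the two
#' edges. For multi-axis input the per-axis velocities and the resultant
#' (Euclidean) speed are returned.
#'
#' @param positions Numeric vector or matrix (samples x axes), in mm.
#' @param time Strictly increasing time vector in seconds.
#' @return A list with `velocity` (same shape as `positions`, mm/s) and
#'   `speed` (resultant speed vector, mm/s).
#' @examples
#' d <- differentiate(cbind(1:10 * 10, 0, 0), (0:9) / 90)
#' d$speed[1]  # 900 mm/s
#' @export
differentiate <- function(positions, time) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 3) stop("need at least 3 samples to differentiate")
  if (length(time) != n) stop("time and positions lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  vel <- apply(positions, 2, function(x) {
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
    v[1] <- (x[2] - x[1]) / (time[2] - time[1])
    v[n] <- (x[n] - x[n - 1]) / (time[n] - time[n - 1])
    v
  })
  vel <- matrix(vel, nrow = n)
  colnames(vel) <- colnames(positions)
  list(velocity = vel, speed = sqrt(rowSums(vel^2)))
}

# First index at which a run of at least k consecutive TRUE values begins,
# searching from `from`; NA if none exists.
run_start <- function(cond, k, from = 1L) {
  n <- length(cond)
  if (from > n) return(NA_integer_)
  cond[is.na(cond)] <- FALSE
  k <- as.integer(k)
  run <- 0L
  for (i in seq.int(as.integer(from), n)) {
    run <- if (cond[i]) run + 1L else 0L
    if (run == k) return(i - k + 1L)
  }
  NA_integer_
}

#' Segment the reach phase from hand speed
#'
#' The reach begins at the first sample of the first run of at least `k`
#' consecutive samples with speed strictly above `threshold`, and ends at
#' the first sample after onset beginning a run of at least `k` consecutive
#' samples strictly below `threshold`.
#'
#' @param hand_speed Resultant hand speed in mm/s.
#' @param threshold Speed threshold in mm/s.
#' @param k Required run length in samples.
#' @return A list with `onset`, `offset` (1-based indices, NA when not
#'   found), `valid`, and `reason` (`NA` or one of `"no_reach_onset"`,
#'   `"no_reach_offset"`).
#' @examples
#' segment_reach(c(0, 0, 60, 70, 80, 90, 40, 40, 40))  # onset 3, offset 7
#' @export
segment_reach <- function(hand_speed, threshold = 50, k = 3) {
  onset <- run_start(hand_speed > threshold, k)
  if (is.na(onset)) {
    return(list(onset = NA_integer_, offset = NA_integer_, valid = FALSE,
                reason = "no_reach_onset"))
  }
  offset <- run_start(hand_speed < threshold, k, from = onset + 1L)
  if (is.na(offset)) {
    return(list(onset = onset, offset = NA_integer_, valid = FALSE,
                reason = "no_reach_offset"))
  }
  list(onset = onset, offset = offset, valid = TRUE, reason = NA_character_)
}

#' Segment the lift phase from hand and object motion
#'
#' Lift onset is where both hand and object speed begin a run of at least
#' `k` consecutive samples strictly above `threshold` (the later of the two
#' run starts). The lift ends at the object's maximum vertical position at
#' or after onset; ties resolve to the earliest sample.
#'
#' @param hand_speed,object_speed Resultant speeds in mm/s.
#' @param object_z Object vertical position in mm.
#' @param threshold Speed threshold in mm/s.
#' @param k Required run length in samples.
#' @return A list with `onset`, `end` (1-based indices), `valid`, `reason`
#'   (`NA` or `"no_lift_onset"`/`"apex_before_onset"`).
#' @export
segment_lift <- function(hand_speed, object_speed, object_z,
                         threshold = 50, k = 3) {
  h0 <- run_start(hand_speed > threshold, k)
  o0 <- run_start(object_speed > threshold, k)
  if (is.na(h0) || is.na(o0)) {
    return(list(onset = NA_integer_, end = NA_integer_, valid = FALSE,
                reason = "no_lift_onset"))
  }
  onset <- max(h0, o0)
  n <- length(object_z)
  end <- onset - 1L + which.max(object_z[onset:n])
  if (onset > 1L && max(object_z[1:(onset - 1L)]) > object_z[end]) {
    return(list(onset = onset, end = end, valid = FALSE,
                reason = "apex_before_onset"))
  }
  list(onset = onset, end = end, valid = TRUE, reason = NA_character_)
}

#' Reach and lift metrics for one (filtered) trial stream
#'
#' Computes maximum reach velocity (MRV, hand resultant speed within the
#' reach window), maximum lift velocity (MLV, object resultant speed within
#' the lift window), and the times of those maxima as a percentage of the
#' respective movement phase duration. Expects an already-smoothed stream
#' (see [lowpass_dual_pass()]). Segmentation failures yield an invalid row
#' with a reason rather than an error; argmax ties resolve to the earliest
#' sample.
#'
#' @param stream Single-trial stream data frame, already filtered.
#' @param threshold Speed threshold in mm/s for segmentation.
#' @param k Consecutive-sample run length for segmentation.
#' @return One-row data frame: `trial_id`, segment indices, `mrv_mm_s`,
#'   `t_mrv_pct`, `mlv_mm_s`, `t_mlv_pct`, `valid`, `failure_reason`.
#' @export
compute_metrics <- function(stream, threshold = 50, k = 3) {
  check_stream_columns(stream)
  if (length(unique(stream$trial_id)) != 1) {
    stop("compute_metrics expects a single trial")
  }
  stream <- stream[order(stream$time_s), , drop = FALSE]
  if (nrow(stream) < 30) {
    return(metrics_row(stream$trial_id[1], valid = FALSE,
                       reason = "too_few_samples"))
  }
  time <- stream$time_s
  hand <- differentiate(as.matrix(stream[, c("wrist_x_mm", "wrist_y_mm",
                                             "wrist_z_mm")]), time)
  obj <- differentiate(as.matrix(stream[, c("obj_x_mm", "obj_y_mm",
                                            "obj_z_mm")]), time)

  reach <- segment_reach(hand$speed, threshold, k)
  lift <- segment_lift(hand$speed, obj$speed, stream$obj_z_mm, threshold, k)
  if (!reach$valid || !lift$valid) {
    return(metrics_row(stream$trial_id[1], reach, lift, valid = FALSE,
                       reason = if (!reach$valid) reach$reason
                                else lift$reason))
  }

  rwin <- reach$onset:reach$offset
  imax_r <- rwin[which.max(hand$speed[rwin])]
  mrv <- hand$speed[imax_r]
  t_mrv <- 100 * (time[imax_r] - time[reach$onset]) /
    (time[reach$offset] - time[reach$onset])

  lwin <- lift$onset:lift$end
  imax_l <- lwin[which.max(obj$speed[lwin])]
  mlv <- obj$speed[imax_l]
  t_mlv <- if (lift$end > lift$onset) {
    100 * (time[imax_l] - time[lift$onset]) /
      (time[lift$end] - time[lift$onset])
  } else 0

  metrics_row(stream$trial_id[1], reach, lift, mrv = mrv, t_mrv = t_mrv,
              mlv = mlv, t_mlv = t_mlv, valid = TRUE)
}

metrics_row <- function(trial_id, reach = NULL, lift = NULL,
                        mrv = NA_real_, t_mrv = NA_real_,
                        mlv = NA_real_, t_mlv = NA_real_,
                        valid = TRUE, reason = NA_character_) {
  data.frame(
    trial_id = trial_id,
    reach_onset_idx = if (is.null(reach)) NA_integer_ else reach$onset,
    reach_offset_idx = if (is.null(reach)) NA_integer_ else reach$offset,
    lift_onset_idx = if (is.null(lift)) NA_integer_ else lift$onset,
    lift_end_idx = if (is.null(lift)) NA_integer_ else lift$end,
    mrv_mm_s = mrv, t_mrv_pct = t_mrv, mlv_mm_s = mlv, t_mlv_pct = t_mlv,
    valid = valid, failure_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Filter and extract metrics for every trial in a stream table
#'
#' Runs the per-trial pipeline (zero-phase low-pass smoothing, velocity
#' computation, reach/lift segmentation, MRV/MLV extraction) over a long
#' stream table and returns one metrics row per trial. Trials failing
#' segmentation are kept with `valid = FALSE` and a reason, so exclusion
#' counts can be reported downstream.
#'
#' @param streams Long stream data frame for one or more trials.
#' @param cutoff,order Filter settings, see [butter_lowpass()].
#' @param threshold,k Segmentation settings, see [segment_reach()].
#' @return Data frame of per-trial metrics (see [compute_metrics()]).
#' @export
trial_metrics <- function(streams, cutoff = 10, order = 2,
                          threshold = 50, k = 3) {
  check_stream_columns(streams)
  filtered <- lowpass_dual_pass(streams, cutoff = cutoff, order = order)
  pieces <- lapply(split(filtered, filtered$trial_id), compute_metrics,
                   threshold = threshold, k = k)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
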