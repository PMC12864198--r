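#' Standardise heaviness ratings within participant
#'
#' Magnitude-estimation ratings live on an arbitrary per-participant scale,
#' so they are z-scored per participant before any group-level comparison.
#' Standardisation pools each participant's test trials across BOTH
#' conditions (sample mean and sd, n - 1 denominator): z-scoring within
#' condition would remove exactly the condition effect the analysis tests.
#' Washout trials never receive a z-score.
#'
#' @param trials Rating trials (columns `participant_id`, `phase`,
#'   `rating`, ...), e.g. from [simulate_ratings()].
#' @return The test-trial rows of `trials` with a `z_rating` column.
#' @examples
#' cfg <- swi_config(n_participants = 2)
#' z <- zscore_ratings(simulate_ratings(cfg))
#' tapply(z$z_rating, z$participant_id, sd)  # all 1
#' @export
zscore_ratings <- function(trials) {
  test <- trials[trials$phase == "test", , drop = FALSE]
  z <- ave(test$rating, test$participant_id, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  })
  if (anyNA(z)) {
    bad <- unique(test$participant_id[is.na(z)])
    stop("zero rating variance for participant(s): ",
         paste(bad, collapse = ", "))
  }
  test$z_rating <- z
  test
}

#' Regress heaviness ratings on object mass and volume
#'
#' Ordinary least squares of raw (not z-scored) heaviness ratings on total
#' lifted mass (grams, object plus tracker) and object volume (cm3), with
#' intercept, for one participant in one condition. In the orthogonal
#' 2 x 2 stimulus design the slopes equal the cell-mean difference
#' quotients, and the mass slope is identical whether base or total mass is
#' used (only the intercept shifts).
#'
#' @param trials Test trials for a single participant x condition (32 rows
#'   covering all four test objects).
#' @param objects Object table from [swi_object_set()].
#' @return A list with `intercept`, `bW` (rating units per g), `bV` (rating
#'   units per cm3).
#' @export
fit_heaviness_regression <- function(trials, objects = swi_object_set()) {
  obj <- object_lookup(trials$object, objects)
  X <- cbind(1, mass = obj$total_mass_g, volume = obj$volume_cm3)
  if (qr(X)$rank < 3) {
    stop("rank-deficient design: need both mass and both volume levels")
  }
  fit <- stats::lm.fit(X, trials$rating)
  co <- fit$coefficients
  list(intercept = unname(co[1]), bW = unname(co[2]), bV = unname(co[3]))
}

#' Size-weight illusion score from regression slopes
#'
#' `-(1/bW) * bV`: grams of perceived weight change per cubic centimetre of
#' volume change. The sign is flipped so that larger scores mean a larger
#' illusion (bigger objects feel lighter, so `bV` is typically negative).
#' The score is invariant to positive affine rescaling of the rating scale
#' because the scale factor cancels in the ratio.
#'
#' @param bW Mass slope (rating units per g); must be nonzero.
#' @param bV Volume slope (rating units per cm3).
#' @return The SWI score in g/cm3.
#' @examples
#' swi_score(bW = 0.01, bV = -0.5)  # 50
#' @export
swi_score <- function(bW, bV) {
  if (!is.finite(bW) || !is.finite(bV)) stop("slopes must be finite")
  if (bW == 0) stop("SWI score undefined: mass slope bW is zero")
  -(1 / bW) * bV
}

#' Per-participant, per-condition SWI scores
#'
#' Fits the heaviness regression for every participant x condition block of
#' test trials and derives the SWI score from each fit, yielding the two
#' paired scores per participant the condition contrast uses.
#'
#' @param trials Rating trials (all participants/conditions).
#' @param objects Object table from [swi_object_set()].
#' @return Data frame: `participant_id`, `condition`, `intercept`, `bW`,
#'   `bV`, `swi_score`.
#' @export
swi_scores <- function(trials, objects = swi_object_set()) {
  test <- trials[trials$phase == "test", , drop = FALSE]
  groups <- split(test, list(test$participant_id, test$condition),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    fit <- fit_heaviness_regression(g, objects)
    data.frame(
      participant_id = g$participant_id[1],
      condition = g$condition[1],
      intercept = fit$intercept, bW = fit$bW, bV = fit$bV,
      swi_score = swi_score(fit$bW, fit$bV),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Presence score from the six-item questionnaire
#'
#' The presence score is the number of the six items answered 6 or 7 on the
#' 1-7 scale, giving an integer in 0..6.
#'
#' @param items Integer vector of six responses, each in 1..7.
#' @return Integer count in 0..6.
#' @examples
#' presence_score(c(7, 6, 7, 6, 6, 7))  # 6
#' @export
presence_score <- function(items) {
  if (length(items) != 6) stop("presence response must have exactly 6 items")
  if (anyNA(items) || any(items < 1 | items > 7) ||
      any(items != round(items))) {
    stop("presence items must be integers in 1..7")
  }
  sum(items >= 6)
}

#' Presence scores for a table of questionnaire responses
#'
#' @param presence Data frame with `participant_id` and `item1`..`item6`.
#' @return Data frame: `participant_id`, `presence_score`.
#' @export
presence_scores <- function(presence) {
  items <- as.matrix(presence[, paste0("item", 1:6)])
  data.frame(
    participant_id = presence$participant_id,
    presence_score = apply(items, 1, presence_score)
  )
}
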