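# Four fixed pseudo-random test-trial orders. Each contains every test
# object exactly 8 times and no object more than twice in a row. Orders are
# assigned to participants cyclically so trial sequences are reproducible.
swi_trial_orders <- function() {
  list(
    c("small_light", "small_heavy", "small_heavy", "large_heavy",
      "small_heavy", "large_light", "small_heavy", "small_light",
      "large_light", "small_heavy", "small_light", "large_heavy",
      "large_light", "large_heavy", "small_heavy", "large_light",
      "small_light", "small_light", "large_light", "small_light",
      "large_light", "large_light", "small_heavy", "large_heavy",
      "large_heavy", "small_light", "large_light", "large_heavy",
      "small_light", "small_heavy", "large_heavy", "large_heavy"),
    c("large_light", "large_light", "small_heavy", "small_light",
      "large_heavy", "small_light", "large_light", "large_light",
      "small_heavy", "large_light", "small_light", "large_heavy",
      "large_heavy", "small_light", "small_heavy", "large_heavy",
      "large_heavy", "small_light", "small_light", "small_heavy",
      "large_heavy", "large_light", "small_heavy", "large_heavy",
      "small_light", "small_heavy", "large_light", "large_light",
      "small_heavy", "small_heavy", "large_heavy", "small_light"),
    c("large_light", "small_light", "small_heavy", "large_light",
      "large_heavy", "small_light", "small_heavy", "small_light",
      "large_heavy", "large_light", "large_heavy", "large_light",
      "small_light", "small_heavy", "small_light", "large_heavy",
      "small_heavy", "small_light", "small_heavy", "large_light",
      "small_light", "large_light", "large_heavy", "large_light",
      "small_heavy", "large_heavy", "large_light", "small_heavy",
      "small_light", "large_heavy", "large_heavy", "small_heavy"),
    c("small_heavy", "small_heavy", "large_light", "small_light",
      "large_light", "large_light", "small_light", "small_light",
      "large_heavy", "large_heavy", "small_light", "large_heavy",
      "small_heavy", "small_light", "large_heavy", "large_light",
      "large_light", "small_heavy", "small_light", "large_light",
      "large_heavy", "small_light", "large_heavy", "large_light",
      "small_heavy", "large_light", "large_heavy", "small_heavy",
      "small_light", "small_heavy", "small_heavy", "large_heavy")
  )
}

#' Build the trial schedule for a study
#'
#' Lays out every lift slot for every participant: two condition blocks
#' (real and virtual, order counterbalanced so odd-numbered participants
#' start with the real condition), each block consisting of 5 washout lifts
#' of the medium cylinder followed by 32 test lifts in one of four fixed
#' pseudo-randomised orders. Orders are assigned cyclically by participant
#' index, so the schedule is fully deterministic.
#'
#' @param config A [swi_config()] object.
#' @return A data frame with columns `participant_id`, `condition`,
#'   `block` (1 or 2, position of the block in the session), `trial_index`
#'   (1..37 within the condition block), `phase` (`"washout"`/`"test"`) and
#'   `object`.
#' @examples
#' sch <- make_schedule(swi_config(n_participants = 2))
#' table(sch$condition, sch$phase) / 2
#' @export
make_schedule <- function(config) {
  stopifnot(inherits(config, "swi_config"))
  orders <- swi_trial_orders()
  rows <- vector("list", config$n_participants * 2L)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    if (config$counterbalance) {
      conds <- if (p %% 2 == 1) c("real", "virtual") else c("virtual", "real")
    } else {
      conds <- c("real", "virtual")
    }
    ord <- orders[[(p - 1L) %% length(orders) + 1L]]
    for (b in 1:2) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = p,
        condition = conds[b],
        block = b,
        trial_index = 1:37,
        phase = rep(c("washout", "test"), c(5L, 32L)),
        object = c(rep("medium_washout", 5L), ord),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
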