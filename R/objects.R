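#' Stimulus set for the size-weight illusion lifting task
#'
#' Builds the five-cylinder stimulus set: a full 2 x 2 cross of diameter
#' (small 5 cm, large 10 cm) and base mass (light 355 g, heavy 490 g), all
#' 7.5 cm tall, plus a medium 7.5 cm / 490 g washout cylinder lifted before
#' each test block. A 75 g motion tracker is screwed to the base of every
#' object, so the mass actually lifted (`total_mass_g`) is base mass plus
#' tracker. Volumes are the cylinder volumes pi * r^2 * h and deliberately
#' exclude the tracker, whose visual footprint is not part of the size cue.
#'
#' @param tracker_mass_g Mass of the attached tracker in grams.
#' @return A data frame with one row per object and columns `label`,
#'   `diameter_cm`, `height_cm`, `base_mass_g`, `tracker_mass_g`,
#'   `total_mass_g`, `volume_cm3`, `is_test`.
#' @examples
#' objs <- swi_object_set()
#' objs[objs$label == "large_heavy", "total_mass_g"]  # 565
#' @export
swi_object_set <- function(tracker_mass_g = 75) {
  objs <- data.frame(
    label = c("small_light", "small_heavy", "large_light", "large_heavy",
              "medium_washout"),
    diameter_cm = c(5, 5, 10, 10, 7.5),
    height_cm = 7.5,
    base_mass_g = c(355, 490, 355, 490, 490),
    tracker_mass_g = tracker_mass_g,
    stringsAsFactors = FALSE
  )
  objs$total_mass_g <- objs$base_mass_g + objs$tracker_mass_g
  objs$volume_cm3 <- pi * (objs$diameter_cm / 2)^2 * objs$height_cm
  objs$is_test <- objs$label != "medium_washout"
  objs
}

#' Look up object properties by label
#'
#' @param labels Character vector of object labels.
#' @param objects Object table from [swi_object_set()].
#' @return Rows of `objects` in the order of `labels`.
#' @keywords internal
object_lookup <- function(labels, objects = swi_object_set()) {
  idx <- match(labels, objects$label)
  if (anyNA(idx)) {
    stop("unknown object label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  objects[idx, , drop = FALSE]
}
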