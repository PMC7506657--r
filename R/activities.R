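#' The five gait activity labels
#'
#' Canonical label vocabulary for the classification task. The five
#' activities, in fixed order with stable integer codes 0..4, are going down
#' an incline, going up an incline, walking on level ground, going down
#' stairs, and going up stairs.
#'
#' @return Character vector of the five canonical labels, in code order.
#' @examples
#' gait_activities()
#' @export
gait_activities <- function() {
  c("down_incline", "up_incline", "level", "down_stairs", "up_stairs")
}

#' @rdname gait_activities
#' @format NULL
#' @export
GAIT_ACTIVITIES <- c("down_incline", "up_incline", "level",
                     "down_stairs", "up_stairs")

# Alias table for tolerant ingestion of third-party label spellings.
# Keys are matched case-insensitively after trimming and mapping
# separators ("-", " ") to "_".
.label_aliases <- c(
  down_incline = "down_incline", incline_down = "down_incline",
  down_slope = "down_incline", down_slope_walk = "down_incline",
  downslope = "down_incline", slope_down = "down_incline",
  up_incline = "up_incline", incline_up = "up_incline",
  up_slope = "up_incline", up_slope_walk = "up_incline",
  upslope = "up_incline", slope_up = "up_incline",
  level = "level", walk = "level", walking = "level",
  level_walk = "level", level_ground = "level", flat = "level",
  down_stairs = "down_stairs", stairs_down = "down_stairs",
  step_down = "down_stairs", stair_down = "down_stairs",
  downstairs = "down_stairs",
  up_stairs = "up_stairs", stairs_up = "up_stairs",
  step_up = "up_stairs", stair_up = "up_stairs", upstairs = "up_stairs"
)

#' Parse activity label text
#'
#' Maps free-text labels onto the canonical vocabulary using a
#' case-insensitive alias table (e.g. `"walk"`, `"level ground"` and
#' `"LEVEL"` all map to `"level"`; `"step up"` maps to `"up_stairs"`).
#'
#' @param x Character vector of label text.
#' @return Factor with levels `gait_activities()`.
#' @examples
#' parse_activity(c("Walk", "step up", "incline-down"))
#' @export
parse_activity <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  mapped <- unname(.label_aliases[key])
  if (anyNA(mapped)) {
    bad <- unique(key[is.na(mapped)])
    stop("unknown activity label(s): ", paste(sQuote(bad), collapse = ", "),
         "; valid labels are: ", paste(GAIT_ACTIVITIES, collapse = ", "),
         call. = FALSE)
  }
  factor(mapped, levels = GAIT_ACTIVITIES)
}

#' Integer codes of activity labels
#'
#' @param x Labels coercible via [parse_activity()].
#' @return Integer codes 0..4 in canonical label order.
#' @export
activity_code <- function(x) {
  as.integer(parse_activity(x)) - 1L
}
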