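#' Ordered urgency levels
#'
#' The five urgency colors of the classification system, ordered from least
#' to most urgent: BLUE < GREEN < YELLOW < ORANGE < RED.
#'
#' @return Character vector of the five level names in increasing urgency.
#' @export
#' @examples
#' urgency_levels()
urgency_levels <- function() {
  c("BLUE", "GREEN", "YELLOW", "ORANGE", "RED")
}

#' Coerce to an ordered urgency factor
#'
#' @param x Character vector of level names (any case).
#' @return Ordered factor with levels BLUE < GREEN < YELLOW < ORANGE < RED.
#' @export
as_urgency <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x[!is.na(x)]), urgency_levels())
  if (length(bad) > 0) {
    stop("unknown urgency level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = urgency_levels(), ordered = TRUE)
}

# integer rank 1..5 of a level name; vectorized
urgency_rank <- function(x) {
  match(toupper(as.character(x)), urgency_levels())
}

#' Map a VIPE total to its urgency color
#'
#' Implements the score legend: 0 is BLUE, 1-2 GREEN, 3-5 YELLOW, 6-9 ORANGE
#' and 10 or more RED.
#'
#' @param total Integer VIPE total(s) in 0..12.
#' @param tables A VIPE table set from [load_vipe_tables()]; defaults to the
#'   bundled tables.
#' @return Character vector of level names.
#' @export
#' @examples
#' color_from_total(c(0, 2, 5, 9, 12))
color_from_total <- function(total, tables = load_vipe_tables()) {
  if (any(is.na(total)) || any(total < 0 | total > 12) || any(total != round(total))) {
    stop("VIPE total must be an integer in 0..12", call. = FALSE)
  }
  cm <- tables$color_map
  out <- rep(NA_character_, length(total))
  for (i in seq_len(nrow(cm))) {
    hit <- total >= cm$lo[i] & total <= cm$hi[i]
    out[hit] <- cm$level[i]
  }
  out
}

#' Waiting-time and destination policy for an urgency level
#'
#' Every level maps to exactly one pair (maximum waiting time in minutes,
#' care destination): RED is seen immediately in the resuscitation room,
#' ORANGE within 10 min in the observation room, YELLOW within 30 min,
#' GREEN within 90 min and BLUE within 180 min in the waiting room.
#'
#' @param level Character vector of urgency level names.
#' @inheritParams color_from_total
#' @return data.frame with columns `level`, `max_wait_minutes`, `destination`.
#' @export
#' @examples
#' policy_for_level(c("RED", "GREEN"))
policy_for_level <- function(level, tables = load_vipe_tables()) {
  level <- toupper(as.character(level))
  if (any(!level %in% urgency_levels())) {
    stop("unknown urgency level", call. = FALSE)
  }
  pol <- tables$policy
  data.frame(
    level = level,
    max_wait_minutes = vapply(level, function(l) pol[[l]]$max_wait_minutes, numeric(1)),
    destination = vapply(level, function(l) pol[[l]]$destination, character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
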