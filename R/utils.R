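# Internal helpers shared across modules.

# Reserved name of the virtual exit node (discharge from hospital).
.EXIT <- "EXIT"

#' Name of the virtual exit node
#'
#' Discharge from hospital is represented by a transfer to a virtual exit
#' node with this reserved name. Ward names may not collide with it; readers
#' reject files that use it as a source ward.
#'
#' @return The string `"EXIT"`.
#' @export
#' @examples
#' exit_node()
exit_node <- function() .EXIT

# Monday of the ISO week containing each date.
iso_week_start <- function(dates) {
  dates <- as.Date(dates)
  dates - (as.integer(format(dates, "%u")) - 1L)
}

# First day of the calendar month containing each date.
month_start <- function(dates) {
  as.Date(format(as.Date(dates), "%Y-%m-01"))
}

is_weekend <- function(dates) {
  format(as.Date(dates), "%u") %in% c("6", "7")
}

# Parse strictly ISO-8601 minute-resolution timestamps (YYYY-MM-DDTHH:MM).
parse_timestamp <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M", tz = "UTC")
}

# Window label for a date under a given frequency.
window_label <- function(dates, frequency) {
  dates <- as.Date(dates)
  switch(frequency,
    day = format(dates, "%Y-%m-%d"),
    week = format(iso_week_start(dates), "%Y-%m-%d"),
    month = format(dates, "%Y-%m"),
    abort(sprintf("unknown window frequency '%s'", frequency))
  )
}

match_frequency <- function(frequency) {
  match.arg(frequency, c("day", "week", "month"))
}
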