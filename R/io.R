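# Readers and writers for the package's file formats:
#   * event CSV:   patient_id,timestamp,site,source_ward,target_ward
#   * weekly CSV:  week_start,site,source_ward,target_ward,count
#   * perf CSV:    date,site,performance_pct,arrivals
#   * network exports: edge-list CSV and GraphML
# Timestamps are ISO-8601 to the minute (YYYY-MM-DDTHH:MM), UTC.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
}

# Report/handle bad rows. `bad` is a logical vector over data rows; line
# numbers reported are file line numbers (header = line 1).
handle_bad_rows <- function(df, bad, what, path, strict) {
  if (!any(bad)) {
    return(df)
  }
  lines <- which(bad) + 1L
  msg <- sprintf(
    "%s: %d row(s) with %s (line%s %s)",
    path, sum(bad), what, if (sum(bad) > 1) "s" else "",
    paste(head(lines, 10), collapse = ", ")
  )
  if (strict) abort(msg)
  inform(paste0(msg, " - skipped"))
  df[!bad, , drop = FALSE]
}

#' Read a transfer event log
#'
#' One row per patient movement between two wards (or to the virtual exit
#' node). Records are returned sorted by patient then timestamp. Self
#' transfers (same source and target ward) are dropped with a message, and
#' a source ward named like the exit sentinel is rejected.
#'
#' @param path CSV file with columns
#'   `patient_id,timestamp,site,source_ward,target_ward`.
#' @param strict In strict mode (default) any malformed row is an error
#'   naming the offending file line(s); in lenient mode malformed rows are
#'   reported and skipped.
#' @return Tibble of transfer records with a POSIXct `timestamp` (UTC).
#' @export
read_transfer_events <- function(path, strict = TRUE) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  require_columns(
    df, c("patient_id", "timestamp", "site", "source_ward", "target_ward"),
    path
  )
  df <- tibble::as_tibble(df)
  ts <- parse_timestamp(df$timestamp)
  df <- handle_bad_rows(df, is.na(ts) & nzchar(df$timestamp) |
                          !nzchar(df$timestamp),
                        "non-parsable timestamp", path, strict)
  df$timestamp <- parse_timestamp(df$timestamp)
  df <- handle_bad_rows(df, df$source_ward == .EXIT,
                        sprintf("source ward '%s' (reserved)", .EXIT),
                        path, strict)
  self <- df$source_ward == df$target_ward
  if (any(self)) {
    inform(sprintf("%s: dropped %d self-transfer row(s)", path, sum(self)))
    df <- df[!self, , drop = FALSE]
  }
  validate_transfer_records(df)
  dplyr::arrange(df, .data$patient_id, .data$timestamp)
}

validate_transfer_records <- function(records) {
  stopifnot(
    all(c("patient_id", "timestamp", "site", "source_ward",
          "target_ward") %in% names(records)),
    inherits(records$timestamp, "POSIXct")
  )
  if (any(records$source_ward == .EXIT)) {
    abort(sprintf("'%s' cannot be a source ward", .EXIT))
  }
  if (any(records$source_ward == records$target_ward)) {
    abort("self-transfers are not valid records")
  }
  invisible(records)
}

#' Write a transfer event log
#'
#' @param records Transfer records as returned by [read_transfer_events()]
#'   or [simulate_hospital()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_events <- function(records, path) {
  out <- records[, c("patient_id", "timestamp", "site", "source_ward",
                     "target_ward")]
  out$timestamp <- format_timestamp(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate transfer events into weekly counts
#'
#' Transfers are pooled per (week, site, source, target); weeks start on
#' Mondays (ISO weeks), so a Sunday transfer is assigned to the preceding
#' Monday. Zero-count combinations are not emitted. The per-site totals
#' equal the number of input records per site.
#'
#' @param records Transfer records.
#' @return Tibble with columns `week_start` (a Monday, `Date`), `site`,
#'   `source_ward`, `target_ward`, `count`.
#' @export
aggregate_weekly <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      week_start = as.Date(character()), site = character(),
      source_ward = character(), target_ward = character(),
      count = integer()
    ))
  }
  out <- dplyr::count(
    records,
    week_start = iso_week_start(as.Date(.data$timestamp, tz = "UTC")),
    .data$site, .data$source_ward, .data$target_ward,
    name = "count"
  )
  dplyr::arrange(out, .data$week_start, .data$site, .data$source_ward,
                 .data$target_ward)
}

#' Read a weekly aggregate transfer table
#'
#' Loads a weekly flow table ("total number of patients sent between each
#' pair of wards per week", weeks starting on Mondays). Files using other
#' header names can be loaded through `col_map`, a named character vector
#' mapping the canonical names to the file's headers, e.g.
#' `c(week_start = "WeekCommencing", count = "n")`.
#'
#' @param path CSV file with columns
#'   `week_start,site,source_ward,target_ward,count` (possibly renamed).
#' @param col_map Optional canonical-name -> file-header mapping.
#' @param strict Error (rather than skip) on malformed rows.
#' @return Tibble of weekly aggregate rows; `week_start` is a `Date`.
#' @export
read_weekly_aggregates <- function(path, col_map = NULL, strict = TRUE) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  canonical <- c("week_start", "site", "source_ward", "target_ward", "count")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  require_columns(df, canonical, path)
  df <- tibble::as_tibble(df)[, canonical]
  ws <- as.Date(df$week_start, format = "%Y-%m-%d")
  df <- handle_bad_rows(df, is.na(ws), "non-parsable week_start", path,
                        strict)
  df$week_start <- as.Date(df$week_start)
  df <- handle_bad_rows(df, format(df$week_start, "%u") != "1",
                        "week_start that is not a Monday", path, strict)
  count <- suppressWarnings(as.integer(df$count))
  df <- handle_bad_rows(df, is.na(count) | count < 1,
                        "non-positive or non-integer count", path, strict)
  df$count <- as.integer(df$count)
  df
}

#' Write a weekly aggregate transfer table
#'
#' @param weekly Weekly aggregate rows (see [aggregate_weekly()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weekly_aggregates <- function(weekly, path) {
  out <- weekly[, c("week_start", "site", "source_ward", "target_ward",
                    "count")]
  out$week_start <- format(as.Date(out$week_start), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily A&E performance series
#'
#' @param path CSV file with columns `date,site,performance_pct,arrivals`,
#'   one row per day and site; `performance_pct` is the percentage of A&E
#'   patients meeting the 4-hour target, in `[0, 100]`.
#' @param strict Error (rather than skip) on malformed rows.
#' @return Tibble with `date` as `Date`, numeric `performance_pct` and
#'   integer `arrivals`.
#' @export
read_performance_series <- function(path, strict = TRUE) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  require_columns(df, c("date", "site", "performance_pct", "arrivals"), path)
  df <- tibble::as_tibble(df)
  d <- as.Date(df$date, format = "%Y-%m-%d")
  df <- handle_bad_rows(df, is.na(d), "non-parsable date", path, strict)
  df$date <- as.Date(df$date)
  perf <- suppressWarnings(as.numeric(df$performance_pct))
  df <- handle_bad_rows(df, is.na(perf) | perf < 0 | perf > 100,
                        "performance_pct outside [0, 100]", path, strict)
  df$performance_pct <- as.numeric(df$performance_pct)
  df$arrivals <- as.integer(df$arrivals)
  if (anyDuplicated(df[, c("date", "site")])) {
    abort(sprintf("%s: duplicate (date, site) rows", path))
  }
  dplyr::arrange(df, .data$site, .data$date)
}

#' Write a daily A&E performance series
#'
#' @param perf Performance rows (see [read_performance_series()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_performance_series <- function(perf, path) {
  out <- perf[, c("date", "site", "performance_pct", "arrivals")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flow network to disk
#'
#' Edge-list CSV (`source,target,weight`; isolated nodes serialised as rows
#' with an empty `target` and `weight`) or GraphML via igraph. The virtual
#' exit node is serialised as an ordinary node with its reserved name.
#' Round-tripping through [read_network()] reproduces node set, edge set
#' and weights.
#'
#' @param net A [flow_network()].
#' @param path Output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    e <- net$edges
    isolated <- setdiff(net$nodes, c(e$source, e$target))
    out <- data.frame(
      source = c(e$source, isolated),
      target = c(e$target, rep("", length(isolated))),
      weight = c(format(e$weight, digits = 17, scientific = FALSE,
                        trim = TRUE),
                 rep("", length(isolated))),
      stringsAsFactors = FALSE
    )
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a flow network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"graphml"`.
#' @param window,site,weight_mode Metadata to attach (the edge-list formats
#'   do not carry them).
#' @param n_transfers Total transfer count, for proportion-mode networks.
#' @return A [flow_network()].
#' @export
read_network <- function(path, format = c("csv", "graphml"),
                         window = NA_character_, site = NA_character_,
                         weight_mode = c("count", "proportion"),
                         n_transfers = NULL) {
  format <- match.arg(format)
  weight_mode <- match.arg(weight_mode)
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character", check.names = FALSE)
    require_columns(df, c("source", "target", "weight"), path)
    isolated <- df$target == ""
    edges <- tibble::tibble(
      source = df$source[!isolated], target = df$target[!isolated],
      weight = as.numeric(df$weight[!isolated])
    )
    nodes <- c(df$source, df$target[!isolated])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    edf <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(source = edf$from, target = edf$to,
                            weight = edf$weight)
    nodes <- igraph::V(g)$name
  }
  flow_network(edges, nodes = nodes, window = window, site = site,
               weight_mode = weight_mode, n_transfers = n_transfers)
}
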