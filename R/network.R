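# Flow-network container and window-by-window construction.

#' Construct a flow network object
#'
#' A `flow_network` is one time-window snapshot of patient flow: a weighted
#' directed graph whose nodes are wards (plus the virtual exit node, see
#' [exit_node()]) and whose edge weights are either raw transfer counts
#' (`weight_mode = "count"`) or the proportion of all transfers in the
#' window (`weight_mode = "proportion"`, weights sum to 1).
#'
#' @param edges Tibble with columns `source`, `target`, `weight`.
#' @param nodes Character vector of node names; defaults to the union of
#'   edge endpoints. May include isolated nodes.
#' @param window Window label (e.g. `"2024-01"` for a calendar month).
#' @param site Site label, or `NA` for unfiltered networks.
#' @param weight_mode `"count"` or `"proportion"`.
#' @param n_transfers Total number of transfers the network was built from;
#'   inferred from the weights in count mode.
#'
#' @return An object of class `flow_network` with fields `edges`, `nodes`,
#'   `window`, `site`, `weight_mode`, `n_transfers`.
#' @export
#' @examples
#' flow_network(tibble::tibble(
#'   source = c("AE", "CDU"), target = c("CDU", "EXIT"), weight = c(2, 1)
#' ))
flow_network <- function(edges, nodes = NULL, window = NA_character_,
                         site = NA_character_,
                         weight_mode = c("count", "proportion"),
                         n_transfers = NULL) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(edges))
  edges <- tibble::tibble(
    source = as.character(edges$source),
    target = as.character(edges$target),
    weight = as.numeric(edges$weight)
  )
  nodes <- sort(unique(c(edges$source, edges$target, as.character(nodes %||% character()))))
  if (is.null(n_transfers)) {
    n_transfers <- if (weight_mode == "count") sum(edges$weight) else NA_real_
  }
  net <- structure(
    list(
      edges = dplyr::arrange(edges, .data$source, .data$target),
      nodes = nodes,
      window = as.character(window), site = as.character(site),
      weight_mode = weight_mode, n_transfers = n_transfers
    ),
    class = "flow_network"
  )
  validate_flow_network(net)
}

validate_flow_network <- function(net) {
  e <- net$edges
  if (any(e$weight <= 0)) abort("flow_network: all edge weights must be > 0")
  if (any(e$source == e$target)) abort("flow_network: self-loop edges are not allowed")
  if (any(e$source == .EXIT)) {
    abort(sprintf("flow_network: '%s' must have zero out-weight", .EXIT))
  }
  if (anyDuplicated(paste(e$source, e$target, sep = "\r"))) {
    abort("flow_network: duplicate edges")
  }
  if (net$weight_mode == "proportion" && nrow(e) > 0 &&
    abs(sum(e$weight) - 1) > 1e-9) {
    abort("flow_network: proportion-mode weights must sum to 1")
  }
  net
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf(
    "<flow_network> window=%s site=%s: %d nodes, %d edges (%s mode)\n",
    x$window, x$site, length(x$nodes), nrow(x$edges), x$weight_mode
  ))
  invisible(x)
}

#' @export
format.flow_network <- function(x, ...) {
  sprintf("flow_network[%s/%s: %dn %de]", x$window, x$site,
          length(x$nodes), nrow(x$edges))
}

n_edges <- function(net) nrow(net$edges)

#' Number of nodes, with and without the virtual exit node
#'
#' @param net A [flow_network()].
#' @return Named numeric vector with elements `nodes` (including the exit
#'   node when present), `nodes_no_exit` and `edges`.
#' @export
network_size <- function(net) {
  c(
    nodes = length(net$nodes),
    nodes_no_exit = sum(net$nodes != .EXIT),
    edges = nrow(net$edges)
  )
}

#' Convert a flow network to an igraph graph
#'
#' @param net A [flow_network()].
#' @return A directed [igraph::graph] with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

# Re-express weights in the other mode. proportion -> count needs the
# total transfer count recorded at build time.
convert_weight_mode <- function(net, weight_mode) {
  if (net$weight_mode == weight_mode || nrow(net$edges) == 0) {
    net$weight_mode <- weight_mode
    return(net)
  }
  if (weight_mode == "proportion") {
    total <- sum(net$edges$weight)
    net$edges$weight <- net$edges$weight / total
    net$n_transfers <- total
  } else {
    if (is.na(net$n_transfers)) {
      abort("cannot convert to count mode: total transfer count unknown")
    }
    net$edges$weight <- round(net$edges$weight * net$n_transfers)
    net$edges <- net$edges[net$edges$weight > 0, ]
  }
  net$weight_mode <- weight_mode
  validate_flow_network(net)
}

#' Derive the ward-to-site assignment implied by a transfer log
#'
#' Each row of an event log carries the site the transfer was recorded at;
#' a ward is assigned to every site it appears under as a source ward. The
#' virtual exit node belongs to no site (an edge into it is included in a
#' site's network through its source ward).
#'
#' @param records Transfer records (see [read_transfer_events()]).
#' @return Tibble with columns `ward`, `site`.
#' @export
ward_site_map <- function(records) {
  m <- dplyr::distinct(records, ward = .data$source_ward, site = .data$site)
  dplyr::arrange(m, .data$site, .data$ward)
}

site_wards <- function(records, site, ward_sites = NULL, strict = FALSE) {
  ward_sites <- ward_sites %||% ward_site_map(records)
  known <- unique(ward_sites$ward)
  if (strict) {
    seen <- setdiff(unique(c(records$source_ward, records$target_ward)),
                    c(known, .EXIT))
    if (length(seen) > 0) {
      abort(sprintf(
        "wards with no site assignment: %s",
        paste(sort(seen), collapse = ", ")
      ))
    }
  }
  ward_sites$ward[ward_sites$site == site]
}

# A transfer belongs to a site's network if its source or target ward is
# assigned to that site.
filter_site <- function(records, site, ward_sites = NULL, strict = FALSE) {
  if (is.null(site) || is.na(site)) {
    return(records)
  }
  wards <- site_wards(records, site, ward_sites, strict)
  records[records$source_ward %in% wards | records$target_ward %in% wards, ]
}

#' Build a flow network from transfer records
#'
#' Aggregates transfer events into one weighted directed network. In count
#' mode the edge weight is the number of matching transfers; in proportion
#' mode it is that count divided by the total number of included transfers,
#' so that networks over windows with different admission volumes are
#' directly comparable.
#'
#' @param records Transfer records (see [read_transfer_events()]). Pass the
#'   subset falling in the window of interest, or use [windowed_networks()].
#' @param window Label attached to the resulting network.
#' @param site Site label; when non-`NULL`, a transfer is included if its
#'   source or target ward is assigned to the site (cross-site transfers
#'   therefore appear in both sites' networks).
#' @param weight_mode `"count"` (default) or `"proportion"`.
#' @param ward_sites Optional ward-to-site map (tibble `ward`, `site`);
#'   defaults to the one implied by `records`, see [ward_site_map()].
#' @param strict_sites Error when a ward has no site assignment.
#'
#' @return A [flow_network()]. No records yield an empty network.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = c("p1", "p2", "p3"),
#'   timestamp = as.POSIXct("2024-01-02 10:00", tz = "UTC") + 0:2 * 3600,
#'   site = "A", source_ward = c("AE", "AE", "W1"),
#'   target_ward = c("W1", "W1", "EXIT")
#' )
#' build_network(recs, weight_mode = "proportion")$edges
build_network <- function(records, window = NA_character_, site = NULL,
                          weight_mode = c("count", "proportion"),
                          ward_sites = NULL, strict_sites = FALSE) {
  weight_mode <- match.arg(weight_mode)
  records <- filter_site(records, site, ward_sites, strict_sites)
  if (nrow(records) == 0) {
    return(flow_network(
      tibble::tibble(source = character(), target = character(),
                     weight = numeric()),
      window = window, site = site %||% NA_character_,
      weight_mode = weight_mode, n_transfers = 0
    ))
  }
  edges <- dplyr::count(records, source = .data$source_ward,
                        target = .data$target_ward, name = "weight")
  total <- sum(edges$weight)
  if (weight_mode == "proportion") edges$weight <- edges$weight / total
  flow_network(edges, window = window, site = site %||% NA_character_,
               weight_mode = weight_mode, n_transfers = total)
}

#' Build one flow network per calendar window
#'
#' Splits the data span into calendar days, ISO weeks (starting Monday) or
#' calendar months and builds one network per unit. Windows inside the span
#' with no transfers yield empty networks that are retained in the sequence,
#' so positional alignment with the calendar is preserved.
#'
#' @inheritParams build_network
#' @param frequency `"day"`, `"week"` or `"month"`.
#' @return A list of [flow_network()] objects in chronological order, named
#'   by window label.
#' @export
windowed_networks <- function(records, frequency = c("day", "week", "month"),
                              site = NULL,
                              weight_mode = c("count", "proportion"),
                              ward_sites = NULL) {
  frequency <- match.arg(frequency)
  weight_mode <- match.arg(weight_mode)
  ward_sites <- ward_sites %||% ward_site_map(records)
  records <- filter_site(records, site, ward_sites)
  if (nrow(records) == 0) {
    return(list())
  }
  dates <- as.Date(records$timestamp, tz = "UTC")
  span <- seq(min(dates), max(dates), by = "day")
  labels <- unique(window_label(span, frequency))
  rec_label <- window_label(dates, frequency)
  nets <- lapply(labels, function(lab) {
    build_network(records[rec_label == lab, ], window = lab,
                  site = site, weight_mode = weight_mode,
                  ward_sites = ward_sites)
  })
  names(nets) <- labels
  nets
}

#' Monthly count-mode networks from a weekly aggregate table
#'
#' Weekly aggregates (see [read_weekly_aggregates()]) carry no event-level
#' timestamps, so a week is assigned to the calendar month containing its
#' Monday. This is an approximation at month boundaries, inherent to the
#' weekly resolution of the input.
#'
#' @param weekly Tibble of weekly aggregate rows.
#' @param site Optional site filter (rows are kept if their `site` matches).
#' @return Named list of count-mode [flow_network()] objects, one per month.
#' @export
networks_from_weekly <- function(weekly, site = NULL) {
  if (!is.null(site)) weekly <- weekly[weekly$site == site, ]
  weekly$month <- format(as.Date(weekly$week_start), "%Y-%m")
  months <- sort(unique(weekly$month))
  nets <- lapply(months, function(m) {
    rows <- weekly[weekly$month == m, ]
    edges <- dplyr::summarise(
      dplyr::group_by(rows, source = .data$source_ward,
                      target = .data$target_ward),
      weight = sum(.data$count), .groups = "drop"
    )
    flow_network(edges, window = m, site = site %||% NA_character_,
                 weight_mode = "count")
  })
  names(nets) <- months
  nets
}
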