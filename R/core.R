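# Core sub-network: edges present in every monthly network, and the
# fraction of flow they carry.

edge_keys <- function(net) paste(net$edges$source, net$edges$target,
                                 sep = "\r")

#' Edges present in every network of a sequence
#'
#' The "core" flow network: the intersection of the edge sets of the
#' monthly transfer networks. Presence is binary (count >= 1); weights play
#' no role. Windows with zero transfers are excluded from the intersection
#' (and reported), otherwise a single empty calendar month would make the
#' core trivially empty.
#'
#' @param nets Non-empty list of [flow_network()] snapshots for one site.
#' @return Tibble of core edges (`source`, `target`).
#' @export
core_edges <- function(nets) {
  if (length(nets) == 0) abort("core_edges needs at least one network")
  sites <- unique(vapply(nets, `[[`, character(1), "site"))
  if (length(sites) > 1) {
    abort("core_edges: networks must all belong to one site")
  }
  empty <- vapply(nets, function(n) nrow(n$edges) == 0, logical(1))
  if (all(empty)) abort("core_edges: all networks are empty")
  if (any(empty)) {
    inform(sprintf(
      "core_edges: excluded %d empty window(s): %s", sum(empty),
      paste(vapply(nets[empty], `[[`, character(1), "window"),
            collapse = ", ")
    ))
    nets <- nets[!empty]
  }
  keys <- Reduce(intersect, lapply(nets, edge_keys))
  e1 <- nets[[1]]$edges
  out <- e1[edge_keys(nets[[1]]) %in% keys, c("source", "target")]
  dplyr::arrange(out, .data$source, .data$target)
}

#' Flow carried by a core edge set, per window
#'
#' For each network, the fraction of edges belonging to the core and the
#' fraction of transfers (count weight) flowing through core edges, with
#' mean and standard deviation across windows.
#'
#' @param nets List of [flow_network()] snapshots (count mode or
#'   convertible); empty windows are skipped as in [core_edges()].
#' @param core Tibble of core edges (`source`, `target`); must be a subset
#'   of every non-empty network's edge set.
#' @return Object of class `core_result`: list with `core_edges`,
#'   `per_month` (tibble `window`, `n_edges`, `edge_fraction`,
#'   `flow_fraction`) and the four summary statistics
#'   `mean_edge_fraction`, `sd_edge_fraction`, `mean_flow_fraction`,
#'   `sd_flow_fraction`.
#' @export
core_flow <- function(nets, core = core_edges(nets)) {
  core_key <- paste(core$source, core$target, sep = "\r")
  nets <- Filter(function(n) nrow(n$edges) > 0, nets)
  per_month <- dplyr::bind_rows(lapply(nets, function(net) {
    net <- convert_weight_mode(net, "count")
    keys <- edge_keys(net)
    if (!all(core_key %in% keys)) {
      abort(sprintf(
        "core edge(s) missing from window %s: core must be a subset of every window",
        net$window
      ))
    }
    in_core <- keys %in% core_key
    tibble::tibble(
      window = net$window,
      n_edges = nrow(net$edges),
      edge_fraction = mean(in_core),
      flow_fraction = sum(net$edges$weight[in_core]) / sum(net$edges$weight)
    )
  }))
  structure(
    list(
      core_edges = core,
      per_month = per_month,
      mean_edge_fraction = mean(per_month$edge_fraction),
      sd_edge_fraction = sd(per_month$edge_fraction),
      mean_flow_fraction = mean(per_month$flow_fraction),
      sd_flow_fraction = sd(per_month$flow_fraction)
    ),
    class = "core_result"
  )
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<core_result> %d core edges over %d windows\n",
      "  edge fraction: %.1f%% (SD %.2f%%)\n",
      "  flow fraction: %.1f%% (SD %.2f%%)\n"
    ),
    nrow(x$core_edges), nrow(x$per_month),
    100 * x$mean_edge_fraction, 100 * x$sd_edge_fraction,
    100 * x$mean_flow_fraction, 100 * x$sd_flow_fraction
  ))
  invisible(x)
}
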