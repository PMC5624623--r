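# Node-level statistics: degree-difference roles, the edge-weight
# variability score, and path-based centrality.

#' In-degree minus out-degree of a ward
#'
#' The difference between the number of distinct wards sending patients
#' into a node and the number of distinct wards it sends patients to.
#' Edge weights are ignored. A large positive value marks a collector
#' (many sources, few destinations); a large negative value a distributor,
#' such as an emergency department.
#'
#' @param net A [flow_network()].
#' @param node Ward name; must be present in the network.
#' @return Integer degree difference.
#' @export
#' @examples
#' net <- flow_network(tibble::tibble(
#'   source = c("A", "B", "C", "D"), target = c("D", "D", "D", "E"),
#'   weight = 1
#' ))
#' degree_difference(net, "D") # 3 in-neighbours, 1 out-neighbour -> 2
degree_difference <- function(net, node) {
  if (!node %in% net$nodes) {
    abort(sprintf("node '%s' not present in network %s", node, net$window))
  }
  e <- net$edges
  length(unique(e$source[e$target == node])) -
    length(unique(e$target[e$source == node]))
}

#' Classify ward roles from degree differences over time
#'
#' Computes each node's in-minus-out degree difference in every window and
#' classifies the node by the mean: `in>>out` when the mean difference is
#' at least `threshold`, `out>>in` when at most `-threshold`, otherwise
#' `balanced`. Windows where a node is absent do not contribute.
#'
#' @param nets List of [flow_network()] snapshots in chronological order.
#' @param threshold Positive integer; minimum mean distinct-neighbour
#'   difference for an unbalanced role. Default 10.
#' @return Tibble with columns `node`, `role` (factor with levels
#'   `out>>in`, `balanced`, `in>>out`), `mean_difference`, and a list
#'   column `trajectory` of per-window differences (NA when absent).
#' @export
classify_degree_roles <- function(nets, threshold = 10) {
  stopifnot(length(nets) >= 1, threshold > 0)
  nodes <- sort(unique(unlist(lapply(nets, `[[`, "nodes"))))
  traj <- vapply(nets, function(net) {
    vapply(nodes, function(nd) {
      if (nd %in% net$nodes) degree_difference(net, nd) else NA_real_
    }, numeric(1))
  }, numeric(length(nodes)))
  traj <- matrix(traj, nrow = length(nodes),
                 dimnames = list(nodes, names(nets)))
  mean_diff <- rowMeans(traj, na.rm = TRUE)
  role <- ifelse(mean_diff >= threshold, "in>>out",
                 ifelse(mean_diff <= -threshold, "out>>in", "balanced"))
  tibble::tibble(
    node = nodes,
    role = factor(role, levels = c("out>>in", "balanced", "in>>out")),
    mean_difference = unname(mean_diff),
    trajectory = lapply(seq_along(nodes), function(i) traj[i, ])
  )
}

# Observed deviation of a weight vector from perfect balance, normalised
# to the mean weight.
deviation_obs <- function(w) sum(abs(w - mean(w))) / mean(w)

# Maximum possible deviation for the same total and edge count: all edges
# at weight 1 except one carrying the rest (closed form).
deviation_max <- function(w) {
  k <- length(w)
  wbar <- mean(w)
  ((k - 1) * (wbar - 1) + (sum(w) - wbar - k + 1)) / wbar
}

#' Edge-weight variability score
#'
#' Measures how unevenly a node's input (or output) edge weights are
#' distributed: the observed deviation from the perfectly balanced state
#' (every edge carrying the mean weight), as a proportion of the maximum
#' possible deviation (all edges at weight 1 except one carrying the
#' remainder). 0 means perfectly balanced, 1 maximally uneven. Defined for
#' integer transfer counts (minimum conceivable edge weight 1) and at least
#' two edges.
#'
#' @param weights Numeric vector of `k >= 2` positive integer edge weights
#'   attached to one node on one side.
#' @return Score in `[0, 1]`. The degenerate all-equal case (including all
#'   weights 1, where the maximum deviation is 0) returns 0: the observed
#'   deviation is 0 and the configuration is perfectly balanced.
#' @export
#' @examples
#' weight_variability(c(5, 5, 5)) # 0
#' weight_variability(c(1, 1, 8)) # 1
#' weight_variability(c(2, 3, 5)) # 5/14
weight_variability <- function(weights) {
  if (length(weights) < 2) {
    abort(paste("the variability score is only defined when there are",
                "at least two (input or output) edges"))
  }
  if (any(weights <= 0)) abort("edge weights must be positive")
  if (any(abs(weights - round(weights)) > 1e-9)) {
    abort("the variability score is defined on integer transfer counts")
  }
  obs <- deviation_obs(weights)
  if (obs == 0) {
    return(0)
  }
  # the two deviations are computed by algebraically different routes, so
  # an extremal configuration can land a rounding error above 1
  min(obs / deviation_max(weights), 1)
}

#' Variability scores for every node of a network
#'
#' Applies [weight_variability()] to the input and output count weights of
#' each node. Proportion-mode networks are converted back to counts first
#' (the score's extremal case presupposes integer weights). Nodes with
#' fewer than two edges on a side get `NA` for that side.
#'
#' @param net A [flow_network()] built from transfer counts.
#' @return Tibble `window`, `site`, `node`, `side` (`input`/`output`),
#'   `k` (number of edges), `score`.
#' @export
network_variability <- function(net) {
  net <- convert_weight_mode(net, "count")
  e <- net$edges
  one_side <- function(node, side) {
    w <- if (side == "input") e$weight[e$target == node] else
      e$weight[e$source == node]
    tibble::tibble(
      window = net$window, site = net$site, node = node, side = side,
      k = length(w),
      score = if (length(w) >= 2) weight_variability(w) else NA_real_
    )
  }
  dplyr::bind_rows(lapply(net$nodes, function(nd) {
    dplyr::bind_rows(one_side(nd, "input"), one_side(nd, "output"))
  }))
}

#' Path-based centrality of a ward
#'
#' The fraction of observed patient ward-sequences that pass through the
#' node at least once. Used instead of shortest-path centralities, which
#' are not meaningful here: the route a patient takes is dictated by
#' clinical need, not by graph distance.
#'
#' @param paths Tibble of patient paths (see [reconstruct_paths()]), or a
#'   list of character vectors.
#' @param node Ward name.
#' @return Fraction in `[0, 1]`.
#' @export
path_centrality <- function(paths, node) {
  seqs <- if (is.data.frame(paths)) paths$sequence else paths
  if (length(seqs) == 0) {
    abort("path_centrality is undefined on an empty path set")
  }
  mean(vapply(seqs, function(s) node %in% s, logical(1)))
}
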