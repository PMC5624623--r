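# Unsupervised clustering of daily flow snapshots: one row per day, one
# column per edge (proportion of that day's transfers), PCA on the centred
# (and by default scaled) columns, and association of component scores with
# performance groups and the weekday/weekend split.

#' Daily edge-weight matrix
#'
#' Builds the day-by-edge matrix used for clustering: each row is one
#' calendar day in the data span, each column one directed edge, and each
#' value the proportion of that day's transfers carried by the edge (0 when
#' absent). Edges present on less than `min_prevalence` of days (strictly)
#' are removed; over the unfiltered edge universe every non-empty row sums
#' to 1.
#'
#' @param records Transfer records.
#' @param site Site label (see [build_network()]).
#' @param perf Optional performance series used to label days High/Mid/Low
#'   via [performance_groups()].
#' @param min_prevalence Minimum fraction of days an edge must appear on
#'   (default 0.01).
#' @return Object of class `daily_edge_matrix`: list with `matrix` (days x
#'   edges, dimnames set), `labels` (tibble `date`, `weekend`, `group`),
#'   `n_edges_total` and `n_edges_removed`.
#' @export
daily_edge_matrix <- function(records, site = NULL, perf = NULL,
                              min_prevalence = 0.01) {
  records <- filter_site(records, site)
  if (nrow(records) == 0) abort("daily_edge_matrix: no transfers")
  dates <- as.Date(records$timestamp, tz = "UTC")
  days <- seq(min(dates), max(dates), by = "day")
  if (length(days) < 100) {
    warn(sprintf(
      "daily_edge_matrix: only %d days; prevalence filtering and PCA are intended for longer series",
      length(days)
    ))
  }
  counts <- dplyr::count(
    tibble::tibble(
      day = dates,
      edge = paste(records$source_ward, records$target_ward, sep = ">")
    ),
    .data$day, .data$edge
  )
  edges <- sort(unique(counts$edge))
  mat <- matrix(0, nrow = length(days), ncol = length(edges),
                dimnames = list(format(days, "%Y-%m-%d"), edges))
  mat[cbind(match(counts$day, days), match(counts$edge, edges))] <- counts$n
  totals <- rowSums(mat)
  nonzero <- totals > 0
  mat[nonzero, ] <- mat[nonzero, , drop = FALSE] / totals[nonzero]
  prevalence <- colMeans(mat > 0)
  keep <- prevalence >= min_prevalence
  labels <- tibble::tibble(
    date = days,
    weekend = is_weekend(days),
    group = factor(NA, levels = c("Low", "Mid", "High"))
  )
  if (!is.null(perf)) {
    groups <- performance_groups(perf, site)
    labels$group <- groups$group[match(days, groups$date)]
  }
  structure(
    list(
      matrix = mat[, keep, drop = FALSE],
      labels = labels,
      n_edges_total = length(edges),
      n_edges_removed = sum(!keep)
    ),
    class = "daily_edge_matrix"
  )
}

#' Principal component analysis of daily flow
#'
#' PCA of the day-by-edge matrix with columns centred and, by default,
#' scaled to unit variance (so no single high-magnitude edge dominates).
#' Zero-variance columns are dropped with a message when scaling. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so results are reproducible across platforms.
#'
#' @param dem A [daily_edge_matrix()] (or a plain numeric matrix).
#' @param n_components Number of components to keep (default 10, capped at
#'   the matrix rank bound).
#' @param scale Unit-scale columns before decomposition (default `TRUE`);
#'   `FALSE` gives the centred-only variant.
#' @return Object of class `flow_pca`: list with `loadings` (edges x
#'   components), `scores` (days x components), `variance_fraction`
#'   (fraction of total variance per retained component), `labels`, and
#'   `scale`.
#' @export
run_flow_pca <- function(dem, n_components = 10, scale = TRUE) {
  mat <- if (inherits(dem, "daily_edge_matrix")) dem$matrix else dem
  labels <- if (inherits(dem, "daily_edge_matrix")) dem$labels else NULL
  variances <- apply(mat, 2, stats::var)
  if (scale && any(variances == 0)) {
    inform(sprintf("run_flow_pca: dropped %d zero-variance column(s)",
                   sum(variances == 0)))
    mat <- mat[, variances > 0, drop = FALSE]
  }
  n_components <- min(n_components, nrow(mat) - 1L, ncol(mat))
  if (all(apply(mat, 2, stats::var) == 0)) {
    # constant matrix: no variance to decompose
    pcs <- paste0("PC", seq_len(max(n_components, 1)))
    return(structure(list(
      loadings = matrix(0, ncol(mat), length(pcs),
                        dimnames = list(colnames(mat), pcs)),
      scores = matrix(0, nrow(mat), length(pcs),
                      dimnames = list(rownames(mat), pcs)),
      variance_fraction = setNames(rep(0, length(pcs)), pcs),
      labels = labels, scale = scale
    ), class = "flow_pca"))
  }
  fit <- prcomp(mat, center = TRUE, scale. = scale)
  total_var <- sum(fit$sdev^2)
  keep <- seq_len(min(n_components, ncol(fit$rotation)))
  loadings <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      loadings = loadings, scores = scores,
      variance_fraction = setNames(fit$sdev[keep]^2 / total_var,
                                   colnames(loadings)),
      labels = labels, scale = scale
    ),
    class = "flow_pca"
  )
}

#' @export
print.flow_pca <- function(x, ...) {
  cat(sprintf(
    "<flow_pca> %d components over %d edges (%s); variance: %s\n",
    ncol(x$loadings), nrow(x$loadings),
    if (x$scale) "centred+scaled" else "centred",
    paste(sprintf("%.2f%%", 100 * head(x$variance_fraction, 5)),
          collapse = " ")
  ))
  invisible(x)
}

point_biserial <- function(score, flag) {
  flag <- as.logical(flag)
  ok <- !is.na(flag) & !is.na(score)
  if (sum(flag[ok]) == 0 || sum(!flag[ok]) == 0) {
    return(NA_real_)
  }
  cor(score[ok], as.numeric(flag[ok]))
}

#' Associate components with performance and the weekend
#'
#' For each retained component, the point-biserial correlation of its day
#' scores with (a) the High-vs-Low performance label (Mid days excluded)
#' and (b) the weekend flag. An empty label class yields `NA` for that
#' contrast.
#'
#' @param pca A [run_flow_pca()] result.
#' @param labels Day labels (tibble `date`, `weekend`, `group`); defaults
#'   to the labels carried by the PCA input.
#' @return Tibble `component`, `variance_fraction`, `r_high_low`,
#'   `r_weekend`.
#' @export
component_association <- function(pca, labels = NULL) {
  labels <- labels %||% pca$labels
  if (is.null(labels)) abort("component_association: no day labels")
  idx <- match(rownames(pca$scores), format(labels$date, "%Y-%m-%d"))
  if (anyNA(idx)) abort("component_association: labels do not cover all days")
  group <- labels$group[idx]
  weekend <- labels$weekend[idx]
  extreme <- group %in% c("High", "Low")
  dplyr::bind_rows(lapply(seq_len(ncol(pca$scores)), function(j) {
    s <- pca$scores[, j]
    tibble::tibble(
      component = colnames(pca$scores)[j],
      variance_fraction = unname(pca$variance_fraction[j]),
      r_high_low = point_biserial(s[extreme], group[extreme] == "High"),
      r_weekend = point_biserial(s, weekend)
    )
  }))
}
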