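# Differential network analysis: pool flow over the best- and
# worst-performing A&E days (optionally lagged) and contrast the two
# proportion-weight networks edge by edge.

#' Split days into High / Mid / Low performance groups
#'
#' Ranks one site's days by the percentage of A&E patients meeting the
#' 4-hour target. The top `floor(0.1 n)` days form the High group, the
#' bottom `floor(0.1 n)` the Low group, and the remainder the Mid group.
#' Ties at a decile boundary are broken deterministically by date, earlier
#' date first.
#'
#' @param perf Performance series (see [read_performance_series()]).
#' @param site Site label to subset on; `NULL` uses all rows (they must
#'   then belong to one site).
#' @return Object of class `performance_groups`: tibble `date`,
#'   `performance_pct`, `arrivals`, `group` (factor Low/Mid/High), with
#'   attribute `site`.
#' @export
performance_groups <- function(perf, site = NULL) {
  if (!is.null(site)) perf <- perf[perf$site == site, ]
  if (length(unique(perf$site)) > 1) {
    abort("performance_groups: supply a single site")
  }
  n <- nrow(perf)
  if (n < 10) abort("performance_groups needs at least 10 days")
  n_tail <- floor(0.1 * n)
  perf <- dplyr::arrange(perf, .data$date)
  ord_best <- order(-perf$performance_pct, perf$date)
  ord_worst <- order(perf$performance_pct, perf$date)
  group <- rep("Mid", n)
  high_idx <- ord_best[seq_len(n_tail)]
  group[high_idx] <- "High"
  # a day claimed by High cannot also be Low (possible when values tie)
  group[setdiff(ord_worst, high_idx)[seq_len(n_tail)]] <- "Low"
  out <- tibble::tibble(
    date = perf$date,
    performance_pct = perf$performance_pct,
    arrivals = perf$arrivals,
    group = factor(group, levels = c("Low", "Mid", "High"))
  )
  structure(out, site = unique(perf$site),
            class = c("performance_groups", class(out)))
}

#' Pool transfers over a set of days into one network
#'
#' Builds a single proportion-mode network from all transfers occurring on
#' `day - lag` for each day in `days` ("the flow on the previous day" for
#' `lag = 1`). Lagged days falling before the start of the transfer data
#' are dropped with a message.
#'
#' @param records Transfer records.
#' @param days Vector of `Date`s (e.g. the High group's days).
#' @param site Site label (see [build_network()]).
#' @param lag Non-negative integer number of days to look back.
#' @param ward_sites Optional ward-to-site map.
#' @return A proportion-mode [flow_network()].
#' @export
pooled_network <- function(records, days, site = NULL, lag = 0,
                           ward_sites = NULL) {
  stopifnot(lag >= 0)
  days <- as.Date(days) - lag
  data_start <- min(as.Date(records$timestamp, tz = "UTC"))
  early <- days < data_start
  if (any(early)) {
    inform(sprintf(
      "pooled_network: dropped %d day(s) lagged before the data start",
      sum(early)
    ))
    days <- days[!early]
  }
  keep <- as.Date(records$timestamp, tz = "UTC") %in% days
  build_network(records[keep, ],
                window = sprintf("pooled(lag=%d)", lag), site = site,
                weight_mode = "proportion", ward_sites = ward_sites)
}

#' Differential network between best and worst days
#'
#' Subtracts each edge's proportion weight in the worst-day network from
#' its weight in the best-day network, over the union of the two edge sets
#' (a missing edge contributes weight 0). A negative difference marks an
#' edge carrying a greater share of transfers on low-performing days. Edges
#' whose difference deviates from the mean difference by strictly more than
#' `k_sd` standard deviations are retained; with both networks in
#' proportion mode the differences sum to zero, so the mean is (numerically)
#' zero.
#'
#' @param best,worst Proportion-mode [flow_network()]s for the High and Low
#'   day groups.
#' @param k_sd Retention threshold in standard deviations (default 2).
#' @return Object of class `differential_network`: list with `diffs`
#'   (tibble `source`, `target`, `diff`), `sd`, `mean`, `k_sd`, `retained`
#'   (subset tibble with `sd_units` and `direction` = better/worse) and
#'   `lag` (`NA` unless set by the caller).
#' @export
differential_network <- function(best, worst, k_sd = 2) {
  stopifnot(k_sd > 0)
  if (best$weight_mode != "proportion" || worst$weight_mode != "proportion") {
    abort("differential_network: both networks must be proportion-mode")
  }
  joined <- dplyr::full_join(
    best$edges, worst$edges, by = c("source", "target"),
    suffix = c("_best", "_worst")
  )
  joined$weight_best[is.na(joined$weight_best)] <- 0
  joined$weight_worst[is.na(joined$weight_worst)] <- 0
  diffs <- tibble::tibble(
    source = joined$source, target = joined$target,
    diff = joined$weight_best - joined$weight_worst
  )
  diffs <- dplyr::arrange(diffs, .data$source, .data$target)
  mu <- if (nrow(diffs) > 0) mean(diffs$diff) else 0
  sdev <- if (nrow(diffs) > 1) sd(diffs$diff) else 0
  retained <- diffs[abs(diffs$diff - mu) > k_sd * sdev, ]
  retained$sd_units <- if (sdev > 0) (retained$diff - mu) / sdev else
    numeric(nrow(retained))
  retained$direction <- ifelse(retained$diff > 0, "better", "worse")
  structure(
    list(diffs = diffs, sd = sdev, mean = mu, k_sd = k_sd,
         retained = retained, lag = NA_integer_),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "<differential_network> %d edges, sd %.3g, %d retained (> %g sd)%s\n",
    nrow(x$diffs), x$sd, nrow(x$retained), x$k_sd,
    if (!is.na(x$lag)) sprintf(", lag %d", x$lag) else ""
  ))
  invisible(x)
}

#' Differential network at a given lag
#'
#' Convenience wrapper: groups days with [performance_groups()], pools the
#' High and Low groups' (lagged) transfers and contrasts them.
#'
#' @inheritParams pooled_network
#' @param perf Performance series for the same site.
#' @param k_sd Retention threshold in standard deviations.
#' @return A [differential_network()] with its `lag` field set.
#' @export
lagged_differential <- function(records, perf, site = NULL, lag = 0,
                                k_sd = 2, ward_sites = NULL) {
  groups <- performance_groups(perf, site)
  best <- pooled_network(records, groups$date[groups$group == "High"],
                         site = site, lag = lag, ward_sites = ward_sites)
  worst <- pooled_network(records, groups$date[groups$group == "Low"],
                          site = site, lag = lag, ward_sites = ward_sites)
  dn <- differential_network(best, worst, k_sd = k_sd)
  dn$lag <- as.integer(lag)
  dn
}

#' Differential-network spread across a range of lags
#'
#' Recomputes the best-minus-worst differential network while shifting the
#' pooled flow back by 0, 1, ... `max_lag` days and records the standard
#' deviation of the edge differences at each lag. A peak at a positive lag
#' indicates that flow differences precede the performance extremes by that
#' many days.
#'
#' @inheritParams lagged_differential
#' @param max_lag Largest lag, in days (default 14).
#' @return Tibble `lag`, `sd`, `n_retained`.
#' @export
lag_sweep <- function(records, perf, site = NULL, max_lag = 14, k_sd = 2,
                      ward_sites = NULL) {
  stopifnot(max_lag >= 0)
  ward_sites <- ward_sites %||% ward_site_map(records)
  dplyr::bind_rows(lapply(0:max_lag, function(lag) {
    dn <- lagged_differential(records, perf, site = site, lag = lag,
                              k_sd = k_sd, ward_sites = ward_sites)
    tibble::tibble(lag = lag, sd = dn$sd, n_retained = nrow(dn$retained))
  }))
}
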