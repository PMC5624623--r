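# End-to-end driver: run every analysis stage on one site's data and
# collect the results (optionally written out as a CSV bundle plus a JSON
# manifest with SHA-256 digests).

skipped_section <- function(reason) {
  structure(list(skipped = TRUE, reason = reason), class = "skipped_section")
}

is_skipped <- function(x) inherits(x, "skipped_section")

#' Run the full patient-flow analysis
#'
#' Orchestrates all stages for one site: monthly network summaries, degree
#' roles, weight-variability distributions, the core sub-network, ward
#' sequence statistics, lagged differential networks and PCA clustering.
#' Stages that need event-level or daily resolution (sequences,
#' differential, PCA) are marked skipped -- never silently approximated --
#' when only a weekly aggregate table is supplied.
#'
#' @param records Transfer records ([read_transfer_events()]), or `NULL`
#'   when running from a weekly aggregate.
#' @param perf Daily performance series ([read_performance_series()]), or
#'   `NULL` (differential and group labels are then skipped).
#' @param weekly Weekly aggregate table ([read_weekly_aggregates()]); used
#'   only when `records` is `NULL`.
#' @param site Site label.
#' @param role_threshold Degree-difference threshold for
#'   [classify_degree_roles()].
#' @param max_lag Largest lag for [lag_sweep()].
#' @param n_components Components for [run_flow_pca()].
#' @param target_fraction Coverage target for [top_k_coverage()].
#' @param out_dir Optional directory to write the CSV bundle and
#'   `manifest.json` into.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Object of class `flow_analysis`: a named list of sections, each
#'   either a result or a skipped marker with a reason.
#' @export
run_flow_analysis <- function(records = NULL, perf = NULL, weekly = NULL,
                              site = NULL, role_threshold = 10,
                              max_lag = 14, n_components = 10,
                              target_fraction = 0.5, out_dir = NULL,
                              seed = NA_integer_) {
  if (is.null(records) && is.null(weekly)) {
    abort("run_flow_analysis: supply event records or a weekly aggregate")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(records)) {
    monthly <- stage("network_build",
                     windowed_networks(records, "month", site = site))
  } else {
    monthly <- stage("network_build", networks_from_weekly(weekly, site))
  }
  sizes <- dplyr::bind_rows(lapply(monthly, function(n) {
    s <- network_size(n)
    tibble::tibble(window = n$window, nodes = s["nodes"],
                   nodes_no_exit = s["nodes_no_exit"], edges = s["edges"])
  }))
  full_net <- if (!is.null(records)) {
    build_network(records, window = "full", site = site)
  } else {
    nets <- networks_from_weekly(weekly, site)
    edges <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(lapply(nets, `[[`, "edges")),
                      .data$source, .data$target),
      weight = sum(.data$weight), .groups = "drop"
    )
    flow_network(edges, window = "full", site = site %||% NA_character_)
  }
  bundle <- list(
    site = site, seed = seed,
    network_summary = list(full = network_size(full_net),
                           monthly = sizes),
    degree_roles = stage("node_metrics",
                         classify_degree_roles(monthly, role_threshold)),
    variability = stage("node_metrics", dplyr::bind_rows(
      lapply(Filter(function(n) nrow(n$edges) > 0, monthly),
             network_variability)
    )),
    core = stage("core_network", core_flow(monthly))
  )

  if (!is.null(records)) {
    paths <- stage("path_analysis", reconstruct_paths(records))
    freqs <- stage("path_analysis", sequence_frequencies(paths))
    bundle$sequences <- list(
      paths = paths, frequencies = freqs,
      top_k = top_k_coverage(freqs, target_fraction),
      target_fraction = target_fraction
    )
  } else {
    bundle$sequences <- skipped_section(
      "requires event-level records (weekly aggregate supplied)")
  }

  if (!is.null(records) && !is.null(perf)) {
    bundle$differential <- stage("differential", list(
      lag0 = lagged_differential(records, perf, site = site, lag = 0),
      lag1 = lagged_differential(records, perf, site = site, lag = 1),
      sweep = lag_sweep(records, perf, site = site, max_lag = max_lag)
    ))
  } else {
    bundle$differential <- skipped_section(
      if (is.null(records)) "requires daily-resolution event records"
      else "requires a daily performance series")
  }

  if (!is.null(records)) {
    dem <- stage("clustering",
                 daily_edge_matrix(records, site = site, perf = perf))
    pca <- stage("clustering", run_flow_pca(dem, n_components))
    bundle$pca <- list(
      matrix = dem, fit = pca,
      association = if (!is.null(perf)) component_association(pca)
                    else skipped_section("no performance labels")
    )
  } else {
    bundle$pca <- skipped_section(
      "requires daily-resolution event records")
  }

  bundle <- structure(bundle, class = "flow_analysis")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.flow_analysis <- function(x, ...) {
  cat(sprintf("<flow_analysis> site %s\n", x$site %||% "(all)"))
  for (s in setdiff(names(x), c("site", "seed"))) {
    cat(sprintf("  %-16s %s\n", s,
                if (is_skipped(x[[s]])) paste("skipped:", x[[s]]$reason)
                else "ok"))
  }
  invisible(x)
}

write_bundle_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Write the bundle as CSVs plus a manifest listing each artifact with its
# SHA-256. Rerunning on identical inputs gives identical digests.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(name, df) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    files[[length(files) + 1]] <<- write_bundle_csv(df, p)
  }
  emit("network_summary", bundle$network_summary$monthly)
  emit("degree_roles",
       bundle$degree_roles[, c("node", "role", "mean_difference")])
  emit("variability", bundle$variability)
  emit("core_edges", bundle$core$core_edges)
  emit("core_months", bundle$core$per_month)
  if (!is_skipped(bundle$sequences)) {
    emit("sequences",
         bundle$sequences$frequencies[, c("rank", "path", "count",
                                          "cumulative_fraction")])
  }
  if (!is_skipped(bundle$differential)) {
    emit("lag_sweep", bundle$differential$sweep)
    emit("differential_edges", dplyr::bind_rows(
      cbind(lag = 0, bundle$differential$lag0$retained),
      cbind(lag = 1, bundle$differential$lag1$retained)
    ))
  }
  if (!is_skipped(bundle$pca)) {
    emit("pca_variance", tibble::tibble(
      component = names(bundle$pca$fit$variance_fraction),
      variance_fraction = unname(bundle$pca$fit$variance_fraction)
    ))
    if (!is_skipped(bundle$pca$association)) {
      emit("pca_association", bundle$pca$association)
    }
  }
  skipped <- Filter(function(s) is_skipped(bundle[[s]]),
                    setdiff(names(bundle), c("site", "seed")))
  manifest <- list(
    site = bundle$site %||% NA,
    seed = bundle$seed,
    skipped = lapply(setNames(skipped, skipped),
                     function(s) bundle[[s]]$reason),
    artifacts = lapply(setNames(files, basename(unlist(files))),
                       function(f) digest::digest(file = f, algo = "sha256"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
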