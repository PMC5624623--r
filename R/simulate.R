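# Synthetic hospital: a discrete-event generator of transfer logs and
# daily A&E performance with planted ground truth. Patients arrive at the
# A&E ward by a (weekend-modulated) Poisson process and move between wards
# by a Markov routing chain until discharge to the virtual exit node.
# Planted structure, all reported in the returned `truth`:
#   * a core edge set: the support of the routing table, present in every
#     month by construction;
#   * ephemeral flow: with a small per-transfer probability the sampled
#     target is replaced by one drawn from a per-ward pool of off-route
#     wards that is redrawn every 30 days at a random per-ward phase, so
#     ephemeral edges recur briefly but not month after month;
#   * a weekend effect: arrivals, A&E-to-CDU routing mass and discharge
#     probabilities are damped on Saturdays and Sundays;
#   * performance coupling: a latent daily "pressure" shifts routing mass
#     away from the clinical decision unit and towards a surgical ward, and
#     next-day A&E performance is a noisy linear function of those edges'
#     proportional flow.

#' Simulation parameter set
#'
#' Assembles and validates the parameters of [simulate_hospital()]. Most
#' users want [default_params()].
#'
#' @param wards Tibble `name`, `site`, `role` (roles: `AE`, `CDU`,
#'   `medical`, `surgical`, `elderly`, `stroke`). Exactly one `AE` ward.
#' @param routing Row-stochastic matrix, one row per ward, one column per
#'   ward plus the exit node: the next-ward distribution.
#' @param ephemeral_rate Per-transfer probability of an off-route hop, in
#'   `[0, 0.2)`.
#' @param ephemeral_pool_size Number of off-route targets per ward in its
#'   rotating pool (redrawn every 30 days at a random per-ward phase).
#' @param daily_arrival_rate Poisson mean of weekday A&E arrivals.
#' @param weekend_multiplier Factor applied on weekends to arrivals and to
#'   the A&E-to-CDU routing mass.
#' @param weekend_discharge_multiplier Factor applied on weekends to every
#'   ward's discharge (exit) probability.
#' @param coupling Tibble `source`, `target`, `lag`, `beta`, `amplitude`:
#'   the edge's routing mass is scaled by `1 + amplitude * z(d)` (z the
#'   daily standard-normal pressure) and `beta` times the edge's
#'   proportion-of-day flow at `d - lag` enters the performance model.
#' @param perf_base,perf_noise_sd Intercept and noise SD (percent units) of
#'   the daily performance model; performance is clipped to `[0, 100]`.
#' @param n_days,start_date Study length and first day.
#' @param site Site label stamped on all records.
#' @param max_hops Path-length cap per admission (forced discharge beyond
#'   it, with a message).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(wards, routing, ephemeral_rate = 0.15,
                       ephemeral_pool_size = 6, daily_arrival_rate = 177,
                       weekend_multiplier = 0.8,
                       weekend_discharge_multiplier = 0.6,
                       coupling = NULL, perf_base = 70, perf_noise_sd = 4,
                       n_days = 152, start_date = as.Date("2024-01-01"),
                       site = "SYN", max_hops = 30, seed = 1) {
  stopifnot(is.data.frame(wards),
            all(c("name", "site", "role") %in% names(wards)))
  if (anyDuplicated(wards$name)) abort("sim_params: duplicate ward names")
  if (.EXIT %in% wards$name) {
    abort(sprintf("sim_params: '%s' is reserved", .EXIT))
  }
  if (sum(wards$role == "AE") != 1) {
    abort("sim_params: exactly one AE ward required")
  }
  targets <- c(wards$name, .EXIT)
  if (!identical(rownames(routing), wards$name) ||
    !identical(colnames(routing), targets)) {
    abort("sim_params: routing must have ward rows and ward+exit columns")
  }
  if (any(routing < 0) || any(abs(rowSums(routing) - 1) > 1e-9)) {
    abort("sim_params: routing rows must be non-negative and sum to 1")
  }
  if (any(diag(routing[, wards$name]) > 0)) {
    abort("sim_params: self-transfer routing mass is not allowed")
  }
  if (ephemeral_rate < 0 || ephemeral_rate >= 0.2) {
    abort("sim_params: ephemeral_rate must lie in [0, 0.2)")
  }
  coupling <- coupling %||%
    tibble::tibble(source = character(), target = character(),
                   lag = integer(), beta = numeric(), amplitude = numeric())
  if (nrow(coupling) > 0) {
    on_support <- routing[cbind(coupling$source, coupling$target)] > 0
    if (!all(on_support) || !all(is.finite(coupling$beta))) {
      abort("sim_params: coupled edges must lie on the routing support with finite betas")
    }
  }
  structure(
    list(
      wards = tibble::as_tibble(wards), routing = routing,
      ephemeral_rate = ephemeral_rate,
      ephemeral_pool_size = ephemeral_pool_size,
      daily_arrival_rate = daily_arrival_rate,
      weekend_multiplier = weekend_multiplier,
      weekend_discharge_multiplier = weekend_discharge_multiplier,
      coupling = coupling, perf_base = perf_base,
      perf_noise_sd = perf_noise_sd, n_days = as.integer(n_days),
      start_date = as.Date(start_date), site = site,
      max_hops = as.integer(max_hops), seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> site %s: %d wards, %.0f arrivals/day, %d days from %s (seed %d)\n",
    x$site, nrow(x$wards), x$daily_arrival_rate, x$n_days,
    format(x$start_date), x$seed
  ))
  invisible(x)
}

# Ward roster and routing table for a site profile. Layout: one A&E
# distributor, two clinical decision units, a ring of "gateway" admission
# wards fed by A&E, and downstream specialty wards fed by the gateways.
# Routing probabilities are chosen so that every support edge expects
# enough monthly transfers to appear in every monthly network.
build_profile <- function(n_wards, n_gateways, arrival_rate, site) {
  n_down <- n_wards - 3L - n_gateways
  stopifnot(n_down >= n_gateways)
  n_med_gw <- ceiling(0.6 * n_gateways)
  gw <- c(sprintf("MED%02d", seq_len(n_med_gw)),
          sprintf("SUR%02d", seq_len(n_gateways - n_med_gw)))
  n_med_dn <- ceiling(0.55 * n_down)
  n_sur_dn <- ceiling(0.2 * n_down)
  n_eld <- ceiling(0.15 * n_down)
  n_str <- n_down - n_med_dn - n_sur_dn - n_eld
  down <- c(sprintf("MED%02d", n_med_gw + seq_len(n_med_dn)),
            sprintf("SUR%02d", (n_gateways - n_med_gw) + seq_len(n_sur_dn)),
            sprintf("ELD%02d", seq_len(n_eld)),
            sprintf("STR%02d", seq_len(n_str)))
  wards <- tibble::tibble(
    name = c("AE", "CDU1", "CDU2", gw, down),
    site = site,
    role = c("AE", "CDU", "CDU",
             ifelse(grepl("^MED", gw), "medical", "surgical"),
             c(rep("medical", n_med_dn), rep("surgical", n_sur_dn),
               rep("elderly", n_eld), rep("stroke", n_str)))
  )
  targets <- c(wards$name, .EXIT)
  routing <- matrix(0, nrow(wards), length(targets),
                    dimnames = list(wards$name, targets))
  routing["AE", "CDU1"] <- 0.30
  routing["AE", "CDU2"] <- 0.12
  routing["AE", gw] <- 0.35 / n_gateways
  routing["AE", down] <- 0.20 / n_down
  routing["AE", .EXIT] <- 0.03
  routing["CDU1", c(gw[1], gw[2], .EXIT)] <- c(0.10, 0.10, 0.80)
  routing["CDU2", c(gw[3], gw[4], .EXIT)] <- c(0.10, 0.10, 0.80)
  for (i in seq_len(n_gateways)) {
    d1 <- down[(2 * i - 2) %% n_down + 1]
    d2 <- down[(2 * i - 1) %% n_down + 1]
    nxt <- gw[i %% n_gateways + 1]
    routing[gw[i], c(d1, d2, nxt, .EXIT)] <-
      c(0.15, 0.15, 0.15, 1 - sum(routing[gw[i], ]) - 0.45)
  }
  for (j in seq_len(n_down)) {
    peer <- down[j %% n_down + 1]
    back <- gw[(j - 1) %% n_gateways + 1]
    routing[down[j], c(peer, back, .EXIT)] <- c(0.15, 0.15, 0.70)
  }
  list(wards = wards, routing = routing)
}

#' Default simulation parameters for a site profile
#'
#' Two ready-made hospital profiles matched in scale to the study sites:
#' `"dh"` (larger teaching-hospital site, 385 A&E arrivals/day, 63 wards)
#' and `"pruh"` (district-hospital site, 177 arrivals/day, 46 wards). Both
#' plant a routing-support core carrying roughly 90% of transfers, a
#' weekend multiplier of 0.8, and two performance-coupled edges at lag 1:
#' flow from A&E into the clinical decision unit raises next-day
#' performance, flow from A&E into a surgical ward lowers it.
#'
#' @param profile `"pruh"` (default) or `"dh"`.
#' @param ... Overrides passed on to [sim_params()] (e.g. `n_days`,
#'   `seed`).
#' @return A [sim_params()] object.
#' @export
#' @examples
#' p <- default_params("pruh", n_days = 35, seed = 42)
#' rowSums(p$routing)[1:3]
default_params <- function(profile = c("pruh", "dh"), ...) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    pruh = list(n_wards = 46L, n_gateways = 10L, rate = 177,
                site = "PRUH", base = 69),
    dh = list(n_wards = 63L, n_gateways = 14L, rate = 385,
              site = "DH", base = 82)
  )
  prof <- build_profile(spec$n_wards, spec$n_gateways, spec$rate, spec$site)
  coupling <- tibble::tibble(
    source = c("AE", "AE"),
    target = c("CDU1", "SUR01"),
    lag = c(1L, 1L),
    beta = c(100, -400),
    amplitude = c(-0.25, 0.5)
  )
  args <- utils::modifyList(
    list(
      wards = prof$wards, routing = prof$routing,
      daily_arrival_rate = spec$rate, coupling = coupling,
      perf_base = spec$base, site = spec$site
    ),
    list(...)
  )
  do.call(sim_params, args)
}

# Sample next wards for a block of patients sharing one routing row.
sample_targets <- function(targets, n, prob) {
  targets[sample.int(length(targets), n, replace = TRUE, prob = prob)]
}

# Routing row adjusted for a day: CDU-bound A&E mass and every ward's exit
# mass damped on weekends; coupled-edge mass scaled by the day's pressure.
adjust_row <- function(row, ward, weekend, z, params) {
  if (weekend) {
    row[.EXIT] <- row[.EXIT] * params$weekend_discharge_multiplier
    if (ward == "AE") {
      cdus <- params$wards$name[params$wards$role == "CDU"]
      row[cdus] <- row[cdus] * params$weekend_multiplier
    }
  }
  cp <- params$coupling[params$coupling$source == ward, ]
  if (nrow(cp) > 0) {
    row[cp$target] <- row[cp$target] * pmax(1 + cp$amplitude * z, 0.05)
  }
  row / sum(row)
}

#' Simulate a synthetic hospital
#'
#' Runs the generative model described in [sim_params()] and returns the
#' transfer log, the daily performance series and the planted ground
#' truth. Output is deterministic given the parameter set (including its
#' seed).
#'
#' @param params A [sim_params()] object, e.g. from [default_params()].
#' @return List with:
#'   * `records`: transfer records (as from [read_transfer_events()]);
#'   * `perf`: daily performance series (`date`, `site`,
#'     `performance_pct`, `arrivals`);
#'   * `truth`: list `core_edges` (routing support), `weekend_edges`,
#'     `coupled_edges`;
#'   * `params`: the input parameters.
#' @export
#' @examples
#' sim <- simulate_hospital(default_params("pruh", n_days = 14, seed = 1))
#' nrow(sim$records); head(sim$perf)
simulate_hospital <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  wards <- params$wards$name
  targets <- c(wards, .EXIT)
  days <- params$start_date + seq_len(params$n_days) - 1L
  weekend <- is_weekend(days)
  z <- rnorm(params$n_days)
  arrivals <- rpois(params$n_days,
                    params$daily_arrival_rate *
                      ifelse(weekend, params$weekend_multiplier, 1))
  n_pat <- sum(arrivals)
  pat_day <- rep.int(seq_len(params$n_days), arrivals)
  ae <- wards[params$wards$role == "AE"]

  # rotating pools of off-route targets (never A&E, never on the ward's
  # own routing support): each ward redraws its pool every 30 days at a
  # random phase, so ephemeral traffic recurs for a few weeks but does not
  # travel down the same edges month after month, and the rotation is not
  # aligned with the calendar windows the analysis bins on
  pool_phase <- setNames(sample(0:29, length(wards), replace = TRUE),
                         wards)
  pool_epoch <- function(w, day) (day + pool_phase[[w]]) %/% 30L + 1L
  n_epochs <- max(vapply(wards, pool_epoch, numeric(1),
                         day = params$n_days))
  pools <- lapply(setNames(wards, wards), function(w) {
    candidates <- setdiff(wards[params$routing[w, wards] == 0], c(w, ae))
    lapply(seq_len(n_epochs), function(e) {
      if (length(candidates) == 0) {
        return(character())
      }
      sample(candidates, min(params$ephemeral_pool_size,
                             length(candidates)))
    })
  })

  # one hop per hospital day: the transfer at step k happens k - 1 days
  # after arrival, so stays span days and weekend discharge damping thins
  # actual weekend discharges. Admissions still in hospital at the study
  # end are censored (their remaining moves are never observed).
  current <- rep(ae, n_pat)
  active <- rep(TRUE, n_pat)
  rec_pat <- rec_day <- integer(0)
  rec_src <- rec_tgt <- character(0)
  truncated <- 0L

  for (step in seq_len(params$max_hops)) {
    cur_day <- pat_day + step - 1L
    over <- active & cur_day > params$n_days
    active[over] <- FALSE # censored at the study boundary
    idx <- which(active)
    if (length(idx) == 0) break
    d_idx <- cur_day[idx]
    nxt <- character(length(idx))
    if (step == 1) {
      # all patients are at A&E; its row varies day by day with the
      # pressure z
      for (d in unique(d_idx)) {
        sel <- d_idx == d
        row <- adjust_row(params$routing[ae, ], ae, weekend[d], z[d],
                          params)
        nxt[sel] <- sample_targets(targets, sum(sel), row)
      }
    } else {
      key <- paste(current[idx], weekend[d_idx])
      for (k in unique(key)) {
        sel <- key == k
        w <- current[idx][sel][1]
        wk <- weekend[d_idx[sel][1]]
        zz <- 0 # pressure only modulates the A&E row (step 1 targets)
        row <- adjust_row(params$routing[w, ], w, wk, zz, params)
        nxt[sel] <- sample_targets(targets, sum(sel), row)
      }
    }
    # ephemeral off-route hops from the source ward's current pool
    eph <- runif(length(idx)) < params$ephemeral_rate
    if (any(eph)) {
      for (i in which(eph)) {
        w <- current[idx[i]]
        pool <- pools[[w]][[pool_epoch(w, d_idx[i])]]
        if (length(pool) > 0) nxt[i] <- sample(pool, 1)
      }
    }
    rec_pat <- c(rec_pat, idx)
    rec_day <- c(rec_day, d_idx)
    rec_src <- c(rec_src, current[idx])
    rec_tgt <- c(rec_tgt, nxt)
    done <- nxt == .EXIT
    active[idx[done]] <- FALSE
    current[idx[!done]] <- nxt[!done]
  }
  still <- which(active & pat_day + params$max_hops <= params$n_days)
  if (length(still) > 0) {
    truncated <- length(still)
    inform(sprintf(
      "simulate_hospital: %d admission(s) hit the %d-hop cap and were discharged",
      truncated, params$max_hops
    ))
    rec_pat <- c(rec_pat, still)
    rec_day <- c(rec_day, pat_day[still] + params$max_hops)
    rec_src <- c(rec_src, current[still])
    rec_tgt <- c(rec_tgt, rep(.EXIT, length(still)))
  }

  ord <- order(rec_pat, rec_day)
  rec_pat <- rec_pat[ord]
  rec_day <- rec_day[ord]
  rec_src <- rec_src[ord]
  rec_tgt <- rec_tgt[ord]
  # one move per patient per day, at a uniform minute of that day;
  # within-patient order follows from the distinct days
  minute <- floor(runif(length(rec_pat)) * 1440)
  ts <- as.POSIXct(format(days[rec_day]), tz = "UTC") + minute * 60

  records <- tibble::tibble(
    patient_id = sprintf("P%06d", rec_pat),
    timestamp = ts,
    site = params$site,
    source_ward = rec_src,
    target_ward = rec_tgt
  )
  records <- dplyr::arrange(records, .data$patient_id, .data$timestamp)

  # daily performance from (lagged) proportional flow on coupled edges
  total_by_day <- tabulate(rec_day, nbins = params$n_days)
  perf_val <- rep(params$perf_base, params$n_days) +
    rnorm(params$n_days, 0, params$perf_noise_sd)
  cp <- params$coupling
  for (i in seq_len(nrow(cp))) {
    on_edge <- rec_src == cp$source[i] & rec_tgt == cp$target[i]
    f <- tabulate(rec_day[on_edge], nbins = params$n_days) /
      pmax(total_by_day, 1)
    f_lagged <- rep(mean(f), params$n_days) # neutral fill before data start
    ok <- seq_len(params$n_days) > cp$lag[i]
    f_lagged[ok] <- f[seq_len(params$n_days)[ok] - cp$lag[i]]
    perf_val <- perf_val + cp$beta[i] * f_lagged
  }
  perf <- tibble::tibble(
    date = days, site = params$site,
    performance_pct = pmin(pmax(perf_val, 0), 100),
    arrivals = as.integer(arrivals)
  )

  support <- which(params$routing > 0, arr.ind = TRUE)
  core <- tibble::tibble(
    source = rownames(params$routing)[support[, 1]],
    target = colnames(params$routing)[support[, 2]]
  )
  cdus <- params$wards$name[params$wards$role == "CDU"]
  weekend_edges <- dplyr::bind_rows(
    tibble::tibble(source = ae, target = cdus),
    tibble::tibble(source = wards, target = .EXIT)
  )
  list(
    records = records,
    perf = perf,
    truth = list(
      core_edges = dplyr::arrange(core, .data$source, .data$target),
      weekend_edges = weekend_edges,
      coupled_edges = cp,
      n_truncated = truncated
    ),
    params = params
  )
}
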