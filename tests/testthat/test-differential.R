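perf_series <- function(values, site = "S",
                        start = as.Date("2024-01-01")) {
  tibble::tibble(
    date = start + seq_along(values) - 1, site = site,
    performance_pct = values, arrivals = 100L
  )
}

test_that("decile groups take the floor of 10% at each tail", {
  groups <- performance_groups(perf_series(seq(10, 100, length.out = 10)))
  expect_equal(as.vector(table(groups$group)), c(1, 8, 1))

  set.seed(1)
  g578 <- performance_groups(perf_series(runif(578, 40, 100)))
  expect_equal(sum(g578$group == "High"), 57)
  expect_equal(sum(g578$group == "Low"), 57)
  expect_equal(sum(g578$group == "Mid"), 464)

  expect_error(performance_groups(perf_series(1:9)), "at least 10")
})

test_that("boundary ties break by earlier date, deterministically", {
  g <- performance_groups(perf_series(rep(50, 20)))
  expect_equal(as.vector(table(g$group)), c(2, 16, 2))
  # earliest dates take the extreme groups in date order
  expect_equal(which(g$group == "High"), 1:2)
  expect_equal(which(g$group == "Low"), 3:4)
  g2 <- performance_groups(perf_series(rep(50, 20)))
  expect_identical(g$group, g2$group)
})

test_that("pooling lag shifts the contributing days", {
  # 5 days, one transfer per day on a distinct edge
  recs <- dplyr::bind_rows(lapply(1:5, function(d) {
    rec(paste0("p", d), sprintf("2024-01-%02d 08:00", d),
        "AE", paste0("W", d))
  }))
  lag0 <- pooled_network(recs, as.Date("2024-01-04"), lag = 0)
  expect_equal(lag0$edges$target, "W4")
  lag1 <- pooled_network(recs, as.Date("2024-01-04"), lag = 1)
  expect_equal(lag1$edges$target, "W3")
  # a lag pushing before the data start drops the day with a message
  expect_message(
    none <- pooled_network(recs, as.Date("2024-01-02"), lag = 3),
    "dropped"
  )
  expect_equal(nrow(none$edges), 0)
  # pooled weights are proportions
  pooled <- pooled_network(recs, as.Date(c("2024-01-02", "2024-01-03")))
  expect_equal(sum(pooled$edges$weight), 1)
})

test_that("differential edges sum to zero and flag only large deviations", {
  mk_prop <- function(df) flow_network(df, weight_mode = "proportion",
                                       site = "S")
  base <- tibble::tibble(
    source = paste0("A", 1:10), target = paste0("B", 1:10),
    weight = c(0.3, rep(0.7 / 9, 9))
  )
  shifted <- base
  shifted$weight <- c(0.3 - 0.27, rep(0.7 / 9, 9) + 0.03)
  dn <- differential_network(mk_prop(base), mk_prop(shifted))
  expect_equal(sum(dn$diffs$diff), 0, tolerance = 1e-12)
  expect_equal(nrow(dn$retained), 1)
  expect_equal(dn$retained$source, "A1")
  expect_equal(dn$retained$direction, "better")

  # identical networks: all zero, nothing retained
  same <- differential_network(mk_prop(base), mk_prop(base))
  expect_equal(same$sd, 0)
  expect_equal(nrow(same$retained), 0)
})

test_that("differential analysis is antisymmetric in best and worst", {
  sim <- sim60()
  groups <- performance_groups(sim$perf, sim$params$site)
  best <- pooled_network(sim$records, groups$date[groups$group == "High"],
                         site = sim$params$site, lag = 1)
  worst <- pooled_network(sim$records, groups$date[groups$group == "Low"],
                          site = sim$params$site, lag = 1)
  fwd <- differential_network(best, worst)
  rev <- differential_network(worst, best)
  merged <- dplyr::inner_join(fwd$diffs, rev$diffs,
                              by = c("source", "target"))
  expect_equal(merged$diff.x, -merged$diff.y)
  expect_equal(fwd$sd, rev$sd)
  expect_equal(nrow(fwd$retained), nrow(rev$retained))
  expect_equal(sum(fwd$diffs$diff), 0, tolerance = 1e-12)
})

test_that("mixed weight modes are rejected", {
  prop <- flow_network(tibble::tibble(source = "A", target = "B",
                                      weight = 1),
                       weight_mode = "proportion")
  cnt <- flow_network(tibble::tibble(source = "A", target = "B",
                                     weight = 3))
  expect_error(differential_network(prop, cnt), "proportion-mode")
})

test_that("planted lag-1 coupling dominates the lag sweep", {
  sim <- sim60()
  sweep <- suppressMessages(lag_sweep(sim$records, sim$perf,
                                      site = sim$params$site, max_lag = 7))
  expect_equal(nrow(sweep), 8)
  expect_equal(sweep$lag[which.max(sweep$sd)], 1)
  dn <- suppressMessages(lagged_differential(sim$records, sim$perf,
                                             site = sim$params$site,
                                             lag = 1))
  kept <- paste(dn$retained$source, dn$retained$target)
  planted <- paste(sim$truth$coupled_edges$source,
                   sim$truth$coupled_edges$target)
  expect_true(all(planted %in% kept))
  # signs match the planted direction: CDU flow with the best days,
  # surgical flow with the worst
  expect_equal(
    dn$retained$direction[match(planted, kept)],
    ifelse(sim$truth$coupled_edges$beta > 0, "better", "worse")
  )
})

test_that("permuted performance flattens the lag profile", {
  # needs the full study length: with very short series the pooled groups
  # are too small for the sd profile to stand clear of sampling noise
  sim <- suppressMessages(simulate_hospital(
    default_params("pruh", n_days = 152, seed = 1)
  ))
  perm <- sim$perf
  set.seed(7)
  perm$performance_pct <- sample(perm$performance_pct)
  sweep <- suppressMessages(lag_sweep(sim$records, perm,
                                      site = sim$params$site, max_lag = 7))
  real <- suppressMessages(lag_sweep(sim$records, sim$perf,
                                     site = sim$params$site, max_lag = 7))
  # the real profile has a pronounced lag-1 spike; the permuted profile
  # is flat by comparison (no lag stands out the way the true one does)
  peakedness <- function(s) max(s$sd) / stats::median(s$sd)
  expect_gt(peakedness(real), 2)
  expect_lt(peakedness(sweep), peakedness(real) / 2)
})
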