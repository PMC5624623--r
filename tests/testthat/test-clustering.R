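test_that("prevalence filtering is strict at the threshold", {
  # 200 days; edge RARE on 1 day (0.5% -> removed), edge EDGE2 on 2 days
  # (1% -> retained), edge BASE every day
  days <- as.Date("2024-01-01") + 0:199
  recs <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(seq_along(days), function(i) {
      rec(paste0("b", i), paste(days[i], "08:00"), "AE", "W1")
    })),
    rec("r1", paste(days[50], "09:00"), "AE", "RARE"),
    rec("e1", paste(days[60], "09:00"), "AE", "W2"),
    rec("e2", paste(days[61], "09:00"), "AE", "W2")
  )
  dem <- daily_edge_matrix(recs)
  expect_true("AE>W1" %in% colnames(dem$matrix))
  expect_true("AE>W2" %in% colnames(dem$matrix))
  expect_false("AE>RARE" %in% colnames(dem$matrix))
  expect_equal(dem$n_edges_removed, 1)
})

test_that("rows are proportions of each day's transfers", {
  sim <- sim60()
  dem <- suppressWarnings(daily_edge_matrix(sim$records,
                                            site = sim$params$site,
                                            min_prevalence = 0))
  # with no filtering, every non-empty day's row sums to exactly 1
  expect_true(all(abs(rowSums(dem$matrix) - 1) < 1e-9))
  expect_true(all(dem$matrix >= 0))
})

test_that("a constant matrix has no variance to decompose", {
  mat <- matrix(0.5, nrow = 10, ncol = 4,
                dimnames = list(format(as.Date("2024-01-01") + 0:9),
                                paste0("e", 1:4)))
  fit <- run_flow_pca(mat, 3)
  expect_true(all(fit$variance_fraction == 0))
})

test_that("a planted rank-1 matrix loads on one component", {
  set.seed(5)
  u <- rnorm(40)
  v <- runif(12)
  mat <- outer(u, v)
  dimnames(mat) <- list(format(as.Date("2024-01-01") + 0:39),
                        paste0("e", 1:12))
  fit <- run_flow_pca(mat, 5, scale = FALSE)
  expect_gt(fit$variance_fraction[1], 0.999)
})

test_that("retaining every component reconstructs the centred matrix", {
  set.seed(11)
  mat <- matrix(runif(30 * 8), 30, 8,
                dimnames = list(format(as.Date("2024-01-01") + 0:29),
                                paste0("e", 1:8)))
  fit <- run_flow_pca(mat, 8, scale = FALSE)
  centred <- scale(mat, center = TRUE, scale = FALSE)
  rebuilt <- fit$scores %*% t(fit$loadings)
  expect_equal(unname(rebuilt), unname(centred)[, ], tolerance = 1e-9)
  expect_equal(sum(fit$variance_fraction), 1, tolerance = 1e-9)
  # variance fractions are non-increasing
  expect_true(all(diff(fit$variance_fraction) <= 1e-12))
})

test_that("component signs follow the largest-loading convention", {
  set.seed(13)
  mat <- matrix(rnorm(50 * 6), 50, 6,
                dimnames = list(format(as.Date("2024-01-01") + 0:49),
                                paste0("e", 1:6)))
  fit <- run_flow_pca(mat, 4)
  for (j in seq_len(ncol(fit$loadings))) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("variance fractions are invariant to row shuffling", {
  set.seed(17)
  mat <- matrix(runif(40 * 6), 40, 6,
                dimnames = list(format(as.Date("2024-01-01") + 0:39),
                                paste0("e", 1:6)))
  f1 <- run_flow_pca(mat, 4)
  f2 <- run_flow_pca(mat[sample(40), ], 4)
  expect_equal(f1$variance_fraction, f2$variance_fraction,
               tolerance = 1e-9)
})

test_that("raising the prevalence threshold never adds edges", {
  sim <- sim60()
  kept <- vapply(c(0, 0.01, 0.05, 0.2), function(p) {
    ncol(suppressWarnings(daily_edge_matrix(sim$records,
                                            site = sim$params$site,
                                            min_prevalence = p))$matrix)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("a component equal to the weekend indicator correlates perfectly", {
  days <- as.Date("2024-01-01") + 0:27
  flag <- wardflow:::is_weekend(days)
  scores <- matrix(as.numeric(flag) - mean(flag), ncol = 1,
                   dimnames = list(format(days), "PC1"))
  fake <- structure(list(
    scores = scores,
    loadings = matrix(1, 1, 1, dimnames = list("e1", "PC1")),
    variance_fraction = c(PC1 = 1),
    labels = tibble::tibble(date = days, weekend = flag,
                            group = factor(rep(NA, 28),
                                           levels = c("Low", "Mid",
                                                      "High"))),
    scale = TRUE
  ), class = "flow_pca")
  assoc <- component_association(fake)
  expect_equal(abs(assoc$r_weekend), 1)
  expect_true(is.na(assoc$r_high_low)) # no labelled extreme days
})

test_that("random scores show no spurious association", {
  set.seed(23)
  days <- as.Date("2024-01-01") + 0:199
  flag <- wardflow:::is_weekend(days)
  rs <- replicate(200, abs(cor(rnorm(200), as.numeric(flag))))
  # 95% of permutation replicates fall below the normal critical value
  expect_gt(mean(rs < 1.96 / sqrt(200)), 0.9)
})

test_that("planted weekend modulation surfaces in a component", {
  sim <- sim60()
  dem <- suppressWarnings(daily_edge_matrix(sim$records,
                                            site = sim$params$site,
                                            perf = sim$perf))
  fit <- suppressMessages(run_flow_pca(dem, 15))
  assoc <- component_association(fit)
  expect_gte(max(abs(assoc$r_weekend)), 0.5)
})
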