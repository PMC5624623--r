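test_that("degree difference counts distinct neighbours, not weights", {
  net <- flow_network(tibble::tibble(
    source = c("A", "B", "C", "D", "D"),
    target = c("D", "D", "D", "E", "F"),
    weight = c(10, 1, 1, 5, 5)
  ), nodes = "ISOLATED")
  expect_equal(degree_difference(net, "D"), 1) # 3 in, 2 out
  expect_equal(degree_difference(net, "ISOLATED"), 0)
  expect_error(degree_difference(net, "NOPE"), "not present")
})

test_that("the exit node's degree difference equals its in-degree", {
  net <- build_network(sim60()$records)
  e <- net$edges
  in_deg <- length(unique(e$source[e$target == "EXIT"]))
  expect_gt(in_deg, 0)
  expect_equal(degree_difference(net, "EXIT"), in_deg)
})

test_that("degree roles split on the mean difference at the threshold", {
  mk <- function(edges) flow_network(edges, window = "m", site = "S")
  # node HUB: 12 in-neighbours, 0 out; node SRC: 0 in, 12 out
  spokes <- paste0("W", 1:12)
  n1 <- mk(tibble::tibble(source = c(spokes, rep("SRC", 12)),
                          target = c(rep("HUB", 12), spokes),
                          weight = 1))
  roles <- classify_degree_roles(list(n1), threshold = 10)
  expect_equal(as.character(roles$role[roles$node == "HUB"]), "in>>out")
  expect_equal(as.character(roles$role[roles$node == "SRC"]), "out>>in")
  expect_true(all(roles$role[roles$node %in% spokes] == "balanced"))

  # mean over windows: +15 then +5 -> mean 10 -> in>>out at threshold 10
  n2 <- mk(tibble::tibble(source = paste0("V", 1:15), target = "HUB",
                          weight = 1))
  n3 <- mk(tibble::tibble(source = paste0("V", 1:5), target = "HUB",
                          weight = 1))
  r2 <- classify_degree_roles(list(n2, n3), threshold = 10)
  expect_equal(as.character(r2$role[r2$node == "HUB"]), "in>>out")
})

test_that("the A&E distributor ward classifies as out>>in across seeds", {
  for (s in c(5, 6)) {
    sim <- suppressMessages(simulate_hospital(
      default_params("pruh", n_days = 60, seed = s)
    ))
    nets <- windowed_networks(sim$records, "month", site = "PRUH")
    roles <- classify_degree_roles(nets, threshold = 10)
    expect_equal(as.character(roles$role[roles$node == "AE"]), "out>>in")
    expect_equal(as.character(roles$role[roles$node == "EXIT"]), "in>>out")
  }
})

test_that("variability score matches its stated values", {
  expect_equal(weight_variability(c(5, 5, 5)), 0)
  expect_equal(weight_variability(c(1, 1, 8)), 1)
  expect_equal(weight_variability(c(2, 3, 5)), 5 / 14)
  # all-ones: maximum deviation degenerates to 0, balanced -> 0
  expect_equal(weight_variability(c(1, 1, 1)), 0)
})

test_that("variability score needs at least two positive integer weights", {
  expect_error(weight_variability(5), "at least two")
  expect_error(weight_variability(c(2, -1)), "positive")
  expect_error(weight_variability(c(0.5, 0.5)), "integer")
})

test_that("variability score equals the brute-force oracle exhaustively", {
  for (k in 2:4) {
    grid <- as.matrix(expand.grid(rep(list(1:6), k)))
    scores <- apply(grid, 1, weight_variability)
    oracle <- apply(grid, 1, variability_oracle)
    expect_equal(scores, oracle, tolerance = 1e-12)
    expect_true(all(scores >= 0 & scores <= 1))
  }
})

test_that("variability score is permutation invariant but not scale free", {
  set.seed(42)
  for (i in 1:20) {
    w <- sample(1:30, sample(2:6, 1), replace = TRUE)
    expect_equal(weight_variability(w), weight_variability(sample(w)))
  }
  # the maximal-deviation reference anchors edge weights at 1, so doubling
  # all weights changes the score
  expect_false(isTRUE(all.equal(weight_variability(c(2, 3, 5)),
                                weight_variability(c(4, 6, 10)))))
})

test_that("network variability converts proportions back to counts", {
  counts <- flow_network(tibble::tibble(
    source = c("A", "B", "C"), target = c("D", "D", "D"),
    weight = c(2, 3, 5)
  ), window = "m", site = "S")
  props <- build_network(
    dplyr::bind_rows(
      rec("p1", "2024-01-02 08:00", "A", "D"),
      rec("p2", "2024-01-02 08:00", "A", "D"),
      rec("p3", "2024-01-02 08:00", "B", "D"),
      rec("p4", "2024-01-02 08:00", "B", "D"),
      rec("p5", "2024-01-02 08:00", "B", "D"),
      rec("p6", "2024-01-02 08:00", "C", "D")
    ),
    weight_mode = "proportion"
  )
  v_counts <- network_variability(counts)
  expect_equal(v_counts$score[v_counts$node == "D" &
                                v_counts$side == "input"], 5 / 14)
  v_props <- network_variability(props)
  expect_equal(v_props$score[v_props$node == "D" &
                               v_props$side == "input"],
               weight_variability(c(2, 3, 1)))
  # fewer than two edges on a side -> NA
  expect_true(is.na(v_counts$score[v_counts$node == "A" &
                                     v_counts$side == "output"]))
})

test_that("path centrality is the fraction of paths through the node", {
  paths <- list(c("A", "B", "EXIT"), c("A", "C", "EXIT"), c("C", "EXIT"))
  expect_equal(path_centrality(paths, "C"), 2 / 3)
  expect_equal(path_centrality(paths, "A"), 2 / 3)
  expect_equal(path_centrality(paths, "EXIT"), 1)
  expect_equal(path_centrality(paths, "Z"), 0)
  expect_error(path_centrality(list(), "A"), "empty")
})
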