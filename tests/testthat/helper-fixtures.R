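# Shared fixtures, built in code.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Quick transfer-record constructor.
rec <- function(pid, when, src, tgt, site = "A") {
  tibble::tibble(
    patient_id = pid, timestamp = ts_utc(when), site = site,
    source_ward = src, target_ward = tgt
  )
}

# A two-patient toy log: p1 AE -> CDU -> EXIT, p2 AE -> W1.
toy_records <- function() {
  dplyr::bind_rows(
    rec("p1", "2024-01-02 08:00", "AE", "CDU"),
    rec("p1", "2024-01-02 17:30", "CDU", "EXIT"),
    rec("p2", "2024-01-02 09:15", "AE", "W1")
  )
}

# One cached mid-size simulation reused by several test files
# (two aligned calendar months, Jan-Feb 2024).
sim60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(simulate_hospital(
        default_params("pruh", n_days = 60, seed = 2024)
      ))
    }
    cache
  }
})

# Independent brute-force evaluation of the variability score: build the
# extremal weight vector explicitly and push it through the observed-
# deviation formula, rather than using any closed form.
variability_oracle <- function(w) {
  k <- length(w)
  wbar <- mean(w)
  dev <- function(v) sum(abs(v - mean(v))) / mean(v)
  obs <- dev(w)
  if (obs == 0) {
    return(0)
  }
  extreme <- c(rep(1, k - 1), sum(w) - (k - 1))
  obs / dev(extreme)
}

random_network <- function(n_nodes = 8, n_edges = 14, seed = 1) {
  set.seed(seed)
  nodes <- c(paste0("W", seq_len(n_nodes)), "EXIT")
  pairs <- expand.grid(source = nodes[seq_len(n_nodes)], target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample(nrow(pairs), n_edges), ]
  pick$weight <- sample(1:50, n_edges, replace = TRUE)
  flow_network(pick, window = "w", site = "A")
}
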