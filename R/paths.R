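# Per-admission ward sequences and their frequency/coverage statistics.

#' Reconstruct each admission's ward sequence
#'
#' Orders each patient's transfers by timestamp and chains them into a
#' single ward sequence from admission to exit. Each transfer's source ward
#' must equal the previous transfer's target ward; admissions still in
#' hospital at the end of the window simply produce sequences that do not
#' end in the exit node.
#'
#' @param records Transfer records.
#' @param strict Error on a broken chain (default), naming the patient and
#'   the offending timestamps; in lenient mode broken patients are skipped
#'   and reported.
#' @return Tibble with `patient_id`, `sequence` (list of character
#'   vectors), `path` (sequence joined by `">"`), `n_wards`, `single_site`
#'   (all the patient's transfers recorded at one site) and `discharged`
#'   (sequence ends at the exit node).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = "p1",
#'   timestamp = as.POSIXct(c("2024-01-01 08:00", "2024-01-01 17:30"),
#'                          tz = "UTC"),
#'   site = "A", source_ward = c("AE", "CDU"), target_ward = c("CDU", "EXIT")
#' )
#' reconstruct_paths(recs)$path
reconstruct_paths <- function(records, strict = TRUE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      patient_id = character(), sequence = list(), path = character(),
      n_wards = integer(), single_site = logical(), discharged = logical()
    ))
  }
  validate_transfer_records(records)
  records <- dplyr::arrange(records, .data$patient_id, .data$timestamp)
  by_patient <- split(records, records$patient_id)
  broken <- character()
  rows <- lapply(by_patient, function(r) {
    ok <- nrow(r) == 1 ||
      all(r$source_ward[-1] == r$target_ward[-nrow(r)])
    if (!ok) {
      at <- which(r$source_ward[-1] != r$target_ward[-nrow(r)])[1] + 1L
      broken[[length(broken) + 1]] <<- sprintf(
        "%s (break at %s -> %s, timestamps %s / %s)",
        r$patient_id[1], r$target_ward[at - 1], r$source_ward[at],
        format_timestamp(r$timestamp[at - 1]),
        format_timestamp(r$timestamp[at])
      )
      return(NULL)
    }
    seq <- c(r$source_ward[1], r$target_ward)
    tibble::tibble(
      patient_id = r$patient_id[1],
      sequence = list(seq),
      path = paste(seq, collapse = ">"),
      n_wards = length(seq),
      single_site = length(unique(r$site)) == 1,
      discharged = seq[length(seq)] == .EXIT
    )
  })
  if (length(broken) > 0) {
    msg <- sprintf("broken transfer chain for %d patient(s): %s",
                   length(broken), paste(head(broken, 5), collapse = "; "))
    if (strict) abort(msg)
    inform(paste0(msg, " - skipped"))
  }
  dplyr::bind_rows(rows)
}

#' Frequency of unique ward sequences
#'
#' Counts identical admission-to-exit ward sequences and ranks them by
#' descending count, ties broken lexicographically by the joined sequence.
#'
#' @param paths Tibble from [reconstruct_paths()].
#' @param single_site_only Keep only admissions whose entire visit was
#'   spent in a single site (default `TRUE`).
#' @param exclude_open Drop admissions still in hospital (sequences not
#'   ending at the exit node). Default `FALSE`: the censoring rule is a
#'   modelling choice, so both behaviours are available.
#' @return Tibble `rank`, `path`, `count`, `fraction`,
#'   `cumulative_fraction`.
#' @export
sequence_frequencies <- function(paths, single_site_only = TRUE,
                                 exclude_open = FALSE) {
  if (nrow(paths) == 0) abort("sequence_frequencies needs at least one path")
  if (single_site_only) paths <- paths[paths$single_site, ]
  if (exclude_open) paths <- paths[paths$discharged, ]
  if (nrow(paths) == 0) abort("no paths left after filtering")
  freq <- dplyr::count(paths, .data$path, name = "count")
  freq <- freq[order(-freq$count, freq$path), ]
  freq$rank <- seq_len(nrow(freq))
  freq$fraction <- freq$count / sum(freq$count)
  freq$cumulative_fraction <- cumsum(freq$fraction)
  freq[, c("rank", "path", "count", "fraction", "cumulative_fraction")]
}

#' Sequences needed to cover a target fraction of visits
#'
#' The smallest `k` such that the `k` most common ward sequences account
#' for at least `target_fraction` of all (filtered) visits.
#'
#' @param freqs Ranked frequency table from [sequence_frequencies()].
#' @param target_fraction Fraction in `(0, 1]`.
#' @return Integer `k`.
#' @export
#' @examples
#' freqs <- tibble::tibble(
#'   rank = 1:3, path = c("a", "b", "c"), count = c(50, 30, 20),
#'   fraction = c(.5, .3, .2), cumulative_fraction = c(.5, .8, 1)
#' )
#' top_k_coverage(freqs, 0.5) # 1
#' top_k_coverage(freqs, 0.6) # 2
top_k_coverage <- function(freqs, target_fraction) {
  if (nrow(freqs) == 0) abort("top_k_coverage needs a non-empty table")
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
    target_fraction > 1) {
    abort("target_fraction must lie in (0, 1]")
  }
  cum <- cumsum(freqs$count) / sum(freqs$count)
  as.integer(which(cum >= target_fraction - 1e-12)[1])
}

#' Rebuild a count-mode network from reconstructed paths
#'
#' Consistency oracle for [reconstruct_paths()]: converting each path back
#' into its constituent transfers and counting them must reproduce the
#' network built directly from the records.
#'
#' @param paths Tibble from [reconstruct_paths()].
#' @param window,site Metadata for the resulting network.
#' @return A count-mode [flow_network()].
#' @export
network_from_paths <- function(paths, window = NA_character_,
                               site = NA_character_) {
  edges <- dplyr::bind_rows(lapply(paths$sequence, function(s) {
    if (length(s) < 2) {
      return(NULL)
    }
    tibble::tibble(source = s[-length(s)], target = s[-1])
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    return(flow_network(
      tibble::tibble(source = character(), target = character(),
                     weight = numeric()),
      window = window, site = site
    ))
  }
  flow_network(dplyr::count(edges, .data$source, .data$target,
                            name = "weight"),
               window = window, site = site, weight_mode = "count")
}
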