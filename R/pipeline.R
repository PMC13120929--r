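# End-to-end experiment drivers: one run = pair statistics on a window and
# category level, significance filtering, direction selection, trajectory
# graph, MCL clusters and cluster demographics.

#' Run one trajectory experiment
#'
#' @param events a `ptra_events` data frame (already at the desired level).
#' @param cohort the `ptra_cohort`.
#' @param window a [time_range()].
#' @param min_patients minimum patients per trajectory edge.
#' @param policy a [matching_policy()].
#' @param n_resamples control redraws per pair.
#' @param rr_threshold,p_threshold see [significance_filter()]; `0` and `1`
#'   give the count-everything mode.
#' @param mcl an [mcl_params()].
#' @param direction_alpha level of the binomial direction test.
#' @return list of class `ptra_experiment`: `pairs` (full table),
#'   `significant` (filtered + direction-selected), `graph`, `clusters`
#'   (`NULL` for an empty graph), `cluster_stats`.
#' @export
run_experiment <- function(events, cohort, window, min_patients = 10L,
                           policy = matching_policy(),
                           n_resamples = 10000L, rr_threshold = 1,
                           p_threshold = 0.01, mcl = mcl_params(),
                           direction_alpha = 0.05) {
  pairs <- pair_statistics(events, cohort, window, policy = policy,
                           n_resamples = n_resamples)
  sig <- significance_filter(pairs, rr_threshold, p_threshold)
  count_all <- rr_threshold <= 0 && p_threshold >= 1
  if (!count_all) {
    # the counting mode keeps both directions so raw counts stay verifiable
    sig <- resolve_directions(sig, events, direction_alpha)
  }
  graph <- build_graph(sig, min_patients, cohort_size(cohort), window)
  clusters <- if (length(graph$nodes)) mcl_cluster(graph, mcl) else NULL
  stats <- if (!is.null(clusters)) {
    cluster_statistics(clusters, graph, cohort, events)
  } else NULL
  structure(list(pairs = pairs, significant = sig, graph = graph,
                 clusters = clusters, cluster_stats = stats,
                 window = window),
            class = "ptra_experiment")
}

#' The six-experiment full-cohort design
#'
#' Three lag windows ([study_windows()]) crossed with the two category levels
#' (main categories and subcategories), at a fixed minimum patient count per
#' trajectory.
#'
#' @param cohort a `ptra_cohort`.
#' @param min_patients minimum patients per edge (10 is about 1% of a
#'   985-patient cohort).
#' @param n_resamples control redraws per pair.
#' @param policy a [matching_policy()].
#' @param config an [event_config()].
#' @param windows named list of [time_range()]s.
#' @return Named list (`"<window>/<level>"`) of `ptra_experiment` results.
#' @export
run_full_design <- function(cohort, min_patients = 10L,
                            n_resamples = 10000L,
                            policy = matching_policy(),
                            config = event_config(),
                            windows = study_windows()) {
  out <- list()
  for (level in c("main", "sub")) {
    events <- extract_events(cohort, level = level, config = config)
    for (wn in names(windows)) {
      out[[paste(wn, level, sep = "/")]] <-
        run_experiment(events, cohort, windows[[wn]],
                       min_patients = min_patients, policy = policy,
                       n_resamples = n_resamples)
    }
  }
  out
}

#' Count-everything runs for the small-cohort design
#'
#' Disease-activity events after the index treatment, evaluated over three
#' observation horizons with the RR and p filters disabled (thresholds 0 and
#' 1) and a minimum patient count of 1, so that the resulting graph carries
#' every observed trajectory for count verification.
#'
#' @param cohort a `ptra_cohort` in which patients carry a CLAD episode.
#' @param horizons_days numeric vector of observation horizons; `NA` means
#'   full study duration (computed from the longest follow-up).
#' @param n_resamples control redraws per pair.
#' @param policy a [matching_policy()]; the small pools usually require
#'   `with_replacement = TRUE`.
#' @param infections optional infections table, see [extract_clad_events()].
#' @return Named list of `ptra_experiment` results keyed by horizon.
#' @export
run_clad_design <- function(cohort, horizons_days = c(365, 730, NA),
                            n_resamples = 1000L,
                            policy = matching_policy(with_replacement = TRUE),
                            infections = NULL) {
  fu <- as.numeric(max(cohort$visits$date) - min(cohort$visits$date)) + 1
  out <- list()
  for (h in horizons_days) {
    hi <- if (is.na(h)) fu else h
    events <- extract_clad_events(cohort, horizon_days = hi,
                                  infections = infections)
    key <- if (is.na(h)) "full" else sprintf("%dd", as.integer(h))
    out[[key]] <- run_experiment(
      events, cohort, time_range(0L, as.integer(hi) + 1L),
      min_patients = 1L, policy = policy, n_resamples = n_resamples,
      rr_threshold = 0, p_threshold = 1
    )
  }
  out
}
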