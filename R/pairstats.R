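# Relative risk of ordered event pairs against age/sex-matched resampled
# controls. For a pair A -> B and lag window [lo, hi) days:
#   rate_exposed   = p_AB / (p_AB + p_AnotB)         over patients with A,
#                    anchored at each patient's first A
#   rate_unexposed = p_notA_B / (p_notA_B + p_notA_notB) over an equal number
#                    of never-A patients matched on sex and age at anchor
#   RR             = rate_exposed / rate_unexposed
# Control sets are redrawn n_resamples times; the empirical p-value is the
# add-one fraction of resamples with RR <= 1.

#' Lag window for ordered event pairs
#'
#' Half-open interval in days: B counts for a pair when
#' `date(B) - anchor(A)` lies in `[lo, hi)`.
#'
#' @param lo,hi window bounds in days, `0 <= lo < hi`.
#' @return list of class `ptra_window`.
#' @export
time_range <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(lo >= 0L, hi > lo)
  structure(list(lo = lo, hi = hi), class = "ptra_window")
}

#' The three study lag windows
#'
#' `[0-1 y]`, `[0-2 y]` and the long-term `[1-5 y]` window (which excludes
#' pairs closer than one year).
#'
#' @return named list of [time_range()] objects.
#' @export
study_windows <- function() {
  list("0-1y" = time_range(0L, 365L),
       "0-2y" = time_range(0L, 730L),
       "1-5y" = time_range(365L, 1826L))
}

#' Matching policy for control resampling
#'
#' @param age_tolerance_years maximum |age difference| at the anchor between a
#'   case and its control, in years.
#' @param match_sex require controls of the same sex as their case.
#' @param with_replacement allow the same control patient to serve several
#'   cases within one resample.
#' @param relax_on_exhaustion when a case's candidate pool at the nominal
#'   tolerance is used up, fall back to widened age bands (2x, 4x tolerance)
#'   and finally drop the age constraint; sex matching is never relaxed.
#' @return list of class `ptra_matching_policy`.
#' @export
matching_policy <- function(age_tolerance_years = 5, match_sex = TRUE,
                            with_replacement = FALSE,
                            relax_on_exhaustion = TRUE) {
  stopifnot(age_tolerance_years >= 0)
  structure(list(
    age_tolerance_years = age_tolerance_years,
    match_sex = isTRUE(match_sex),
    with_replacement = isTRUE(with_replacement),
    relax_on_exhaustion = isTRUE(relax_on_exhaustion)
  ), class = "ptra_matching_policy")
}

# --- internal event index ---------------------------------------------------

# Precomputed per-cohort structures shared across pairs: integer dates of
# birth / first / last visit per patient and, per event label, a CSR layout of
# sorted event dates plus the first-occurrence anchor per patient.
event_index <- function(events, cohort) {
  ids <- cohort$patients$patient_id
  n <- length(ids)
  birth <- as.integer(cohort$patients$birth_date)
  fv <- as.integer(tapply(as.integer(cohort$visits$date),
                          factor(cohort$visits$patient_id, levels = ids), min))
  lv <- as.integer(tapply(as.integer(cohort$visits$date),
                          factor(cohort$visits$patient_id, levels = ids), max))
  fv[is.na(fv)] <- birth[is.na(fv)]
  lv[is.na(lv)] <- birth[is.na(lv)]
  pat_f <- factor(events$patient_id, levels = ids)
  date_i <- as.integer(events$date)
  ord <- order(as.integer(pat_f), date_i)
  lab_sorted <- events$label[ord]
  csr <- lapply(split(seq_along(ord), lab_sorted), function(ii) {
    p <- as.integer(pat_f)[ord][ii]
    d <- date_i[ord][ii]
    counts <- tabulate(p, nbins = n)
    list(dates = d, offsets = c(0L, cumsum(counts)), pat = p)
  })
  list(ids = ids, n = n, birth = birth, fv = fv, lv = lv,
       sex = cohort$patients$sex, csr = csr,
       labels = names(csr))
}

label_csr <- function(index, label) {
  csr <- index$csr[[label]]
  if (is.null(csr)) {
    list(dates = integer(0), offsets = rep(0L, index$n + 1L),
         pat = integer(0))
  } else csr
}

# exposed cases for label a: patient index + integer anchor (first occurrence)
exposed_idx <- function(index, a) {
  csr <- label_csr(index, a)
  has <- which(diff(csr$offsets) > 0L)
  anchors <- csr$dates[csr$offsets[has] + 1L]
  list(pat = has, anchor = anchors)
}

# Candidate pools per case, ordered by relaxation tier. A candidate must (a)
# match on sex, (b) have an age window within the tier's tolerance of the
# case's anchor age, and (c) — when an observation window is supplied — remain
# under observation after its age-aligned pseudo-anchor for at least the
# case's own post-anchor span, truncated at the window end. Without (c), the
# shorter follow-up of never-exposed patients deflates the control outcome
# rate and inflates RR under the null.
build_candidates <- function(index, exposed, policy, window = NULL) {
  csr_has <- exposed$pat
  pool <- setdiff(seq_len(index$n), csr_has)
  if (!length(pool)) return(NULL)
  tol <- policy$age_tolerance_years
  tols <- if (policy$relax_on_exhaustion) c(tol, 2 * tol, 4 * tol, Inf) else tol
  age_f <- (index$fv[pool] - index$birth[pool]) / 365.25
  age_l <- (index$lv[pool] - index$birth[pool]) / 365.25
  pool_sex <- index$sex[pool]
  n_cases <- length(exposed$pat)
  cand <- vector("list", n_cases)
  tier_ends <- vector("list", n_cases)
  age_days <- exposed$anchor - index$birth[exposed$pat]
  age_yrs <- age_days / 365.25
  case_sex <- index$sex[exposed$pat]
  case_span <- index$lv[exposed$pat] - exposed$anchor
  for (i in seq_len(n_cases)) {
    ok <- if (policy$match_sex) pool_sex == case_sex[i] else
      rep(TRUE, length(pool))
    if (!is.null(window)) {
      anchor_c <- pmin(pmax(index$birth[pool] + round(age_days[i]),
                            index$fv[pool]), index$lv[pool])
      need <- min(case_span[i], window$hi)
      ok <- ok & (index$lv[pool] - anchor_c) >= need
    }
    d <- pmax(0, age_f - age_yrs[i], age_yrs[i] - age_l)
    d[!ok] <- Inf
    tier <- rep(NA_integer_, length(pool))
    for (t in rev(seq_along(tols))) tier[d <= tols[t]] <- t
    sel <- which(!is.na(tier))
    sel <- sel[order(tier[sel])]
    cand[[i]] <- pool[sel]
    tier_ends[[i]] <- cumsum(tabulate(tier[sel], nbins = length(tols)))
  }
  list(cand = cand, tier_ends = tier_ends,
       anchor_age_days = as.integer(round(age_days)), pool = pool)
}

check_pool_feasible <- function(index, exposed, bc, policy) {
  if (is.null(bc)) {
    stop("matching error: no unexposed patients available", call. = FALSE)
  }
  if (any(lengths(bc$cand) == 0L)) {
    i <- which(lengths(bc$cand) == 0L)[1L]
    stop(sprintf(
      "matching error: no eligible control for case %s (sex %s, age %.1f)",
      index$ids[exposed$pat[i]], index$sex[exposed$pat[i]],
      bc$anchor_age_days[i] / 365.25), call. = FALSE)
  }
  if (!policy$with_replacement) {
    if (policy$match_sex) {
      for (s in unique(index$sex[exposed$pat])) {
        n_c <- sum(index$sex[exposed$pat] == s)
        n_p <- sum(index$sex[bc$pool] == s)
        if (n_p < n_c) {
          stop(sprintf(
            "matching error: control pool exhausted for sex %s (%d cases, %d candidates); consider with_replacement",
            s, n_c, n_p), call. = FALSE)
        }
      }
    } else if (length(bc$pool) < length(exposed$pat)) {
      stop("matching error: control pool smaller than the exposed set",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# --- spec-level operations --------------------------------------------------

#' Exposed set of an event label
#'
#' One row per patient with at least one occurrence of `label`, anchored at
#' the patient's first occurrence.
#'
#' @param events a `ptra_events` data frame.
#' @param label event label (at the level the events were extracted).
#' @return data frame (`patient_id`, `anchor` `Date`).
#' @export
exposed_set <- function(events, label) {
  ev <- events[events$label == label, , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(patient_id = character(0),
                      anchor = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  first <- tapply(as.integer(ev$date), ev$patient_id, min)
  data.frame(patient_id = names(first),
             anchor = as.Date(as.integer(first), origin = "1970-01-01"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Outcome rate among exposed patients
#'
#' Counts exposed patients with at least one `b` event whose lag from the
#' anchor falls in the half-open window, and returns the exposed outcome rate
#' `p_AB / (p_AB + p_AnotB)`.
#'
#' @param exposed data frame from [exposed_set()].
#' @param events a `ptra_events` data frame.
#' @param b outcome event label.
#' @param window a [time_range()].
#' @return list with `p_AB`, `p_AnotB`, `rate`.
#' @export
outcome_rate_exposed <- function(exposed, events, b, window) {
  if (!nrow(exposed)) {
    stop("outcome_rate_exposed(): empty exposed set", call. = FALSE)
  }
  ev_b <- events[events$label == b, , drop = FALSE]
  b_by_pat <- split(as.integer(ev_b$date), ev_b$patient_id)
  anchor <- as.integer(exposed$anchor)
  hit <- vapply(seq_len(nrow(exposed)), function(i) {
    d <- b_by_pat[[exposed$patient_id[i]]]
    !is.null(d) && any(d >= anchor[i] + window$lo & d < anchor[i] + window$hi)
  }, logical(1))
  p_ab <- sum(hit)
  list(p_AB = p_ab, p_AnotB = nrow(exposed) - p_ab,
       rate = p_ab / nrow(exposed))
}

#' Relative risk from a 2x2 pair-count table
#'
#' `RR = (p_AB / (p_AB + p_AnotB)) / (p_notA_B / (p_notA_B + p_notA_notB))`.
#' A zero unexposed rate with a positive exposed rate yields `Inf` (treated as
#' RR > 1 by the resampling tally); a zero exposed rate yields 0.
#'
#' @param p_AB,p_AnotB,p_notA_B,p_notA_notB the four patient counts.
#' @return Relative risk (may be `Inf` or `NaN` when both rates are zero).
#' @export
relative_risk <- function(p_AB, p_AnotB, p_notA_B, p_notA_notB) {
  stopifnot(p_AB >= 0, p_AnotB >= 0, p_notA_B >= 0, p_notA_notB >= 0)
  r1 <- p_AB / (p_AB + p_AnotB)
  r0 <- p_notA_B / (p_notA_B + p_notA_notB)
  if (r1 == 0) return(if (r0 == 0) NaN else 0)
  if (r0 == 0) return(Inf)
  r1 / r0
}

#' Draw one set of age/sex-matched controls
#'
#' Selects, for each exposed case, one never-`a` patient matched on sex and on
#' age at the case's anchor (within the policy tolerance, with tiered
#' relaxation). The control's pseudo-anchor is the calendar date at which the
#' control reaches the case's anchor age, clamped into the control's
#' follow-up.
#'
#' @param cohort a `ptra_cohort`.
#' @param exposed data frame from [exposed_set()].
#' @param a exposure label (controls must have no `a` event anywhere).
#' @param events a `ptra_events` data frame.
#' @param policy a [matching_policy()].
#' @param window optional [time_range()]; when given, eligibility additionally
#'   requires each control to remain under observation after its pseudo-anchor
#'   for the case's own post-anchor span truncated at the window end, so that
#'   the two arms observe comparable windows.
#' @return data frame (`case_id`, `patient_id`, `anchor`): one control per
#'   case. Errors when a pool is exhausted even after relaxation.
#' @export
sample_matched_controls <- function(cohort, exposed, a, events,
                                    policy = matching_policy(),
                                    window = NULL) {
  index <- event_index(events, cohort)
  exp_i <- list(pat = match(exposed$patient_id, index$ids),
                anchor = as.integer(exposed$anchor))
  bc <- build_candidates(index, exp_i, policy, window)
  check_pool_feasible(index, exp_i, bc, policy)
  empty_csr <- list(dates = integer(0), offsets = rep(0L, index$n + 1L))
  res <- pair_resample(bc$cand, bc$tier_ends, bc$anchor_age_days,
                       index$birth, index$fv, index$lv, empty_csr$dates,
                       empty_csr$offsets, 0L, 1L, 1L,
                       policy$with_replacement)
  if (isTRUE(res$exhausted)) {
    stop(sprintf(
      "matching error: candidate pool exhausted at case %s even after relaxation",
      exposed$patient_id[res$case]), call. = FALSE)
  }
  ctrl <- res$first_controls
  anchor <- pmin(pmax(index$birth[ctrl] + bc$anchor_age_days,
                      index$fv[ctrl]), index$lv[ctrl])
  data.frame(case_id = exposed$patient_id,
             patient_id = index$ids[ctrl],
             anchor = as.Date(anchor, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

# core per-pair computation on a prebuilt index; returns NULL if a has no
# exposed patients
pair_core <- function(index, a, b, window, policy, n_resamples) {
  exposed <- exposed_idx(index, a)
  if (!length(exposed$pat)) return(NULL)
  n_e <- length(exposed$pat)
  csr_b <- label_csr(index, b)
  hit_a <- window_hit(csr_b$dates, csr_b$offsets, exposed$pat,
                      exposed$anchor + window$lo, exposed$anchor + window$hi)
  p_ab <- sum(hit_a)
  bc <- build_candidates(index, exposed, policy, window)
  check_pool_feasible(index, exposed, bc, policy)
  res <- pair_resample(bc$cand, bc$tier_ends, bc$anchor_age_days,
                       index$birth, index$fv, index$lv, csr_b$dates,
                       csr_b$offsets, window$lo, window$hi,
                       as.integer(n_resamples), policy$with_replacement)
  if (isTRUE(res$exhausted)) {
    stop(sprintf(
      "matching error: candidate pool exhausted at case %s even after relaxation",
      index$ids[exposed$pat[res$case]]), call. = FALSE)
  }
  k <- res$k
  if (p_ab == 0L) {
    rr_mean <- 0; rr_sd <- 0; n_le1 <- n_resamples; frac_inf <- 0
  } else {
    finite <- k > 0L
    rr_fin <- p_ab / k[finite]
    rr_mean <- if (any(finite)) mean(rr_fin) else Inf
    rr_sd <- if (sum(finite) > 1L) sd(rr_fin) else 0
    frac_inf <- mean(!finite)
    n_le1 <- sum(k >= p_ab)
  }
  list(
    event_a = a, event_b = b,
    window_lo_days = window$lo, window_hi_days = window$hi,
    p_AB = p_ab, p_AnotB = n_e - p_ab,
    p_notA_B = k[1L], p_notA_notB = n_e - k[1L],
    n_exposed = n_e, n_patients = p_ab,
    rr_mean = rr_mean, rr_sd = rr_sd,
    p_empirical = (1 + n_le1) / (n_resamples + 1),
    n_resamples = as.integer(n_resamples),
    frac_rr_infinite = frac_inf,
    patients_ab = index$ids[exposed$pat[hit_a]]
  )
}

#' Empirical matched-control test for one ordered event pair
#'
#' Recomputes the relative risk of `a -> b` under `n_resamples` independent
#' matched control sets and reports the resampling mean and standard deviation
#' of the RR together with the add-one empirical p-value
#' `(1 + #\{RR <= 1\}) / (n_resamples + 1)`. Infinite RRs (no control
#' outcome) count as RR > 1 in the tally and are excluded from the mean, with
#' their fraction reported.
#'
#' @param events a `ptra_events` data frame.
#' @param cohort the `ptra_cohort` the events came from.
#' @param a,b exposure and outcome labels.
#' @param window a [time_range()].
#' @param policy a [matching_policy()].
#' @param n_resamples number of control redraws (>= 1).
#' @return list of class `ptra_pair_result`; `counts` holds the 2x2 table of
#'   the first resample, `patients_ab` the ids of exposed patients with the
#'   outcome in window.
#' @export
empirical_pair_test <- function(events, cohort, a, b, window,
                                policy = matching_policy(),
                                n_resamples = 10000L) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  index <- event_index(events, cohort)
  res <- pair_core(index, a, b, window, policy, n_resamples)
  if (is.null(res)) {
    stop(sprintf("no patient is exposed to '%s'", a), call. = FALSE)
  }
  structure(res, class = "ptra_pair_result")
}

#' @export
print.ptra_pair_result <- function(x, ...) {
  cat(sprintf(
    "<pair %s -> %s, window [%d, %d) d>\n  n=%d of %d exposed, RR %.3f (sd %.3f), p=%.4g (%d resamples)\n",
    x$event_a, x$event_b, x$window_lo_days, x$window_hi_days, x$n_patients,
    x$n_exposed, x$rr_mean, x$rr_sd, x$p_empirical, x$n_resamples))
  invisible(x)
}

#' Relative-risk table for all ordered event pairs
#'
#' Runs [empirical_pair_test()] machinery over every ordered pair of distinct
#' labels with a nonempty exposed set, sharing the cohort index. Pairs whose
#' matched-control pool is infeasible under the policy (exposure prevalence
#' above 50% without replacement) are reported with `matched = FALSE` and `NA`
#' statistics rather than failing the whole table.
#'
#' @inheritParams empirical_pair_test
#' @param labels labels to cross (default: all labels present in `events`).
#' @param min_exposed skip pairs whose exposure count is below this (default 1).
#' @return data frame with one row per ordered pair: the 2x2 counts of the
#'   first resample, `n_patients`, `pct_of_cohort`, `rr_mean`, `rr_sd`,
#'   `p_empirical`, `n_resamples`, `frac_rr_infinite`, `matched`, and a
#'   `patients` list-column of exposed-with-outcome patient ids.
#' @export
pair_statistics <- function(events, cohort, window,
                            policy = matching_policy(),
                            n_resamples = 10000L, labels = NULL,
                            min_exposed = 1L) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  index <- event_index(events, cohort)
  if (is.null(labels)) labels <- index$labels
  n_coh <- index$n
  rows <- list()
  for (a in labels) {
    n_e <- sum(diff(label_csr(index, a)$offsets) > 0L)
    if (n_e < min_exposed || n_e == 0L) next
    for (b in setdiff(labels, a)) {
      res <- tryCatch(pair_core(index, a, b, window, policy, n_resamples),
                      error = function(e) {
                        if (grepl("matching error", conditionMessage(e))) {
                          NA
                        } else stop(e)
                      })
      if (is.null(res)) next
      if (identical(res, NA)) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_a = a, event_b = b, window_lo_days = window$lo,
          window_hi_days = window$hi, p_AB = NA_integer_,
          p_AnotB = NA_integer_, p_notA_B = NA_integer_,
          p_notA_notB = NA_integer_, n_exposed = n_e,
          n_patients = NA_integer_, pct_of_cohort = NA_real_,
          rr_mean = NA_real_, rr_sd = NA_real_, p_empirical = NA_real_,
          n_resamples = as.integer(n_resamples), frac_rr_infinite = NA_real_,
          matched = FALSE, stringsAsFactors = FALSE)
        rows[[length(rows)]]$patients <- list(character(0))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          event_a = res$event_a, event_b = res$event_b,
          window_lo_days = res$window_lo_days,
          window_hi_days = res$window_hi_days, p_AB = res$p_AB,
          p_AnotB = res$p_AnotB, p_notA_B = res$p_notA_B,
          p_notA_notB = res$p_notA_notB, n_exposed = res$n_exposed,
          n_patients = res$n_patients,
          pct_of_cohort = 100 * res$n_patients / n_coh,
          rr_mean = res$rr_mean, rr_sd = res$rr_sd,
          p_empirical = res$p_empirical, n_resamples = res$n_resamples,
          frac_rr_infinite = res$frac_rr_infinite, matched = TRUE,
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$patients <- list(res$patients_ab)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  out
}

#' Filter pair results on relative risk and empirical significance
#'
#' Retains pairs with `rr_mean > rr_threshold` and
#' `p_empirical < p_threshold`. Setting the thresholds to 0 and 1 disables
#' both filters ("count everything" mode) and returns the input unchanged.
#' Unmatched pairs (`matched = FALSE`) are dropped whenever any filter is
#' active.
#'
#' @param results data frame from [pair_statistics()].
#' @param rr_threshold minimum RR, exclusive (default 1).
#' @param p_threshold maximum empirical p, exclusive (default 0.01).
#' @return The filtered data frame.
#' @export
significance_filter <- function(results, rr_threshold = 1,
                                p_threshold = 0.01) {
  if (rr_threshold <= 0 && p_threshold >= 1) return(results)
  keep <- !is.na(results$rr_mean) & !is.na(results$p_empirical) &
    results$rr_mean > rr_threshold & results$p_empirical < p_threshold
  results[keep, , drop = FALSE]
}

#' Select the dominant direction of a reciprocal pair
#'
#' When both `a -> b` and `b -> a` exceed RR 1, an exact two-sided binomial
#' test on the per-patient temporal order (first `a` vs first `b`; ties
#' dropped) selects the more prominent direction at level `alpha`. A
#' non-significant test falls back to the direction with the larger RR,
#' flagged as unresolved. When the reverse RR is at most 1 the forward pair is
#' kept without a test.
#'
#' @param forward,reverse single rows of a [pair_statistics()] table (or
#'   `ptra_pair_result` lists) describing `(a, b)` and `(b, a)` on the same
#'   window.
#' @param events the `ptra_events` the results came from.
#' @param alpha significance level of the binomial test.
#' @return list: `kept` (`"forward"`/`"reverse"`), `p_value`, `n_forward`,
#'   `n_reverse`, `resolved` (binomial test decisive), `tested`.
#' @export
select_direction <- function(forward, reverse, events, alpha = 0.05) {
  if (!identical(forward$event_a, reverse$event_b) ||
      !identical(forward$event_b, reverse$event_a)) {
    stop("select_direction(): forward and reverse do not describe mirrored pairs",
         call. = FALSE)
  }
  if (!identical(forward$window_lo_days, reverse$window_lo_days) ||
      !identical(forward$window_hi_days, reverse$window_hi_days)) {
    stop("select_direction(): forward and reverse use different windows",
         call. = FALSE)
  }
  if (is.na(reverse$rr_mean) || reverse$rr_mean <= 1) {
    return(list(kept = "forward", p_value = NA_real_, n_forward = NA_integer_,
                n_reverse = NA_integer_, resolved = TRUE, tested = FALSE))
  }
  if (is.na(forward$rr_mean) || forward$rr_mean <= 1) {
    return(list(kept = "reverse", p_value = NA_real_, n_forward = NA_integer_,
                n_reverse = NA_integer_, resolved = TRUE, tested = FALSE))
  }
  fa <- exposed_set(events, forward$event_a)
  fb <- exposed_set(events, forward$event_b)
  both <- merge(fa, fb, by = "patient_id", suffixes = c("_a", "_b"))
  n_f <- sum(both$anchor_a < both$anchor_b)
  n_r <- sum(both$anchor_b < both$anchor_a)
  if (n_f + n_r == 0L) {
    kept <- if (forward$rr_mean >= reverse$rr_mean) "forward" else "reverse"
    return(list(kept = kept, p_value = NA_real_, n_forward = 0L,
                n_reverse = 0L, resolved = FALSE, tested = TRUE))
  }
  p <- binom.test(n_f, n_f + n_r, p = 0.5,
                  alternative = "two.sided")$p.value
  if (p < alpha) {
    kept <- if (n_f > n_r) "forward" else "reverse"
    resolved <- TRUE
  } else {
    kept <- if (forward$rr_mean >= reverse$rr_mean) "forward" else "reverse"
    resolved <- FALSE
  }
  list(kept = kept, p_value = p, n_forward = n_f, n_reverse = n_r,
       resolved = resolved, tested = TRUE)
}

#' Resolve reciprocal pairs across a whole results table
#'
#' Applies [select_direction()] to every unordered pair present in both
#' directions with RR above 1 in both, dropping the losing row. Adds columns
#' `direction_p` and `direction_resolved`.
#'
#' @param results data frame from [pair_statistics()] (usually already passed
#'   through [significance_filter()]).
#' @param events the `ptra_events` the results came from.
#' @param alpha significance level of the binomial test.
#' @return The pruned, annotated data frame.
#' @export
resolve_directions <- function(results, events, alpha = 0.05) {
  if (!nrow(results)) {
    results$direction_p <- numeric(0)
    results$direction_resolved <- logical(0)
    return(results)
  }
  results$direction_p <- NA_real_
  results$direction_resolved <- TRUE
  drop <- rep(FALSE, nrow(results))
  key <- paste(results$event_a, results$event_b, sep = "\r")
  rev_key <- paste(results$event_b, results$event_a, sep = "\r")
  for (i in seq_len(nrow(results))) {
    if (drop[i]) next
    j <- which(key == rev_key[i])
    if (!length(j) || j[1L] <= i) next
    j <- j[1L]
    if (is.na(results$rr_mean[i]) || is.na(results$rr_mean[j]) ||
        results$rr_mean[i] <= 1 || results$rr_mean[j] <= 1) next
    sel <- select_direction(results[i, ], results[j, ], events, alpha)
    loser <- if (sel$kept == "forward") j else i
    winner <- if (sel$kept == "forward") i else j
    drop[loser] <- TRUE
    results$direction_p[winner] <- sel$p_value
    results$direction_resolved[winner] <- sel$resolved
  }
  out <- results[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
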