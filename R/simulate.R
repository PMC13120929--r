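# Synthetic longitudinal-cohort generator. Event streams are thinned Poisson
# processes with per-label baseline hazards and optional planted lagged
# dependencies (a trigger event multiplies the outcome hazard inside a lag
# window). EDSS/FSS visit series are synthesized backwards from the intended
# confirmed-change events (one step at the event visit, held afterwards) so
# the extractor's confirmation rule is exercised rather than bypassed.

#' A planted lagged dependency between two event labels
#'
#' Inside `[lag_lo_days, lag_hi_days)` after every occurrence of `trigger`,
#' the hazard of `outcome` is multiplied by `hazard_ratio`. This provides the
#' simulator's ground truth for relative-risk recovery tests.
#'
#' @param trigger,outcome event labels (see [default_hazards()] for the menu).
#' @param hazard_ratio multiplicative hazard boost (> 0).
#' @param lag_lo_days,lag_hi_days lag window bounds in days.
#' @return list of class `ptra_planted_effect`.
#' @export
planted_effect <- function(trigger, outcome, hazard_ratio,
                           lag_lo_days = 0L, lag_hi_days = 365L) {
  stopifnot(hazard_ratio > 0, lag_lo_days >= 0, lag_hi_days > lag_lo_days)
  structure(list(trigger = trigger, outcome = outcome,
                 hazard_ratio = hazard_ratio,
                 lag_lo_days = as.integer(lag_lo_days),
                 lag_hi_days = as.integer(lag_hi_days)),
            class = "ptra_planted_effect")
}

#' Default per-label baseline hazards (events per patient-year)
#'
#' Sized so that a default-size cohort produces an event volume of the order
#' of ten events per patient over a typical follow-up, split across relapses,
#' regional MRI activity, confirmed EDSS/FSS changes and DMT switches.
#'
#' @return Named numeric vector.
#' @export
default_hazards <- function() {
  c("Relapse" = 0.30, "MRI BR" = 0.15, "MRI SC" = 0.07,
    "+EDSS" = 0.20, "-EDSS" = 0.10,
    "+Pyramidal" = 0.05, "+Sensory" = 0.05, "+Mental" = 0.05,
    "+Ambulation" = 0.05, "+Bowel/Bladder" = 0.04, "+Cerebellar" = 0.03,
    "+Brainstem" = 0.03, "+Visual" = 0.03,
    "-Pyramidal" = 0.03, "-Sensory" = 0.03, "-Mental" = 0.03,
    "-Ambulation" = 0.03, "-Bowel/Bladder" = 0.02, "-Cerebellar" = 0.02,
    "-Brainstem" = 0.02, "-Visual" = 0.02,
    "IFN/GLAT" = 0.06, "CD20" = 0.02, "OTH" = 0.04, "TRF" = 0.01,
    "DMF" = 0.02, "FNG" = 0.02, "NTZ" = 0.02, "ALZ" = 0.01)
}

#' Event labels the generator can materialize
#'
#' Relapses, regional MRI activity, confirmed EDSS/FSS changes and DMT-group
#' switches — the streams that have a home in the cohort tables.
#'
#' @return Character vector of valid `baseline_hazards` names.
#' @export
simulated_labels <- function() {
  c("Relapse", "MRI BR", "MRI SC", "+EDSS", "-EDSS",
    paste0("+", fss_display), paste0("-", fss_display),
    unique(dmt_inventory()$group))
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate a tertiary-center MS cohort: 985 patients, 69.75% female,
#' age at first visit lognormal around a 43-year median, follow-up lognormal
#' around an 80.8-month median, visit intervals giving a median of about 15
#' visits, and the baseline course mix dominated by an administratively
#' recorded CIS at entry.
#'
#' @param n_patients cohort size.
#' @param female_fraction probability of female sex.
#' @param age_meanlog,age_sdlog lognormal parameters of age at baseline
#'   (years).
#' @param followup_meanlog,followup_sdlog lognormal parameters of follow-up
#'   duration (months); clamped to `[followup_min_months,
#'   followup_max_months]`.
#' @param followup_min_months,followup_max_months follow-up clamp (months).
#' @param visit_meanlog,visit_sdlog lognormal parameters of the inter-visit
#'   interval (days); intervals below 14 days are lifted to 14.
#' @param baseline_hazards named events-per-patient-year vector; see
#'   [default_hazards()]. FSS/EDSS labels generate confirmed score changes,
#'   DMT-group labels generate treatment starts, `Relapse`/`MRI *` labels
#'   generate their streams directly.
#' @param planted_effects list of [planted_effect()]s.
#' @param dmt_menu drug names available per group (defaults to the full
#'   [dmt_inventory()]).
#' @param p_cis,p_ppms baseline course mix (remainder starts unrecorded);
#'   CIS converts to RRMS with median `cis_conversion_median_months`, RRMS
#'   progresses to SPMS at `spms_hazard_per_year`.
#' @param cis_conversion_median_months,spms_hazard_per_year course dynamics.
#' @param edss_missing_rate fraction of visits with a missing EDSS score.
#' @param baseline_start,baseline_end calendar window of first visits.
#' @param seed RNG seed; the generator is deterministic given the full config.
#' @return list of class `ptra_synth_config`.
#' @export
synthetic_config <- function(n_patients = 985L,
                             female_fraction = 0.6975,
                             age_meanlog = log(43.1), age_sdlog = 0.32,
                             followup_meanlog = log(80.8),
                             followup_sdlog = 0.893,
                             followup_min_months = 3,
                             followup_max_months = 300,
                             visit_meanlog = log(165), visit_sdlog = 0.45,
                             baseline_hazards = default_hazards(),
                             planted_effects = list(),
                             dmt_menu = NULL,
                             p_cis = 0.85, p_ppms = 0.09,
                             cis_conversion_median_months = 14,
                             spms_hazard_per_year = 0.035,
                             edss_missing_rate = 0.02,
                             baseline_start = "2005-01-01",
                             baseline_end = "2016-12-31",
                             seed = 1L) {
  stopifnot(n_patients >= 0, female_fraction > 0, female_fraction < 1,
            all(baseline_hazards >= 0), p_cis + p_ppms <= 1,
            edss_missing_rate >= 0, edss_missing_rate < 1)
  unknown <- setdiff(names(baseline_hazards), simulated_labels())
  if (length(unknown)) {
    stop("synthetic_config(): labels without a simulated stream: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(dmt_menu)) dmt_menu <- dmt_inventory()
  for (pe in planted_effects) stopifnot(inherits(pe, "ptra_planted_effect"))
  structure(as.list(environment()), class = "ptra_synth_config")
}

#' Small-cohort preset
#'
#' Mirrors the limited-sample treatment-effectiveness regime: 83 patients,
#' 63.9% female, short follow-up (mean about 22 months), sparse events, every
#' patient starting the index treatment (Cladribine) after 0-3 prior DMTs.
#' Returned as a ready configuration; pass to [generate_cohort()] and note
#' that CLAD treatment rows are added by the generator for this preset via the
#' `clad_fraction` attribute.
#'
#' @param seed RNG seed.
#' @return A `ptra_synth_config` with `attr(, "clad_fraction") = 1`.
#' @export
small_cohort_config <- function(seed = 1L) {
  cfg <- synthetic_config(
    n_patients = 83L, female_fraction = 0.6386,
    followup_meanlog = log(21), followup_sdlog = 0.45,
    followup_min_months = 4, followup_max_months = 35,
    visit_meanlog = log(120), visit_sdlog = 0.35,
    baseline_hazards = c("Relapse" = 0.18, "MRI BR" = 0.05, "MRI SC" = 0.02,
                         "+EDSS" = 0.10, "-EDSS" = 0.05,
                         "IFN/GLAT" = 0.0, "FNG" = 0.0, "TRF" = 0.0),
    baseline_start = "2018-08-01", baseline_end = "2021-11-30",
    seed = seed
  )
  attr(cfg, "clad_fraction") <- 1
  cfg
}

# simulate one thinned Poisson stream over [0, T) days.
# boosts: data.frame(lo, hi, hr) of active multiplicative windows (days).
sim_stream <- function(rate_per_year, T_days, boosts = NULL) {
  lam <- rate_per_year / 365.25
  if (lam <= 0 || T_days <= 0) return(numeric(0))
  hr_max <- if (!is.null(boosts) && nrow(boosts)) {
    prod(pmax(vapply(split(boosts, boosts$effect), function(b)
      max(b$hr, 1), 1), 1))
  } else 1
  lam_max <- lam * hr_max
  n <- rpois(1L, lam_max * T_days)
  if (!n) return(numeric(0))
  t <- sort(runif(n, 0, T_days))
  if (is.null(boosts) || !nrow(boosts)) return(t)
  rate_at <- function(ti) {
    m <- 1
    for (eff in unique(boosts$effect)) {
      be <- boosts[boosts$effect == eff, , drop = FALSE]
      if (any(ti >= be$lo & ti < be$hi)) m <- m * be$hr[1L]
    }
    lam * m
  }
  keep <- vapply(t, function(ti) runif(1) < rate_at(ti) / lam_max, logical(1))
  t[keep]
}

# snap intended score-change times (days from baseline) to visit indices such
# that each lands on visit 2..(m-1) and consecutive changes are >= 2 visits
# apart (the confirmation visit must not itself carry the next change).
snap_to_visits <- function(times, visit_days) {
  m <- length(visit_days)
  if (m < 3L || !length(times)) return(integer(0))
  idx <- findInterval(times, visit_days + 1e-9) + 1L  # first visit >= time
  idx <- idx[idx >= 2L & idx <= m - 1L]
  out <- integer(0)
  for (i in idx) {
    if (!length(out) || i >= out[length(out)] + 2L) out <- c(out, i)
  }
  out
}

# build a piecewise-constant score series over visits from signed steps
score_series <- function(m, base, steps_at, step_sign, step_size, lo, hi) {
  s <- rep(base, m)
  if (length(steps_at)) {
    for (j in seq_along(steps_at)) {
      i <- steps_at[j]
      new <- s[i - 1L] + step_sign[j] * step_size
      if (new < lo || new > hi) next  # clamp by dropping the no-op step
      s[i:m] <- new
    }
  }
  s
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws demographics, a visit grid, course transitions and event streams per
#' patient under the configuration, then synthesizes visit-level EDSS/FSS
#' series such that the intended confirmed score changes are recoverable by
#' [extract_events()].
#'
#' @param config a [synthetic_config()].
#' @return A `ptra_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ptra_synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  clad_fraction <- attr(config, "clad_fraction")
  if (is.null(clad_fraction)) clad_fraction <- 0
  empty <- as_cohort(
    data.frame(patient_id = character(0), sex = character(0),
               birth_date = as.Date(character(0))),
    data.frame(patient_id = character(0), date = as.Date(character(0)),
               edss = numeric(0),
               setNames(as.data.frame(matrix(numeric(0), 0, 8)),
                        fss_columns()),
               ms_course = character(0), check.names = FALSE),
    drop_single_visit = FALSE)
  if (n == 0L) return(empty)

  hz <- config$baseline_hazards
  effects <- config$planted_effects
  labels <- union(names(hz), unlist(lapply(effects, function(e)
    c(e$trigger, e$outcome))))
  hz <- setNames(hz[labels], labels)
  hz[is.na(hz)] <- 0
  # simulate triggers before outcomes
  dep_order <- labels
  for (rep_i in seq_along(effects)) {
    for (e in effects) {
      it <- match(e$trigger, dep_order); io <- match(e$outcome, dep_order)
      if (it > io) dep_order <- append(dep_order[-it], e$trigger, after = io - 1L)
    }
  }

  base_lo <- as.integer(as.Date(config$baseline_start))
  base_hi <- as.integer(as.Date(config$baseline_end))
  fss_labels <- as.character(fss_display)
  menu <- split(config$dmt_menu$drug_name, config$dmt_menu$group)

  pat <- vis <- rel <- mri <- trt <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("P%05d", p)
    sex <- if (runif(1) < config$female_fraction) "F" else "M"
    age0 <- rlnorm(1, config$age_meanlog, config$age_sdlog)
    baseline <- as.Date(sample(base_lo:base_hi, 1L), origin = "1970-01-01")
    birth <- baseline - round(age0 * 365.25)
    fu_months <- min(max(rlnorm(1, config$followup_meanlog,
                                config$followup_sdlog),
                         config$followup_min_months),
                     config$followup_max_months)
    T_days <- fu_months * 30.4375

    gaps <- pmax(rlnorm(60L, config$visit_meanlog, config$visit_sdlog), 14)
    vdays <- c(0, cumsum(gaps))
    vdays <- vdays[vdays <= T_days]
    if (length(vdays) < 2L) vdays <- c(0, T_days)
    m <- length(vdays)
    vdates <- baseline + round(vdays)

    # course: administrative CIS at entry converting to RRMS, possible SPMS
    u <- runif(1)
    course <- rep(NA_character_, m)
    if (u < config$p_cis) {
      conv <- rexp(1, log(2) / (config$cis_conversion_median_months * 30.4375))
      spms_at <- conv + rexp(1, config$spms_hazard_per_year / 365.25)
      course <- ifelse(vdays < conv, "CIS",
                       ifelse(vdays < spms_at, "RRMS", "SPMS"))
    } else if (u < config$p_cis + config$p_ppms) {
      course <- rep("PPMS", m)
    }  # remainder: course never recorded

    # event streams with planted boosts
    stream <- list()
    for (lab in dep_order) {
      boosts <- NULL
      for (ei in seq_along(effects)) {
        e <- effects[[ei]]
        if (e$outcome != lab) next
        trig <- stream[[e$trigger]]
        if (is.null(trig) || !length(trig)) next
        boosts <- rbind(boosts, data.frame(
          lo = trig + e$lag_lo_days, hi = trig + e$lag_hi_days,
          hr = e$hazard_ratio, effect = ei))
      }
      stream[[lab]] <- sim_stream(hz[[lab]], T_days, boosts)
    }

    if (length(stream[["Relapse"]])) {
      rel[[pid]] <- data.frame(patient_id = pid,
                               onset_date = baseline + round(stream$Relapse),
                               stringsAsFactors = FALSE)
    }
    mr <- NULL
    for (lab in c("MRI BR", "MRI SC")) {
      if (length(stream[[lab]])) {
        mr <- rbind(mr, data.frame(
          patient_id = pid, date = baseline + round(stream[[lab]]),
          region = if (lab == "MRI BR") "BR" else "SC",
          lesion_increase = 1L, stringsAsFactors = FALSE))
      }
    }
    if (!is.null(mr)) mri[[pid]] <- mr

    tr <- NULL
    for (lab in intersect(names(menu), dep_order)) {
      tt <- stream[[lab]]
      if (length(tt)) {
        tr <- rbind(tr, data.frame(
          patient_id = pid, start_date = baseline + round(tt),
          drug_name = sample(rep(menu[[lab]], 2L), length(tt),
                             replace = TRUE),
          stringsAsFactors = FALSE))
      }
    }
    if (clad_fraction > 0 && runif(1) < clad_fraction) {
      n_prior <- sample(0:3, 1L, prob = c(0.25, 0.35, 0.25, 0.15))
      prior_groups <- sample(setdiff(names(menu), "CLAD"), n_prior)
      if (n_prior > 0) {
        tr <- rbind(tr, data.frame(
          patient_id = pid,
          start_date = birth + round(age0 * 365.25) -
            round(runif(n_prior, 200, 2000)),
          drug_name = vapply(prior_groups, function(g)
            sample(rep(menu[[g]], 2L), 1L), ""),
          stringsAsFactors = FALSE))
      }
      tr <- rbind(tr, data.frame(patient_id = pid, start_date = baseline,
                                 drug_name = "Cladribine",
                                 stringsAsFactors = FALSE))
    }
    if (!is.null(tr)) trt[[pid]] <- tr

    # EDSS series from intended confirmed changes
    ed_plus <- stream[["+EDSS"]]; if (is.null(ed_plus)) ed_plus <- numeric(0)
    ed_min <- stream[["-EDSS"]]; if (is.null(ed_min)) ed_min <- numeric(0)
    ed_times <- sort(c(ed_plus, ed_min))
    ed_sign <- c(rep(1, length(ed_plus)),
                 rep(-1, length(ed_min)))[order(c(ed_plus, ed_min))]
    at <- snap_to_visits(ed_times, vdays)
    sgn <- ed_sign[match(at, findInterval(ed_times, vdays + 1e-9) + 1L)]
    edss <- score_series(m, 0.5 * sample(2:9, 1L), at, sgn, 0.5, 0, 10)
    if (config$edss_missing_rate > 0 && m > 2L) {
      miss <- which(runif(m) < config$edss_missing_rate)
      edss[setdiff(miss, c(at, at + 1L, 1L))] <- NA
    }

    fss <- matrix(NA_real_, m, 8, dimnames = list(NULL, fss_columns()))
    for (si in seq_along(functional_systems)) {
      disp <- fss_labels[si]
      tp <- stream[[paste0("+", disp)]]
      if (is.null(tp)) tp <- numeric(0)
      tm <- stream[[paste0("-", disp)]]
      if (is.null(tm)) tm <- numeric(0)
      tt <- sort(c(tp, tm))
      ss <- c(rep(1, length(tp)), rep(-1, length(tm)))[order(c(tp, tm))]
      at_s <- snap_to_visits(tt, vdays)
      sg_s <- ss[match(at_s, findInterval(tt, vdays + 1e-9) + 1L)]
      fss[, si] <- score_series(m, sample(0:3, 1L), at_s, sg_s, 1, 0, 6)
    }

    pat[[pid]] <- data.frame(patient_id = pid, sex = sex, birth_date = birth,
                             stringsAsFactors = FALSE)
    vis[[pid]] <- data.frame(patient_id = pid, date = vdates, edss = edss,
                             as.data.frame(fss), ms_course = course,
                             check.names = FALSE, stringsAsFactors = FALSE)
  }

  as_cohort(do.call(rbind, pat), do.call(rbind, vis),
            if (length(rel)) do.call(rbind, rel) else NULL,
            if (length(mri)) do.call(rbind, mri) else NULL,
            if (length(trt)) do.call(rbind, trt) else NULL,
            drop_single_visit = TRUE)
}

#' Null cohort: independent event streams
#'
#' [generate_cohort()] with no planted effects — every stream is an
#' independent Poisson process, for type-I-error calibration of the pair
#' pipeline.
#'
#' @param n_patients cohort size.
#' @param hazards named events-per-patient-year vector.
#' @param seed RNG seed.
#' @param ... further arguments to [synthetic_config()].
#' @return A `ptra_cohort`.
#' @export
null_cohort <- function(n_patients, hazards = default_hazards(), seed = 1L,
                        ...) {
  generate_cohort(synthetic_config(n_patients = n_patients,
                                   baseline_hazards = hazards,
                                   planted_effects = list(), seed = seed,
                                   ...))
}

#' Closed-form expected relative risk of a planted effect
#'
#' Probability of at least one outcome event inside the observation window
#' after the trigger, for triggered vs untriggered patients, under the
#' piecewise-constant hazard model: with per-day baseline hazard `l`, window
#' length `w`, boost `h` active over the overlap `v` of the window with the
#' lag interval,
#' `RR = (1 - exp(-l (w - v) - l h v)) / (1 - exp(-l w))`.
#'
#' @param effect a [planted_effect()].
#' @param baseline_hazard outcome baseline hazard, events per patient-year.
#' @param window a [time_range()] observation window (days after the
#'   trigger anchor).
#' @return Expected RR; 1.0 when the window does not overlap the lag
#'   interval.
#' @export
expected_rr <- function(effect, baseline_hazard, window) {
  l <- baseline_hazard / 365.25
  w <- window$hi - window$lo
  v <- max(0, min(window$hi, effect$lag_hi_days) -
             max(window$lo, effect$lag_lo_days))
  if (v == 0 || l <= 0) return(1.0)
  p1 <- 1 - exp(-l * (w - v) - l * effect$hazard_ratio * v)
  p0 <- 1 - exp(-l * w)
  p1 / p0
}
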