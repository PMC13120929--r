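# Fixture builders and independent oracles used across the suite. The oracles
# are deliberately written as plain nested loops / enumerations, sharing no
# code with the package internals they check.

fss_cols <- paste0("fss_", ptra::functional_systems)

mk_patients <- function(ids, sex, birth) {
  data.frame(patient_id = ids, sex = sex, birth_date = as.Date(birth),
             stringsAsFactors = FALSE)
}

# visits for one patient; edss/course recycled; fss defaults to all zero
mk_visits <- function(pid, dates, edss = NA, course = NA, fss = NULL) {
  n <- length(dates)
  df <- data.frame(patient_id = pid, date = as.Date(dates),
                   edss = rep_len(edss, n), stringsAsFactors = FALSE)
  for (col in fss_cols) {
    df[[col]] <- if (!is.null(fss) && col %in% names(fss)) {
      rep_len(fss[[col]], n)
    } else 0
  }
  df$ms_course <- rep_len(course, n)
  df
}

mk_events <- function(patient_id, date, label,
                      main = label, sub = label) {
  df <- data.frame(patient_id = patient_id, date = as.Date(date),
                   main_category = main, subcategory = sub, label = label,
                   level = "sub", stringsAsFactors = FALSE)
  class(df) <- c("ptra_events", "data.frame")
  df
}

# brute-force exposed set + in-window outcome counts (half-open [lo, hi))
oracle_pair_counts <- function(events, a, b, lo, hi) {
  p_ab <- 0L; p_anotb <- 0L; patients <- character(0)
  for (pid in unique(events$patient_id)) {
    ev <- events[events$patient_id == pid, ]
    a_dates <- sort(ev$date[ev$label == a])
    if (!length(a_dates)) next
    anchor <- a_dates[1]
    b_dates <- ev$date[ev$label == b]
    hit <- FALSE
    for (d in as.numeric(b_dates)) {
      lag <- d - as.numeric(anchor)
      if (lag >= lo && lag < hi) hit <- TRUE
    }
    if (hit) {
      p_ab <- p_ab + 1L
      patients <- c(patients, pid)
    } else {
      p_anotb <- p_anotb + 1L
    }
  }
  list(p_AB = p_ab, p_AnotB = p_anotb, patients = patients)
}

# two-sided exact binomial p at p0 = 1/2 by direct enumeration
oracle_binom_two_sided <- function(x, n) {
  probs <- sapply(0:n, function(k) choose(n, k) * 0.5^n)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# independent reference MCL: dense loops, attractor-based cluster readout
oracle_mcl <- function(adj, inflation = 2, max_iter = 200) {
  n <- nrow(adj)
  diag(adj) <- pmax(diag(adj), 1)
  M <- adj
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (iter in 1:max_iter) {
    old <- M
    M <- M %*% M
    M <- M^inflation
    for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
    M[M < 1e-12] <- 0
    if (max(abs(M - old)) < 1e-9) break
  }
  attractors <- which(diag(M) > 1e-6)
  clusters <- list()
  for (a in attractors) {
    members <- which(M[a, ] > 1e-6)
    placed <- FALSE
    if (length(clusters)) {
      for (ci in seq_along(clusters)) {
        if (length(intersect(clusters[[ci]], members))) {
          clusters[[ci]] <- union(clusters[[ci]], members)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- members
  }
  lapply(clusters, sort)
}

# quick synthetic cohort at reduced size for structural tests
tiny_synth <- function(n = 40, seed = 1, hazards = NULL, effects = list()) {
  if (is.null(hazards)) {
    hazards <- c("Relapse" = 0.3, "MRI BR" = 0.15, "+EDSS" = 0.2,
                 "-EDSS" = 0.1, "+Mental" = 0.08, "IFN/GLAT" = 0.1,
                 "ALZ" = 0.05)
  }
  ptra::generate_cohort(ptra::synthetic_config(
    n_patients = n, baseline_hazards = hazards, planted_effects = effects,
    seed = seed))
}
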