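# Event taxonomy: every emitted diagnostic event carries a main category and a
# subcategory; each subcategory belongs to exactly one main category, and when
# an event type has no distinct subcategory the main label serves as both.

#' Disease-modifying-therapy inventory and mode-of-action groups
#'
#' The DMT product names recognized by [group_dmt()], grouped by primary mode
#' of action and strength. Cladribine (`CLAD`) is carried as its own group
#' because it is the index treatment of the small-cohort analysis and never a
#' "prior DMT" group.
#'
#' @return data frame with columns `drug_name`, `group`.
#' @export
dmt_inventory <- function() {
  inv <- list(
    "IFN/GLAT" = c("Interferon-beta-1a", "Interferon-beta-1b",
                   "Peg-Interferon-beta-1a", "Glatiramer acetate"),
    "CD20"     = c("Rituximab", "Ocrelizumab", "Ofatumumab"),
    "OTH"      = c("Mitoxantrone", "Methotrexate", "Azathioprine",
                   "Cyclophosphamide"),
    "TRF"      = "Teriflunomide",
    "DMF"      = "Dimethyl Fumarate",
    "FNG"      = "Fingolimod",
    "NTZ"      = "Natalizumab",
    "ALZ"      = "Alemtuzumab",
    "CLAD"     = "Cladribine"
  )
  data.frame(
    drug_name = unlist(inv, use.names = FALSE),
    group = rep(names(inv), lengths(inv)),
    stringsAsFactors = FALSE
  )
}

#' Map a drug name to its DMT group
#'
#' Case-insensitive lookup against the [dmt_inventory()]. Unrecognized names
#' are an error (never a silent drop).
#'
#' @param drug_name character vector of product names.
#' @return Character vector of group labels (`"IFN/GLAT"`, `"CD20"`, `"OTH"`,
#'   `"TRF"`, `"DMF"`, `"FNG"`, `"NTZ"`, `"ALZ"`, `"CLAD"`).
#' @export
group_dmt <- function(drug_name) {
  inv <- dmt_inventory()
  idx <- match(tolower(trimws(drug_name)), tolower(inv$drug_name))
  if (anyNA(idx)) {
    stop("group_dmt(): unknown drug name(s): ",
         paste(unique(drug_name[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  inv$group[idx]
}

#' Event-extraction configuration
#'
#' @param confirmation_visits number of subsequent visits (with a non-missing
#'   score) that must confirm a score change before it becomes an event.
#' @param cdw_sustain_days confirmed-disability-worsening sustain window; an
#'   EDSS increase counts as CDW only if sustained this long (183 days = 6
#'   months).
#' @param relapse_infection_gap_days minimum separation of a relapse from any
#'   recorded infection/fever date (small-cohort analysis only; applies only
#'   when an infections table is supplied).
#' @param neda_anchor date that anchors the no-evidence-of-disease-activity
#'   event: treatment start (default) or first visit.
#' @return A list of class `ptra_event_config`.
#' @export
event_config <- function(confirmation_visits = 1L,
                         cdw_sustain_days = 183L,
                         relapse_infection_gap_days = 30L,
                         neda_anchor = c("clad_start", "first_visit")) {
  stopifnot(confirmation_visits >= 1L, cdw_sustain_days > 0L,
            relapse_infection_gap_days > 0L)
  structure(list(
    confirmation_visits = as.integer(confirmation_visits),
    cdw_sustain_days = as.integer(cdw_sustain_days),
    relapse_infection_gap_days = as.integer(relapse_infection_gap_days),
    neda_anchor = match.arg(neda_anchor)
  ), class = "ptra_event_config")
}

fss_display <- c(
  bowel_bladder = "Bowel/Bladder", pyramidal = "Pyramidal",
  cerebellar = "Cerebellar", brainstem = "Brainstem", mental = "Mental",
  sensory = "Sensory", visual = "Visual", ambulation = "Ambulation"
)

# Confirmed persistent changes in a longitudinal score.
#
# A change at visit k (score differs from the running reference) becomes an
# event iff the next `confirm` visits with a non-missing score all differ from
# the reference in the same direction; the event is dated at the first changed
# visit and the reference then moves to the changed value. Confirmation
# compares against the pre-change value, not the changed value.
confirmed_changes <- function(dates, scores, confirm = 1L) {
  keep <- !is.na(scores)
  dates <- dates[keep]; scores <- scores[keep]
  n <- length(scores)
  out_date <- integer(0); out_dir <- character(0)
  if (n < 2L) {
    return(data.frame(date = as.Date(out_date, origin = "1970-01-01"),
                      direction = out_dir, stringsAsFactors = FALSE))
  }
  ref <- scores[1L]
  k <- 2L
  while (k <= n) {
    if (scores[k] != ref) {
      dir <- sign(scores[k] - ref)
      conf <- k + seq_len(confirm)
      if (max(conf) <= n && all(sign(scores[conf] - ref) == dir)) {
        out_date <- c(out_date, as.integer(dates[k]))
        out_dir <- c(out_dir, if (dir > 0) "+" else "-")
        ref <- scores[k]
      }
    }
    k <- k + 1L
  }
  data.frame(date = as.Date(out_date, origin = "1970-01-01"),
             direction = out_dir, stringsAsFactors = FALSE)
}

event_row <- function(patient_id, date, main, sub) {
  data.frame(patient_id = patient_id, date = date, main_category = main,
             subcategory = sub, stringsAsFactors = FALSE)
}

extract_events_one <- function(pid, visits, relapses, mri, treatments,
                               config) {
  out <- list()

  # MS course transitions: "to CIS" only at the very first recording, then a
  # labeled event at each recorded change to RRMS or SPMS (PPMS and re-entries
  # have no subcategory and are not emitted).
  crs <- visits$ms_course
  obs <- which(!is.na(crs))
  if (length(obs)) {
    if (crs[obs[1L]] == "CIS") {
      out[[length(out) + 1L]] <-
        event_row(pid, visits$date[obs[1L]], "MS course change", "to CIS")
    }
    if (length(obs) > 1L) {
      prev <- crs[obs[-length(obs)]]
      cur <- crs[obs[-1L]]
      chg <- which(cur != prev & cur %in% c("RRMS", "SPMS"))
      for (j in chg) {
        out[[length(out) + 1L]] <- event_row(
          pid, visits$date[obs[j + 1L]], "MS course change",
          paste0("to ", cur[j])
        )
      }
    }
  }

  if (nrow(relapses)) {
    out[[length(out) + 1L]] <-
      event_row(pid, relapses$onset_date, "Relapse", "Relapse")
  }

  inc <- mri[mri$lesion_increase == 1L, , drop = FALSE]
  if (nrow(inc)) {
    out[[length(out) + 1L]] <- event_row(
      pid, inc$date, "MRI activity",
      ifelse(inc$region == "BR", "MRI BR", "MRI SC")
    )
  }

  ed <- confirmed_changes(visits$date, visits$edss, config$confirmation_visits)
  if (nrow(ed)) {
    out[[length(out) + 1L]] <- event_row(
      pid, ed$date, "EDSS change", paste0(ed$direction, "EDSS")
    )
  }

  # per-system confirmed FSS changes; >= 2 systems moving in the same
  # direction between the same visit pair merge into a single +FSS/-FSS event
  fs <- do.call(rbind, lapply(functional_systems, function(sys) {
    ch <- confirmed_changes(visits$date, visits[[paste0("fss_", sys)]],
                            config$confirmation_visits)
    if (nrow(ch)) cbind(ch, system = sys, stringsAsFactors = FALSE) else NULL
  }))
  if (!is.null(fs) && nrow(fs)) {
    key <- paste(as.integer(fs$date), fs$direction)
    for (k in unique(key)) {
      grp <- fs[key == k, , drop = FALSE]
      if (nrow(grp) >= 2L) {
        out[[length(out) + 1L]] <- event_row(
          pid, grp$date[1L], "FSS change", paste0(grp$direction[1L], "FSS")
        )
      } else {
        out[[length(out) + 1L]] <- event_row(
          pid, grp$date, "FSS change",
          paste0(grp$direction, fss_display[[grp$system]])
        )
      }
    }
  }

  if (nrow(treatments)) {
    out[[length(out) + 1L]] <- event_row(
      pid, treatments$start_date, "DMT change", group_dmt(treatments$drug_name)
    )
  }

  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$date, res$subcategory), , drop = FALSE]
}

split_stream <- function(tbl, ids) {
  idx <- split(seq_len(nrow(tbl)), factor(tbl$patient_id, levels = ids))
  lapply(idx, function(i) tbl[i, , drop = FALSE])
}

#' Extract context-specific diagnostic events (full-cohort analysis)
#'
#' Converts each patient record into dated diagnostic events under the
#' two-tier taxonomy: MS-course changes (to CIS at first recording, to RRMS,
#' to SPMS), relapses, regional MRI activity (lesion increases), confirmed
#' EDSS changes (+/-), confirmed per-system FSS changes with the multi-system
#' merge rule, and DMT switches labeled by mode-of-action group.
#'
#' @param cohort a `ptra_cohort`.
#' @param level `"sub"` (default) keeps subcategory labels; `"main"` collapses
#'   labels to the main category, with EDSS/FSS retaining their sign
#'   (`"+EDSS"`, `"-FSS"`, ...). At main level exact duplicate
#'   (patient, date, label) rows created by the collapse are deduplicated.
#' @param config an [event_config()].
#' @return data frame of class `ptra_events` with columns `patient_id`,
#'   `date`, `main_category`, `subcategory`, `label`, `level`; `label` is the
#'   analysis label at the requested level.
#' @export
extract_events <- function(cohort, level = c("sub", "main"),
                           config = event_config()) {
  stopifnot(inherits(cohort, "ptra_cohort"))
  level <- match.arg(level)
  ids <- cohort$patients$patient_id
  vis <- split_stream(cohort$visits, ids)
  rel <- split_stream(cohort$relapses, ids)
  mri <- split_stream(cohort$mri, ids)
  trt <- split_stream(cohort$treatments, ids)
  res <- do.call(rbind, lapply(ids, function(pid) {
    extract_events_one(pid, vis[[pid]], rel[[pid]], mri[[pid]], trt[[pid]],
                       config)
  }))
  if (is.null(res)) {
    res <- data.frame(patient_id = character(0),
                      date = as.Date(character(0)),
                      main_category = character(0),
                      subcategory = character(0), stringsAsFactors = FALSE)
  }
  finish_events(res, level)
}

main_label <- function(main_category, subcategory) {
  ifelse(main_category == "EDSS change", paste0(substr(subcategory, 1, 1), "EDSS"),
  ifelse(main_category == "FSS change", paste0(substr(subcategory, 1, 1), "FSS"),
         main_category))
}

finish_events <- function(res, level) {
  res$label <- if (level == "main") {
    main_label(res$main_category, res$subcategory)
  } else {
    res$subcategory
  }
  if (level == "main") {
    res <- res[!duplicated(res[c("patient_id", "date", "label")]), ,
               drop = FALSE]
  }
  res$level <- rep(level, nrow(res))
  res <- res[order(res$patient_id, res$date, res$label), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ptra_events", "data.frame")
  res
}

#' Extract disease-activity events after treatment initiation
#'
#' Event taxonomy of the small-cohort (treatment-effectiveness) analysis,
#' anchored at each patient's first Cladribine (CLAD) start: evidence of
#' disease activity (EDA-3) as post-initiation relapses, confirmed disability
#' worsening (CDW: an EDSS increase over the peri-initiation baseline sustained
#' for at least `cdw_sustain_days`), and MRI activity; a single NEDA-3 event
#' (dated anchor + `horizon_days`) for patients without any EDA-3 event; one
#' prior-DMT event labeled by the group of the last pre-initiation treatment;
#' and one prior-DMT-count event (`"<2 DMTs"` / `">=2 DMTs"`, counting distinct
#' groups). Patients without a CLAD treatment episode are skipped (or an error
#' for the single-record worker [extract_clad_events_one()]).
#'
#' @param cohort a `ptra_cohort`.
#' @param horizon_days the study time-range appended to the anchor to date
#'   NEDA-3 events.
#' @param infections optional data frame (`patient_id`, `date`): recorded
#'   infection/fever dates used to guard the relapse definition. When absent
#'   the plain 24-hour relapse definition applies and a warning is emitted
#'   once.
#' @param config an [event_config()].
#' @return A `ptra_events` data frame (sub level); main categories are
#'   `"EDA-3"` (subcategories `Relapse`, `CDW`, `MRI`), `"NEDA-3"`,
#'   `"Prior DMT"` (subcategories = DMT groups) and `"Prior DMT count"`.
#' @export
extract_clad_events <- function(cohort, horizon_days, infections = NULL,
                                config = event_config()) {
  stopifnot(inherits(cohort, "ptra_cohort"), horizon_days > 0)
  if (is.null(infections)) {
    warning("no infections table supplied; relapses use the plain 24-hour ",
            "definition without the infection gap", call. = FALSE)
  }
  ids <- cohort$patients$patient_id
  vis <- split_stream(cohort$visits, ids)
  rel <- split_stream(cohort$relapses, ids)
  mri <- split_stream(cohort$mri, ids)
  trt <- split_stream(cohort$treatments, ids)
  res <- do.call(rbind, lapply(ids, function(pid) {
    tr <- trt[[pid]]
    if (!nrow(tr) || !any(group_dmt(tr$drug_name) == "CLAD")) return(NULL)
    inf <- if (!is.null(infections)) {
      as.Date(infections$date[infections$patient_id == pid])
    } else NULL
    extract_clad_events_one(pid, vis[[pid]], rel[[pid]], mri[[pid]], tr,
                            horizon_days = horizon_days, infections = inf,
                            config = config)
  }))
  if (is.null(res)) {
    res <- data.frame(patient_id = character(0),
                      date = as.Date(character(0)),
                      main_category = character(0),
                      subcategory = character(0), stringsAsFactors = FALSE)
  }
  finish_events(res, "sub")
}

#' @rdname extract_clad_events
#' @param pid patient id.
#' @param visits,relapses,mri,treatments the patient's streams.
#' @export
extract_clad_events_one <- function(pid, visits, relapses, mri, treatments,
                                    horizon_days, infections = NULL,
                                    config = event_config()) {
  grp <- group_dmt(treatments$drug_name)
  clad_idx <- which(grp == "CLAD")
  if (!length(clad_idx)) {
    stop("patient ", pid, " has no CLAD treatment episode", call. = FALSE)
  }
  clad_start <- min(treatments$start_date[clad_idx])
  out <- list()

  rel_dates <- relapses$onset_date[relapses$onset_date >= clad_start]
  if (length(infections) && length(rel_dates)) {
    gap <- config$relapse_infection_gap_days
    near_inf <- vapply(rel_dates, function(d) {
      any(abs(as.numeric(d - infections)) < gap)
    }, logical(1))
    rel_dates <- rel_dates[!near_inf]
  }
  if (length(rel_dates)) {
    out[[length(out) + 1L]] <- event_row(pid, rel_dates, "EDA-3", "Relapse")
  }

  cdw <- cdw_events(visits, clad_start, config$cdw_sustain_days)
  if (length(cdw)) {
    out[[length(out) + 1L]] <- event_row(pid, cdw, "EDA-3", "CDW")
  }

  inc <- mri[mri$lesion_increase == 1L & mri$date >= clad_start, ,
             drop = FALSE]
  if (nrow(inc)) {
    out[[length(out) + 1L]] <- event_row(pid, inc$date, "EDA-3", "MRI")
  }

  if (!length(out)) {
    anchor <- if (config$neda_anchor == "clad_start") clad_start else
      min(visits$date)
    out[[length(out) + 1L]] <- event_row(
      pid, anchor + as.integer(horizon_days), "NEDA-3", "NEDA-3"
    )
  }

  prior <- treatments[treatments$start_date < clad_start &
                        grp != "CLAD", , drop = FALSE]
  if (nrow(prior)) {
    last_grp <- group_dmt(prior$drug_name[which.max(
      as.integer(prior$start_date))])
    out[[length(out) + 1L]] <- event_row(pid, clad_start, "Prior DMT",
                                         last_grp)
  }
  n_prior <- length(unique(group_dmt(prior$drug_name)))
  out[[length(out) + 1L]] <- event_row(
    pid, clad_start, "Prior DMT count",
    if (n_prior >= 2L) ">=2 DMTs" else "<2 DMTs"
  )

  res <- do.call(rbind, out)
  res[order(res$date, res$subcategory), , drop = FALSE]
}

# Confirmed disability worsening after an anchor date: EDSS increases over the
# peri-anchor baseline sustained >= sustain_days. Baseline = closest
# non-missing EDSS within [anchor - 183 d, anchor + 91 d]. After a confirmed
# worsening the baseline moves to the increased value, so repeated distinct
# episodes each emit an event. Sustain check: every non-missing EDSS at visits
# in (d, d + sustain] must exceed baseline; if no visit falls in that window,
# the first visit after d decides; with no subsequent visit at all the
# increase cannot be confirmed.
cdw_events <- function(visits, anchor, sustain_days) {
  keep <- !is.na(visits$edss)
  dates <- visits$date[keep]; edss <- visits$edss[keep]
  if (!length(dates)) return(as.Date(character(0)))
  near <- which(dates >= anchor - 183 & dates <= anchor + 91)
  if (!length(near)) return(as.Date(character(0)))
  base <- edss[near[which.min(abs(as.numeric(dates[near] - anchor)))]]
  post <- which(dates > anchor)
  out <- as.Date(character(0))
  for (i in post) {
    if (edss[i] <= base) next
    win <- which(dates > dates[i] & dates <= dates[i] + sustain_days)
    if (!length(win)) {
      nxt <- which(dates > dates[i])
      if (!length(nxt)) next
      win <- nxt[1L]
    }
    if (all(edss[win] > base)) {
      out <- c(out, dates[i])
      base <- edss[i]
    }
  }
  out
}

#' Tabulate an event list
#'
#' @param events a `ptra_events` data frame.
#' @return data frame (`main_category`, `subcategory`, `n_events`,
#'   `n_patients`) sorted by main category and descending event count.
#' @export
event_inventory <- function(events) {
  if (!nrow(events)) {
    return(data.frame(main_category = character(0),
                      subcategory = character(0),
                      n_events = integer(0), n_patients = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(events$main_category, events$subcategory, sep = "\r")
  n_events <- tapply(events$patient_id, key, length)
  n_patients <- tapply(events$patient_id, key, function(x) length(unique(x)))
  parts <- strsplit(names(n_events), "\r", fixed = TRUE)
  out <- data.frame(
    main_category = vapply(parts, `[`, "", 1L),
    subcategory = vapply(parts, `[`, "", 2L),
    n_events = as.integer(n_events),
    n_patients = as.integer(n_patients),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$main_category, -out$n_events, out$subcategory), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
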