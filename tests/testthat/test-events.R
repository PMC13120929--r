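test_that("drug names map to mode-of-action groups case-insensitively", {
  expect_equal(group_dmt("Glatiramer acetate"), "IFN/GLAT")
  expect_equal(group_dmt("Fingolimod"), "FNG")
  expect_equal(group_dmt("Cyclophosphamide"), "OTH")
  expect_equal(group_dmt(c("ocrelizumab", "NATALIZUMAB", "cladribine")),
               c("CD20", "NTZ", "CLAD"))
  expect_error(group_dmt("Aspirin"), "Aspirin")
})

edss_cohort <- function(edss, dates = NULL) {
  n <- length(edss)
  if (is.null(dates)) dates <- as.Date("2010-01-01") + 90 * (seq_len(n) - 1)
  as_cohort(mk_patients("A", "F", "1970-01-01"),
            mk_visits("A", dates, edss = edss))
}

test_that("EDSS changes need confirmation by the subsequent visit", {
  ev <- extract_events(edss_cohort(c(3.0, 4.0, 4.0)))
  ed <- ev[ev$main_category == "EDSS change", ]
  expect_equal(ed$label, "+EDSS")
  expect_equal(ed$date, as.Date("2010-01-01") + 90)  # dated at first change
  # unconfirmed change emits nothing
  expect_equal(sum(extract_events(
    edss_cohort(c(3.0, 4.0, 3.0)))$main_category == "EDSS change"), 0L)
  # confirmation compares against the pre-change value, same direction:
  # 3.0 -> 4.0 is confirmed by 3.5 (> 3.0); the settled 4.0 -> 3.5 drop is
  # then itself a confirmed decrease against the new reference
  ev3 <- extract_events(edss_cohort(c(3.0, 4.0, 3.5, 3.5)))
  expect_equal(ev3$label[ev3$main_category == "EDSS change"],
               c("+EDSS", "-EDSS"))
  # a confirmed reversal later emits a new opposite event
  ev4 <- extract_events(edss_cohort(c(3.0, 4.0, 4.0, 3.0, 3.0)))
  expect_equal(ev4$label[ev4$main_category == "EDSS change"],
               c("+EDSS", "-EDSS"))
})

test_that("simultaneous same-direction FSS changes merge into one event", {
  vis <- mk_visits("A", as.Date("2010-01-01") + c(0, 90, 180),
                   fss = list(fss_pyramidal = c(2, 3, 3),
                              fss_sensory = c(1, 2, 2)))
  ev <- extract_events(as_cohort(mk_patients("A", "F", "1970-01-01"), vis))
  fs <- ev[ev$main_category == "FSS change", ]
  expect_equal(fs$label, "+FSS")  # merged, not two per-system events
  expect_equal(nrow(fs), 1L)
  # a single-system change keeps its system label
  vis2 <- mk_visits("A", as.Date("2010-01-01") + c(0, 90, 180),
                    fss = list(fss_mental = c(1, 2, 2)))
  ev2 <- extract_events(as_cohort(mk_patients("A", "F", "1970-01-01"), vis2))
  expect_equal(ev2$label[ev2$main_category == "FSS change"], "+Mental")
  # mixed directions merge per direction
  vis3 <- mk_visits("A", as.Date("2010-01-01") + c(0, 90, 180),
                    fss = list(fss_pyramidal = c(2, 3, 3),
                               fss_sensory = c(1, 2, 2),
                               fss_mental = c(2, 1, 1)))
  ev3 <- extract_events(as_cohort(mk_patients("A", "F", "1970-01-01"), vis3))
  expect_setequal(ev3$label[ev3$main_category == "FSS change"],
                  c("+FSS", "-Mental"))
})

test_that("course transitions emit to-CIS only at first recording", {
  vis <- mk_visits("A", as.Date("2010-01-01") + c(0, 90, 180, 270, 360),
                   course = c("CIS", "CIS", "CIS", "CIS", "RRMS"))
  ev <- extract_events(as_cohort(mk_patients("A", "F", "1970-01-01"), vis))
  cc <- ev[ev$main_category == "MS course change", ]
  expect_equal(cc$label, c("to CIS", "to RRMS"))
  expect_equal(cc$date, as.Date("2010-01-01") + c(0, 360))
  # starting at RRMS: no to-CIS, progression to SPMS recorded
  vis2 <- mk_visits("B", as.Date("2011-01-01") + c(0, 90, 180),
                    course = c("RRMS", "SPMS", "SPMS"))
  ev2 <- extract_events(as_cohort(mk_patients("B", "M", "1960-01-01"), vis2))
  expect_equal(ev2$label[ev2$main_category == "MS course change"], "to SPMS")
})

test_that("main-level labels collapse but EDSS/FSS keep their sign", {
  coh <- tiny_synth(n = 30, seed = 11)
  sub <- extract_events(coh, level = "sub")
  main <- extract_events(coh, level = "main")
  expect_true(all(main$label %in%
    c("MS course change", "Relapse", "MRI activity", "+EDSS", "-EDSS",
      "+FSS", "-FSS", "DMT change")))
  # every sub label maps to exactly one main category (two-tier hierarchy)
  map <- unique(sub[, c("subcategory", "main_category")])
  expect_false(any(duplicated(map$subcategory)))
  # no duplicated (patient, date, label) rows at main level
  expect_false(any(duplicated(main[, c("patient_id", "date", "label")])))
})

test_that("dropping the last visit never creates a confirmed score event", {
  coh <- tiny_synth(n = 25, seed = 13)
  ev_full <- extract_events(coh)
  vis <- coh$visits
  keep <- unlist(lapply(split(seq_len(nrow(vis)), vis$patient_id),
                        function(i) i[-length(i)]))
  coh_trim <- as_cohort(coh$patients, vis[sort(keep), ], coh$relapses,
                        coh$mri, coh$treatments)
  ev_trim <- extract_events(coh_trim)
  score_key <- function(e) {
    e <- e[e$main_category %in% c("EDSS change", "FSS change"), ]
    paste(e$patient_id, e$date, e$label)
  }
  expect_true(all(score_key(ev_trim) %in% score_key(ev_full)))
})

test_that("event inventory equals an independent group-by recount", {
  coh <- tiny_synth(n = 30, seed = 17)
  ev <- extract_events(coh)
  inv <- event_inventory(ev)
  for (i in seq_len(nrow(inv))) {
    sel <- ev$main_category == inv$main_category[i] &
      ev$subcategory == inv$subcategory[i]
    expect_equal(inv$n_events[i], sum(sel))
    expect_equal(inv$n_patients[i], length(unique(ev$patient_id[sel])))
  }
  expect_equal(sum(inv$n_events), nrow(ev))
  expect_equal(nrow(event_inventory(ev[0, ])), 0L)
})

clad_patient <- function(pid = "A", relapse_after = NULL, edss = NULL,
                         prior = character(0), mri_after = NULL,
                         clad = "2019-06-01") {
  clad <- as.Date(clad)
  dates <- clad + seq(-30, 700, by = 90)
  vis <- mk_visits(pid, dates,
                   edss = if (is.null(edss)) 2.5 else rep_len(edss,
                                                              length(dates)))
  trt <- data.frame(patient_id = pid, start_date = clad,
                    drug_name = "Cladribine", stringsAsFactors = FALSE)
  if (length(prior)) {
    trt <- rbind(data.frame(patient_id = pid,
                            start_date = clad - 300 * seq_along(prior),
                            drug_name = prior, stringsAsFactors = FALSE), trt)
  }
  rel <- if (!is.null(relapse_after)) {
    data.frame(patient_id = pid, onset_date = clad + relapse_after,
               stringsAsFactors = FALSE)
  } else NULL
  mri <- if (!is.null(mri_after)) {
    data.frame(patient_id = pid, date = clad + mri_after, region = "BR",
               lesion_increase = 1L, stringsAsFactors = FALSE)
  } else NULL
  as_cohort(mk_patients(pid, "F", "1980-01-01"), vis, rel, mri, trt)
}

test_that("NEDA-3 is emitted exactly when no disease activity is recorded", {
  coh <- clad_patient()
  ev <- suppressWarnings(extract_clad_events(coh, horizon_days = 730))
  expect_equal(ev$label[ev$main_category %in% c("EDA-3", "NEDA-3")], "NEDA-3")
  expect_equal(ev$date[ev$label == "NEDA-3"], as.Date("2019-06-01") + 730)
  coh2 <- clad_patient(relapse_after = 100)
  ev2 <- suppressWarnings(extract_clad_events(coh2, horizon_days = 730))
  expect_true("Relapse" %in% ev2$label)
  expect_false("NEDA-3" %in% ev2$label)
})

test_that("prior DMT and prior count come from the pre-CLAD stream", {
  coh <- clad_patient(prior = c("Fingolimod", "Interferon-beta-1a"))
  ev <- suppressWarnings(extract_clad_events(coh, horizon_days = 365))
  # priors dated clad - 300 (FNG) and clad - 600 (IFN): last one is FNG
  expect_equal(ev$label[ev$main_category == "Prior DMT"], "FNG")
  expect_equal(ev$label[ev$main_category == "Prior DMT count"], ">=2 DMTs")
  expect_true(all(ev$date[ev$main_category %in%
                            c("Prior DMT", "Prior DMT count")] ==
                    as.Date("2019-06-01")))
  coh2 <- clad_patient(prior = "Fingolimod")
  ev2 <- suppressWarnings(extract_clad_events(coh2, horizon_days = 365))
  expect_equal(ev2$label[ev2$main_category == "Prior DMT count"], "<2 DMTs")
})

test_that("CDW requires the EDSS increase to be sustained six months", {
  clad <- as.Date("2019-06-01")
  # rises at day 60 and stays up through day 60+200: one CDW dated at day 60
  edss <- c(2.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5)
  coh <- clad_patient(edss = edss)
  ev <- suppressWarnings(extract_clad_events(coh, horizon_days = 730))
  cdw <- ev[ev$subcategory == "CDW", ]
  expect_equal(nrow(cdw), 1L)
  expect_equal(cdw$date, clad + 60)
  # a transient rise that falls back within the window is not CDW
  edss2 <- c(2.5, 3.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5)
  ev2 <- suppressWarnings(
    extract_clad_events(clad_patient(edss = edss2), horizon_days = 730))
  expect_false("CDW" %in% ev2$subcategory)
})

test_that("a patient without the index treatment is a precondition error", {
  vis <- mk_visits("A", as.Date("2019-01-01") + c(0, 90), edss = 2)
  trt <- data.frame(patient_id = "A", start_date = as.Date("2019-01-01"),
                    drug_name = "Fingolimod", stringsAsFactors = FALSE)
  expect_error(
    extract_clad_events_one("A", vis, vis[0, c("patient_id", "date")],
                            data.frame(), trt, horizon_days = 365),
    "CLAD")
})

test_that("relapses near recorded infections are excluded when supplied", {
  coh <- clad_patient(relapse_after = c(100, 200))
  inf <- data.frame(patient_id = "A",
                    date = as.Date("2019-06-01") + 190,
                    stringsAsFactors = FALSE)
  ev <- extract_clad_events(coh, horizon_days = 730, infections = inf)
  expect_equal(sum(ev$label == "Relapse"), 1L)  # day-200 relapse guarded
  expect_warning(extract_clad_events(coh, horizon_days = 730), "infection")
})
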