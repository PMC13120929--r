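#' @useDynLib ptra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats binom.test dbinom median pnorm quantile rbinom rexp rlnorm
#'   rpois runif sd setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

#' The eight functional systems of the disability score
#'
#' Seven neurological functional-system scores plus ambulation, the components
#' underlying the composite EDSS disability scale.
#'
#' @format Character vector of length 8.
#' @export
functional_systems <- c(
  "bowel_bladder", "pyramidal", "cerebellar", "brainstem",
  "mental", "sensory", "visual", "ambulation"
)

fss_columns <- function() paste0("fss_", functional_systems)

ms_courses <- c("CIS", "RRMS", "SPMS", "PPMS")

cohort_schemas <- function() {
  list(
    patients   = c("patient_id", "sex", "birth_date"),
    visits     = c("patient_id", "date", "edss", fss_columns(), "ms_course"),
    relapses   = c("patient_id", "onset_date"),
    mri        = c("patient_id", "date", "region", "lesion_increase"),
    treatments = c("patient_id", "start_date", "drug_name")
  )
}

date_column <- function(tbl) {
  switch(tbl,
    patients = "birth_date", visits = "date", relapses = "onset_date",
    mri = "date", treatments = "start_date"
  )
}

# Parse a date column; rows that fail to parse are dropped with a row-level
# warning (the row numbers refer to the data rows of the file, header excluded).
parse_dates <- function(df, col, what) {
  raw <- as.character(df[[col]])
  parsed <- as.Date(raw, format = "%Y-%m-%d")
  bad <- which(is.na(parsed))
  if (length(bad)) {
    warning(sprintf(
      "%s: dropping %d row(s) with unparseable %s (rows %s)",
      what, length(bad), col, paste(head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    parsed <- parsed[-bad]
  }
  df[[col]] <- parsed
  df
}

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Assemble and validate a longitudinal cohort
#'
#' Builds a `ptra_cohort` from the five component tables, sorting every
#' per-patient stream by date and enforcing the data-model invariants:
#' unique patient ids, no duplicated visit dates within a patient, EDSS on the
#' half-point grid in \[0, 10\], and all event dates on or after birth.
#'
#' @param patients data frame with columns `patient_id`, `sex` (`"F"`/`"M"`),
#'   `birth_date` (`Date` or ISO-8601 string).
#' @param visits data frame with `patient_id`, `date`, `edss`, the eight
#'   `fss_*` columns and `ms_course`; scores may be `NA` (missing).
#' @param relapses data frame with `patient_id`, `onset_date`.
#' @param mri data frame with `patient_id`, `date`, `region` (`"BR"`/`"SC"`),
#'   `lesion_increase` (0/1).
#' @param treatments data frame with `patient_id`, `start_date`, `drug_name`.
#' @param drop_single_visit drop patients with fewer than two visits (default
#'   `TRUE`); single-entry records cannot anchor confirmed score changes.
#' @return An object of class `ptra_cohort`: a list of the five cleaned tables
#'   plus a `baseline` table (`patient_id`, `baseline_date` = first visit).
#'   The number of patients removed by the single-visit filter is stored in
#'   `attr(, "n_dropped_single_visit")`.
#' @export
as_cohort <- function(patients, visits, relapses = NULL, mri = NULL,
                      treatments = NULL, drop_single_visit = TRUE) {
  empty <- function(tbl) {
    cols <- cohort_schemas()[[tbl]]
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df[[date_column(tbl)]] <- as.Date(character(0))
    df
  }
  if (is.null(relapses)) relapses <- empty("relapses")
  if (is.null(mri)) mri <- empty("mri")
  if (is.null(treatments)) treatments <- empty("treatments")

  sch <- cohort_schemas()
  check_schema(patients, sch$patients, "patients")
  check_schema(visits, sch$visits, "visits")
  check_schema(relapses, sch$relapses, "relapses")
  check_schema(mri, sch$mri, "mri")
  check_schema(treatments, sch$treatments, "treatments")

  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("patients table: duplicated patient_id", call. = FALSE)
  }
  patients$sex <- as.character(patients$sex)
  if (!all(patients$sex %in% c("F", "M"))) {
    stop("patients table: sex must be 'F' or 'M'", call. = FALSE)
  }
  patients$birth_date <- as.Date(patients$birth_date)

  visits$patient_id <- as.character(visits$patient_id)
  visits$date <- as.Date(visits$date)
  visits$edss <- num_or_na(visits$edss)
  bad_edss <- !is.na(visits$edss) &
    (visits$edss < 0 | visits$edss > 10 | (visits$edss * 2) %% 1 != 0)
  if (any(bad_edss)) {
    stop("visits table: edss must be a multiple of 0.5 in [0, 10]",
         call. = FALSE)
  }
  for (col in fss_columns()) visits[[col]] <- num_or_na(visits[[col]])
  visits$ms_course <- as.character(visits$ms_course)
  visits$ms_course[!is.na(visits$ms_course) & !nzchar(visits$ms_course)] <- NA
  if (!all(is.na(visits$ms_course) | visits$ms_course %in% ms_courses)) {
    stop("visits table: ms_course must be one of CIS, RRMS, SPMS, PPMS",
         call. = FALSE)
  }
  if (anyDuplicated(visits[c("patient_id", "date")])) {
    dup <- visits[duplicated(visits[c("patient_id", "date")]), ]
    stop(sprintf("visits table: duplicate (patient_id, date): %s on %s",
                 dup$patient_id[1], dup$date[1]), call. = FALSE)
  }

  relapses$patient_id <- as.character(relapses$patient_id)
  relapses$onset_date <- as.Date(relapses$onset_date)
  mri$patient_id <- as.character(mri$patient_id)
  mri$date <- as.Date(mri$date)
  mri$region <- as.character(mri$region)
  if (nrow(mri) && !all(mri$region %in% c("BR", "SC"))) {
    stop("mri table: region must be 'BR' or 'SC'", call. = FALSE)
  }
  mri$lesion_increase <- as.integer(mri$lesion_increase)
  treatments$patient_id <- as.character(treatments$patient_id)
  treatments$start_date <- as.Date(treatments$start_date)
  treatments$drug_name <- as.character(treatments$drug_name)

  known <- patients$patient_id
  for (nm in c("visits", "relapses", "mri", "treatments")) {
    tbl <- get(nm)
    unknown <- setdiff(tbl$patient_id, known)
    if (length(unknown)) {
      stop(sprintf("%s table: unknown patient_id(s): %s",
                   nm, paste(head(unknown, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }

  sort_stream <- function(df, col) {
    df[order(df$patient_id, df[[col]]), , drop = FALSE]
  }
  visits <- sort_stream(visits, "date")
  relapses <- sort_stream(relapses, "onset_date")
  mri <- sort_stream(mri, "date")
  treatments <- sort_stream(treatments, "start_date")

  n_dropped <- 0L
  if (drop_single_visit) {
    nv <- table(factor(visits$patient_id, levels = known))
    keep <- names(nv)[nv >= 2L]
    n_dropped <- length(known) - length(keep)
    patients <- patients[patients$patient_id %in% keep, , drop = FALSE]
    visits <- visits[visits$patient_id %in% keep, , drop = FALSE]
    relapses <- relapses[relapses$patient_id %in% keep, , drop = FALSE]
    mri <- mri[mri$patient_id %in% keep, , drop = FALSE]
    treatments <- treatments[treatments$patient_id %in% keep, , drop = FALSE]
  }

  # all event dates must be on or after birth
  birth <- setNames(patients$birth_date, patients$patient_id)
  for (spec in list(list(visits, "date"), list(relapses, "onset_date"),
                    list(mri, "date"), list(treatments, "start_date"))) {
    tbl <- spec[[1]]; col <- spec[[2]]
    if (nrow(tbl) && any(tbl[[col]] < birth[tbl$patient_id], na.rm = TRUE)) {
      stop(sprintf("event dates before birth_date in column %s", col),
           call. = FALSE)
    }
  }

  first_visit <- tapply(as.integer(visits$date), visits$patient_id, min)
  baseline <- data.frame(
    patient_id = patients$patient_id,
    baseline_date = as.Date(
      as.integer(first_visit[patients$patient_id]), origin = "1970-01-01"
    ),
    stringsAsFactors = FALSE
  )
  rownames(patients) <- rownames(visits) <- rownames(relapses) <- NULL
  rownames(mri) <- rownames(treatments) <- NULL

  out <- structure(
    list(patients = patients, visits = visits, relapses = relapses,
         mri = mri, treatments = treatments, baseline = baseline),
    class = "ptra_cohort"
  )
  attr(out, "n_dropped_single_visit") <- n_dropped
  out
}

#' Load a cohort from five delimited tables
#'
#' Reads the comma-delimited, headered tables of the cohort data model and
#' assembles a validated [as_cohort()] object. Rows with unparseable dates are
#' rejected with a row-level warning; a missing required column is an error
#' naming the column.
#'
#' @param patients_table,visits_table,relapses_table,mri_table,treatments_table
#'   paths to the five CSV files.
#' @param drop_single_visit see [as_cohort()].
#' @return A `ptra_cohort`.
#' @export
load_cohort <- function(patients_table, visits_table, relapses_table,
                        mri_table, treatments_table,
                        drop_single_visit = TRUE) {
  paths <- list(patients = patients_table, visits = visits_table,
                relapses = relapses_table, mri = mri_table,
                treatments = treatments_table)
  sch <- cohort_schemas()
  tabs <- lapply(names(paths), function(nm) {
    if (!file.exists(paths[[nm]])) {
      stop(sprintf("%s table: file not found: %s", nm, paths[[nm]]),
           call. = FALSE)
    }
    df <- read.csv(paths[[nm]], colClasses = "character",
                   check.names = FALSE, na.strings = "")
    check_schema(df, sch[[nm]], nm)
    parse_dates(df, date_column(nm), nm)
  })
  names(tabs) <- names(paths)
  as_cohort(tabs$patients, tabs$visits, tabs$relapses, tabs$mri,
            tabs$treatments, drop_single_visit = drop_single_visit)
}

#' Write a cohort back to five delimited tables
#'
#' Serializes a cohort so that `load_cohort(write_cohort(x))` reproduces `x`
#' field for field. Missing scores are written as empty cells.
#'
#' @param cohort a `ptra_cohort`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the five file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ptra_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in c("patients", "visits", "relapses", "mri", "treatments")) {
    df <- cohort[[nm]]
    df[[date_column(nm)]] <- format(df[[date_column(nm)]], "%Y-%m-%d")
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, path, row.names = FALSE, na = "", quote = TRUE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Age in years at a given date
#'
#' Exact day-count / 365.25 convention. Vectorized over both arguments.
#'
#' @param birth_date,date `Date` vectors; every `date` must be on or after the
#'   corresponding `birth_date`.
#' @return Numeric vector of ages in years.
#' @export
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date)) {
    stop("age_at(): date precedes birth_date", call. = FALSE)
  }
  as.numeric(date - birth_date) / 365.25
}

#' @export
print.ptra_cohort <- function(x, ...) {
  cat(sprintf(
    "<ptra_cohort> %d patients (%.1f%% female), %d visits, %d relapses, %d MRI findings, %d treatment starts\n",
    nrow(x$patients), 100 * mean(x$patients$sex == "F"), nrow(x$visits),
    nrow(x$relapses), nrow(x$mri), nrow(x$treatments)
  ))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `ptra_cohort`.
#' @return Integer patient count.
#' @export
cohort_size <- function(cohort) nrow(cohort$patients)
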