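# Data model and preprocessing for longitudinal coded EHR cohorts.
#
# A cohort is a list of patients; each patient carries an ordered sequence of
# hospital visits with ICD-9 diagnosis codes, DRG treatment codes, an
# admission type, admission/discharge timestamps and an in-hospital death
# flag. The preprocessing rules mirror the standard MIMIC-III-style cleaning
# pipeline: visit-count filtering, ICD-9 truncation, admission-type
# regrouping, inter-visit interval derivation and multi-hot encoding.

ADMISSION_TYPES <- c("ELECTIVE", "URGENT", "NEWBORN", "EMERGENCY")

new_patient <- function(patient_id, visits) {
  structure(list(patient_id = as.character(patient_id), visits = visits),
            class = "ehr_patient")
}

#' Construct a cohort from a list of patients
#'
#' @param patients list of `ehr_patient` objects.
#' @return an `ehr_cohort` object.
#' @keywords internal
new_cohort <- function(patients) {
  structure(list(patients = patients), class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  nv <- vapply(x$patients, function(p) nrow(p$visits), integer(1))
  died <- vapply(x$patients, function(p) any(p$visits$died_in_hospital),
                 logical(1))
  cat(sprintf("EHR cohort: %d patients, %d visits (%.2f per patient), %d deaths (%.1f%%)\n",
              length(x$patients), sum(nv), mean(nv), sum(died),
              100 * mean(died)))
  invisible(x)
}

#' @export
length.ehr_cohort <- function(x) length(x$patients)

parse_dt <- function(x, what, rows) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  todo <- nzchar(x)
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d")) {
    idx <- which(todo)
    if (!length(idx)) break
    p <- strptime(x[idx], fmt, tz = "UTC")   # NA on mismatch, never errors
    ok <- !is.na(p)
    out[idx[ok]] <- as.POSIXct(p[ok], tz = "UTC")
    todo[idx[ok]] <- FALSE
  }
  bad <- which(nzchar(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparsable datetime in %s at row %d: '%s'",
                 what, rows[bad[1]], x[bad[1]]), call. = FALSE)
  }
  out
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Load a cohort from MIMIC-III-style CSV tables
#'
#' Reads four comma-separated tables (admissions, diagnoses, DRG codes and
#' patients), groups rows into per-patient visit sequences ordered by
#' admission time, and derives the in-hospital death flag from the date of
#' death falling inside an admission (or an explicit expire flag). A living
#' patient is indicated by an empty/missing date of death.
#'
#' Expected columns:
#' \describe{
#'   \item{admissions}{`subject_id, hadm_id, admittime, dischtime,
#'     admission_type, hospital_expire_flag`}
#'   \item{diagnoses}{`hadm_id, icd9_code`}
#'   \item{drg}{`hadm_id, drg_code`}
#'   \item{patients}{`subject_id, dod`}
#' }
#' Datetimes are ISO-8601.
#'
#' @param admissions_path,diagnoses_path,drg_path,patients_path file paths.
#' @return an `ehr_cohort`.
#' @export
load_cohort_csv <- function(admissions_path, diagnoses_path, drg_path,
                            patients_path) {
  read1 <- function(p) utils::read.csv(p, colClasses = "character",
                                       check.names = TRUE)
  adm <- read1(admissions_path)
  dx  <- read1(diagnoses_path)
  drg <- read1(drg_path)
  pat <- read1(patients_path)

  check_columns(adm, c("subject_id", "hadm_id", "admittime", "dischtime",
                       "admission_type", "hospital_expire_flag"), "admissions")
  check_columns(dx, c("hadm_id", "icd9_code"), "diagnoses")
  check_columns(drg, c("hadm_id", "drg_code"), "drg")
  check_columns(pat, c("subject_id", "dod"), "patients")

  adm$admittime_p <- parse_dt(adm$admittime, "admissions$admittime",
                              seq_len(nrow(adm)))
  adm$dischtime_p <- parse_dt(adm$dischtime, "admissions$dischtime",
                              seq_len(nrow(adm)))

  bad_dx <- which(!dx$hadm_id %in% adm$hadm_id)
  if (length(bad_dx)) {
    stop(sprintf("diagnoses row %d references unknown hadm_id '%s'",
                 bad_dx[1], dx$hadm_id[bad_dx[1]]), call. = FALSE)
  }
  bad_drg <- which(!drg$hadm_id %in% adm$hadm_id)
  if (length(bad_drg)) {
    stop(sprintf("drg row %d references unknown hadm_id '%s'",
                 bad_drg[1], drg$hadm_id[bad_drg[1]]), call. = FALSE)
  }

  dod <- parse_dt(pat$dod, "patients$dod", seq_len(nrow(pat)))
  names(dod) <- pat$subject_id

  dx_by_hadm <- split(dx$icd9_code, dx$hadm_id)
  drg_by_hadm <- split(drg$drg_code, drg$hadm_id)

  patients <- lapply(split(adm, adm$subject_id), function(a) {
    a <- a[order(a$admittime_p), , drop = FALSE]
    pid <- a$subject_id[1]
    pdod <- if (pid %in% names(dod)) dod[[pid]] else as.POSIXct(NA)
    died <- (!is.na(pdod) & pdod >= a$admittime_p & pdod <= a$dischtime_p) |
      a$hospital_expire_flag %in% c("1", "TRUE", "true")
    visits <- data.frame(
      hadm_id = a$hadm_id,
      admit_time = a$admittime_p,
      discharge_time = a$dischtime_p,
      admission_type = toupper(a$admission_type),
      died_in_hospital = died,
      stringsAsFactors = FALSE
    )
    visits$dx  <- lapply(a$hadm_id, function(h)
      sort(unique(dx_by_hadm[[h]] %||% character(0))))
    visits$drg <- lapply(a$hadm_id, function(h)
      sort(unique(drg_by_hadm[[h]] %||% character(0))))
    new_patient(pid, visits)
  })
  new_cohort(unname(patients))
}

#' Write a cohort back to the CSV dialect
#'
#' Inverse of [load_cohort_csv()]: emits `admissions.csv`, `diagnoses.csv`,
#' `drg.csv` and `patients.csv` under `dir`. The date of death of a decedent
#' is written as the discharge time of the fatal visit, so a load/write/load
#' round trip preserves the encoded sequences.
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  adm <- dx <- drg <- pat <- list()
  for (p in cohort$patients) {
    v <- p$visits
    adm[[length(adm) + 1L]] <- data.frame(
      subject_id = p$patient_id, hadm_id = v$hadm_id,
      admittime = fmt(v$admit_time), dischtime = fmt(v$discharge_time),
      admission_type = v$admission_type,
      hospital_expire_flag = as.integer(v$died_in_hospital),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(v))) {
      if (length(v$dx[[i]]))
        dx[[length(dx) + 1L]] <- data.frame(hadm_id = v$hadm_id[i],
                                            icd9_code = v$dx[[i]])
      if (length(v$drg[[i]]))
        drg[[length(drg) + 1L]] <- data.frame(hadm_id = v$hadm_id[i],
                                              drg_code = v$drg[[i]])
    }
    death <- which(v$died_in_hospital)
    pat[[length(pat) + 1L]] <- data.frame(
      subject_id = p$patient_id,
      dod = if (length(death)) fmt(v$discharge_time[death[1]]) else "",
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, adm), file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dx), file.path(dir, "diagnoses.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, drg), file.path(dir, "drg.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pat), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Filter a cohort by visit count
#'
#' Retains exactly the patients with between `min_visits` and `max_visits`
#' hospitalisations. Patients with a single record carry no temporal signal;
#' patients with very long histories span decades of weakly related disease
#' evolution, so both tails are excluded.
#'
#' @param cohort an `ehr_cohort`.
#' @param min_visits,max_visits inclusive bounds on the retained visit count
#'   (defaults 2 and 10).
#' @param verbose log the number of patients removed per rule.
#' @return the filtered `ehr_cohort`.
#' @export
clean_cohort <- function(cohort, min_visits = 2L, max_visits = 10L,
                         verbose = FALSE) {
  nv <- vapply(cohort$patients, function(p) nrow(p$visits), integer(1))
  too_few <- nv < min_visits
  too_many <- nv > max_visits
  keep <- !(too_few | too_many)
  if (verbose) {
    message(sprintf("clean_cohort: removed %d patients with < %d visits, %d with > %d visits; %d retained",
                    sum(too_few), min_visits, sum(too_many), max_visits,
                    sum(keep)))
  }
  if (!any(keep)) stop("no patients survive filters", call. = FALSE)
  new_cohort(cohort$patients[keep])
}

#' Truncate an ICD-9 code to its category prefix
#'
#' Keeps the first `length` characters of each code (default 3), collapsing
#' detailed codes onto their three-character disease category to curb
#' vocabulary size and overfitting. Vectorised.
#'
#' @param code character vector of ICD-9 codes.
#' @param length prefix length to keep.
#' @return character vector of truncated codes.
#' @examples
#' truncate_icd9("42831")  # "428"
#' truncate_icd9("V1006")  # "V10"
#' @export
truncate_icd9 <- function(code, length = 3L) {
  if (any(!nzchar(code)) || any(is.na(code))) {
    stop("ICD-9 codes must be non-empty strings", call. = FALSE)
  }
  substr(code, 1L, length)
}

#' Apply ICD-9 truncation across a cohort
#'
#' @param cohort an `ehr_cohort`.
#' @param length prefix length passed to [truncate_icd9()].
#' @return the cohort with truncated, deduplicated diagnosis code sets.
#' @export
truncate_cohort_codes <- function(cohort, length = 3L) {
  cohort$patients <- lapply(cohort$patients, function(p) {
    p$visits$dx <- lapply(p$visits$dx, function(cs)
      sort(unique(truncate_icd9(cs, length))))
    p
  })
  cohort
}

#' Regroup a raw admission type into the admission-type weight m
#'
#' The four raw admission types are regrouped into emergency (EMERGENCY,
#' URGENT) and non-emergency (ELECTIVE, NEWBORN). The returned weight enters
#' the model as 1/m on the input gate and additively in the harmonic weight,
#' so emergency admissions (m = 1) carry more weight than non-emergency ones
#' (m = 2).
#'
#' @param raw_label character vector of raw admission types
#'   (case-insensitive).
#' @param emergency_m,nonemergency_m the weights assigned to the two groups.
#' @return integer vector of m values.
#' @export
regroup_admission_type <- function(raw_label, emergency_m = 1L,
                                   nonemergency_m = 2L) {
  lab <- toupper(raw_label)
  unknown <- setdiff(unique(lab), ADMISSION_TYPES)
  if (length(unknown)) {
    stop(sprintf("unknown admission type(s): %s (accepted: %s)",
                 paste(unknown, collapse = ", "),
                 paste(ADMISSION_TYPES, collapse = ", ")), call. = FALSE)
  }
  ifelse(lab %in% c("EMERGENCY", "URGENT"), emergency_m, nonemergency_m)
}

days_between <- function(later, earlier) {
  floor(as.numeric(difftime(later, earlier, units = "days")))
}

#' Inter-visit intervals for one patient
#'
#' `delta_prev[t]` is the gap in whole days between visit t's admission and
#' visit t-1's discharge (0 for the first visit; negative raw gaps from
#' overlapping admissions are clamped to 0). `delta_to_last[t]` is the number
#' of days between visit t's admission and the final discharge.
#'
#' @param patient an `ehr_patient`.
#' @return list with numeric vectors `delta_prev` and `delta_to_last`.
#' @export
compute_intervals <- function(patient) {
  v <- patient$visits
  if (is.unsorted(v$admit_time)) {
    stop(sprintf("visits of patient %s are not ordered by admission time",
                 patient$patient_id), call. = FALSE)
  }
  T_ <- nrow(v)
  delta_prev <- numeric(T_)
  if (T_ > 1) {
    delta_prev[-1] <- pmax(0, days_between(v$admit_time[-1],
                                           v$discharge_time[-T_]))
  }
  delta_to_last <- pmax(0, days_between(v$discharge_time[T_], v$admit_time))
  list(delta_prev = delta_prev, delta_to_last = delta_to_last)
}

#' Build a code vocabulary from a cohort
#'
#' Collects the distinct diagnosis or DRG codes of a cleaned cohort into a
#' deterministic (lexicographically sorted) indexed vocabulary.
#'
#' @param cohort an `ehr_cohort`.
#' @param kind `"diagnosis"` or `"drg"`.
#' @return a `code_vocab`: list with `kind`, `codes` (ordered) and `index`
#'   (named integer map, 1-based).
#' @export
build_vocab <- function(cohort, kind = c("diagnosis", "drg")) {
  kind <- match.arg(kind)
  if (!length(cohort$patients)) stop("empty cohort", call. = FALSE)
  field <- if (kind == "diagnosis") "dx" else "drg"
  codes <- sort(unique(unlist(lapply(cohort$patients,
                                     function(p) unlist(p$visits[[field]])))))
  index <- seq_along(codes)
  names(index) <- codes
  structure(list(kind = kind, codes = codes, index = index),
            class = "code_vocab")
}

#' @export
print.code_vocab <- function(x, ...) {
  cat(sprintf("code vocabulary (%s): %d codes\n", x$kind, length(x$codes)))
  invisible(x)
}

#' Encode a cohort into multi-hot sequence matrices
#'
#' Each patient becomes an encoded sequence holding, for its T visits: the
#' T x |D| multi-hot diagnosis matrix `x`, the T x |L| DRG matrix `p`, the
#' admission-type weights `m` (1 = emergency, 2 = non-emergency), the
#' inter-visit gaps `delta_prev`, the admission-to-final-discharge gaps
#' `delta_to_last`, the per-visit death labels `y` (1 only on a fatal final
#' visit), a `mask` of real (non-padded) steps, and the admission/discharge
#' day offsets from the first admission used for per-prefix recency weights.
#'
#' Out-of-vocabulary codes are dropped with a single summary warning; a visit
#' left without any in-vocabulary diagnosis code is an error.
#'
#' @param cohort an `ehr_cohort` (cleaned).
#' @param vocab_dx,vocab_drg `code_vocab` objects built from (a superset of)
#'   the cohort.
#' @return list of encoded sequences, one per patient.
#' @export
encode_sequences <- function(cohort, vocab_dx, vocab_drg) {
  stopifnot(inherits(vocab_dx, "code_vocab"), inherits(vocab_drg, "code_vocab"))
  n_oov <- 0L
  seqs <- lapply(cohort$patients, function(p) {
    v <- p$visits
    T_ <- nrow(v)
    x <- matrix(0, T_, length(vocab_dx$codes))
    pm <- matrix(0, T_, length(vocab_drg$codes))
    for (t in seq_len(T_)) {
      ids <- vocab_dx$index[intersect(v$dx[[t]], vocab_dx$codes)]
      n_oov <<- n_oov + length(setdiff(v$dx[[t]], vocab_dx$codes))
      if (!length(ids)) {
        stop(sprintf("visit %s of patient %s has no in-vocabulary diagnosis codes",
                     v$hadm_id[t], p$patient_id), call. = FALSE)
      }
      x[t, ids] <- 1
      gids <- vocab_drg$index[intersect(v$drg[[t]], vocab_drg$codes)]
      n_oov <<- n_oov + length(setdiff(v$drg[[t]], vocab_drg$codes))
      if (length(gids)) pm[t, gids] <- 1
    }
    iv <- compute_intervals(p)
    list(
      patient_id = p$patient_id,
      x = x, p = pm,
      m = regroup_admission_type(v$admission_type),
      delta_prev = iv$delta_prev,
      delta_to_last = iv$delta_to_last,
      y = as.integer(v$died_in_hospital),
      mask = rep(TRUE, T_),
      admit_day = days_between(v$admit_time, v$admit_time[1]),
      discharge_day = days_between(v$discharge_time, v$admit_time[1])
    )
  })
  if (n_oov > 0) {
    warning(sprintf("dropped %d out-of-vocabulary code occurrences", n_oov),
            call. = FALSE)
  }
  seqs
}
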