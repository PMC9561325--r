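# Cohort loading, cleaning and encoding rules.

test_that("ICD-9 truncation keeps the category prefix", {
  expect_equal(truncate_icd9("42831"), "428")
  expect_equal(truncate_icd9("V1006"), "V10")
  expect_equal(truncate_icd9("496"), "496")
  expect_equal(truncate_icd9(c("25000", "4280"), length = 4), c("2500", "4280"))
  expect_error(truncate_icd9(""), "non-empty")
})

test_that("admission types regroup into emergency/non-emergency weights", {
  expect_equal(regroup_admission_type("URGENT"), 1L)
  expect_equal(regroup_admission_type("EMERGENCY"), 1L)
  expect_equal(regroup_admission_type("NEWBORN"), 2L)
  expect_equal(regroup_admission_type("elective"), 2L)
  expect_error(regroup_admission_type("DAYCASE"), "accepted")
})

test_that("visit-count filter retains exactly 2..10 visits and is idempotent", {
  co <- make_fixture_cohort()
  nv <- vapply(co$patients, function(p) nrow(p$visits), integer(1))
  expect_true(any(nv == 1) && any(nv == 11))   # fixture covers both tails
  cleaned <- clean_cohort(co)
  nv2 <- vapply(cleaned$patients, function(p) nrow(p$visits), integer(1))
  expect_true(all(nv2 >= 2 & nv2 <= 10))
  expect_equal(length(cleaned$patients), sum(nv >= 2 & nv <= 10))
  again <- clean_cohort(cleaned)
  expect_equal(again, cleaned)
  only_single <- co
  only_single$patients <- co$patients[nv == 1]
  expect_error(clean_cohort(only_single), "no patients")
})

test_that("intervals are day-valued, clamped and zero on the first visit", {
  co <- make_fixture_cohort()
  # p3 has overlapping admissions: visit 3 admits 3 days before visit 2 ends
  p3 <- co$patients[[3]]
  iv <- compute_intervals(p3)
  expect_equal(iv$delta_prev[1], 0)
  expect_true(all(iv$delta_prev >= 0))
  expect_equal(iv$delta_prev[3], 0)            # clamped negative gap
  expect_equal(iv$delta_prev[2], floor(as.numeric(difftime(
    p3$visits$admit_time[2], p3$visits$discharge_time[1], units = "days"))))
  expect_true(all(iv$delta_to_last >= 0))
  expect_equal(iv$delta_to_last[3],
               floor(as.numeric(difftime(p3$visits$discharge_time[3],
                                         p3$visits$admit_time[3],
                                         units = "days"))))
  bad <- p3
  bad$visits <- bad$visits[c(2, 1, 3), ]
  expect_error(compute_intervals(bad), "ordered")
})

test_that("vocabularies are deduplicated, sorted and kind-partitioned", {
  co <- clean_cohort(make_fixture_cohort())
  v_dx <- build_vocab(co, "diagnosis")
  v_drg <- build_vocab(co, "drg")
  expect_equal(v_dx$codes, sort(unique(v_dx$codes)))
  expect_false(any(v_dx$codes %in% v_drg$codes))
  expect_equal(unname(v_dx$index[v_dx$codes]), seq_along(v_dx$codes))
  # deterministic across rebuilds
  expect_identical(build_vocab(co, "diagnosis"), v_dx)
})

test_that("encoding produces multi-hot rows, m weights and death labels", {
  co <- clean_cohort(make_fixture_cohort())
  v_dx <- build_vocab(co, "diagnosis")
  v_drg <- build_vocab(co, "drg")
  seqs <- encode_sequences(co, v_dx, v_drg)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    p <- co$patients[[i]]
    counts <- vapply(p$visits$dx, function(cs)
      length(intersect(unique(cs), v_dx$codes)), integer(1))
    expect_equal(unname(rowSums(s$x)), as.numeric(counts))
    expect_true(all(s$x %in% c(0, 1)))
    expect_true(all(s$m %in% c(1L, 2L)))
  }
  # death label sits on the final visit of the decedent (fixture patient S2)
  s2 <- seqs[[which(vapply(seqs, `[[`, "", "patient_id") == "S2")]]
  expect_equal(s2$y, c(0L, 1L))
  survivors <- seqs[vapply(seqs, `[[`, "", "patient_id") != "S2"]
  expect_true(all(vapply(survivors, function(s) all(s$y == 0), logical(1))))
})

test_that("out-of-vocabulary codes warn; empty visits error", {
  co <- clean_cohort(make_fixture_cohort())
  v_dx <- build_vocab(co, "diagnosis")
  v_drg <- build_vocab(co, "drg")
  extra <- make_fixture_cohort()
  extra$patients <- extra$patients[c(2, 3)]
  extra$patients[[1]]$visits$dx[[1]] <- c("42831", "ZZZ9")  # OOV code
  expect_warning(encode_sequences(extra, v_dx, v_drg), "out-of-vocabulary")
  bad <- extra
  bad$patients[[1]]$visits$dx[[1]] <- "ZZZ9"                # all OOV
  expect_error(suppressWarnings(encode_sequences(bad, v_dx, v_drg)),
               "no in-vocabulary")
})

test_that("CSV round trip preserves the encoded sequences", {
  co <- clean_cohort(make_fixture_cohort())
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  co2 <- load_cohort_csv(file.path(dir, "admissions.csv"),
                         file.path(dir, "diagnoses.csv"),
                         file.path(dir, "drg.csv"),
                         file.path(dir, "patients.csv"))
  v_dx <- build_vocab(co, "diagnosis"); v_drg <- build_vocab(co, "drg")
  s1 <- encode_sequences(co, v_dx, v_drg)
  ord <- order(vapply(co2$patients, `[[`, "", "patient_id"))
  co2$patients <- co2$patients[ord]
  ord1 <- order(vapply(co$patients, `[[`, "", "patient_id"))
  s1 <- s1[ord1]
  s2 <- encode_sequences(co2, v_dx, v_drg)
  expect_equal(s2, s1)
})

test_that("loader errors are specific", {
  co <- clean_cohort(make_fixture_cohort())
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  adm <- read.csv(file.path(dir, "admissions.csv"))
  # missing column
  write.csv(adm[, -3], file.path(dir, "bad_adm.csv"), row.names = FALSE)
  expect_error(load_cohort_csv(file.path(dir, "bad_adm.csv"),
                               file.path(dir, "diagnoses.csv"),
                               file.path(dir, "drg.csv"),
                               file.path(dir, "patients.csv")),
               "missing required column")
  # diagnosis row pointing to an unknown admission
  dx <- read.csv(file.path(dir, "diagnoses.csv"), colClasses = "character")
  dx$hadm_id[1] <- "NOPE"
  write.csv(dx, file.path(dir, "bad_dx.csv"), row.names = FALSE)
  expect_error(load_cohort_csv(file.path(dir, "admissions.csv"),
                               file.path(dir, "bad_dx.csv"),
                               file.path(dir, "drg.csv"),
                               file.path(dir, "patients.csv")),
               "unknown hadm_id")
  # unparsable datetime names the row
  adm2 <- read.csv(file.path(dir, "admissions.csv"), colClasses = "character")
  adm2$admittime[2] <- "not-a-date"
  write.csv(adm2, file.path(dir, "bad_dt.csv"), row.names = FALSE)
  expect_error(load_cohort_csv(file.path(dir, "bad_dt.csv"),
                               file.path(dir, "diagnoses.csv"),
                               file.path(dir, "drg.csv"),
                               file.path(dir, "patients.csv")),
               "row 2")
})

test_that("a living patient (null DOD) has no death flags", {
  co <- clean_cohort(make_fixture_cohort())
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  co2 <- load_cohort_csv(file.path(dir, "admissions.csv"),
                         file.path(dir, "diagnoses.csv"),
                         file.path(dir, "drg.csv"),
                         file.path(dir, "patients.csv"))
  s3 <- co2$patients[[which(vapply(co2$patients, `[[`, "", "patient_id") == "S3")]]
  expect_false(any(s3$visits$died_in_hospital))
})
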