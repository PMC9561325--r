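# Synthetic longitudinal EHR cohorts.
#
# The generator produces abstract-token cohorts with the statistical
# structure the model assumes: short varying-length visit sequences with a
# long-tailed inter-visit gap distribution, multi-code visits drawn from
# comorbidity blocks of co-occurring codes, emergency/non-emergency admission
# types, and a death label on the final visit driven by a logistic model on
# the number of lethal codes the patient accumulated. Codes are tokens (D001,
# G001, ...), not real ICD-9/DRG semantics.

#' Configuration for the synthetic cohort generator
#'
#' Defaults scale the real-data statistics the model targets down to desk
#' size: visit counts follow a truncated geometric on \[2, 10\] with mean
#' 2.57, visits carry about 8 distinct diagnosis codes from a 100-code
#' vocabulary (and ~2 DRG codes from 50), diagnosis codes co-occur in four
#' comorbidity blocks, inter-visit gaps are log-normal with median ~55 days,
#' and the death mechanism is a Bernoulli on the final visit with
#' logit = `baseline_logit + lethal_effect * #distinct lethal codes present`.
#'
#' @param n_patients number of patients to simulate.
#' @param visit_mean target mean of the truncated-geometric visit-count
#'   distribution on `[min_visits, max_visits]`.
#' @param min_visits,max_visits visit-count support (defaults 2 and 10).
#' @param n_dx_codes,n_drg_codes vocabulary sizes.
#' @param comorbidity_blocks list of integer index sets of co-occurring
#'   diagnosis codes; default four disjoint blocks of 20 over codes 1..80.
#' @param block_prob probability that a sampled code is drawn from the
#'   patient's own comorbidity block rather than the whole vocabulary.
#' @param codes_per_visit_mean,drg_per_visit_mean mean distinct code counts
#'   per visit (Poisson, floored at 1).
#' @param lethal_codes diagnosis code indices that raise mortality risk;
#'   default the last 8 codes, outside the comorbidity blocks.
#' @param high_risk_prob probability that a patient belongs to the
#'   high-burden subgroup that accumulates lethal codes frequently; models
#'   patient-level heterogeneity in chronic disease burden.
#' @param lethal_prev_high,lethal_prev_low per-visit inclusion probability of
#'   each lethal code for high-burden and low-burden patients.
#' @param baseline_logit,lethal_effect parameters of the death model
#'   (log-odds scale).
#' @param gap_lognormal `c(meanlog, sdlog)` of inter-visit day gaps.
#' @param los_lognormal `c(meanlog, sdlog)` of length-of-stay in days.
#' @param emergency_prob per-visit probability of an emergency-group
#'   admission type.
#' @param seed integer seed; a fixed seed yields a byte-identical cohort.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 500L,
                         visit_mean = 2.57,
                         min_visits = 2L, max_visits = 10L,
                         n_dx_codes = 100L, n_drg_codes = 50L,
                         comorbidity_blocks = lapply(0:3, function(b) b * 20L + 1:20),
                         block_prob = 0.8,
                         codes_per_visit_mean = 8,
                         drg_per_visit_mean = 2,
                         lethal_codes = (n_dx_codes - 7L):n_dx_codes,
                         high_risk_prob = 0.5,
                         lethal_prev_high = 0.25,
                         lethal_prev_low = 0.02,
                         baseline_logit = -2.5,
                         lethal_effect = 1.5,
                         gap_lognormal = c(meanlog = 4, sdlog = 1),
                         los_lognormal = c(meanlog = 1.5, sdlog = 0.5),
                         emergency_prob = 0.7,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (codes_per_visit_mean > n_dx_codes || drg_per_visit_mean > n_drg_codes) {
    stop("codes_per_visit_mean exceeds vocabulary size", call. = FALSE)
  }
  stopifnot(block_prob >= 0, block_prob <= 1,
            emergency_prob >= 0, emergency_prob <= 1,
            visit_mean > min_visits, visit_mean < max_visits,
            all(unlist(comorbidity_blocks) <= n_dx_codes),
            all(lethal_codes >= 1), all(lethal_codes <= n_dx_codes))
  structure(cfg, class = "synth_config")
}

# Success probability of a geometric truncated to [lo, hi] matching a target
# mean; solved by root finding on the closed-form truncated mean.
truncated_geom_prob <- function(mean_target, lo = 2L, hi = 10L) {
  support <- lo:hi
  mean_at <- function(q) {
    w <- (1 - q)^(support - lo) * q
    sum(support * w) / sum(w)
  }
  stats::uniroot(function(q) mean_at(q) - mean_target,
                 interval = c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

sample_visit_counts <- function(n, mean_target, lo = 2L, hi = 10L) {
  q <- truncated_geom_prob(mean_target, lo, hi)
  support <- lo:hi
  w <- (1 - q)^(support - lo) * q
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

dx_token <- function(i) sprintf("D%03d", i)
drg_token <- function(i) sprintf("G%03d", i)

#' Generate a synthetic cohort
#'
#' Simulates `config$n_patients` patients under [synth_config()]. Visit code
#' sets mix the patient's comorbidity block with background codes; death can
#' occur only on the final visit (the record ends with death), with
#' probability `plogis(baseline_logit + lethal_effect * k)` where k is the
#' number of distinct lethal codes across the patient's visits.
#'
#' @param config a `synth_config`.
#' @return an `ehr_cohort` consumable by [encode_sequences()].
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    n_blocks <- length(config$comorbidity_blocks)
    patients <- lapply(seq_len(config$n_patients), function(i) {
      T_ <- sample_visit_counts(1, config$visit_mean, config$min_visits,
                                config$max_visits)
      block <- config$comorbidity_blocks[[sample.int(n_blocks, 1)]]
      gaps <- stats::rlnorm(T_ - 1, config$gap_lognormal[["meanlog"]],
                            config$gap_lognormal[["sdlog"]])
      los <- pmax(0.25, stats::rlnorm(T_, config$los_lognormal[["meanlog"]],
                                      config$los_lognormal[["sdlog"]]))
      admit <- numeric(T_)
      for (t in seq_len(T_)[-1]) admit[t] <- admit[t - 1] + los[t - 1] + gaps[t - 1]
      base <- as.POSIXct("2100-01-01 12:00:00", tz = "UTC")
      admit_time <- base + admit * 86400
      discharge_time <- admit_time + los * 86400

      high_risk <- stats::runif(1) < config$high_risk_prob
      lethal_prev <- if (high_risk) config$lethal_prev_high else
        config$lethal_prev_low
      dxs <- lapply(seq_len(T_), function(t) {
        k <- max(1L, stats::rpois(1, config$codes_per_visit_mean))
        from_block <- stats::runif(k) < config$block_prob
        idx <- integer(k)
        idx[from_block] <- sample(block, sum(from_block), replace = TRUE)
        idx[!from_block] <- sample.int(config$n_dx_codes, sum(!from_block),
                                       replace = TRUE)
        lethal <- config$lethal_codes[stats::runif(length(config$lethal_codes)) <
                                        lethal_prev]
        sort(unique(dx_token(c(idx, lethal))))
      })
      drgs <- lapply(seq_len(T_), function(t) {
        k <- max(1L, stats::rpois(1, config$drg_per_visit_mean))
        sort(unique(drg_token(sample.int(config$n_drg_codes, k,
                                         replace = TRUE))))
      })

      n_lethal <- length(intersect(unlist(dxs),
                                   dx_token(config$lethal_codes)))
      p_die <- stats::plogis(config$baseline_logit +
                               config$lethal_effect * n_lethal)
      died <- logical(T_)
      died[T_] <- stats::runif(1) < p_die

      emergency <- stats::runif(T_) < config$emergency_prob
      atype <- ifelse(emergency,
                      sample(c("EMERGENCY", "URGENT"), T_, replace = TRUE),
                      sample(c("ELECTIVE", "NEWBORN"), T_, replace = TRUE))

      visits <- data.frame(
        hadm_id = sprintf("H%06d", i * 100L + seq_len(T_)),
        admit_time = admit_time,
        discharge_time = discharge_time,
        admission_type = atype,
        died_in_hospital = died,
        stringsAsFactors = FALSE
      )
      visits$dx <- dxs
      visits$drg <- drgs
      new_patient(sprintf("P%05d", i), visits)
    })
    new_cohort(patients)
  })
}

#' Tiny deterministic fixture cohort
#'
#' A hand-written cohort of six patients exercising the preprocessing edge
#' cases: a single-visit patient and an eleven-visit patient (both removed by
#' [clean_cohort()]), overlapping admissions (negative raw gap), a code that
#' becomes out-of-vocabulary after cleaning, full-length ICD-9 codes
#' (including a V-code) for the truncation rule, all four admission types,
#' and one in-hospital death on a final visit.
#'
#' @return an `ehr_cohort`.
#' @export
make_fixture_cohort <- function() {
  dt <- function(s) as.POSIXct(s, tz = "UTC")
  pid_counter <- 0L
  mk_visits <- function(admit, discharge, type, died, dx, drg) {
    pid_counter <<- pid_counter + 1L
    v <- data.frame(hadm_id = sprintf("F%d%03d", pid_counter,
                                      seq_along(admit)),
                    admit_time = dt(admit), discharge_time = dt(discharge),
                    admission_type = type, died_in_hospital = died,
                    stringsAsFactors = FALSE)
    v$dx <- dx
    v$drg <- drg
    v
  }

  # single-visit patient: removed by cleaning; carries code 9999 seen nowhere
  # else, so it is out-of-vocabulary for a vocab built on the cleaned cohort
  p1 <- new_patient("S1", mk_visits(
    "2100-01-01 08:00:00", "2100-01-05 12:00:00", "EMERGENCY", FALSE,
    list(c("42831", "9999")), list("101")))

  # two visits, death on the final one; V-code tests truncation
  p2 <- new_patient("S2", mk_visits(
    c("2100-02-01 09:00:00", "2100-03-20 10:00:00"),
    c("2100-02-10 10:00:00", "2100-03-28 16:00:00"),
    c("ELECTIVE", "EMERGENCY"), c(FALSE, TRUE),
    list(c("42831", "V1006"), c("42822", "496")), list("101", "202")))

  # three visits with overlapping admissions: visit 3 admits before visit 2
  # discharges (negative raw gap, clamped to 0)
  p3 <- new_patient("S3", mk_visits(
    c("2100-04-01 08:00:00", "2100-05-10 08:00:00", "2100-05-12 08:00:00"),
    c("2100-04-06 12:00:00", "2100-05-15 12:00:00", "2100-05-20 12:00:00"),
    c("URGENT", "NEWBORN", "EMERGENCY"), c(FALSE, FALSE, FALSE),
    list("41401", c("41401", "4280"), "4280"), list("202", "202", "303")))

  # eleven visits: removed by cleaning
  adm <- sprintf("2100-%02d-01 08:00:00", 1:11)
  dis <- sprintf("2100-%02d-03 08:00:00", 1:11)
  p4 <- new_patient("S4", mk_visits(
    adm, dis, rep("EMERGENCY", 11), rep(FALSE, 11),
    rep(list("25000"), 11), rep(list("404"), 11)))

  # ten visits: exactly at the retention boundary
  adm <- sprintf("2100-%02d-05 08:00:00", 1:10)
  dis <- sprintf("2100-%02d-07 08:00:00", 1:10)
  p5 <- new_patient("S5", mk_visits(
    adm, dis, rep(c("ELECTIVE", "URGENT"), 5), rep(FALSE, 10),
    rep(list(c("25000", "4280")), 10), rep(list("404"), 10)))

  # survivor with a long gap between visits
  p6 <- new_patient("S6", mk_visits(
    c("2100-01-10 08:00:00", "2101-01-10 08:00:00"),
    c("2100-01-15 08:00:00", "2101-01-20 08:00:00"),
    c("NEWBORN", "EMERGENCY"), c(FALSE, FALSE),
    list("V3000", c("V3000", "769")), list("505", "505")))

  new_cohort(list(p1, p2, p3, p4, p5, p6))
}
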