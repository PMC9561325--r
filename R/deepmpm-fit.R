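# User-facing model interface: fit a DeepMPM mortality-risk model on a
# cohort and interrogate it with the usual S3 verbs.

#' Prepare a cohort for modelling
#'
#' Optionally applies the visit-count filter, builds the diagnosis and DRG
#' vocabularies and encodes every patient into multi-hot sequence matrices.
#' ICD-9 truncation is deliberately left to [truncate_cohort_codes()], since
#' synthetic cohorts use abstract tokens.
#'
#' @param cohort an `ehr_cohort`.
#' @param clean apply [clean_cohort()] first.
#' @return list with `seqs`, `vocab_dx`, `vocab_drg` and `cohort` (the
#'   cleaned cohort).
#' @export
deepmpm_prepare <- function(cohort, clean = TRUE) {
  if (clean) cohort <- clean_cohort(cohort)
  vocab_dx <- build_vocab(cohort, "diagnosis")
  vocab_drg <- build_vocab(cohort, "drg")
  seqs <- encode_sequences(cohort, vocab_dx, vocab_drg)
  list(seqs = seqs, vocab_dx = vocab_dx, vocab_drg = vocab_drg,
       cohort = cohort)
}

# Initial parameters, optionally with skip-gram-pretrained embedding weights.
init_params_for <- function(cohort, vocab_dx, vocab_drg, config) {
  params <- deepmpm_params(length(vocab_dx$codes), length(vocab_drg$codes),
                           config$d, config$hidden_alpha, config$hidden_beta,
                           seed = config$seed)
  if (config$pretrain) {
    params$emb_x$W <- unname(pretrain_code_embeddings(
      cohort, "diagnosis", config$d, config$pretrain_epochs,
      config$pretrain_negatives, seed = config$seed, vocab = vocab_dx))
    if (length(vocab_drg$codes) >= 2) {
      params$emb_p$W <- unname(pretrain_code_embeddings(
        cohort, "drg", config$d, config$pretrain_epochs,
        config$pretrain_negatives, seed = config$seed + 1L, vocab = vocab_drg))
    }
  }
  params
}

#' Fit a DeepMPM mortality-risk model
#'
#' The full pipeline: visit-count cleaning, vocabulary construction,
#' multi-hot encoding, optional skip-gram pretraining of the code
#' embeddings, and end-to-end mini-batch training of the Care-LSTM
#' attention model under the configured protocol.
#'
#' @param cohort an `ehr_cohort` (e.g. from [load_cohort_csv()] or
#'   [generate_cohort()]).
#' @param config a [deepmpm_config()].
#' @param clean apply the visit-count filter before fitting.
#' @param verbose print per-epoch training loss.
#' @return a fitted `deepmpm` object with components `params`, `config`,
#'   `vocab_dx`, `vocab_drg`, `log` (training trace) and `call`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_patients = 60, seed = 7))
#' cfg <- deepmpm_config(d = 8, hidden_alpha = 8, hidden_beta = 8,
#'                       epochs = 2, batch_size = 20, seed = 7)
#' fit <- deepmpm(cohort, cfg)
#' predict(fit, cohort)[1:3, ]
#' @export
deepmpm <- function(cohort, config = deepmpm_config(), clean = TRUE,
                    verbose = FALSE) {
  prep <- deepmpm_prepare(cohort, clean = clean)
  params0 <- init_params_for(prep$cohort, prep$vocab_dx, prep$vocab_drg,
                             config)
  fit <- train_deepmpm(prep$seqs, config, params = params0,
                       verbose = verbose)
  structure(list(params = fit$params, config = config, log = fit$log,
                 vocab_dx = prep$vocab_dx, vocab_drg = prep$vocab_drg,
                 n_patients = length(prep$seqs),
                 call = match.call()),
            class = "deepmpm")
}

#' @export
print.deepmpm <- function(x, ...) {
  cat("DeepMPM mortality-risk model\n")
  cat(sprintf("  %d patients, %d diagnosis codes, %d DRG codes\n",
              x$n_patients, length(x$vocab_dx$codes),
              length(x$vocab_drg$codes)))
  cat(sprintf("  embedding dim %d, hidden %d/%d, %s\n", x$config$d,
              x$config$hidden_alpha, x$config$hidden_beta,
              if (x$config$ablate_beta) "visit-level attention only"
              else "two-level attention"))
  cat(sprintf("  trained %d epochs; final loss %.5f\n",
              nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.deepmpm <- function(object, cohort = NULL, ...) {
  print(object)
  if (!is.null(cohort)) {
    seqs <- encode_sequences(clean_cohort(cohort), object$vocab_dx,
                             object$vocab_drg)
    ev <- deepmpm_evaluate(object, seqs)
    cat("evaluation on supplied cohort:\n")
    print(ev)
    return(invisible(ev))
  }
  invisible(object)
}

#' @export
coef.deepmpm <- function(object, ...) object$params

#' Predict mortality risk for new patients
#'
#' @param object a fitted `deepmpm`.
#' @param newdata an `ehr_cohort` or a list of encoded sequences compatible
#'   with the model's vocabularies.
#' @param type `"risk"` for the patient-level death probability (final
#'   prefix), `"class"` for the thresholded 0/1 call, `"prefix"` for the
#'   full per-visit risk trajectories (a list).
#' @param threshold decision threshold for `type = "class"`.
#' @param ... unused.
#' @return a data.frame (`risk`/`class`) or a named list (`prefix`).
#' @export
predict.deepmpm <- function(object, newdata,
                            type = c("risk", "class", "prefix"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  seqs <- if (inherits(newdata, "ehr_cohort")) {
    encode_sequences(newdata, object$vocab_dx, object$vocab_drg)
  } else newdata
  fws <- lapply(seqs, deepmpm_forward, params = object$params,
                ablate_beta = object$config$ablate_beta,
                scales = object$config$scales)
  ids <- vapply(fws, `[[`, "", "patient_id")
  if (type == "prefix") {
    return(stats::setNames(lapply(fws, `[[`, "risk"), ids))
  }
  risk <- vapply(fws, function(f) f$risk[length(f$risk)], numeric(1))
  out <- data.frame(patient_id = ids, risk = risk)
  if (type == "class") out$class <- as.integer(risk >= threshold)
  out
}

#' @export
plot.deepmpm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
       ylab = "regularised loss", main = "training loss", ...)
  plot(x$log$epoch, x$log$eta, type = "l", xlab = "epoch",
       ylab = expression(eta), main = "learning rate (STLR)", ...)
  invisible(x)
}

#' Attention-based interpretability report for one patient
#'
#' Emits, for each visit, its visit-level attention weight and, for each
#' active diagnosis code, a variable-level relevance score. The per-code
#' score projects the visit's variable-level weights onto the code's
#' embedding column (`sum(beta_t * W_xemb[, c])`) and normalises within the
#' visit by the sum of absolute scores; this projection is a reporting
#' convention, since the variable-level weights live in embedding space
#' rather than code space. Negative scores suggest suppression, positive
#' synergy.
#'
#' @param object a fitted `deepmpm`.
#' @param cohort an `ehr_cohort` containing the patient.
#' @param patient_id the patient to explain.
#' @return data.frame with columns `visit`, `visit_weight`, `code`,
#'   `code_weight`.
#' @export
deepmpm_explain <- function(object, cohort, patient_id) {
  idx <- which(vapply(cohort$patients, `[[`, "", "patient_id") == patient_id)
  if (!length(idx)) stop(sprintf("patient %s not found", patient_id),
                         call. = FALSE)
  sub <- new_cohort(cohort$patients[idx])
  seq <- encode_sequences(sub, object$vocab_dx, object$vocab_drg)[[1]]
  fw <- deepmpm_forward(seq, object$params, object$config$ablate_beta,
                        object$config$scales)
  rows <- list()
  for (t in seq_len(nrow(seq$x))) {
    active <- which(seq$x[t, ] == 1)
    raw <- vapply(active, function(c)
      sum(fw$beta[t, ] * object$params$emb_x$W[, c]), numeric(1))
    norm <- sum(abs(raw))
    wts <- if (norm > 0) raw / norm else raw
    rows[[t]] <- data.frame(visit = t, visit_weight = fw$alpha[t],
                            code = object$vocab_dx$codes[active],
                            code_weight = wts)
  }
  do.call(rbind, rows)
}

#' Code-code correlation matrices of a fitted model
#'
#' @param object a fitted `deepmpm`.
#' @return list with `Corr_x` (diagnoses) and `Corr_p` (DRGs), each from
#'   [code_correlation_matrix()] of the trained embedding weights.
#' @export
deepmpm_correlations <- function(object) {
  Wx <- object$params$emb_x$W
  colnames(Wx) <- object$vocab_dx$codes
  Wp <- object$params$emb_p$W
  colnames(Wp) <- object$vocab_drg$codes
  list(Corr_x = code_correlation_matrix(Wx),
       Corr_p = code_correlation_matrix(Wp))
}

#' Export correlation matrices as tables and heatmaps
#'
#' Writes, for each code family, a long-format table
#' (`code_i, code_j, corr`) and a PNG heatmap of the code-code correlation
#' matrix of the trained embeddings.
#'
#' @param object a fitted `deepmpm`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_correlations <- function(object, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cc <- deepmpm_correlations(object)
  for (nm in names(cc)) {
    Corr <- cc[[nm]]
    pairs <- which(upper.tri(Corr, diag = TRUE), arr.ind = TRUE)
    tab <- data.frame(code_i = rownames(Corr)[pairs[, 1]],
                      code_j = colnames(Corr)[pairs[, 2]],
                      corr = Corr[pairs])
    utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
    grDevices::png(file.path(dir, paste0(nm, ".png")), width = 900,
                   height = 900)
    Corr0 <- Corr
    Corr0[is.na(Corr0)] <- 0
    stats::heatmap(Corr0, symm = TRUE, scale = "none", main = nm,
                   col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Save / load a model checkpoint
#'
#' Serialises every named parameter array plus the vocabularies and the
#' configuration to a single JSON file (requires the `jsonlite` package).
#'
#' @param object a fitted `deepmpm`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `deepmpm` object (load).
#' @export
deepmpm_save <- function(object, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for checkpoints", call. = FALSE)
  }
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  payload <- list(params = strip(object$params),
                  config = unclass(object$config),
                  vocab_dx = object$vocab_dx$codes,
                  vocab_drg = object$vocab_drg$codes,
                  log = object$log, n_patients = object$n_patients)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname deepmpm_save
#' @export
deepmpm_load <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for checkpoints", call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(deepmpm_config, raw$config[names(raw$config) %in%
                                              names(formals(deepmpm_config))])
  n_dx <- length(raw$vocab_dx)
  n_drg <- length(raw$vocab_drg)
  params <- deepmpm_params(n_dx, n_drg, cfg$d, cfg$hidden_alpha,
                           cfg$hidden_beta, init = "zero")
  restore <- function(target, src) {
    for (nm in names(src)) {
      if (is.list(target[[nm]]) && is.list(src[[nm]])) {
        target[[nm]] <- restore(target[[nm]], src[[nm]])
      } else if (is.matrix(target[[nm]])) {
        target[[nm]] <- if (is.matrix(src[[nm]])) {
          matrix(as.numeric(src[[nm]]), nrow(target[[nm]]),
                 ncol(target[[nm]]))
        } else {
          # list of rows from non-simplified JSON
          matrix(unlist(src[[nm]]), nrow(target[[nm]]), ncol(target[[nm]]),
                 byrow = TRUE)
        }
      } else if (is.double(target[[nm]])) {
        target[[nm]] <- as.numeric(unlist(src[[nm]]))
      }
    }
    target
  }
  params <- restore(params, raw$params)
  mkvocab <- function(kind, codes) {
    idx <- seq_along(codes); names(idx) <- codes
    structure(list(kind = kind, codes = codes, index = idx),
              class = "code_vocab")
  }
  structure(list(params = params, config = cfg,
                 log = as.data.frame(raw$log),
                 vocab_dx = mkvocab("diagnosis", raw$vocab_dx),
                 vocab_drg = mkvocab("drg", raw$vocab_drg),
                 n_patients = raw$n_patients, call = NULL),
            class = "deepmpm")
}
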