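# Training protocol and evaluation: the per-visit cross-entropy loss,
# slanted triangular learning-rate schedule, Adadelta with elastic-net
# regularisation and dropout, mini-batch training, metrics, stratified
# cross-validation and hard-positive-example collection.

#' Training configuration
#'
#' Defaults follow the published protocol: batch size 80, 100 epochs,
#' Adadelta with decay 0.1, L1 + L2 regularisation at 1e-4, dropout keep
#' probability 0.8 on the pooled health-status vector, STLR with
#' cut_frac 0.1, ratio 32 and maximum rate 0.1, and five-fold stratified
#' cross-validation.
#'
#' @param d embedding dimension.
#' @param hidden_alpha,hidden_beta Care-LSTM state sizes.
#' @param batch_size mini-batch size.
#' @param epochs passes over the training set.
#' @param adadelta_rho Adadelta decay coefficient.
#' @param adadelta_eps Adadelta stability constant. Also sets the scale of
#'   the optimiser's first steps (`sqrt(eps)` before the rate multiplier),
#'   i.e. how fast the accumulators leave their warm-up; the default suits
#'   schedules of a few hundred iterations.
#' @param reg_l1,reg_l2 regularisation coefficients (weights only, biases
#'   excluded).
#' @param dropout_keep keep probability of the dropout on `h_bar` at train
#'   time (1 disables dropout).
#' @param grad_clip elementwise ceiling on each mini-batch gradient entry
#'   (`Inf` disables). The pooled average's denominator can come arbitrarily
#'   close to zero when visit weights cancel, which produces occasional
#'   extreme gradient entries; clipping keeps them from derailing the
#'   optimiser.
#' @param stlr_cut_frac,stlr_ratio,stlr_eta_max schedule parameters; the
#'   total iteration count is `epochs * ceil(N / batch_size)`.
#' @param cv_folds folds for [deepmpm_cv()].
#' @param ablate_beta train the variant without variable-level attention.
#' @param pretrain initialise embeddings by intra-visit skip-gram.
#' @param pretrain_epochs,pretrain_negatives skip-gram settings.
#' @param scales Care-LSTM time-scale divisors in days.
#' @param seed master RNG seed for initialisation, batching and dropout.
#' @return a `deepmpm_config` list.
#' @export
deepmpm_config <- function(d = 32L, hidden_alpha = 64L, hidden_beta = 64L,
                           batch_size = 80L, epochs = 100L,
                           adadelta_rho = 0.1, adadelta_eps = 1e-3,
                           reg_l1 = 1e-4, reg_l2 = 1e-4,
                           dropout_keep = 0.8,
                           grad_clip = 5,
                           stlr_cut_frac = 0.1, stlr_ratio = 32,
                           stlr_eta_max = 0.1,
                           cv_folds = 5L, ablate_beta = FALSE,
                           pretrain = TRUE, pretrain_epochs = 3L,
                           pretrain_negatives = 5L,
                           scales = c(60, 180, 365), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$adadelta_rho > 0, cfg$adadelta_rho < 1,
            cfg$dropout_keep > 0, cfg$dropout_keep <= 1,
            cfg$stlr_cut_frac > 0, cfg$stlr_cut_frac < 1,
            cfg$stlr_ratio > 1, cfg$stlr_eta_max > 0)
  structure(cfg, class = "deepmpm_config")
}

#' Per-visit cross-entropy loss
#'
#' Mean over patients of the per-patient mean over visits of binary
#' cross-entropy between the prefix predictions and the per-visit death
#' labels. Predictions are clipped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param predictions list (one element per patient) of per-visit death
#'   probabilities.
#' @param labels list of matching 0/1 label vectors.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  per_patient <- mapply(function(yhat, y) {
    stopifnot(length(yhat) == length(y))
    yhat <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
    mean(-(y * log(yhat) + (1 - y) * log(1 - yhat)))
  }, predictions, labels)
  mean(per_patient)
}

#' Slanted triangular learning rate
#'
#' Linear warm-up from `eta_max / ratio` to `eta_max` over the first
#' `cut = T_total * cut_frac` iterations, then linear decay back to
#' `eta_max / ratio` at `t = T_total`.
#'
#' @param t iteration index in `[0, T_total]`.
#' @param T_total total number of training iterations.
#' @param cut_frac fraction of iterations in the rising segment.
#' @param ratio ratio between the maximum and minimum rate.
#' @param eta_max peak learning rate.
#' @return the learning rate at iteration t.
#' @export
stlr_schedule <- function(t, T_total, cut_frac = 0.1, ratio = 32,
                          eta_max = 0.1) {
  if (any(t < 0) || any(t > T_total)) {
    stop("t must lie in [0, T_total]", call. = FALSE)
  }
  cut <- T_total * cut_frac
  p <- ifelse(t < cut, t / cut, 1 - (t - cut) / (cut * (1 / cut_frac - 1)))
  eta_max * (1 + p * (ratio - 1)) / ratio
}

map_grad_leaves <- function(g, f, path = "") {
  if (is.list(g)) {
    for (nm in names(g)) g[[nm]] <- map_grad_leaves(g[[nm]], f,
                                                    paste0(path, "$", nm))
    g
  } else {
    f(g, path)
  }
}

#' One Adadelta update
#'
#' Standard Adadelta accumulator updates with decay `rho`, the proposed step
#' additionally scaled by the current learning rate `lr` (from
#' [stlr_schedule()]).
#'
#' @param params nested parameter list (e.g. `deepmpm_params`).
#' @param grads gradient list mirroring the learnable leaves of `params`.
#' @param state optimiser state (`NULL` on the first call).
#' @param rho decay coefficient in (0, 1).
#' @param lr learning-rate multiplier.
#' @param eps stability constant.
#' @return list with updated `params` and `state`.
#' @export
adadelta_step <- function(params, grads, state = NULL, rho = 0.1, lr = 1,
                          eps = 1e-3) {
  stopifnot(rho > 0, rho < 1)
  if (is.null(state)) {
    zero <- map_grad_leaves(grads, function(g, p) g * 0)
    state <- list(Eg2 = zero, Edx2 = zero)
  }
  update <- function(p, g, eg2, edx2, path) {
    if (is.list(g)) {
      for (nm in names(g)) {
        res <- update(p[[nm]], g[[nm]], eg2[[nm]], edx2[[nm]],
                      paste0(path, "$", nm))
        p[[nm]] <- res$p; eg2[[nm]] <- res$eg2; edx2[[nm]] <- res$edx2
      }
      return(list(p = p, eg2 = eg2, edx2 = edx2))
    }
    if (any(!is.finite(g))) {
      stop(sprintf("non-finite gradient for parameter %s", path),
           call. = FALSE)
    }
    eg2 <- rho * eg2 + (1 - rho) * g^2
    dx <- -sqrt(edx2 + eps) / sqrt(eg2 + eps) * g
    edx2 <- rho * edx2 + (1 - rho) * dx^2
    list(p = p + lr * dx, eg2 = eg2, edx2 = edx2)
  }
  res <- update(params, grads, state$Eg2, state$Edx2, "")
  # restore classes lost through list surgery
  attributes(res$p) <- attributes(params)
  list(params = res$p, state = list(Eg2 = res$eg2, Edx2 = res$edx2))
}

is_bias_leaf <- function(path) {
  leaf <- sub(".*\\$", "", path)
  leaf == "b" || startsWith(leaf, "b_")
}

#' Elastic-net regularised loss
#'
#' Adds `l1 * sum(|w|) + l2 * sum(w^2)` over the weight matrices (biases
#' excluded) to a data loss.
#'
#' @param loss scalar data loss.
#' @param params nested parameter list.
#' @param l1,l2 regularisation coefficients.
#' @return the regularised loss.
#' @export
apply_regularization <- function(loss, params, l1 = 1e-4, l2 = 1e-4) {
  penalty <- 0
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(path, "$", nm))
    } else if (is.double(x) && !is_bias_leaf(path)) {
      penalty <<- penalty + l1 * sum(abs(x)) + l2 * sum(x^2)
    }
    invisible(NULL)
  }
  walk(unclass(params), "")
  loss + penalty
}

# Values of `params` restricted to the learnable leaves of a gradient mirror.
grad_leaves_values <- function(params, grads) {
  if (is.list(grads)) {
    out <- lapply(names(grads), function(nm)
      grad_leaves_values(params[[nm]], grads[[nm]]))
    names(out) <- names(grads)
    out
  } else {
    params
  }
}

# Gradient of the elastic-net penalty, mirroring the gradient structure.
regularization_gradients <- function(params, l1, l2) {
  leaves <- grad_leaves_values(params, zero_like_deepmpm(params))
  map_grad_leaves(leaves, function(w, path) {
    if (is_bias_leaf(path)) w * 0 else l1 * sign(w) + l2 * 2 * w
  })
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

# Elementwise gradient clipping: caps each entry at +/- `clip`, so the few
# coordinates hit by a near-singular pooling denominator cannot dominate the
# batch direction while the remaining coordinates keep their signal.
clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  map_grad_leaves(grads, function(g, path) pmin(pmax(g, -clip), clip))
}

sample_dropout_masks <- function(seqs, d, keep) {
  if (keep >= 1) return(NULL)
  lapply(seqs, function(s) {
    lapply(seq_len(nrow(s$x)), function(i)
      (stats::runif(d) < keep) / keep)
  })
}

#' Train DeepMPM on encoded sequences
#'
#' Mini-batch Adadelta with the slanted triangular learning-rate schedule,
#' elastic-net regularisation on the weights and dropout on the pooled
#' health-status vector. All randomness (batch order, dropout) flows from
#' `config$seed`; a fixed seed yields an identical checkpoint.
#'
#' @param seqs list of encoded sequences (see [encode_sequences()]).
#' @param config a [deepmpm_config()].
#' @param params initial `deepmpm_params`; drawn from `config$seed` when
#'   missing.
#' @param n_dx,n_drg vocabulary sizes (required when `params` is missing).
#' @param verbose print per-epoch loss.
#' @return list with `params` (trained), `log` (data.frame of epoch, mean
#'   regularised batch loss, final learning rate of the epoch) and `config`.
#' @export
train_deepmpm <- function(seqs, config = deepmpm_config(), params = NULL,
                          n_dx = NULL, n_drg = NULL, verbose = FALSE) {
  labels <- vapply(seqs, function(s) max(s$y), numeric(1))
  if (length(unique(labels)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (is.null(params)) {
    params <- deepmpm_params(n_dx, n_drg, config$d, config$hidden_alpha,
                             config$hidden_beta, seed = config$seed)
  }
  N <- length(seqs)
  batches_per_epoch <- ceiling(N / config$batch_size)
  T_total <- config$epochs * batches_per_epoch
  state <- NULL
  log <- data.frame(epoch = integer(0), loss = numeric(0), eta = numeric(0))

  with_local_seed(config$seed + 1L, {
    iter <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      epoch_loss <- 0
      eta <- NA_real_
      for (b in seq_len(batches_per_epoch)) {
        idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, N)]
        batch <- seqs[idx]
        masks <- sample_dropout_masks(batch, config$d, config$dropout_keep)
        lg <- deepmpm_loss(batch, params, config$ablate_beta, config$scales,
                           dropout_masks = masks, with_grads = TRUE)
        grads <- add_grads(clip_grads(lg$grads, config$grad_clip),
                           regularization_gradients(params, config$reg_l1,
                                                    config$reg_l2))
        eta <- stlr_schedule(iter, T_total, config$stlr_cut_frac,
                             config$stlr_ratio, config$stlr_eta_max)
        upd <- adadelta_step(params, grads, state, config$adadelta_rho, eta,
                             config$adadelta_eps)
        params <- upd$params
        state <- upd$state
        iter <- iter + 1
        epoch_loss <- epoch_loss +
          apply_regularization(lg$loss, params, config$reg_l1, config$reg_l2)
      }
      log <- rbind(log, data.frame(epoch = ep,
                                   loss = epoch_loss / batches_per_epoch,
                                   eta = eta))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  eta %.5f", ep,
                        epoch_loss / batches_per_epoch, eta))
      }
    }
  })
  list(params = params, log = log, config = config)
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return area under the ROC curve.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: scores contain a single class", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate patient-level mortality predictions
#'
#' Scores each patient by the final-visit (full-sequence) prefix prediction,
#' thresholds at `threshold` for the confusion matrix and computes
#' precision, recall, F1 and rank-based AUC.
#'
#' @param params a `deepmpm_params` (or a fitted `deepmpm` model).
#' @param seqs list of encoded sequences.
#' @param threshold decision threshold for the confusion counts.
#' @param ablate_beta evaluate the beta-ablated forward pass.
#' @param scales time-scale divisors.
#' @return a `deepmpm_eval` list with `auc`, `precision`, `recall`, `f1`,
#'   the confusion counts and the per-patient `scores`/`labels`.
#' @export
deepmpm_evaluate <- function(params, seqs, threshold = 0.5,
                             ablate_beta = FALSE, scales = c(60, 180, 365)) {
  if (inherits(params, "deepmpm")) {
    ablate_beta <- params$config$ablate_beta
    scales <- params$config$scales
    params <- params$params
  }
  out <- vapply(seqs, function(s) {
    fw <- deepmpm_forward(s, params, ablate_beta, scales)
    T_ <- length(fw$risk)
    c(fw$risk[T_], fw$logit[T_])
  }, numeric(2))
  labels <- vapply(seqs, function(s) max(s$y), numeric(1))
  eval_from_scores(out[1, ], labels, threshold,
                   ids = vapply(seqs, `[[`, "", "patient_id"),
                   ranking = out[2, ])
}

# `ranking` is an optional monotone transform of `scores` used for the AUC
# (e.g. log-odds, which do not saturate to exact ties the way clipped
# probabilities do); the confusion matrix always thresholds `scores`.
eval_from_scores <- function(scores, labels, threshold = 0.5, ids = NULL,
                             ranking = scores) {
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  TN <- sum(pred == 0 & labels == 0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(auc = auc_rank(ranking, labels),
                 precision = precision, recall = recall, f1 = f1,
                 TP = TP, FP = FP, FN = FN, TN = TN,
                 scores = scores, labels = labels, ids = ids),
            class = "deepmpm_eval")
}

#' @export
print.deepmpm_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$auc, x$precision, x$recall, x$f1))
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

# Stratified fold assignment at the patient level (prevents leakage of a
# patient's prefixes across folds).
make_folds <- function(labels, k, seed) {
  if (length(labels) < k) stop("fewer patients than folds", call. = FALSE)
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified cross-validation on encoded sequences
#'
#' Splits patients into label-stratified folds, trains on k-1 folds and
#' evaluates on the held-out fold, optionally repeating with reshuffled
#' folds. Also tracks, per positive patient, how often it was misclassified
#' across its test appearances (input to [collect_hard_positives()]).
#'
#' @param seqs list of encoded sequences.
#' @param config a [deepmpm_config()].
#' @param repeats number of repetitions with different fold assignments.
#' @param params_fn optional function(train_seqs, config) returning initial
#'   parameters (e.g. with pretrained embeddings); defaults to a fresh draw.
#' @param n_dx,n_drg vocabulary sizes for the default initialisation.
#' @return a `deepmpm_cv` list: `folds` (per-fold `deepmpm_eval`s),
#'   `summary` (mean and sd of each metric) and `history` (per-patient test
#'   appearances and misclassification counts).
#' @export
deepmpm_cv <- function(seqs, config = deepmpm_config(), repeats = 1L,
                       params_fn = NULL, n_dx = NULL, n_drg = NULL) {
  labels <- vapply(seqs, function(s) max(s$y), numeric(1))
  ids <- vapply(seqs, `[[`, "", "patient_id")
  appearances <- stats::setNames(rep(0L, length(seqs)), ids)
  misclassified <- appearances
  folds_out <- list()

  for (rep_i in seq_len(repeats)) {
    fold <- make_folds(labels, config$cv_folds,
                       seed = config$seed + 1000L * rep_i)
    for (k in seq_len(config$cv_folds)) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      cfg_k <- config
      cfg_k$seed <- config$seed + 1000L * rep_i + k
      params0 <- if (is.null(params_fn)) NULL else
        params_fn(seqs[train_idx], cfg_k)
      fit <- train_deepmpm(seqs[train_idx], cfg_k, params = params0,
                           n_dx = n_dx, n_drg = n_drg)
      ev <- deepmpm_evaluate(fit$params, seqs[test_idx],
                             ablate_beta = config$ablate_beta,
                             scales = config$scales)
      folds_out[[length(folds_out) + 1L]] <- ev
      appearances[test_idx] <- appearances[test_idx] + 1L
      wrong <- (ev$scores >= 0.5) != (ev$labels == 1)
      misclassified[test_idx] <- misclassified[test_idx] + as.integer(wrong)
    }
  }

  metric <- function(f) vapply(folds_out, `[[`, numeric(1), f)
  summary <- data.frame(
    metric = c("auc", "precision", "recall", "f1"),
    mean = vapply(c("auc", "precision", "recall", "f1"),
                  function(f) mean(metric(f)), numeric(1)),
    sd = vapply(c("auc", "precision", "recall", "f1"),
                function(f) stats::sd(metric(f)), numeric(1))
  )
  history <- data.frame(patient_id = ids, label = labels,
                        appearances = as.integer(appearances),
                        misclassified = as.integer(misclassified))
  structure(list(folds = folds_out, summary = summary, history = history),
            class = "deepmpm_cv")
}

#' @export
print.deepmpm_cv <- function(x, ...) {
  cat(sprintf("cross-validation over %d fold fits\n", length(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f ± %.4f (sd over folds)\n",
                s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Collect hard positive examples
#'
#' Positive (deceased) patients misclassified in strictly more than half of
#' their test appearances across repeated cross-validation.
#'
#' @param history the `history` data.frame from [deepmpm_cv()].
#' @return character vector of patient ids (possibly empty).
#' @export
collect_hard_positives <- function(history) {
  pos <- history[history$label == 1 & history$appearances > 0, , drop = FALSE]
  pos$patient_id[pos$misclassified > pos$appearances / 2]
}
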