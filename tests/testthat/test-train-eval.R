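# Loss closed forms, schedule, optimiser, regularisation, metrics,
# cross-validation bookkeeping and hard-example collection.

test_that("cross-entropy loss closed forms", {
  # uniform predictions: loss = ln 2
  expect_equal(cross_entropy_loss(list(c(0.5, 0.5), 0.5),
                                  list(c(0L, 1L), 1L)), log(2))
  # perfect predictions: essentially zero
  expect_lt(cross_entropy_loss(list(c(1e-7, 1 - 1e-7)), list(c(0L, 1L))),
            1e-6)
  # hand-evaluated single patient, two visits
  expect_equal(cross_entropy_loss(list(c(0.9, 0.8)), list(c(1L, 1L))),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  # clipping guards the logs instead of erroring
  expect_true(is.finite(cross_entropy_loss(list(c(0, 1)), list(c(1L, 0L)))))
})

test_that("STLR rises to eta_max at cut and decays to eta_max/ratio", {
  Tt <- 100
  eta <- function(t) stlr_schedule(t, Tt, cut_frac = 0.1, ratio = 32,
                                   eta_max = 0.1)
  expect_equal(eta(10), 0.1)                 # peak at cut = T * cut_frac
  expect_equal(eta(0), 0.1 / 32)
  expect_equal(eta(Tt), 0.1 / 32)
  # piecewise linear: exact midpoints, continuity at the cut
  expect_equal(eta(5), (eta(0) + eta(10)) / 2)
  expect_equal(eta(55), (eta(10) + eta(100)) / 2)
  expect_equal(eta(10 - 1e-9), eta(10), tolerance = 1e-6)
  ts <- seq(0, Tt, by = 0.5)
  vals <- vapply(ts, eta, numeric(1))
  expect_equal(which.max(vals), which(ts == 10))
  expect_error(stlr_schedule(-1, Tt), "must lie")
  expect_error(stlr_schedule(101, Tt), "must lie")
})

test_that("Adadelta matches a hand-rolled scalar recurrence", {
  rho <- 0.3; eps <- 1e-6
  p <- list(w = 1)
  g <- list(w = 0.5)                          # constant gradient
  st <- NULL
  Eg2 <- 0; Edx2 <- 0; w <- 1
  for (k in 1:3) {
    res <- adadelta_step(p, g, st, rho = rho, lr = 1, eps = eps)
    p <- res$params; st <- res$state
    Eg2 <- rho * Eg2 + (1 - rho) * 0.5^2
    dx <- -sqrt(Edx2 + eps) / sqrt(Eg2 + eps) * 0.5
    Edx2 <- rho * Edx2 + (1 - rho) * dx^2
    w <- w + dx
    expect_equal(p$w, w, tolerance = 1e-12)
  }
  # zero gradient leaves parameters untouched
  res0 <- adadelta_step(list(w = 2), list(w = 0), NULL, rho = 0.3)
  expect_equal(res0$params$w, 2)
  expect_error(adadelta_step(list(w = 1), list(w = NaN), NULL, rho = 0.3),
               "non-finite gradient for parameter \\$w")
})

test_that("elastic-net regularisation adds l1+l2 over weights only", {
  p <- list(layer = list(W = matrix(2), b_hidden = 5))
  expect_equal(apply_regularization(1, p), 1 + 1e-4 * (2 + 4))
  expect_equal(apply_regularization(0, list(W = matrix(0))), 0)
  # pure-L1 penalty is homogeneous of degree one
  p1 <- list(W = matrix(c(1, -2)))
  p2 <- list(W = matrix(c(2, -4)))
  expect_equal(apply_regularization(0, p2, l1 = 1e-4, l2 = 0),
               2 * apply_regularization(0, p1, l1 = 1e-4, l2 = 0))
})

test_that("metric identities hold on a toy confusion matrix", {
  ev <- deepmpm:::eval_from_scores(c(.9, .8, .7, .6, .1, .2, .3),
                                   c(1, 1, 1, 0, 1, 0, 0))
  expect_equal(c(ev$TP, ev$FP, ev$FN), c(3, 1, 1))
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f1, 0.75)
  expect_equal(ev$f1,
               2 * ev$precision * ev$recall / (ev$precision + ev$recall),
               tolerance = 1e-12)
})

test_that("rank AUC: separation, chance level, and pROC agreement", {
  expect_equal(auc_rank(c(.1, .2, .8, .9), c(0, 0, 1, 1)), 1)
  expect_error(auc_rank(c(.1, .2), c(1, 1)), "single class")
  set.seed(33)
  n <- 10000
  sc <- runif(n); lb <- rbinom(n, 1, 0.5)      # independent scores
  expect_lt(abs(auc_rank(sc, lb) - 0.5), 0.02)
  skip_if_not_installed("pROC")
  set.seed(34)
  sc2 <- runif(200); lb2 <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb2, sc2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(sc2, lb2), ref, tolerance = 1e-12)
})

test_that("training is deterministic and reduces the loss on strong signal", {
  co <- generate_cohort(synth_config(n_patients = 80, lethal_effect = 3,
                                     seed = 41))
  prep <- deepmpm_prepare(co)
  cfg <- deepmpm_config(d = 8, hidden_alpha = 8, hidden_beta = 8,
                        epochs = 6, batch_size = 40, stlr_eta_max = 1,
                        pretrain = FALSE, seed = 41)
  f1 <- train_deepmpm(prep$seqs, cfg, n_dx = length(prep$vocab_dx$codes),
                      n_drg = length(prep$vocab_drg$codes))
  f2 <- train_deepmpm(prep$seqs, cfg, n_dx = length(prep$vocab_dx$codes),
                      n_drg = length(prep$vocab_drg$codes))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log, f2$log)
  expect_lt(f1$log$loss[nrow(f1$log)], f1$log$loss[1])
  # single-class training set is refused
  pos <- prep$seqs[vapply(prep$seqs, function(s) max(s$y) == 1, logical(1))]
  expect_error(train_deepmpm(pos, cfg), "single class")
})

test_that("cross-validation partitions patients and tracks test appearances", {
  co <- generate_cohort(synth_config(n_patients = 60, seed = 43))
  prep <- deepmpm_prepare(co)
  cfg <- deepmpm_config(d = 6, hidden_alpha = 6, hidden_beta = 6,
                        epochs = 2, batch_size = 30, cv_folds = 5,
                        pretrain = FALSE, seed = 43)
  cv <- deepmpm_cv(prep$seqs, cfg, repeats = 2,
                   n_dx = length(prep$vocab_dx$codes),
                   n_drg = length(prep$vocab_drg$codes))
  expect_length(cv$folds, 10)
  expect_true(all(cv$history$appearances == 2))
  expect_true(all(cv$history$misclassified <= cv$history$appearances))
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"],
               mean(vapply(cv$folds, `[[`, numeric(1), "auc")))
  expect_error(deepmpm_cv(prep$seqs[1:3], cfg), "fewer patients")
})

test_that("held-out AUC grows with the lethal-code effect size", {
  # scaled-down recovery runs (smaller cohort and model, short schedule),
  # averaged over three generator seeds; the no-signal runs use fair-coin
  # labels (baseline 0) so chance AUC is estimated on a balanced test set
  auc_at <- function(effect, seed) {
    cfg <- deepmpm_config(d = 16, hidden_alpha = 32, hidden_beta = 32,
                          epochs = 8, stlr_eta_max = 1, pretrain = FALSE,
                          seed = seed)
    signal_recovery_run(seed, lethal_effect = effect, n_patients = 800,
                        config = cfg,
                        baseline_logit = if (effect == 0) 0 else NULL)$auc
  }
  aucs <- vapply(c(0, 1, 3), function(eff)
    mean(vapply(71:73, function(s) auc_at(eff, s), numeric(1))), numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(abs(aucs[1] - 0.5), 0.05)
  expect_gt(aucs[3], 0.8)
})

test_that("the beta-ablated variant also recovers a strong signal", {
  r <- signal_recovery_run(121, lethal_effect = 3, ablate_beta = TRUE)
  expect_gt(r$auc, 0.85)
})

test_that("hard positives use the strict-majority rule", {
  hist <- data.frame(
    patient_id = c("a", "b", "c", "d", "e"),
    label = c(1, 1, 1, 0, 1),
    appearances = c(4, 4, 4, 4, 0),
    misclassified = c(3, 2, 0, 4, 0)
  )
  expect_equal(collect_hard_positives(hist), "a")  # 3/4 in, 2/4 out
  none <- hist[hist$label == 0, ]
  expect_equal(collect_hard_positives(none), character(0))
})
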