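# Shared experiment harness for the heavier validation tests.
#
# The signal-recovery experiments train on 2,000-patient synthetic cohorts
# with the reference model sizes (d = 32, hidden 64); the schedule is 15
# epochs at peak rate 1 — the desk-scale setting documented in the methods
# vignette. A quarter of the patients are held out.

recovery_config <- function(seed, epochs = 15, ablate_beta = FALSE,
                            pretrain = FALSE) {
  deepmpm_config(epochs = epochs, seed = seed, stlr_eta_max = 1,
                 pretrain = pretrain, ablate_beta = ablate_beta)
}

# train/test split + fit + held-out evaluation on one generated cohort;
# null-effect runs use baseline_logit = 0 (fair-coin labels) so the chance
# AUC is estimated from a balanced test set
signal_recovery_run <- function(seed, lethal_effect, n_patients = 2000,
                                epochs = 15, ablate_beta = FALSE,
                                pretrain = FALSE, config = NULL,
                                baseline_logit = NULL) {
  scfg <- if (is.null(baseline_logit)) {
    synth_config(n_patients = n_patients, lethal_effect = lethal_effect,
                 seed = seed)
  } else {
    synth_config(n_patients = n_patients, lethal_effect = lethal_effect,
                 baseline_logit = baseline_logit, seed = seed)
  }
  co <- generate_cohort(scfg)
  prep <- deepmpm_prepare(co)
  n <- length(prep$seqs)
  test_idx <- deepmpm:::with_local_seed(seed + 500L, sample(n, round(n / 4)))
  cfg <- config %||% recovery_config(seed, epochs, ablate_beta, pretrain)
  params0 <- deepmpm:::init_params_for(prep$cohort, prep$vocab_dx,
                                       prep$vocab_drg, cfg)
  fit <- train_deepmpm(prep$seqs[-test_idx], cfg, params = params0)
  ev <- deepmpm_evaluate(fit$params, prep$seqs[test_idx],
                         ablate_beta = cfg$ablate_beta)
  list(auc = ev$auc, eval = ev, fit = fit, prep = prep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
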