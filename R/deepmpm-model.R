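# Model assembly: two-level attention, harmonic recency weighting, pooled
# health-status vector and the two-class risk head.
#
# A patient's risk after visit i is computed from the prefix of visits 1..i:
# the visit-level attention softmax, the harmonic weights and the pooled
# health-status vector are all recomputed on that prefix, so the per-visit
# labels of the training loss are well defined and predictions at visit i
# never depend on later visits.

POOL_EPS <- 1e-8

# The pooled average can produce extreme values when the combined visit
# weights nearly cancel in some dimension; the head sees a clamped copy so a
# handful of near-singular denominators cannot saturate the risk output.
# The reported health-status vector stays the exact weighted average.
HBAR_CLAMP <- 10

#' Parameters of the two-level attention module
#'
#' @param p hidden size of the visit-level (alpha) Care-LSTM.
#' @param q hidden size of the variable-level (beta) Care-LSTM.
#' @param d embedding dimension.
#' @param init `"glorot"` or `"zero"`.
#' @param beta_zero_init start the variable-level projection at zero
#'   (default). With `W_beta = 0` the combined weights are proportional to
#'   `r * alpha`, so the freshly initialised model coincides with the
#'   beta-ablated variant — the weighted average is invariant to the overall
#'   weight scale — and the variable-level attention grows from zero only
#'   where the data support it. This also avoids sign cancellation in the
#'   pooling denominator early in training.
#' @return an `attention_params` list with `W_alpha` (length p), `b_alpha`
#'   (scalar), `W_beta` (d x q) and `b_beta` (length d).
#' @export
attention_params <- function(p, q, d, init = c("glorot", "zero"),
                             beta_zero_init = TRUE) {
  init <- match.arg(init)
  structure(list(
    W_alpha = if (init == "zero") numeric(p) else drop(glorot(p, 1L)),
    b_alpha = 0,
    W_beta = if (init == "zero" || beta_zero_init) matrix(0, d, q) else
      glorot(d, q),
    b_beta = numeric(d),
    p = as.integer(p), q = as.integer(q), d = as.integer(d)
  ), class = "attention_params")
}

#' Parameters of the risk head
#'
#' A fully connected layer from the pooled health-status vector to two
#' logits (discharged, death) followed by softmax.
#'
#' @param d input dimension.
#' @param init `"glorot"` or `"zero"`.
#' @return a `head_params` list with `W` (2 x d) and `b` (length 2).
#' @export
head_params <- function(d, init = c("glorot", "zero")) {
  init <- match.arg(init)
  structure(list(W = if (init == "zero") matrix(0, 2L, d) else glorot(2L, d),
                 b = numeric(2L), d = as.integer(d)),
            class = "head_params")
}

#' Visit-level attention weights
#'
#' Scalar scores `W_alpha' g_t + b_alpha` are normalised by a softmax taken
#' across the (unmasked) visits of a patient, so the weights compare visits
#' against each other.
#'
#' @param G T x p matrix of alpha-LSTM hidden states (rows = visits).
#' @param params an `attention_params`.
#' @param mask length-T logical; masked positions receive weight 0.
#' @return length-T vector of non-negative weights summing to 1 over
#'   unmasked visits.
#' @export
visit_attention <- function(G, params, mask = rep(TRUE, nrow(G))) {
  if (!any(mask)) stop("all visits are masked", call. = FALSE)
  s <- drop(G %*% params$W_alpha) + params$b_alpha
  alpha <- numeric(nrow(G))
  alpha[mask] <- softmax(s[mask])
  alpha
}

#' Variable-level attention weights
#'
#' `tanh(W_beta e_t + b_beta)`: a per-dimension weight in \[-1, 1\] for one
#' visit. Negative entries indicate a suppression relation between diseases
#' and treatments, positive entries a synergistic effect.
#'
#' @param e_t beta-LSTM hidden state (length q).
#' @param params an `attention_params`.
#' @return length-d vector in \[-1, 1\].
#' @export
variable_attention <- function(e_t, params) {
  if (length(e_t) != params$q) {
    stop("hidden-state length does not match W_beta", call. = FALSE)
  }
  tanh(drop(params$W_beta %*% e_t) + params$b_beta)
}

#' Harmonic recency weight
#'
#' `r_t = 1 / (m_t + log(1 + delta))` with the natural logarithm, where
#' `delta` is the number of days between visit t's admission and the last
#' discharge. Down-weights non-emergency (m = 2) and long-ago visits.
#'
#' @param m_t admission-type weight (>= 1).
#' @param delta_to_last non-negative day gap.
#' @return scalar in (0, 1].
#' @export
harmonic_weight <- function(m_t, delta_to_last) {
  if (any(delta_to_last < 0)) stop("delta_to_last must be >= 0", call. = FALSE)
  if (any(m_t < 1)) stop("m_t must be >= 1", call. = FALSE)
  1 / (m_t + log1p(delta_to_last))
}

#' Combine the attention levels into the final visit weights
#'
#' `w_t = r_t * (alpha_t + beta_t) / 2`, with the scalar `alpha_t` broadcast
#' across the d dimensions; in the beta-ablated variant `w_t = r_t * alpha_t`.
#'
#' @param alpha length-T visit weights.
#' @param beta T x d variable weights (ignored when `ablate_beta`).
#' @param r length-T harmonic weights.
#' @param ablate_beta drop the variable-level attention.
#' @return T x d weight matrix.
#' @export
combine_weights <- function(alpha, beta, r, ablate_beta = FALSE) {
  T_ <- length(alpha)
  if (length(r) != T_ || (!ablate_beta && nrow(beta) != T_)) {
    stop("shape mismatch in combine_weights", call. = FALSE)
  }
  if (ablate_beta) {
    d <- if (is.matrix(beta)) ncol(beta) else 1L
    r * alpha * matrix(1, T_, d)
  } else {
    r * (alpha + beta) / 2
  }
}

# Guarded denominator for the pooled average: keeps the sign but floors the
# magnitude, since alpha + beta can cancel.
guard_denominator <- function(s, eps = POOL_EPS) {
  s + eps * ifelse(s >= 0, 1, -1)
}

#' Pool visit embeddings into the health-status vector
#'
#' Elementwise weighted average `h_bar = sum_t w_t * X_t / sum_t w_t` across
#' the unmasked visits; the denominator magnitude is floored at 1e-8 because
#' the combined weights can be negative and cancel.
#'
#' @param w T x d weight matrix.
#' @param X T x d matrix of visit embeddings.
#' @param mask length-T logical.
#' @return length-d vector.
#' @export
pool_health_status <- function(w, X, mask = rep(TRUE, nrow(X))) {
  if (!identical(dim(w), dim(X))) {
    stop("shape mismatch in pool_health_status", call. = FALSE)
  }
  wu <- w[mask, , drop = FALSE]
  Xu <- X[mask, , drop = FALSE]
  colSums(wu * Xu) / guard_denominator(colSums(wu))
}

#' Two-class risk from the health-status vector
#'
#' `softmax(FCN(h_bar))`; the second component is the death probability.
#'
#' @param h_bar length-d vector.
#' @param head a `head_params`.
#' @return length-2 vector `(p_discharged, p_death)` summing to 1.
#' @export
predict_risk <- function(h_bar, head) {
  if (any(!is.finite(h_bar))) stop("non-finite h_bar", call. = FALSE)
  softmax(drop(head$W %*% h_bar) + head$b)
}

#' Full DeepMPM parameter set
#'
#' Draws all learnable tensors: the two ReLU embedding layers, the two
#' Care-LSTMs feeding the visit-level and variable-level attention, the
#' attention projections and the risk head.
#'
#' @param n_dx,n_drg vocabulary sizes.
#' @param d embedding dimension (default 32).
#' @param hidden_alpha,hidden_beta Care-LSTM state sizes (default 64).
#' @param init `"glorot"` or `"zero"`.
#' @param seed RNG seed for the initial draw.
#' @param beta_zero_init see [attention_params()].
#' @return a `deepmpm_params` nested list.
#' @export
deepmpm_params <- function(n_dx, n_drg, d = 32L, hidden_alpha = 64L,
                           hidden_beta = 64L, init = "glorot", seed = 1L,
                           beta_zero_init = TRUE) {
  with_local_seed(seed, {
    structure(list(
      emb_x = embedding_params(n_dx, d, init),
      emb_p = embedding_params(n_drg, d, init),
      lstm_a = care_lstm_params(d, hidden_alpha, init = init),
      lstm_b = care_lstm_params(d, hidden_beta, init = init),
      att = attention_params(hidden_alpha, hidden_beta, d, init,
                             beta_zero_init),
      head = head_params(d, init)
    ), class = "deepmpm_params")
  })
}

# Per-prefix harmonic weights: delta for visit t within prefix i is the day
# gap between visit t's admission and the discharge of visit i (the last
# visit visible to that prefix).
prefix_harmonic <- function(m, admit_day, discharge_day, i) {
  delta <- pmax(0, discharge_day[i] - admit_day[seq_len(i)])
  harmonic_weight(m[seq_len(i)], delta)
}

#' Forward pass for one encoded patient sequence
#'
#' Computes the per-visit (prefix) death risks and the attention tensors.
#' For each visit i, the visit-level softmax, harmonic weights, pooling and
#' head are applied to visits 1..i only.
#'
#' @param seq one encoded sequence from [encode_sequences()].
#' @param params a `deepmpm_params`.
#' @param ablate_beta drop the variable-level attention
#'   (`w_t = r_t * alpha_t`).
#' @param scales Care-LSTM time-scale divisors.
#' @param dropout_mask optional list of length-d multiplier vectors (one per
#'   prefix) applied to `h_bar`; used internally during training.
#' @param keep_cache keep intermediates for backpropagation.
#' @return a `deepmpm_prediction`: list with `risk` (length T), `logit`
#'   (death log-odds per prefix, a saturation-free ranking score), `alpha`,
#'   `r`, `beta`, `w` (from the full-sequence prefix), `h_bar` (T x d, one
#'   row per prefix) and `y`.
#' @export
deepmpm_forward <- function(seq, params, ablate_beta = FALSE,
                            scales = c(60, 180, 365), dropout_mask = NULL,
                            keep_cache = FALSE) {
  T_ <- nrow(seq$x)
  if (T_ < 1) stop("empty sequence", call. = FALSE)
  d <- params$emb_x$d

  ex <- embed_matrix(seq$x, params$emb_x)     # T x d diagnoses
  ep <- embed_matrix(seq$p, params$emb_p)     # T x d treatments
  Xe <- ex$act; Pe <- ep$act

  ra <- run_sequence(Xe, Pe, seq$m, seq$delta_prev, params$lstm_a,
                     mask = seq$mask, scales = scales, keep_cache = keep_cache)
  rb <- run_sequence(Xe, Pe, seq$m, seq$delta_prev, params$lstm_b,
                     mask = seq$mask, scales = scales, keep_cache = keep_cache)
  s_alpha <- drop(ra$H %*% params$att$W_alpha) + params$att$b_alpha
  pre_beta <- rb$H %*% t(params$att$W_beta)
  pre_beta <- sweep(pre_beta, 2, params$att$b_beta, "+")
  Beta <- tanh(pre_beta)

  risk <- numeric(T_)
  logit <- numeric(T_)
  h_bar_all <- matrix(0, T_, d)
  prob_all <- matrix(0, T_, 2L)
  prefix <- vector("list", T_)
  for (i in seq_len(T_)) {
    idx <- seq_len(i)
    alpha_i <- softmax(s_alpha[idx])
    r_i <- prefix_harmonic(seq$m, seq$admit_day, seq$discharge_day, i)
    w_i <- combine_weights(alpha_i, Beta[idx, , drop = FALSE], r_i,
                           ablate_beta)
    sw <- colSums(w_i)
    den <- guard_denominator(sw)
    num <- colSums(w_i * Xe[idx, , drop = FALSE])
    h_bar <- num / den
    h_clamp <- pmin(pmax(h_bar, -HBAR_CLAMP), HBAR_CLAMP)
    h_drop <- if (is.null(dropout_mask)) h_clamp else
      h_clamp * dropout_mask[[i]]
    z <- drop(params$head$W %*% h_drop) + params$head$b
    pr <- softmax(z)
    risk[i] <- pr[2]
    logit[i] <- z[2] - z[1]      # death log-odds: saturation-free ranking
    h_bar_all[i, ] <- h_bar
    prob_all[i, ] <- pr
    if (keep_cache) {
      prefix[[i]] <- list(alpha = alpha_i, r = r_i, w = w_i, num = num,
                          den = den, h_bar = h_bar,
                          unclamped = abs(h_bar) < HBAR_CLAMP,
                          h_drop = h_drop, pr = pr)
    }
  }

  alpha_T <- softmax(s_alpha)
  r_T <- prefix_harmonic(seq$m, seq$admit_day, seq$discharge_day, T_)
  out <- structure(list(
    patient_id = seq$patient_id,
    risk = risk,
    logit = logit,
    alpha = alpha_T,
    beta = Beta,
    r = r_T,
    w = combine_weights(alpha_T, Beta, r_T, ablate_beta),
    h_bar = h_bar_all,
    prob = prob_all,
    y = seq$y
  ), class = "deepmpm_prediction")
  if (keep_cache) {
    out$cache <- list(ex = ex, ep = ep, ra = ra, rb = rb, s_alpha = s_alpha,
                      Beta = Beta, prefix = prefix, seq = seq,
                      ablate_beta = ablate_beta, scales = scales,
                      dropout_mask = dropout_mask)
  }
  out
}

# Backward pass for one patient given d(loss)/d(logit pair) per prefix
# (rows of dZ). Accumulates into `grads`, a zeroed mirror of `params`.
deepmpm_backward <- function(fw, params, dZ, grads) {
  cache <- fw$cache
  seq <- cache$seq
  T_ <- nrow(seq$x)
  d <- params$emb_x$d
  Xe <- cache$ex$act
  ablate <- cache$ablate_beta

  dXe <- matrix(0, T_, d)
  dBeta <- matrix(0, T_, d)
  ds_alpha <- numeric(T_)

  for (i in seq_len(T_)) {
    pf <- cache$prefix[[i]]
    idx <- seq_len(i)
    dz <- dZ[i, ]
    grads$head$W <- grads$head$W + dz %o% pf$h_drop
    grads$head$b <- grads$head$b + dz
    dh_drop <- drop(crossprod(params$head$W, dz))
    dh_clamp <- if (is.null(cache$dropout_mask)) dh_drop else
      dh_drop * cache$dropout_mask[[i]]
    dh_bar <- dh_clamp * cache$prefix[[i]]$unclamped
    # h_bar = num / den (elementwise); den has unit-gradient guard
    dnum <- dh_bar / pf$den
    dden <- -dh_bar * pf$num / pf$den^2
    # num_j = sum_t w_tj X_tj ; den_j = sum_t w_tj (+ guard)
    dw <- outer(rep(1, i), dnum) * Xe[idx, , drop = FALSE] +
      outer(rep(1, i), dden)
    dXe[idx, ] <- dXe[idx, ] + outer(rep(1, i), dnum) * pf$w
    if (ablate) {
      dalpha <- drop((dw * pf$r) %*% rep(1, d))
    } else {
      dhalf <- dw * pf$r / 2
      dalpha <- drop(dhalf %*% rep(1, d))
      dBeta[idx, ] <- dBeta[idx, ] + dhalf
    }
    a <- pf$alpha
    ds_alpha[idx] <- ds_alpha[idx] + a * (dalpha - sum(a * dalpha))
  }

  # variable-level attention: Beta = tanh(H_b W_beta' + b_beta)
  dpre_b <- dBeta * (1 - cache$Beta^2)
  grads$att$W_beta <- grads$att$W_beta + crossprod(dpre_b, cache$rb$H)
  grads$att$b_beta <- grads$att$b_beta + colSums(dpre_b)
  dHb <- dpre_b %*% params$att$W_beta

  # visit-level scores: s = H_a W_alpha + b_alpha
  grads$att$W_alpha <- grads$att$W_alpha + drop(crossprod(cache$ra$H, ds_alpha))
  grads$att$b_alpha <- grads$att$b_alpha + sum(ds_alpha)
  dHa <- ds_alpha %o% params$att$W_alpha

  bka <- run_sequence_backward(dHa, cache$ra$caches, params$lstm_a, seq$mask)
  bkb <- run_sequence_backward(dHb, cache$rb$caches, params$lstm_b, seq$mask)
  for (nm in names(bka$grads)) {
    grads$lstm_a[[nm]] <- grads$lstm_a[[nm]] + bka$grads[[nm]]
    grads$lstm_b[[nm]] <- grads$lstm_b[[nm]] + bkb$grads[[nm]]
  }
  dXe <- dXe + bka$dX + bkb$dX
  dPe <- bka$dP + bkb$dP

  dpre_x <- dXe * (cache$ex$pre > 0)
  grads$emb_x$W <- grads$emb_x$W + crossprod(dpre_x, seq$x)
  grads$emb_x$b <- grads$emb_x$b + colSums(dpre_x)
  dpre_p <- dPe * (cache$ep$pre > 0)
  grads$emb_p$W <- grads$emb_p$W + crossprod(dpre_p, seq$p)
  grads$emb_p$b <- grads$emb_p$b + colSums(dpre_p)
  grads
}

zero_like_deepmpm <- function(params) {
  structure(list(
    emb_x = list(W = params$emb_x$W * 0, b = params$emb_x$b * 0),
    emb_p = list(W = params$emb_p$W * 0, b = params$emb_p$b * 0),
    lstm_a = zero_like_params(params$lstm_a),
    lstm_b = zero_like_params(params$lstm_b),
    att = list(W_alpha = params$att$W_alpha * 0, b_alpha = 0,
               W_beta = params$att$W_beta * 0, b_beta = params$att$b_beta * 0),
    head = list(W = params$head$W * 0, b = params$head$b * 0)
  ), class = "deepmpm_grads")
}

#' Mean data loss and its gradients over a batch of sequences
#'
#' Evaluates the per-visit cross-entropy loss (mean over patients of the
#' per-patient mean over visit prefixes) and, optionally, its exact gradient
#' with respect to every parameter group via reverse-mode differentiation.
#' Regularisation is not included (see [apply_regularization()]).
#'
#' @param seqs list of encoded sequences.
#' @param params a `deepmpm_params`.
#' @param ablate_beta drop the variable-level attention.
#' @param scales time-scale divisors.
#' @param dropout_masks optional list (per patient) of per-prefix dropout
#'   multiplier vectors.
#' @param with_grads also compute gradients.
#' @return list with `loss` and (if requested) `grads` mirroring the
#'   parameter structure.
#' @export
deepmpm_loss <- function(seqs, params, ablate_beta = FALSE,
                         scales = c(60, 180, 365), dropout_masks = NULL,
                         with_grads = FALSE) {
  N <- length(seqs)
  loss <- 0
  grads <- if (with_grads) zero_like_deepmpm(params)
  for (n in seq_len(N)) {
    seq <- seqs[[n]]
    dm <- if (is.null(dropout_masks)) NULL else dropout_masks[[n]]
    fw <- deepmpm_forward(seq, params, ablate_beta, scales,
                          dropout_mask = dm, keep_cache = with_grads)
    T_ <- length(fw$risk)
    yhat <- pmin(pmax(fw$risk, 1e-7), 1 - 1e-7)
    loss <- loss + mean(-(seq$y * log(yhat) + (1 - seq$y) * log(1 - yhat))) / N
    if (with_grads) {
      # d(-log p_class)/d logits = prob - onehot, scaled by the double mean
      dZ <- fw$prob
      cls <- seq$y + 1L
      for (i in seq_len(T_)) dZ[i, cls[i]] <- dZ[i, cls[i]] - 1
      dZ <- dZ / (N * T_)
      grads <- deepmpm_backward(fw, params, dZ, grads)
    }
  }
  out <- list(loss = loss)
  if (with_grads) out$grads <- grads
  out
}
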