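# Recurrent cells: a standard LSTM reference and the modified Care-LSTM.
#
# The Care-LSTM extends the standard cell with clinically meaningful inputs:
# the input gate is scaled by 1/m_t (m = 1 emergency, m = 2 non-emergency),
# the forget gate additionally receives the previous visit's treatment
# embedding P_{t-1} and a three-scale representation of the gap since the
# previous discharge, and the output gate receives the current treatment
# embedding P_t. The candidate cell keeps the standard tanh form: only the
# gates are modified.
#
# Backward passes are hand-written (reverse-mode through the step
# recurrences) and verified against central finite differences in the tests.

#' Three-scale time interval representation
#'
#' Represents a day gap at three clinical time scales by dividing it by 60,
#' 180 and 365 days, giving the forget gate a multi-resolution view of how
#' long ago the previous discharge was.
#'
#' @param delta_days non-negative gap in days.
#' @param scales divisors in days (default `c(60, 180, 365)`).
#' @return numeric vector, one entry per scale.
#' @export
time_scale_vector <- function(delta_days, scales = c(60, 180, 365)) {
  stopifnot_scalar_number(delta_days, "delta_days")
  if (delta_days < 0) stop("delta_days must be non-negative", call. = FALSE)
  delta_days / scales
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Parameters of a standard LSTM cell
#'
#' Gate weights act on the concatenation `[x_t, h_{t-1}]`.
#'
#' @param d input dimension.
#' @param hidden state dimension.
#' @param init `"glorot"` for uniform Glorot draws (uses the current RNG
#'   stream) or `"zero"`.
#' @return a `std_lstm_params` list with `W_f, W_i, W_c, W_o`
#'   (hidden x (d+hidden)) and biases `b_f, b_i, b_c, b_o`.
#' @export
standard_lstm_params <- function(d, hidden, init = c("glorot", "zero")) {
  init <- match.arg(init)
  mk <- function() if (init == "zero") matrix(0, hidden, d + hidden) else
    glorot(hidden, d + hidden)
  structure(list(W_f = mk(), W_i = mk(), W_c = mk(), W_o = mk(),
                 b_f = numeric(hidden), b_i = numeric(hidden),
                 b_c = numeric(hidden), b_o = numeric(hidden),
                 d = as.integer(d), hidden = as.integer(hidden)),
            class = "std_lstm_params")
}

#' One step of the standard LSTM recurrence
#'
#' @param x input vector (length d).
#' @param state list with `h` and `C` (length hidden).
#' @param params a `std_lstm_params`.
#' @return list with the next `h` and `C`.
#' @export
standard_lstm_step <- function(x, state, params) {
  if (length(x) != params$d || length(state$h) != params$hidden) {
    stop("shape mismatch in standard_lstm_step", call. = FALSE)
  }
  xh <- c(x, state$h)
  f <- sigmoid(drop(params$W_f %*% xh) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% xh) + params$b_i)
  ctil <- tanh(drop(params$W_c %*% xh) + params$b_c)
  C <- f * state$C + i * ctil
  o <- sigmoid(drop(params$W_o %*% xh) + params$b_o)
  list(h = o * tanh(C), C = C)
}

#' Parameters of the modified Care-LSTM cell
#'
#' @param d input (embedding) dimension; both the diagnosis embedding X_t and
#'   the treatment embedding P_t have length d.
#' @param hidden state dimension (default 64).
#' @param n_scales number of time scales fed to the forget gate (3).
#' @param init `"glorot"` or `"zero"`.
#' @return a `care_lstm_params` list with input weights `W_i, W_f, W_c, W_o`
#'   (hidden x d), recurrent weights `U_i, U_f, U_c, U_o` (hidden x hidden),
#'   treatment weights `P_f, P_o` (hidden x d), interval weights `Q_f`
#'   (hidden x n_scales) and biases.
#' @export
care_lstm_params <- function(d, hidden = 64L, n_scales = 3L,
                             init = c("glorot", "zero")) {
  init <- match.arg(init)
  mk <- function(nr, nc) if (init == "zero") matrix(0, nr, nc) else
    glorot(nr, nc)
  structure(list(
    W_i = mk(hidden, d), U_i = mk(hidden, hidden),
    W_f = mk(hidden, d), U_f = mk(hidden, hidden),
    P_f = mk(hidden, d), Q_f = mk(hidden, n_scales),
    W_c = mk(hidden, d), U_c = mk(hidden, hidden),
    W_o = mk(hidden, d), U_o = mk(hidden, hidden),
    P_o = mk(hidden, d),
    b_i = numeric(hidden), b_f = numeric(hidden),
    b_c = numeric(hidden), b_o = numeric(hidden),
    d = as.integer(d), hidden = as.integer(hidden),
    n_scales = as.integer(n_scales)
  ), class = "care_lstm_params")
}

#' One step of the Care-LSTM recurrence
#'
#' Computes the gate activations with the care-specific inputs: the input
#' gate is `sigmoid(W_i X_t + U_i h + b_i) / m_t`, the forget gate receives
#' `P_f P_{t-1} + Q_f q(delta_prev)`, the output gate receives `P_o P_t`.
#' Candidate cell and state/output updates follow the standard form.
#'
#' @param X_t diagnosis embedding at the current visit (length d).
#' @param P_t treatment embedding at the current visit (length d).
#' @param P_prev treatment embedding of the previous visit (zeros at t = 1).
#' @param m_t admission-type weight (>= 1; 1 emergency, 2 non-emergency).
#' @param delta_prev days since the previous discharge (>= 0; 0 at t = 1).
#' @param state list with `h` and `C`.
#' @param params a `care_lstm_params`.
#' @param scales time-scale divisors for [time_scale_vector()].
#' @param keep_cache keep intermediate activations for the backward pass.
#' @return list with `h`, `C` and (optionally) `cache`.
#' @export
care_lstm_step <- function(X_t, P_t, P_prev, m_t, delta_prev, state, params,
                           scales = c(60, 180, 365), keep_cache = FALSE) {
  if (length(X_t) != params$d || length(P_t) != params$d ||
      length(state$h) != params$hidden) {
    stop("shape mismatch in care_lstm_step", call. = FALSE)
  }
  if (m_t < 1) stop("m_t must be >= 1", call. = FALSE)
  q <- time_scale_vector(delta_prev, scales)
  si <- sigmoid(drop(params$W_i %*% X_t) + drop(params$U_i %*% state$h) +
                  params$b_i)
  i <- si / m_t
  f <- sigmoid(drop(params$W_f %*% X_t) + drop(params$U_f %*% state$h) +
                 drop(params$P_f %*% P_prev) + drop(params$Q_f %*% q) +
                 params$b_f)
  ctil <- tanh(drop(params$W_c %*% X_t) + drop(params$U_c %*% state$h) +
                 params$b_c)
  C <- f * state$C + i * ctil
  o <- sigmoid(drop(params$W_o %*% X_t) + drop(params$U_o %*% state$h) +
                 drop(params$P_o %*% P_t) + params$b_o)
  tC <- tanh(C)
  out <- list(h = o * tC, C = C)
  if (keep_cache) {
    out$cache <- list(X = X_t, P = P_t, P_prev = P_prev, m = m_t, q = q,
                      h_prev = state$h, C_prev = state$C,
                      si = si, i = i, f = f, ctil = ctil, o = o, tC = tC)
  }
  out
}

zero_like_params <- function(params) {
  keep <- setdiff(names(params), c("d", "hidden", "n_scales"))
  lapply(params[keep], function(p) p * 0)
}

# Reverse-mode pass through one Care-LSTM step. `dh`/`dC` are the gradients
# arriving at this step's outputs; returns gate-level parameter gradients
# (accumulated into `grads`) plus the gradients flowing to the step inputs.
care_lstm_step_backward <- function(dh, dC, cache, params, grads) {
  o <- cache$o; tC <- cache$tC; f <- cache$f; i <- cache$i
  do <- dh * tC
  dC <- dC + dh * o * (1 - tC^2)
  df <- dC * cache$C_prev
  di <- dC * cache$ctil
  dctil <- dC * i
  dC_prev <- dC * f
  da_o <- do * o * (1 - o)
  da_f <- df * f * (1 - f)
  da_i <- di * cache$si * (1 - cache$si) / cache$m
  da_c <- dctil * (1 - cache$ctil^2)

  grads$W_i <- grads$W_i + da_i %o% cache$X
  grads$U_i <- grads$U_i + da_i %o% cache$h_prev
  grads$b_i <- grads$b_i + da_i
  grads$W_f <- grads$W_f + da_f %o% cache$X
  grads$U_f <- grads$U_f + da_f %o% cache$h_prev
  grads$P_f <- grads$P_f + da_f %o% cache$P_prev
  grads$Q_f <- grads$Q_f + da_f %o% cache$q
  grads$b_f <- grads$b_f + da_f
  grads$W_c <- grads$W_c + da_c %o% cache$X
  grads$U_c <- grads$U_c + da_c %o% cache$h_prev
  grads$b_c <- grads$b_c + da_c
  grads$W_o <- grads$W_o + da_o %o% cache$X
  grads$U_o <- grads$U_o + da_o %o% cache$h_prev
  grads$P_o <- grads$P_o + da_o %o% cache$P
  grads$b_o <- grads$b_o + da_o

  dX <- drop(crossprod(params$W_i, da_i)) + drop(crossprod(params$W_f, da_f)) +
    drop(crossprod(params$W_c, da_c)) + drop(crossprod(params$W_o, da_o))
  dh_prev <- drop(crossprod(params$U_i, da_i)) +
    drop(crossprod(params$U_f, da_f)) + drop(crossprod(params$U_c, da_c)) +
    drop(crossprod(params$U_o, da_o))
  dP <- drop(crossprod(params$P_o, da_o))
  dP_prev <- drop(crossprod(params$P_f, da_f))
  list(grads = grads, dX = dX, dP = dP, dP_prev = dP_prev,
       dh_prev = dh_prev, dC_prev = dC_prev)
}

#' Run a Care-LSTM over an embedded visit sequence
#'
#' Starts from zero state; the previous treatment embedding at t = 1 is the
#' zero vector; padded (masked-out) steps leave the state untouched and
#' report a zero hidden state.
#'
#' @param X T x d matrix of diagnosis embeddings (rows = visits).
#' @param P T x d matrix of treatment embeddings.
#' @param m length-T admission-type weights.
#' @param delta_prev length-T gaps since the previous discharge (days).
#' @param params a `care_lstm_params`.
#' @param mask length-T logical; `FALSE` marks padded steps.
#' @param scales time-scale divisors.
#' @param keep_cache keep per-step caches for backpropagation.
#' @return list with `H` (T x hidden matrix of hidden states) and, if
#'   requested, `caches`.
#' @export
run_sequence <- function(X, P, m, delta_prev, params,
                         mask = rep(TRUE, nrow(X)),
                         scales = c(60, 180, 365), keep_cache = FALSE) {
  T_ <- nrow(X)
  if (T_ < 1) stop("empty sequence", call. = FALSE)
  H <- matrix(0, T_, params$hidden)
  state <- list(h = numeric(params$hidden), C = numeric(params$hidden))
  caches <- if (keep_cache) vector("list", T_)
  P_prev <- numeric(params$d)
  for (t in seq_len(T_)) {
    if (!mask[t]) next
    st <- care_lstm_step(X[t, ], P[t, ], P_prev, m[t], delta_prev[t], state,
                         params, scales, keep_cache)
    state <- list(h = st$h, C = st$C)
    H[t, ] <- st$h
    if (keep_cache) caches[[t]] <- st$cache
    P_prev <- P[t, ]
  }
  out <- list(H = H)
  if (keep_cache) out$caches <- caches
  out
}

# Backpropagation through time for one sequence. `dH` holds dLoss/dh_t for
# every step (zeros on padded steps). Returns parameter gradients and the
# gradients w.r.t. the embedded inputs X and P.
run_sequence_backward <- function(dH, caches, params, mask = rep(TRUE, nrow(dH))) {
  T_ <- nrow(dH)
  grads <- zero_like_params(params)
  dX <- matrix(0, T_, params$d)
  dP <- matrix(0, T_, params$d)
  dh_next <- numeric(params$hidden)
  dC_next <- numeric(params$hidden)
  real <- which(mask)
  for (t in rev(real)) {
    bk <- care_lstm_step_backward(dH[t, ] + dh_next, dC_next, caches[[t]],
                                  params, grads)
    grads <- bk$grads
    dX[t, ] <- dX[t, ] + bk$dX
    dP[t, ] <- dP[t, ] + bk$dP
    prev <- real[real < t]
    if (length(prev)) dP[max(prev), ] <- dP[max(prev), ] + bk$dP_prev
    dh_next <- bk$dh_prev
    dC_next <- bk$dC_prev
  }
  list(grads = grads, dX = dX, dP = dP)
}
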