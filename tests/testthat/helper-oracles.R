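# Independent scalar-loop oracles for the recurrent cells and the attention
# arithmetic. Deliberately written with explicit index loops and no shared
# code with the package internals, so they can arbitrate correctness.

osigmoid <- function(z) 1 / (1 + exp(-z))

oracle_std_lstm_step <- function(x, h, C, params) {
  H <- params$hidden
  xh <- c(x, h)
  f <- i <- ct <- o <- Cn <- hn <- numeric(H)
  for (j in seq_len(H)) {
    af <- params$b_f[j]; ai <- params$b_i[j]; ac <- params$b_c[j]
    ao <- params$b_o[j]
    for (k in seq_along(xh)) {
      af <- af + params$W_f[j, k] * xh[k]
      ai <- ai + params$W_i[j, k] * xh[k]
      ac <- ac + params$W_c[j, k] * xh[k]
      ao <- ao + params$W_o[j, k] * xh[k]
    }
    f[j] <- osigmoid(af); i[j] <- osigmoid(ai); ct[j] <- tanh(ac)
    o[j] <- osigmoid(ao)
    Cn[j] <- f[j] * C[j] + i[j] * ct[j]
    hn[j] <- o[j] * tanh(Cn[j])
  }
  list(h = hn, C = Cn)
}

oracle_care_lstm_step <- function(X, P, P_prev, m, delta, h, C, params,
                                  scales = c(60, 180, 365)) {
  H <- params$hidden
  q <- delta / scales
  f <- i <- ct <- o <- Cn <- hn <- numeric(H)
  for (j in seq_len(H)) {
    ai <- params$b_i[j]; af <- params$b_f[j]; ac <- params$b_c[j]
    ao <- params$b_o[j]
    for (k in seq_along(X)) {
      ai <- ai + params$W_i[j, k] * X[k]
      af <- af + params$W_f[j, k] * X[k]
      ac <- ac + params$W_c[j, k] * X[k]
      ao <- ao + params$W_o[j, k] * X[k]
    }
    for (k in seq_along(h)) {
      ai <- ai + params$U_i[j, k] * h[k]
      af <- af + params$U_f[j, k] * h[k]
      ac <- ac + params$U_c[j, k] * h[k]
      ao <- ao + params$U_o[j, k] * h[k]
    }
    for (k in seq_along(P)) {
      af <- af + params$P_f[j, k] * P_prev[k]
      ao <- ao + params$P_o[j, k] * P[k]
    }
    for (k in seq_along(q)) af <- af + params$Q_f[j, k] * q[k]
    i[j] <- osigmoid(ai) / m
    f[j] <- osigmoid(af)
    ct[j] <- tanh(ac)
    Cn[j] <- f[j] * C[j] + i[j] * ct[j]
    o[j] <- osigmoid(ao)
    hn[j] <- o[j] * tanh(Cn[j])
  }
  list(h = hn, C = Cn, i = i, f = f, o = o)
}

# scalar-loop weight combination (w = r * (alpha + beta) / 2) and pooled
# average with the same 1e-8 sign-preserving denominator guard
oracle_combine_pool <- function(alpha, beta, r, X, ablate = FALSE) {
  T_ <- length(alpha); d <- ncol(X)
  w <- matrix(0, T_, d)
  for (t in seq_len(T_)) {
    for (j in seq_len(d)) {
      w[t, j] <- if (ablate) r[t] * alpha[t] else
        r[t] * (alpha[t] + beta[t, j]) / 2
    }
  }
  h <- numeric(d)
  for (j in seq_len(d)) {
    num <- 0; den <- 0
    for (t in seq_len(T_)) {
      num <- num + w[t, j] * X[t, j]
      den <- den + w[t, j]
    }
    den <- den + 1e-8 * (if (den >= 0) 1 else -1)
    h[j] <- num / den
  }
  list(w = w, h_bar = h)
}

random_care_params <- function(d, hidden, seed) {
  set.seed(seed)
  p <- care_lstm_params(d, hidden, init = "zero")
  for (nm in c("W_i", "U_i", "W_f", "U_f", "P_f", "Q_f", "W_c", "U_c",
               "W_o", "U_o", "P_o", "b_i", "b_f", "b_c", "b_o")) {
    p[[nm]][] <- rnorm(length(p[[nm]]), sd = 0.5)
  }
  p
}

random_std_params <- function(d, hidden, seed) {
  set.seed(seed)
  p <- standard_lstm_params(d, hidden, init = "zero")
  for (nm in c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o")) {
    p[[nm]][] <- rnorm(length(p[[nm]]), sd = 0.5)
  }
  p
}

# tiny encoded sequence with explicit fields, for model-level tests
toy_sequence <- function(T_ = 3, n_dx = 5, n_drg = 4, seed = 1,
                         y_last = 1L) {
  set.seed(seed)
  x <- matrix(0, T_, n_dx)
  p <- matrix(0, T_, n_drg)
  for (t in seq_len(T_)) {
    x[t, sample(n_dx, sample(2:3, 1))] <- 1
    p[t, sample(n_drg, 1)] <- 1
  }
  admit <- cumsum(c(0, stats::runif(T_ - 1, 5, 90)))
  discharge <- admit + stats::runif(T_, 1, 10)
  list(patient_id = paste0("T", seed),
       x = x, p = p,
       m = sample(c(1L, 2L), T_, replace = TRUE),
       delta_prev = c(0, pmax(0, floor(admit[-1] - discharge[-T_]))),
       delta_to_last = pmax(0, floor(discharge[T_] - admit)),
       y = c(rep(0L, T_ - 1), y_last),
       mask = rep(TRUE, T_),
       admit_day = floor(admit), discharge_day = floor(discharge))
}

small_params <- function(n_dx = 5, n_drg = 4, d = 4, ha = 3, hb = 3,
                         seed = 2) {
  # draw the variable-level projection too, so tests exercise beta != 0
  deepmpm_params(n_dx, n_drg, d, ha, hb, seed = seed,
                 beta_zero_init = FALSE)
}

# relative agreement at 1e-4 with an absolute floor so that near-zero
# gradients are not judged on finite-difference noise
expect_grad_match <- function(analytic, fd, label) {
  rel <- abs(analytic - fd) / max(1e-4, abs(analytic) + abs(fd))
  expect_lt(rel, 1e-4, label = label)
}
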