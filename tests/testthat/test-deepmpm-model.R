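# Two-level attention, harmonic weighting, pooling, risk head and the
# assembled forward/backward pass.

test_that("visit attention is a softmax across visits", {
  ap <- attention_params(3, 2, 4, init = "zero")
  ap$W_alpha <- c(1, -1, 0.5)
  G1 <- matrix(rnorm(3), 1, 3)
  expect_equal(visit_attention(G1, ap), 1)
  G4 <- matrix(rep(c(0.3, -0.2, 0.1), each = 4), 4, 3)
  expect_equal(visit_attention(G4, ap), rep(0.25, 4))
  set.seed(4)
  G <- matrix(rnorm(12), 4, 3)
  a <- visit_attention(G, ap)
  expect_equal(sum(a), 1)
  expect_true(all(a >= 0))
  # masked positions get zero weight and the rest renormalise
  am <- visit_attention(G, ap, mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(am[4], 0)
  expect_equal(sum(am), 1)
  expect_error(visit_attention(G, ap, mask = rep(FALSE, 4)), "masked")
})

test_that("variable attention is tanh-bounded with saturation limits", {
  ap <- attention_params(3, 2, 4, init = "zero")
  expect_equal(variable_attention(c(0.5, -0.5), ap), rep(0, 4))
  set.seed(5)
  ap2 <- attention_params(3, 2, 4)
  b <- variable_attention(rnorm(2), ap2)
  expect_true(all(b >= -1 & b <= 1))
  ap2$b_beta <- rep(50, 4)
  expect_equal(variable_attention(c(0, 0), ap2), rep(1, 4),
               tolerance = 1e-12)
  expect_error(variable_attention(rnorm(3), ap2), "W_beta")
})

test_that("harmonic weight closed forms", {
  expect_equal(harmonic_weight(1, 0), 1)
  expect_equal(harmonic_weight(1, exp(1) - 1), 0.5)
  expect_equal(harmonic_weight(2, 0), 0.5)
  expect_error(harmonic_weight(1, -3), ">= 0")
  expect_error(harmonic_weight(0.5, 3), ">= 1")
  set.seed(6)
  r <- harmonic_weight(sample(1:2, 20, TRUE), runif(20, 0, 5000))
  expect_true(all(r > 0 & r <= 1))
})

test_that("weight combination and pooling match the scalar-loop oracle", {
  for (k in 1:20) {
    set.seed(k)
    T_ <- sample(1:5, 1); d <- sample(2:6, 1)
    alpha <- as.vector(stats::rmultinom(1, 100, rep(1, T_))) / 100
    beta <- matrix(runif(T_ * d, -1, 1), T_, d)
    r <- harmonic_weight(sample(1:2, T_, TRUE), runif(T_, 0, 800))
    X <- matrix(rnorm(T_ * d), T_, d)
    want <- oracle_combine_pool(alpha, beta, r, X)
    w <- combine_weights(alpha, beta, r)
    expect_equal(w, want$w, tolerance = 1e-12)
    expect_equal(pool_health_status(w, X), want$h_bar, tolerance = 1e-10)
    # ablated variant equals r * alpha broadcast
    want_a <- oracle_combine_pool(alpha, beta, r, X, ablate = TRUE)
    expect_equal(combine_weights(alpha, beta, r, ablate_beta = TRUE),
                 want_a$w, tolerance = 1e-12)
  }
})

test_that("beta forced to alpha reproduces the ablated weights", {
  set.seed(30)
  T_ <- 4; d <- 3
  sc <- exp(rnorm(T_)); alpha <- sc / sum(sc)
  r <- harmonic_weight(rep(1, T_), runif(T_, 0, 100))
  beta_as_alpha <- matrix(alpha, T_, d)
  expect_equal(combine_weights(alpha, beta_as_alpha, r),
               combine_weights(alpha, beta_as_alpha, r, ablate_beta = TRUE))
})

test_that("single-visit pooling returns the visit embedding", {
  set.seed(7)
  X <- matrix(rnorm(4), 1, 4)
  w <- matrix(runif(4, 0.2, 1), 1, 4)
  expect_equal(pool_health_status(w, X), drop(X), tolerance = 1e-6)
  # equal weights across visits give the plain mean
  X3 <- matrix(rnorm(12), 3, 4)
  w3 <- matrix(0.5, 3, 4)
  expect_equal(pool_health_status(w3, X3), colMeans(X3), tolerance = 1e-6)
})

test_that("risk head is a proper two-class softmax", {
  hp <- head_params(3, init = "zero")
  expect_equal(predict_risk(c(1, -2, 0.5), hp), c(0.5, 0.5))
  set.seed(8)
  hp2 <- head_params(3)
  pr <- predict_risk(rnorm(3), hp2)
  expect_equal(sum(pr), 1)
  expect_true(all(pr > 0 & pr < 1))
  hp3 <- hp2
  hp3$b[2] <- hp3$b[2] + 1          # raising the death logit raises the risk
  expect_gt(predict_risk(c(1, 1, 1), hp3)[2], predict_risk(c(1, 1, 1), hp2)[2])
  expect_error(predict_risk(c(NaN, 1, 1), hp2), "non-finite")
})

test_that("forward output satisfies the attention contracts", {
  s <- toy_sequence(T_ = 4, seed = 10)
  pp <- small_params(seed = 11)
  fw <- deepmpm_forward(s, pp)
  expect_equal(sum(fw$alpha), 1)
  expect_true(all(fw$alpha >= 0))
  expect_true(all(fw$beta >= -1 & fw$beta <= 1))
  expect_true(all(fw$r > 0 & fw$r <= 1))
  expect_true(all(fw$risk > 0 & fw$risk < 1))
  expect_true(all(abs(rowSums(fw$prob) - 1) < 1e-12))
})

test_that("predictions at visit i ignore later visits (prefix property)", {
  s <- toy_sequence(T_ = 5, seed = 12)
  pp <- small_params(seed = 13)
  full <- deepmpm_forward(s, pp)
  for (i in 2:4) {
    sub <- s
    keep <- seq_len(i)
    for (f in c("x", "p")) sub[[f]] <- s[[f]][keep, , drop = FALSE]
    for (f in c("m", "delta_prev", "y", "mask", "admit_day",
                "discharge_day")) sub[[f]] <- s[[f]][keep]
    sub$delta_to_last <- pmax(0, s$discharge_day[i] - s$admit_day[keep])
    part <- deepmpm_forward(sub, pp)
    expect_equal(part$risk, full$risk[keep], tolerance = 1e-12)
  }
})

test_that("single-visit patient composes the singleton cases", {
  s <- toy_sequence(T_ = 1, seed = 14, y_last = 0L)
  pp <- small_params(seed = 15)
  fw <- deepmpm_forward(s, pp)
  expect_equal(fw$alpha, 1)
  Xe <- t(apply(s$x, 1, embed_visit, params = pp$emb_x))
  expect_equal(drop(fw$h_bar), drop(Xe), tolerance = 1e-6)
  expect_equal(fw$risk, predict_risk(drop(Xe), pp$head)[2],
               tolerance = 1e-6)
})

test_that("the beta-ablated forward uses w = r * alpha", {
  s <- toy_sequence(T_ = 3, seed = 16)
  pp <- small_params(seed = 17)
  fa <- deepmpm_forward(s, pp, ablate_beta = TRUE)
  expect_equal(fa$w, fa$r * fa$alpha * matrix(1, 3, 4), tolerance = 1e-12)
  fb <- deepmpm_forward(s, pp)
  expect_false(isTRUE(all.equal(fa$risk, fb$risk)))
})

test_that("loss gradients match finite differences for every group", {
  seqs <- list(toy_sequence(T_ = 3, seed = 18, y_last = 1L),
               toy_sequence(T_ = 3, seed = 19, y_last = 0L))
  pp <- small_params(seed = 20)
  lg <- deepmpm_loss(seqs, pp, with_grads = TRUE)
  eps <- 1e-5
  set.seed(21)
  for (grp in names(lg$grads)) {
    for (leaf in names(lg$grads[[grp]])) {
      g <- lg$grads[[grp]][[leaf]]
      for (k in sample(length(g), min(4, length(g)))) {
        pplus <- pp; pplus[[grp]][[leaf]][k] <- pplus[[grp]][[leaf]][k] + eps
        pminus <- pp; pminus[[grp]][[leaf]][k] <- pminus[[grp]][[leaf]][k] - eps
        fd <- (deepmpm_loss(seqs, pplus)$loss -
                 deepmpm_loss(seqs, pminus)$loss) / (2 * eps)
        expect_grad_match(g[k], fd, sprintf("dLoss/d%s$%s[%d]", grp, leaf, k))
      }
    }
  }
})

test_that("dropout masks scale the pooled vector and its gradient", {
  s <- toy_sequence(T_ = 2, seed = 22)
  pp <- small_params(seed = 23)
  masks <- list(lapply(1:2, function(i) c(0, 1.25, 1.25, 0)))
  lg <- deepmpm_loss(list(s), pp, dropout_masks = masks, with_grads = TRUE)
  eps <- 1e-5
  k <- 3
  pplus <- pp; pplus$head$W[k] <- pplus$head$W[k] + eps
  pminus <- pp; pminus$head$W[k] <- pminus$head$W[k] - eps
  fd <- (deepmpm_loss(list(s), pplus, dropout_masks = masks)$loss -
           deepmpm_loss(list(s), pminus, dropout_masks = masks)$loss) /
    (2 * eps)
  expect_equal(lg$grads$head$W[k], fd, tolerance = 1e-4)
})
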