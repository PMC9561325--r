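# Medical code embeddings.
#
# Codes are embedded by a single ReLU layer per code family (diagnoses,
# DRGs). The weight matrices can be initialised by an intra-visit skip-gram
# with negative sampling — the context of a code is the other codes recorded
# in the same visit, so codes that co-occur across visits end up with similar
# columns — and are then fine-tuned end-to-end with the supervised
# objective. Column-wise correlation of a trained weight matrix yields the
# interpretable code-code correlation matrix.

#' Parameters of a ReLU code-embedding layer
#'
#' @param n_codes vocabulary size.
#' @param d embedding dimension (default 32).
#' @param init `"glorot"` (uses the current RNG stream) or `"zero"`.
#' @param W optional d x n_codes matrix to use instead of a fresh draw, e.g.
#'   from [pretrain_code_embeddings()].
#' @return an `embedding_params` list with `W` (d x n_codes) and `b`
#'   (length d).
#' @export
embedding_params <- function(n_codes, d = 32L, init = c("glorot", "zero"),
                             W = NULL) {
  init <- match.arg(init)
  if (is.null(W)) {
    W <- if (init == "zero") matrix(0, d, n_codes) else glorot(d, n_codes)
  }
  stopifnot(nrow(W) == d, ncol(W) == n_codes)
  structure(list(W = W, b = numeric(d), d = as.integer(d),
                 n_codes = as.integer(n_codes)),
            class = "embedding_params")
}

#' Embed one multi-hot visit vector
#'
#' `ReLU(W x + b)`: the embedding of a visit is the rectified sum of the
#' embedding columns of its active codes.
#'
#' @param x_t binary vector of length `n_codes`.
#' @param params an `embedding_params`.
#' @return non-negative numeric vector of length d.
#' @export
embed_visit <- function(x_t, params) {
  if (length(x_t) != params$n_codes) {
    stop("multi-hot vector length does not match the vocabulary", call. = FALSE)
  }
  relu(drop(params$W %*% x_t) + params$b)
}

# Embed all visits of a sequence at once: rows of `xmat` are multi-hot visit
# vectors. Returns the T x d matrix of pre-activations and activations.
embed_matrix <- function(xmat, params) {
  pre <- xmat %*% t(params$W)
  pre <- sweep(pre, 2, params$b, "+")
  list(pre = pre, act = pmax(pre, 0))
}

#' Skip-gram pretraining of code vectors
#'
#' Trains code vectors with skip-gram + negative sampling where the context
#' of a code is the set of other codes in the same visit, so the model learns
#' intra-visit co-occurrence (comorbidity) structure. Negative examples are
#' drawn from the unigram code distribution. Used to initialise the
#' embedding-layer weights, which are then fine-tuned end-to-end.
#'
#' @param cohort an `ehr_cohort`.
#' @param kind `"diagnosis"` or `"drg"`.
#' @param d embedding dimension (>= 2).
#' @param epochs passes over the visit corpus.
#' @param negatives negative samples per positive pair.
#' @param lr SGD learning rate.
#' @param seed RNG seed; a fixed seed gives an identical matrix.
#' @param vocab optional `code_vocab`; built from the cohort when missing.
#' @return d x |vocab| matrix with codes as column names.
#' @export
pretrain_code_embeddings <- function(cohort, kind = c("diagnosis", "drg"),
                                     d = 32L, epochs = 5L, negatives = 5L,
                                     lr = 0.05, seed = 1L, vocab = NULL) {
  kind <- match.arg(kind)
  if (d < 2) stop("embedding dimension must be >= 2", call. = FALSE)
  if (is.null(vocab)) vocab <- build_vocab(cohort, kind)
  V <- length(vocab$codes)
  if (V < 2) stop("vocabulary must contain at least 2 codes", call. = FALSE)
  field <- if (kind == "diagnosis") "dx" else "drg"
  visits <- unlist(lapply(cohort$patients, function(p)
    lapply(p$visits[[field]], function(cs)
      unname(vocab$index[cs[cs %in% vocab$codes]]))), recursive = FALSE)
  visits <- visits[vapply(visits, length, integer(1)) >= 1]

  counts <- tabulate(unlist(visits), nbins = V)
  neg_prob <- (counts + 1)^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  with_local_seed(seed, {
    Win <- matrix(stats::runif(d * V, -0.5, 0.5) / d, d, V)
    Wout <- matrix(0, d, V)
    for (ep in seq_len(epochs)) {
      for (codes in visits[sample.int(length(visits))]) {
        if (length(codes) < 2) next
        for (centre in codes) {
          ctx <- setdiff(codes, centre)
          neg <- sample.int(V, negatives * length(ctx), replace = TRUE,
                            prob = neg_prob)
          targets <- c(ctx, neg)
          label <- c(rep(1, length(ctx)), rep(0, length(neg)))
          v <- Win[, centre]
          s <- sigmoid(drop(crossprod(Wout[, targets, drop = FALSE], v)))
          g <- (label - s)                       # d logsigma / d score
          Win[, centre] <- v + lr * drop(Wout[, targets, drop = FALSE] %*% g)
          Wout[, targets] <- Wout[, targets, drop = FALSE] + lr * (v %o% g)
        }
      }
    }
    colnames(Win) <- vocab$codes
    Win
  })
}

#' Code-code correlation matrix from an embedding weight matrix
#'
#' Pearson correlation between the embedding columns of every pair of codes.
#' Highly correlated columns indicate codes the model treats as related
#' (co-occurring diseases or treatments).
#'
#' @param W d x |vocab| weight matrix (columns = codes).
#' @return |vocab| x |vocab| symmetric correlation matrix with unit diagonal;
#'   rows/columns of constant (zero-variance) embedding columns are `NA` and
#'   reported via a warning.
#' @export
code_correlation_matrix <- function(W) {
  if (ncol(W) < 2) stop("need at least 2 codes", call. = FALSE)
  sds <- apply(W, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  Corr <- matrix(NA_real_, ncol(W), ncol(W),
                 dimnames = list(colnames(W), colnames(W)))
  ok <- which(!const)
  if (length(ok) >= 2) Corr[ok, ok] <- stats::cor(W[, ok, drop = FALSE])
  diag(Corr)[ok] <- 1
  if (any(const)) {
    warning(sprintf("%d constant embedding column(s); correlations set to NA",
                    sum(const)), call. = FALSE)
  }
  Corr
}

#' Mean within-block vs cross-block embedding correlation
#'
#' Summarises how strongly a correlation matrix separates predefined
#' comorbidity blocks: the mean correlation between code pairs inside the
#' same block against the mean correlation across different blocks.
#'
#' @param Corr correlation matrix from [code_correlation_matrix()].
#' @param blocks list of integer column index sets.
#' @return list with `within`, `cross` and their difference.
#' @export
block_correlation_summary <- function(Corr, blocks) {
  V <- ncol(Corr)
  member <- rep(NA_integer_, V)
  for (b in seq_along(blocks)) member[blocks[[b]]] <- b
  pairs <- which(upper.tri(Corr), arr.ind = TRUE)
  same <- !is.na(member[pairs[, 1]]) & !is.na(member[pairs[, 2]]) &
    member[pairs[, 1]] == member[pairs[, 2]]
  diff_block <- !is.na(member[pairs[, 1]]) & !is.na(member[pairs[, 2]]) &
    member[pairs[, 1]] != member[pairs[, 2]]
  vals <- Corr[pairs]
  within <- mean(vals[same], na.rm = TRUE)
  cross <- mean(vals[diff_block], na.rm = TRUE)
  list(within = within, cross = cross, difference = within - cross)
}
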