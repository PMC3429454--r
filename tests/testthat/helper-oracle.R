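# Independent reference implementations and fixture factories used across
# the suite. The oracle PLS below is a deliberately plain, loop-based
# transcription of the textbook NIPALS PLS1 algorithm; it knows nothing
# about blocks and is kept independent of the package implementation.

oracle_nipals_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(Xc); p <- ncol(Xc)
  scores <- matrix(0, n, ncomp)
  weights <- matrix(0, p, ncomp)
  loadings <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in 1:ncomp) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(Xc[, j] * yc)
    w <- w / sqrt(sum(w * w))
    t_a <- numeric(n)
    for (i in 1:n) t_a[i] <- sum(Xc[i, ] * w)
    q[a] <- sum(t_a * yc) / sum(t_a * t_a)
    p_a <- numeric(p)
    for (j in 1:p) p_a[j] <- sum(Xc[, j] * t_a) / sum(t_a * t_a)
    Xc <- Xc - outer(t_a, p_a)
    yc <- yc - t_a * q[a]
    scores[, a] <- t_a
    weights[, a] <- w
    loadings[, a] <- p_a
  }
  yhat <- mean(y) + {
    W <- weights; P <- loadings
    drop(as.matrix(scale(X, center = TRUE, scale = FALSE)) %*%
           (W %*% solve(t(P) %*% W, q)))
  }
  list(scores = scores, weights = weights, loadings = loadings, q = q,
       fitted = yhat)
}

# random multi-block instance: n samples, blocks of random widths
random_blockset <- function(n, p, n_blocks = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    cuts <- sort(sample(seq_len(p - 1), n_blocks - 1))
    sizes <- diff(c(0, cuts, p))
    col_blocks <- split(seq_len(p), rep(seq_len(n_blocks), sizes))
  })
  blockset_from_matrix(X, col_blocks, y)
}

# align the sign of score columns to a reference (PLS components are
# sign-indeterminate across implementations)
align_signs <- function(A, B) {
  for (a in seq_len(ncol(A))) {
    if (sum(A[, a] * B[, a]) < 0) B[, a] <- -B[, a]
  }
  B
}

# small, fast study design for plumbing tests
tiny_design <- function(seed = 1, ...) {
  study_design(n_fo = 5, n_hoso = 6,
               class_sizes = c(Cer = 3, lysoPC = 3, lysoPE = 2, PA = 2,
                               PC = 8, PE = 4, PG = 3, PS = 3, SM = 4,
                               TG = 8, PI = 1),
               seed = seed, ...)
}
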