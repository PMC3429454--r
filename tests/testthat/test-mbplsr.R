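test_that("multi-block super scores equal plain NIPALS PLS on the concatenation", {
  # the block layer is a readout, not a different model
  for (seed in 1:8) {
    bs <- random_blockset(n = 12 + seed, p = 20 + 3 * seed,
                          n_blocks = 2 + seed %% 3, seed = seed)
    X <- do.call(cbind, lapply(seq_along(bs$raw), function(b) {
      sweep(bs$raw[[b]], 2, bs$centers[[b]], "-") / bs$scaling_factors[b]
    }))
    A <- 3
    fit <- fit_mbplsr(bs, A)
    oracle <- oracle_nipals_pls1(X, bs$y, A)
    expect_equal(fit$super_scores,
                 align_signs(fit$super_scores, oracle$scores),
                 tolerance = 1e-8)
    expect_equal(predict(fit, bs), oracle$fitted, tolerance = 1e-8)
    # block scores recombine into the super score via the weight sub-norms
    for (a in 1:A) {
      recombined <- Reduce(`+`, lapply(seq_along(bs$raw), function(b) {
        w_norm <- sqrt(sum((fit$weights[fit$block_id == b, a])^2))
        fit$block_scores[[b]][, a] * w_norm
      }))
      expect_equal(recombined, fit$super_scores[, a], tolerance = 1e-10)
    }
  }
})

test_that("single-block fit matches the mixOmics PLS oracle", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:3) {
    withr::with_seed(100 + seed, {
      X <- matrix(rnorm(20 * 15), 20, 15)
      y <- rnorm(20)
    })
    bs <- blockset_from_matrix(X, list(seq_len(15)), y)
    fit <- fit_mbplsr(bs, 3)
    Xs <- scale(X, center = TRUE, scale = FALSE) / bs$scaling_factors[1]
    mo <- mixOmics::pls(Xs, y, ncomp = 3, scale = FALSE, mode = "regression")
    mo_scores <- unname(as.matrix(mo$variates$X))
    expect_equal(unname(fit$super_scores),
                 align_signs(unname(fit$super_scores), mo_scores),
                 tolerance = 1e-8)
  }
})

test_that("a noise-free response in the column space is fully explained at the rank", {
  withr::with_seed(5, X <- matrix(rnorm(30 * 6), 30, 6))
  y <- X[, 3] - mean(X[, 3])
  bs <- blockset_from_matrix(X, list(1:3, 4:6), y)
  fit <- fit_mbplsr(bs, 6)
  expect_equal(fit$explained_Y_variance[6], 1, tolerance = 1e-8)
  expect_true(all(diff(fit$explained_Y_variance) >= -1e-12))
  # perfect collinearity: y duplicated as the only informative direction
  X1 <- cbind(y, y * 2)
  bs1 <- blockset_from_matrix(X1, list(1, 2), y + 5)
  fit1 <- fit_mbplsr(bs1, 1)
  expect_equal(fit1$explained_Y_variance[1], 1, tolerance = 1e-10)
})

test_that("a four-sample two-block toy matches the brute-force oracle", {
  X <- matrix(c(1, 2, 3, 4,
                0, 1, 0, 1,
                2, 0, 1, 3,
                1, 1, 2, 0), 4, 4)
  y <- c(-1, -1, 1, 1)
  bs <- blockset_from_matrix(X, list(1:2, 3:4), y)
  fit <- fit_mbplsr(bs, 2)
  Xs <- do.call(cbind, bs$processed)
  oracle <- oracle_nipals_pls1(sweep(Xs, 2, colMeans(Xs)), y, 2)
  expect_equal(unname(fit$super_scores),
               align_signs(unname(fit$super_scores), oracle$scores),
               tolerance = 1e-10)
  expect_equal(unname(predict(fit, bs)), oracle$fitted, tolerance = 1e-10)
})

test_that("model invariants: orthogonal scores, monotone explained variance, coefficient equivalence", {
  bs <- random_blockset(25, 40, 4, seed = 77)
  fit <- fit_mbplsr(bs, 5)
  G <- crossprod(fit$super_scores)
  expect_equal(G - diag(diag(G)), matrix(0, 5, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_Y_variance) >= -1e-12))
  expect_true(all(fit$explained_Y_variance <= 1 + 1e-12))
  # predictions from regression coefficients match the factorization
  X <- do.call(cbind, bs$processed)
  yhat_coef <- drop(X %*% fit$regression_coefficients) + fit$y_mean
  yhat_factor <- fit$y_mean +
    drop(fit$super_scores %*% fit$y_loadings)
  expect_equal(yhat_coef, unname(yhat_factor), tolerance = 1e-10)
  # sign convention: largest |weight| entry is positive per component
  for (a in 1:5) {
    w <- fit$weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("permuting variables within blocks leaves super scores unchanged", {
  bs <- random_blockset(15, 24, 3, seed = 9)
  fit <- fit_mbplsr(bs, 3)
  perm_raw <- lapply(bs$raw, function(m) {
    m[, sample(ncol(m)), drop = FALSE]
  })
  bs_perm <- blockset_from_matrix(
    do.call(cbind, perm_raw),
    split(seq_len(24), rep(seq_along(perm_raw),
                           vapply(perm_raw, ncol, integer(1)))),
    bs$y)
  fit_perm <- fit_mbplsr(bs_perm, 3)
  expect_equal(fit_perm$super_scores,
               align_signs(fit_perm$super_scores, fit$super_scores),
               tolerance = 1e-8)
  # loadings permute accordingly: same multiset of weight values
  expect_equal(sort(abs(fit$weights[, 1])), sort(abs(fit_perm$weights[, 1])),
               tolerance = 1e-10)
})

test_that("prediction degenerates gracefully", {
  bs <- random_blockset(10, 12, 2, seed = 13)
  fit <- fit_mbplsr(bs, 9)   # full rank
  expect_equal(predict(fit, bs), bs$y, tolerance = 1e-6)
  # a sample at the training mean predicts the training y mean
  mean_raw <- lapply(bs$raw, function(m) {
    matrix(colMeans(m), 1, ncol(m), dimnames = list(NULL, colnames(m)))
  })
  expect_equal(unname(predict(fit, mean_raw)), mean(bs$y), tolerance = 1e-8)
  # mismatched block structure errors
  expect_error(predict(fit, rev(bs$raw)), "structure")
  # constant y errors
  bs_const <- bs; bs_const$y <- rep(1, 10)
  expect_error(fit_mbplsr(bs_const, 2), "constant")
  # over-large ncomp truncates with warning
  expect_warning(fit_big <- fit_mbplsr(bs, 50), "truncated")
  expect_lte(fit_big$n_components, 9)
})

test_that("held-out predictions recover the arm for strong planted effects", {
  sim <- generate_study(study_design(seed = 60, noise_sd = 0.2,
                                     effect_log2fc = list(mean = 1.5, sd = 0.3)))
  bs <- build_blockset(sim$concentrations, 3)
  n <- length(bs$y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    bs_train <- lipidblocks:::subset_blockset(bs, setdiff(seq_len(n), i))
    fit <- fit_mbplsr(bs_train, 2)
    pred <- predict(fit, lapply(bs$raw, function(m) m[i, , drop = FALSE]))
    correct[i] <- sign(pred) == sign(bs$y[i])
  }
  expect_gt(mean(correct), 0.9)
})

test_that("correlation loadings are Pearson correlations with the super scores", {
  bs <- random_blockset(20, 10, 2, seed = 3)
  fit <- fit_mbplsr(bs, 2)
  cl <- correlation_loadings(fit, bs)
  X <- do.call(cbind, bs$processed)
  expect_equal(cl$comp1, unname(drop(cor(X, fit$super_scores[, 1]))),
               tolerance = 1e-12)
  expect_equal(cl$comp2, unname(drop(cor(X, fit$super_scores[, 2]))),
               tolerance = 1e-12)
  expect_equal(cl$block, fit$labels[fit$block_id])
  # a variable exactly equal to the first super score correlates (1, 0):
  # super scores of successive components are orthogonal
  expect_lt(abs(cor(fit$super_scores[, 1], fit$super_scores[, 2])), 1e-8)

  # zero-variance variable flagged NA, not silently 0
  raw0 <- bs$raw
  raw0[[2]][, 1] <- 5
  bs0 <- blockset_from_matrix(do.call(cbind, raw0),
                              split(seq_len(10),
                                    rep(seq_along(raw0),
                                        vapply(raw0, ncol, integer(1)))),
                              bs$y)
  suppressWarnings(fit0 <- fit_mbplsr(bs0, 2))
  cl0 <- correlation_loadings(fit0, bs0)
  j <- ncol(bs$raw[[1]]) + 1
  expect_true(cl0$zero_variance[j])
  expect_true(is.na(cl0$comp1[j]))
  expect_false(anyNA(cl0$comp1[-j]))
})

test_that("planted responders dominate the first-component correlation loadings", {
  # sign-balanced strong effects: responders carry the share-space signal,
  # non-responders only the small class-total compensation
  sim <- generate_study(study_design(
    seed = 71, remodeling = FALSE,
    effect_log2fc = list(mean = 1.5, sd = 0.3), effect_prob_positive = 0.5))
  bs <- build_blockset(sim$concentrations, 3)
  fit <- fit_mbplsr(bs, 2)
  cl <- correlation_loadings(fit, bs)
  tr <- sim$truth
  cl <- cl[cl$variable %in% tr$peak_id, ]
  resp <- tr$is_responder[match(cl$variable, tr$peak_id)]
  null_q95 <- quantile(abs(cl$comp1[!resp]), 0.95)
  expect_gt(mean(abs(cl$comp1[resp]) > null_q95), 0.8)
})
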