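# Multi-block PLS1 regression. The global model is a NIPALS PLS on the
# concatenated block-scaled matrix; block weights, block scores and per-block
# explained variances are readouts of that one global model (deflation is by
# the super score, not block-wise), so the super scores and predictions are
# identical to standard PLS on the concatenation.

#' Fit a multi-block PLS regression
#'
#' Sequential NIPALS components on the concatenated centered, block-scaled
#' matrix. Per component: the global weight vector `w` (unit norm, signed so
#' its largest-magnitude entry is positive), super score `t = X w`, y-loading
#' `q = t'y / t't`, loadings `p = X't / t't`, and deflation `X <- X - t p'`,
#' `y <- y - t q`. Block weights are the sub-vector of `w` for block `b`
#' renormalized to unit norm, and block scores are `t_b = X_b w_b` on the
#' current (deflated) block.
#'
#' @param blocks A `block_set` (see [build_blockset()],
#'   [blockset_from_matrix()]).
#' @param ncomp Number of components; truncated to the data rank with a
#'   warning if too large.
#' @return An object of class `mbplsr` with super scores, per-block
#'   scores/weights/loadings, y-loadings, regression coefficients (for
#'   `ncomp` components, on the processed scale), cumulative explained
#'   Y-variance and per-block per-component explained X-variance.
#' @export
fit_mbplsr <- function(blocks, ncomp) {
  stopifnot(inherits(blocks, "block_set"), ncomp >= 1)
  Xb <- blocks$processed
  p_per_block <- vapply(Xb, ncol, integer(1))
  block_id <- rep(seq_along(Xb), p_per_block)
  X <- do.call(cbind, Xb)
  n <- nrow(X)
  y <- blocks$y
  if (length(unique(y)) < 2) stop("response y is constant")
  y_mean <- mean(y)
  yc <- y - y_mean
  rank_max <- min(n - 1L, ncol(X))
  if (ncomp > rank_max) {
    warning("ncomp truncated from ", ncomp, " to rank ", rank_max)
    ncomp <- rank_max
  }

  ss_y0 <- sum(yc^2)
  ss_x_block0 <- vapply(Xb, function(m) sum(m^2), numeric(1))

  W <- P <- matrix(0, ncol(X), ncomp,
                   dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  block_weights <- lapply(p_per_block, function(p) matrix(0, p, ncomp))
  block_scores <- lapply(seq_along(Xb), function(b) matrix(0, n, ncomp))
  names(block_weights) <- names(block_scores) <- blocks$labels
  expl_y <- numeric(ncomp)
  expl_x_block <- matrix(0, length(Xb), ncomp,
                         dimnames = list(blocks$labels, NULL))
  Xd <- X
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      warning("residual X'y vanished; model truncated to ", a - 1L,
              " component(s)")
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    q_a <- sum(t_a * yd) / tt
    p_a <- drop(crossprod(Xd, t_a)) / tt
    for (b in seq_along(Xb)) {
      w_sub <- w[block_id == b]
      nb <- sqrt(sum(w_sub^2))
      wb <- if (nb > 0) w_sub / nb else w_sub
      block_weights[[b]][, a] <- wb
      block_scores[[b]][, a] <- Xd[, block_id == b, drop = FALSE] %*% wb
      expl_x_block[b, a] <- tt * sum(p_a[block_id == b]^2) / ss_x_block0[b]
    }
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    expl_y[a] <- 1 - sum(yd^2) / ss_y0
  }
  if (ncomp == 0L) stop("no usable component (X'y is zero)")
  keep <- seq_len(ncomp)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]
  block_weights <- lapply(block_weights, function(m) m[, keep, drop = FALSE])
  block_scores <- lapply(block_scores, function(m) m[, keep, drop = FALSE])

  coefficients <- mbplsr_coef(W, P, q, ncomp)
  structure(list(n_components = ncomp,
                 super_scores = Tm,
                 block_scores = block_scores,
                 block_weights = block_weights,
                 block_loadings = lapply(seq_along(Xb), function(b) {
                   P[block_id == b, , drop = FALSE]
                 }),
                 weights = W, loadings = P,
                 y_loadings = q,
                 regression_coefficients = coefficients,
                 explained_Y_variance = expl_y[keep],
                 explained_X_block_variance = expl_x_block[, keep, drop = FALSE],
                 y_mean = y_mean,
                 centers = blocks$centers,
                 scaling_factors = blocks$scaling_factors,
                 labels = blocks$labels,
                 p_per_block = p_per_block,
                 block_id = block_id),
            class = "mbplsr")
}

# regression coefficients for the first `a` components: B = W (P'W)^-1 q
mbplsr_coef <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' @export
print.mbplsr <- function(x, ...) {
  cat(sprintf("<mbplsr> %d component(s), %d blocks, %d samples\n",
              x$n_components, length(x$labels), nrow(x$super_scores)))
  cat("  cumulative explained Y variance:",
      paste(sprintf("%.3f", x$explained_Y_variance), collapse = " "), "\n")
  invisible(x)
}

# apply a fitted model's centering/scaling to new raw blocks
process_new_blocks <- function(object, blocks) {
  raw <- if (inherits(blocks, "block_set")) blocks$raw else blocks
  if (!identical(vapply(raw, ncol, integer(1)), object$p_per_block)) {
    stop("block structure of new data does not match the fitted model")
  }
  process_blocks(raw, centers = object$centers,
                 factors = object$scaling_factors)$processed
}

#' Predict from a multi-block PLS model
#'
#' New samples are centered and scaled with the training centers and block
#' scaling factors. `decompose = TRUE` additionally returns, per component
#' count `a`, each block's contribution to the prediction (the block's part
#' of the super score times the y-loading, accumulated over components),
#' which underlies the per-block validated explained variance.
#'
#' @param object A fitted `mbplsr`.
#' @param blocks A `block_set` or list of raw block matrices matching the
#'   training block structure.
#' @param ncomp Number of components to use (default: all fitted).
#' @param decompose Return per-block prediction contributions.
#' @return Numeric vector of predictions, or (with `decompose`) a list with
#'   `yhat` (samples x ncomp matrix, cumulative by component) and
#'   `block_contrib` (samples x blocks x ncomp array, cumulative).
#' @export
predict.mbplsr <- function(object, blocks, ncomp = object$n_components,
                           decompose = FALSE, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$n_components)
  Xb <- process_new_blocks(object, blocks)
  X <- do.call(cbind, Xb)
  if (!decompose) {
    B <- mbplsr_coef(object$weights, object$loadings, object$y_loadings, ncomp)
    return(drop(X %*% B) + object$y_mean)
  }
  n <- nrow(X)
  nb <- length(object$labels)
  yhat <- matrix(0, n, ncomp)
  contrib <- array(0, c(n, nb, ncomp),
                   dimnames = list(NULL, object$labels, NULL))
  Xd <- X
  acc <- 0
  acc_b <- matrix(0, n, nb)
  for (a in seq_len(ncomp)) {
    w <- object$weights[, a]
    t_a <- drop(Xd %*% w)
    for (b in seq_len(nb)) {
      jb <- object$block_id == b
      t_b_part <- drop(Xd[, jb, drop = FALSE] %*% w[jb])
      acc_b[, b] <- acc_b[, b] + t_b_part * object$y_loadings[a]
    }
    acc <- acc + t_a * object$y_loadings[a]
    yhat[, a] <- acc + object$y_mean
    contrib[, , a] <- acc_b
    Xd <- Xd - tcrossprod(t_a, object$loadings[, a])
  }
  list(yhat = yhat, block_contrib = contrib)
}

#' Correlation loadings
#'
#' Pearson correlation of every (processed) variable with the super scores of
#' the requested components; the standard readout for identifying which
#' species drive a component.
#'
#' @param model A fitted `mbplsr`.
#' @param blocks The `block_set` the model was fitted to.
#' @param components Integer vector of components (default first two).
#' @return Data frame with `variable`, `block`, one correlation column per
#'   component, and `zero_variance` flagging variables whose correlation is
#'   undefined (recorded as `NA`, not 0).
#' @export
correlation_loadings <- function(model, blocks, components = c(1L, 2L)) {
  stopifnot(inherits(model, "mbplsr"),
            all(components <= model$n_components))
  Xb <- process_new_blocks(model, blocks)
  X <- do.call(cbind, Xb)
  sds <- apply(X, 2, stats::sd)
  zero_var <- sds == 0
  out <- data.frame(variable = colnames(X),
                    block = model$labels[model$block_id],
                    stringsAsFactors = FALSE)
  for (a in components) {
    r <- rep(NA_real_, ncol(X))
    r[!zero_var] <- drop(stats::cor(X[, !zero_var, drop = FALSE],
                                    model$super_scores[, a]))
    out[[paste0("comp", a)]] <- r
  }
  out$zero_variance <- zero_var
  out
}
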