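# Cross-validation, RMSECV component selection, per-block validated
# explained variance, jack-knife coefficient significance, and Hotelling T2
# score outlier flagging.

subset_blockset <- function(blocks, rows) {
  raw <- lapply(blocks$raw, function(m) m[rows, , drop = FALSE])
  new_blockset(raw, blocks$y[rows], blocks$labels,
               samples = if (!is.null(blocks$samples)) {
                 blocks$samples[rows, , drop = FALSE]
               },
               species_map = blocks$species_map)
}

#' Cross-validation folds
#'
#' @param blocks A `block_set`.
#' @param scheme `"loo"` for leave-one-out (rows of the baseline-adjusted
#'   data are subjects, so this is leave-one-subject-out), an integer number
#'   of folds (assigned round-robin within each group so both arms stay
#'   represented in every training set), or an explicit list of held-out
#'   index vectors.
#' @return List of integer vectors of held-out rows.
#' @export
cv_folds <- function(blocks, scheme = "loo") {
  n <- length(blocks$y)
  if (is.list(scheme)) {
    folds <- lapply(scheme, as.integer)
  } else if (identical(scheme, "loo")) {
    folds <- as.list(seq_len(n))
  } else if (is.numeric(scheme) && length(scheme) == 1L) {
    k <- as.integer(scheme)
    stopifnot(k >= 2, k <= n)
    assign <- integer(n)
    for (g in unique(blocks$y)) {
      idx <- which(blocks$y == g)
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds <- split(seq_len(n), assign)
  } else {
    stop("scheme must be 'loo', an integer fold count, or a list of index vectors")
  }
  if (length(folds) < 2) stop("need at least 2 folds")
  stopifnot(setequal(unlist(folds), seq_len(n)),
            !anyDuplicated(unlist(folds)))
  binary <- length(unique(blocks$y)) == 2L
  for (f in folds) {
    if (binary && length(unique(blocks$y[-f])) < 2) {
      stop("a fold leaves only one group in the training set")
    }
  }
  folds
}

#' Cross-validate a multi-block PLS model
#'
#' For each fold, centering and block scaling are recomputed on the training
#' samples only, the model is refitted, and held-out samples are predicted
#' with 1..`A_max` components. Reports the global RMSECV curve (component 0
#' is the null mean predictor), the validated explained Y-variance, and the
#' per-block validated explained Y-variance computed from each block's
#' contribution to the cross-validated predictions alone (its share of the
#' super score times the y-loading), normalized by the total y sum of
#' squares.
#'
#' @param blocks A `block_set`.
#' @param A_max Largest number of components to assess.
#' @param scheme Fold scheme, see [cv_folds()].
#' @param .leak_preprocessing Diagnostic flag: if `TRUE`, centering and
#'   scaling from the full data are (wrongly) reused in every fold. Only for
#'   demonstrating the leakage effect; never use for inference.
#' @return An object of class `mbplsr_cv`: `rmsecv` (components 0..A_max),
#'   `validated_explained_Y`, `validated_explained_Y_per_block` (blocks x
#'   components), `selected_A`, `fold_assignments`.
#' @export
cross_validate <- function(blocks, A_max, scheme = "loo",
                           .leak_preprocessing = FALSE) {
  stopifnot(inherits(blocks, "block_set"), A_max >= 1)
  folds <- cv_folds(blocks, scheme)
  n <- length(blocks$y)
  p_tot <- sum(vapply(blocks$raw, ncol, integer(1)))
  A_eff <- min(A_max, min(lengths(lapply(folds, function(f) seq_len(n)[-f]))) - 1L,
               p_tot)
  if (A_eff < A_max) {
    warning("A_max reduced to ", A_eff, " (training-set rank limit)")
  }
  y <- blocks$y
  tss <- sum((y - mean(y))^2)
  nb <- length(blocks$labels)

  press <- numeric(A_eff)
  press_block <- matrix(0, nb, A_eff, dimnames = list(blocks$labels, NULL))
  fold_assignments <- integer(n)
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    train <- setdiff(seq_len(n), test)
    fold_assignments[test] <- k
    bs_train <- subset_blockset(blocks, train)
    if (.leak_preprocessing) {
      bs_train$processed <- process_blocks(bs_train$raw, blocks$centers,
                                           blocks$scaling_factors)$processed
      bs_train$centers <- blocks$centers
      bs_train$scaling_factors <- blocks$scaling_factors
    }
    fit <- suppressWarnings(fit_mbplsr(bs_train, A_eff))
    a_fit <- fit$n_components
    test_raw <- lapply(blocks$raw, function(m) m[test, , drop = FALSE])
    pred <- predict(fit, test_raw, ncomp = a_fit, decompose = TRUE)
    for (a in seq_len(A_eff)) {
      a_use <- min(a, a_fit)
      press[a] <- press[a] + sum((y[test] - pred$yhat[, a_use])^2)
      contrib_a <- matrix(pred$block_contrib[, , a_use],
                          nrow = length(test), ncol = nb)
      resid_b <- (y[test] - fit$y_mean) - contrib_a
      press_block[, a] <- press_block[, a] + colSums(resid_b^2)
    }
  }
  # component 0: the null model predicts the mean of centered y
  rmsecv <- c(sqrt(tss / n), sqrt(press / n))
  names(rmsecv) <- as.character(0:A_eff)
  val_expl <- 1 - press / tss
  val_expl_block <- 1 - press_block / tss
  res <- structure(list(rmsecv = rmsecv,
                        validated_explained_Y = val_expl,
                        validated_explained_Y_per_block = val_expl_block,
                        fold_assignments = fold_assignments,
                        A_max = A_eff,
                        n = n),
                   class = "mbplsr_cv")
  res$selected_A <- select_components(res)
  res
}

#' @export
print.mbplsr_cv <- function(x, ...) {
  cat(sprintf("<mbplsr_cv> %d samples, %d folds, A_max=%d, selected A=%d\n",
              x$n, max(x$fold_assignments), x$A_max, x$selected_A))
  cat("  RMSECV:", paste(sprintf("%.3f", x$rmsecv), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of components from the RMSECV curve
#'
#' Returns the arg-min of the RMSECV curve, counting the null model as 0
#' components; exact ties break toward fewer components. An explicit
#' `override` (e.g. a choice made by inspecting the curve) short-circuits
#' the rule.
#'
#' @param result An `mbplsr_cv` object or a numeric RMSECV vector whose
#'   first element is the 0-component null model.
#' @param override Optional integer forced choice.
#' @return Integer number of components.
#' @export
select_components <- function(result, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  rmsecv <- if (inherits(result, "mbplsr_cv")) result$rmsecv else result
  sel <- unname(which.min(rmsecv)) - 1L
  if (sel == 0L) {
    warning("RMSECV is minimized by the null model; no component is supported")
  }
  sel
}

#' Jack-knife significance of regression coefficients
#'
#' Refits the model on every cross-validation segment and measures the
#' stability of each variable's regression coefficient (expressed on the
#' original variable scale, so segments with different block scaling are
#' comparable). The jack-knife variance against the full-model coefficient,
#' `s_j^2 = (K-1)/K * sum_k (b_j^(k) - b_j)^2`, yields `t_j = b_j / s_j` and
#' a two-sided p-value on K-1 degrees of freedom.
#'
#' @param blocks A `block_set`.
#' @param A Number of components of the model under test.
#' @param scheme Fold scheme, see [cv_folds()].
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame per variable: `variable`, `block`, `coefficient`,
#'   `jackknife_sd`, `t`, `p`, `significant`, `degenerate` (coefficient with
#'   zero jack-knife spread).
#' @export
jackknife_significance <- function(blocks, A, scheme = "loo", alpha = 0.05) {
  stopifnot(inherits(blocks, "block_set"), A >= 1)
  folds <- cv_folds(blocks, scheme)
  K <- length(folds)
  full <- fit_mbplsr(blocks, A)
  raw_scale <- function(fit) {
    fit$regression_coefficients / fit$scaling_factors[fit$block_id]
  }
  b_full <- raw_scale(full)
  b_seg <- matrix(0, length(b_full), K)
  for (k in seq_len(K)) {
    bs_train <- subset_blockset(blocks, setdiff(seq_along(blocks$y), folds[[k]]))
    fit_k <- suppressWarnings(fit_mbplsr(bs_train, A))
    if (fit_k$n_components < A) {
      stop("segment ", k, " supports only ", fit_k$n_components,
           " component(s); lower A")
    }
    b_seg[, k] <- raw_scale(fit_k)
  }
  s2 <- rowSums((b_seg - b_full)^2) * (K - 1) / K
  s <- sqrt(s2)
  ok <- s > 0
  t_stat <- ifelse(ok, b_full / s, ifelse(b_full == 0, 0, Inf * sign(b_full)))
  p <- rep(1, length(b_full))
  p[ok] <- 2 * stats::pt(-abs(t_stat[ok]), df = K - 1)
  p[!ok & b_full != 0] <- 0
  degenerate <- !ok & b_full != 0
  data.frame(variable = names(b_full),
             block = full$labels[full$block_id],
             coefficient = unname(b_full),
             jackknife_sd = unname(s),
             t = unname(t_stat),
             p = unname(p),
             significant = unname(p < alpha),
             degenerate = unname(degenerate),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag score-space outliers by Hotelling T2
#'
#' Computes each sample's Hotelling T2 over the model's super scores and
#' flags samples exceeding the F-distribution control limit
#' `A(n-1)/(n-A) * F_{1-level}(A, n-A)`. Flags are advisory: excluding a
#' subject is an explicit user decision.
#'
#' @param model A fitted `mbplsr`.
#' @param level Confidence level of the control limit.
#' @return Data frame `sample`, `T2`, `flagged`, with the limit in
#'   `attr(, "limit")`.
#' @export
detect_outliers <- function(model, level = 0.95) {
  stopifnot(inherits(model, "mbplsr"), level > 0, level < 1)
  Tm <- model$super_scores
  n <- nrow(Tm)
  A <- ncol(Tm)
  if (A >= n - 1) stop("T2 limit undefined for A >= n - 1")
  score_var <- colSums(Tm^2) / (n - 1)
  if (all(score_var == 0)) {
    t2 <- rep(0, n)
  } else {
    score_var[score_var == 0] <- Inf  # degenerate direction contributes 0
    t2 <- rowSums(sweep(Tm^2, 2, score_var, "/"))
  }
  limit <- A * (n - 1) / (n - A) * stats::qf(level, A, n - A)
  out <- data.frame(sample = rownames(Tm) %||% seq_len(n),
                    T2 = t2,
                    flagged = t2 > limit)
  attr(out, "limit") <- limit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
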