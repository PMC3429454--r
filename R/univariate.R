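# Univariate screening: per-lipid fold changes from baseline, two-sample
# Student's t on the baseline-adjusted log2 ratios, and FDR q-values.

#' Fold change from baseline
#'
#' Per species, the geometric mean over an arm's subjects of the per-subject
#' ratio `conc_week / conc_week0`, i.e. `2^mean(log2 ratio)`. The geometric
#' mean is coherent with the log2-scale analysis; an arithmetic-mean variant
#' is available via `aggregate = "arithmetic"`.
#'
#' @param conc A concentration [lipid_dataset()].
#' @param arm `"FO"` or `"HOSO"`.
#' @param week Analysis week.
#' @param aggregate `"geometric"` (default) or `"arithmetic"`.
#' @param floor Optional concentration floor, see [log2_baseline_adjust()].
#' @return Named numeric vector of fold changes per peak.
#' @export
fold_change_from_baseline <- function(conc, arm = c("FO", "HOSO"), week,
                                      aggregate = c("geometric", "arithmetic"),
                                      floor = NULL) {
  arm <- match.arg(arm)
  aggregate <- match.arg(aggregate)
  adj <- log2_baseline_adjust(conc, week, floor = floor)
  rows <- adj$subjects$arm == arm
  if (!any(rows)) stop("no subjects in arm ", arm)
  if (aggregate == "geometric") {
    2^colMeans(adj$ratios[rows, , drop = FALSE])
  } else {
    colMeans(2^adj$ratios[rows, , drop = FALSE])
  }
}

#' Pooled two-sample Student's t test
#'
#' Two-sided pooled-variance t test (Welch available via
#' `var_equal = FALSE`). Degenerate inputs are resolved explicitly: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors (at least 2 finite values each).
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 finite values per group")
  d <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (d == 0) {
      return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    }
    return(list(t = Inf * sign(d), p = 0, df = df, degenerate = TRUE))
  }
  t_stat <- d / se
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df), df = df,
       degenerate = FALSE)
}

# vectorized pooled t over the columns of a ratio matrix
t_test_columns <- function(ratios, group1, group2) {
  m1 <- colMeans(ratios[group1, , drop = FALSE])
  m2 <- colMeans(ratios[group2, , drop = FALSE])
  n1 <- sum(group1); n2 <- sum(group2)
  v1 <- apply(ratios[group1, , drop = FALSE], 2, stats::var)
  v2 <- apply(ratios[group2, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  d <- m1 - m2
  t_stat <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(ifelse(se > 0, d / se, 0)), df),
              ifelse(d == 0, 1, 0))
  data.frame(t = t_stat, p = p, df = df,
             degenerate = se == 0 & d != 0)
}

#' FDR q-values (Storey or Benjamini-Hochberg)
#'
#' The default is the Storey procedure: the null proportion pi0 is estimated
#' on the grid `lambda = 0.05, 0.10, ..., 0.90` via
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)`, smoothed with a cubic
#' smoothing spline (df = 3) and read off at the largest lambda; then
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. `method = "bh"` fixes
#' `pi0 = 1`, which reproduces `stats::p.adjust(method = "BH")` exactly.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 (overrides estimation).
#' @return Numeric vector of q-values, in the input order, with the
#'   estimated pi0 in `attr(, "pi0")`.
#' @export
fdr_qvalues <- function(p, method = c("storey", "bh"),
                        lambda = seq(0.05, 0.90, by = 0.05), pi0 = NULL) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (method == "bh") {
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                           numeric(1))
      if (m >= 4 && length(lambda) >= 4 && stats::var(pi0_lambda) > 0) {
        fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
      } else {
        pi0 <- min(pi0_lambda)
      }
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warning("estimated pi0 <= 0; clamping to a small positive value")
        pi0 <- .Machine$double.eps
      }
    }
  }
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Build the per-lipid result table
#'
#' One row per identified peak: fold changes from baseline in each arm,
#' pooled t test of FO vs HOSO on the baseline-adjusted log2 ratios, FDR
#' q-values, direction (increased means FO fold change from baseline > 1),
#' and significance flags from both the univariate route (`q < fdr_threshold`)
#' and, when supplied, the MBPLSR jack-knife route.
#'
#' @param conc A concentration [lipid_dataset()].
#' @param week Analysis week.
#' @param jackknife Optional data frame from [jackknife_significance()];
#'   its per-species rows are matched by peak id (rows for class totals are
#'   ignored).
#' @param fdr_threshold Univariate significance threshold on q.
#' @param fdr_method Passed to [fdr_qvalues()].
#' @param floor Optional concentration floor.
#' @return Data frame with one row per identified peak.
#' @export
build_result_table <- function(conc, week, jackknife = NULL,
                               fdr_threshold = 0.05,
                               fdr_method = "storey", floor = NULL) {
  stopifnot(inherits(conc, "lipid_dataset"))
  keep <- conc$species$identified
  species <- conc$species[keep, , drop = FALSE]
  conc_id <- lipid_dataset(conc$values[, keep, drop = FALSE], conc$samples,
                           species, unit = "concentration")
  adj <- log2_baseline_adjust(conc_id, week, floor = floor)
  fo <- adj$subjects$arm == "FO"
  tests <- t_test_columns(adj$ratios, fo, !fo)
  q <- fdr_qvalues(tests$p, method = fdr_method)
  fc_fo <- fold_change_from_baseline(conc_id, "FO", week, floor = floor)
  fc_hoso <- fold_change_from_baseline(conc_id, "HOSO", week, floor = floor)
  out <- data.frame(peak_id = species$peak_id,
                    raw_name = species$raw_name,
                    lipid_class = species$lipid_class,
                    fold_change_FO = unname(fc_fo),
                    fold_change_HOSO = unname(fc_hoso),
                    t_statistic = tests$t,
                    p_value = tests$p,
                    q_value = as.numeric(q),
                    degenerate = tests$degenerate,
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$fold_change_FO > 1, "increased", "decreased")
  out$significant_univariate <- out$q_value < fdr_threshold
  if (!is.null(jackknife)) {
    hit <- match(out$peak_id, jackknife$variable)
    if (anyNA(hit)) {
      stop("jackknife results do not cover all peaks: upstream stage mismatch")
    }
    out$significant_mbplsr <- jackknife$significant[hit]
  } else {
    out$significant_mbplsr <- NA
  }
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "week") <- week
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}
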