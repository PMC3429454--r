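make_conc <- function(vals, arms, weeks = NULL, names = NULL) {
  n_subj <- length(arms)
  if (is.null(weeks)) weeks <- c(0, 3)
  if (is.null(names)) names <- sprintf("PC(3%d:2)", seq_len(ncol(vals)))
  ann <- annotate_species(data.frame(
    peak_id = paste0("p", seq_len(ncol(vals))), raw_name = names))
  samples <- data.frame(subject_id = rep(paste0("s", seq_len(n_subj)),
                                         each = length(weeks)),
                        arm = rep(arms, each = length(weeks)),
                        week = rep(weeks, n_subj))
  lipid_dataset(vals, samples, ann, unit = "concentration")
}

test_that("fold change from baseline is the geometric mean of subject ratios", {
  # three FO subjects with ratios 2, 2, 2 and two HOSO with ratios 4, 1
  vals <- rbind(c(1), c(2), c(1), c(2), c(1), c(2),   # FO: ratio 2 each
                c(1), c(4), c(1), c(1))               # HOSO: ratios 4 and 1
  conc <- make_conc(vals, c("FO", "FO", "FO", "HOSO", "HOSO"))
  expect_equal(unname(fold_change_from_baseline(conc, "FO", 3)), 2)
  expect_equal(unname(fold_change_from_baseline(conc, "HOSO", 3)), 2)
  # arithmetic option gives 2.5 for the {4, 1} pair
  expect_equal(unname(fold_change_from_baseline(conc, "HOSO", 3,
                                                aggregate = "arithmetic")),
               2.5)
})

test_that("a planted noise-free effect reproduces its fold change", {
  sizes <- c(PC = 5, TG = 5)
  delta <- c(log2(4.35), rep(0, 9))
  sim <- generate_study(study_design(
    n_fo = 6, n_hoso = 6, class_sizes = sizes, effect_log2fc = delta,
    subject_sd = 0, noise_sd = 0, drift_sd = 0, remodeling = FALSE,
    seed = 8))
  fc <- fold_change_from_baseline(sim$concentrations, "FO", 3)
  expect_equal(unname(fc[1]), 4.35, tolerance = 1e-9)
  expect_equal(unname(fc[-1]), rep(1, 9), tolerance = 1e-12)
})

test_that("pooled two-sample t matches the closed form and t.test", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)  # -3.674...
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)

  for (s in 1:5) {
    withr::with_seed(s, { x <- rnorm(9); y <- rnorm(12, 0.5) })
    mine <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    welch <- two_sample_t(x, y, var_equal = FALSE)
    ref_w <- t.test(x, y)
    expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(welch$p, ref_w$p.value, tolerance = 1e-12)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-9)
  }

  ident <- two_sample_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_false(ident$degenerate)
  sep <- two_sample_t(c(1, 1), c(2, 2))
  expect_equal(sep$p, 0)
  expect_true(sep$degenerate)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("vectorized column t-tests agree with the scalar routine", {
  withr::with_seed(11, mat <- matrix(rnorm(20 * 6), 20, 6))
  g <- rep(c(TRUE, FALSE), each = 10)
  cols <- lipidblocks:::t_test_columns(mat, g, !g)
  for (j in 1:6) {
    ref <- two_sample_t(mat[g, j], mat[!g, j])
    expect_equal(cols$t[j], ref$t, tolerance = 1e-12)
    expect_equal(cols$p[j], ref$p, tolerance = 1e-12)
  }
})

test_that("q-values: BH mode reproduces p.adjust and the step-up example", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- fdr_qvalues(p, method = "bh")
  expect_equal(as.numeric(q), rep(0.04, 4))
  for (s in 1:4) {
    withr::with_seed(s, pv <- runif(200)^1.5)
    expect_equal(as.numeric(fdr_qvalues(pv, method = "bh")),
                 p.adjust(pv, method = "BH"), tolerance = 1e-12)
    # Storey with pi0 forced to 1 is exactly BH
    expect_equal(as.numeric(fdr_qvalues(pv, method = "storey", pi0 = 1)),
                 p.adjust(pv, method = "BH"), tolerance = 1e-12)
  }
  expect_equal(as.numeric(fdr_qvalues(0.03, pi0 = 1)), 0.03)
  expect_equal(as.numeric(fdr_qvalues(rep(1, 5), method = "bh")), rep(1, 5))
  expect_identical(fdr_qvalues(numeric(0)), numeric(0))
  expect_error(fdr_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey q-values shrink toward pi0 and stay monotone in p", {
  withr::with_seed(21, pv <- c(runif(150), rbeta(50, 0.2, 5)))
  q <- fdr_qvalues(pv, method = "storey")
  pi0 <- attr(q, "pi0")
  expect_gt(pi0, 0.3)
  expect_lte(pi0, 1)
  # q = pi0 * BH
  expect_equal(as.numeric(q),
               pmin(pi0 * p.adjust(pv, "BH"), 1), tolerance = 1e-12)
  ord <- order(pv)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("the result table reproduces the published counting logic", {
  # build a concentration dataset whose fold changes mimic the fixture rows
  tab <- tables_fixture()
  n_lip <- nrow(tab)
  n_fo <- 4; n_hoso <- 4
  base <- matrix(10, 2 * (n_fo + n_hoso), n_lip)
  arms <- rep(c("FO", "HOSO"), c(n_fo, n_hoso))
  week_rows <- seq(2, nrow(base), by = 2)
  fo_rows <- week_rows[arms == "FO"]
  ho_rows <- week_rows[arms == "HOSO"]
  base[fo_rows, ] <- rep(10 * tab$fold_change_FO, each = n_fo)
  base[ho_rows, ] <- rep(10 * tab$fold_change_HOSO, each = n_hoso)
  # small per-subject jitter so the t test is defined
  withr::with_seed(2, base[week_rows, ] <- base[week_rows, ] *
                     2^matrix(rnorm(length(week_rows) * n_lip, 0, 0.01),
                              length(week_rows), n_lip))
  ann <- annotate_species(data.frame(peak_id = paste0("p", seq_len(n_lip)),
                                     raw_name = tab$raw_name))
  samples <- data.frame(subject_id = rep(paste0("s", seq_len(n_fo + n_hoso)),
                                         each = 2),
                        arm = rep(arms, each = 2),
                        week = rep(c(0, 3), n_fo + n_hoso))
  conc <- lipid_dataset(base, samples, ann, unit = "concentration")
  rt <- build_result_table(conc, 3, fdr_method = "bh")
  expect_equal(nrow(rt), 74)
  expect_equal(rt$fold_change_FO, tab$fold_change_FO, tolerance = 0.02)
  expect_equal(rt$fold_change_HOSO, tab$fold_change_HOSO, tolerance = 0.02)
  expect_equal(sum(rt$direction == "increased"), 51)
  expect_equal(sum(rt$direction == "decreased"), 23)
  expect_equal(sum(rt$significant_univariate), 74)
  expect_equal(sum(rt$direction == "increased") +
                 sum(rt$direction == "decreased"), nrow(rt))
  # directions follow the FO fold change, not the FO/HOSO contrast
  expect_true(all((rt$fold_change_FO > 1) == (rt$direction == "increased")))
})

test_that("result table wires jack-knife flags and rejects stage mismatches", {
  sim <- generate_study(tiny_design(seed = 33))
  conc <- normalize_intensities(sim$dataset, sim$standards)
  bs <- build_blockset(conc, 3)
  jk <- jackknife_significance(bs, 2)
  rt <- build_result_table(conc, 3, jackknife = jk)
  expect_equal(nrow(rt), sum(conc$species$identified))
  expect_type(rt$significant_mbplsr, "logical")
  expect_false(anyNA(rt$significant_mbplsr))
  jk_bad <- jk[-(1:3), ]
  expect_error(build_result_table(conc, 3, jackknife = jk_bad), "mismatch")
})

test_that("null simulations control the FDR and give uniform p-values", {
  qrate <- numeric(8); pks <- numeric(8)
  for (r in 1:8) {
    sim <- generate_study(tiny_design(seed = 900 + r, responder_fraction = 0))
    rt <- build_result_table(sim$concentrations, 3)
    qrate[r] <- mean(rt$q_value < 0.05)
    pks[r] <- stats::ks.test(rt$p_value, "punif")$p.value
  }
  expect_lte(mean(qrate), 0.05)
  # aggregate uniformity: Fisher combination of per-replicate KS p-values
  fisher <- -2 * sum(log(pks))
  expect_gt(stats::pchisq(fisher, df = 2 * length(pks), lower.tail = FALSE),
            0.01)
})
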