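# Synthetic two-arm, three-timepoint lipidomics study generator.
#
# The generator works on the log2 concentration scale:
#   log2 conc(s, j, w) = mu_j + b_s + 1[arm=FO, w>0] * delta_j * decay(w)
#                             + 1[arm=HOSO, w>0] * eta_{j,w} + eps_{s,j,w}
# with subject effects b_s ~ N(0, subject_sd^2), control-arm drift
# eta ~ N(0, drift_sd^2) shared by all HOSO subjects, and residual noise
# eps ~ N(0, noise_sd^2). Under remodeling, post-effect concentrations in
# each FO sample are rescaled per class so the class total equals the class
# total before the effect was applied: within-class composition changes
# while the "sums of lipids" stay put. Raw intensities are constructed by
# inverting the internal-standard normalization, so normalize_intensities()
# recovers the concentrations exactly.

DEFAULT_CLASS_SIZES <- c(Cer = 15L, lysoPC = 12L, lysoPE = 6L, PA = 8L,
                         PC = 70L, PE = 30L, PG = 12L, PS = 16L, SM = 20L,
                         TG = 70L, PI = 1L)

DEFAULT_STANDARD_CONC <- c("PC(17:0/0:0)" = 5, "PC(17:0/17:0)" = 10,
                           "PE(17:0/17:0)" = 5, "Cer(d18:1/17:0)" = 2.5,
                           "TG(17:0/17:0/17:0)" = 10)

#' Default species counts per lipid class
#'
#' Sizes approximate the class representation of an identified plasma
#' lipidome of 260 species (PC and TG largest, a single PI species); they are
#' simulation defaults, not measured values.
#'
#' @return Named integer vector over the 11 lipid classes, summing to 260.
#' @export
default_class_sizes <- function() DEFAULT_CLASS_SIZES

#' Describe a synthetic two-arm intervention study
#'
#' Defines the design of a simulated fish-oil (FO) versus high-oleic
#' sunflower-oil (HOSO) plasma lipidomics study: arm sizes, sampling weeks,
#' species counts per lipid class, which fraction of species respond to the
#' intervention and how strongly, and the variance components of the log2
#' concentration model.
#'
#' @param n_fo,n_hoso Subjects per arm.
#' @param weeks Sampling weeks; must contain 0 (the baseline).
#' @param class_sizes Named integer vector of species counts per class.
#' @param responder_fraction Fraction of species per class that receive an
#'   intervention effect in the FO arm.
#' @param effect_log2fc Either `list(mean =, sd =)` describing the magnitude
#'   distribution |delta| ~ N(mean, sd^2) truncated below at `effect_min`, or
#'   a numeric vector of explicit per-species log2 effects (nonzero entries
#'   define the responders and `responder_fraction` is ignored).
#' @param effect_prob_positive Probability that a drawn effect is positive.
#' @param effect_min Lower truncation for drawn effect magnitudes.
#' @param subject_sd Between-subject log2 SD (a global subject offset).
#' @param noise_sd Residual log2 SD per sample x species.
#' @param drift_sd SD of the HOSO-only per-species week effect. The default
#'   0 models a control arm with no systematic lipidome change, matching the
#'   stable control-oil design; any positive value plants genuine group
#'   differences in every species and is meant for stress-testing.
#' @param week7_decay Multiplier applied to the FO effect at week 7
#'   (default 1: the week-3 effect persists).
#' @param remodeling If `TRUE` (default), FO class totals are held at their
#'   pre-effect values so the intervention remodels composition within
#'   classes only.
#' @param mu_mean,mu_sd Mean and SD of baseline log2 concentrations.
#' @param is_nominal_intensity,is_intensity_cv Log-normal model of the
#'   per-sample measured internal-standard intensities.
#' @param standard_concentrations Named vector of spiked standard
#'   concentrations (micromolar).
#' @param sm_standard Internal standard assigned to SM species.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_fo = 16L, n_hoso = 17L, weeks = c(0, 3, 7),
                         class_sizes = default_class_sizes(),
                         responder_fraction = 0.28,
                         effect_log2fc = list(mean = 0.94, sd = 0.60),
                         effect_prob_positive = 0.68,
                         effect_min = 0.29,
                         subject_sd = 0.3, noise_sd = 0.3, drift_sd = 0,
                         week7_decay = 1, remodeling = TRUE,
                         mu_mean = 3, mu_sd = 1,
                         is_nominal_intensity = 1e5, is_intensity_cv = 0.2,
                         standard_concentrations = DEFAULT_STANDARD_CONC,
                         sm_standard = "PC(17:0/17:0)",
                         seed = 1L) {
  stopifnot(n_fo >= 1, n_hoso >= 1, all(class_sizes >= 0),
            subject_sd >= 0, noise_sd >= 0, drift_sd >= 0,
            responder_fraction >= 0, responder_fraction <= 1,
            is_nominal_intensity > 0, is_intensity_cv >= 0)
  if (!0 %in% weeks) stop("weeks must contain 0: the baseline is mandatory")
  if (is.null(names(class_sizes)) ||
      !all(names(class_sizes) %in% lipid_classes())) {
    stop("class_sizes must be named by canonical lipid classes")
  }
  if (is.numeric(effect_log2fc)) {
    if (length(effect_log2fc) != sum(class_sizes)) {
      stop("explicit effect_log2fc must have one value per species (",
           sum(class_sizes), ")")
    }
  } else if (!is.list(effect_log2fc) ||
             !all(c("mean", "sd") %in% names(effect_log2fc))) {
    stop("effect_log2fc must be list(mean =, sd =) or an explicit numeric vector")
  }
  structure(list(n_fo = as.integer(n_fo), n_hoso = as.integer(n_hoso),
                 weeks = sort(unique(weeks)),
                 class_sizes = class_sizes,
                 responder_fraction = responder_fraction,
                 effect_log2fc = effect_log2fc,
                 effect_prob_positive = effect_prob_positive,
                 effect_min = effect_min,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 drift_sd = drift_sd, week7_decay = week7_decay,
                 remodeling = isTRUE(remodeling),
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 is_nominal_intensity = is_nominal_intensity,
                 is_intensity_cv = is_intensity_cv,
                 standard_concentrations = standard_concentrations,
                 sm_standard = sm_standard,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> FO n=%d, HOSO n=%d, weeks %s, %d species\n",
              x$n_fo, x$n_hoso, paste(x$weeks, collapse = "/"),
              sum(x$class_sizes)))
  cat(sprintf("  responder_fraction=%.2f, subject_sd=%.2f, noise_sd=%.2f, drift_sd=%.2f, remodeling=%s\n",
              x$responder_fraction, x$subject_sd, x$noise_sd, x$drift_sd,
              x$remodeling))
  invisible(x)
}

# plausible shorthand names per class (cosmetic: exercises the parser)
synth_species_names <- function(class_sizes) {
  one_name <- function(cls) {
    switch(cls,
      Cer = sprintf("Cer(d18:1/%d:%d)", sample(16:26, 1), sample(0:2, 1)),
      SM = sprintf("SM(d18:%d/%d:%d)", sample(0:1, 1), sample(14:26, 1),
                   sample(0:2, 1)),
      lysoPC = sprintf("LysoPC(%d:%d)", sample(14:22, 1), sample(0:6, 1)),
      lysoPE = sprintf("LysoPE(%d:%d)", sample(16:22, 1), sample(0:6, 1)),
      TG = sprintf("TG(%d:%d)", sample(44:60, 1), sample(0:12, 1)),
      sprintf("%s(%d:%d%s)", cls, sample(30:44, 1), sample(0:8, 1),
              if (stats::runif(1) < 0.15) "e" else ""))
  }
  unlist(lapply(names(class_sizes), function(cls) {
    vapply(seq_len(class_sizes[[cls]]), function(i) one_name(cls), character(1))
  }))
}

#' Generate a synthetic study
#'
#' Simulates raw intensities, internal-standard measurements and ground-truth
#' effect labels under the design's log2 concentration model. Raw intensities
#' are built as `conc * IS_intensity / IS_concentration`, the exact inverse of
#' [normalize_intensities()].
#'
#' @param design A [study_design()].
#' @return A list with elements `dataset` (raw-intensity [lipid_dataset()]),
#'   `standards` ([standards_table()]), `truth` (data frame `peak_id`,
#'   `lipid_class`, `is_responder`, `true_log2fc`), `concentrations` (the
#'   generated concentration [lipid_dataset()], kept for verification) and
#'   `design`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::with_seed(design$seed, generate_study_impl(design))
}

generate_study_impl <- function(design) {
  class_sizes <- design$class_sizes[design$class_sizes > 0]
  n_species <- sum(class_sizes)
  classes <- rep(names(class_sizes), class_sizes)
  peak_ids <- sprintf("P%03d", seq_len(n_species))

  species <- annotate_species(data.frame(
    peak_id = peak_ids,
    raw_name = synth_species_names(class_sizes),
    identified = TRUE))

  n_subj <- design$n_fo + design$n_hoso
  subjects <- c(sprintf("FO%02d", seq_len(design$n_fo)),
                sprintf("HO%02d", seq_len(design$n_hoso)))
  arms <- rep(c("FO", "HOSO"), c(design$n_fo, design$n_hoso))
  samples <- data.frame(
    subject_id = rep(subjects, each = length(design$weeks)),
    arm = rep(arms, each = length(design$weeks)),
    week = rep(design$weeks, times = n_subj))
  n_rows <- nrow(samples)

  # responders and effect sizes
  if (is.numeric(design$effect_log2fc)) {
    delta <- design$effect_log2fc
    is_responder <- delta != 0
  } else {
    is_responder <- logical(n_species)
    for (cls in names(class_sizes)) {
      idx <- which(classes == cls)
      n_resp <- round(design$responder_fraction * length(idx))
      if (n_resp > 0) {
        is_responder[sample(idx, n_resp)] <- TRUE
      }
    }
    magnitude <- abs(stats::rnorm(n_species, design$effect_log2fc$mean,
                                  design$effect_log2fc$sd))
    magnitude <- pmax(magnitude, design$effect_min)
    sign <- ifelse(stats::runif(n_species) < design$effect_prob_positive, 1, -1)
    delta <- ifelse(is_responder, sign * magnitude, 0)
  }
  if (design$remodeling) {
    lone <- names(class_sizes)[class_sizes == 1]
    lone_hit <- lone[vapply(lone, function(cls) {
      any(is_responder[classes == cls])
    }, logical(1))]
    if (length(lone_hit)) {
      warning("remodeling with responder(s) in single-species class(es) ",
              paste(lone_hit, collapse = ", "),
              ": the class-total rescale makes their effect unobservable")
    }
  }

  mu <- stats::rnorm(n_species, design$mu_mean, design$mu_sd)
  b_subj <- stats::rnorm(n_subj, 0, design$subject_sd)
  names(b_subj) <- subjects
  post_weeks <- setdiff(design$weeks, 0)
  eta <- matrix(stats::rnorm(n_species * length(post_weeks), 0,
                             design$drift_sd),
                n_species, length(post_weeks),
                dimnames = list(NULL, as.character(post_weeks)))
  decay <- function(w) if (w >= 7) design$week7_decay else 1

  conc <- matrix(0, n_rows, n_species,
                 dimnames = list(NULL, peak_ids))
  class_fac <- factor(classes, levels = names(class_sizes))
  for (i in seq_len(n_rows)) {
    s <- samples$subject_id[i]
    w <- samples$week[i]
    eps <- stats::rnorm(n_species, 0, design$noise_sd)
    base_log2 <- mu + b_subj[[s]] + eps
    if (w > 0 && samples$arm[i] == "HOSO") {
      base_log2 <- base_log2 + eta[, as.character(w)]
    }
    if (w > 0 && samples$arm[i] == "FO") {
      eff_log2 <- base_log2 + delta * decay(w)
      row <- 2^eff_log2
      if (design$remodeling) {
        pre <- 2^base_log2
        tot_pre <- tapply(pre, class_fac, sum)
        tot_post <- tapply(row, class_fac, sum)
        row <- row * as.numeric((tot_pre / tot_post)[class_fac])
      }
      conc[i, ] <- row
    } else {
      conc[i, ] <- 2^base_log2
    }
  }

  # internal standards: spiked concentration is known, measured intensity
  # varies log-normally per sample around the nominal value
  std_names <- unique(standard_for_class(names(class_sizes),
                                         sm_standard = design$sm_standard))
  std_conc <- design$standard_concentrations[std_names]
  if (anyNA(std_conc)) {
    stop("standard_concentrations missing entries for: ",
         paste(std_names[is.na(std_conc)], collapse = ", "))
  }
  sdlog <- sqrt(log(1 + design$is_intensity_cv^2))
  is_int <- matrix(
    stats::rlnorm(n_rows * length(std_names),
                  meanlog = log(design$is_nominal_intensity) - sdlog^2 / 2,
                  sdlog = sdlog),
    n_rows, length(std_names), dimnames = list(NULL, std_names))
  standards <- standards_table(
    data.frame(standard_name = std_names,
               concentration = as.numeric(std_conc)),
    is_int)

  std_of_species <- standard_for_class(classes,
                                       sm_standard = design$sm_standard)
  raw <- conc * is_int[, std_of_species, drop = FALSE] /
    rep(as.numeric(std_conc[std_of_species]), each = n_rows)
  colnames(raw) <- peak_ids

  truth <- data.frame(peak_id = peak_ids, lipid_class = classes,
                      is_responder = is_responder, true_log2fc = delta)

  list(dataset = lipid_dataset(raw, samples, species, unit = "intensity"),
       standards = standards,
       truth = truth,
       concentrations = lipid_dataset(conc, samples, species,
                                      unit = "concentration"),
       design = design)
}

#' Simulate a generic latent-variable block structure
#'
#' Builds a block set from a low-rank latent model `X = T P' + E`,
#' `y = T q + e`: `n_latent` orthogonal latent directions drive both the
#' predictor blocks and the response. Used to study component selection:
#' cross-validated RMSECV should bottom out at `n_latent` components.
#'
#' @param n Samples.
#' @param p Total variables, split evenly into `n_blocks` blocks.
#' @param n_latent Number of latent components.
#' @param n_blocks Number of blocks.
#' @param score_sd SDs of the latent scores (recycled to `n_latent`).
#' @param y_weights Response loadings on the latent scores.
#' @param x_noise_sd,y_noise_sd Residual SDs.
#' @param seed Integer seed.
#' @return A `block_set` (see [blockset_from_matrix()]).
#' @export
simulate_latent_blocks <- function(n = 40, p = 50, n_latent = 2, n_blocks = 2,
                                   score_sd = c(3, 2), y_weights = c(1, 1),
                                   x_noise_sd = 0.5, y_noise_sd = 0.5,
                                   seed = 1L) {
  stopifnot(n_latent >= 1, length(y_weights) == n_latent)
  score_sd <- rep_len(score_sd, n_latent)
  withr::with_seed(seed, {
    scores <- sapply(score_sd, function(s) stats::rnorm(n, 0, s))
    scores <- qr.Q(qr(scores)) %*% diag(sqrt(colSums(scores^2)), n_latent)
    loadings <- matrix(stats::rnorm(p * n_latent), p, n_latent)
    loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
    X <- tcrossprod(scores, loadings) +
      matrix(stats::rnorm(n * p, 0, x_noise_sd), n, p)
    y <- drop(scores %*% y_weights) + stats::rnorm(n, 0, y_noise_sd)
  })
  sizes <- diff(round(seq(0, p, length.out = n_blocks + 1)))
  col_blocks <- split(seq_len(p), rep(seq_len(n_blocks), sizes))
  blockset_from_matrix(X, col_blocks, y,
                       labels = paste0("block", seq_len(n_blocks)))
}
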