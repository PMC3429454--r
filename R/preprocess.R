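# Preprocessing: internal-standard normalization, baseline-adjusted log2
# ratios, and the 11-block class-share structure consumed by the MBPLSR.

#' Convert raw intensities to concentrations via internal standards
#'
#' Each species is divided by the measured per-sample intensity of its class
#' standard and multiplied by the standard's spiked concentration:
#' `conc = raw / IS_intensity * IS_concentration`.
#'
#' @param raw A raw-intensity [lipid_dataset()].
#' @param standards A [standards_table()] with one intensity row per sample
#'   of `raw`, in the same order.
#' @param sm_standard,overrides Passed to [standard_for_class()].
#' @return A concentration [lipid_dataset()].
#' @export
normalize_intensities <- function(raw, standards,
                                  sm_standard = "PC(17:0/17:0)",
                                  overrides = NULL) {
  stopifnot(inherits(raw, "lipid_dataset"), inherits(standards, "standards_table"),
            nrow(standards$intensities) == nrow(raw$values))
  std <- standard_for_class(raw$species$lipid_class,
                            sm_standard = sm_standard, overrides = overrides)
  missing <- setdiff(unique(std), standards$info$standard_name)
  if (length(missing)) {
    stop("standards table lacks: ", paste(missing, collapse = ", "))
  }
  ints <- standards$intensities
  bad <- which(ints <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive standard intensity: sample '%s', standard '%s'",
                 rownames(raw$values)[bad[1, 1]], colnames(ints)[bad[1, 2]]))
  }
  conc_std <- stats::setNames(standards$info$concentration,
                              standards$info$standard_name)
  conc <- raw$values / ints[, std, drop = FALSE] *
    rep(conc_std[std], each = nrow(raw$values))
  colnames(conc) <- colnames(raw$values)
  lipid_dataset(conc, raw$samples, raw$species, unit = "concentration")
}

# split a concentration dataset into paired baseline / analysis-week
# matrices with one row per subject (same subject order)
paired_weeks <- function(conc, week) {
  stopifnot(inherits(conc, "lipid_dataset"), week %in% conc$samples$week,
            week != 0)
  base_rows <- which(conc$samples$week == 0)
  week_rows <- which(conc$samples$week == week)
  base_subj <- conc$samples$subject_id[base_rows]
  week_subj <- conc$samples$subject_id[week_rows]
  missing <- union(setdiff(week_subj, base_subj), setdiff(base_subj, week_subj))
  if (length(missing)) {
    stop("subject(s) lacking a paired baseline/week-", week, " sample: ",
         paste(missing, collapse = ", "))
  }
  week_rows <- week_rows[match(base_subj, week_subj)]
  list(baseline = conc$values[base_rows, , drop = FALSE],
       at_week = conc$values[week_rows, , drop = FALSE],
       subjects = data.frame(subject_id = base_subj,
                             arm = conc$samples$arm[base_rows]))
}

check_positive_baseline <- function(mat, subjects, floor = NULL, what = "value") {
  if (!is.null(floor)) {
    n_floored <- sum(mat < floor)
    if (n_floored > 0) {
      message("floored ", n_floored, " ", what, "(s) below ", floor)
    }
    return(pmax(mat, floor))
  }
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive %s for subject '%s', species '%s'; set 'floor' to impute",
                 what, subjects$subject_id[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  mat
}

#' Baseline-adjusted log2 ratios
#'
#' For each subject, `log2(conc_week / conc_week0)` per species.
#'
#' @param conc A concentration [lipid_dataset()] containing week 0 and the
#'   requested week for every subject.
#' @param week Analysis week (3 or 7).
#' @param floor Optional small positive value used to floor concentrations
#'   before taking ratios; by default a non-positive value is an error.
#' @return A list with `ratios` (subjects x species matrix) and `subjects`
#'   (data frame `subject_id`, `arm`).
#' @export
log2_baseline_adjust <- function(conc, week, floor = NULL) {
  pw <- paired_weeks(conc, week)
  base <- check_positive_baseline(pw$baseline, pw$subjects, floor,
                                  "baseline concentration")
  at_w <- check_positive_baseline(pw$at_week, pw$subjects, floor,
                                  "concentration")
  ratios <- log2(at_w / base)
  rownames(ratios) <- pw$subjects$subject_id
  list(ratios = ratios, subjects = pw$subjects)
}

# center columns, then scale the whole block so its total sum of squares
# is 1 ("same footing"); factors/centers can be supplied (CV: training-only)
process_blocks <- function(raw_blocks, centers = NULL, factors = NULL) {
  out <- vector("list", length(raw_blocks))
  names(out) <- names(raw_blocks)
  if (is.null(centers)) {
    centers <- lapply(raw_blocks, colMeans)
  }
  compute_factors <- is.null(factors)
  if (compute_factors) factors <- numeric(length(raw_blocks))
  for (b in seq_along(raw_blocks)) {
    centered <- sweep(raw_blocks[[b]], 2, centers[[b]], "-")
    if (compute_factors) {
      ss <- sum(centered^2)
      if (ss == 0) {
        warning("block '", names(raw_blocks)[b],
                "' is constant; scaling factor set to 1")
        factors[b] <- 1
      } else {
        factors[b] <- sqrt(ss)
      }
    }
    out[[b]] <- centered / factors[b]
  }
  list(processed = out, centers = centers, factors = factors)
}

new_blockset <- function(raw_blocks, y, labels, samples = NULL,
                         species_map = NULL, class_totals = NULL) {
  stopifnot(length(raw_blocks) == length(labels))
  names(raw_blocks) <- labels
  proc <- process_blocks(raw_blocks)
  structure(list(raw = raw_blocks,
                 processed = proc$processed,
                 centers = proc$centers,
                 scaling_factors = stats::setNames(proc$factors, labels),
                 labels = labels,
                 y = y,
                 samples = samples,
                 species_map = species_map,
                 class_totals = class_totals),
            class = "block_set")
}

#' Build a block set from a plain matrix
#'
#' Generic constructor used for simulations and oracle checks: splits the
#' columns of `X` into blocks, mean-centers each block and scales it to unit
#' total sum of squares.
#'
#' @param X Numeric matrix.
#' @param col_blocks List of column index vectors (disjoint, covering all
#'   columns).
#' @param y Numeric response (for a two-arm study, +1/-1 group coding).
#' @param labels Block labels.
#' @return A `block_set`.
#' @export
blockset_from_matrix <- function(X, col_blocks, y,
                                 labels = paste0("block", seq_along(col_blocks))) {
  X <- as.matrix(X)
  idx <- unlist(col_blocks)
  stopifnot(!anyDuplicated(idx), setequal(idx, seq_len(ncol(X))),
            length(y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  raw_blocks <- lapply(col_blocks, function(j) X[, j, drop = FALSE])
  new_blockset(raw_blocks, y, labels,
               species_map = lapply(raw_blocks, colnames))
}

#' @export
print.block_set <- function(x, ...) {
  sizes <- vapply(x$raw, ncol, integer(1))
  cat(sprintf("<block_set> %d samples, %d blocks (%d variables)\n",
              nrow(x$raw[[1]]), length(x$raw), sum(sizes)))
  cat("  ", paste(sprintf("%s[%d]", x$labels, sizes), collapse = " "), "\n")
  invisible(x)
}

#' Build the 11-block class-share structure
#'
#' Organizes baseline-adjusted lipid data into the multi-block layout: one
#' block per lipid class (Cer, lysoPC, lysoPE, PA, PC, PE, PG, PS, SM, TG, in
#' that order), each class-share normalized, plus a final "sums of lipids"
#' block holding the per-class totals together with the PI species.
#'
#' By default the class-share division is applied to concentrations at each
#' timepoint and the baseline log2 ratio is then taken on the shares (and on
#' the class totals for the sums block); this makes within-class remodeling
#' and class-total changes exactly separable. The alternative order (per-
#' species baseline ratios first, then division by the class total of
#' ratios) is available via `ratio_then_share = TRUE`.
#'
#' Unidentified species are excluded. Each block is mean-centered and scaled
#' to unit total sum of squares so all blocks enter the model on the same
#' footing; the pre-centering matrices are retained so cross-validation can
#' redo centering and scaling on training samples only.
#'
#' @param conc A concentration [lipid_dataset()].
#' @param week Analysis week (3 or 7).
#' @param ratio_then_share Order-of-operations flag, see above.
#' @param floor Optional concentration floor, see [log2_baseline_adjust()].
#' @return A `block_set` whose `y` codes FO = +1, HOSO = -1.
#' @export
build_blockset <- function(conc, week, ratio_then_share = FALSE, floor = NULL) {
  stopifnot(inherits(conc, "lipid_dataset"))
  keep <- conc$species$identified
  if (!all(keep)) {
    conc <- lipid_dataset(conc$values[, keep, drop = FALSE], conc$samples,
                          conc$species[keep, , drop = FALSE],
                          unit = "concentration")
  }
  species <- conc$species
  blocked_classes <- names(BLOCK_ORDER)[BLOCK_ORDER <= 10]
  present <- blocked_classes[blocked_classes %in% species$lipid_class]
  dropped <- setdiff(blocked_classes, present)
  if (length(dropped)) {
    warning("no species in class(es) ", paste(dropped, collapse = ", "),
            "; block(s) dropped")
  }
  pi_cols <- species$peak_id[species$lipid_class == "PI"]

  pw <- paired_weeks(conc, week)
  base <- check_positive_baseline(pw$baseline, pw$subjects, floor,
                                  "baseline concentration")
  at_w <- check_positive_baseline(pw$at_week, pw$subjects, floor,
                                  "concentration")
  subjects <- pw$subjects

  all_classes <- intersect(names(BLOCK_ORDER), unique(species$lipid_class))
  totals_of <- function(mat) {
    out <- sapply(all_classes, function(cls) {
      rowSums(mat[, species$peak_id[species$lipid_class == cls],
                  drop = FALSE])
    })
    if (any(out == 0)) {
      bad <- which(out == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("class total is zero for subject '%s', class '%s'",
                   subjects$subject_id[bad[1]], all_classes[bad[2]]))
    }
    out
  }
  tot_base <- totals_of(base)
  tot_week <- totals_of(at_w)

  shares_of <- function(mat, totals) {
    out <- mat
    for (cls in all_classes) {
      j <- species$peak_id[species$lipid_class == cls]
      out[, j] <- mat[, j, drop = FALSE] / totals[, cls]
    }
    out
  }

  if (!ratio_then_share) {
    share_ratio <- log2(shares_of(at_w, tot_week) / shares_of(base, tot_base))
    total_ratio <- log2(tot_week / tot_base)
  } else {
    ratios <- at_w / base
    tot_r <- totals_of(ratios)
    share_ratio <- log2(shares_of(ratios, tot_r))
    total_ratio <- log2(tot_r)
  }

  rownames(share_ratio) <- rownames(total_ratio) <- subjects$subject_id
  raw_blocks <- lapply(present, function(cls) {
    share_ratio[, species$peak_id[species$lipid_class == cls], drop = FALSE]
  })
  sums_cols <- total_ratio[, setdiff(all_classes, "PI"), drop = FALSE]
  colnames(sums_cols) <- paste0("total_", setdiff(all_classes, "PI"))
  if (length(pi_cols)) {
    pi_ratio <- log2(at_w[, pi_cols, drop = FALSE] /
                     base[, pi_cols, drop = FALSE])
    rownames(pi_ratio) <- subjects$subject_id
    sums_cols <- cbind(sums_cols, pi_ratio)
  }
  raw_blocks <- c(raw_blocks, list(sums_cols))
  labels <- c(present, "sums")

  y <- ifelse(subjects$arm == "FO", 1, -1)
  new_blockset(raw_blocks, y, labels, samples = subjects,
               species_map = lapply(raw_blocks, colnames),
               class_totals = rbind(tot_base, tot_week))
}
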