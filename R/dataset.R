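#' Construct a lipid dataset
#'
#' Container for a samples x species value matrix (raw peak intensities or
#' internal-standard-normalized concentrations) together with sample metadata
#' and species annotations.
#'
#' @param values Numeric matrix, rows = samples, columns = species; column
#'   names must equal `species$peak_id`.
#' @param samples Data frame with columns `subject_id`, `arm` (`"FO"` or
#'   `"HOSO"`) and `week`; one row per row of `values`.
#' @param species Species annotation data frame as returned by
#'   [annotate_species()].
#' @param unit Either `"intensity"` or `"concentration"`.
#' @return An object of class `lipid_dataset`.
#' @export
lipid_dataset <- function(values, samples, species,
                          unit = c("intensity", "concentration")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.data.frame(samples), is.data.frame(species),
            nrow(values) == nrow(samples), ncol(values) == nrow(species))
  req <- c("subject_id", "arm", "week")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns ", paste(req, collapse = ", "))
  }
  if (anyNA(samples[req])) stop("sample metadata contains missing values")
  if (!all(samples$arm %in% c("FO", "HOSO"))) {
    stop("arm must be 'FO' or 'HOSO'")
  }
  if (!all(is.finite(values))) stop("values must be finite")
  if (is.null(colnames(values))) colnames(values) <- species$peak_id
  if (!identical(colnames(values), as.character(species$peak_id))) {
    stop("column names of values must match species$peak_id")
  }
  if (anyDuplicated(paste(samples$subject_id, samples$week))) {
    stop("duplicated subject/week combination in sample metadata")
  }
  rownames(values) <- paste0(samples$subject_id, "_w", samples$week)
  structure(list(values = values, samples = samples, species = species,
                 unit = unit),
            class = "lipid_dataset")
}

#' @export
print.lipid_dataset <- function(x, ...) {
  cat(sprintf("<lipid_dataset> %d samples x %d species (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("  subjects: %d FO, %d HOSO; weeks: %s\n",
              length(unique(x$samples$subject_id[x$samples$arm == "FO"])),
              length(unique(x$samples$subject_id[x$samples$arm == "HOSO"])),
              paste(sort(unique(x$samples$week)), collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(names(sort(table(x$species$lipid_class), decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Construct an internal-standard table
#'
#' @param info Data frame with columns `standard_name` and `concentration`
#'   (the spiked concentration, micromolar).
#' @param intensities Numeric matrix of measured standard intensities, rows =
#'   samples (matching the dataset row order), columns = standards.
#' @return An object of class `standards_table`.
#' @export
standards_table <- function(info, intensities) {
  stopifnot(is.data.frame(info),
            all(c("standard_name", "concentration") %in% names(info)))
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities))) colnames(intensities) <- info$standard_name
  stopifnot(identical(colnames(intensities), as.character(info$standard_name)),
            all(info$concentration > 0))
  structure(list(info = info, intensities = intensities),
            class = "standards_table")
}

#' @export
print.standards_table <- function(x, ...) {
  cat(sprintf("<standards_table> %d standards x %d samples\n",
              nrow(x$info), nrow(x$intensities)))
  print(x$info)
  invisible(x)
}
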