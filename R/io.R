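# Plain-text interchange: TSV with '#'-prefixed metadata header lines.

write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a lipid dataset as TSV
#'
#' One row per sample: `subject_id`, `arm`, `week`, then one intensity (or
#' concentration) column per peak id.
#'
#' @param dataset A [lipid_dataset()].
#' @param path Output file.
#' @param meta Character vector of metadata lines written as `#` comments.
#' @export
write_dataset_tsv <- function(dataset, path, meta = character()) {
  stopifnot(inherits(dataset, "lipid_dataset"))
  df <- cbind(dataset$samples[c("subject_id", "arm", "week")],
              as.data.frame(dataset$values, check.names = FALSE))
  write_tsv_meta(df, path, meta)
}

#' @rdname write_dataset_tsv
#' @param annotations Species annotation data frame (or path to an
#'   annotations TSV with columns `peak_id`, `raw_name`, `identified`).
#' @param unit `"intensity"` or `"concentration"`.
#' @export
read_dataset_tsv <- function(path, annotations,
                             unit = c("intensity", "concentration")) {
  unit <- match.arg(unit)
  df <- read_tsv_meta(path)
  if (is.character(annotations)) {
    annotations <- read_tsv_meta(annotations)
  }
  species <- annotate_species(annotations)
  meta_cols <- c("subject_id", "arm", "week")
  stopifnot(all(meta_cols %in% names(df)))
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  values <- values[, as.character(species$peak_id), drop = FALSE]
  lipid_dataset(values, df[meta_cols], species, unit = unit)
}

#' Write / read an internal-standard table as TSV
#'
#' One row per standard: `standard_name`, `concentration`, then one measured
#' intensity column per sample (named by the dataset's sample row names).
#'
#' @param standards A [standards_table()].
#' @param path File path.
#' @param meta Metadata comment lines.
#' @export
write_standards_tsv <- function(standards, path, meta = character()) {
  stopifnot(inherits(standards, "standards_table"))
  ints <- t(standards$intensities)
  colnames(ints) <- rownames(standards$intensities) %||%
    paste0("sample", seq_len(nrow(standards$intensities)))
  df <- cbind(standards$info, as.data.frame(ints, check.names = FALSE))
  write_tsv_meta(df, path, meta)
}

#' @rdname write_standards_tsv
#' @export
read_standards_tsv <- function(path) {
  df <- read_tsv_meta(path)
  stopifnot(all(c("standard_name", "concentration") %in% names(df)))
  ints <- t(as.matrix(df[, setdiff(names(df),
                                   c("standard_name", "concentration")),
                         drop = FALSE]))
  colnames(ints) <- df$standard_name
  standards_table(df[c("standard_name", "concentration")], ints)
}
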