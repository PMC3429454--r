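#' Packaged table of significantly altered lipids
#'
#' Machine-readable transcription of the published week-3 result tables: the
#' 74 lipids significantly altered (FDR < 0.05) in the fish-oil arm relative
#' to the control arm, with their q-values and fold changes from baseline in
#' both arms. Serves as the in-package worked example: 51 of the 74 rows
#' have an FO fold change above 1 (increased), 23 below 1 (decreased).
#'
#' @return Data frame with columns `source_table`, `raw_name`, `q_value`,
#'   `q_censored` (entries printed as "<0.001", stored as 0.001),
#'   `fold_change_HOSO`, `fold_change_FO`, `lipid_class` (parsed primary
#'   class) and `direction`.
#' @export
tables_fixture <- function() {
  path <- system.file("extdata", "significant_lipids_week3.tsv",
                      package = "lipidblocks", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(source_table = "character"))
  if (nrow(tab) != 74) {
    stop("fixture corrupted: expected 74 rows, found ", nrow(tab))
  }
  parsed <- lapply(tab$raw_name, parse_lipid_name)
  tab$lipid_class <- vapply(parsed, `[[`, character(1), "lipid_class")
  tab$direction <- ifelse(tab$fold_change_FO > 1, "increased", "decreased")
  tab
}
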