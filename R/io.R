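#' Write a data frame as a plain TSV
#'
#' Deterministic writer used for all tabular outputs: tab separator, no
#' quoting, no row names, `NA` written literally.
#'
#' @param df data frame
#' @param path output path
#' @return invisibly, `df`
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(df)
}
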