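#' Read and write the package's long-format TSV tables
#'
#' Every simulator output and analysis input is interchanged as plain
#' tab-separated text with a header row: variant tables (`variant`,
#' `region`, `depth`, `alt_reads`, `aaf`, ...), amplicon tables
#' (`variant`, `region`, `primer`, `depth`, `alt_reads`, `flank_error`),
#' cell metadata (`cell`, `region`, `cell_type`), panel read tables
#' (`cell`, `site`, `ref_reads`, `alt_reads`) and UMI tallies (`cell`,
#' `variant`, `total_umis`, `mut_umis`).  Writers and readers are paired:
#' `read_table_tsv(write_table_tsv(x, f))` reproduces `x`.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a data frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
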