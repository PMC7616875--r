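#' Delimited-text readers and writers for pipeline tables
#'
#' All pipeline tables travel as tab-delimited text with a header.
#' Column names (including `pgs_5e-08`-style names) are preserved
#' verbatim. `read_cohort()` accepts comma- or tab-delimited files,
#' sniffing the separator from the header line.
#'
#' @param cohort,gwas Data frames to write.
#' @param dosages Participant x SNP matrix with SNP-id colnames.
#' @param path File path.
#' @return Readers return data frames (`read_dosages()` a matrix with
#'   participant ids as rownames); writers return `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  read.delim(path, sep = sep, check.names = FALSE)
}

#' @rdname write_cohort
#' @export
write_gwas <- function(gwas, path) {
  write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_gwas <- function(path) {
  validate_gwas(read.delim(path, check.names = FALSE))
}

#' @rdname write_cohort
#' @export
write_dosages <- function(dosages, path) {
  df <- data.frame(id = rownames(dosages) %||% seq_len(nrow(dosages)),
                   dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_dosages <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(m) <- df$id
  m
}
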