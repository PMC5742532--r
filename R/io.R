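# FASTA / TSV plumbing. Parsing is delegated to Biostrings and
# utils::read.delim; this file only fixes the package's file conventions.

#' Read a FASTA file into a named character vector
#'
#' Headers are truncated at the first whitespace, so `>id description`
#' yields the name `id`.
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Read one of the library's TSV tables, checking its schema.
read_table_checked <- function(path, required, optional = character(0),
                               what = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("load error [%s]: file not found: %s", what, path))
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = character(0))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("load error [%s]: missing column(s): %s",
                 what, paste(missing, collapse = ", ")))
  for (col in setdiff(optional, names(df))) df[[col]] <- ""
  df[, c(required, optional), drop = FALSE]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# Split a packed multi-value field ("a;b;c" -> c("a","b","c")).
split_multi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
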