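# IUPAC nucleotide alphabet helpers shared across the package.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
UNAMBIGUOUS <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of a nucleotide string
#'
#' Complements all IUPAC codes (ambiguity codes map to their complementary
#' ambiguity code) and reverses the sequence.  Case is upper-cased.
#'
#' @param seq Single nucleotide string.
#' @return The reverse-complemented string.
#' @examples
#' revcomp("ATGAAAAC")  # "GTTTTCAT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Split a sequence into an upper-case character vector.
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

# TRUE where a character is an unambiguous base.
is_acgt <- function(chars) chars %in% UNAMBIGUOUS

# Substitution class of an unambiguous base pair: "ts", "tv" or "match".
subst_class <- function(a, b) {
  cls <- ifelse(a == b, "match",
         ifelse((a %in% PURINES) == (b %in% PURINES), "ts", "tv"))
  cls
}
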