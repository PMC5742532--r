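# Query quality control.

MARKER_MIN_LENGTH <- c("ITS2" = 150L, "psbA-trnH" = 100L)
MAX_AMBIGUOUS_FRACTION <- 0.01

#' Quality-control a query barcode sequence
#'
#' A query passes when its length meets the marker-specific floor
#' (ITS2 >= 150 bp, psbA-trnH >= 100 bp), its fraction of ambiguity
#' characters (any IUPAC code outside A/C/G/T) is <= 1%, and it contains no
#' characters outside the IUPAC nucleotide alphabet.  All thresholds are
#' inclusive.
#'
#' @param seq Nucleotide string.
#' @param marker `"ITS2"` or `"psbA-trnH"`.
#' @return An object of class `qc_result`: list with `passed`, `length`,
#'   `ambiguous_fraction`, `invalid_chars`, `failure_reasons`.
#' @examples
#' validate_query(strrep("ACGT", 50), "ITS2")$passed  # TRUE
#' @export
validate_query <- function(seq, marker = c("ITS2", "psbA-trnH")) {
  marker <- match.arg(marker)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("query sequence is empty")
  chars <- seq_chars(seq)
  len <- length(chars)
  invalid <- sort(unique(chars[!(chars %in% IUPAC_CHARS)]))
  amb_frac <- mean(!(chars %in% UNAMBIGUOUS) & chars %in% IUPAC_CHARS)
  reasons <- character(0)
  min_len <- MARKER_MIN_LENGTH[[marker]]
  if (len < min_len)
    reasons <- c(reasons, sprintf("length < %d", min_len))
  if (amb_frac > MAX_AMBIGUOUS_FRACTION)
    reasons <- c(reasons,
                 sprintf("ambiguous bases %.2f%% exceed 1%%", 100 * amb_frac))
  if (length(invalid) > 0)
    reasons <- c(reasons,
                 sprintf("invalid characters: %s", paste(invalid, collapse = "")))
  structure(list(passed = length(reasons) == 0L,
                 length = len,
                 ambiguous_fraction = amb_frac,
                 invalid_chars = invalid,
                 failure_reasons = reasons),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC %s: %d bp, %.2f%% ambiguous\n",
              if (x$passed) "passed" else "FAILED",
              x$length, 100 * x$ambiguous_fraction))
  for (r in x$failure_reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
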