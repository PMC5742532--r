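# Small-inversion normalization for psbA-trnH reads.
#
# The psbA-trnH spacer carries short inversions between closely related
# origins (e.g. an ATGAAAAC locus appearing as GTTTTCAT). Left in place
# they grossly inflate intra-/inter-specific distances and break
# similarity-based identification, so the query is screened against a
# reference and a dense block of mismatching columns is trial
# reverse-complemented.
#
# A strict run of consecutive mismatches cannot describe these inversions:
# a segment aligned to its own reverse complement retains matching columns
# wherever a base faces the complement of its mirror position (the
# ATGAAAAC/GTTTTCAT pair itself matches at two of eight columns). The
# detector therefore looks for the maximal-scoring *mismatch-dense window*
# (maximum subarray with mismatch = +1, match = -1 over compared columns)
# and requires at least `min_run` mismatches inside it.

#' Detect and undo a short inversion in a query relative to a reference
#'
#' Globally aligns query and reference, finds the maximal mismatch-dense
#' window (see file notes) containing at least `min_run` mismatching
#' compared columns, reverse-complements that segment of the query and
#' re-aligns.  The correction is kept only when the global alignment
#' identity improves by at least `min_gain`; otherwise the query is
#' returned unchanged.  Identity never decreases, and applying the
#' operation to its own output leaves it unchanged.
#'
#' @param query,reference Nucleotide strings that passed QC (intended for
#'   psbA-trnH).
#' @param min_run Minimum number of mismatching columns inside the
#'   candidate window (default 6).
#' @param min_gain Minimum identity improvement required to keep the
#'   correction (default 0.02).
#' @return List with `query` (possibly corrected), `inverted` (flag),
#'   `segment` (query-coordinate span of the corrected segment, or `NULL`),
#'   `identity_before`, `identity_after`.
#' @export
normalize_inversion <- function(query, reference, min_run = 6L,
                                min_gain = 0.02) {
  aln <- align_pair(query, reference, mode = "global")
  id0 <- aln$identity
  ca <- seq_chars(aln$aligned_a)
  cb <- seq_chars(aln$aligned_b)
  unchanged <- list(query = query, inverted = FALSE, segment = NULL,
                    identity_before = id0, identity_after = id0)
  # column disturbance score: +1 for a mismatching base pair or a gap in
  # either row (the aligner shreds an inverted segment into mismatches
  # interleaved with compensating gaps and chance matches - a quarter of
  # the columns of a segment aligned to its own reverse complement match
  # by chance), -0.5 for a matching base pair so isolated lucky matches do
  # not fragment the window, 0 for ambiguity columns
  gap <- ca == "-" | cb == "-"
  compared <- !gap & is_acgt(ca) & is_acgt(cb)
  mism <- compared & ca != cb
  score <- ifelse(gap | mism, 1, ifelse(compared, -0.5, 0))
  best <- c(0, 0L, 0L)  # score, start col, end col
  cur <- 0; cur_start <- 1L
  for (i in seq_along(score)) {
    if (cur <= 0) { cur <- 0; cur_start <- i }
    cur <- cur + score[i]
    if (cur > best[1]) best <- c(cur, cur_start, i)
  }
  if (best[1] <= 0) return(unchanged)
  window <- seq(best[2], best[3])
  if (sum(mism[window]) < min_run) return(unchanged)
  # map window edges (alignment columns) back to query coordinates
  qpos <- cumsum(ca != "-")
  qs <- if (ca[best[2]] != "-") qpos[best[2]] else qpos[best[2]] + 1L
  qe <- qpos[best[3]]
  if (qs < 1 || qe < qs || qe > nchar(query)) return(unchanged)
  corrected <- paste0(substr(query, 1, qs - 1),
                      revcomp(substr(query, qs, qe)),
                      substr(query, qe + 1, nchar(query)))
  id1 <- align_pair(corrected, reference, mode = "global")$identity
  if (!is.na(id1) && !is.na(id0) && id1 - id0 >= min_gain) {
    list(query = corrected, inverted = TRUE, segment = c(qs, qe),
         identity_before = id0, identity_after = id1)
  } else {
    unchanged
  }
}
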