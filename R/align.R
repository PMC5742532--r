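# Pairwise alignment. Optimal global (Needleman-Wunsch) and local
# (Smith-Waterman) alignment with affine gaps is delegated to
# Biostrings::pairwiseAlignment; this file fixes the scoring scheme and
# derives the quantities downstream code needs (compared columns,
# transition/transversion counts, identity).

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
ALIGN_GAP_OPEN <- 2    # penalty (subtracted)
ALIGN_GAP_EXTEND <- 0.5

.subst_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- Biostrings::nucleotideSubstitutionMatrix(
        match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH, baseOnly = FALSE)
      cache <<- m
    }
    cache
  }
})

#' Align two nucleotide sequences
#'
#' Optimal pairwise alignment under a fixed scoring scheme: match +1,
#' mismatch -1, gap open -2, gap extension -0.5.  Identity and the
#' transition/transversion counts used by [k2p_distance()] are computed over
#' *compared columns* only: columns carrying an unambiguous base (A/C/G/T)
#' in both rows.  Columns with a gap in either row, or any IUPAC ambiguity
#' character, are excluded from those counts.
#'
#' @param a,b Nucleotide strings (IUPAC alphabet).
#' @param mode `"global"` (end-to-end) or `"local"` (best subsequence).
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   `compared_columns`, `matches`, `P_count` (transitions), `Q_count`
#'   (transversions), `identity` (matches / compared columns), `mode`,
#'   and for local mode `a_span`/`b_span` (start, end within the inputs).
#' @examples
#' aln <- align_pair("ACGT", "AGGT")
#' aln$identity  # 0.75
#' @export
align_pair <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(a)),
    subject = Biostrings::DNAString(toupper(b)),
    type = mode,
    substitutionMatrix = .subst_matrix(),
    gapOpening = ALIGN_GAP_OPEN,
    gapExtension = ALIGN_GAP_EXTEND)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  res <- alignment_from_strings(aligned_a, aligned_b,
                                score = Biostrings::score(pa), mode = mode)
  if (mode == "local") {
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    res$a_span <- c(Biostrings::start(pat), Biostrings::end(pat))
    res$b_span <- c(Biostrings::start(sub), Biostrings::end(sub))
  }
  res
}

#' Build a pairwise_alignment object from two gapped rows
#'
#' Used for already-aligned sequence pairs (e.g. equal-length simulated
#' reads) and internally by [align_pair()].  Counting rules are identical
#' to [align_pair()].
#'
#' @param aligned_a,aligned_b Equal-length gapped strings (`-` for gaps).
#' @param score Optional alignment score to carry along.
#' @param mode Label stored on the object.
#' @return A `pairwise_alignment` object.
#' @export
alignment_from_strings <- function(aligned_a, aligned_b, score = NA_real_,
                                   mode = "global") {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  if (length(ca) != length(cb))
    stop("aligned rows must have equal length")
  compared <- is_acgt(ca) & is_acgt(cb)
  a2 <- ca[compared]
  b2 <- cb[compared]
  cls <- subst_class(a2, b2)
  n_match <- sum(cls == "match")
  n_comp <- length(a2)
  structure(list(
    aligned_a = aligned_a,
    aligned_b = aligned_b,
    score = score,
    compared_columns = n_comp,
    matches = n_match,
    P_count = sum(cls == "ts"),
    Q_count = sum(cls == "tv"),
    identity = if (n_comp > 0) n_match / n_comp else NA_real_,
    mode = mode
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment (%s), score %.1f\n", x$mode, x$score))
  cat(sprintf("  columns compared: %d  identity: %s\n", x$compared_columns,
              ifelse(is.na(x$identity), "NA", sprintf("%.4f", x$identity))))
  cat(sprintf("  transitions: %d  transversions: %d\n", x$P_count, x$Q_count))
  invisible(x)
}

is_pure_acgt <- function(x) !grepl("[^ACGT]", toupper(x))

# Per-element alignment statistics of a PairwiseAlignments object without
# extracting aligned strings (which is orders of magnitude slower).
# Matching the align_pair() counting contract: compared columns are
# base/base columns with both characters unambiguous.  The fast counting
# path (nmatch/nmismatch/mismatchTable) is exact whenever at least one of
# the two strings is pure A/C/G/T (an ambiguity column then always
# surfaces as a mismatch row); pairs where both sides carry ambiguity
# codes fall back to string extraction.
pa_stats <- function(pa, pattern_pure, subject_pure) {
  n <- length(pa)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  P <- integer(n); Q <- integer(n); amb <- integer(n)
  mt <- Biostrings::mismatchTable(pa)
  if (nrow(mt) > 0) {
    pc <- as.character(mt$PatternSubstring)
    sc <- as.character(mt$SubjectSubstring)
    ok <- pc %in% UNAMBIGUOUS & sc %in% UNAMBIGUOUS
    ts <- ok & ((pc %in% PURINES) == (sc %in% PURINES))
    P <- tabulate(mt$PatternId[ts], nbins = n)
    Q <- tabulate(mt$PatternId[ok & !ts], nbins = n)
    amb <- tabulate(mt$PatternId[!ok], nbins = n)
  }
  compared <- nm + nmm - amb
  matches <- nm
  slow <- which(!(pattern_pure | subject_pure))
  if (length(slow) > 0) {
    ali_p <- as.character(Biostrings::alignedPattern(pa[slow]))
    ali_s <- as.character(Biostrings::alignedSubject(pa[slow]))
    for (k in seq_along(slow)) {
      al <- alignment_from_strings(ali_p[k], ali_s[k])
      i <- slow[k]
      compared[i] <- al$compared_columns
      matches[i] <- al$matches
      P[i] <- al$P_count
      Q[i] <- al$Q_count
    }
  }
  data.frame(score = Biostrings::score(pa), compared = compared,
             matches = matches, P_count = P, Q_count = Q,
             identity = ifelse(compared > 0, matches / compared, 0))
}

# Score many subjects against one query in a single vectorized call.
# Returns a data.frame with score, identity, coverage of the query.
score_candidates <- function(query, subjects, mode = "local") {
  if (length(subjects) == 0L)
    return(data.frame(score = numeric(0), identity = numeric(0),
                      coverage = numeric(0)))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(subjects)),
    subject = Biostrings::DNAString(toupper(query)),
    type = mode,
    substitutionMatrix = .subst_matrix(),
    gapOpening = ALIGN_GAP_OPEN,
    gapExtension = ALIGN_GAP_EXTEND)
  st <- pa_stats(pa, is_pure_acgt(subjects),
                 rep(is_pure_acgt(query), length(subjects)))
  qspan <- if (mode == "local") {
    sub <- Biostrings::subject(pa)
    Biostrings::end(sub) - Biostrings::start(sub) + 1L
  } else rep(nchar(query), length(subjects))
  data.frame(score = st$score,
             identity = st$identity,
             coverage = pmin(1, qspan / nchar(query)))
}
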