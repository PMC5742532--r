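# Marker routing and core-region delimitation.
#
# Each marker is represented by a pair of synthetic flank consensi (the
# conserved gene fragments bordering the variable core: 5.8S/28S rDNA for
# ITS2, the psbA and trnH gene edges for psbA-trnH). Queries are routed to
# the marker whose flanks align best, and the core region is the span
# between the located flanks.  The consensi ship as a plain-text fixture in
# inst/extdata and are synthetic stand-ins seeded with the canonical
# priming motifs, not curated biological consensus sequences.

.marker_profile_cache <- new.env(parent = emptyenv())

# Local-align a set of flank consensi against one query in one call.
flank_scores <- function(flanks, seq, score_only = TRUE) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(flanks)),
    subject = Biostrings::DNAString(toupper(seq)),
    type = "local",
    substitutionMatrix = .subst_matrix(),
    gapOpening = ALIGN_GAP_OPEN,
    gapExtension = ALIGN_GAP_EXTEND,
    scoreOnly = score_only)
}

#' Marker flank profiles
#'
#' Loads the per-marker flank consensus sequences shipped with the package.
#'
#' @return Named list (one element per marker) of lists with `flank_left`
#'   and `flank_right` nucleotide strings.
#' @export
marker_profiles <- function() {
  if (is.null(.marker_profile_cache$profiles)) {
    path <- system.file("extdata", "marker_flanks_synthetic.fasta",
                        package = "herbid")
    if (!nzchar(path)) stop("marker flank fixture not found")
    fa <- read_fasta(path)
    nm <- sub("_flank_(left|right)$", "", names(fa))
    side <- sub("^.*_flank_", "flank_", names(fa))
    prof <- list()
    for (i in seq_along(fa)) prof[[nm[i]]][[side[i]]] <- unname(fa[i])
    .marker_profile_cache$profiles <- prof
  }
  .marker_profile_cache$profiles
}

#' Detect the barcode marker of a query sequence
#'
#' Locally aligns both flank consensi of every marker profile against the
#' query and sums the two alignment scores per marker.  The marker with the
#' highest total wins.  If no marker reaches `min_score` the query is not
#' recognizable as any shipped marker and an error is thrown.
#'
#' @param seq Query nucleotide string.
#' @param profiles Marker profiles, see [marker_profiles()].
#' @param min_score Score floor below which the query is declared
#'   unrecognized (default 30; two exact 40 bp flanks score 80).
#' @return List with `marker`, `score` (winning total), `orientation`
#'   (`"+"` as given, `"-"` when the reverse complement matched the flanks)
#'   and `scores` (named per-marker totals in the winning orientation).
#' @export
detect_marker <- function(seq, profiles = marker_profiles(), min_score = 30) {
  stopifnot(nzchar(seq))
  flanks <- unlist(lapply(profiles, function(p)
    c(p$flank_left, p$flank_right)), use.names = FALSE)
  totals_for <- function(s) {
    scores <- flank_scores(flanks, s, score_only = TRUE)
    setNames(scores[c(TRUE, FALSE)] + scores[c(FALSE, TRUE)],
             names(profiles))
  }
  fwd <- totals_for(seq)
  rev <- totals_for(revcomp(seq))
  orientation <- if (max(rev) > max(fwd)) "-" else "+"
  totals <- if (orientation == "-") rev else fwd
  best <- which.max(totals)
  if (totals[best] < min_score)
    stop("unrecognized marker: no flank profile scored above the floor")
  list(marker = names(profiles)[best],
       score = unname(totals[best]),
       orientation = orientation,
       scores = totals)
}

#' Extract the core region of a barcode read
#'
#' Locates the conserved flanks of `marker` in the read by local alignment
#' and returns the span between them.  A flank counts as found when its
#' local alignment score reaches `min_flank_score`.  With both flanks found
#' the status is `"trimmed"`; with exactly one, `"partial"` (the missing
#' edge falls back to the read end); with neither, the whole read is
#' returned with status `"untrimmed"`.
#'
#' @param seq Read passing QC.
#' @param marker `"ITS2"` or `"psbA-trnH"`.
#' @param profiles Marker profiles.
#' @param min_flank_score Acceptance floor per flank (default 20, i.e. at
#'   least half of a 40 bp flank aligning cleanly).
#' @return List with `core_seq`, `span` (start, end, 1-based inclusive) and
#'   `status` in `{"trimmed", "partial", "untrimmed"}`.
#' @export
extract_core_region <- function(seq, marker, profiles = marker_profiles(),
                                min_flank_score = 20) {
  stopifnot(nzchar(seq), marker %in% names(profiles))
  p <- profiles[[marker]]
  len <- nchar(seq)
  pa <- flank_scores(c(p$flank_left, p$flank_right), seq, score_only = FALSE)
  sc <- Biostrings::score(pa)
  sub <- Biostrings::subject(pa)
  left_found <- sc[1] >= min_flank_score
  right_found <- sc[2] >= min_flank_score
  s <- if (left_found) Biostrings::end(sub)[1] + 1L else 1L
  e <- if (right_found) Biostrings::start(sub)[2] - 1L else len
  if (s > e) { # flanks abut or overlap: degrade to untrimmed
    left_found <- right_found <- FALSE
    s <- 1L; e <- len
  }
  status <- if (left_found && right_found) "trimmed"
            else if (left_found || right_found) "partial"
            else "untrimmed"
  list(core_seq = substr(seq, s, e), span = c(s, e), status = status)
}
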