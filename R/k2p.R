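# Kimura 2-parameter distances. The estimator itself is authored here;
# ape::dist.dna serves only as an independent cross-check in the test suite.

#' Kimura 2-parameter distance from a pairwise alignment
#'
#' Computes the K2P distance `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`
#' where `P` and `Q` are the transition and transversion proportions over
#' the alignment's compared columns (pairwise deletion: gapped or ambiguous
#' columns are never counted).  When the log arguments are non-positive the
#' estimator is undefined ("saturated") and `d` is reported as `Inf`.
#'
#' @param alignment A `pairwise_alignment` (see [align_pair()]), or any list
#'   with `compared_columns`, `P_count`, `Q_count`.
#' @return An object of class `k2p_distance`: list with `d`, `P`, `Q`,
#'   `compared_columns` and logical `saturated`.
#' @examples
#' k2p_distance(align_pair("ACGT", "ACGT"))$d  # 0
#' @export
k2p_distance <- function(alignment) {
  n <- alignment$compared_columns
  if (is.null(n) || n < 1)
    stop("K2P distance needs at least one compared column")
  P <- alignment$P_count / n
  Q <- alignment$Q_count / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- (w1 <= 0) || (w2 <= 0)
  d <- if (saturated) Inf else -0.5 * log(w1 * sqrt(w2))
  structure(list(d = d, P = P, Q = Q, compared_columns = n,
                 saturated = saturated),
            class = "k2p_distance")
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("K2P distance: %s (P = %.4f, Q = %.4f, %d columns%s)\n",
              if (x$saturated) "saturated (Inf)" else sprintf("%.6f", x$d),
              x$P, x$Q, x$compared_columns,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Pairwise K2P distance matrix for a set of sequences
#'
#' Aligns every pair globally with [align_pair()] and applies
#' [k2p_distance()]. Each pair is computed once, so the matrix is symmetric
#' by construction with a zero diagonal.  Saturated pairs are stored as
#' `Inf` with a warning; [build_nj_tree()] refuses such matrices.
#'
#' @param seqs Named character vector of nucleotide sequences (names become
#'   matrix labels; must be unique).
#' @param aligned If `TRUE`, sequences are treated as already-aligned rows
#'   of equal length and no re-alignment is performed.
#' @return A symmetric numeric matrix with dimnames.
#' @export
build_distance_matrix <- function(seqs, aligned = FALSE) {
  if (length(seqs) < 2)
    stop("need at least two sequences")
  labels <- names(seqs)
  if (is.null(labels) || anyDuplicated(labels))
    stop("sequences must carry unique names")
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  pure <- is_pure_acgt(seqs)
  for (i in seq_len(n - 1)) {
    js <- seq(i + 1, n)
    if (aligned) {
      d <- vapply(js, function(j) {
        k2p_distance(alignment_from_strings(seqs[[i]], seqs[[j]]))$d
      }, numeric(1))
    } else {
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(toupper(seqs[js])),
        subject = Biostrings::DNAString(toupper(seqs[[i]])),
        type = "global",
        substitutionMatrix = .subst_matrix(),
        gapOpening = ALIGN_GAP_OPEN,
        gapExtension = ALIGN_GAP_EXTEND)
      st <- pa_stats(pa, pure[js], rep(pure[i], length(js)))
      d <- vapply(seq_along(js), function(k) {
        k2p_distance(list(compared_columns = st$compared[k],
                          P_count = st$P_count[k],
                          Q_count = st$Q_count[k]))$d
      }, numeric(1))
    }
    m[i, js] <- d
    m[js, i] <- d
  }
  if (any(!is.finite(m)))
    warning("distance matrix contains saturated (infinite) K2P entries")
  m
}
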