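# Neighbour-joining tree construction (Saitou & Nei agglomeration with the
# Studier-Keppler Q criterion). Authored here rather than wrapping an
# existing implementation so that tie-breaking is deterministic
# (lexicographically smallest label pair) and negative branch estimates are
# clamped to zero; ape::nj is used as an independent oracle in the tests.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration.  Q-criterion ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf label), so runs are reproducible.  Negative branch
#' length estimates are clamped to 0.  The result is an unrooted `phylo`
#' tree (ape) serializable with [ape::write.tree()].
#'
#' @param dist_matrix Symmetric numeric matrix with unique dimnames and zero
#'   diagonal, as from [build_distance_matrix()].  Must be finite: matrices
#'   carrying saturated (infinite) K2P entries are refused.
#' @return An object of class `phylo`.
#' @examples
#' d <- matrix(c(0, 5, 9, 9,  5, 0, 10, 10,  9, 10, 0, 8,  9, 10, 8, 0), 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' tr <- build_nj_tree(d)
#' ape::write.tree(tr)
#' @export
build_nj_tree <- function(dist_matrix) {
  m <- as.matrix(dist_matrix)
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix must have unique row/column labels")
  if (nrow(m) < 3)
    stop("neighbour joining needs at least 3 labels")
  if (any(!is.finite(m)))
    stop("distance matrix contains saturated (non-finite) entries; ",
         "refusing to build a tree")
  if (max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")

  fmt <- function(x) sprintf("%.10g", max(0, x))
  # active clusters: newick fragment + sort key (smallest leaf label)
  frag <- labels
  key <- labels
  D <- m
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    best <- NULL
    best_q <- Inf
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        q <- Qm[i, j]
        if (q < best_q - 1e-12) {
          best_q <- q; best <- c(i, j)
        } else if (abs(q - best_q) <= 1e-12) {
          # tie: lexicographically smallest (sorted) label pair wins
          cand <- sort(c(key[i], key[j]))
          cur <- sort(c(key[best[1]], key[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    new_key <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  # resolve the final three clusters onto one internal node
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  ape::read.tree(text = nwk)
}
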