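# Independent oracles used by the tests. These deliberately share no code
# with the package implementation paths they check.

# --- brute-force Gotoh alignment oracle (global, affine gaps) --------------
# match +1, mismatch -1, gap open -2, gap extend -0.5; a gap of length L
# costs open + L * extend (the package's documented convention).
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = -2, extend = -0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1) {
        X[i, j] <- max(M[i - 1, j] + open + extend,
                       X[i - 1, j] + extend)
      }
      if (j > 1) {
        Y[i, j] <- max(M[i, j - 1] + open + extend,
                       Y[i, j - 1] + extend)
      }
      if (i > 1 && j > 1) {
        s <- if (A[i - 1] == B[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                       Y[i - 1, j - 1]) + s
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- unrooted topology enumeration + least-squares fit ---------------------
# Trees are edge lists over nodes; leaves are 1..n, internal nodes n+1, ...
# Enumeration by sequential leaf insertion yields all (2n-5)!! topologies.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(edges = rbind(c(1, n + 1), c(2, n + 1), c(3, n + 1)),
               next_node = n + 2)
  trees <- list(base)
  if (n == 3) return(trees)
  for (leaf in 4:n) {
    grown <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        new_int <- tr$next_node
        edges <- tr$edges
        u <- edges[e, 1]; v <- edges[e, 2]
        edges <- edges[-e, , drop = FALSE]
        edges <- rbind(edges, c(u, new_int), c(new_int, v),
                       c(leaf, new_int))
        grown[[length(grown) + 1L]] <- list(edges = edges,
                                            next_node = new_int + 1L)
      }
    }
    trees <- grown
  }
  trees
}

# incidence matrix of leaf-pair paths over edges
path_matrix <- function(edges, n) {
  nodes <- max(edges)
  adj <- lapply(seq_len(nodes), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], e); adj[[v]] <- c(adj[[v]], e)
  }
  other <- function(e, x) if (edges[e, 1] == x) edges[e, 2] else edges[e, 1]
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    # DFS path from pairs[p,1] to pairs[p,2]
    target <- pairs[p, 2]
    stack <- list(list(node = pairs[p, 1], used = integer(0)))
    visited <- rep(FALSE, nodes)
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == target) { A[p, cur$used] <- 1; break }
      visited[cur$node] <- TRUE
      for (e in adj[[cur$node]]) {
        nb <- other(e, cur$node)
        if (!visited[nb])
          stack[[length(stack) + 1L]] <- list(node = nb,
                                              used = c(cur$used, e))
      }
    }
  }
  A
}

# least-squares branch fit; returns sum of squared residuals
ls_fit_ssq <- function(edges, n, dvec) {
  A <- path_matrix(edges, n)
  x <- qr.solve(A, dvec)
  sum((A %*% x - dvec)^2)
}

# best topology under least squares for labelled distance matrix; returns
# newick (branch lengths from the LS fit, clamped at 0 for readability)
oracle_ls_tree <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  dvec <- d[t(combn(n, 2))]
  best <- NULL; best_ssq <- Inf
  for (tr in enumerate_topologies(n)) {
    ssq <- ls_fit_ssq(tr$edges, n, dvec)
    if (ssq < best_ssq - 1e-10) { best_ssq <- ssq; best <- tr }
  }
  list(tree = edges_to_phylo(best$edges, labels), ssq = best_ssq)
}

edges_to_phylo <- function(edges, labels) {
  n <- length(labels)
  nodes <- max(edges)
  # ape phylo: tips 1..n, root n+1, internals n+1..; reuse numbering but
  # build via newick to avoid ordering constraints
  adj <- lapply(seq_len(nodes), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  build <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0) return(labels[node])
    paste0("(", paste(vapply(kids, build, "", parent = node),
                      collapse = ","), ")")
  }
  root <- n + 1L
  nwk <- paste0("(", paste(vapply(setdiff(adj[[root]], 0L), build, "",
                                  parent = root), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

# random additive tree over n leaves; returns phylo + its exact distances
random_additive_tree <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  topos <- NULL
  # random topology by random sequential insertion
  edges <- rbind(c(1, n + 1), c(2, n + 1), c(3, n + 1))
  next_node <- n + 2L
  if (n > 3) {
    for (leaf in 4:n) {
      e <- sample(nrow(edges), 1)
      u <- edges[e, 1]; v <- edges[e, 2]
      edges <- edges[-e, , drop = FALSE]
      edges <- rbind(edges, c(u, next_node), c(next_node, v),
                     c(leaf, next_node))
      next_node <- next_node + 1L
    }
  }
  lens <- stats::runif(nrow(edges), 0.5, 5)
  A <- path_matrix(edges, n)
  dvec <- as.numeric(A %*% lens)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[t(combn(n, 2))] <- dvec
  d <- d + t(d)
  list(tree = edges_to_phylo(edges, labels), d = d)
}

# --- flat double-loop divergence oracle ------------------------------------
# seqs: named equal-length vector; species/genus: named by sequence id.
# Distances via ape::dist.dna (K80, pairwise deletion) - an implementation
# independent of the package's K2P path.
oracle_divergence <- function(seqs, species, genus) {
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  D <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                               pairwise.deletion = TRUE))
  ids <- names(seqs)
  sp_list <- unique(species[ids])
  per <- list()
  for (sp in sp_list) {
    mine <- ids[species[ids] == sp]
    cong <- ids[genus[ids] == genus[mine[1]] & species[ids] != sp]
    intra <- c(); inter <- c()
    for (i in mine) for (j in mine) if (i < j) intra <- c(intra, D[i, j])
    for (i in mine) for (j in cong) inter <- c(inter, D[i, j])
    per[[sp]] <- list(
      avg_intra = if (length(intra)) mean(intra) else NA,
      depth = if (length(intra)) max(intra) else NA,
      avg_inter = if (length(inter)) mean(inter) else NA,
      min_inter = if (length(inter)) min(inter) else NA,
      n = length(mine))
  }
  pooled_intra <- c()
  for (i in ids) for (j in ids)
    if (i < j && species[i] == species[j])
      pooled_intra <- c(pooled_intra, D[i, j])
  genus_means <- c()
  for (g in unique(genus[ids])) {
    vals <- c()
    gi <- ids[genus[ids] == g]
    for (i in gi) for (j in gi)
      if (i < j && species[i] != species[j]) vals <- c(vals, D[i, j])
    if (length(vals)) genus_means <- c(genus_means, mean(vals))
  }
  g <- function(f) unlist(lapply(per, `[[`, f))
  multi <- vapply(per, function(x) x$n >= 2, logical(1))
  list(avg_inter = mean(g("avg_inter"), na.rm = TRUE),
       theta_prime = mean(genus_means),
       avg_min_inter = mean(g("min_inter"), na.rm = TRUE),
       avg_intra_pooled = mean(pooled_intra),
       theta = mean(g("avg_intra")[multi], na.rm = TRUE),
       avg_coalescent_depth = mean(g("depth")[multi], na.rm = TRUE))
}
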