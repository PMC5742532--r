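# Sequence operations: QC, marker routing, core trimming, alignment, K2P,
# distance matrices, inversion normalization, NJ trees.

test_that("QC applies the inclusive length/ambiguity/alphabet rules", {
  expect_false(validate_query(random_acgt(149), "ITS2")$passed)
  expect_true(validate_query(random_acgt(150), "ITS2")$passed)
  expect_false(validate_query(random_acgt(99), "psbA-trnH")$passed)
  expect_true(validate_query(random_acgt(100), "psbA-trnH")$passed)
  base <- random_acgt(198)
  expect_true(validate_query(paste0(base, "NN"), "ITS2")$passed)      # 1.0%
  qc <- validate_query(paste0(substr(base, 1, 197), "NNN"), "ITS2")   # 1.5%
  expect_false(qc$passed)
  expect_match(qc$failure_reasons, "ambiguous", all = FALSE)
  qcx <- validate_query(paste0(base, "X", "A"), "ITS2")
  expect_false(qcx$passed)
  expect_equal(qcx$invalid_chars, "X")
  expect_error(validate_query("", "ITS2"), "empty")
  r149 <- validate_query(random_acgt(149), "ITS2")
  expect_match(r149$failure_reasons, "length < 150", all = FALSE)
})

test_that("marker detection routes flank-bearing reads and rejects noise", {
  set.seed(7)
  its2 <- wrap_read(random_acgt(200), "ITS2")
  psba <- wrap_read(random_acgt(250), "psbA-trnH")
  expect_equal(detect_marker(its2)$marker, "ITS2")
  expect_equal(detect_marker(psba)$marker, "psbA-trnH")
  expect_error(detect_marker(random_acgt(200)), "unrecognized marker")
})

test_that("core extraction recovers the generator's true span", {
  set.seed(8)
  core <- random_acgt(210)
  p <- marker_profiles()[["ITS2"]]
  res <- extract_core_region(wrap_read(core, "ITS2"), "ITS2")
  expect_equal(res$status, "trimmed")
  expect_equal(res$core_seq, core)
  expect_equal(res$span, c(nchar(p$flank_left) + 1,
                           nchar(p$flank_left) + nchar(core)))
  # no flanks: whole read back, untrimmed
  res2 <- extract_core_region(core, "ITS2")
  expect_equal(res2$status, "untrimmed")
  expect_equal(res2$span, c(1, nchar(core)))
  # left flank only: right edge falls back to the read end
  res3 <- extract_core_region(paste0(p$flank_left, core), "ITS2")
  expect_equal(res3$status, "partial")
  expect_equal(res3$core_seq, core)
})

test_that("alignment identity and counts follow the compared-column rules", {
  al <- align_pair("ACGT", "ACGT")
  expect_equal(al$identity, 1)
  expect_equal(al$compared_columns, 4)
  al2 <- align_pair("ACGT", "AGGT")
  expect_equal(al2$identity, 0.75)
  # C vs G: pyrimidine vs purine, a transversion
  expect_equal(al2$P_count, 0)
  expect_equal(al2$Q_count, 1)
  # ambiguity columns are excluded from comparison
  al3 <- alignment_from_strings("ACNT", "ACGT")
  expect_equal(al3$compared_columns, 3)
  expect_equal(al3$identity, 1)
})

test_that("global alignment scores equal an exhaustive Gotoh oracle", {
  set.seed(21)
  alphabet <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    a <- paste(sample(alphabet, sample(2:8, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(2:8, 1), TRUE), collapse = "")
    expect_equal(align_pair(a, b, "global")$score,
                 oracle_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("K2P distance matches its closed form and flags saturation", {
  mk <- function(n, ts, tv) list(compared_columns = n, P_count = ts,
                                 Q_count = tv)
  expect_equal(k2p_distance(mk(100, 10, 0))$d, -0.5 * log(0.8),
               tolerance = 1e-12)
  expect_equal(k2p_distance(mk(100, 0, 10))$d,
               -0.5 * log(0.9 * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(k2p_distance(align_pair("ACGTACGT", "ACGTACGT"))$d, 0)
  sat <- k2p_distance(mk(100, 50, 0))   # P = 0.5, Q = 0: log-domain edge
  expect_true(sat$saturated)
  expect_equal(sat$d, Inf)
  expect_error(k2p_distance(mk(0, 0, 0)), "at least one")
})

test_that("K2P is monotone in P and Q and dominates the p-distance", {
  for (P in seq(0, 0.3, by = 0.05)) {
    for (Q in seq(0, 0.2, by = 0.05)) {
      r <- k2p_distance(list(compared_columns = 1000,
                             P_count = round(1000 * P),
                             Q_count = round(1000 * Q)))
      if (!r$saturated) expect_gte(r$d, P + Q - 1e-12)
      r2 <- k2p_distance(list(compared_columns = 1000,
                              P_count = round(1000 * P) + 10,
                              Q_count = round(1000 * Q)))
      if (!r$saturated && !r2$saturated) expect_gt(r2$d, r$d)
      r3 <- k2p_distance(list(compared_columns = 1000,
                              P_count = round(1000 * P),
                              Q_count = round(1000 * Q) + 10))
      if (!r$saturated && !r3$saturated) expect_gt(r3$d, r$d)
    }
  }
})

test_that("package K2P agrees with an independent implementation", {
  set.seed(31)
  for (i in 1:5) {
    a <- random_acgt(300)
    b <- mutate_sequence(a, 0.08)
    mine <- k2p_distance(alignment_from_strings(a, b))$d
    mat <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, order-stable", {
  set.seed(32)
  base <- random_acgt(200)
  seqs <- c(s1 = base, s2 = mutate_sequence(base, 0.05),
            s3 = mutate_sequence(base, 0.1), s4 = base)
  m <- build_distance_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_equal(m["s1", "s4"], 0)
  # element-wise agreement with independent per-pair calls
  expect_equal(m["s1", "s2"],
               k2p_distance(align_pair(seqs["s1"], seqs["s2"]))$d)
  # permuting inputs permutes the matrix identically
  perm <- c("s3", "s1", "s4", "s2")
  m2 <- build_distance_matrix(seqs[perm])
  expect_equal(m2, m[perm, perm])
  # identical sequences: zero matrix
  m0 <- build_distance_matrix(c(a = base, b = base, c = base))
  expect_true(all(m0 == 0))
})

test_that("inversion normalization corrects published motif cases", {
  set.seed(41)
  for (motif in c("ATGAAAAC", "AACAAAAC")) {
    left <- random_acgt(120)
    right <- random_acgt(130)
    segment <- paste0("CCGACGTT", motif, "CTGGTGAC")
    reference <- paste0(left, segment, right)
    query <- paste0(left, revcomp(segment), right)
    res <- normalize_inversion(query, reference)
    expect_true(res$inverted)
    expect_gt(res$identity_after, res$identity_before)
    # K2P distance to the reference strictly decreases
    d_before <- k2p_distance(align_pair(query, reference))$d
    d_after <- k2p_distance(align_pair(res$query, reference))$d
    expect_lt(d_after, d_before)
    # idempotent on its own output
    res2 <- normalize_inversion(res$query, reference)
    expect_false(res2$inverted)
    expect_equal(res2$query, res$query)
  }
})

test_that("inversion normalization leaves matching queries alone", {
  set.seed(42)
  ref <- random_acgt(250)
  res <- normalize_inversion(ref, ref)
  expect_false(res$inverted)
  expect_equal(res$query, ref)
  # never decreases identity, and is idempotent, on arbitrary input
  for (i in 1:10) {
    noisy <- mutate_sequence(ref, 0.03)
    segment <- substr(noisy, 100, 123)
    maybe_inv <- paste0(substr(noisy, 1, 99), revcomp(segment),
                        substr(noisy, 124, nchar(noisy)))
    for (q in c(noisy, maybe_inv)) {
      resn <- normalize_inversion(q, ref)
      expect_gte(resn$identity_after, resn$identity_before)
      resn2 <- normalize_inversion(resn$query, ref)
      expect_equal(resn2$query, resn$query)
    }
  }
})

test_that("NJ resolves the classic additive 4-taxon case exactly", {
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj_tree(d)
  expect_s3_class(tr, "phylo")
  # topology ((A,B),(C,D))
  o <- oracle_ls_tree(d)
  expect_equal(o$ssq, 0, tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(o$tree)), 0)
  # branch lengths {A:2, B:3, C:4, D:4, internal:3}
  tip_len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                           tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(tip_len[LETTERS[1:4]]), c(2, 3, 4, 4))
  expect_equal(sort(tr$edge.length), c(2, 3, 3, 4, 4))
})

test_that("NJ on three taxa resolves the unique star exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- build_nj_tree(d)
  expect_setequal(tr$tip.label, c("x", "y", "z"))
  # lengths satisfy the three-point formulas: x=0, y=2, z=3
  tip_len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                           tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(tip_len[c("x", "y", "z")]), c(0, 2, 3))
})

test_that("NJ recovers random additive trees and agrees with ape", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    ad <- random_additive_tree(n)
    tr <- build_nj_tree(ad$d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ad$tree)), 0,
                 info = paste("leaves:", n, "rep:", i))
    ref <- ape::nj(as.dist(ad$d))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ref)), 0)
  }
})

test_that("NJ refuses saturated matrices", {
  d <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(build_nj_tree(d), "saturated")
})
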