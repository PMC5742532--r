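# Nearest-neighbour retrieval over a barcode database: a canonical k-mer
# posting index generates candidates cheaply, exact local alignment ranks
# them.  This replaces an external similarity search engine so that
# ranking is fully reproducible and the package has no binary dependency.

#' Search parameters
#'
#' @param k K-mer length for the candidate index (4..15, default 8).
#' @param min_shared_kmers Minimum distinct shared k-mers for an entry to
#'   become an alignment candidate (default 5).
#' @param top_n Number of hits returned (default 20, the hit-panel size of
#'   the identification report).
#' @return List of class `search_params`.
#' @export
search_params <- function(k = 8L, min_shared_kmers = 5L, top_n = 20L) {
  stopifnot(k >= 4, k <= 15, top_n >= 1, min_shared_kmers >= 1)
  structure(list(k = as.integer(k),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 top_n = as.integer(top_n), mode = "local"),
            class = "search_params")
}

# distinct canonical k-mers of a sequence (canonical = lexicographic min of
# the k-mer and its reverse complement, so indexing is strand-insensitive);
# k-mers containing ambiguity characters are skipped
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(toupper(seq), starts, starts + k - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0) return(character(0))
  rcs <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rcs))
}

#' Build the k-mer candidate index of a database
#'
#' Posting map from each canonical k-mer to the entry ids containing it.
#' Deterministic for a given database and `k`; cached on the database
#' object.  Entries shorter than `k` are indexed with zero k-mers (with a
#' warning) and can only be retrieved through the fallback path.
#'
#' @param db A `barcode_db`.
#' @param params A `search_params`.
#' @return Environment mapping k-mer strings to character vectors of
#'   sequence ids.
#' @export
build_index <- function(db, params = search_params()) {
  stopifnot(inherits(db, "barcode_db"))
  key <- paste0("k", params$k)
  cached <- db$index[[key]]
  if (!is.null(cached)) return(cached)
  idx <- new.env(parent = emptyenv(), size = 4096L)
  for (i in seq_len(nrow(db$entries))) {
    id <- db$entries$sequence_id[i]
    kms <- canonical_kmers(db$entries$seq[i], params$k)
    if (length(kms) == 0)
      warning(sprintf("entry %s shorter than k = %d: indexed with 0 k-mers",
                      id, params$k))
    for (km in kms) idx[[km]] <- c(idx[[km]], id)
  }
  db$index[[key]] <- idx
  idx
}

#' Search a barcode database for the nearest neighbours of a query
#'
#' Candidates are entries sharing at least `min_shared_kmers` distinct
#' canonical k-mers with the query; if that yields fewer candidates than
#' `top_n` (in particular, none), all entries are aligned, so results never
#' silently miss low-similarity neighbours.  Each candidate is scored by
#' exact local alignment in both query orientations (market reads may be
#' reverse-complemented) and the better orientation reported.  Hits are
#' ranked by score, then identity, then sequence id, so ranking is
#' deterministic.
#'
#' @param query Trimmed query sequence (QC passed).
#' @param db A `barcode_db`.
#' @param params A `search_params`.
#' @param marker Optional marker filter applied to db entries before
#'   searching (mixed-marker databases are searched marker-filtered).
#' @return Data frame of hits: `rank`, `sequence_id`, `species_name`,
#'   `marker`, `identity`, `coverage`, `score`, `orientation` (`"+"` or
#'   `"-"`).
#' @export
search_database <- function(query, db, params = search_params(),
                            marker = NULL) {
  stopifnot(inherits(db, "barcode_db"), nzchar(query))
  entries <- db$entries
  if (!is.null(marker))
    entries <- entries[entries$marker == marker, , drop = FALSE]
  if (nrow(entries) == 0) stop("empty database (no entries for this marker)")

  idx <- build_index(db, params)
  qk <- canonical_kmers(query, params$k)
  shared <- integer(0)
  if (length(qk) > 0) {
    postings <- unlist(lapply(qk, function(km) idx[[km]]), use.names = FALSE)
    shared <- table(postings)
  }
  cand_ids <- names(shared)[shared >= params$min_shared_kmers]
  cand_ids <- intersect(cand_ids, entries$sequence_id)
  if (length(cand_ids) == 0) cand_ids <- entries$sequence_id
  cand <- entries[match(cand_ids, entries$sequence_id), , drop = FALSE]

  fwd <- score_candidates(query, cand$seq, mode = "local")
  rev <- score_candidates(revcomp(query), cand$seq, mode = "local")
  use_rev <- rev$score > fwd$score
  hits <- data.frame(
    sequence_id = cand$sequence_id,
    species_name = cand$species_name,
    marker = cand$marker,
    identity = ifelse(use_rev, rev$identity, fwd$identity),
    coverage = ifelse(use_rev, rev$coverage, fwd$coverage),
    score = pmax(fwd$score, rev$score),
    orientation = ifelse(use_rev, "-", "+"),
    stringsAsFactors = FALSE)
  ord <- order(-hits$score, -hits$identity, hits$sequence_id)
  hits <- hits[ord, , drop = FALSE][seq_len(min(params$top_n, nrow(hits))), ,
                                    drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits[, c("rank", "sequence_id", "species_name", "marker", "identity",
           "coverage", "score", "orientation")]
}
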