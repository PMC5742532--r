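# The identification pipeline: QC and marker routing, core-region
# trimming, optional inversion normalization, nearest-neighbour search,
# taxonomic assignment, and an NJ tree over the query plus its top hits.

#' Identify a query barcode read against a barcode database
#'
#' Runs the full pipeline.  Stages, in order: marker detection (skipped
#' when `marker` is given), quality control (failure short-circuits to an
#' unidentified report; no search or tree is computed), core-region
#' trimming, search, inversion normalization (psbA-trnH only, against the
#' provisional top hit, with re-search if a correction is applied),
#' taxonomic assignment, NJ tree over query plus hits.  The executed
#' stages are recorded on the report (`stages`).
#'
#' @param query Query sequence: a single (optionally named) nucleotide
#'   string, or the path of a FASTA file whose first record is used.
#' @param db A `barcode_db` from [compile_database()] or [sdd_database()].
#' @param policy An [assignment_policy()].
#' @param params A [search_params()].
#' @param marker Force the marker (`"ITS2"`/`"psbA-trnH"`) instead of
#'   detecting it.
#' @param build_tree Build the NJ tree panel (default `TRUE`; disable for
#'   bulk runs where only the assignment is needed).
#' @param n_alignments Number of top hits to render pairwise alignments
#'   for (default 3).
#' @return An object of class `identification_report` with fields
#'   `query_id`, `qc`, `marker`, `assignment`, `hits`, `tree` (newick
#'   string or `NA`), `alignments`, `inversion`, `database_tier`, `stages`.
#' @export
identify_query <- function(query, db, policy = assignment_policy(),
                           params = search_params(), marker = NULL,
                           build_tree = TRUE, n_alignments = 3L) {
  stopifnot(inherits(db, "barcode_db"))
  if (length(query) == 1L && is.character(query) && file.exists(query) &&
      !grepl("^[ACGTURYSWKMBDHVN]+$", toupper(query))) {
    fa <- read_fasta(query)
    if (length(fa) == 0) stop("unreadable or empty FASTA query")
    query <- fa[1]
  }
  query_id <- if (!is.null(names(query)) && nzchar(names(query)[1]))
    names(query)[1] else "query"
  seq <- unname(toupper(query[[1]]))
  stages <- character(0)
  report <- function(qc = NULL, marker = NA_character_, assignment = NULL,
                     hits = NULL, tree = NA_character_, alignments = list(),
                     inversion = list(flag = FALSE, segment = NULL)) {
    if (is.null(assignment))
      assignment <- list(rank = "unidentified", name = NA_character_,
                         identity = NA_real_, basis = "pipeline aborted")
    structure(list(query_id = query_id, qc = qc, marker = marker,
                   assignment = assignment, hits = hits, tree = tree,
                   alignments = alignments, inversion = inversion,
                   database_tier = db$tier, stages = stages),
              class = "identification_report")
  }

  if (is.null(marker)) {
    stages <- c(stages, "marker_detection")
    det <- tryCatch(detect_marker(seq), error = function(e) NULL)
    if (is.null(det)) {
      qc <- tryCatch(validate_query(seq, "ITS2"), error = function(e) NULL)
      if (!is.null(qc)) {
        qc$passed <- FALSE
        qc$failure_reasons <- c(qc$failure_reasons, "unrecognized marker")
      }
      return(report(qc = qc,
                    assignment = list(rank = "unidentified",
                                      name = NA_character_,
                                      identity = NA_real_,
                                      basis = "unrecognized marker")))
    }
    marker <- det$marker
    if (det$orientation == "-") {
      # flanks matched the reverse complement: reorient before QC/trimming
      stages <- c(stages, "reorient")
      seq <- revcomp(seq)
    }
  }

  stages <- c(stages, "qc")
  qc <- validate_query(seq, marker)
  if (!qc$passed) {
    return(report(qc = qc, marker = marker,
                  assignment = list(rank = "unidentified",
                                    name = NA_character_,
                                    identity = NA_real_,
                                    basis = paste("QC failed:",
                                                  paste(qc$failure_reasons,
                                                        collapse = "; ")))))
  }

  stages <- c(stages, "trim")
  core <- extract_core_region(seq, marker)
  qseq <- core$core_seq

  stages <- c(stages, "search")
  hits <- search_database(qseq, db, params, marker = marker)

  inversion <- list(flag = FALSE, segment = NULL)
  if (marker == "psbA-trnH" && nrow(hits) > 0) {
    stages <- c(stages, "inversion_check")
    top_seq <- db$entries$seq[match(hits$sequence_id[1],
                                    db$entries$sequence_id)]
    qtest <- if (hits$orientation[1] == "-") revcomp(qseq) else qseq
    inv <- normalize_inversion(qtest, top_seq)
    if (inv$inverted) {
      stages <- c(stages, "inversion_corrected")
      qseq <- if (hits$orientation[1] == "-") revcomp(inv$query) else inv$query
      inversion <- list(flag = TRUE, segment = inv$segment)
      hits <- search_database(qseq, db, params, marker = marker)
    }
  }

  stages <- c(stages, "assign")
  assignment <- assign_taxon(hits, policy)

  tree <- NA_character_
  if (build_tree && nrow(hits) >= 2) {
    stages <- c(stages, "tree")
    labels <- c(paste0("query|", query_id), hits$sequence_id)
    seqs <- setNames(c(qseq, db$entries$seq[match(hits$sequence_id,
                                                  db$entries$sequence_id)]),
                     labels)
    tree <- tryCatch({
      dm <- suppressWarnings(build_distance_matrix(seqs))
      ape::write.tree(build_nj_tree(dm))
    }, error = function(e) NA_character_)
  }

  alignments <- list()
  n_al <- min(n_alignments, nrow(hits))
  if (n_al > 0) {
    stages <- c(stages, "alignments")
    for (i in seq_len(n_al)) {
      hseq <- db$entries$seq[match(hits$sequence_id[i],
                                   db$entries$sequence_id)]
      qa <- if (hits$orientation[i] == "-") revcomp(qseq) else qseq
      aln <- align_pair(qa, hseq, mode = "global")
      alignments[[i]] <- list(sequence_id = hits$sequence_id[i],
                              aligned_query = aln$aligned_a,
                              aligned_hit = aln$aligned_b,
                              identity = aln$identity)
    }
  }

  report(qc = qc, marker = marker, assignment = assignment, hits = hits,
         tree = tree, alignments = alignments, inversion = inversion)
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("Identification report for '%s' [%s, db %s]\n", x$query_id,
              ifelse(is.na(x$marker), "marker unknown", x$marker),
              x$database_tier))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %s\n",
                if (x$qc$passed) "passed"
                else paste("FAILED -", paste(x$qc$failure_reasons,
                                             collapse = "; "))))
  a <- x$assignment
  cat(sprintf("  Assignment: %s%s (%s)\n", a$rank,
              if (!is.na(a$name)) paste0(" ", a$name) else "", a$basis))
  if (!is.null(x$hits) && nrow(x$hits) > 0)
    cat(sprintf("  Top hit: %s (%s), identity %.4f\n",
                x$hits$sequence_id[1], x$hits$species_name[1],
                x$hits$identity[1]))
  if (isTRUE(x$inversion$flag))
    cat("  Inversion detected and normalized\n")
  invisible(x)
}
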