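# Report serialization: the four panels (assignment, hit table, NJ tree,
# alignments) rendered as plain text, JSON or minimal HTML.

# canonical plain-list form used for JSON (stable field order, no
# environments or classes)
as_report_list <- function(report) {
  qc <- report$qc
  list(
    query_id = report$query_id,
    marker = report$marker,
    database_tier = report$database_tier,
    qc = if (is.null(qc)) NULL else list(
      passed = qc$passed,
      length = qc$length,
      ambiguous_fraction = qc$ambiguous_fraction,
      invalid_chars = as.list(qc$invalid_chars),
      failure_reasons = as.list(qc$failure_reasons)),
    assignment = list(rank = report$assignment$rank,
                      name = report$assignment$name,
                      identity = report$assignment$identity,
                      basis = report$assignment$basis),
    hits = report$hits,
    tree = report$tree,
    alignments = report$alignments,
    inversion = list(flag = report$inversion$flag,
                     segment = as.list(report$inversion$segment)),
    stages = as.list(report$stages))
}

#' Render an identification report
#'
#' Serializes all four report panels (taxonomic assignment, hit table,
#' NJ tree, alignments).  The JSON form round-trips losslessly through
#' [parse_report_json()]; the newick string is readable by standard tree
#' parsers.
#'
#' @param report An `identification_report`.
#' @param format `"text"`, `"json"` or `"html"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("text", "json", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "identification_report"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(as_report_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", na = "null")))
  }
  txt <- character(0)
  add <- function(...) txt <<- c(txt, sprintf(...))
  a <- report$assignment
  add("== Taxonomic assignment ==")
  add("query: %s   marker: %s   database: %s", report$query_id,
      report$marker, report$database_tier)
  if (!is.null(report$qc))
    add("QC: %s", if (report$qc$passed) "passed" else
        paste("FAILED -", paste(report$qc$failure_reasons, collapse = "; ")))
  add("assignment: %s%s", a$rank,
      if (!is.na(a$name)) paste0(" ", a$name) else "")
  add("basis: %s", a$basis)
  if (isTRUE(report$inversion$flag))
    add("inversion normalized at query positions %d-%d",
        report$inversion$segment[1], report$inversion$segment[2])
  add("")
  add("== Sequence similarity (top hits) ==")
  if (!is.null(report$hits) && nrow(report$hits) > 0) {
    h <- report$hits
    add("%4s  %-20s  %-30s  %-9s  %8s  %8s  %8s  %3s", "rank", "sequence_id",
        "species", "marker", "identity", "coverage", "score", "ori")
    for (i in seq_len(nrow(h)))
      add("%4d  %-20s  %-30s  %-9s  %8.4f  %8.4f  %8.1f  %3s", h$rank[i],
          h$sequence_id[i], h$species_name[i], h$marker[i], h$identity[i],
          h$coverage[i], h$score[i], h$orientation[i])
  } else add("(no hits: pipeline short-circuited)")
  add("")
  add("== NJ tree (newick) ==")
  add("%s", if (is.na(report$tree)) "(not built)" else report$tree)
  add("")
  add("== Alignments vs top hits ==")
  if (length(report$alignments) > 0) {
    for (al in report$alignments) {
      add("vs %s (identity %.4f)", al$sequence_id, al$identity)
      add("query: %s", al$aligned_query)
      add("hit:   %s", al$aligned_hit)
    }
  } else add("(none)")
  body <- paste(txt, collapse = "\n")
  if (format == "text") return(body)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
         "<title>Identification report: ", report$query_id,
         "</title></head>\n<body><pre>\n", body, "\n</pre></body></html>")
}

#' Parse a JSON identification report back into an object
#'
#' Inverse of `render_report(report, "json")`:
#' `render_report(parse_report_json(render_report(r, "json")), "json")`
#' reproduces the original string byte for byte.
#'
#' @param json JSON string produced by [render_report()].
#' @return An `identification_report`.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  qc <- x$qc
  if (!is.null(qc))
    qc <- structure(list(passed = qc$passed, length = qc$length,
                         ambiguous_fraction = qc$ambiguous_fraction,
                         invalid_chars = as.character(unlist(qc$invalid_chars)),
                         failure_reasons = as.character(unlist(qc$failure_reasons))),
                    class = "qc_result")
  alignments <- x$alignments
  if (is.data.frame(alignments)) {
    alignments <- lapply(seq_len(nrow(alignments)), function(i)
      as.list(alignments[i, , drop = FALSE]))
    alignments <- lapply(alignments, function(al)
      list(sequence_id = al$sequence_id, aligned_query = al$aligned_query,
           aligned_hit = al$aligned_hit, identity = al$identity))
  } else if (is.null(alignments)) alignments <- list()
  hits <- x$hits
  if (!is.null(hits) && nrow(hits) > 0) rownames(hits) <- NULL
  structure(list(
    query_id = x$query_id,
    qc = qc,
    marker = if (is.null(x$marker)) NA_character_ else x$marker,
    assignment = list(rank = x$assignment$rank,
                      name = if (is.null(x$assignment$name)) NA_character_
                             else x$assignment$name,
                      identity = if (is.null(x$assignment$identity)) NA_real_
                                 else x$assignment$identity,
                      basis = x$assignment$basis),
    hits = hits,
    tree = if (is.null(x$tree)) NA_character_ else x$tree,
    alignments = alignments,
    inversion = list(flag = x$inversion$flag,
                     segment = if (length(x$inversion$segment))
                       as.integer(unlist(x$inversion$segment)) else NULL),
    stages = as.character(unlist(x$stages)),
    database_tier = x$database_tier), class = "identification_report")
}

#' Write the hit table of a report as TSV
#'
#' @param report An `identification_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(report, path) {
  stopifnot(inherits(report, "identification_report"))
  hits <- report$hits
  if (is.null(hits)) hits <- data.frame()
  write_tsv(hits, path)
}
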