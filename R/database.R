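# Barcode database tiers: SBD (study records), PBD (public records), ABD
# (their union), SDD (user-supplied FASTA). A database is the searchable
# projection of the library: species-labelled core sequences plus a lazy
# k-mer index.

#' Compile a searchable barcode database tier from a library
#'
#' SBD keeps sequences with `source == "study"`, PBD those with
#' `source == "public"`, ABD their union deduplicated by `sequence_id`.
#' Entries carry the core sequence when a core span is annotated, the raw
#' sequence otherwise; species labels are the primary names of the linked
#' taxonomy entries.
#'
#' @param library A `herb_library`.
#' @param tier `"SBD"`, `"PBD"` or `"ABD"`.  For a self-defined database
#'   from a FASTA file use [sdd_database()].
#' @param marker Optional marker filter (`"ITS2"` or `"psbA-trnH"`).
#' @return An object of class `barcode_db`.
#' @export
compile_database <- function(library, tier = c("SBD", "PBD", "ABD"),
                             marker = NULL) {
  stopifnot(inherits(library, "herb_library"))
  tier <- match.arg(tier)
  seqs <- library$sequences
  keep <- switch(tier,
    SBD = seqs$source == "study",
    PBD = seqs$source == "public",
    ABD = rep(TRUE, nrow(seqs)))
  seqs <- seqs[keep, , drop = FALSE]
  seqs <- seqs[!duplicated(seqs$sequence_id), , drop = FALSE]
  if (!is.null(marker)) seqs <- seqs[seqs$marker == marker, , drop = FALSE]
  if (nrow(seqs) == 0)
    stop(sprintf("empty database tier: %s", tier))
  sp_of <- setNames(library$taxonomy$primary_name, library$taxonomy$taxon_id)
  entries <- data.frame(
    sequence_id = seqs$sequence_id,
    species_name = unname(sp_of[seqs$taxon_id]),
    marker = seqs$marker,
    seq = ifelse(nzchar(seqs$core_seq), seqs$core_seq, seqs$raw_seq),
    stringsAsFactors = FALSE)
  new_barcode_db(tier, entries)
}

#' Build a self-defined barcode database (SDD) from a user FASTA
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param species_map Optional path to a TSV (or a data frame) with columns
#'   `sequence_id`, `species_name` and optionally `marker`.  Without a map,
#'   species labels default to the sequence ids and the marker to
#'   `default_marker`.
#' @param default_marker Marker recorded for unmapped entries.
#' @return An object of class `barcode_db`, tier `"SDD"`.
#' @export
sdd_database <- function(fasta, species_map = NULL,
                         default_marker = "ITS2") {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) read_fasta(fasta) else fasta
  if (length(seqs) == 0) stop("empty database tier: SDD")
  entries <- data.frame(sequence_id = names(seqs),
                        species_name = names(seqs),
                        marker = default_marker,
                        seq = unname(seqs), stringsAsFactors = FALSE)
  if (!is.null(species_map)) {
    map <- if (is.data.frame(species_map)) species_map else
      read_table_checked(species_map, c("sequence_id", "species_name"),
                         optional = "marker")
    hit <- match(entries$sequence_id, map$sequence_id)
    ok <- !is.na(hit)
    entries$species_name[ok] <- map$species_name[hit[ok]]
    if ("marker" %in% names(map)) {
      mk <- map$marker[hit[ok]]
      entries$marker[ok][nzchar(mk)] <- mk[nzchar(mk)]
    }
  }
  new_barcode_db("SDD", entries)
}

new_barcode_db <- function(tier, entries) {
  if (anyDuplicated(entries$sequence_id))
    stop("duplicate sequence_id in database entries")
  structure(list(tier = tier, entries = entries,
                 index = new.env(parent = emptyenv())),
            class = "barcode_db")
}

#' @export
print.barcode_db <- function(x, ...) {
  cat(sprintf("Barcode database [%s]: %d sequences, %d species\n",
              x$tier, nrow(x$entries), length(unique(x$entries$species_name))))
  per <- table(x$entries$marker)
  cat("  per marker: ",
      paste(sprintf("%s=%d", names(per), per), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Resolve a `-d/--database` CLI argument into a database
#'
#' Accepts `"SBD"`, `"PBD"`, `"ABD"` (compiled from `library`), or
#' `"SDD:path.fasta"` / `"selfDefinded:path.fasta"` for a user FASTA.
#'
#' @param spec Database tier string.
#' @param library A `herb_library`, required for the built-in tiers.
#' @param marker Optional marker filter for built-in tiers.
#' @return A `barcode_db`.
#' @export
resolve_database_arg <- function(spec, library = NULL, marker = NULL) {
  if (grepl("^(SDD|selfDefinded|selfdefined)(:|$)", spec, ignore.case = TRUE)) {
    path <- sub("^[^:]*:?", "", spec)
    if (!nzchar(path))
      stop("SDD database requires a path, e.g. SDD:my_refs.fasta")
    return(sdd_database(path))
  }
  if (is.null(library))
    stop("built-in tiers need a reference library")
  compile_database(library, match.arg(toupper(spec), c("SBD", "PBD", "ABD")),
                   marker = marker)
}
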