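# The record data model of a barcode reference library: taxonomy records
# (with synonym sets), specimen records, sequence records, reference
# records and drug monographs, serialized as five TSV tables plus a FASTA
# of raw sequences.
#
# TSV schemas (tab-separated, UTF-8, header row, one record per line):
#   taxonomy.tsv    taxon_id, primary_name, authority, rank, parent_id,
#                   synonyms            ("Name::source;Name::source", source
#                                        in {ChP, FloraOfChina, NCBI})
#   specimens.tsv   specimen_id, taxon_id, material_kind, drug_name,
#                   locality, voucher
#   sequences.tsv   sequence_id, specimen_id, taxon_id, marker, source,
#                   reference_id, core_start, core_end
#   references.tsv  reference_id, title, authors, year, journal,
#                   linked_taxa          (";"-joined taxon_ids)
#   monographs.tsv  drug_name, pharmacopeia, origins (";"-joined names),
#                   medicinal_part
#   sequences.fasta  ">sequence_id" headers; raw sequences

TAXONOMY_COLS <- c("taxon_id", "primary_name", "authority", "rank",
                   "parent_id", "synonyms")
SPECIMEN_COLS <- c("specimen_id", "taxon_id", "material_kind", "drug_name",
                   "locality", "voucher")
SEQUENCE_COLS <- c("sequence_id", "specimen_id", "taxon_id", "marker",
                   "source", "reference_id", "core_start", "core_end")
REFERENCE_COLS <- c("reference_id", "title", "authors", "year", "journal",
                    "linked_taxa")
MONOGRAPH_COLS <- c("drug_name", "pharmacopeia", "origins", "medicinal_part")
SPECIES_RANKS <- c("species", "infraspecies")

#' Read a barcode reference library from disk
#'
#' Loads the five TSV record tables and the raw-sequence FASTA from a
#' directory and cross-links them.  Structural problems (missing files or
#' columns, a FASTA id absent from the sequence table or vice versa, a
#' dangling foreign key) abort with an error naming the record and field;
#' semantic rule violations are the business of [validate_library()], which
#' reports rather than throws.
#'
#' @param dir Directory holding `taxonomy.tsv`, `specimens.tsv`,
#'   `sequences.tsv`, `sequences.fasta` and optionally `references.tsv`
#'   and `monographs.tsv`.
#' @return An object of class `herb_library`.
#' @export
read_library <- function(dir) {
  stopifnot(dir.exists(dir))
  p <- function(f) file.path(dir, f)
  taxonomy <- read_table_checked(p("taxonomy.tsv"), TAXONOMY_COLS)
  specimens <- read_table_checked(p("specimens.tsv"), SPECIMEN_COLS)
  sequences <- read_table_checked(p("sequences.tsv"), SEQUENCE_COLS)
  references <- if (file.exists(p("references.tsv"))) {
    read_table_checked(p("references.tsv"), REFERENCE_COLS)
  } else {
    as.data.frame(setNames(rep(list(character(0)), length(REFERENCE_COLS)),
                           REFERENCE_COLS))
  }
  monographs <- if (file.exists(p("monographs.tsv"))) {
    read_table_checked(p("monographs.tsv"), MONOGRAPH_COLS)
  } else {
    as.data.frame(setNames(rep(list(character(0)), length(MONOGRAPH_COLS)),
                           MONOGRAPH_COLS))
  }
  fasta <- read_fasta(p("sequences.fasta"))
  herb_library(taxonomy, specimens, sequences, fasta,
               references = references, monographs = monographs)
}

#' Assemble a barcode reference library from in-memory tables
#'
#' @param taxonomy,specimens,sequences,references,monographs Data frames
#'   following the documented TSV schemas.
#' @param fasta Named character vector of raw sequences keyed by
#'   `sequence_id`.
#' @return An object of class `herb_library`: a list of the five record
#'   tables with `raw_seq` and `core_seq` materialized on the sequence
#'   table.
#' @export
herb_library <- function(taxonomy, specimens, sequences, fasta,
                         references = NULL, monographs = NULL) {
  empty <- function(cols)
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  if (is.null(references)) references <- empty(REFERENCE_COLS)
  if (is.null(monographs)) monographs <- empty(MONOGRAPH_COLS)

  # cross-link FASTA <-> sequence table
  extra <- setdiff(names(fasta), sequences$sequence_id)
  if (length(extra) > 0)
    stop(sprintf(
      "load error [sequences.fasta]: id(s) absent from sequence table: %s",
      paste(extra, collapse = ", ")))
  missing_seq <- setdiff(sequences$sequence_id, names(fasta))
  if (length(missing_seq) > 0)
    stop(sprintf(
      "load error [sequences.tsv, sequence_id]: no FASTA sequence for: %s",
      paste(missing_seq, collapse = ", ")))
  sequences$raw_seq <- unname(fasta[sequences$sequence_id])
  cs <- suppressWarnings(as.integer(sequences$core_start))
  ce <- suppressWarnings(as.integer(sequences$core_end))
  sequences$core_seq <- ifelse(!is.na(cs) & !is.na(ce) & cs >= 1 & ce >= cs,
                               substr(sequences$raw_seq, cs, ce), "")

  # dangling foreign keys are load errors
  check_fk <- function(keys, universe, table, field) {
    keys <- keys[nzchar(keys)]
    bad <- setdiff(keys, universe)
    if (length(bad) > 0)
      stop(sprintf("load error [%s, %s]: dangling reference(s): %s",
                   table, field, paste(unique(bad), collapse = ", ")))
  }
  tax_ids <- taxonomy$taxon_id
  check_fk(taxonomy$parent_id, tax_ids, "taxonomy.tsv", "parent_id")
  check_fk(specimens$taxon_id, tax_ids, "specimens.tsv", "taxon_id")
  check_fk(sequences$taxon_id, tax_ids, "sequences.tsv", "taxon_id")
  check_fk(sequences$specimen_id, specimens$specimen_id,
           "sequences.tsv", "specimen_id")
  check_fk(sequences$reference_id, references$reference_id,
           "sequences.tsv", "reference_id")
  check_fk(unlist(split_multi(references$linked_taxa)), tax_ids,
           "references.tsv", "linked_taxa")

  structure(list(taxonomy = taxonomy, specimens = specimens,
                 sequences = sequences, references = references,
                 monographs = monographs),
            class = "herb_library")
}

#' Write a barcode reference library to disk
#'
#' Inverse of [read_library()]: writes the five TSV tables and the raw
#' FASTA into `dir`.
#'
#' @param library A `herb_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "herb_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- library$sequences
  write_tsv(library$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(library$specimens, file.path(dir, "specimens.tsv"))
  write_tsv(seqs[, SEQUENCE_COLS], file.path(dir, "sequences.tsv"))
  write_tsv(library$references, file.path(dir, "references.tsv"))
  write_tsv(library$monographs, file.path(dir, "monographs.tsv"))
  write_fasta(setNames(seqs$raw_seq, seqs$sequence_id),
              file.path(dir, "sequences.fasta"))
  invisible(dir)
}

#' @export
print.herb_library <- function(x, ...) {
  s <- library_stats(x)
  cat("Barcode reference library\n")
  cat(sprintf("  %d taxonomy, %d specimen, %d sequence, %d reference records\n",
              s$n_taxonomy, s$n_specimens, s$n_sequences, s$n_references))
  if (s$n_monographs > 0)
    cat(sprintf("  %d drug monographs\n", s$n_monographs))
  per <- s$sequences_per_marker
  if (length(per) > 0)
    cat("  sequences per marker: ",
        paste(sprintf("%s=%d", names(per), per), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Record counts of a library
#'
#' @param library A `herb_library`.
#' @return List of counts: records per type, sequences per marker, and
#'   distinct species per source tier (study/public/all).
#' @export
library_stats <- function(library) {
  stopifnot(inherits(library, "herb_library"))
  seqs <- library$sequences
  sp_of <- setNames(library$taxonomy$primary_name, library$taxonomy$taxon_id)
  species_in <- function(rows)
    length(unique(sp_of[rows$taxon_id]))
  list(
    n_taxonomy = nrow(library$taxonomy),
    n_specimens = nrow(library$specimens),
    n_sequences = nrow(seqs),
    n_references = nrow(library$references),
    n_monographs = nrow(library$monographs),
    sequences_per_marker = if (nrow(seqs)) table(seqs$marker) else table(character(0)),
    species_per_tier = c(
      SBD = species_in(seqs[seqs$source == "study", , drop = FALSE]),
      PBD = species_in(seqs[seqs$source == "public", , drop = FALSE]),
      ABD = species_in(seqs))
  )
}

# --- name normalization and resolution -------------------------------------

#' Normalize a scientific name for matching
#'
#' Case-insensitive, internal whitespace collapsed, leading/trailing space
#' stripped.  Infraspecific markers ("var.", "subsp.") are retained.
#'
#' @param x Character vector of names.
#' @return Normalized names.
#' @export
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# name index: one row per matchable name
name_index <- function(taxonomy) {
  prim <- data.frame(norm = normalize_name(taxonomy$primary_name),
                     taxon_id = taxonomy$taxon_id,
                     kind = "primary", source = "",
                     name = taxonomy$primary_name,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(prim$norm))
    stop("taxonomy invariant violated: duplicate primary names: ",
         paste(unique(prim$name[duplicated(prim$norm)]), collapse = ", "))
  syn_rows <- list()
  for (i in seq_len(nrow(taxonomy))) {
    packed <- taxonomy$synonyms[i]
    if (!nzchar(packed)) next
    for (item in split_multi(packed)[[1]]) {
      parts <- strsplit(item, "::", fixed = TRUE)[[1]]
      syn_rows[[length(syn_rows) + 1L]] <- data.frame(
        norm = normalize_name(parts[1]),
        taxon_id = taxonomy$taxon_id[i],
        kind = "synonym",
        source = if (length(parts) > 1) parts[2] else "",
        name = parts[1], stringsAsFactors = FALSE)
    }
  }
  rbind(prim, do.call(rbind, syn_rows))
}

#' Resolve a scientific name against the library taxonomy
#'
#' Matches the (normalized) input against primary names and synonyms.  When
#' no exact match exists, trailing tokens are stripped one at a time (down
#' to a binomial, or a quadrinomial around an infraspecific marker) so that
#' names carrying an authority string still resolve.
#'
#' @param name Name to resolve.
#' @param library A `herb_library`.
#' @return List with `found` (logical); when found also `taxon_id`,
#'   `primary_name`, `rank`, `matched_via` (`"primary"` or `"synonym"`),
#'   `synonym_source` (`""` for primary matches) and `matched_name`.  A
#'   synonym claimed by more than one taxonomy entry raises an ambiguity
#'   error.
#' @examples
#' \dontrun{resolve_name("Tetradium ruticarpum", lib)}
#' @export
resolve_name <- function(name, library) {
  stopifnot(inherits(library, "herb_library"))
  idx <- name_index(library$taxonomy)
  candidates <- normalize_name(name)
  toks <- strsplit(candidates, " ", fixed = TRUE)[[1]]
  infra <- which(toks %in% c("var.", "subsp.", "f."))
  floor_len <- if (length(infra) > 0) max(infra) + 1L else 2L
  while (length(toks) > floor_len) {
    toks <- toks[-length(toks)]
    candidates <- c(candidates, paste(toks, collapse = " "))
  }
  for (cand in candidates) {
    rows <- idx[idx$norm == cand, , drop = FALSE]
    if (nrow(rows) == 0) next
    if (length(unique(rows$taxon_id)) > 1)
      stop(sprintf("ambiguous name '%s': claimed by taxa %s", name,
                   paste(unique(rows$taxon_id), collapse = ", ")))
    row <- rows[order(rows$kind != "primary"), , drop = FALSE][1, ]
    entry <- library$taxonomy[library$taxonomy$taxon_id == row$taxon_id, ]
    return(list(found = TRUE,
                taxon_id = row$taxon_id,
                primary_name = entry$primary_name[1],
                rank = entry$rank[1],
                matched_via = row$kind,
                synonym_source = row$source,
                matched_name = row$name))
  }
  list(found = FALSE)
}

# Resolve a vector of names to primary names; unknown names pass through
# normalized (used when monograph origins cite taxa outside the library).
resolve_to_primary <- function(names, library = NULL) {
  vapply(names, function(nm) {
    if (!is.null(library)) {
      r <- resolve_name(nm, library)
      if (r$found) return(normalize_name(r$primary_name))
    }
    normalize_name(nm)
  }, character(1), USE.NAMES = FALSE)
}

# --- validation -------------------------------------------------------------

#' Validate a loaded library against the record-model rules
#'
#' Checks, and reports as data rather than raising: every specimen,
#' sequence and reference-linked taxon maps at or below species rank; every
#' specimen has at least one companion sequence record; raw sequences are
#' non-empty and within the IUPAC alphabet; record ids are unique per
#' table.  An empty report means the library is valid.
#'
#' @param library A `herb_library`.
#' @return Data frame with columns `class`, `record_id`, `message`; zero
#'   rows when the library is valid.
#' @export
validate_library <- function(library) {
  stopifnot(inherits(library, "herb_library"))
  out <- list()
  add <- function(class, id, msg)
    out[[length(out) + 1L]] <<- data.frame(class = class, record_id = id,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  tax <- library$taxonomy
  rank_of <- setNames(tax$rank, tax$taxon_id)

  check_rank <- function(ids, record_ids, what) {
    bad <- which(!(rank_of[ids] %in% SPECIES_RANKS))
    for (i in bad)
      add("above_species_level", record_ids[i],
          sprintf("%s maps to taxon %s of rank '%s' (above species level)",
                  what, ids[i], rank_of[ids[i]]))
  }
  check_rank(library$specimens$taxon_id, library$specimens$specimen_id,
             "specimen")
  check_rank(library$sequences$taxon_id, library$sequences$sequence_id,
             "sequence")
  if (nrow(library$references) > 0) {
    for (i in seq_len(nrow(library$references))) {
      ids <- split_multi(library$references$linked_taxa[i])[[1]]
      if (length(ids) == 0)
        add("empty_linked_taxa", library$references$reference_id[i],
            "reference links no taxa")
      check_rank(ids, rep(library$references$reference_id[i], length(ids)),
                 "reference")
    }
  }

  with_seq <- unique(library$sequences$specimen_id)
  orphans <- setdiff(library$specimens$specimen_id, with_seq)
  for (id in orphans)
    add("specimen_without_sequence", id,
        "specimen without companion sequence record")

  for (i in seq_len(nrow(library$sequences))) {
    s <- library$sequences$raw_seq[i]
    id <- library$sequences$sequence_id[i]
    if (!nzchar(s)) {
      add("invalid_alphabet", id, "empty sequence")
    } else {
      bad <- setdiff(unique(seq_chars(s)), IUPAC_CHARS)
      if (length(bad) > 0)
        add("invalid_alphabet", id,
            sprintf("non-IUPAC character(s): %s", paste(bad, collapse = "")))
    }
  }

  check_dups <- function(ids, table) {
    for (id in unique(ids[duplicated(ids)]))
      add("duplicate_id", id, sprintf("duplicate id in %s", table))
  }
  check_dups(tax$taxon_id, "taxonomy")
  check_dups(library$specimens$specimen_id, "specimens")
  check_dups(library$sequences$sequence_id, "sequences")
  check_dups(library$references$reference_id, "references")

  if (length(out) == 0)
    return(data.frame(class = character(0), record_id = character(0),
                      message = character(0)))
  do.call(rbind, out)
}
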