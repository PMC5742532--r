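# Rule-based taxonomic assignment from ranked hits, and label matching
# against drug monographs.

#' Assignment policy
#'
#' Thresholds governing how ranked hits are turned into a taxonomic
#' assignment.  All identities are proportions in (0, 1].
#'
#' @param species_identity_min Minimum best-hit identity for a
#'   species-level call (default 0.97).  The default sits inside the
#'   barcode gap: intraspecific pairwise identities for these markers
#'   typically stay above ~0.98 (two reads each ~0.5% diverged from their
#'   species consensus meet near 1% apart) while congeneric interspecific
#'   identities fall below ~0.92, so a cutoff at 0.97 separates the two
#'   distributions rather than bisecting the intraspecific one.
#' @param tie_margin Hits within this identity margin of the best hit are
#'   considered tied (default 0.003).
#' @param genus_identity_min Minimum best-hit identity for a genus-level
#'   call (default 0.95).
#' @param min_coverage Hits whose local alignment covers less than this
#'   fraction of the query are ignored by the assignment rule (default
#'   0.5): a short perfect local match carries identity 1 but is not
#'   evidence about the whole read.
#' @return List of class `assignment_policy`.
#' @export
assignment_policy <- function(species_identity_min = 0.97,
                              tie_margin = 0.003,
                              genus_identity_min = 0.95,
                              min_coverage = 0.5) {
  stopifnot(genus_identity_min > 0,
            genus_identity_min <= species_identity_min,
            species_identity_min <= 1, tie_margin >= 0,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(species_identity_min = species_identity_min,
                 tie_margin = tie_margin,
                 genus_identity_min = genus_identity_min,
                 min_coverage = min_coverage),
            class = "assignment_policy")
}

genus_of <- function(species_name) {
  vapply(strsplit(species_name, "\\s+"), `[[`, "", 1L)
}

#' Assign a taxon from ranked search hits
#'
#' Species call: the best identity reaches `species_identity_min` and all
#' hits within `tie_margin` of it agree on one species.  Genus call: those
#' tied hits span several species of a single genus, or the best identity
#' sits in `[genus_identity_min, species_identity_min)`; the call is the
#' majority genus among the tied hits (ties broken alphabetically).
#' Otherwise unidentified.  Hits covering less than the policy's
#' `min_coverage` of the query are ignored throughout.  Deterministic for
#' a given hit table.
#'
#' @param hits Hit data frame from [search_database()] (non-empty).
#' @param policy An [assignment_policy()].
#' @return List with `rank` (`"species"`, `"genus"` or `"unidentified"`),
#'   `name` (assigned name or `NA`), `identity` (best hit identity) and
#'   `basis` (human-readable explanation).
#' @export
assign_taxon <- function(hits, policy = assignment_policy()) {
  stopifnot(nrow(hits) > 0)
  if ("coverage" %in% names(hits))
    hits <- hits[hits$coverage >= policy$min_coverage, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(rank = "unidentified", name = NA_character_,
                identity = NA_real_,
                basis = "no hit covers enough of the query"))
  best <- max(hits$identity)
  tied <- hits[hits$identity >= best - policy$tie_margin, , drop = FALSE]
  tied_species <- unique(tied$species_name)
  tied_genera <- unique(genus_of(tied$species_name))

  if (best >= policy$species_identity_min) {
    if (length(tied_species) == 1L) {
      return(list(rank = "species", name = tied_species,
                  identity = best,
                  basis = sprintf("best identity %.4f, unambiguous within tie margin",
                                  best)))
    }
    if (length(tied_genera) == 1L) {
      return(list(rank = "genus", name = tied_genera, identity = best,
                  basis = sprintf("tied hits span %d species of one genus",
                                  length(tied_species))))
    }
    return(list(rank = "unidentified", name = NA_character_,
                identity = best,
                basis = "tied hits span multiple genera"))
  }
  if (best >= policy$genus_identity_min) {
    tab <- sort(table(genus_of(tied$species_name)), decreasing = TRUE)
    maj <- names(tab)[tab == max(tab)]
    return(list(rank = "genus", name = sort(maj)[1L], identity = best,
                basis = sprintf("best identity %.4f below species threshold %.4f",
                                best, policy$species_identity_min)))
  }
  list(rank = "unidentified", name = NA_character_, identity = best,
       basis = sprintf("best identity %.4f below genus threshold %.4f",
                       best, policy$genus_identity_min))
}

#' Match an assignment against a labelled drug's official origins
#'
#' `matched` iff the assignment is species-rank and the assigned species
#' (after synonym resolution) is among the drug's official origin species;
#' `mismatched` iff it is species-rank and not an origin (an adulterant
#' signal); genus-rank or unidentified assignments are `inconclusive`.
#'
#' @param assignment Result of [assign_taxon()].
#' @param drug_name Label on the market sample; must name a monograph.
#' @param monographs Monograph data frame or list of [drug_monograph()]s.
#' @param library Optional `herb_library` for synonym resolution.
#' @return One of `"matched"`, `"mismatched"`, `"inconclusive"`.
#' @export
match_label <- function(assignment, drug_name, monographs, library = NULL) {
  mono <- monograph_list(monographs)
  names_norm <- normalize_name(vapply(mono, `[[`, "", "drug_name"))
  hit <- which(names_norm == normalize_name(drug_name))
  if (length(hit) == 0)
    stop(sprintf("unknown drug name: %s", drug_name))
  if (!identical(assignment$rank, "species")) return("inconclusive")
  origins <- unique(resolve_to_primary(mono[[hit[1]]]$origins, library))
  assigned <- resolve_to_primary(assignment$name, library)
  if (assigned %in% origins) "matched" else "mismatched"
}
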