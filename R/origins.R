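# Pharmacopeia origin comparison: for each herbal drug of one pharmacopeia
# (e.g. the Korean), classify how its prescribed origin species relate to
# another pharmacopeia's monographs (e.g. the Chinese).

ORIGIN_CATEGORIES <- c("absence", "identical", "alternation", "expansion",
                       "contraction", "repartition")

#' Construct a drug monograph record
#'
#' @param drug_name Monograph (drug) name.
#' @param origins Character vector of origin species names.
#' @param pharmacopeia `"KP"` or `"ChP"`.
#' @param medicinal_part Free text.
#' @return A list of class `drug_monograph`.
#' @export
drug_monograph <- function(drug_name, origins, pharmacopeia = "KP",
                           medicinal_part = "") {
  if (length(origins) == 0 || all(!nzchar(origins)))
    stop("monograph origin set is empty")
  structure(list(drug_name = drug_name, pharmacopeia = pharmacopeia,
                 origins = origins, medicinal_part = medicinal_part),
            class = "drug_monograph")
}

# coerce a monographs data.frame (packed origins) to a list of monographs
monograph_list <- function(x) {
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i)
      drug_monograph(x$drug_name[i], split_multi(x$origins[i])[[1]],
                     pharmacopeia = if ("pharmacopeia" %in% names(x))
                       x$pharmacopeia[i] else "",
                     medicinal_part = if ("medicinal_part" %in% names(x))
                       x$medicinal_part[i] else ""))
  } else if (inherits(x, "drug_monograph")) list(x) else x
}

#' Classify the origin difference of one drug between two pharmacopeias
#'
#' Compares the origin species set of a (Korean pharmacopeia) drug
#' monograph against a second pharmacopeia's monograph index.  All origin
#' names are first collapsed to primary names through the library taxonomy
#' (so synonym substitutions never change the category).  Categories, in
#' precedence order:
#'
#' 1. *absence* — no monograph of the other pharmacopeia matches by drug
#'    name and no origin of this drug appears in any of its monographs;
#' 2. *repartition* — some origin of this drug is prescribed by a
#'    *different* drug of the other pharmacopeia than the name-matched one
#'    (its origins are split across that pharmacopeia's monographs);
#' 3. set relations against the name-matched monograph: equal sets →
#'    *identical*; strict superset → *expansion*; strict subset →
#'    *contraction*; anything else → *alternation*.
#'
#' @param kp_drug A `drug_monograph` (or one-row monograph data frame).
#' @param chp_index List of `drug_monograph`s (or monograph data frame) of
#'   the other pharmacopeia.
#' @param library Optional `herb_library` used for synonym resolution;
#'   without it, names are only normalized.
#' @return One of `"absence"`, `"identical"`, `"alternation"`,
#'   `"expansion"`, `"contraction"`, `"repartition"`.
#' @export
classify_origin_difference <- function(kp_drug, chp_index, library = NULL) {
  kp_drug <- monograph_list(kp_drug)[[1]]
  chp_index <- monograph_list(chp_index)
  if (length(kp_drug$origins) == 0) stop("monograph origin set is empty")
  kp_set <- unique(resolve_to_primary(kp_drug$origins, library))
  chp_sets <- lapply(chp_index, function(m)
    unique(resolve_to_primary(m$origins, library)))
  chp_names <- normalize_name(vapply(chp_index, `[[`, "", "drug_name"))

  name_hit <- which(chp_names == normalize_name(kp_drug$drug_name))
  origin_hits <- which(vapply(chp_sets, function(s)
    any(kp_set %in% s), logical(1)))

  if (length(name_hit) == 0 && length(origin_hits) == 0)
    return("absence")
  if (length(setdiff(origin_hits, name_hit)) > 0)
    return("repartition")
  chp_set <- chp_sets[[name_hit[1]]]
  if (setequal(kp_set, chp_set)) return("identical")
  if (all(chp_set %in% kp_set)) return("expansion")
  if (all(kp_set %in% chp_set)) return("contraction")
  "alternation"
}

#' Classify every drug of one pharmacopeia against another
#'
#' @param kp_monographs,chp_monographs Monograph data frames (or lists of
#'   `drug_monograph`s).
#' @param library Optional `herb_library` for synonym resolution.
#' @return Data frame with columns `drug_name`, `category`.
#' @export
compare_pharmacopeias <- function(kp_monographs, chp_monographs,
                                  library = NULL) {
  kp <- monograph_list(kp_monographs)
  chp <- monograph_list(chp_monographs)
  data.frame(
    drug_name = vapply(kp, `[[`, "", "drug_name"),
    category = vapply(kp, classify_origin_difference, "", chp, library),
    stringsAsFactors = FALSE)
}
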