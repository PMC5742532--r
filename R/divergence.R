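# Barcode-gap analytics: per-species divergence distributions and the six
# global parameters (average inter-specific distance, theta prime, average
# minimum inter-specific distance, average intraspecific distance, theta,
# average coalescent depth).
#
# Definitions (distances are pairwise K2P, pairwise deletion):
#   per species S:  avg_intra  = mean d over pairs within S
#                   coalescent_depth = max d over pairs within S
#                   avg_inter  = mean d from S's sequences to sequences of
#                                other (congeneric) species of S's genus
#                   min_inter  = min of those distances
#   summary:  (i)   mean/sd over species of avg_inter
#             (ii)  theta' = mean/sd over multi-species genera of the
#                   genus's mean inter-specific distance
#             (iii) mean/sd over species of min_inter
#             (iv)  mean/sd over ALL intraspecific pairs pooled
#             (v)   theta = mean/sd over multi-sequence species of avg_intra
#             (vi)  mean/sd over multi-sequence species of coalescent_depth
# (iv) pools pairs while (v) averages per-species means: with unbalanced
# sampling the two differ, which is why both are reported.

# Collect within-genus pairwise K2P distances for a single-marker database.
# Returns list(pairs = data.frame(genus, sp_i, sp_j, d), n_saturated).
genus_pairwise <- function(db, aligned = FALSE) {
  stopifnot(inherits(db, "barcode_db"))
  entries <- db$entries
  if (length(unique(entries$marker)) > 1)
    stop("divergence analytics need a single-marker database; ",
         "filter with compile_database(marker = ...)")
  entries$genus <- genus_of(entries$species_name)
  rows <- list()
  n_sat <- 0L
  for (g in unique(entries$genus)) {
    e <- entries[entries$genus == g, , drop = FALSE]
    if (nrow(e) < 2) next
    dm <- suppressWarnings(
      build_distance_matrix(setNames(e$seq, e$sequence_id),
                            aligned = aligned))
    for (i in seq_len(nrow(e) - 1)) {
      for (j in seq(i + 1, nrow(e))) {
        d <- dm[i, j]
        if (!is.finite(d)) { n_sat <- n_sat + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          genus = g, sp_i = e$species_name[i], sp_j = e$species_name[j],
          d = d, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genus = character(0), sp_i = character(0),
               sp_j = character(0), d = numeric(0))
  if (n_sat > 0)
    warning(sprintf("%d saturated pair(s) excluded from divergence analytics",
                    n_sat))
  list(pairs = pairs, n_saturated = n_sat,
       species = unique(entries$species_name),
       n_seqs = table(entries$species_name),
       genus_map = setNames(entries$genus, entries$species_name))
}

#' Per-species divergence table of a barcode database
#'
#' For every species in a single-marker database: the number of sequences,
#' mean and maximum (coalescent depth) within-species K2P distance, and
#' mean and minimum distance to congeneric species' sequences.  Fields
#' whose inputs are insufficient (singleton species; no congener in the
#' database) are `NA`, not zero.  Saturated pairs are excluded with a
#' warning.
#'
#' @param db A single-marker `barcode_db`.
#' @param aligned Treat database sequences as already aligned equal-length
#'   rows (skips re-alignment; used for simulated no-indel libraries).
#' @return Data frame with columns `species`, `genus`, `n_sequences`,
#'   `avg_intra`, `coalescent_depth`, `avg_inter`, `min_inter`.
#' @export
per_species_divergence <- function(db, aligned = FALSE) {
  per_species_divergence_from(genus_pairwise(db, aligned = aligned))
}

msd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  c(mean = if (n) mean(x) else NA_real_,
    sd = if (n == 0) NA_real_ else if (n == 1) 0 else sd(x),
    n = n)
}

#' Six-parameter divergence summary of a barcode database
#'
#' Computes the six barcode-gap parameters (see the file-level definitions
#' above) from a single-marker database: average inter-specific distance,
#' theta prime, average minimum inter-specific distance, average (pooled)
#' intraspecific distance, theta, and average coalescent depth; each as
#' mean, sd and the number of contributing species/genera/pairs.
#'
#' @inheritParams per_species_divergence
#' @return Object of class `divergence_summary`: list with `marker`,
#'   `per_species` (the [per_species_divergence()] table), `n_saturated`,
#'   and the six named `c(mean, sd, n)` vectors `avg_inter`, `theta_prime`,
#'   `avg_min_inter`, `avg_intra_pooled`, `theta`, `avg_coalescent_depth`.
#' @export
summarize_divergence <- function(db, aligned = FALSE) {
  gp <- genus_pairwise(db, aligned = aligned)
  pairs <- gp$pairs
  per <- per_species_divergence_from(gp)
  intra_pool <- pairs$d[pairs$sp_i == pairs$sp_j]
  inter <- pairs[pairs$sp_i != pairs$sp_j, , drop = FALSE]
  genus_means <- if (nrow(inter)) tapply(inter$d, inter$genus, mean) else
    numeric(0)
  structure(list(
    marker = unique(c(db$entries$marker, NA_character_))[1],
    per_species = per,
    n_saturated = gp$n_saturated,
    avg_inter = msd(per$avg_inter),
    theta_prime = msd(as.numeric(genus_means)),
    avg_min_inter = msd(per$min_inter),
    avg_intra_pooled = msd(intra_pool),
    theta = msd(per$avg_intra[per$n_sequences >= 2]),
    avg_coalescent_depth = msd(per$coalescent_depth[per$n_sequences >= 2])),
    class = "divergence_summary")
}

# shared core so summarize_divergence aligns each pair exactly once
per_species_divergence_from <- function(gp) {
  pairs <- gp$pairs
  res <- lapply(gp$species, function(sp) {
    n <- as.integer(gp$n_seqs[[sp]])
    intra <- pairs$d[pairs$sp_i == sp & pairs$sp_j == sp]
    involves <- xor(pairs$sp_i == sp, pairs$sp_j == sp)
    inter <- pairs$d[involves]
    data.frame(
      species = sp, genus = unname(gp$genus_map[sp]), n_sequences = n,
      avg_intra = if (length(intra)) mean(intra) else NA_real_,
      coalescent_depth = if (length(intra)) max(intra) else NA_real_,
      avg_inter = if (length(inter)) mean(inter) else NA_real_,
      min_inter = if (length(inter)) min(inter) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Divergence summary [%s marker]\n", x$marker))
  show <- function(lab, v)
    cat(sprintf("  %-26s %s\n", lab,
                if (is.na(v[["mean"]])) "absent (insufficient data)"
                else sprintf("%.4f +/- %.4f  (n = %d)", v[["mean"]],
                             v[["sd"]], as.integer(v[["n"]]))))
  show("avg inter-specific", x$avg_inter)
  show("theta prime", x$theta_prime)
  show("avg minimum inter-specific", x$avg_min_inter)
  show("avg intraspecific (pooled)", x$avg_intra_pooled)
  show("theta", x$theta)
  show("avg coalescent depth", x$avg_coalescent_depth)
  if (x$n_saturated > 0)
    cat(sprintf("  (%d saturated pair(s) excluded)\n", x$n_saturated))
  invisible(x)
}
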