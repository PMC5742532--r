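# Seeded simulator of reference libraries and market-sample query sets
# with known truth.  It emulates the sampling design of a pharmacopeia
# barcode library - a few hundred species, several specimens per species,
# drug monographs prescribing origin species - with a K2P-type per-site
# substitution process, so the package's K2P estimator is the matched
# estimator and rate recovery is a meaningful end-to-end check.

#' Simulation configuration
#'
#' Defaults describe a gap-separated library: 20 genera of 3 species with
#' 4 specimens each, per-site interspecific divergence 0.05 from the genus
#' root and intraspecific divergence 0.005 from the species consensus,
#' transition/transversion ratio kappa = 2.  ITS2-like cores are 230 bp,
#' psbA-trnH-like cores 300 bp; reads are wrapped in the marker's flank
#' consensi so core-region trimming is exercised.
#'
#' @param n_genera,species_per_genus,specimens_per_species Library shape.
#' @param seq_length Named core lengths per marker (bp).
#' @param inter_rate Per-site substitution probability species-vs-genus
#'   root (in `[0, 0.3]`).
#' @param intra_rate Per-site substitution probability specimen-vs-species
#'   consensus (in `[0, 0.3]`).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param indel_rate Per-site indel probability (default 0).
#' @param markers Markers to emit per specimen.
#' @param inversion Optional list `list(motif=, prob=, length=)`: the motif
#'   is planted in every genus root of psbA-trnH-like sequences and, with
#'   the given probability per specimen, the window of `length` bp starting
#'   at the motif is reverse-complemented (default length 24).
#' @param public_fraction Fraction of specimens whose sequences are marked
#'   `source = "public"` (the rest are `"study"`).
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genera = 20L, species_per_genus = 3L,
                       specimens_per_species = 4L,
                       seq_length = c("ITS2" = 230L, "psbA-trnH" = 300L),
                       inter_rate = 0.05, intra_rate = 0.005, kappa = 2,
                       indel_rate = 0, markers = "ITS2",
                       inversion = NULL, public_fraction = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_genera >= 1, species_per_genus >= 1,
            specimens_per_species >= 1,
            inter_rate >= 0, inter_rate <= 0.3,
            intra_rate >= 0, intra_rate <= 0.3,
            indel_rate >= 0, indel_rate <= 0.3,
            all(markers %in% names(seq_length)))
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n) paste(sample(UNAMBIGUOUS, n, replace = TRUE),
                                collapse = "")

#' Mutate a sequence under a K2P-type substitution process
#'
#' Each site is independently substituted with probability `rate`; a
#' substitution is a transition with odds `kappa` : 1 against each of the
#' two transversion targets.  Indels (insertion or deletion of one base,
#' equal odds) occur independently at `indel_rate`.  Uses the current RNG
#' state; seed the caller (e.g. via the simulator entry points).
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param rate Substitution probability per site (in `[0, 0.3]`).
#' @param kappa Transition/transversion rate ratio.
#' @param indel_rate Indel probability per site.
#' @return Mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, kappa = 2, indel_rate = 0) {
  stopifnot(rate >= 0, rate <= 0.3)
  chars <- seq_chars(seq)
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) > 0) {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
    for (i in seq_along(hit)) {
      b <- chars[hit[i]]
      chars[hit[i]] <- if (is_ts[i]) transition[[b]] else
        sample(transversions[[b]], 1L)
    }
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_len(length(chars))) {
      ev <- stats::runif(1)
      if (ev < indel_rate / 2) next                      # deletion
      out <- c(out, chars[i])
      if (ev >= indel_rate / 2 && ev < indel_rate)       # insertion
        out <- c(out, sample(UNAMBIGUOUS, 1L))
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

plant_motif <- function(seq, motif, pos) {
  paste0(substr(seq, 1, pos - 1), motif,
         substr(seq, pos + nchar(motif), nchar(seq)))
}

#' Simulate a reference library with known truth
#'
#' Genus root cores are drawn uniformly over A/C/G/T; each species
#' consensus is the root mutated at `inter_rate`; each specimen sequence is
#' its species consensus mutated at `intra_rate`; reads are wrapped in the
#' marker flank consensi (recorded as the true core span).  Drug monographs
#' are emitted one per genus, prescribing all but the genus's last species
#' as official origins, so the remaining species acts as a potential
#' adulterant.  Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_library` with elements `library`
#'   (a `herb_library`), `truth` (per-sequence data frame: species, genus,
#'   true core span, inversion flag), `consensus` (per marker, named list
#'   species -> core consensus), `roots` (per marker, genus root cores) and
#'   `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  profiles <- marker_profiles()
  with_seed(config$seed, {
    tax <- list(); spec <- list(); seqr <- list(); fasta <- character(0)
    truth <- list(); consensus <- list(); roots <- list(); monos <- list()
    tax[[1]] <- data.frame(taxon_id = "T_ROOT", primary_name = "Plantae",
                           authority = "", rank = "family", parent_id = "",
                           synonyms = "", stringsAsFactors = FALSE)
    seq_counter <- 0L
    for (g in seq_len(config$n_genera)) {
      genus_name <- sprintf("Genus%03d", g)
      genus_id <- sprintf("T_G%03d", g)
      tax[[length(tax) + 1L]] <- data.frame(
        taxon_id = genus_id, primary_name = genus_name, authority = "",
        rank = "genus", parent_id = "T_ROOT", synonyms = "",
        stringsAsFactors = FALSE)
      for (mk in config$markers) {
        root <- random_seq(config$seq_length[[mk]])
        if (!is.null(config$inversion) && mk == "psbA-trnH")
          root <- plant_motif(root, config$inversion$motif, 31L)
        roots[[mk]][[genus_name]] <- root
      }
      species_names <- sprintf("%s species%02d", genus_name,
                               seq_len(config$species_per_genus))
      for (s in seq_len(config$species_per_genus)) {
        sp_name <- species_names[s]
        sp_id <- sprintf("T_G%03dS%02d", g, s)
        tax[[length(tax) + 1L]] <- data.frame(
          taxon_id = sp_id, primary_name = sp_name, authority = "",
          rank = "species", parent_id = genus_id, synonyms = "",
          stringsAsFactors = FALSE)
        for (mk in config$markers)
          consensus[[mk]][[sp_name]] <-
            mutate_sequence(roots[[mk]][[genus_name]], config$inter_rate,
                            config$kappa)
        for (k in seq_len(config$specimens_per_species)) {
          spec_id <- sprintf("SP_G%03dS%02dN%02d", g, s, k)
          spec[[length(spec) + 1L]] <- data.frame(
            specimen_id = spec_id, taxon_id = sp_id,
            material_kind = if (k %% 2 == 1) "leaf" else "medicinal_material",
            drug_name = "", locality = "simulated", voucher = spec_id,
            stringsAsFactors = FALSE)
          src <- if (stats::runif(1) < config$public_fraction) "public"
                 else "study"
          for (mk in config$markers) {
            seq_counter <- seq_counter + 1L
            seq_id <- sprintf("SEQ%05d", seq_counter)
            core <- mutate_sequence(consensus[[mk]][[sp_name]],
                                    config$intra_rate, config$kappa,
                                    config$indel_rate)
            inverted <- FALSE
            if (!is.null(config$inversion) && mk == "psbA-trnH" &&
                stats::runif(1) < config$inversion$prob) {
              len <- if (is.null(config$inversion$length)) 24L
                     else config$inversion$length
              seg <- substr(core, 31L, 30L + len)
              core <- paste0(substr(core, 1, 30L), revcomp(seg),
                             substr(core, 31L + len, nchar(core)))
              inverted <- TRUE
            }
            fl <- profiles[[mk]]$flank_left
            fr <- profiles[[mk]]$flank_right
            read <- paste0(fl, core, fr)
            fasta[[seq_id]] <- read
            seqr[[length(seqr) + 1L]] <- data.frame(
              sequence_id = seq_id, specimen_id = spec_id, taxon_id = sp_id,
              marker = mk, source = src, reference_id = "",
              core_start = as.character(nchar(fl) + 1L),
              core_end = as.character(nchar(fl) + nchar(core)),
              stringsAsFactors = FALSE)
            truth[[length(truth) + 1L]] <- data.frame(
              sequence_id = seq_id, species = sp_name, genus = genus_name,
              marker = mk, source = src,
              core_start = nchar(fl) + 1L,
              core_end = nchar(fl) + nchar(core),
              inverted = inverted, stringsAsFactors = FALSE)
          }
        }
      }
      monos[[length(monos) + 1L]] <- data.frame(
        drug_name = sprintf("%s Drug", genus_name), pharmacopeia = "KP",
        origins = paste(head(species_names,
                             max(1L, length(species_names) - 1L)),
                        collapse = ";"),
        medicinal_part = "root", stringsAsFactors = FALSE)
    }
    lib <- herb_library(do.call(rbind, tax), do.call(rbind, spec),
                        do.call(rbind, seqr), unlist(fasta),
                        monographs = do.call(rbind, monos))
    structure(list(library = lib, truth = do.call(rbind, truth),
                   consensus = consensus, roots = roots, config = config),
              class = "sim_library")
  })
}

#' Simulate a market-sample query set with truth
#'
#' Draws `n_queries` reads from the simulated species consensi (specimen
#' process: consensus mutated at `intra_rate`, wrapped in flanks), with an
#' optional defect per query: `"none"`, `"short"` (truncated below the QC
#' length floor), `"ambiguous"` (>1% N characters), `"revcomp"` (whole
#' read reverse-complemented), `"inversion"` (a 24 bp core window
#' reverse-complemented), `"adulterant"` (drawn from a species outside its
#' genus-drug's official origins, labelled with that drug).
#'
#' @param sim A `sim_library` from [simulate_library()].
#' @param n_queries Number of queries.
#' @param marker Marker to draw from.
#' @param defects Either a single defect name applied to all queries or a
#'   character vector of length `n_queries`.
#' @param intra_rate Per-site divergence of a query from its species
#'   consensus (defaults to the library's `intra_rate`).
#' @param seed RNG seed.
#' @return List with `queries` (named character vector of reads) and
#'   `truth` (data frame: query_id, species, genus, marker, defect,
#'   drug_name - the label a market sample would carry, i.e. its genus's
#'   drug).
#' @export
simulate_queries <- function(sim, n_queries, marker = "ITS2",
                             defects = "none",
                             intra_rate = sim$config$intra_rate, seed) {
  stopifnot(inherits(sim, "sim_library"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (length(defects) == 1L) defects <- rep(defects, n_queries)
  stopifnot(length(defects) == n_queries)
  profiles <- marker_profiles()
  fl <- profiles[[marker]]$flank_left
  fr <- profiles[[marker]]$flank_right
  cons <- sim$consensus[[marker]]
  species <- names(cons)
  mono <- sim$library$monographs
  origin_sets <- lapply(split_multi(mono$origins), identity)
  with_seed(seed, {
    queries <- character(0); rows <- list()
    for (i in seq_len(n_queries)) {
      defect <- defects[i]
      if (defect == "adulterant") {
        # species outside its genus drug's origins (the genus's last species)
        genus_pick <- sample(unique(genus_of(species)), 1L)
        in_genus <- species[genus_of(species) == genus_pick]
        sp <- in_genus[length(in_genus)]
      } else {
        sp <- sample(species, 1L)
      }
      genus <- genus_of(sp)
      drug <- mono$drug_name[grepl(paste0("^", genus, " "), mono$drug_name)][1]
      core <- mutate_sequence(cons[[sp]], intra_rate, sim$config$kappa)
      if (defect == "inversion") {
        seg <- substr(core, 31L, 54L)
        core <- paste0(substr(core, 1, 30L), revcomp(seg),
                       substr(core, 55L, nchar(core)))
      }
      read <- paste0(fl, core, fr)
      if (defect == "short")
        read <- substr(read, 1, MARKER_MIN_LENGTH[[marker]] - 30L)
      if (defect == "ambiguous") {
        n_amb <- ceiling(0.02 * nchar(read))
        pos <- sample(nchar(read), n_amb)
        ch <- seq_chars(read); ch[pos] <- "N"
        read <- paste(ch, collapse = "")
      }
      if (defect == "revcomp") read <- revcomp(read)
      qid <- sprintf("Q%04d", i)
      queries[[qid]] <- read
      rows[[i]] <- data.frame(query_id = qid, species = sp, genus = genus,
                              marker = marker, defect = defect,
                              drug_name = drug, stringsAsFactors = FALSE)
    }
    list(queries = unlist(queries), truth = do.call(rbind, rows))
  })
}
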