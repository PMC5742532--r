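# Record model: loading, cross-linking, name resolution, validation,
# database compilation, counts, pharmacopeia comparison.

test_that("library round-trips through the TSV+FASTA layout", {
  dir <- write_toy_library()
  lib <- read_library(dir)
  s <- library_stats(lib)
  expect_equal(s$n_taxonomy, 5)
  expect_equal(s$n_specimens, 2)
  expect_equal(s$n_sequences, 2)
  expect_equal(s$n_references, 0)   # optional table absent -> valid, empty
  expect_equal(as.integer(s$sequences_per_marker[c("ITS2", "psbA-trnH")]),
               c(1L, 1L))
  # core span materialized from the raw sequence
  expect_equal(lib$sequences$core_seq[1],
               substr(lib$sequences$raw_seq[1], 3, 18))
  expect_equal(lib$sequences$core_seq[2], "")
})

test_that("structural load errors name the offending record and field", {
  dir <- write_toy_library()
  # FASTA record whose id is absent from the sequence table
  cat(">GHOST\nACGT\n", file = file.path(dir, "sequences.fasta"),
      append = TRUE)
  expect_error(read_library(dir), "GHOST")
  dir2 <- write_toy_library()
  tx <- file.path(dir2, "specimens.tsv")
  tab <- read.delim(tx, colClasses = "character")
  tab$taxon_id[1] <- "NO_SUCH"
  write.table(tab, tx, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_library(dir2), "NO_SUCH")
  dir3 <- write_toy_library()
  tab <- read.delim(file.path(dir3, "taxonomy.tsv"),
                    colClasses = "character")
  tab$rank <- NULL
  write.table(tab, file.path(dir3, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_library(dir3), "rank")
})

test_that("resolve_name matches primaries and synonyms, reporting source", {
  lib <- toy_library()
  r <- resolve_name("Tetradium ruticarpum", lib)
  expect_true(r$found)
  expect_equal(r$primary_name, "Evodia rutaecarpa")
  expect_equal(r$matched_via, "synonym")
  expect_equal(r$synonym_source, "FloraOfChina")
  # exact primary, case/whitespace-insensitive
  r2 <- resolve_name("  evodia   RUTAECARPA ", lib)
  expect_equal(r2$matched_via, "primary")
  expect_equal(r2$taxon_id, "T1")
  # authority strings are stripped token by token
  r3 <- resolve_name("Rubus coreanus Miq.", lib)
  expect_true(r3$found)
  expect_equal(r3$primary_name, "Rubus coreanus")
  expect_false(resolve_name("Nonexistens plantarum", lib)$found)
})

test_that("resolve_name is idempotent on returned primary names", {
  lib <- toy_library()
  for (nm in c("Tetradium ruticarpum", "Rubus crataegifolius")) {
    r <- resolve_name(nm, lib)
    r2 <- resolve_name(r$primary_name, lib)
    expect_equal(r2$taxon_id, r$taxon_id)
    expect_equal(r2$matched_via, "primary")
  }
})

test_that("a synonym claimed by two taxa is an ambiguity error", {
  lib <- toy_library()
  lib$taxonomy$synonyms[2] <- "Tetradium ruticarpum::ChP"
  expect_error(resolve_name("Tetradium ruticarpum", lib), "ambiguous")
})

test_that("validate_library reports exactly the injected violation class", {
  lib <- toy_library()
  expect_equal(nrow(validate_library(lib)), 0)

  # specimen without companion sequence
  lib1 <- toy_library()
  lib1$specimens <- rbind(lib1$specimens,
                          data.frame(specimen_id = "S3", taxon_id = "T3",
                                     material_kind = "leaf", drug_name = "",
                                     locality = "", voucher = ""))
  v1 <- validate_library(lib1)
  expect_equal(v1$class, "specimen_without_sequence")
  expect_equal(v1$record_id, "S3")

  # sequence mapped to genus-rank taxon
  lib2 <- toy_library()
  lib2$sequences$taxon_id[1] <- "G1"
  v2 <- validate_library(lib2)
  expect_equal(v2$class, "above_species_level")
  expect_equal(v2$record_id, "Q1")

  # alphabet violation
  lib3 <- toy_library()
  lib3$sequences$raw_seq[2] <- "ACGTXXACGT"
  v3 <- validate_library(lib3)
  expect_equal(v3$class, "invalid_alphabet")

  # duplicate id
  lib4 <- toy_library()
  lib4$taxonomy <- rbind(lib4$taxonomy, lib4$taxonomy[1, ])
  v4 <- validate_library(lib4)
  expect_true("duplicate_id" %in% v4$class)
})

test_that("database tiers partition by record source", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 3, public_fraction = 0.5,
                    seed = 11)
  sim <- simulate_library(cfg)
  sbd <- compile_database(sim$library, "SBD")
  pbd <- compile_database(sim$library, "PBD")
  abd <- compile_database(sim$library, "ABD")
  expect_equal(sbd$tier, "SBD")
  expect_equal(nrow(sbd$entries), sum(sim$truth$source == "study"))
  expect_equal(nrow(pbd$entries), sum(sim$truth$source == "public"))
  # partition property: disjoint sources, |SBD| + |PBD| = |ABD|
  expect_equal(nrow(sbd$entries) + nrow(pbd$entries), nrow(abd$entries))
  # set-union semantics by sequence_id
  expect_setequal(abd$entries$sequence_id,
                  union(sbd$entries$sequence_id, pbd$entries$sequence_id))
  # entries prefer the annotated core over the raw read
  i <- match(sbd$entries$sequence_id[1], sim$library$sequences$sequence_id)
  expect_equal(sbd$entries$seq[1], sim$library$sequences$core_seq[i])
  # species labels are primary names
  expect_true(all(grepl("^Genus\\d+ species\\d+$", abd$entries$species_name)))
})

test_that("an empty tier selection errors rather than returning nothing", {
  cfg <- sim_config(n_genera = 1, species_per_genus = 2,
                    specimens_per_species = 2, public_fraction = 0, seed = 5)
  sim <- simulate_library(cfg)
  expect_error(compile_database(sim$library, "PBD"), "empty database tier")
})

test_that("self-defined databases load from FASTA with an optional map", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(a = "ACGTACGTACGT", b = "TTTTAAAACCCC", c = "GGGGTTTTAAAA"),
              fa)
  db <- sdd_database(fa)
  expect_equal(db$tier, "SDD")
  expect_equal(nrow(db$entries), 3)
  db2 <- resolve_database_arg(paste0("selfDefinded:", fa))
  expect_equal(db2$entries$sequence_id, db$entries$sequence_id)
  map <- data.frame(sequence_id = "a", species_name = "Panax ginseng")
  db3 <- sdd_database(fa, map)
  expect_equal(db3$entries$species_name[1], "Panax ginseng")
})

test_that("library_stats matches generator bookkeeping", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 2, seed = 42)
  sim <- simulate_library(cfg)
  s <- library_stats(sim$library)
  expect_equal(s$n_sequences, 8)
  expect_equal(s$n_specimens, 8)
  expect_equal(s$n_taxonomy, 1 + 2 + 4)  # root + genera + species
  expect_equal(unname(s$species_per_tier["SBD"]), 4L)
})
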