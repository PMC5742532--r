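# Assignment policy, label matching, the identify pipeline and report
# serialization.

test_that("assignment rules follow the policy thresholds", {
  mk_hits <- function(ids, species, identity)
    data.frame(rank = seq_along(ids), sequence_id = ids,
               species_name = species, marker = "ITS2",
               identity = identity, coverage = 1,
               score = 200 * identity, orientation = "+",
               stringsAsFactors = FALSE)
  # clear species call
  a <- assign_taxon(mk_hits(c("h1", "h2"),
                            c("Aconitum carmichaelii", "Aconitum kusnezoffii"),
                            c(1.00, 0.96)))
  expect_equal(a$rank, "species")
  expect_equal(a$name, "Aconitum carmichaelii")
  # two congeneric species inside the tie margin: genus call
  b <- assign_taxon(mk_hits(c("h1", "h2"),
                            c("Aconitum carmichaelii", "Aconitum kusnezoffii"),
                            c(0.995, 0.994)))
  expect_equal(b$rank, "genus")
  expect_equal(b$name, "Aconitum")
  # below the genus floor: unidentified
  c_ <- assign_taxon(mk_hits("h1", "Aconitum carmichaelii", 0.90))
  expect_equal(c_$rank, "unidentified")
  # between floors: genus fallback
  d <- assign_taxon(mk_hits("h1", "Aconitum carmichaelii", 0.96))
  expect_equal(d$rank, "genus")
  expect_equal(d$name, "Aconitum")
  # short perfect local matches carry no weight
  h <- mk_hits(c("h1", "h2"),
               c("Aconitum carmichaelii", "Panax ginseng"),
               c(0.995, 1.0))
  h$coverage[2] <- 0.05
  e <- assign_taxon(h)
  expect_equal(e$rank, "species")
  expect_equal(e$name, "Aconitum carmichaelii")
})

test_that("label matching distinguishes matched/mismatched/inconclusive", {
  monos <- list(
    drug_monograph("Achyranthes Root", c("Achyranthes bidentata",
                                         "Achyranthes japonica")),
    drug_monograph("Rubus Fruit", "Rubus coreanus"))
  sp <- function(name) list(rank = "species", name = name, identity = 1,
                            basis = "")
  expect_equal(match_label(sp("Achyranthes bidentata"), "Achyranthes Root",
                           monos), "matched")
  # market sample identified as a congener of the official origin
  expect_equal(match_label(sp("Rubus crataegifolius"), "Rubus Fruit",
                           monos), "mismatched")
  genus_call <- list(rank = "genus", name = "Rubus", identity = 0.96,
                     basis = "")
  expect_equal(match_label(genus_call, "Rubus Fruit", monos), "inconclusive")
  expect_error(match_label(sp("Panax ginseng"), "No Such Drug", monos),
               "unknown drug")
})

test_that("label matching resolves synonyms before comparing", {
  lib <- toy_library()
  monos <- list(drug_monograph("Evodia Fruit", "Evodia rutaecarpa"))
  syn <- list(rank = "species", name = "Tetradium ruticarpum",
              identity = 1, basis = "")
  expect_equal(match_label(syn, "Evodia Fruit", monos, lib), "matched")
})

test_that("identify assigns simulated market samples to their species", {
  cfg <- sim_config(n_genera = 4, species_per_genus = 2,
                    specimens_per_species = 3, seed = 71)
  sim <- simulate_library(cfg)
  db <- compile_database(sim$library, "SBD")
  qs <- simulate_queries(sim, 6, seed = 72)
  for (i in seq_len(6)) {
    rep <- identify_query(qs$queries[i], db, build_tree = (i == 1))
    expect_equal(rep$assignment$rank, "species")
    expect_equal(rep$assignment$name, qs$truth$species[i])
    expect_equal(rep$marker, "ITS2")
    if (i == 1) {
      # the tree panel contains the query leaf plus all hits
      tr <- ape::read.tree(text = rep$tree)
      expect_true(paste0("query|", qs$truth$query_id[1]) %in% tr$tip.label)
      expect_setequal(setdiff(tr$tip.label,
                              paste0("query|", qs$truth$query_id[1])),
                      rep$hits$sequence_id)
    }
  }
})

test_that("QC failure short-circuits before any search or tree work", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 2, seed = 73)
  sim <- simulate_library(cfg)
  db <- compile_database(sim$library, "SBD")
  rep <- identify_query(c(short = random_acgt(149)), db, marker = "ITS2")
  expect_false(rep$qc$passed)
  expect_equal(rep$assignment$rank, "unidentified")
  expect_false(any(c("search", "tree", "assign") %in% rep$stages))
  expect_null(rep$hits)
})

test_that("a congener-only database yields a genus-level call", {
  set.seed(74)
  consensus_a <- random_acgt(230)              # the true species (absent)
  # congener: exactly 9 interior transitions -> identity 221/230 = 0.9609,
  # inside the genus band [0.95, 0.97)
  ch <- strsplit(consensus_a, "")[[1]]
  flip <- c(A = "G", G = "A", C = "T", T = "C")
  at <- seq(20, 220, by = 25)
  ch[at] <- flip[ch[at]]
  consensus_b <- paste(ch, collapse = "")
  db <- sdd_database(c(b1 = consensus_b, b2 = consensus_b),
                     data.frame(sequence_id = c("b1", "b2"),
                                species_name = "Genx speciesB"))
  q <- wrap_read(consensus_a, "ITS2")
  rep <- identify_query(c(q1 = q), db, marker = "ITS2", build_tree = FALSE)
  expect_equal(rep$assignment$rank, "genus")
  expect_equal(rep$assignment$name, "Genx")
})

test_that("reports round-trip losslessly through JSON", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 2, seed = 75)
  sim <- simulate_library(cfg)
  db <- compile_database(sim$library, "SBD")
  qs <- simulate_queries(sim, 1, seed = 76)
  rep <- identify_query(qs$queries[1], db)
  js <- render_report(rep, "json")
  rep2 <- parse_report_json(js)
  expect_identical(render_report(rep2, "json"), js)
  # text contains the full hit table; html wraps the text
  txt <- render_report(rep, "text")
  for (id in rep$hits$sequence_id) expect_match(txt, id, fixed = TRUE)
  expect_match(render_report(rep, "html"), "<html>", fixed = TRUE)
  # newick in the report loads in an independent reader with the leaf set
  tr <- ape::read.tree(text = rep$tree)
  expect_equal(sort(tr$tip.label),
               sort(c(paste0("query|", qs$truth$query_id[1]),
                      rep$hits$sequence_id)))
})

test_that("identical inputs produce byte-identical JSON reports", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 2, seed = 77)
  sim <- simulate_library(cfg)
  db <- compile_database(sim$library, "SBD")
  qs <- simulate_queries(sim, 1, seed = 78)
  r1 <- render_report(identify_query(qs$queries[1], db), "json")
  r2 <- render_report(identify_query(qs$queries[1], db), "json")
  expect_identical(r1, r2)
})

test_that("the CLI identifies a query end to end", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = 2, seed = 79)
  sim <- simulate_library(cfg)
  libdir <- tempfile("cli-lib")
  write_library(sim$library, libdir)
  qs <- simulate_queries(sim, 1, seed = 80)
  qfile <- tempfile(fileext = ".fasta")
  write_fasta(qs$queries, qfile)
  out <- tempfile(fileext = ".json")
  cli_main(c("identify", "-q", qfile, "-d", "SBD", "--library", libdir,
             "--format", "json", "--out", out))
  parsed <- parse_report_json(readLines(out, warn = FALSE))
  expect_equal(parsed$assignment$rank, "species")
  expect_equal(parsed$assignment$name, qs$truth$species[1])
})
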