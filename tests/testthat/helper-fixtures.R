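# In-code fixtures shared across test files.

# A small hand-built library: 3 genera incl. the Evodia/Tetradium synonym
# case, 2 specimens with sequences, 1 specimen deliberately linked.
toy_library <- function() {
  taxonomy <- data.frame(
    taxon_id = c("T1", "T2", "T3", "G1", "R"),
    primary_name = c("Evodia rutaecarpa", "Rubus coreanus",
                     "Rubus crataegifolius", "Rubus", "Rosaceae"),
    authority = c("(Juss.) Benth.", "Miq.", "Bunge", "", ""),
    rank = c("species", "species", "species", "genus", "family"),
    parent_id = c("R", "G1", "G1", "R", ""),
    synonyms = c("Tetradium ruticarpum::FloraOfChina;Tetradium ruticarpum::NCBI",
                 "", "", "", ""),
    stringsAsFactors = FALSE)
  specimens <- data.frame(
    specimen_id = c("S1", "S2"),
    taxon_id = c("T1", "T2"),
    material_kind = c("leaf", "medicinal_material"),
    drug_name = c("Evodia Fruit", "Rubus Fruit"),
    locality = c("market", "market"),
    voucher = c("V1", "V2"), stringsAsFactors = FALSE)
  sequences <- data.frame(
    sequence_id = c("Q1", "Q2"),
    specimen_id = c("S1", "S2"),
    taxon_id = c("T1", "T2"),
    marker = c("ITS2", "psbA-trnH"),
    source = c("study", "public"),
    reference_id = c("", ""),
    core_start = c("3", ""),
    core_end = c("18", ""), stringsAsFactors = FALSE)
  fasta <- c(Q1 = "GGACGTACGTACGTACGTAA", Q2 = "TTTTACCCGGGTTTACCAAT")
  herb_library(taxonomy, specimens, sequences, fasta)
}

write_toy_library <- function(dir = tempfile("lib")) {
  write_library(toy_library(), dir)
  dir
}

# monograph fixtures reproducing the published pharmacopeia comparisons
kp_chp_monographs <- function() {
  kp <- list(
    drug_monograph("Epimedium Herb",
                   c("Epimedium koreanum", "Epimedium brevicornum",
                     "Epimedium pubescens", "Epimedium wushanense",
                     "Epimedium sagittatum")),
    drug_monograph("Liriope Tuber",
                   c("Liriope platyphylla", "Ophiopogon japonicus")),
    drug_monograph("Phellodendron Bark",
                   c("Phellodendron amurense", "Phellodendron chinense")),
    drug_monograph("Cardamon", c("Amomum villosum")),
    drug_monograph("Ginseng Root", c("Panax ginseng")),
    drug_monograph("Mint Herb", c("Mentha arvensis var. piperascens",
                                  "Mentha canadensis")),
    drug_monograph("Jujube Fruit", c("Zizyphus jujuba")),
    drug_monograph("Peony Root", c("Paeonia lactiflora")))
  chp <- list(
    drug_monograph("Epimedium Herb",
                   c("Epimedium koreanum", "Epimedium brevicornum",
                     "Epimedium pubescens", "Epimedium sagittatum"),
                   pharmacopeia = "ChP"),
    drug_monograph("Epimedium wushanense Herb", "Epimedium wushanense",
                   pharmacopeia = "ChP"),
    drug_monograph("Liriope Tuber", "Liriope platyphylla",
                   pharmacopeia = "ChP"),
    drug_monograph("Ophiopogon Tuber", "Ophiopogon japonicus",
                   pharmacopeia = "ChP"),
    drug_monograph("Phellodendron Amurense Bark", "Phellodendron amurense",
                   pharmacopeia = "ChP"),
    drug_monograph("Phellodendron Chinense Bark", "Phellodendron chinense",
                   pharmacopeia = "ChP"),
    drug_monograph("Ginseng Root", "Panax ginseng", pharmacopeia = "ChP"),
    drug_monograph("Mint Herb", "Mentha canadensis", pharmacopeia = "ChP"),
    drug_monograph("Jujube Fruit", c("Zizyphus jujuba", "Zizyphus spinosa"),
                   pharmacopeia = "ChP"),
    drug_monograph("Peony Root", c("Paeonia veitchii"),
                   pharmacopeia = "ChP"))
  list(kp = kp, chp = chp)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# wrap a core in the marker's flank consensi (true reads look like this)
wrap_read <- function(core, marker = "ITS2") {
  p <- marker_profiles()[[marker]]
  paste0(p$flank_left, core, p$flank_right)
}
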