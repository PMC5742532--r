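---
title: "Methods: barcode reference libraries and species identification in herbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode reference libraries and species identification in herbid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbid)
```

## Scope and model

`herbid` implements a DNA-barcode workbench for herbal drug authentication:
a record data model for a pharmacopeia reference library, a species
identification pipeline for unknown market samples, barcode-gap divergence
analytics, and a comparison of prescribed origin species between two
pharmacopeias. The two markers supported are the nuclear ribosomal ITS2
spacer and the chloroplast psbA-trnH intergenic spacer, the standard pair
for medicinal plants: ITS2 is short, highly variable and flanked by the
strongly conserved 5.8S and 28S rDNA fragments; psbA-trnH is variable but
prone to micro-structural artifacts (short inversions, indels, repeats)
that inflate distance estimates if left uncorrected.

## The record model

A library consists of five cross-linked record collections — taxonomy,
specimens, sequences, references and drug monographs — serialized as TSV
tables plus a FASTA of raw reads (schemas are documented in `R/library.R`
and the help pages). The taxonomy is the hub: every specimen, sequence and
reference record must resolve to a taxonomy entry at or below species rank.
Each taxonomy entry carries one primary name (the pharmacopeia's usage), an
authority, and any number of synonyms tagged with their source nomenclature
(Chinese pharmacopeia, Flora of China, NCBI). Name resolution
(`resolve_name()`) is case-insensitive, collapses whitespace and strips
trailing authority tokens; infraspecific markers (`var.`, `subsp.`) are
retained because pharmacopeia origins are often varieties. A synonym
claimed by two entries raises an error rather than silently resolving to
the first claimant: synonym conflicts are data defects that must be fixed
before records are added, not papered over at query time.

Structural defects (missing columns, dangling foreign keys, FASTA/table
mismatches) abort loading with an error naming the record and field;
semantic rule violations (a sequence mapped to a genus, a specimen without
a companion sequence, an alphabet violation, duplicate ids) are *data*,
returned as a violation table by `validate_library()` so curators can fix
them in bulk.

## Database tiers and search

`compile_database()` projects a library onto a searchable tier: study
records (SBD), public records (PBD), or their union (ABD), deduplicated by
sequence id; `sdd_database()` wraps a user FASTA (SDD). Entries carry the
annotated core region when present, otherwise the raw read, labelled with
the species' primary name.

Search is seed-and-extend: entries sharing at least `min_shared_kmers`
(default 5) distinct canonical 8-mers with the query are aligned locally
(match +1, mismatch −1, gap open −2, gap extension −0.5) and ranked by
score, then identity, then sequence id. Canonical k-mers (the
lexicographic minimum of a k-mer and its reverse complement) make the
index strand-insensitive; each candidate is additionally scored in both
query orientations and the better one reported, since market reads may be
submitted reverse-complemented. If no entry passes the k-mer floor, all
entries are aligned, so results are never silently empty. Identity is
computed over *compared columns* only — columns with an unambiguous base
in both rows — and coverage is the aligned fraction of the query. These
definitions differ slightly from BLAST's, and the seeded filter is exact
rather than heuristic: rankings are bit-for-bit reproducible, which we
consider more important for a reference tool than raw speed.

## Quality control and marker handling

A query passes QC when it meets the marker length floor (ITS2 ≥ 150 bp,
psbA-trnH ≥ 100 bp, inclusive), carries at most 1% IUPAC ambiguity
characters (inclusive), and no characters outside the IUPAC alphabet.
Failing queries short-circuit the pipeline: the report explains why and no
search or tree construction happens.

Marker routing and core-region trimming use per-marker *flank consensi*
shipped as plain-text fixtures: 40 bp synthetic stand-ins for the
conserved gene fragments bordering each marker (5.8S/28S for ITS2, the
psbA and trnH gene edges for psbA-trnH), seeded with the canonical priming
motifs. A read is routed to the marker whose flanks align best (both
orientations are tried; reverse-complement reads are reoriented), and the
core region is the span between the located flanks. A flank counts as
found at a local alignment score of 20 — half of a perfect 40 bp flank —
which tolerates several mismatches while rejecting chance matches on
random sequence (which plateau around score 10–14 at these lengths). With
one flank missing the read is flagged `partial`, with both missing
`untrimmed`, and the whole read is used: trimming degrades, it never
discards a query. A full profile-HMM annotation of the core regions is out
of scope; the flank-alignment contract preserves what downstream code
needs (comparable core spans) and is exactly testable against the
simulator's true spans.

## Distances and trees

Distances are Kimura 2-parameter:
`d = -1/2 ln((1 − 2P − Q) · sqrt(1 − 2Q))`, with transition proportion `P`
and transversion proportion `Q` computed over compared columns of the
pairwise alignment (pairwise deletion). Ambiguity columns are excluded
outright rather than scored fractionally because the P/Q decomposition
needs unambiguous base pairs. When `1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0` the
estimator is undefined: the pair is *saturated*, reported as `Inf`, and
poisons tree building rather than being capped — a capped value would
silently understate exactly the distances that inversions and other
artifacts inflate.

Trees are neighbour-joining over pairwise K2P matrices, written in newick.
The agglomeration is the standard Q-criterion procedure with two
determinism guarantees the usual library routines do not make: ties in the
Q criterion are broken by the lexicographically smallest pair of cluster
labels, and negative branch-length estimates are clamped to zero. Tests
verify exact recovery of additive matrices against both an exhaustive
least-squares topology search and an independent NJ implementation.

## Inversion normalization

Short inversions in psbA-trnH (e.g. a locus reading ATGAAAAC in one origin
and GTTTTCAT in another) masquerade as dense mismatch blocks and can
double an intraspecific distance. `normalize_inversion()` aligns the query
to a reference, then looks for the maximal-scoring *disturbed window*: a
maximum-subarray scan scoring mismatching columns and gap columns +1 and
matching columns −0.5. A strict run of consecutive mismatches would be the
obvious detector, but it cannot work: a segment aligned against its own
reverse complement matches at about a quarter of its columns by chance
(the ATGAAAAC/GTTTTCAT pair itself matches at two of eight positions), and
the aligner further shreds the block with compensating gaps, so the
detector must tolerate embedded matches. The window must contain at least
`min_run = 6` mismatching columns; the corresponding query segment is
reverse-complemented and the correction kept only if global identity
improves by at least `min_gain = 0.02` (about five columns on a typical
read — large enough that chance never clears it, small enough that any
distance-inflating inversion does). Consequences of this design: identity
never decreases, the operation is idempotent on its own output, and
weakly-disturbing inversions (those costing less than the gain floor) are
deliberately left alone, since they do not materially bias distances. In
the pipeline the check runs for psbA-trnH only, against the provisional
top hit, with a re-search afterwards.

## Assignment policy

Ranked hits are turned into a taxonomic call by explicit thresholds
(`assignment_policy()`), all exposed to the user because no published
decision rule exists for this engine family. Hits covering less than half
the query are ignored: a short perfect local match has identity 1 and no
evidential value. A species call requires the best identity to reach
`species_identity_min` (default 0.97) with all hits inside the tie margin
(0.003) agreeing on one species; tied hits spanning several congeneric
species, or a best identity in the genus band (0.95–0.97), give a genus
call; anything below 0.95 is unidentified. The species threshold sits
deliberately *inside* the barcode gap rather than near the intraspecific
ceiling: two conspecific reads each ~0.5% diverged from their species
consensus meet near 99% identity, so a 0.99 cutoff would bisect the
intraspecific identity distribution and reject roughly one conspecific
match in six, while congeneric identities sit below ~0.92 for these
markers. At 0.97 conspecific matches pass with several percent to spare
and interspecific matches remain far below the bar. Identification does
not stop at the call: `match_label()` compares a species-level call
(synonym-resolved) against the labelled drug's official origins and
returns matched/mismatched/inconclusive, which is how adulterants — a
congener sold under the official drug name — surface even when the
assignment itself is confident and correct.

## Divergence analytics

`summarize_divergence()` reports six statistics of a single-marker
database, all from within-genus pairwise K2P distances: (i) the mean over
species of the average interspecific distance to congeners, (ii) theta
prime — the mean over multi-species genera of the genus's mean
interspecific distance, (iii) the mean over species of the minimum
interspecific distance, (iv) the mean over all intraspecific pairs pooled,
(v) theta — the mean over multi-sequence species of the per-species
average intraspecific distance, and (vi) the mean coalescent depth
(per-species maximum intraspecific distance). (iv) pools pairs while (v)
averages per-species means; with unbalanced sampling they differ, which is
why both are reported. Undefined quantities (singleton species, genera
without congeners) are absent, never zero — a zero would fabricate a
barcode gap. Saturated pairs are excluded and counted. Per-species
averaging (rather than per-pair) is used for (i)–(iii) to match the
per-species framing of barcode-gap distribution plots.

## The simulator

`simulate_library()` emulates the sampling design of a pharmacopeia
reference library: genus root cores drawn uniformly over A/C/G/T, species
consensi mutated from the root at `inter_rate`, specimen reads mutated
from the consensus at `intra_rate`, wrapped in the marker flank consensi.
The substitution process is K2P-type (per-site, transition:transversion
odds `kappa` : 1 with `kappa = 2`), chosen deliberately so the package's
K2P estimator is the matched estimator and rate recovery is a meaningful
end-to-end check. Defaults — 20 genera × 3 species × 4 specimens, ITS2
cores 230 bp, psbA-trnH cores 300 bp, `intra_rate = 0.005`,
`inter_rate = 0.05` — describe a gap-separated library in the range
reported for medicinal-plant ITS2 surveys (intraspecific divergence a few
tenths of a percent to one percent, congeneric divergence several
percent). One drug monograph is emitted per genus prescribing all but the
genus's last species, so adulterant scenarios (a correct identification
that is not an official origin) are generated, not hand-crafted.
`simulate_queries()` adds per-query defects: truncation below the QC
floor, >1% ambiguity, whole-read reverse complement, a 24 bp core
inversion, or adulterant sampling. All randomness flows through a
mandatory seed; the same seed reproduces byte-identical libraries.

What the simulator does *not* model — real ITS2 secondary structure and
GC bias, length variation, sequencing chemistry error profiles, chimeras,
shared polymorphism between recently diverged species — bounds what
passing tests show: they validate the machinery (parsing, indexing,
alignment book-keeping, estimator algebra, decision logic) under a process
the estimators match, not performance on real trace data. In particular,
pairwise divergence in the simulator concentrates near twice the
per-lineage rate, so recovery tests use that expectation; real data have
no such truth to recover.

## Numerical and problem-size choices

Distance computations under simulated (equal-length, indel-free) data use
the known coordinate frame (`aligned = TRUE`) instead of re-aligning;
everything else aligns explicitly. Alignment statistics are derived from
match/mismatch tables rather than extracted alignment strings, which is
exact whenever at least one side of a pair is pure A/C/G/T and falls back
to string extraction otherwise. Tests and the acceptance script run the
generator at its default 240-sequence scale for divergence and
identification checks, 50-entry databases for search-oracle equality, 100
random additive trees of up to 7 leaves for NJ-oracle equality, and toy
libraries elsewhere; these sizes give stable statistics (binomial standard
errors well inside the asserted tolerances) while keeping a full run in a
few minutes on one CPU.

## Known limitations

* Pairwise alignment throughout (no multiple alignment): distances between
  highly gapped real sequences can differ from an MSA-based estimate.
* Flank-consensus trimming is a functional stand-in for profile-HMM
  annotation; on real reads with degraded flanks it degrades to
  `partial`/`untrimmed` more often than an HMM would.
* The inversion normalizer corrects one disturbed window per pass and
  targets inversions long enough to bias distances; repeats and rps19
  insertion artifacts of psbA-trnH are not modelled.
* Assignment thresholds are policy, not estimates; for markers or clades
  with narrower barcode gaps they should be re-examined by the user
  against `summarize_divergence()` output.
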