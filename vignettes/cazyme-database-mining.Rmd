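---
title: "Mining a local CAZyme database: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a local CAZyme database: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazymine)
```

## The problem

The CAZy classification assigns carbohydrate-active enzymes to
sequence-similarity families within six classes — glycoside hydrolases
(GH), glycosyltransferases (GT), polysaccharide lyases (PL),
carbohydrate esterases (CE), auxiliary activities (AA) and
carbohydrate-binding modules (CBM). The public form of the catalogue is
a flat text dump: one family–protein link per line carrying the family
label, the source organism's kingdom-level group and name, and a
versioned NCBI protein accession. Everything else a survey needs —
protein sequences, EC numbers, PDB structure identifiers, genome
assemblies, full taxonomic lineages — lives in other databases, keyed by
that accession.

`cazymine` compiles the dump into a relational SQLite file, attaches
those annotations from *snapshot files* (offline, versioned stand-ins
for the external services, behind a uniform provider contract), and
implements the survey statistics on top. Nothing in the package touches
the network: reproducibility comes from the dump + snapshots + YAML
criteria being ordinary files you can archive.

## Data model and import semantics

The store has one `proteins` table keyed by the versioned accession
(compared case-sensitively: `ABC1.1` and `ABC1.2` are distinct records),
entity tables for families and taxa, and joint-unique link tables for
family, taxon, UniProt, EC, PDB and assembly associations, plus
per-accession NCBI lineages and per-assembly GTDB lineages. Import is
one transaction per call and idempotent by construction (`INSERT OR
IGNORE` against the uniqueness constraints), so re-importing the same
dump, an overlapping filtered subset, or a later release never
duplicates a record.

Two deliberate policies:

* **Taxonomy conflicts are kept, not resolved.** A protein reported from
  two distinct source organisms keeps both taxon links and gains a row
  in a `conflicts` table (with first/last observation timestamps).
  Silently dropping either assignment would hide a data-quality signal
  that is itself worth reporting; the conflict table makes it one query.
* **An append-only audit log.** Every mutating operation — import or any
  enrichment — writes exactly one log row (UTC ISO-8601 timestamp,
  source, criteria text, row counts), so a shared database file carries
  its own provenance.

`count_cazymes()` counts *distinct accessions* matching the criteria;
this mirrors counting unique accessions in an SQL console and is the
semantic every summary in the package inherits. A protein in GH5 and
CBM35 therefore counts once overall, and once in each class row of a
class-by-kingdom table — which is why class totals may legitimately
exceed the distinct-protein total.

## The selection-criteria algebra

Criteria have eight categories in four groups:

| group | categories | within | across groups |
|---|---|---|---|
| family scheme | classes, families, subfamilies | OR | AND |
| kingdom | kingdoms | OR | AND |
| organism | genera, species, strains | OR | AND |
| activity | ec_numbers | OR | AND |

Empty criteria match everything. A *family* selector (GH5) also matches
its subfamilies (GH5_4), because subfamilies are refinements of the
family; a *subfamily* selector matches exactly. Species and strain
selectors union within the organism group: asking for species
*Trichoderma reesei* and strain *Aspergillus flavus AF13* in one call
means "all T. reesei strains plus that one A. flavus strain". Whether
these two categories should union or intersect is genuinely open from
the command semantics alone; the union reading is the only one under
which such a combined command is not a contradiction, so it is adopted
and extended to genera. Kingdoms conjoin with the organism group (a
bacterial-kingdom filter restricts any organism filter), which keeps
`--families PL20,PL28 --kingdoms bacteria` an intersection.

EC selectors accept trailing dashes (`3.1.1.-`) as wildcards at the
dashed levels, since partially specified Enzyme Commission numbers are
legal annotations. EC criteria are ignored at import time — the dump
carries no EC data; they bind during enrichment, query and export.

## Enrichment and the provider contract

Each external database is modelled as a headered TSV snapshot:
UniProt-like (accession → id, name, EC set, PDB set, sequence, version
date), NCBI-taxonomy-like (accession → lineage string), GTDB-like
(assembly → lineage) and an accession→assembly mapping. `read_snapshot()`
validates rows against the type invariants (EC grammar
`^\d+\.[\d-]+\.[\d-]+\.[\d-]+$`, 4-character PDB codes, rank-prefix
lineages); invalid values become row-level issues rather than fatal
errors, duplicate keys resolve last-wins with a warning.

All enrichment operations are idempotent and filter-respecting:
proteins outside the criteria are untouched, accessions missing from a
snapshot are counted as misses, and GTDB linking distinguishes
*unlinkable* proteins (no assembly link yet) from misses. Sequence
refresh overwrites only on a strictly newer version date — with an
identical or older date the stored sequence stays untouched, so refresh
is safe to re-run. "More recent" is deliberately date-based rather than
accession-version-based: snapshots carry an explicit version date,
while an accession's version suffix changes the accession itself and
hence the record's identity.

`run_batched()` gives enrichment its resume semantics: accessions are
processed in ordered batches (default 150, an arbitrary but
conventional request size for annotation services) and each completed
batch is appended to a newline-delimited cache file *before* the next
batch starts. An interruption at any point therefore loses at most the
in-flight batch, and a re-run processes exactly the remainder; the final
state provably equals an uninterrupted run (a property the test suite
checks over random cut points).

## The survey statistics

**Representation rates.** Given per-kingdom counts of species-level
taxa and of species with ≥1 / ≥50 catalogued CAZymes, the rate is
$100\,n/N$ rounded *half-up* to two decimals — `round_half_up()` exists
because base R rounds half-to-even, which disagrees with how such
census tables are conventionally printed (1.2999 → 1.30, 0.8577 →
0.86). A `Total` row sums the counts first and then applies the same
formula. The package ships the published desk-scale census tables as
plain-text inputs (`species_census()`, `ce_structure_census()`); the
percentages and column totals are recomputed from the counts at run
time, never stored.

**χ² decomposition.** `chisq_decompose()` supports goodness-of-fit
($E_i = N p_i$, df $= k-1$), homogeneity of two count vectors (stacked
as a 2×k table with the standard row×column/total expectation) and
independence on a matrix. Beyond the statistic
$\chi^2 = \sum (O-E)^2/E$ it reports Pearson residuals
$r = (O-E)/\sqrt{E}$ and per-cell explained variance
$V = 100\,r^2/\chi^2$. Only the squared-residual form makes the cell
contributions sum to 100% (to within 1e-9, asserted as an invariant),
which is what justifies calling $V$ a variance decomposition; the
residual's sign separately gives the direction of deviation. Degenerate
inputs are errors rather than silent NaNs: any $E=0$ cell asks the
caller to pool sparse categories, and an exact $O=E$ table reports
"degenerate: zero statistic" because $V$ is then undefined. The
implementation is the explicit formula; the test suite cross-checks it
against `stats::chisq.test()` as an independent route.

**BSR.** The BLAST Score Ratio of an ordered pair is the raw alignment
score of query vs subject divided by the query's self-alignment score.
The built-in scorer is Smith–Waterman under BLOSUM62 with gap open 11 /
extend 1 (the blastp defaults), for which random-pair expected scores
are non-positive and ratios live in $[0, 1]$; the diagonal is exactly 1
by construction. The matrix is query-normalised and may be asymmetric
for length-mismatched pairs. Ratios of *raw* scores differ from ratios
of BLAST bit scores only through an affine transform of the scale, so
for exact replication of an external survey the function accepts a
blastp tabular score file instead of the scorer, keeping the highest
score per pair (the "top-ranked alignment" reading; ties among HSPs are
resolved by raw score). Scaling every raw score by a constant leaves
the matrix unchanged — an invariant the tests assert.

**Redundancy.** `find_redundant_pairs()` reports every unordered pair
of byte-identical sequences (a group of $m$ identical sequences yields
$\binom{m}{2}$ pairs), annotated with accession kind; the GenBank/RefSeq
prefix rule (`^[A-Z]{2}_` → RefSeq) classifies the members. This is the
cleanup step that matters before building non-redundant training sets,
and it is checked against a brute-force all-pairs oracle.

**Clustering.** `greedy_cluster()` is an incremental single-linkage-to-
representative scheme in the CD-HIT tradition, standing in for heavier
clustering engines at desk scale: sequences are visited by decreasing
length (accession order as the deterministic tie-break); each joins the
first cluster whose representative it matches at ≥ identity over ≥
coverage of *both* sequences, else founds a new cluster. Identity is
matches / alignment columns of a global (Needleman–Wunsch, BLOSUM62
11/1) alignment. Coverage is defined as the *mutually aligned* columns
(both sequences contribute a residue) divided by each sequence's length
— a strict end-to-end span would be identically 1 under a global
alignment, which would silence the coverage threshold entirely, whereas
the mutually-aligned definition correctly blocks a fragment from
joining a full-length representative. Raising the identity threshold
can only split, never merge, clusters (monotonicity, asserted on
fixture sweeps). Cluster sets round-trip through the two-column
representative/member TSV used by common clustering tools, so an
external clustering can be dropped in.

**Structural coverage.** Per family: distinct members and distinct
members with ≥1 PDB link; totals are column sums. Per cluster: a flag
if any member has a structure — unflagged clusters are the candidate
targets for structure determination. When an independent list of
"structurally characterised" accessions is supplied, the two
discrepancy lists (annotated but no PDB link; PDB link but not
annotated) are reported, since the two sources genuinely disagree in
practice.

## The synthetic-data generator

`fixture_spec()` + `generate_fixture()` produce the complete input set
— dump, four snapshots, FASTA — with planted ground truth, as a pure
function of the spec: the same spec (including its seed) reproduces
every file byte for byte. The default plan is a small three-family ×
two-kingdom design with four records per cell, which keeps whole-suite
alignment work in seconds; tests that need specific structure pass
their own plans.

What it emulates: multi-family proteins (a protein absorbing a second
family link without disturbing per-family×kingdom distinct counts),
GenBank/RefSeq redundant twins with identical sequences, cross-kingdom
taxonomy conflicts (planted cross-kingdom so the kingdom-partition
property — the per-kingdom counts exceeding the distinct total by
exactly the number of conflicts — is exercised), *Candidatus* and
incomplete lineages, partial snapshot coverage, and sequence clusters:
cluster seeds diverge from a common random ancestor to the target
between-cluster identity, members diverge from their seed at half the
within-cluster divergence so member–member identity lands near the
target.

What it does not emulate: real amino-acid composition or
phylogenetic correlation (sequences are i.i.d. uniform over the 20
residues), real family size distributions, the live dump's column
order (the dialect abstraction isolates that), or HTML/scraping
concerns, which are out of scope by design. Passing tests therefore
demonstrate the *relational and algorithmic* contracts — counting,
idempotence, filtering, detection and recovery of planted signal — not
biological realism of the sequences.

## Numerical and interface choices

* Percent rounding is half-up (with an ulp-scale nudge so exactly
  representable halves like 0.125 round up in binary floating point).
* Multi-valued query cells are comma-joined and lexicographically
  sorted; all writers (CSV per RFC 4180, JSON array-of-objects, FASTA,
  dump TSV) are byte-stable for fixed input, so exports diff cleanly.
* Unknown kingdom tokens canonicalise to the catch-all `unclassified`
  group with a warning rather than failing an import.
* Malformed dump lines and invalid snapshot values are collected as
  issues; only structural problems (unknown dialect, missing mandatory
  columns, unreadable files) are fatal.
* The store file is plain SQLite; any third-party console can query it.
* Problem sizes used by the test suite and the acceptance script: 1000
  randomized criteria draws across four fixtures for count semantics,
  1000 random tables for the χ² invariants, 200 sequences for the
  redundancy oracle, ~10-sequence planted cluster fixtures for
  alignment-heavy checks. These sizes were chosen to make each property
  run in seconds while still randomizing over the relevant structure.

## Known limitations

* The greedy clusterer is order-dependent (by design, like its
  tradition): a borderline sequence joins the first qualifying
  representative, not the best one. Planted-cluster recovery at the
  default thresholds is asserted; agreement with any specific external
  tool is not claimed.
* Live retrieval clients are intentionally absent; a new provider is
  added by writing its snapshot reader behind the same contract.
* Multi-user concurrent writes are out of scope (single-file embedded
  store).
* BSR values from the built-in scorer are raw-score ratios; when
  comparing against published bit-score-ratio heatmaps, supply the
  external score table instead.
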