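# cazymine

Local, reproducible mining of carbohydrate-active-enzyme (CAZyme)
annotations in R.

The CAZy classification groups CAZymes — the enzymes that build, modify
and degrade glycans — into sequence-similarity families within six
classes (GH, GT, PL, CE, AA, CBM). The public distribution of this
catalogue is a flat text dump with no query interface, while the
sequence, taxonomy, genome and structure annotations a family survey
needs live in other resources (NCBI, UniProt, GTDB, RCSB PDB).
`cazymine` turns the dump into a single-file SQLite database with a
proper relational model, enriches it from offline snapshot files behind
a provider contract, and implements the statistics a family-level survey
runs on top: who is in the database, how unevenly, and how diverse and
how structurally covered each family is.

It is written for computational biologists and database curators who
need filtered, citable slices of the CAZyme catalogue (e.g. "all
bacterial PL20 sequences, as FASTA") and desk-scale summary statistics,
without scraping anything live.

## What it computes

* **Idempotent relational import.** Distinct CAZymes are keyed by their
  versioned NCBI accession; re-importing any dump or filtered subset
  never duplicates a record. Multi-family membership becomes multiple
  family links; proteins reported from several source organisms keep all
  taxon links and gain an explicit conflict record. Every mutating
  operation appends one row to an audit log.
* **Conjunctive/disjunctive selection criteria** over classes, families
  (a family filter includes its subfamilies), subfamilies, kingdoms,
  genera, species, strains and EC numbers, from function arguments,
  command-line flags or YAML.
* **Representation rates.** For a kingdom with `N` species-level taxa of
  which `n` carry at least one (or at least 50) catalogued CAZymes, the
  rate is `100 n / N`, rounded half-up to two decimals.
* **χ² decomposition.** For observed counts `O` and expected counts `E`,
  the package reports the statistic `χ² = Σ (O−E)²/E` together with the
  Pearson residuals `r = (O−E)/√E` and each cell's explained variance
  `V = 100 r²/χ²`, which sums to 100% and localises which kingdoms drive
  a significant imbalance.
* **BLAST Score Ratio (BSR) matrices.** For each ordered pair `(a, b)`,
  `bsr(a, b) = score(a, b) / score(a, a)` with a Smith–Waterman raw
  score (BLOSUM62, gap open 11 / extend 1); external blastp tabular
  scores can be substituted. Identical sequences score 1, unrelated
  ones near 0.
* **Redundancy detection** (byte-identical sequences under distinct
  accessions, e.g. a GenBank record and its RefSeq twin) and **greedy
  identity/coverage clustering** (CD-HIT style, default thresholds 40%
  identity / 80% coverage of both sequences), feeding a
  **structural-coverage report**: members per family, members with at
  least one PDB link, and clusters lacking any structural
  representative.
* **A synthetic fixture generator** that writes an internally consistent
  dump + snapshots + FASTA with planted ground truth (counts, duplicate
  pairs, taxonomy conflicts, sequence clusters), so every pipeline stage
  is testable offline and deterministically.

## Worked example

```r
library(cazymine)

# a deterministic synthetic dataset standing in for a CAZy download
spec <- fixture_spec(n_redundant_pairs = 2, cluster_sizes = c(3, 3),
                     n_with_pdb = 3, rng_seed = 2026)
gt <- generate_fixture(spec, tempfile("fx"))

store <- init_store(tempfile(fileext = ".db"))
import_dump(store, parse_dump(gt$files[["dump"]]))
#> # A tibble: 1 × 4
#>   proteins_new links_new skipped_by_filter conflicts_recorded
#>          <int>     <int>             <int>              <int>
#> 1           26        52                 0                  0

count_cazymes(store, selection_criteria(families = "PL20",
                                        kingdoms = "bacteria"))
#> [1] 4

attach_uniprot(store, read_snapshot(gt$files[["uniprot"]], "uniprot"))
cazy_query(store, selection_criteria(classes = "CE"),
           include = c("family", "kingdom", "pdb"))
#> # A tibble: 10 × 4
#>   accession  family kingdom  pdb
#>   <chr>      <chr>  <chr>    <chr>
#> 1 SYN00001.1 CE12   Bacteria 2ABC
#> 2 SYN00002.1 CE12   Bacteria 3ABC
#> 3 SYN00003.1 CE12   Bacteria 4ABC
#> 4 SYN00004.1 CE12   Bacteria NA
#> # ...

find_redundant_pairs(store)[, 1:4]
#> # A tibble: 2 × 4
#>   accession_a accession_b kind_a  kind_b
#>   <chr>       <chr>       <chr>   <chr>
#> 1 SYN00007.1  WP_000001.1 genbank refseq
#> 2 SYN00008.1  WP_000002.1 genbank refseq
```

The import summary says 26 distinct proteins entered the store (24
planned records plus the two planted RefSeq twins); the filtered count
returns the four bacterial PL20 records; the query shows which CE
proteins carry PDB structure links after UniProt enrichment; and the
redundancy detector recovers exactly the two planted identical-sequence
GenBank/RefSeq pairs.

The same operations are available from a shell through the launcher in
`exec/`:

```sh
cazymine build dump.tsv --families PL20,PL28 --kingdoms bacteria -o cazyme.db
cazymine extract-seqs cazyme.db genbank --kingdoms archaea --fasta_file archaea.fasta
cazymine query cazyme.db --include family,ec,pdb -o out.csv
```

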