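# Snapshot enrichment: UniProt, lineages, assemblies, sequence refresh,
# resumable batching.

test_that("uniprot enrichment writes requested fields and counts misses", {
  gt <- make_fixture(fixture_spec(n_with_ec = 4, n_with_pdb = 3,
                                  uniprot_coverage = 0.7, rng_seed = 12))
  store <- make_store(gt)
  up <- read_snapshot(gt$files[["uniprot"]], "uniprot")
  s <- attach_uniprot(store, up)
  n_all <- count_cazymes(store)
  expect_equal(s$hits, nrow(up))
  expect_equal(s$misses, n_all - nrow(up))
  view <- protein_view(store)
  # every planted EC/PDB annotation landed as a link
  expect_equal(sort(unique(unlist(view$ecs))),
               sort(unique(unlist(up$ec_numbers))))
  expect_equal(sort(unique(unlist(view$pdbs))),
               sort(unique(unlist(up$pdb_ids))))
})

test_that("a snapshot hit carrying a PDB id yields that structure link", {
  db <- withr::local_tempfile(fileext = ".db")
  store <- init_store(db)
  withr::defer(close_store(store))
  import_dump(store, parse_dump(
    "CE19\tBacteria\tBacteroides thetaiotaomicron\tALJ42174.1"))
  snap <- tibble::tibble(accession = "ALJ42174.1", uniprot_id = "U1",
                         protein_name = "carbohydrate esterase",
                         ec_numbers = list(character()),
                         pdb_ids = list("6GOC"),
                         sequence = NA_character_,
                         version_date = as.Date("2022-04-01"))
  attach_uniprot(store, snap)
  view <- protein_view(store)
  expect_equal(view$pdbs[[1]], "6GOC")
})

test_that("enrichment is idempotent and filter-respecting", {
  gt <- make_fixture(fixture_spec(n_with_ec = 4, n_with_pdb = 3,
                                  rng_seed = 12))
  store <- make_store(gt)
  up <- read_snapshot(gt$files[["uniprot"]], "uniprot")
  crit <- selection_criteria(kingdoms = "Bacteria")
  before <- protein_view(store)
  attach_uniprot(store, up, crit)
  mid <- protein_view(store)
  # non-matching proteins are bit-identical before/after
  out <- !matches(before, crit)
  expect_equal(mid[out, ], before[out, ])
  s2 <- attach_uniprot(store, up, crit)
  expect_equal(s2$rows_added, 0)
  expect_equal(s2$rows_updated, 0)
  expect_equal(mid, protein_view(store))
})

test_that("empty snapshots produce an all-zero summary", {
  gt <- make_fixture(fixture_spec(rng_seed = 12))
  store <- make_store(gt)
  empty <- tibble::tibble(accession = character(), uniprot_id = character(),
                          protein_name = character(),
                          ec_numbers = list(), pdb_ids = list(),
                          sequence = character(),
                          version_date = as.Date(character()))
  s <- attach_uniprot(store, empty)
  expect_equal(s$hits + s$rows_added + s$rows_updated, 0)
})

test_that("NCBI lineages attach with flags retained; re-run adds nothing", {
  gt <- make_fixture(fixture_spec(n_candidatus = 2, n_incomplete = 1,
                                  rng_seed = 13))
  store <- make_store(gt)
  tax <- read_snapshot(gt$files[["ncbi_tax"]], "ncbi_tax")
  s <- attach_ncbi_lineage(store, tax)
  expect_equal(s$hits, count_cazymes(store))
  s2 <- attach_ncbi_lineage(store, tax)
  expect_equal(s2$rows_added, 0)
  lin <- DBI::dbGetQuery(store$con,
    "SELECT SUM(candidatus) AS c, SUM(incomplete) AS i FROM ncbi_lineages")
  expect_equal(lin$c, 2)   # candidatus flag round-trips into the store
  expect_equal(lin$i, 1)
})

test_that("a lineage filter only touches matching proteins", {
  counts <- tidyr::expand_grid(family = c("GH3", "PL20"),
                               kingdom = c("Archaea", "Bacteria"))
  counts$n <- 3L
  gt <- make_fixture(fixture_spec(counts = counts, rng_seed = 13))
  store <- make_store(gt)
  tax <- read_snapshot(gt$files[["ncbi_tax"]], "ncbi_tax")
  crit <- selection_criteria(families = "GH3", kingdoms = "Archaea")
  s <- attach_ncbi_lineage(store, tax, crit)
  expect_equal(s$hits, count_cazymes(store, crit))
  n_lineages <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM ncbi_lineages")$n
  expect_equal(n_lineages, count_cazymes(store, crit))
})

test_that("GTDB linking needs an assembly; unlinkable and misses are counted", {
  gt <- make_fixture(fixture_spec(assembly_coverage = 0.5, rng_seed = 14))
  store <- make_store(gt)
  asm <- read_snapshot(gt$files[["assembly"]], "assembly")
  attach_assemblies(store, asm)
  gtdb <- read_snapshot(gt$files[["gtdb_tax"]], "gtdb_tax")
  s <- attach_gtdb_lineage(store, gtdb)
  n_all <- count_cazymes(store)
  expect_equal(s$unlinkable, n_all - length(unique(asm$accession)))
  expect_gt(s$hits, 0)
  # an assembly absent from the snapshot is a miss, not an error
  s2 <- attach_gtdb_lineage(store, gtdb[0, ])
  expect_equal(s2$hits, 0)
  expect_equal(s2$misses, length(unique(asm$assembly)))
})

test_that("sequence refresh only overwrites on a strictly newer version", {
  db <- withr::local_tempfile(fileext = ".db")
  store <- init_store(db)
  withr::defer(close_store(store))
  import_dump(store, parse_dump(c("GH5\tBacteria\tEscherichia coli\tAAA1.1",
                                  "GH5\tBacteria\tEscherichia coli\tAAA2.1",
                                  "GH5\tBacteria\tEscherichia coli\tAAA3.1")))
  snap1 <- tibble::tibble(accession = c("AAA1.1", "AAA2.1", "AAA3.1"),
                          sequence = c("MKVA", "MKVC", "MKVD"),
                          version_date = as.Date("2022-01-01"))
  refresh_sequences(store, snap1, source = "genbank")
  # same date: untouched; newer date: updated; per-row decision
  snap2 <- tibble::tibble(accession = c("AAA1.1", "AAA2.1", "AAA3.1"),
                          sequence = c("WWWW", "XXXX", "YYYY"),
                          version_date = as.Date(c("2022-01-01", "2022-06-01",
                                                   "2021-06-01")))
  s <- refresh_sequences(store, snap2, source = "genbank")
  expect_equal(s$rows_updated, 1)
  view <- protein_view(store)
  expect_equal(view$sequence[view$accession == "AAA1.1"], "MKVA")
  expect_equal(view$sequence[view$accession == "AAA2.1"], "XXXX")
  expect_equal(view$sequence[view$accession == "AAA3.1"], "MKVD")
})

test_that("a mixed refresh updates exactly the newer fraction", {
  gt <- make_fixture(fixture_spec(rng_seed = 15))
  store <- make_store(gt)
  up <- read_snapshot(gt$files[["uniprot"]], "uniprot")
  attach_uniprot(store, up)            # baseline dated 2022-04-01
  acc <- head(up$accession, 10)
  newer <- tibble::tibble(
    accession = acc,
    sequence = toupper(substr(gt$sequences[acc], 1, 50)),
    version_date = as.Date(c(rep("2023-01-01", 4), rep("2021-01-01", 6))))
  s <- refresh_sequences(store, newer, source = "uniprot")
  expect_equal(s$rows_updated, 4)
})

test_that("batched runs resume from the cache after an interruption", {
  seen <- list()
  flaky_after <- function(k) {
    calls <- 0
    function(batch) {
      calls <<- calls + 1
      if (calls > k) stop("simulated network failure")
      seen[[length(seen) + 1]] <<- batch
    }
  }
  accs <- sprintf("ACC%03d.1", 1:100)
  cache <- withr::local_tempfile()
  expect_error(run_batched(flaky_after(2), accs, batch_size = 30,
                           cache = cache),
               "simulated")
  expect_equal(length(readLines(cache)), 60)   # two completed batches persist
  # resume processes exactly the remaining 40
  received <- character()
  s <- run_batched(function(b) received <<- c(received, b), accs,
                   batch_size = 30, cache = cache)
  expect_equal(s$skipped_cached, 60)
  expect_equal(s$processed, 40)
  expect_equal(received, accs[61:100])
  # resume on a completed run gives the provider nothing
  s2 <- run_batched(function(b) stop("should not be called"), accs,
                    batch_size = 30, cache = cache)
  expect_equal(s2$processed, 0)
})

test_that("batch size >= n is a single batch; unreadable cache starts fresh", {
  got <- NULL
  s <- run_batched(function(b) got <<- b, c("A.1", "B.1"), batch_size = 500,
                   cache = withr::local_tempfile())
  expect_equal(s$batches, 1)
  expect_equal(got, c("A.1", "B.1"))

  baddir <- withr::local_tempdir()   # a directory is not a readable cache
  expect_warning(
    s2 <- run_batched(function(b) NULL, c("A.1"), cache = baddir),
    "fresh")
  expect_equal(s2$skipped_cached, 0)
})
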