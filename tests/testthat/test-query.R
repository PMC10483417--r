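# Queries, writers, FASTA extraction, summaries and rollups.

enriched_store <- function(gt, env = parent.frame()) {
  store <- make_store(gt, env = env)
  attach_uniprot(store, read_snapshot(gt$files[["uniprot"]], "uniprot"))
  store
}

test_that("the default query is the sorted distinct accession list", {
  gt <- make_fixture()
  store <- make_store(gt)
  q <- cazy_query(store)
  expect_equal(names(q), "accession")
  expect_equal(nrow(q), count_cazymes(store))
  expect_equal(q$accession, sort(q$accession))
  expect_false(any(duplicated(q$accession)))
})

test_that("query row counts equal count_cazymes for any criteria", {
  gt <- make_fixture()
  store <- make_store(gt)
  crits <- list(selection_criteria(),
                selection_criteria(kingdoms = "Bacteria"),
                selection_criteria(families = "PL20"),
                selection_criteria(classes = "CE", kingdoms = "Eukaryota"))
  for (cr in crits) {
    expect_equal(nrow(cazy_query(store, cr)), count_cazymes(store, cr))
  }
})

test_that("multi-valued fields serialize comma-joined and sorted", {
  gt <- make_fixture(fixture_spec(n_multifamily_proteins = 1, rng_seed = 5))
  store <- make_store(gt)
  q <- cazy_query(store, include = c("family", "kingdom"))
  multi_acc <- gt$records |>
    dplyr::distinct(family, accession) |>
    dplyr::count(accession) |>
    dplyr::filter(n == 2) |>
    dplyr::pull(accession)
  cell <- q$family[q$accession == multi_acc[1]]
  fams <- sort(unique(gt$records$family[gt$records$accession == multi_acc[1]]))
  expect_equal(cell, paste(fams, collapse = ","))
  expect_equal(nrow(q[q$accession == multi_acc[1], ]), 1)
})

test_that("unknown include fields are a configuration error", {
  gt <- make_fixture(fixture_spec(rng_seed = 5))
  store <- make_store(gt)
  expect_error(cazy_query(store, include = "nonsense"),
               class = "cazymine_config_error")
})

test_that("ec/pdb fields surface enrichment results per accession", {
  gt <- make_fixture(fixture_spec(n_with_ec = 3, n_with_pdb = 2,
                                  rng_seed = 16))
  store <- enriched_store(gt)
  q <- cazy_query(store, include = c("ec", "pdb"))
  expect_equal(names(q), c("accession", "ec", "pdb"))
  annotated <- gt$uniprot$accession[nzchar(gt$uniprot$ec_numbers)]
  expect_true(all(!is.na(q$ec[q$accession %in% annotated])))
})

test_that("CSV and JSON writers are byte-stable and round-trip", {
  gt <- make_fixture(fixture_spec(rng_seed = 16))
  store <- make_store(gt)
  q <- cazy_query(store, include = c("family", "kingdom", "organism"))
  csv1 <- withr::local_tempfile(fileext = ".csv")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_query_csv(q, csv1); write_query_csv(q, csv2)
  expect_identical(readBin(csv1, "raw", file.size(csv1)),
                   readBin(csv2, "raw", file.size(csv2)))
  back <- readr::read_csv(csv1, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  expect_equal(tibble::as_tibble(back), q)

  js <- withr::local_tempfile(fileext = ".json")
  write_query_json(q, js)
  jback <- jsonlite::fromJSON(js)
  expect_equal(tibble::as_tibble(jback), q)

  # empty table: header-only CSV, empty JSON array
  write_query_csv(q[0, ], csv1)
  expect_equal(readLines(csv1), "accession,family,kingdom,organism")
  write_query_json(q[0, ], js)
  expect_equal(jsonlite::fromJSON(js), list())
})

test_that("fields containing commas are quoted per the CSV rules", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_query_csv(tibble::tibble(accession = "A.1", ec = "1.1.1.1,2.2.2.2"), f)
  expect_match(readLines(f)[2], "\"1.1.1.1,2.2.2.2\"")
})

test_that("FASTA export honours criteria and source, and re-parses exactly", {
  counts <- tidyr::expand_grid(family = c("GH3", "GH5"),
                               kingdom = c("Archaea", "Bacteria"))
  counts$n <- 3L
  gt <- make_fixture(fixture_spec(counts = counts, rng_seed = 17))
  store <- enriched_store(gt)
  fa <- withr::local_tempfile(fileext = ".fasta")
  res <- extract_fasta(store, fa, selection_criteria(kingdoms = "Archaea"),
                       source = "uniprot")
  seqs <- Biostrings::readAAStringSet(fa)
  ids <- sub(" .*", "", names(seqs))
  arch <- unique(gt$records$accession[gt$records$kingdom == "Archaea"])
  expect_setequal(ids, arch)
  expect_equal(res$written, length(arch))
  # sequences round-trip byte-identically
  view <- protein_view(store)
  for (i in seq_along(seqs)) {
    expect_equal(as.character(seqs[[i]]),
                 view$sequence[view$accession == ids[i]])
  }
  # nothing stored from genbank yet: empty FASTA, everything skipped
  res2 <- extract_fasta(store, fa, source = "genbank")
  expect_equal(res2$written, 0)
  expect_equal(res2$skipped_no_sequence, count_cazymes(store))
})

test_that("kingdom summaries reproduce ground truth and multi-class rules", {
  gt <- make_fixture()
  store <- make_store(gt)
  fam_sum <- summarize_kingdoms(store, by = "family")
  long <- tidyr::pivot_longer(tibble::as_tibble(fam_sum),
                              cols = -c("family", "total"),
                              names_to = "kingdom", values_to = "n") |>
    dplyr::filter(n > 0)
  merged <- dplyr::full_join(long, gt$counts, by = c("family", "kingdom"),
                             suffix = c("_obs", "_exp"))
  expect_true(all(merged$n_obs == merged$n_exp))
  # summarize cell sums: row sums equal per-family counts with conflicts
  for (f in unique(gt$counts$family)) {
    row <- long[long$family == f, ]
    per_kingdom <- sum(row$n)
    expect_equal(per_kingdom, sum(gt$counts$n[gt$counts$family == f]))
  }
})

test_that("a protein in two classes counts once per class row", {
  db <- withr::local_tempfile(fileext = ".db")
  store <- init_store(db)
  withr::defer(close_store(store))
  import_dump(store, parse_dump(
    c("GH5\tBacteria\tEscherichia coli\tAAA1.1",
      "CBM35\tBacteria\tEscherichia coli\tAAA1.1")))
  cls <- summarize_kingdoms(store, by = "class")
  expect_equal(sum(cls$total), 2)         # once per class row
  expect_equal(count_cazymes(store), 1)   # one distinct protein
  dom <- dominant_kingdoms(cls)
  expect_equal(dom$dominant_kingdom, c("Bacteria", "Bacteria"))
})

test_that("family dominance labels recover the planted majority kingdom", {
  counts <- tibble::tibble(
    family = c("AA9", "AA9", "PL20", "PL20"),
    kingdom = c("Eukaryota", "Bacteria", "Bacteria", "Eukaryota"),
    n = c(6L, 2L, 5L, 1L))
  gt <- make_fixture(fixture_spec(counts = counts, rng_seed = 18))
  store <- make_store(gt)
  dom <- dominant_kingdoms(summarize_kingdoms(store, by = "family"))
  expect_equal(dom$dominant_kingdom[dom$family == "AA9"], "Eukaryota")
  expect_equal(dom$dominant_kingdom[dom$family == "PL20"], "Bacteria")
})

test_that("lineage rollups nest child counts under parents and honour
           exclusions", {
  counts <- tibble::tibble(family = "GH3", kingdom = "Archaea", n = 8L)
  gt <- make_fixture(fixture_spec(counts = counts, n_candidatus = 2,
                                  rng_seed = 19))
  store <- make_store(gt)
  attach_ncbi_lineage(store, read_snapshot(gt$files[["ncbi_tax"]],
                                           "ncbi_tax"))
  roll <- lineage_rollup(store, "Archaea")
  phyla <- roll[roll$rank == "phylum", ]
  fams <- roll[roll$rank == "family", ]
  # child counts sum to parent counts (no exclusions at inner ranks)
  for (p in phyla$name) {
    kids <- roll[roll$rank == "class" & roll$parent == p, ]
    expect_equal(sum(kids$n), phyla$n[phyla$name == p])
  }
  with_cand <- lineage_rollup(store, "Archaea", exclude_candidatus = FALSE)
  expect_equal(sum(with_cand$n[with_cand$rank == "phylum"]),
               sum(phyla$n) + 2)

  # an all-candidatus store rolls up empty under exclusion
  lin <- DBI::dbGetQuery(store$con, "SELECT COUNT(*) n FROM ncbi_lineages
                                     WHERE candidatus = 1")
  expect_equal(lin$n, 2)
})
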