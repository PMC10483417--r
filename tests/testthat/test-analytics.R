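# Representation rates, chi-squared decomposition, BSR, redundancy,
# clustering, structural coverage.

test_that("representation rates reproduce the published kingdom percentages", {
  rates <- representation_rates(species_census())
  get <- function(k, col) rates[[col]][rates$kingdom == k]
  expect_equal(get("Archaea", "pct_ge1"), 5.23)
  expect_equal(get("Bacteria", "pct_ge1"), 3.02)
  expect_equal(get("Eukaryota", "pct_ge1"), 0.96)
  expect_equal(get("Viruses", "pct_ge1"), 1.35)
  expect_equal(get("Archaea", "pct_ge50"), 0.86)
  expect_equal(get("Bacteria", "pct_ge50"), 1.30)
  expect_equal(get("Eukaryota", "pct_ge50"), 0.03)
  expect_equal(get("Total", "pct_ge1"), 1.50)
  expect_equal(get("Total", "pct_ge50"), 0.34)
  expect_equal(get("Total", "species_total"), 1954393)
})

test_that("rate edge cases: zero totals, impossible counts", {
  z <- representation_rates(tibble::tibble(
    kingdom = "Viruses", species_total = 100, n_ge1 = 0, n_ge50 = 0))
  expect_equal(z$pct_ge1, c(0, 0))
  expect_error(representation_rates(tibble::tibble(
    kingdom = "X", species_total = 0, n_ge1 = 1, n_ge50 = 0)))
  expect_error(representation_rates(tibble::tibble(
    kingdom = "X", species_total = 10, n_ge1 = 2, n_ge50 = 5)))
})

test_that("half-up rounding matches the published convention", {
  expect_equal(round_half_up(1.2999, 2), 1.30)
  expect_equal(round_half_up(0.8577, 2), 0.86)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("the chi-squared statistic matches the brute-force formula and
           stats::chisq.test on random tables", {
  set.seed(2209)
  for (i in 1:50) {
    nr <- sample(2:5, 1); nc <- sample(2:6, 1)
    O <- matrix(rpois(nr * nc, lambda = 40) + 1, nr, nc)
    d <- chisq_decompose(O)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(d$statistic, sum((O - E)^2 / E))       # brute force
    ct <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
    expect_equal(d$statistic, unname(ct$statistic))     # independent route
    expect_equal(d$p_value, ct$p.value)
    expect_equal(unname(d$residuals), unname(ct$residuals),
                 tolerance = 1e-12)
    expect_equal(sum(d$explained), 100, tolerance = 1e-9)
  }
})

test_that("goodness-of-fit mode uses E = N p and df = k - 1", {
  d <- chisq_decompose(c(10, 20), expected_probs = c(0.5, 0.5))
  expect_equal(unname(d$expected[1, ]), c(15, 15))
  expect_equal(d$statistic, 25 / 15 + 25 / 15)
  expect_equal(d$dof, 1L)
  ct <- stats::chisq.test(c(10, 20), p = c(0.5, 0.5))
  expect_equal(d$p_value, ct$p.value)
  # expected marginals match observed marginals in homogeneity mode
  d2 <- chisq_decompose(c(12, 30, 8), reference_counts = c(20, 25, 15))
  expect_equal(rowSums(d2$expected), rowSums(d2$observed))
  expect_equal(colSums(d2$expected), colSums(d2$observed))
})

test_that("degenerate chi-squared inputs raise domain errors", {
  expect_error(chisq_decompose(c(15, 15), expected_probs = c(0.5, 0.5)),
               "degenerate")
  expect_error(chisq_decompose(c(5, 0), reference_counts = c(5, 0)),
               "pool")
  expect_error(chisq_decompose(c(-1, 2), expected_probs = c(0.5, 0.5)))
})

test_that("tidy and glance expose the decomposition tables", {
  d <- chisq_decompose(matrix(c(10, 20, 30, 25), 2))
  td <- tidy(d)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$explained_pct), 100)
  g <- glance(d)
  expect_equal(g$statistic, d$statistic)
  expect_equal(g$n_cells, 4)
})

test_that("BSR is 1 on the diagonal and for identical sequences", {
  s <- random_protein(80, seed = 31)
  m <- bsr_matrix(c(A.1 = s, B.1 = s, C.1 = random_protein(80)))
  expect_equal(unname(diag(m$bsr)), c(1, 1, 1))
  expect_equal(m$bsr["A.1", "B.1"], 1)
  expect_true(all(m$bsr >= 0 & m$bsr <= 1))
})

test_that("random length-60 pairs stay below the unrelatedness bound", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    a <- random_protein(60); b <- random_protein(60)
    m <- bsr_matrix(c(A.1 = a, B.1 = b))
    expect_lt(m$bsr["A.1", "B.1"], 0.35)
    expect_lt(m$bsr["B.1", "A.1"], 0.35)
  }
})

test_that("BSR is invariant under scaling of the raw scores", {
  seqs <- setNames(sapply(c(60, 80, 100), random_protein),
                   c("A.1", "B.1", "C.1"))
  set.seed(77)
  base <- bsr_matrix(seqs)
  scaled <- bsr_matrix(seqs, scorer = function(a, b)
    7.5 * local_alignment_score(a, b))
  expect_equal(base$bsr, scaled$bsr)
})

test_that("external score tables replace the scorer; zero self-score errors", {
  scores <- tibble::tibble(
    query = c("A.1", "A.1", "B.1", "B.1"),
    subject = c("A.1", "B.1", "B.1", "A.1"),
    score = c(100, 40, 80, 40))
  m <- bsr_matrix(c(A.1 = "MKV", B.1 = "MKW"), scores = scores)
  expect_equal(m$bsr["A.1", "B.1"], 0.4)
  expect_equal(m$bsr["B.1", "A.1"], 0.5)   # asymmetric by construction
  expect_error(bsr_matrix(c(A.1 = "MKV"),
                          scores = tibble::tibble(query = "A.1",
                                                  subject = "A.1",
                                                  score = 0)),
               class = "cazymine_domain_error")
  expect_error(bsr_matrix(c(A.1 = "")), "Empty")
})

test_that("redundancy detection equals the brute-force all-pairs oracle", {
  set.seed(55)
  pool <- replicate(40, random_protein(30))
  seqs <- setNames(sample(pool, 200, replace = TRUE),
                   sprintf("SYN%03d.1", 1:200))
  found <- find_redundant_pairs(seqs)
  # brute force over all unordered pairs
  oracle <- list()
  accs <- names(seqs)
  for (i in 1:199) for (j in (i + 1):200) {
    if (seqs[[i]] == seqs[[j]]) {
      p <- sort(c(accs[i], accs[j]))
      oracle[[length(oracle) + 1]] <- paste(p, collapse = "|")
    }
  }
  expect_setequal(paste(found$accession_a, found$accession_b, sep = "|"),
                  unlist(oracle))
})

test_that("redundant pair combinatorics and annotations are right", {
  s <- random_protein(40, seed = 9)
  trip <- find_redundant_pairs(c(B.1 = s, A.1 = s, WP_1.1 = s))
  expect_equal(nrow(trip), 3)   # triple-identical -> all 3 pairs
  expect_true(all(trip$accession_a < trip$accession_b))
  expect_equal(trip$kind_b[trip$accession_b == "WP_1.1"],
               c("refseq", "refseq"))
  expect_equal(nrow(find_redundant_pairs(c(A.1 = "MKV", B.1 = "MKW"))), 0)
})

test_that("planted clusters are recovered exactly at the survey thresholds", {
  spec <- fixture_spec(cluster_sizes = c(4, 3, 3), within_identity = 0.9,
                       between_identity = 0.2, rng_seed = 21)
  gt <- make_fixture(spec)
  cl <- greedy_cluster(gt$sequences[gt$clusters$accession],
                       identity_threshold = 0.4, coverage_threshold = 0.8)
  expect_equal(length(unique(cl$cluster)), 3)
  # same partition as planted
  canon <- function(p) sort(vapply(p, function(x)
    paste(sort(x), collapse = ","), ""))
  expect_equal(canon(split(cl$accession, cl$cluster)),
               canon(split(gt$clusters$accession, gt$clusters$cluster)),
               ignore_attr = TRUE)
})

test_that("clustering limits: all-identical collapses, strict thresholds
           isolate", {
  s <- random_protein(60, seed = 23)
  all_same <- greedy_cluster(c(A.1 = s, B.1 = s, C.1 = s))
  expect_equal(length(unique(all_same$cluster)), 1)
  set.seed(24)
  distinct <- setNames(sapply(c(60, 70, 80), random_protein),
                       c("A.1", "B.1", "C.1"))
  strict <- greedy_cluster(distinct, 1.0, 1.0)
  expect_equal(length(unique(strict$cluster)), 3)
})

test_that("clusters partition the input and grow monotonically with the
           identity threshold", {
  gt <- make_fixture(fixture_spec(cluster_sizes = c(4, 3, 3),
                                  rng_seed = 25))
  seqs <- gt$sequences[gt$clusters$accession]
  prev <- 0
  for (thr in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
    cl <- greedy_cluster(seqs, thr, 0.8)
    expect_setequal(cl$accession, names(seqs))       # partition: covers input
    expect_false(any(duplicated(cl$accession)))      # ... disjointly
    n <- length(unique(cl$cluster))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("cluster TSVs round-trip through the interchange format", {
  gt <- make_fixture(fixture_spec(cluster_sizes = c(3, 2), rng_seed = 26))
  cl <- greedy_cluster(gt$sequences[gt$clusters$accession])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_tsv(cl, f)
  back <- read_cluster_tsv(f)
  expect_equal(tibble::as_tibble(back)[, c("accession", "cluster",
                                           "representative")],
               tibble::as_tibble(cl)[, c("accession", "cluster",
                                         "representative")],
               ignore_attr = TRUE)
})

test_that("structural coverage counts per family and flags clusters", {
  gt <- make_fixture(fixture_spec(n_with_pdb = 4, cluster_sizes = c(4, 3, 3),
                                  rng_seed = 27))
  store <- make_store(gt)
  attach_uniprot(store, read_snapshot(gt$files[["uniprot"]], "uniprot"))
  clusters <- greedy_cluster(gt$sequences[gt$clusters$accession], 0.4, 0.8)
  cov <- structural_coverage(store, clusters = clusters)
  # per-family totals mirror ground truth counts
  fam_totals <- gt$records |>
    dplyr::distinct(family, accession) |>
    dplyr::mutate(family = sub("_\\d+$", "", family)) |>
    dplyr::distinct() |>
    dplyr::count(family)
  merged <- dplyr::inner_join(cov$families, fam_totals, by = "family")
  expect_equal(merged$n_members, merged$n)
  expect_equal(cov$totals$n_members, sum(cov$families$n_members))
  expect_equal(cov$totals$n_with_pdb, sum(cov$families$n_with_pdb))
  # the planted PDB annotations land on the first snapshot accessions
  with_pdb_acc <- gt$uniprot$accession[nzchar(gt$uniprot$pdb_ids)]
  expect_equal(cov$totals$n_with_pdb, length(with_pdb_acc))
  flagged <- cov$clusters$has_structure
  members <- split(clusters$accession, clusters$cluster)
  expect_equal(flagged,
               unname(vapply(members[cov$clusters$cluster], function(m)
                 any(m %in% with_pdb_acc), TRUE)))
})

test_that("no structure links anywhere gives all zeros and all-false flags", {
  gt <- make_fixture(fixture_spec(cluster_sizes = c(3, 2), rng_seed = 28))
  store <- make_store(gt)
  clusters <- greedy_cluster(gt$sequences[gt$clusters$accession])
  cov <- structural_coverage(store, clusters = clusters)
  expect_equal(cov$totals$n_with_pdb, 0)
  expect_false(any(cov$clusters$has_structure))
})

test_that("discrepancy lists compare UniProt links with external annotations", {
  gt <- make_fixture(fixture_spec(n_with_pdb = 3, rng_seed = 29))
  store <- make_store(gt)
  attach_uniprot(store, read_snapshot(gt$files[["uniprot"]], "uniprot"))
  with_pdb <- gt$uniprot$accession[nzchar(gt$uniprot$pdb_ids)]
  annotated <- c(with_pdb[1], "SYN99999.1")   # one overlap, one extra
  cov <- structural_coverage(store, annotated_structured = annotated)
  expect_equal(cov$annotated_not_in_pdb_links, "SYN99999.1")
  expect_setequal(cov$pdb_links_not_annotated, setdiff(with_pdb, annotated))
})

test_that("the CE structural census sums to the published class totals", {
  census <- ce_structure_census()
  expect_equal(nrow(census), 20)
  expect_equal(sum(census$total_cazymes), 104844)
  expect_equal(sum(census$with_pdb), 101)
})
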