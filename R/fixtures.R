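# Deterministic synthetic fixtures: a complete, internally consistent set
# of input files (dump + snapshots + FASTA) with known ground truth, so
# the whole pipeline can be exercised end to end without network access.
# Generation is a pure function of the FixtureSpec: same spec (including
# seed) => byte-identical files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ORGANISM_POOL <- list(
  Bacteria = c("Streptomyces coelicolor", "Bacillus subtilis",
               "Escherichia coli", "Cellvibrio japonicus"),
  Eukaryota = c("Trichoderma reesei", "Aspergillus flavus",
                "Saccharomyces cerevisiae"),
  Archaea = c("Methanococcus maripaludis", "Sulfolobus acidocaldarius"),
  Viruses = c("Chlorovirus PBCV1"),
  unclassified = c("uncultured organism")
)

#' Specify a synthetic fixture
#'
#' A fixture spec fixes every knob of the generated dataset: per
#' (family, kingdom) record counts, planted multi-family proteins,
#' planted redundant GenBank/RefSeq sequence pairs, planted multi-taxon
#' (cross-kingdom) conflicts, a sequence-cluster plan, snapshot coverage
#' and flagged-lineage counts, and the RNG seed.
#'
#' @param counts Tibble with columns `family`, `kingdom`, `n` (records to
#'   generate per pair). The default plants three families across two
#'   kingdoms with four records each.
#' @param n_multifamily_proteins Proteins that absorb one extra family
#'   link each (reducing the distinct-protein count accordingly).
#' @param n_redundant_pairs Identical-sequence pairs catalogued under a
#'   GenBank accession plus a planted RefSeq twin.
#' @param n_multitaxon_conflicts Proteins additionally reported from a
#'   second organism in a different kingdom.
#' @param cluster_sizes Integer vector: sizes of planted sequence
#'   clusters (empty for none).
#' @param within_identity,between_identity Target pairwise amino-acid
#'   identities inside a planted cluster and between cluster seeds, in
#'   `[0, 1]`.
#' @param uniprot_coverage,assembly_coverage Fraction of proteins present
#'   in the UniProt-like / assembly snapshots.
#' @param n_with_ec,n_with_pdb UniProt snapshot entries carrying EC
#'   numbers / PDB ids.
#' @param n_candidatus,n_incomplete NCBI lineages flagged *Candidatus* /
#'   truncated before species.
#' @param seq_length Base sequence length.
#' @param rng_seed Integer seed; fixes every random draw.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(counts = NULL,
                         n_multifamily_proteins = 0,
                         n_redundant_pairs = 0,
                         n_multitaxon_conflicts = 0,
                         cluster_sizes = integer(),
                         within_identity = 0.9,
                         between_identity = 0.2,
                         uniprot_coverage = 1,
                         assembly_coverage = 1,
                         n_with_ec = 0,
                         n_with_pdb = 0,
                         n_candidatus = 0,
                         n_incomplete = 0,
                         seq_length = 150,
                         rng_seed = 1) {
  if (is.null(counts)) {
    counts <- tidyr::expand_grid(family = c("GH5", "PL20", "CE12"),
                                 kingdom = c("Bacteria", "Eukaryota"))
    counts$n <- 4L
  }
  stopifnot(all(c("family", "kingdom", "n") %in% names(counts)),
            all(counts$n >= 0),
            n_multifamily_proteins >= 0, n_redundant_pairs >= 0,
            n_multitaxon_conflicts >= 0,
            within_identity >= 0, within_identity <= 1,
            between_identity >= 0, between_identity <= 1,
            uniprot_coverage >= 0, uniprot_coverage <= 1)
  parse_family_label(unique(counts$family))  # validate labels
  counts$kingdom <- canonical_kingdom(counts$kingdom, warn = FALSE)
  structure(list(
    counts = tibble::as_tibble(counts),
    n_multifamily_proteins = as.integer(n_multifamily_proteins),
    n_redundant_pairs = as.integer(n_redundant_pairs),
    n_multitaxon_conflicts = as.integer(n_multitaxon_conflicts),
    cluster_sizes = as.integer(cluster_sizes),
    within_identity = within_identity,
    between_identity = between_identity,
    uniprot_coverage = uniprot_coverage,
    assembly_coverage = assembly_coverage,
    n_with_ec = as.integer(n_with_ec),
    n_with_pdb = as.integer(n_with_pdb),
    n_candidatus = as.integer(n_candidatus),
    n_incomplete = as.integer(n_incomplete),
    seq_length = as.integer(seq_length),
    rng_seed = as.integer(rng_seed)
  ), class = "fixture_spec")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Mutate a fraction of positions to a different residue; expected identity
# to the input is 1 - rate.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  k <- round(length(chars) * rate)
  if (k == 0) return(seq)
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos],
                       function(c) sample(setdiff(AA20, c), 1), "")
  paste(chars, collapse = "")
}

#' Generate a synthetic fixture with ground truth
#'
#' Writes `dump.tsv`, `uniprot.tsv`, `ncbi_tax.tsv`, `gtdb_tax.tsv`,
#' `assembly.tsv` and `sequences.fasta` under `out_dir` and returns the
#' ground-truth tables the generator planted. Re-running with the same
#' spec reproduces the files byte for byte.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `fixture_ground_truth`:
#'   `records` (final dump tibble), `unique_proteins`,
#'   `counts` (distinct accessions per family x kingdom),
#'   `redundant_pairs`, `conflicts`, `clusters` (`accession`, `cluster`),
#'   `sequences` (named vector), `uniprot` / `ncbi_tax` / `gtdb_tax` /
#'   `assembly` (snapshot tibbles as written) and `files` (paths).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create ", sQuote(out_dir)),
                   class = "cazymine_io_error")
  }
  withr::with_seed(spec$rng_seed, generate_fixture_impl(spec, out_dir))
}

generate_fixture_impl <- function(spec, out_dir) {
  plan <- spec$counts[spec$counts$n > 0, , drop = FALSE]
  plan <- plan[order(plan$family, plan$kingdom), , drop = FALSE]

  # --- base records -------------------------------------------------------
  records <- purrr::pmap_dfr(plan, function(family, kingdom, n) {
    pool <- ORGANISM_POOL[[kingdom]]
    base <- pool[((seq_len(n) - 1) %% length(pool)) + 1]
    round <- ((seq_len(n) - 1) %/% length(pool)) + 1
    organisms <- ifelse(round == 1, base, paste0(base, " STR", round))
    tibble::tibble(family = family, kingdom = kingdom, organism = organisms)
  })
  records$accession <- sprintf("SYN%05d.1", seq_len(nrow(records)))

  # --- multi-family proteins: record i of one family absorbs the slot of a
  # record in another family (same kingdom), keeping per-family x kingdom
  # distinct counts intact while reducing the distinct-protein total ------
  if (spec$n_multifamily_proteins > 0) {
    planted <- 0L
    for (kg in unique(records$kingdom)) {
      fams_k <- unique(records$family[records$kingdom == kg])
      if (length(fams_k) < 2) next
      donors <- which(records$kingdom == kg & records$family == fams_k[1])
      targets <- which(records$kingdom == kg & records$family == fams_k[2])
      m <- min(length(donors), length(targets),
               spec$n_multifamily_proteins - planted)
      if (m <= 0) next
      for (t in seq_len(m)) {
        # the target record's slot is absorbed by the donor protein, which
        # thereby belongs to two families; per-family distinct counts are
        # unchanged, the distinct-protein total drops by one
        records$accession[targets[t]] <- records$accession[donors[t]]
        records$organism[targets[t]] <- records$organism[donors[t]]
      }
      planted <- planted + m
      if (planted >= spec$n_multifamily_proteins) break
    }
    if (planted < spec$n_multifamily_proteins) {
      abort("Could not plant the requested number of multi-family proteins
             (need two families sharing a kingdom with enough records).")
    }
  }

  base_acc <- unique(records$accession)

  # --- sequences ----------------------------------------------------------
  sequences <- setNames(rep(NA_character_, length(base_acc)), base_acc)
  clusters <- tibble::tibble(accession = character(), cluster = integer())
  if (length(spec$cluster_sizes) > 0) {
    need <- sum(spec$cluster_sizes)
    if (need > length(base_acc)) {
      abort("Cluster plan needs more proteins than the fixture generates.")
    }
    member_acc <- base_acc[seq_len(need)]
    ancestor <- random_aa(spec$seq_length)
    # seeds diverge from a common ancestor so between-cluster identity is
    # controlled; members diverge from their seed
    idx <- 0L
    for (k in seq_along(spec$cluster_sizes)) {
      seed_seq <- mutate_seq(ancestor, (1 - spec$between_identity) / 1.6)
      for (m in seq_len(spec$cluster_sizes[k])) {
        idx <- idx + 1L
        acc <- member_acc[idx]
        # each member at half the within divergence from the seed, so
        # member-member identity ~= within_identity
        sequences[[acc]] <- mutate_seq(seed_seq,
                                       (1 - spec$within_identity) / 2)
        clusters <- dplyr::bind_rows(clusters,
          tibble::tibble(accession = acc, cluster = k))
      }
    }
  }
  for (acc in names(sequences)[is.na(sequences)]) {
    sequences[[acc]] <- random_aa(spec$seq_length +
                                    sample.int(40, 1) - 20L)
  }

  # --- redundant GenBank/RefSeq pairs ------------------------------------
  redundant_pairs <- tibble::tibble(accession_a = character(),
                                    accession_b = character())
  if (spec$n_redundant_pairs > 0) {
    non_cluster <- setdiff(base_acc, clusters$accession)
    source_acc <- head(non_cluster, spec$n_redundant_pairs)
    if (length(source_acc) < spec$n_redundant_pairs) {
      abort("Not enough non-cluster proteins to plant redundant pairs.")
    }
    twins <- sprintf("WP_%06d.1", seq_along(source_acc))
    for (i in seq_along(source_acc)) {
      src_rows <- records[records$accession == source_acc[i], ][1, ]
      records <- dplyr::bind_rows(records, dplyr::mutate(
        src_rows, accession = twins[i]))
      sequences[[twins[i]]] <- sequences[[source_acc[i]]]
    }
    pair_mat <- t(mapply(function(a, b) sort(c(a, b)), source_acc, twins))
    redundant_pairs <- tibble::tibble(accession_a = pair_mat[, 1],
                                      accession_b = pair_mat[, 2])
    redundant_pairs <- dplyr::arrange(redundant_pairs, .data$accession_a)
  }

  # --- multi-taxon (cross-kingdom) conflicts ------------------------------
  conflicts <- tibble::tibble(accession = character(),
                              kingdom_a = character(),
                              kingdom_b = character())
  if (spec$n_multitaxon_conflicts > 0) {
    cand <- records[!duplicated(records$accession), , drop = FALSE]
    cand <- head(cand[order(cand$accession), ], spec$n_multitaxon_conflicts)
    if (nrow(cand) < spec$n_multitaxon_conflicts) {
      abort("Not enough proteins to plant the requested conflicts.")
    }
    other_kingdom <- vapply(cand$kingdom, function(k) {
      setdiff(c("Archaea", "Bacteria", "Eukaryota"), k)[1]
    }, "", USE.NAMES = FALSE)
    # the conflicting organism is reported for every family of the protein,
    # so each protein's records stay a full family x taxon product
    extra <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
      fams <- unique(records$family[records$accession == cand$accession[i]])
      tibble::tibble(
        family = fams,
        kingdom = other_kingdom[i],
        organism = paste(ORGANISM_POOL[[other_kingdom[i]]][1], "CONFL"),
        accession = cand$accession[i])
    })
    records <- dplyr::bind_rows(records, extra)
    conflicts <- tibble::tibble(accession = cand$accession,
                                kingdom_a = cand$kingdom,
                                kingdom_b = other_kingdom)
  }

  all_acc <- unique(records$accession)

  # --- snapshots ----------------------------------------------------------
  n_up <- round(spec$uniprot_coverage * length(all_acc))
  up_acc <- head(all_acc, n_up)
  uniprot <- tibble::tibble(
    accession = up_acc,
    uniprot_id = sprintf("U%05d", seq_along(up_acc)),
    protein_name = paste("synthetic CAZyme", seq_along(up_acc)),
    ec_numbers = "",
    pdb_ids = "",
    sequence = unname(sequences[up_acc]),
    version_date = "2022-04-01")
  ec_pool <- c("4.2.2.14", "3.1.1.72", "3.2.1.4", "3.1.1.-")
  if (spec$n_with_ec > 0) {
    k <- min(spec$n_with_ec, nrow(uniprot))
    uniprot$ec_numbers[seq_len(k)] <-
      ec_pool[((seq_len(k) - 1) %% length(ec_pool)) + 1]
  }
  if (spec$n_with_pdb > 0) {
    k <- min(spec$n_with_pdb, nrow(uniprot))
    uniprot$pdb_ids[seq_len(k)] <- sprintf("%dABC", (seq_len(k) %% 9) + 1)
  }

  first_taxon <- records[!duplicated(records$accession), ]
  ncbi_tax <- tibble::tibble(
    accession = first_taxon$accession,
    lineage = purrr::map2_chr(first_taxon$kingdom, first_taxon$organism,
                              synth_lineage))
  if (spec$n_incomplete > 0) {
    k <- min(spec$n_incomplete, nrow(ncbi_tax))
    ncbi_tax$lineage[seq_len(k)] <- purrr::map_chr(
      strsplit(ncbi_tax$lineage[seq_len(k)], ";", fixed = TRUE),
      ~ paste(head(.x, 4), collapse = ";"))
  }
  if (spec$n_candidatus > 0) {
    lo <- spec$n_incomplete + 1
    hi <- min(spec$n_incomplete + spec$n_candidatus, nrow(ncbi_tax))
    if (hi >= lo) {
      ncbi_tax$lineage[lo:hi] <- sub("^([^;]*);([^;]*)",
                                     "\\1;Candidatus \\2",
                                     ncbi_tax$lineage[lo:hi])
    }
  }

  org_assembly <- dplyr::distinct(first_taxon, .data$organism)
  org_assembly$assembly <- sprintf("GCA_%06d.1", seq_len(nrow(org_assembly)))
  assembly <- dplyr::left_join(first_taxon[, c("accession", "organism")],
                               org_assembly, by = "organism")
  n_as <- round(spec$assembly_coverage * nrow(assembly))
  assembly <- head(assembly[, c("accession", "assembly")], n_as)

  gtdb_rows <- dplyr::distinct(
    dplyr::inner_join(assembly, first_taxon[, c("accession", "kingdom",
                                                "organism")],
                      by = "accession"),
    .data$assembly, .data$kingdom, .data$organism)
  gtdb_tax <- tibble::tibble(
    assembly = gtdb_rows$assembly,
    lineage = purrr::map2_chr(gtdb_rows$kingdom, gtdb_rows$organism,
                              synth_lineage))

  # --- write files --------------------------------------------------------
  files <- c(dump = file.path(out_dir, "dump.tsv"),
             uniprot = file.path(out_dir, "uniprot.tsv"),
             ncbi_tax = file.path(out_dir, "ncbi_tax.tsv"),
             gtdb_tax = file.path(out_dir, "gtdb_tax.tsv"),
             assembly = file.path(out_dir, "assembly.tsv"),
             fasta = file.path(out_dir, "sequences.fasta"))
  write_dump(records, files[["dump"]])
  readr::write_tsv(uniprot, files[["uniprot"]], progress = FALSE)
  readr::write_tsv(ncbi_tax, files[["ncbi_tax"]], progress = FALSE)
  readr::write_tsv(gtdb_tax, files[["gtdb_tax"]], progress = FALSE)
  readr::write_tsv(assembly, files[["assembly"]], progress = FALSE)
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)),
             files[["fasta"]])

  counts <- records |>
    dplyr::distinct(.data$family, .data$kingdom, .data$accession) |>
    dplyr::count(.data$family, .data$kingdom)

  structure(list(
    records = tibble::as_tibble(records),
    unique_proteins = length(all_acc),
    counts = counts,
    redundant_pairs = redundant_pairs,
    conflicts = conflicts,
    clusters = clusters,
    sequences = sequences,
    uniprot = uniprot,
    ncbi_tax = ncbi_tax,
    gtdb_tax = gtdb_tax,
    assembly = assembly,
    files = files
  ), class = "fixture_ground_truth")
}

# Deterministic synthetic lineage for one organism.
synth_lineage <- function(kingdom, organism) {
  genus <- split_organism(organism)$genus
  paste(c(kingdom,
          paste0(substr(genus, 1, 3), "ota"),
          paste0(substr(genus, 1, 3), "ia"),
          paste0(substr(genus, 1, 3), "ales"),
          paste0(substr(genus, 1, 3), "aceae"),
          genus,
          organism_binomial(organism)),
        collapse = ";")
}
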