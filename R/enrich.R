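# Enrichment: attach annotations from offline snapshot providers to the
# proteins already in the store. All operations are idempotent and
# filter-respecting — proteins outside the criteria are untouched.

enrich_summary <- function(hits = 0, misses = 0, rows_added = 0,
                           rows_updated = 0, unlinkable = 0) {
  tibble::tibble(hits = hits, misses = misses, rows_added = rows_added,
                 rows_updated = rows_updated, unlinkable = unlinkable)
}

insert_links <- function(con, table, cols, df) {
  if (nrow(df) == 0) return(0L)
  before <- DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", table))$n
  DBI::dbExecute(con, paste0(
    "INSERT OR IGNORE INTO ", table, " (", paste(cols, collapse = ", "),
    ") VALUES (", paste0(":", cols, collapse = ", "), ")"),
    params = as.list(df[, cols]))
  DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", table))$n - before
}

#' Attach UniProt annotations from a snapshot
#'
#' For every stored protein matching the criteria, looks up its accession
#' in a UniProt-style snapshot and writes the requested annotation fields:
#' UniProt id + protein name (`"name"`), EC-number links (`"ec"`), PDB-id
#' links (`"pdb"`) and/or the amino-acid sequence (`"sequence"`, recorded
#' with source `uniprot` and the snapshot's version date). Accessions
#' absent from the snapshot are counted as misses, never errors.
#'
#' @param store A `cazy_store`.
#' @param snapshot Tibble from `read_snapshot(kind = "uniprot")`.
#' @param criteria Optional [selection_criteria()].
#' @param fields Subset of `c("name", "ec", "pdb", "sequence")`.
#' @return An `EnrichSummary` tibble: `hits`, `misses`, `rows_added`,
#'   `rows_updated`, `unlinkable`.
#' @export
attach_uniprot <- function(store, snapshot, criteria = NULL,
                           fields = c("name", "ec", "pdb", "sequence")) {
  stopifnot(inherits(store, "cazy_store"))
  fields <- match.arg(fields, several.ok = TRUE)
  check_snapshot(snapshot, "uniprot")
  acc <- matching_accessions(store, criteria)
  hit_rows <- snapshot[match(acc, snapshot$accession), ]
  found <- !is.na(hit_rows$accession)
  hits <- hit_rows[found, , drop = FALSE]
  added <- 0L
  updated <- 0L
  con <- store$con
  DBI::dbWithTransaction(con, {
    if (nrow(hits) > 0) {
      if ("name" %in% fields) {
        added <- added + insert_links(con, "uniprot_links",
          c("accession", "uniprot_id", "protein_name"),
          dplyr::filter(hits[, c("accession", "uniprot_id", "protein_name")],
                        !is.na(.data$uniprot_id)))
      }
      if ("ec" %in% fields) {
        ec_df <- tidyr::unnest(hits[, c("accession", "ec_numbers")],
                               "ec_numbers")
        names(ec_df) <- c("accession", "ec")
        added <- added + insert_links(con, "ec_links", c("accession", "ec"),
                                      ec_df)
      }
      if ("pdb" %in% fields) {
        pdb_df <- tidyr::unnest(hits[, c("accession", "pdb_ids")], "pdb_ids")
        names(pdb_df) <- c("accession", "pdb")
        added <- added + insert_links(con, "pdb_links", c("accession", "pdb"),
                                      pdb_df)
      }
      if ("sequence" %in% fields) {
        updated <- updated + write_sequences(con, hits, source = "uniprot",
                                             only_newer = FALSE)
      }
    }
  })
  log_retrieval(store, "uniprot", criteria, rows_added = added,
                rows_updated = updated)
  enrich_summary(hits = nrow(hits), misses = sum(!found),
                 rows_added = added, rows_updated = updated)
}

# Write sequences for snapshot rows that have one. only_newer = TRUE keeps
# the stored sequence unless the snapshot's version date is strictly newer
# (accession version integer breaks date ties).
write_sequences <- function(con, rows, source, only_newer) {
  rows <- rows[!is.na(rows$sequence) & nzchar(rows$sequence), , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  if (any(!grepl("^[A-Za-z*]+$", rows$sequence))) {
    abort("Snapshot sequences must be plain amino-acid strings.",
          class = "cazymine_format_error")
  }
  stored <- DBI::dbGetQuery(con, paste0(
    "SELECT accession, sequence, sequence_version_date FROM proteins ",
    "WHERE accession IN (",
    paste(DBI::dbQuoteString(con, rows$accession), collapse = ","), ")"))
  m <- match(rows$accession, stored$accession)
  new_date <- as.Date(rows$version_date)
  old_date <- as.Date(stored$sequence_version_date[m])
  if (only_newer) {
    do_write <- is.na(stored$sequence[m]) | is.na(old_date) |
      (!is.na(new_date) & new_date > old_date)
  } else {
    do_write <- is.na(stored$sequence[m]) | is.na(old_date) |
      (!is.na(new_date) & new_date >= old_date)
  }
  do_write[is.na(do_write)] <- FALSE
  rows <- rows[do_write, , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  # skip writes that change nothing, so idempotence is literal
  m2 <- match(rows$accession, stored$accession)
  same <- !is.na(stored$sequence[m2]) &
    stored$sequence[m2] == rows$sequence &
    !is.na(stored$sequence_version_date[m2]) &
    !is.na(rows$version_date) &
    as.Date(stored$sequence_version_date[m2]) == as.Date(rows$version_date)
  rows <- rows[!same, , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  DBI::dbExecute(con,
    "UPDATE proteins SET sequence = :sequence, sequence_source = :src,
            sequence_version_date = :vd WHERE accession = :accession",
    params = list(sequence = rows$sequence,
                  src = rep(source, nrow(rows)),
                  vd = as.character(rows$version_date),
                  accession = rows$accession))
  nrow(rows)
}

check_snapshot <- function(snapshot, kind) {
  need <- switch(kind,
                 uniprot = c("accession", "uniprot_id", "ec_numbers",
                             "pdb_ids", "sequence"),
                 ncbi_tax = c("accession", LINEAGE_RANKS),
                 gtdb_tax = c("assembly", LINEAGE_RANKS),
                 assembly = c("accession", "assembly"),
                 sequence = c("accession", "sequence", "version_date"))
  if (!all(need %in% names(snapshot))) {
    abort(paste0("Snapshot does not look like a ", kind, " snapshot ",
                 "(missing: ",
                 paste(setdiff(need, names(snapshot)), collapse = ", "), ")"),
          class = "cazymine_format_error")
  }
  invisible(TRUE)
}

#' Attach NCBI-taxonomy lineages from a snapshot
#'
#' Stores the rank-wise lineage (kingdom ... species) for every matching
#' protein found in the snapshot, together with the `incomplete` and
#' `candidatus` flags, which are retained in the store so that rollups can
#' exclude them later.
#'
#' @inheritParams attach_uniprot
#' @param tax_snapshot Tibble from `read_snapshot(kind = "ncbi_tax")`.
#' @return An `EnrichSummary` tibble.
#' @export
attach_ncbi_lineage <- function(store, tax_snapshot, criteria = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  check_snapshot(tax_snapshot, "ncbi_tax")
  acc <- matching_accessions(store, criteria)
  rows <- tax_snapshot[match(acc, tax_snapshot$accession), ]
  found <- !is.na(rows$accession)
  rows <- rows[found, , drop = FALSE]
  added <- 0L
  if (nrow(rows) > 0) {
    added <- DBI::dbWithTransaction(store$con, {
      before <- store_count(store, "ncbi_lineages")
      DBI::dbExecute(store$con,
        "INSERT INTO ncbi_lineages (accession, kingdom, phylum, class,
           \"order\", family, genus, species, incomplete, candidatus)
         VALUES (:accession, :kingdom, :phylum, :class, :order, :family,
                 :genus, :species, :incomplete, :candidatus)
         ON CONFLICT(accession) DO UPDATE SET
           kingdom = excluded.kingdom, phylum = excluded.phylum,
           class = excluded.class, \"order\" = excluded.\"order\",
           family = excluded.family, genus = excluded.genus,
           species = excluded.species, incomplete = excluded.incomplete,
           candidatus = excluded.candidatus",
        params = list(accession = rows$accession, kingdom = rows$kingdom,
                      phylum = rows$phylum, class = rows$class,
                      order = rows$order, family = rows$family,
                      genus = rows$genus, species = rows$species,
                      incomplete = as.integer(rows$incomplete),
                      candidatus = as.integer(rows$candidatus)))
      store_count(store, "ncbi_lineages") - before
    })
  }
  log_retrieval(store, "ncbi", criteria, rows_added = added)
  enrich_summary(hits = nrow(rows), misses = sum(!found), rows_added = added)
}

#' Attach genome-assembly links from a snapshot
#'
#' Imports the protein-accession to genome-assembly mapping as assembly
#' links; these are the join key the GTDB lineage attachment requires.
#'
#' @inheritParams attach_uniprot
#' @param assembly_snapshot Tibble from `read_snapshot(kind = "assembly")`.
#' @return An `EnrichSummary` tibble.
#' @export
attach_assemblies <- function(store, assembly_snapshot, criteria = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  check_snapshot(assembly_snapshot, "assembly")
  acc <- matching_accessions(store, criteria)
  rows <- assembly_snapshot[assembly_snapshot$accession %in% acc, ,
                            drop = FALSE]
  missed <- sum(!acc %in% assembly_snapshot$accession)
  added <- DBI::dbWithTransaction(store$con,
    insert_links(store$con, "assembly_links", c("accession", "assembly"),
                 rows))
  log_retrieval(store, "ncbi", criteria, rows_added = added)
  enrich_summary(hits = length(unique(rows$accession)), misses = missed,
                 rows_added = added)
}

#' Attach GTDB lineages from a snapshot
#'
#' GTDB classifies genomes, not proteins, so a protein can only be linked
#' when it already carries an assembly link (see [attach_assemblies()])
#' and that assembly is present in the GTDB snapshot. Proteins without an
#' assembly are counted `unlinkable`; assemblies absent from the snapshot
#' are misses. Neither is an error.
#'
#' @inheritParams attach_uniprot
#' @param gtdb_snapshot Tibble from `read_snapshot(kind = "gtdb_tax")`.
#' @return An `EnrichSummary` tibble.
#' @export
attach_gtdb_lineage <- function(store, gtdb_snapshot, criteria = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  check_snapshot(gtdb_snapshot, "gtdb_tax")
  acc <- matching_accessions(store, criteria)
  links <- store_table(store, "assembly_links")
  links <- links[links$accession %in% acc, , drop = FALSE]
  unlinkable <- sum(!acc %in% links$accession)
  assemblies <- unique(links$assembly)
  rows <- gtdb_snapshot[match(assemblies, gtdb_snapshot$assembly), ]
  found <- !is.na(rows$assembly)
  rows <- rows[found, , drop = FALSE]
  added <- 0L
  if (nrow(rows) > 0) {
    added <- DBI::dbWithTransaction(store$con, {
      before <- store_count(store, "gtdb_lineages")
      DBI::dbExecute(store$con,
        "INSERT INTO gtdb_lineages (assembly, kingdom, phylum, class,
           \"order\", family, genus, species, incomplete, candidatus)
         VALUES (:assembly, :kingdom, :phylum, :class, :order, :family,
                 :genus, :species, :incomplete, :candidatus)
         ON CONFLICT(assembly) DO UPDATE SET
           kingdom = excluded.kingdom, phylum = excluded.phylum,
           class = excluded.class, \"order\" = excluded.\"order\",
           family = excluded.family, genus = excluded.genus,
           species = excluded.species, incomplete = excluded.incomplete,
           candidatus = excluded.candidatus",
        params = list(assembly = rows$assembly, kingdom = rows$kingdom,
                      phylum = rows$phylum, class = rows$class,
                      order = rows$order, family = rows$family,
                      genus = rows$genus, species = rows$species,
                      incomplete = as.integer(rows$incomplete),
                      candidatus = as.integer(rows$candidatus)))
      store_count(store, "gtdb_lineages") - before
    })
  }
  log_retrieval(store, "gtdb", criteria, rows_added = added)
  enrich_summary(hits = nrow(rows), misses = sum(!found),
                 rows_added = added, unlinkable = unlinkable)
}

#' Refresh stored protein sequences from a snapshot
#'
#' Overwrites a stored sequence only when the snapshot carries a strictly
#' more recent version (by version date; the accession's version-suffix
#' integer breaks exact date ties). Everything else is untouched, so
#' re-running a refresh is a no-op.
#'
#' @inheritParams attach_uniprot
#' @param snapshot Tibble with columns `accession`, `sequence`,
#'   `version_date` (a UniProt snapshot works).
#' @param source Sequence provenance to record: `"genbank"` or `"uniprot"`.
#' @return An `EnrichSummary` tibble (`rows_updated` counts overwrites).
#' @export
refresh_sequences <- function(store, snapshot, criteria = NULL,
                              source = c("genbank", "uniprot")) {
  stopifnot(inherits(store, "cazy_store"))
  source <- match.arg(source)
  check_snapshot(snapshot, "sequence")
  acc <- matching_accessions(store, criteria)
  rows <- snapshot[match(acc, snapshot$accession), ]
  found <- !is.na(rows$accession)
  rows <- rows[found, , drop = FALSE]
  updated <- DBI::dbWithTransaction(store$con,
    write_sequences(store$con, rows, source = source, only_newer = TRUE))
  log_retrieval(store, source, criteria, rows_updated = updated)
  enrich_summary(hits = nrow(rows), misses = sum(!found),
                 rows_updated = updated)
}

#' Run a provider over accessions in resumable batches
#'
#' Splits the requested accessions into ordered batches, calls
#' `provider_fn` on each batch, and records every processed accession in a
#' newline-delimited cache file *before* the next batch starts. If a run is
#' interrupted (an error in the provider, a killed process), re-running
#' with the same cache processes exactly the remaining accessions, and the
#' final state is identical to an uninterrupted run.
#'
#' @param provider_fn Function taking a character vector of accessions.
#' @param accessions Character vector to process.
#' @param batch_size Positive integer; batch 150 is the default.
#' @param cache Path to the cache file (created if absent; an unreadable
#'   cache triggers a fresh start with a warning).
#' @return Tibble: `requested`, `skipped_cached`, `processed`, `batches`.
#' @export
run_batched <- function(provider_fn, accessions, batch_size = 150,
                        cache = tempfile("cazymine-cache-")) {
  stopifnot(is.function(provider_fn), batch_size >= 1)
  done <- character()
  if (dir.exists(cache)) {
    warn("Cache path is a directory; starting fresh with a new cache file.")
    cache <- tempfile("cazymine-cache-")
  }
  if (file.exists(cache)) {
    done <- tryCatch(readLines(cache, warn = FALSE), error = function(e) {
      warn(paste0("Cache unreadable (", conditionMessage(e),
                  "); starting fresh."))
      character()
    })
  }
  todo <- accessions[!accessions %in% done]
  skipped <- length(accessions) - length(todo)
  n_batches <- 0L
  processed <- 0L
  while (length(todo) > 0) {
    batch <- head(todo, batch_size)
    todo <- todo[-seq_along(batch)]
    provider_fn(batch)
    # persist progress before touching the next batch
    con <- file(cache, open = "a")
    writeLines(batch, con)
    close(con)
    n_batches <- n_batches + 1L
    processed <- processed + length(batch)
  }
  tibble::tibble(requested = length(accessions), skipped_cached = skipped,
                 processed = processed, batches = n_batches)
}
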