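# Import of parsed dump records into the store. Import is atomic per call
# (one transaction) and idempotent: re-importing any subset of records
# changes nothing.

#' Import dump records into a store
#'
#' Inserts the proteins, family links and taxon links carried by a parsed
#' dump, subject to optional selection criteria evaluated per record
#' (line). Distinct CAZymes are identified by their versioned NCBI
#' accession, compared case-sensitively, so repeated imports — of the same
#' dump, of overlapping filtered subsets, or of successive releases — never
#' duplicate records. A protein reported from two distinct source organisms
#' keeps both taxon links and gains a conflict record; a protein in several
#' families gains several family links but remains one record.
#'
#' @param store A `cazy_store`.
#' @param records A `cazy_dump` tibble from [parse_dump()] (or any tibble
#'   with columns `family`, `kingdom`, `organism`, `accession`).
#' @param criteria Optional [selection_criteria()]; only matching records
#'   are imported. EC criteria are ignored at import (the dump carries no
#'   EC annotations).
#' @return An `ImportSummary` tibble (one row): `proteins_new`,
#'   `links_new` (family + taxon links), `skipped_by_filter`,
#'   `conflicts_recorded`.
#' @export
import_dump <- function(store, records, criteria = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  records <- tibble::as_tibble(records)[, c("family", "kingdom", "organism",
                                            "accession")]
  keep <- record_matches(records, criteria)
  skipped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  con <- store$con

  summary <- DBI::dbWithTransaction(con, {
    proteins_before <- DBI::dbGetQuery(con,
      "SELECT COUNT(*) AS n FROM proteins")$n
    links_before <- DBI::dbGetQuery(con,
      "SELECT (SELECT COUNT(*) FROM family_links) +
              (SELECT COUNT(*) FROM taxon_links) AS n")$n
    conflicts_before <- DBI::dbGetQuery(con,
      "SELECT COUNT(*) AS n FROM conflicts")$n

    if (nrow(records) > 0) {
      # entities first, links second; INSERT OR IGNORE keeps it idempotent
      fams <- parse_family_label(unique(records$family))
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO families
           (family, class_code, family_number, subfamily_number)
         VALUES (:label, :class_code, :family_number, :subfamily_number)",
        params = as.list(fams))

      prot <- dplyr::distinct(records, .data$accession)
      prot$accession_kind <- classify_accession(prot$accession)
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO proteins (accession, accession_kind)
         VALUES (:accession, :accession_kind)",
        params = as.list(prot))

      taxa <- dplyr::distinct(records, .data$kingdom, .data$organism)
      taxa <- dplyr::bind_cols(taxa, split_organism(taxa$organism))
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO taxa
           (kingdom, genus, species_epithet, strain, organism)
         VALUES (:kingdom, :genus, :species_epithet, :strain, :organism)",
        params = as.list(taxa[, c("kingdom", "genus", "species_epithet",
                                  "strain", "organism")]))

      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO family_links (accession, family)
         VALUES (:accession, :family)",
        params = as.list(dplyr::distinct(records, .data$accession,
                                         .data$family)))

      tl <- dplyr::distinct(records, .data$accession, .data$kingdom,
                            .data$organism)
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO taxon_links (accession, taxon_id)
         SELECT :accession, taxon_id FROM taxa
          WHERE kingdom = :kingdom AND organism = :organism",
        params = as.list(tl))

      record_taxon_conflicts(con)
    }

    tibble::tibble(
      proteins_new = DBI::dbGetQuery(con,
        "SELECT COUNT(*) AS n FROM proteins")$n - proteins_before,
      links_new = DBI::dbGetQuery(con,
        "SELECT (SELECT COUNT(*) FROM family_links) +
                (SELECT COUNT(*) FROM taxon_links) AS n")$n - links_before,
      skipped_by_filter = skipped,
      conflicts_recorded = DBI::dbGetQuery(con,
        "SELECT COUNT(*) AS n FROM conflicts")$n - conflicts_before
    )
  })
  log_retrieval(store, "cazy", criteria,
                rows_added = summary$proteins_new + summary$links_new,
                rows_updated = 0)
  summary
}

# Proteins currently linked to >= 2 distinct taxa get (or refresh) a
# conflict record; the conflicting assignments stay in the store.
record_taxon_conflicts <- function(con) {
  multi <- DBI::dbGetQuery(con,
    "SELECT tl.accession,
            GROUP_CONCAT(t.kingdom || ':' || t.organism, ' | ') AS taxa
       FROM taxon_links tl JOIN taxa t ON t.taxon_id = tl.taxon_id
      GROUP BY tl.accession HAVING COUNT(DISTINCT tl.taxon_id) >= 2")
  if (nrow(multi) == 0) return(invisible(0L))
  now <- utc_timestamp()
  DBI::dbExecute(con,
    "INSERT INTO conflicts (accession, taxa, first_seen, last_seen)
     VALUES (:accession, :taxa, :now, :now)
     ON CONFLICT(accession) DO UPDATE SET taxa = excluded.taxa,
        last_seen = excluded.last_seen",
    params = list(accession = multi$accession, taxa = multi$taxa,
                  now = rep(now, nrow(multi))))
  invisible(nrow(multi))
}

#' Taxonomy conflicts recorded in a store
#'
#' Proteins annotated as deriving from more than one source organism; all
#' their taxon links are retained, and the conflict is surfaced here.
#'
#' @param store A `cazy_store`.
#' @return Tibble: `accession`, `taxa` (pipe-joined `kingdom:organism`
#'   assignments), `first_seen`, `last_seen`.
#' @export
taxonomy_conflicts <- function(store) {
  tibble::as_tibble(DBI::dbGetQuery(
    store$con, "SELECT * FROM conflicts ORDER BY accession"))
}

#' Count CAZymes matching criteria
#'
#' The count of DISTINCT protein accessions matching the criteria — the
#' same semantics as counting unique accessions returned by an SQL query
#' on the store. A protein in families GH5 and CBM35 counts once with
#' empty criteria, once under `families = "GH5"` and once under
#' `families = "CBM35"`.
#'
#' @param store A `cazy_store`.
#' @param criteria Optional [selection_criteria()].
#' @return Integer count.
#' @export
count_cazymes <- function(store, criteria = NULL) {
  length(matching_accessions(store, criteria))
}
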