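# Single-file relational store. The backing file is a plain SQLite3
# database, so it can be opened by any third-party SQLite console or
# connector; the handle is an environment wrapping a DBI connection plus a
# mutation counter used to invalidate the cached per-protein view.

STORE_SCHEMA <- c(
  proteins = "CREATE TABLE IF NOT EXISTS proteins (
     accession TEXT PRIMARY KEY,
     accession_kind TEXT NOT NULL CHECK (accession_kind IN ('genbank','refseq')),
     sequence TEXT,
     sequence_source TEXT CHECK (sequence_source IN ('genbank','uniprot')),
     sequence_version_date TEXT)",
  families = "CREATE TABLE IF NOT EXISTS families (
     family TEXT PRIMARY KEY,
     class_code TEXT NOT NULL,
     family_number INTEGER NOT NULL,
     subfamily_number INTEGER)",
  family_links = "CREATE TABLE IF NOT EXISTS family_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     family TEXT NOT NULL REFERENCES families(family),
     UNIQUE (accession, family))",
  taxa = "CREATE TABLE IF NOT EXISTS taxa (
     taxon_id INTEGER PRIMARY KEY AUTOINCREMENT,
     kingdom TEXT NOT NULL,
     genus TEXT,
     species_epithet TEXT,
     strain TEXT,
     organism TEXT NOT NULL,
     UNIQUE (kingdom, organism))",
  taxon_links = "CREATE TABLE IF NOT EXISTS taxon_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     taxon_id INTEGER NOT NULL REFERENCES taxa(taxon_id),
     UNIQUE (accession, taxon_id))",
  conflicts = "CREATE TABLE IF NOT EXISTS conflicts (
     accession TEXT PRIMARY KEY,
     taxa TEXT NOT NULL,
     first_seen TEXT NOT NULL,
     last_seen TEXT NOT NULL)",
  uniprot_links = "CREATE TABLE IF NOT EXISTS uniprot_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     uniprot_id TEXT NOT NULL,
     protein_name TEXT,
     UNIQUE (accession, uniprot_id))",
  ec_links = "CREATE TABLE IF NOT EXISTS ec_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     ec TEXT NOT NULL,
     UNIQUE (accession, ec))",
  pdb_links = "CREATE TABLE IF NOT EXISTS pdb_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     pdb TEXT NOT NULL,
     UNIQUE (accession, pdb))",
  assembly_links = "CREATE TABLE IF NOT EXISTS assembly_links (
     accession TEXT NOT NULL REFERENCES proteins(accession),
     assembly TEXT NOT NULL,
     UNIQUE (accession, assembly))",
  ncbi_lineages = "CREATE TABLE IF NOT EXISTS ncbi_lineages (
     accession TEXT PRIMARY KEY REFERENCES proteins(accession),
     kingdom TEXT, phylum TEXT, class TEXT, \"order\" TEXT, family TEXT,
     genus TEXT, species TEXT,
     incomplete INTEGER NOT NULL DEFAULT 0,
     candidatus INTEGER NOT NULL DEFAULT 0)",
  gtdb_lineages = "CREATE TABLE IF NOT EXISTS gtdb_lineages (
     assembly TEXT PRIMARY KEY,
     kingdom TEXT, phylum TEXT, class TEXT, \"order\" TEXT, family TEXT,
     genus TEXT, species TEXT,
     incomplete INTEGER NOT NULL DEFAULT 0,
     candidatus INTEGER NOT NULL DEFAULT 0)",
  retrieval_log = "CREATE TABLE IF NOT EXISTS retrieval_log (
     id INTEGER PRIMARY KEY AUTOINCREMENT,
     timestamp TEXT NOT NULL,
     source TEXT NOT NULL,
     criteria TEXT,
     rows_added INTEGER NOT NULL,
     rows_updated INTEGER NOT NULL)"
)

#' Open (or create) a local CAZyme store
#'
#' Creates the full relational schema on a fresh path; on an existing path
#' it is a plain open and all content persists, so `init_store()` is
#' idempotent. The file is a standard SQLite3 database and remains
#' queryable from any SQLite console.
#'
#' @param path File path for the database (created if absent).
#' @return A `cazy_store` handle.
#' @examples
#' store <- init_store(tempfile(fileext = ".db"))
#' count_cazymes(store)
#' close_store(store)
#' @export
init_store <- function(path) {
  existed <- file.exists(path)
  con <- tryCatch(
    suppressWarnings(DBI::dbConnect(RSQLite::SQLite(), path)),
    error = function(e) abort(paste0("Cannot open store at ", sQuote(path),
                                     ": ", conditionMessage(e)),
                              class = "cazymine_io_error"))
  if (existed) {
    ok <- tryCatch({
      res <- DBI::dbGetQuery(con, "PRAGMA integrity_check")
      tabs <- DBI::dbListTables(con)
      identical(tolower(res[[1]][1]), "ok") &&
        (length(tabs) == 0 || "proteins" %in% tabs)
    }, error = function(e) FALSE)
    if (!ok) {
      DBI::dbDisconnect(con)
      abort(paste0("Existing file is not a valid store: ", sQuote(path)),
            class = "cazymine_integrity_error")
    }
  }
  for (stmt in STORE_SCHEMA) DBI::dbExecute(con, stmt)
  store <- new.env(parent = emptyenv())
  store$con <- con
  store$path <- path
  store$mutations <- 0L
  store$view_cache <- NULL
  store$view_cache_at <- -1L
  class(store) <- "cazy_store"
  store
}

#' Close a store handle
#' @param store A `cazy_store`.
#' @return `NULL`, invisibly.
#' @export
close_store <- function(store) {
  stopifnot(inherits(store, "cazy_store"))
  if (DBI::dbIsValid(store$con)) DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.cazy_store <- function(x, ...) {
  n <- store_count(x, "proteins")
  cat(sprintf("<cazy_store> %s\n  proteins: %d  families: %d  log entries: %d\n",
              x$path, n, store_count(x, "families"),
              store_count(x, "retrieval_log")))
  invisible(x)
}

store_count <- function(store, table) {
  DBI::dbGetQuery(store$con,
                  paste0("SELECT COUNT(*) AS n FROM ", table))$n[1]
}

# Read a whole table as a tibble.
store_table <- function(store, table) {
  tibble::as_tibble(DBI::dbReadTable(store$con, table))
}

mark_mutated <- function(store) {
  store$mutations <- store$mutations + 1L
  invisible(store)
}

# Every mutating operation appends exactly one entry.
log_retrieval <- function(store, source, criteria = NULL, rows_added = 0,
                          rows_updated = 0) {
  crit_text <- if (is_match_all(criteria)) "" else
    paste(purrr::imap_chr(purrr::keep(unclass(criteria), ~ length(.x) > 0),
                          ~ paste0(.y, "=", paste(.x, collapse = ","))),
          collapse = "; ")
  DBI::dbExecute(store$con,
    "INSERT INTO retrieval_log (timestamp, source, criteria, rows_added,
       rows_updated) VALUES (:t, :s, :c, :a, :u)",
    params = list(t = utc_timestamp(), s = source, c = crit_text,
                  a = as.integer(rows_added), u = as.integer(rows_updated)))
  mark_mutated(store)
}

#' Audit log of all data retrievals
#'
#' The append-only retrieval log: one row per mutating operation, with a
#' UTC timestamp, the data source, the criteria text and the row counts.
#'
#' @param store A `cazy_store`.
#' @return Tibble of log entries in insertion order.
#' @export
retrieval_log <- function(store) {
  tibble::as_tibble(DBI::dbGetQuery(
    store$con, "SELECT * FROM retrieval_log ORDER BY id"))
}

#' Per-protein view of the store
#'
#' One row per distinct accession with list-columns collecting its family
#' labels, kingdoms, organism strings, EC numbers, PDB ids, UniProt ids and
#' assemblies. This is the table [matches()] evaluates criteria against;
#' it is cached per store and rebuilt after any mutation.
#'
#' @param store A `cazy_store`.
#' @return Tibble with one row per protein.
#' @export
protein_view <- function(store) {
  stopifnot(inherits(store, "cazy_store"))
  if (!is.null(store$view_cache) &&
      store$view_cache_at == store$mutations) {
    return(store$view_cache)
  }
  proteins <- store_table(store, "proteins")
  collect_links <- function(table, value_col, out_name) {
    df <- store_table(store, table)
    df <- df[order(df$accession, df[[value_col]]), c("accession", value_col)]
    grouped <- dplyr::summarise(
      dplyr::group_by(df, .data$accession),
      !!out_name := list(unique(.data[[value_col]])), .groups = "drop")
    grouped
  }
  taxa <- dplyr::inner_join(store_table(store, "taxon_links"),
                            store_table(store, "taxa"), by = "taxon_id")
  taxa_grouped <- dplyr::summarise(
    dplyr::group_by(taxa, .data$accession),
    kingdoms = list(unique(.data$kingdom)),
    organisms = list(unique(.data$organism)), .groups = "drop")
  view <- proteins |>
    dplyr::left_join(collect_links("family_links", "family", "families"),
                     by = "accession") |>
    dplyr::left_join(taxa_grouped, by = "accession") |>
    dplyr::left_join(collect_links("ec_links", "ec", "ecs"),
                     by = "accession") |>
    dplyr::left_join(collect_links("pdb_links", "pdb", "pdbs"),
                     by = "accession") |>
    dplyr::left_join(collect_links("uniprot_links", "uniprot_id", "uniprot_ids"),
                     by = "accession") |>
    dplyr::left_join(collect_links("assembly_links", "assembly", "assemblies"),
                     by = "accession")
  for (col in c("families", "kingdoms", "organisms", "ecs", "pdbs",
                "uniprot_ids", "assemblies")) {
    view[[col]] <- purrr::map(view[[col]], ~ .x %||% character())
  }
  view <- dplyr::arrange(view, .data$accession)
  store$view_cache <- view
  store$view_cache_at <- store$mutations
  view
}

# Accessions matching criteria (sorted).
matching_accessions <- function(store, criteria = NULL) {
  view <- protein_view(store)
  view$accession[matches(view, criteria)]
}
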