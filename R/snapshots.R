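# Offline annotation snapshots. Each snapshot is a headered UTF-8 TSV that
# stands in for one external database behind a uniform provider contract:
# UniProt (protein annotations), NCBI Taxonomy (lineages keyed by protein
# accession), GTDB (lineages keyed by genome assembly) and the NCBI
# assembly mapping (protein accession -> assembly id). Multi-valued cells
# (EC numbers, PDB ids) are comma-separated.

SNAPSHOT_COLUMNS <- list(
  uniprot = c("accession", "uniprot_id", "protein_name", "ec_numbers",
              "pdb_ids", "sequence", "version_date"),
  ncbi_tax = c("accession", "lineage"),
  gtdb_tax = c("assembly", "lineage"),
  assembly = c("accession", "assembly")
)

EC_PATTERN <- "^\\d+\\.[\\d-]+\\.[\\d-]+\\.[\\d-]+$"
PDB_PATTERN <- "^[0-9][A-Za-z0-9]{3}$"

#' Read an annotation snapshot file
#'
#' Loads one offline snapshot TSV and validates every row against the type
#' invariants of its kind. Rows that violate an invariant become row-level
#' issues (the file still loads); a missing mandatory column is fatal.
#' Duplicate keys resolve last-wins with a warning.
#'
#' @param path Path to the snapshot TSV.
#' @param kind One of `"uniprot"`, `"ncbi_tax"`, `"gtdb_tax"`, `"assembly"`.
#' @return A tibble whose shape depends on `kind`:
#'   * `uniprot`: `accession`, `uniprot_id`, `protein_name`, `ec_numbers`
#'     and `pdb_ids` (list-columns of validated strings), `sequence`,
#'     `version_date` (Date).
#'   * `ncbi_tax` / `gtdb_tax`: key column (`accession` / `assembly`) plus
#'     one column per rank `kingdom` ... `species` and logical flags
#'     `incomplete` (lineage stops before species) and `candidatus`
#'     (any rank name starts with "Candidatus").
#'   * `assembly`: `accession`, `assembly`.
#'   Row-level problems are attached as a tibble in `attr(x, "issues")`.
#' @export
read_snapshot <- function(path, kind = c("uniprot", "ncbi_tax", "gtdb_tax",
                                         "assembly")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("Snapshot file not found: ", sQuote(path)),
          class = "cazymine_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- SNAPSHOT_COLUMNS[[kind]]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Snapshot ", sQuote(path), " lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cazymine_format_error")
  }
  key <- need[1]
  dup <- duplicated(raw[[key]], fromLast = TRUE)
  if (any(dup)) {
    warn(sprintf("%d duplicate %s key(s) in %s; keeping the last occurrence.",
                 sum(dup), kind, basename(path)))
    raw <- raw[!dup, , drop = FALSE]
  }
  out <- switch(kind,
    uniprot = validate_uniprot(raw),
    ncbi_tax = parse_lineage_snapshot(raw, key = "accession"),
    gtdb_tax = parse_lineage_snapshot(raw, key = "assembly"),
    assembly = list(rows = tibble::as_tibble(raw[, need]),
                    issues = no_issues())
  )
  structure(out$rows, issues = out$issues)
}

no_issues <- function() {
  tibble::tibble(row = integer(), key = character(), reason = character())
}

split_multi <- function(x) {
  purrr::map(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(character())
    trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  })
}

validate_uniprot <- function(raw) {
  ecs <- split_multi(raw$ec_numbers)
  pdbs <- split_multi(raw$pdb_ids)
  bad_ec <- purrr::map_lgl(ecs, ~ any(!stringr::str_detect(.x, EC_PATTERN)))
  bad_pdb <- purrr::map_lgl(pdbs, ~ any(!stringr::str_detect(.x, PDB_PATTERN)))
  issues <- no_issues()
  if (any(bad_ec | bad_pdb)) {
    idx <- which(bad_ec | bad_pdb)
    issues <- tibble::tibble(
      row = idx, key = raw$accession[idx],
      reason = ifelse(bad_ec[idx], "malformed EC number", "malformed PDB id"))
    ecs[bad_ec] <- purrr::map(ecs[bad_ec],
                              ~ .x[stringr::str_detect(.x, EC_PATTERN)])
    pdbs[bad_pdb] <- purrr::map(pdbs[bad_pdb],
                                ~ .x[stringr::str_detect(.x, PDB_PATTERN)])
  }
  rows <- tibble::tibble(
    accession = raw$accession,
    uniprot_id = raw$uniprot_id,
    protein_name = raw$protein_name,
    ec_numbers = ecs,
    pdb_ids = pdbs,
    sequence = raw$sequence,
    version_date = as.Date(raw$version_date)
  )
  list(rows = rows, issues = issues)
}

# Lineage strings are semicolon-separated rank names in canonical order
# (kingdom/domain;phylum;class;order;family;genus;species); a shorter string
# is a prefix of that order and marks the lineage incomplete.
parse_lineage_snapshot <- function(raw, key) {
  parts <- purrr::map(raw$lineage, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  too_long <- lengths(parts) > length(LINEAGE_RANKS)
  issues <- no_issues()
  if (any(too_long)) {
    issues <- tibble::tibble(row = which(too_long),
                             key = raw[[key]][too_long],
                             reason = "lineage has more ranks than expected")
    parts[too_long] <- purrr::map(parts[too_long],
                                  ~ .x[seq_along(LINEAGE_RANKS)])
  }
  rank_mat <- t(vapply(parts, function(p) {
    c(p, rep(NA_character_, length(LINEAGE_RANKS) - length(p)))
  }, character(length(LINEAGE_RANKS))))
  colnames(rank_mat) <- LINEAGE_RANKS
  rows <- dplyr::bind_cols(
    tibble::tibble(!!key := raw[[key]]),
    tibble::as_tibble(rank_mat),
    tibble::tibble(
      incomplete = lengths(parts) < length(LINEAGE_RANKS),
      candidatus = purrr::map_lgl(parts,
                                  ~ any(stringr::str_starts(.x, "Candidatus")))
    )
  )
  list(rows = rows, issues = issues)
}

#' Row-level issues recorded while reading a snapshot
#'
#' @param x A snapshot tibble from [read_snapshot()].
#' @return Tibble with columns `row`, `key`, `reason`.
#' @export
snapshot_issues <- function(x) {
  attr(x, "issues") %||% no_issues()
}
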