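# Filtered queries, CSV/JSON writers, FASTA extraction and the summary
# aggregations (class-by-kingdom contingency tables, lineage rollups).

QUERY_FIELDS <- c("class", "family", "subfamily", "kingdom", "genus",
                  "organism", "genbank_sequence", "uniprot_accession",
                  "protein_name", "ec", "pdb", "uniprot_sequence")

#' Query the store
#'
#' Returns one row per distinct matching accession, ordered
#' lexicographically. By default only the accession column is returned;
#' `include` adds annotation fields. Multi-valued fields (families, EC
#' numbers, PDB ids, ...) are serialized comma-joined and sorted within
#' the cell, so output is byte-stable.
#'
#' @param store A `cazy_store`.
#' @param criteria Optional [selection_criteria()].
#' @param include Character vector of extra fields, a subset of: `class`,
#'   `family`, `subfamily`, `kingdom`, `genus`, `organism`,
#'   `genbank_sequence`, `uniprot_accession`, `protein_name`, `ec`, `pdb`,
#'   `uniprot_sequence`.
#' @return A tibble with column `accession` plus one column per included
#'   field.
#' @export
cazy_query <- function(store, criteria = NULL, include = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  unknown <- setdiff(include, QUERY_FIELDS)
  if (length(unknown) > 0) {
    abort(paste0("Unknown query field(s): ", paste(unknown, collapse = ", "),
                 ". Known fields: ", paste(QUERY_FIELDS, collapse = ", ")),
          class = "cazymine_config_error")
  }
  view <- protein_view(store)
  view <- view[matches(view, criteria), , drop = FALSE]
  out <- tibble::tibble(accession = view$accession)
  if (length(include) == 0) return(out)

  fam_parts <- purrr::map(view$families, function(labels) {
    if (length(labels) == 0) {
      return(tibble::tibble(label = character(), class_code = character(),
                            family_number = integer(),
                            subfamily_number = integer()))
    }
    parse_family_label(labels)
  })
  uniprot <- store_table(store, "uniprot_links")
  name_of <- function(acc) {
    rows <- uniprot[uniprot$accession == acc, ]
    join_sorted(rows$protein_name)
  }
  for (f in include) {
    out[[f]] <- switch(f,
      class = purrr::map_chr(fam_parts, ~ join_sorted(.x$class_code)),
      family = purrr::map_chr(fam_parts, ~ join_sorted(
        unique(format_family_label(.x$class_code, .x$family_number)))),
      subfamily = purrr::map_chr(fam_parts, ~ join_sorted(
        .x$label[!is.na(.x$subfamily_number)])),
      kingdom = purrr::map_chr(view$kingdoms, join_sorted),
      genus = purrr::map_chr(view$organisms, ~ join_sorted(
        unique(split_organism(.x)$genus))),
      organism = purrr::map_chr(view$organisms, join_sorted),
      genbank_sequence = ifelse(
        !is.na(view$sequence_source) & view$sequence_source == "genbank",
        view$sequence, NA_character_),
      uniprot_sequence = ifelse(
        !is.na(view$sequence_source) & view$sequence_source == "uniprot",
        view$sequence, NA_character_),
      uniprot_accession = purrr::map_chr(view$uniprot_ids, join_sorted),
      protein_name = purrr::map_chr(view$accession, name_of),
      ec = purrr::map_chr(view$ecs, join_sorted),
      pdb = purrr::map_chr(view$pdbs, join_sorted)
    )
  }
  out
}

#' Write a query table to CSV / JSON
#'
#' `write_query_csv()` emits RFC-4180 CSV with a header row (fields
#' containing commas or quotes are quoted); `write_query_json()` emits a
#' JSON array of objects keyed by the column names. Both are byte-stable
#' for a fixed input table.
#'
#' @param table A tibble (typically from [cazy_query()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_csv <- function(table, path) {
  readr::write_csv(table, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_query_csv
#' @export
write_query_json <- function(table, path) {
  jsonlite::write_json(table, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Extract stored sequences to a multi-sequence FASTA file
#'
#' Writes one FASTA record per distinct matching accession whose stored
#' sequence came from the requested source. Headers are
#' `accession organism`. Matching proteins without such a sequence are
#' counted, not errors.
#'
#' @param store A `cazy_store`.
#' @param path Output FASTA path.
#' @param criteria Optional [selection_criteria()].
#' @param source Sequence provenance to export: `"genbank"` or `"uniprot"`.
#' @return Tibble (invisible): `written`, `skipped_no_sequence`.
#' @export
extract_fasta <- function(store, path, criteria = NULL,
                          source = c("genbank", "uniprot")) {
  stopifnot(inherits(store, "cazy_store"))
  source <- match.arg(source)
  view <- protein_view(store)
  view <- view[matches(view, criteria), , drop = FALSE]
  has_seq <- !is.na(view$sequence) & !is.na(view$sequence_source) &
    view$sequence_source == source
  seqs <- view[has_seq, , drop = FALSE]
  aas <- Biostrings::AAStringSet(setNames(seqs$sequence, seqs$accession))
  desc <- purrr::map_chr(seqs$organisms, ~ if (length(.x) > 0) .x[1] else "")
  names(aas) <- trimws(paste(seqs$accession, desc))
  Biostrings::writeXStringSet(aas, path)
  invisible(tibble::tibble(written = nrow(seqs),
                           skipped_no_sequence = sum(!has_seq)))
}

#' Class- or family-by-kingdom contingency table
#'
#' Cell (r, k) counts DISTINCT accessions having at least one family in
#' row group r and kingdom k. A protein assigned to several classes (or
#' families) counts once per row group, so row totals may exceed the
#' distinct-protein total; within one row each protein counts once.
#'
#' @param store A `cazy_store`.
#' @param by `"class"` or `"family"`.
#' @return A tibble of class `cazy_kingdom_summary`: one row per class /
#'   family, one column per kingdom present, plus `total` (distinct
#'   accessions in the row group).
#' @export
summarize_kingdoms <- function(store, by = c("class", "family")) {
  by <- match.arg(by)
  view <- protein_view(store)
  long <- tibble::tibble(accession = view$accession,
                         families = view$families,
                         kingdoms = view$kingdoms) |>
    tidyr::unnest("families") |>
    tidyr::unnest("kingdoms")
  parsed <- parse_family_label(long$families)
  long$group <- if (by == "class") parsed$class_code else
    format_family_label(parsed$class_code, parsed$family_number)
  counts <- long |>
    dplyr::distinct(.data$group, .data$kingdoms, .data$accession) |>
    dplyr::count(.data$group, .data$kingdoms) |>
    tidyr::pivot_wider(names_from = "kingdoms", values_from = "n",
                       values_fill = 0L)
  totals <- long |>
    dplyr::distinct(.data$group, .data$accession) |>
    dplyr::count(.data$group, name = "total")
  out <- dplyr::left_join(counts, totals, by = "group") |>
    dplyr::arrange(.data$group)
  names(out)[1] <- by
  structure(out, class = c("cazy_kingdom_summary", class(out)), by = by)
}

#' Majority kingdom per family (or class)
#'
#' @param summary A `cazy_kingdom_summary` from [summarize_kingdoms()].
#' @return Tibble: row group, `dominant_kingdom`, `dominant_n`. Ties break
#'   alphabetically for determinism.
#' @export
dominant_kingdoms <- function(summary) {
  stopifnot(inherits(summary, "cazy_kingdom_summary"))
  by <- attr(summary, "by")
  kcols <- intersect(names(summary), KINGDOMS)
  mat <- as.matrix(summary[, kcols, drop = FALSE])
  idx <- apply(mat, 1, which.max)
  tibble::tibble(!!by := summary[[by]],
                 dominant_kingdom = kcols[idx],
                 dominant_n = mat[cbind(seq_len(nrow(mat)), idx)])
}

#' Roll up CAZyme counts down an attached NCBI taxonomy
#'
#' Counts distinct accessions at every taxonomy node from phylum down to
#' (taxonomic) family for one kingdom, using the NCBI lineages attached by
#' [attach_ncbi_lineage()]. Incomplete lineages and *Candidatus* lineages
#' can be excluded, mirroring how archaeal census plots are conventionally
#' cleaned before display.
#'
#' @param store A `cazy_store`.
#' @param kingdom Kingdom whose lineages to roll up (e.g. `"Archaea"`).
#' @param ranks Ordered ranks to report (default phylum to family).
#' @param exclude_incomplete,exclude_candidatus Drop flagged lineages.
#' @return Tibble: `rank`, `name`, `parent` (name at the previous rank,
#'   `NA` at the first), `n` (distinct accessions under the node).
#' @export
lineage_rollup <- function(store, kingdom,
                           ranks = c("phylum", "class", "order", "family"),
                           exclude_incomplete = TRUE,
                           exclude_candidatus = TRUE) {
  stopifnot(inherits(store, "cazy_store"),
            all(ranks %in% LINEAGE_RANKS))
  lin <- store_table(store, "ncbi_lineages")
  lin <- lin[!is.na(lin$kingdom) & lin$kingdom == kingdom, , drop = FALSE]
  if (exclude_incomplete) lin <- lin[lin$incomplete == 0L, , drop = FALSE]
  if (exclude_candidatus) lin <- lin[lin$candidatus == 0L, , drop = FALSE]
  out <- purrr::map_dfr(seq_along(ranks), function(i) {
    r <- ranks[i]
    parent_col <- if (i == 1) NULL else ranks[i - 1]
    df <- lin[!is.na(lin[[r]]), , drop = FALSE]
    if (nrow(df) == 0) {
      return(tibble::tibble(rank = character(), name = character(),
                            parent = character(), n = integer()))
    }
    grouped <- df |>
      dplyr::mutate(parent = if (is.null(parent_col)) NA_character_ else
        .data[[parent_col]]) |>
      dplyr::distinct(name = .data[[r]], .data$parent, .data$accession) |>
      dplyr::count(.data$name, .data$parent)
    tibble::tibble(rank = r, name = grouped$name, parent = grouped$parent,
                   n = grouped$n)
  })
  dplyr::arrange(out, match(.data$rank, ranks), .data$name)
}
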