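# CAZy-style database dump: one family<->protein link per line. A protein
# belonging to several families appears on several lines.

# Dialect registry. A dialect names the field separator and column order of
# the plain-text dump; the column order of the real download is not
# standardised, so alternatives plug in by name.
dump_dialects <- list(
  tsv4 = list(sep = "\t",
              columns = c("family", "kingdom", "organism", "accession"))
)

get_dialect <- function(dialect) {
  if (!dialect %in% names(dump_dialects)) {
    abort(paste0("Unknown dump dialect ", sQuote(dialect),
                 ". Known dialects: ",
                 paste(names(dump_dialects), collapse = ", ")),
          class = "cazymine_config_error")
  }
  dump_dialects[[dialect]]
}

#' Parse a CAZy-style plain-text dump
#'
#' Reads the plain-text dump of family membership records (family label,
#' kingdom, source organism, NCBI protein accession; one family link per
#' line). Malformed lines are not fatal: they are collected into an issue
#' table attached to the result, so a single corrupt line never discards a
#' multi-million-line import.
#'
#' @param path Path to the dump file (optionally a `.zip` containing it), or
#'   a character vector of lines.
#' @param dialect Dump dialect name; `"tsv4"` (the default) is
#'   tab-separated `family  kingdom  organism  accession`.
#' @return A tibble of class `cazy_dump` with columns `family`, `kingdom`
#'   (canonicalized to the five kingdom-level groups), `organism`,
#'   `accession` and `accession_kind`, in input order. Malformed lines are
#'   available via [dump_issues()].
#' @seealso [write_dump()], [import_dump()]
#' @export
parse_dump <- function(path, dialect = "tsv4") {
  d <- get_dialect(dialect)
  lines <- read_dump_lines(path)
  n <- length(lines)
  issues <- tibble::tibble(line = integer(), text = character(),
                           reason = character())
  if (n == 0) {
    rec <- tibble::tibble(family = character(), kingdom = character(),
                          organism = character(), accession = character(),
                          accession_kind = character())
    return(new_cazy_dump(rec, issues))
  }
  fields <- stringr::str_split(lines, stringr::fixed(d$sep))
  nf <- lengths(fields)
  ok <- nf == length(d$columns)
  add_issue <- function(issues, idx, reason) {
    dplyr::bind_rows(issues, tibble::tibble(line = idx, text = lines[idx],
                                            reason = reason))
  }
  if (any(!ok)) {
    issues <- add_issue(issues, which(!ok),
                        sprintf("expected %d fields", length(d$columns)))
  }
  mat <- do.call(rbind, fields[ok])
  if (is.null(mat)) mat <- matrix(character(), ncol = length(d$columns))
  rec <- tibble::as_tibble(setNames(as.data.frame(mat,
                                                  stringsAsFactors = FALSE),
                                    d$columns))
  rec$.line <- which(ok)

  fam_ok <- stringr::str_detect(rec$family, "^(GH|GT|PL|CE|AA|CBM)\\d+(_\\d+)?$")
  acc_ok <- nzchar(trimws(rec$accession))
  bad_rows <- !fam_ok | !acc_ok
  if (any(bad_rows)) {
    reason <- ifelse(!fam_ok[bad_rows], "unparseable family label",
                     "empty accession")
    issues <- add_issue(issues, rec$.line[bad_rows], reason)
    rec <- rec[!bad_rows, , drop = FALSE]
  }
  rec$kingdom <- canonical_kingdom(rec$kingdom)
  rec$accession <- trimws(rec$accession)
  rec$accession_kind <- classify_accession(rec$accession)
  rec <- rec[order(rec$.line), setdiff(names(rec), ".line")]
  issues <- dplyr::arrange(issues, .data$line)
  new_cazy_dump(tibble::as_tibble(rec), issues)
}

new_cazy_dump <- function(records, issues) {
  structure(records, issues = issues,
            class = c("cazy_dump", class(records)))
}

#' Issue report from a parsed dump
#'
#' @param x A `cazy_dump` as returned by [parse_dump()].
#' @return Tibble of malformed lines: `line`, `text`, `reason`.
#' @export
dump_issues <- function(x) {
  attr(x, "issues") %||%
    tibble::tibble(line = integer(), text = character(), reason = character())
}

#' Write dump records back to the plain-text dump format
#'
#' @param records Tibble with columns `family`, `kingdom`, `organism`,
#'   `accession` (the `cazy_dump` columns; extra columns are ignored).
#' @param path Output file path.
#' @param dialect Dump dialect name (see [parse_dump()]).
#' @return `path`, invisibly.
#' @export
write_dump <- function(records, path, dialect = "tsv4") {
  d <- get_dialect(dialect)
  stopifnot(all(d$columns %in% names(records)))
  lines <- do.call(paste, c(unname(as.list(records[d$columns])), sep = d$sep))
  writeLines(lines, path)
  invisible(path)
}

read_dump_lines <- function(path) {
  stopifnot(is.character(path))
  if (length(path) != 1) return(path)           # already lines
  if (!nzchar(path)) return(character())        # empty stream
  if (!file.exists(path)) {
    if (grepl("[\n\t]", path)) {                 # in-memory dump content
      return(strsplit(path, "\n", fixed = TRUE)[[1]])
    }
    abort(paste0("Cannot read dump: ", sQuote(path)),
          class = "cazymine_io_error")
  }
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    entries <- utils::unzip(path, list = TRUE)$Name
    if (length(entries) == 0) {
      abort("Empty ZIP container.", class = "cazymine_io_error")
    }
    con <- unz(path, entries[1])
    on.exit(close(con))
    return(readLines(con, warn = FALSE, encoding = "UTF-8"))
  }
  readLines(path, warn = FALSE, encoding = "UTF-8")
}
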