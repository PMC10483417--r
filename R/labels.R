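#' Parse CAZy family labels
#'
#' CAZy names sequence-similarity families as `<class><number>[_<subfamily>]`,
#' e.g. `GH5`, `PL20` or the subfamily `GH5_4`. The class code is one of the
#' six CAZy classes: GH (glycoside hydrolase), GT (glycosyltransferase),
#' PL (polysaccharide lyase), CE (carbohydrate esterase), AA (auxiliary
#' activity) and CBM (carbohydrate-binding module).
#'
#' @param x Character vector of family labels.
#' @return A tibble with one row per label: `label` (canonical text form),
#'   `class_code`, `family_number` (integer) and `subfamily_number`
#'   (integer, `NA` when the label names a whole family).
#' @examples
#' parse_family_label(c("PL20", "GH5_4"))
#' @export
parse_family_label <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) {
    return(tibble::tibble(label = character(), class_code = character(),
                          family_number = integer(),
                          subfamily_number = integer()))
  }
  if (any(is.na(x) | !nzchar(x))) {
    abort("Family labels must be non-empty strings.")
  }
  m <- stringr::str_match(x, "^(GH|GT|PL|CE|AA|CBM)(\\d+)(?:_(\\d+))?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("Not a valid CAZy family label: ",
                 paste(sQuote(unique(x[bad])), collapse = ", ")))
  }
  fam <- as.integer(m[, 3])
  sub <- as.integer(m[, 4])
  if (any(fam <= 0, na.rm = TRUE) || any(sub <= 0, na.rm = TRUE)) {
    abort("Family and subfamily numbers must be positive.")
  }
  tibble::tibble(
    label = format_family_label(m[, 2], fam, sub),
    class_code = m[, 2],
    family_number = fam,
    subfamily_number = sub
  )
}

#' Format a family label from its parts
#'
#' Inverse of [parse_family_label()]: the text round trip
#' `format_family_label(parse_family_label(x))` is lossless.
#'
#' @param class_code Class code (`GH`, `GT`, `PL`, `CE`, `AA`, `CBM`), or a
#'   tibble as returned by [parse_family_label()].
#' @param family_number,subfamily_number Integer parts (subfamily optional).
#' @return Character vector of labels.
#' @export
format_family_label <- function(class_code, family_number = NULL,
                                subfamily_number = NA_integer_) {
  if (is.data.frame(class_code)) {
    df <- class_code
    return(format_family_label(df$class_code, df$family_number,
                               df$subfamily_number))
  }
  out <- paste0(class_code, family_number)
  has_sub <- !is.na(subfamily_number)
  out[has_sub] <- paste0(out[has_sub], "_", subfamily_number[has_sub])
  out
}

#' Classify a protein accession as GenBank or RefSeq
#'
#' RefSeq protein accessions carry a two-letter + underscore prefix
#' (`XP_`, `WP_`, `NP_`, ...); every other NCBI protein accession is a
#' submitter-derived GenBank accession. Both kinds may denote the same
#' amino-acid sequence, which is one source of redundancy in CAZy.
#'
#' @param accession Character vector of versioned protein accessions.
#' @return Character vector, each element `"refseq"` or `"genbank"`.
#' @examples
#' classify_accession(c("XP_391536.1", "CEF86689.1"))
#' @export
classify_accession <- function(accession) {
  stopifnot(is.character(accession))
  if (any(is.na(accession) | !nzchar(accession))) {
    abort("Accessions must be non-empty strings.")
  }
  ifelse(stringr::str_detect(accession, "^[A-Z]{2}_"), "refseq", "genbank")
}
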