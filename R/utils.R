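# Shared internal helpers.

# The five kingdom-level groups CAZy uses.
KINGDOMS <- c("Bacteria", "Eukaryota", "Archaea", "Viruses", "unclassified")

# Ordered taxonomic ranks stored for lineages (kingdom in NCBI flavour,
# domain in GTDB flavour, both stored under "kingdom").
LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' Round half away from zero
#'
#' Decimal rounding where ties go up (`0.005` -> `0.01`), matching how
#' percentage tables in enzyme-census reports are conventionally rounded,
#' rather than base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(1.2999, 2)  # 1.30
#' round_half_up(0.125, 2)   # 0.13 (base round() gives 0.12)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly representable
  # halves (0.125) round up despite binary floating point
  floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

# Canonicalize kingdom tokens: case-insensitive match against the five
# groups; anything else maps to "unclassified" (CAZy's own catch-all group),
# with a warning when warn = TRUE.
canonical_kingdom <- function(x, warn = TRUE) {
  idx <- match(tolower(x), tolower(KINGDOMS))
  unknown <- is.na(idx) & !is.na(x)
  if (any(unknown) && warn) {
    warn(paste0("Unknown kingdom token(s) mapped to 'unclassified': ",
                paste(unique(x[unknown]), collapse = ", ")))
  }
  out <- unname(KINGDOMS[idx])
  out[unknown] <- "unclassified"
  out
}

# Split an organism string into genus / species epithet / strain.
# Single-token names get the "sp." sentinel as species.
split_organism <- function(organism) {
  parts <- strsplit(trimws(organism), "\\s+")
  tibble::tibble(
    genus = purrr::map_chr(parts, ~ .x[1] %||% NA_character_),
    species_epithet = purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[2] else "sp."),
    strain = purrr::map_chr(parts, ~ if (length(.x) >= 3)
      paste(.x[-(1:2)], collapse = " ") else NA_character_)
  )
}

# "Genus epithet" binomial for the species filter.
organism_binomial <- function(organism) {
  sp <- split_organism(organism)
  paste(sp$genus, sp$species_epithet)
}

utc_timestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Comma-join a character vector sorted lexicographically (stable cells in
# exported tables); empty input -> NA.
join_sorted <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  if (length(x) == 0) return(NA_character_)
  paste(stringr::str_sort(x, locale = "C"), collapse = ",")
}
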