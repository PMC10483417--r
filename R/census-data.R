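# Bundled desk-scale census tables (plain-text TSVs under inst/extdata).

#' Bundled kingdom-level species census
#'
#' Species-level taxon counts per kingdom from the NCBI Taxonomy (May
#' 2022), alongside the number of those species with at least one and at
#' least 50 CAZymes catalogued in the January-2022 CAZy release. Input for
#' [representation_rates()].
#'
#' @return Tibble: `kingdom`, `species_total`, `n_ge1`, `n_ge50`.
#' @export
species_census <- function() {
  readr::read_tsv(system.file("extdata", "species_census.tsv",
                              package = "cazymine"),
                  col_types = "ciii", progress = FALSE)
}

#' Bundled carbohydrate-esterase structural census
#'
#' Per-family CAZyme totals for the 20 CE families (January-2022 CAZy
#' release) and the number of members associated with at least one PDB id
#' in UniProt (April 2022). Family `CE0` collects CE proteins without a
#' specific family assignment. Column sums give the class-wide structural
#' coverage.
#'
#' @return Tibble: `family`, `total_cazymes`, `with_pdb`.
#' @export
ce_structure_census <- function() {
  readr::read_tsv(system.file("extdata", "ce_structure_census.tsv",
                              package = "cazymine"),
                  col_types = "cii", progress = FALSE)
}
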