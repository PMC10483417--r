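# Selection criteria: the single filter object used by import, enrichment,
# query and export. Membership within a category is disjunctive; categories
# (grouped as family-scheme, kingdoms, organism, EC) combine conjunctively.

CRITERIA_CATEGORIES <- c("classes", "families", "subfamilies", "kingdoms",
                         "genera", "species", "strains", "ec_numbers")

#' Build a selection-criteria object
#'
#' Criteria restrict which CAZyme records an operation touches. Within one
#' category the listed values are alternatives (`families = c("PL20","PL28")`
#' matches either family); across category groups the filters conjoin.
#' The categories form four groups:
#' * family scheme: `classes`, `families`, `subfamilies` — a protein matches
#'   if any of its family labels satisfies any listed selector. A family
#'   selector (`GH5`) also matches all its subfamilies (`GH5_4`); a
#'   subfamily selector matches exactly.
#' * `kingdoms` — case-insensitive, canonicalized to the five groups.
#' * organism: `genera`, `species` (genus + epithet, matching every strain
#'   of that species) and `strains` (exact organism string) are unioned, so
#'   `species = "Trichoderma reesei", strains = "Aspergillus flavus AF13"`
#'   selects all T. reesei strains plus that one A. flavus strain.
#' * `ec_numbers` — EC strings; trailing dashes (`3.1.1.-`) act as
#'   wildcards at the dashed levels.
#'
#' An empty object (`selection_criteria()`) matches everything.
#'
#' @param classes,families,subfamilies,kingdoms,genera,species,strains,ec_numbers
#'   Character vectors (or `NULL`) of admitted values for each category.
#' @return An object of class `selection_criteria`.
#' @examples
#' selection_criteria(families = c("PL20", "PL28"), kingdoms = "bacteria")
#' @export
selection_criteria <- function(classes = NULL, families = NULL,
                               subfamilies = NULL, kingdoms = NULL,
                               genera = NULL, species = NULL, strains = NULL,
                               ec_numbers = NULL) {
  clean <- function(x) {
    x <- unique(trimws(as.character(x %||% character())))
    x[nzchar(x)]
  }
  crit <- list(classes = clean(classes), families = clean(families),
               subfamilies = clean(subfamilies),
               kingdoms = clean(kingdoms), genera = clean(genera),
               species = clean(species), strains = clean(strains),
               ec_numbers = clean(ec_numbers))
  bad_class <- setdiff(crit$classes, c("GH", "GT", "PL", "CE", "AA", "CBM"))
  if (length(bad_class) > 0) {
    abort(paste0("Unknown CAZy class code(s): ",
                 paste(bad_class, collapse = ", ")))
  }
  if (length(crit$families) > 0) {
    fams <- parse_family_label(crit$families)
    if (any(!is.na(fams$subfamily_number))) {
      abort("`families` must not carry subfamily suffixes; use `subfamilies`.")
    }
    crit$families <- fams$label
  }
  if (length(crit$subfamilies) > 0) {
    subs <- parse_family_label(crit$subfamilies)
    if (any(is.na(subs$subfamily_number))) {
      abort("`subfamilies` entries must carry a subfamily suffix (e.g. GH5_4).")
    }
    crit$subfamilies <- subs$label
  }
  crit$kingdoms <- unique(canonical_kingdom(crit$kingdoms, warn = FALSE))
  bad_ec <- crit$ec_numbers[!stringr::str_detect(crit$ec_numbers, EC_PATTERN)]
  if (length(bad_ec) > 0) {
    abort(paste0("Malformed EC number(s): ", paste(bad_ec, collapse = ", ")))
  }
  structure(crit, class = "selection_criteria")
}

#' @export
print.selection_criteria <- function(x, ...) {
  if (is_match_all(x)) {
    cat("<selection_criteria: match-all>\n")
    return(invisible(x))
  }
  cat("<selection_criteria>\n")
  for (cat_name in CRITERIA_CATEGORIES) {
    if (length(x[[cat_name]]) > 0) {
      cat("  ", cat_name, ": ", paste(x[[cat_name]], collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Does a criteria object match everything?
#' @param criteria A `selection_criteria` object (or `NULL`, which matches all).
#' @return Logical scalar.
#' @export
is_match_all <- function(criteria) {
  is.null(criteria) || all(lengths(unclass(criteria)) == 0)
}

#' Compile criteria from command-line style arguments and a YAML file
#'
#' Mirrors the two configuration surfaces of the command-line interface:
#' flag-style arguments and an optional YAML file with top-level keys
#' `classes`, `families`, `subfamilies`, `kingdoms`, `genera`, `species`,
#' `strains`, `ec_numbers` (each a list of strings). The two sources merge
#' by set union per category, so a YAML baseline can be widened from the
#' command line.
#'
#' @param cli_args Named list of character vectors (comma-separated strings
#'   accepted), e.g. `list(families = "PL20,PL28", kingdoms = "bacteria")`.
#' @param yaml_config Optional path to a YAML criteria file.
#' @return A `selection_criteria` object.
#' @export
compile_criteria <- function(cli_args = list(), yaml_config = NULL) {
  stopifnot(is.list(cli_args))
  from_yaml <- list()
  if (!is.null(yaml_config)) {
    if (length(yaml_config) != 1) {
      abort("At most one YAML configuration file is accepted.",
            class = "cazymine_config_error")
    }
    if (!file.exists(yaml_config)) {
      abort(paste0("Configuration file not found: ", sQuote(yaml_config)),
            class = "cazymine_config_error")
    }
    from_yaml <- yaml::read_yaml(yaml_config) %||% list()
  }
  unknown <- setdiff(union(names(cli_args), names(from_yaml)),
                     CRITERIA_CATEGORIES)
  if (length(unknown) > 0) {
    abort(paste0("Unknown criteria categor(ies): ",
                 paste(unknown, collapse = ", ")),
          class = "cazymine_config_error")
  }
  split_tokens <- function(x) {
    x <- as.character(unlist(x, use.names = FALSE))
    unlist(strsplit(x, ",", fixed = TRUE), use.names = FALSE)
  }
  merged <- purrr::map(setNames(CRITERIA_CATEGORIES, CRITERIA_CATEGORIES),
                       function(cat_name) {
                         union(split_tokens(cli_args[[cat_name]]),
                               split_tokens(from_yaml[[cat_name]]))
                       })
  do.call(selection_criteria, merged)
}

#' Serialize criteria to a YAML file
#'
#' Inverse of the YAML half of [compile_criteria()]:
#' `compile_criteria(yaml_config = write_criteria_yaml(x, f))` round-trips.
#'
#' @param criteria A `selection_criteria` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criteria_yaml <- function(criteria, path) {
  stopifnot(inherits(criteria, "selection_criteria"))
  keep <- purrr::keep(unclass(criteria), ~ length(.x) > 0)
  yaml::write_yaml(purrr::map(keep, as.list), path)
  invisible(path)
}

# --- matching -------------------------------------------------------------

# Family-scheme selector over a character vector of family labels.
family_scheme_hit <- function(labels, criteria) {
  if (length(criteria$classes) == 0 && length(criteria$families) == 0 &&
      length(criteria$subfamilies) == 0) {
    return(TRUE)
  }
  if (length(labels) == 0) return(FALSE)
  parsed <- parse_family_label(labels)
  family_part <- format_family_label(parsed$class_code, parsed$family_number)
  any(parsed$class_code %in% criteria$classes) ||
    any(family_part %in% criteria$families) ||
    any(parsed$label %in% criteria$subfamilies)
}

organism_hit <- function(organisms, criteria) {
  if (length(criteria$genera) == 0 && length(criteria$species) == 0 &&
      length(criteria$strains) == 0) {
    return(TRUE)
  }
  if (length(organisms) == 0) return(FALSE)
  sp <- split_organism(organisms)
  any(sp$genus %in% criteria$genera) ||
    any(organism_binomial(organisms) %in% criteria$species) ||
    any(trimws(organisms) %in% criteria$strains)
}

ec_hit <- function(ecs, criteria) {
  if (length(criteria$ec_numbers) == 0) return(TRUE)
  if (length(ecs) == 0) return(FALSE)
  any(purrr::map_lgl(ecs, function(e) {
    any(purrr::map_lgl(criteria$ec_numbers, ec_wildcard_match, ec = e))
  }))
}

# pattern "3.1.1.-" matches ec "3.1.1.4"; exact equality always matches.
ec_wildcard_match <- function(pattern, ec) {
  if (identical(pattern, ec)) return(TRUE)
  p <- strsplit(pattern, ".", fixed = TRUE)[[1]]
  e <- strsplit(ec, ".", fixed = TRUE)[[1]]
  if (length(p) != 4 || length(e) != 4) return(FALSE)
  all(p == "-" | p == e)
}

#' Evaluate criteria against per-protein views
#'
#' The workhorse predicate behind counting, querying, enrichment and
#' export. It is pure and total: every protein row yields `TRUE` or
#' `FALSE`, and empty criteria match everything.
#'
#' @param view Tibble with one row per protein: `accession`, list-columns
#'   `families` (family labels), `kingdoms`, `organisms` and `ecs` (may be
#'   absent, treated as empty). [protein_view()] builds this from a store.
#' @param criteria A `selection_criteria` object or `NULL`.
#' @return Logical vector, one element per row of `view`.
#' @export
matches <- function(view, criteria = NULL) {
  if (is_match_all(criteria)) return(rep(TRUE, nrow(view)))
  get_list <- function(col) {
    if (col %in% names(view)) view[[col]] else rep(list(character()), nrow(view))
  }
  fams <- get_list("families")
  kings <- get_list("kingdoms")
  orgs <- get_list("organisms")
  ecs <- get_list("ecs")
  out <- logical(nrow(view))
  for (i in seq_len(nrow(view))) {
    out[i] <- family_scheme_hit(fams[[i]], criteria) &&
      (length(criteria$kingdoms) == 0 ||
         any(kings[[i]] %in% criteria$kingdoms)) &&
      organism_hit(orgs[[i]], criteria) &&
      ec_hit(ecs[[i]], criteria)
  }
  out
}

# Record-level (one dump line) filter used at import time. The EC category
# is inapplicable before enrichment and is ignored here.
record_matches <- function(records, criteria = NULL) {
  if (is_match_all(criteria)) return(rep(TRUE, nrow(records)))
  fam_ok <- purrr::map_lgl(records$family, family_scheme_hit, criteria = criteria)
  king_ok <- if (length(criteria$kingdoms) == 0) TRUE else
    records$kingdom %in% criteria$kingdoms
  org_ok <- purrr::map_lgl(records$organism, organism_hit, criteria = criteria)
  fam_ok & king_ok & org_ok
}
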