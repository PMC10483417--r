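# Family-survey statistics: representation rates, chi-squared decomposition
# with Pearson-residual explained variance, BLAST-Score-Ratio matrices,
# redundancy detection, greedy clustering, structural coverage.

#' Species representation-rate table
#'
#' Given, per kingdom, the total number of species-level taxa in the
#' reference taxonomy and the numbers of those species with at least one
#' and at least 50 catalogued CAZymes, computes the percentage each count
#' represents of its kingdom, appends a `Total` row (sums of the counts,
#' then the same percentage formula), and rounds percentages half-up to
#' two decimals.
#'
#' @param census Tibble with columns `kingdom`, `species_total`,
#'   `n_ge1`, `n_ge50` (counts; `0 <= n_ge50 <= n_ge1 <= species_total`).
#' @return Tibble with the input columns plus `pct_ge1` and `pct_ge50`,
#'   and a final `Total` row.
#' @examples
#' representation_rates(tibble::tibble(
#'   kingdom = "Archaea", species_total = 12709, n_ge1 = 665, n_ge50 = 109))
#' @export
representation_rates <- function(census) {
  need <- c("kingdom", "species_total", "n_ge1", "n_ge50")
  stopifnot(all(need %in% names(census)))
  with(census, {
    if (any(n_ge50 > n_ge1 | n_ge1 > species_total | n_ge50 < 0)) {
      abort("Counts must satisfy 0 <= n_ge50 <= n_ge1 <= species_total.")
    }
    if (any(species_total == 0 & n_ge1 > 0)) {
      abort("A kingdom with zero species cannot have CAZyme-bearing species.",
            class = "cazymine_domain_error")
    }
  })
  totals <- tibble::tibble(
    kingdom = "Total",
    species_total = sum(census$species_total),
    n_ge1 = sum(census$n_ge1),
    n_ge50 = sum(census$n_ge50))
  out <- dplyr::bind_rows(census[, need], totals)
  pct <- function(n, total) {
    ifelse(total == 0, 0, round_half_up(100 * n / total, 2))
  }
  out$pct_ge1 <- pct(out$n_ge1, out$species_total)
  out$pct_ge50 <- pct(out$n_ge50, out$species_total)
  out
}

#' Chi-squared test with Pearson-residual explained-variance decomposition
#'
#' Beyond the omnibus statistic, each cell's contribution is expressed as
#' an explained-variance percentage
#' \deqn{V = 100 \, r^2 / \chi^2, \qquad r = (O - E)/\sqrt{E},}
#' which sums to exactly 100 over all cells and shows *which* categories
#' drive a significant result (e.g. which kingdoms are over- or
#' under-represented relative to a reference protein census). The sign of
#' the residual `r` gives the direction.
#'
#' Three reference forms are supported:
#' * `observed` a vector + `expected_probs`: goodness of fit,
#'   \eqn{E_i = N p_i}, df = k - 1.
#' * `observed` a vector + `reference_counts`: the two vectors form a
#'   2-by-k homogeneity table (standard row-by-column expected counts).
#' * `observed` a matrix: test of independence on the matrix.
#'
#' @param observed Non-negative counts: vector or matrix.
#' @param expected_probs Probabilities summing to 1 (goodness of fit).
#' @param reference_counts Second count vector (homogeneity).
#' @return An object of class `chisq_decomposition` with elements
#'   `statistic`, `dof`, `p_value`, `observed`, `expected`, `residuals`
#'   and `explained` (percent, same shape as `observed`). [tidy()] gives
#'   the per-cell table, [glance()] the one-row summary.
#' @export
chisq_decompose <- function(observed, expected_probs = NULL,
                            reference_counts = NULL) {
  if (!is.null(expected_probs) && !is.null(reference_counts)) {
    abort("Give either expected_probs or reference_counts, not both.")
  }
  if (any(observed < 0)) abort("Observed counts must be non-negative.")
  if (is.matrix(observed)) {
    O <- observed
  } else if (!is.null(reference_counts)) {
    if (length(reference_counts) != length(observed)) {
      abort("reference_counts must have the same length as observed.")
    }
    O <- rbind(observed = observed, reference = reference_counts)
  } else if (!is.null(expected_probs)) {
    if (length(expected_probs) != length(observed)) {
      abort("expected_probs must have the same length as observed.")
    }
    if (abs(sum(expected_probs) - 1) > 1e-8) {
      abort("expected_probs must sum to 1.")
    }
    O <- matrix(observed, nrow = 1,
                dimnames = list(NULL, names(observed)))
  } else {
    abort("A reference (expected_probs or reference_counts) is required
           for a vector of observed counts.")
  }
  if (length(O) < 2) abort("At least two cells are required.")

  if (!is.null(expected_probs)) {
    E <- matrix(sum(observed) * expected_probs, nrow = 1,
                dimnames = dimnames(O))
    dof <- length(observed) - 1L
  } else {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    dimnames(E) <- dimnames(O)
    dof <- (nrow(O) - 1L) * (ncol(O) - 1L)
  }
  if (any(E == 0)) {
    abort("Expected count of zero in at least one cell; pool sparse
           categories before testing.", class = "cazymine_domain_error")
  }
  r <- (O - E) / sqrt(E)
  chi2 <- sum(r^2)
  if (chi2 == 0) {
    abort("degenerate: zero statistic (observed equals expected exactly;
           explained variance is undefined).",
          class = "cazymine_domain_error")
  }
  structure(list(
    statistic = chi2,
    dof = dof,
    p_value = pchisq(chi2, dof, lower.tail = FALSE),
    observed = O,
    expected = E,
    residuals = r,
    explained = 100 * r^2 / chi2
  ), class = "chisq_decomposition")
}

#' @export
print.chisq_decomposition <- function(x, ...) {
  cat(sprintf("Chi-squared decomposition: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$dof, x$p_value))
  cat("Explained variance (%):\n")
  print(round(x$explained, 2))
  invisible(x)
}

#' @describeIn chisq_decompose Per-cell tibble: `row`, `col`, `observed`,
#'   `expected`, `residual`, `explained_pct`.
#' @param x A `chisq_decomposition`.
#' @param ... Unused.
#' @method tidy chisq_decomposition
#' @export
tidy.chisq_decomposition <- function(x, ...) {
  O <- x$observed
  rows <- rownames(O) %||% as.character(seq_len(nrow(O)))
  cols <- colnames(O) %||% as.character(seq_len(ncol(O)))
  tibble::tibble(
    row = rep(rows, times = ncol(O)),
    col = rep(cols, each = nrow(O)),
    observed = as.vector(O),
    expected = as.vector(x$expected),
    residual = as.vector(x$residuals),
    explained_pct = as.vector(x$explained)
  )
}

#' @describeIn chisq_decompose One-row summary: `statistic`, `dof`,
#'   `p_value`, `n_cells`.
#' @method glance chisq_decomposition
#' @export
glance.chisq_decomposition <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, dof = x$dof, p_value = x$p_value,
                 n_cells = length(x$observed))
}

#' BLAST-Score-Ratio matrix over a set of sequences
#'
#' All-vs-all pairwise comparison: the BSR of an ordered pair (a, b) is
#' the raw alignment score of a against b divided by a's self-alignment
#' score, so `bsr(a, a) = 1` exactly, identical sequences score 1, and
#' unrelated sequences score near 0. The matrix is query-normalized and
#' may be asymmetric when sequence lengths differ.
#'
#' @param sequences Named character vector, `accession`/`sequence` tibble,
#'   or `AAStringSet`.
#' @param scorer Pairwise raw-score function `f(a, b)`; the default is the
#'   built-in Smith-Waterman scorer ([local_alignment_score()]). Ignored
#'   when `scores` is given.
#' @param scores Optional external score table (tibble with columns
#'   `query`, `subject`, `score`), e.g. parsed blastp tabular output;
#'   missing pairs score 0.
#' @return Object of class `bsr_matrix`: list with `accessions`, `scores`
#'   (raw), `bsr` (ratio matrix, rows = query).
#' @export
bsr_matrix <- function(sequences, scorer = NULL, scores = NULL) {
  seqs <- as_sequence_vector(sequences)
  acc <- names(seqs)
  n <- length(seqs)
  raw <- matrix(0, n, n, dimnames = list(acc, acc))
  if (!is.null(scores)) {
    stopifnot(all(c("query", "subject", "score") %in% names(scores)))
    keep <- scores$query %in% acc & scores$subject %in% acc
    scores <- scores[keep, , drop = FALSE]
    # top-ranked alignment per pair: keep the highest raw score
    scores <- scores |>
      dplyr::group_by(.data$query, .data$subject) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
    raw[cbind(match(scores$query, acc), match(scores$subject, acc))] <-
      scores$score
  } else {
    scorer <- scorer %||% local_alignment_score
    for (i in seq_len(n)) raw[i, i] <- scorer(seqs[[i]], seqs[[i]])
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        raw[i, j] <- if (identical(seqs[[i]], seqs[[j]])) {
          raw[i, i]  # identical sequences: alignment equals self-alignment
        } else {
          scorer(seqs[[i]], seqs[[j]])
        }
      }
    }
  }
  self <- diag(raw)
  if (any(self <= 0)) {
    abort("Self-alignment score must be positive for every sequence.",
          class = "cazymine_domain_error")
  }
  bsr <- raw / self  # divides each row by its query's self score
  diag(bsr) <- 1
  structure(list(accessions = acc, scores = raw, bsr = bsr),
            class = "bsr_matrix")
}

#' @export
print.bsr_matrix <- function(x, ...) {
  cat(sprintf("<bsr_matrix> %d sequences; mean off-diagonal BSR %.3f\n",
              length(x$accessions),
              mean(x$bsr[row(x$bsr) != col(x$bsr)])))
  invisible(x)
}

#' @describeIn bsr_matrix Long tibble of ordered pairs: `query`, `subject`,
#'   `score`, `bsr`.
#' @param x A `bsr_matrix`.
#' @param ... Unused.
#' @method tidy bsr_matrix
#' @export
tidy.bsr_matrix <- function(x, ...) {
  acc <- x$accessions
  tibble::tibble(
    query = rep(acc, times = length(acc)),
    subject = rep(acc, each = length(acc)),
    score = as.vector(x$scores),
    bsr = as.vector(x$bsr)
  )
}

#' Find redundant (byte-identical) sequence pairs
#'
#' CAZy can catalogue the same amino-acid sequence under both a GenBank
#' and a RefSeq accession; such pairs inflate family counts and should be
#' collapsed before e.g. building machine-learning training sets. Every
#' unordered pair of byte-identical sequences is reported (a group of m
#' identical sequences yields choose(m, 2) pairs).
#'
#' @param sequences Named character vector, `accession`/`sequence` tibble,
#'   `AAStringSet`, or a `cazy_store` (stored sequences are used).
#' @param criteria Optional [selection_criteria()] when `sequences` is a
#'   store.
#' @return Tibble: `accession_a`, `accession_b` (a < b lexicographically),
#'   `kind_a`, `kind_b` (genbank/refseq), `sequence`.
#' @export
find_redundant_pairs <- function(sequences, criteria = NULL) {
  if (inherits(sequences, "cazy_store")) {
    view <- protein_view(sequences)
    view <- view[matches(view, criteria) & !is.na(view$sequence), ]
    seqs <- setNames(view$sequence, view$accession)
  } else {
    seqs <- as_sequence_vector(sequences)
  }
  empty <- tibble::tibble(accession_a = character(),
                          accession_b = character(),
                          kind_a = character(), kind_b = character(),
                          sequence = character())
  if (length(seqs) < 2) return(empty)
  groups <- split(names(seqs), seqs)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) return(empty)
  purrr::map_dfr(names(groups), function(s) {
    members <- stringr::str_sort(groups[[s]], locale = "C")
    pairs <- t(utils::combn(members, 2))
    tibble::tibble(accession_a = pairs[, 1], accession_b = pairs[, 2],
                   kind_a = classify_accession(pairs[, 1]),
                   kind_b = classify_accession(pairs[, 2]),
                   sequence = s)
  }) |>
    dplyr::arrange(.data$accession_a, .data$accession_b)
}

#' Greedy identity/coverage clustering of protein sequences
#'
#' Incremental single-representative clustering in the CD-HIT tradition:
#' sequences are visited in order of decreasing length (accession order
#' breaks ties); each sequence joins the first existing cluster whose
#' *representative* it matches at `>= identity_threshold` over
#' `>= coverage_threshold` of **both** sequences, otherwise it founds a
#' new cluster. Identity is matches / alignment columns of a global
#' alignment; coverage is the mutually aligned span over each sequence's
#' length.
#'
#' @param sequences Named character vector, `accession`/`sequence` tibble,
#'   or `AAStringSet`.
#' @param identity_threshold,coverage_threshold Numbers in (0, 1]; the
#'   conventional survey setting is 0.4 identity / 0.8 coverage.
#' @return Object of class `cluster_set`: tibble `members` (`accession`,
#'   `cluster`, `representative`, `is_representative`) plus the thresholds
#'   as attributes. The clusters partition the input.
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.4,
                           coverage_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  seqs <- as_sequence_vector(sequences)
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character()     # representative accessions, founding order
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      rep_seq <- seqs[[reps[k]]]
      if (identical(seqs[[i]], rep_seq)) {
        assign[i] <- k; placed <- TRUE; break
      }
      st <- global_alignment_stats(seqs[[i]], rep_seq)
      if (st$identity >= identity_threshold &&
          st$coverage_a >= coverage_threshold &&
          st$coverage_b >= coverage_threshold) {
        assign[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      assign[i] <- length(reps)
    }
  }
  members <- tibble::tibble(
    accession = names(seqs),
    cluster = assign,
    representative = reps[assign],
    is_representative = names(seqs) == reps[assign]
  ) |> dplyr::arrange(.data$cluster, .data$accession)
  structure(members,
            class = c("cluster_set", class(members)),
            identity_threshold = identity_threshold,
            coverage_threshold = coverage_threshold)
}

#' Read / write cluster membership TSV
#'
#' Two-column `representative<TAB>member` files, the de-facto interchange
#' format of common clustering tools, can stand in for the built-in
#' clusterer.
#'
#' @param path TSV path (no header, two columns).
#' @return For `read_cluster_tsv()`: a `cluster_set`.
#' @export
read_cluster_tsv <- function(path) {
  df <- readr::read_tsv(path, col_names = c("representative", "accession"),
                        col_types = "cc", progress = FALSE)
  reps <- unique(df$representative)
  members <- tibble::tibble(
    accession = df$accession,
    cluster = match(df$representative, reps),
    representative = df$representative,
    is_representative = df$accession == df$representative
  ) |> dplyr::arrange(.data$cluster, .data$accession)
  structure(members, class = c("cluster_set", class(members)),
            identity_threshold = NA_real_, coverage_threshold = NA_real_)
}

#' @rdname read_cluster_tsv
#' @param clusters A `cluster_set`.
#' @export
write_cluster_tsv <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  readr::write_tsv(clusters[, c("representative", "accession")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Structural coverage of families and clusters
#'
#' Per family: how many distinct member accessions exist and how many
#' carry at least one PDB structure link. Per cluster (when a
#' `cluster_set` is given): whether any member has a structure — clusters
#' without one are candidate targets for structure determination. When an
#' independent list of structurally characterized accessions is supplied
#' (e.g. the source database's own structure annotations), the two
#' discrepancy lists are reported as well.
#'
#' @param store A `cazy_store` with PDB links attached.
#' @param clusters Optional `cluster_set` over (a subset of) the stored
#'   accessions.
#' @param annotated_structured Optional character vector of accessions
#'   annotated as structurally characterized by an independent source.
#' @param criteria Optional [selection_criteria()] restricting the family
#'   census.
#' @return List of class `structural_coverage`:
#'   `families` (tibble `family`, `n_members`, `n_with_pdb`),
#'   `totals` (one-row tibble of column sums),
#'   `clusters` (tibble `cluster`, `representative`, `size`,
#'   `has_structure`, or `NULL`),
#'   `annotated_not_in_pdb_links` / `pdb_links_not_annotated`
#'   (character vectors, when `annotated_structured` given).
#' @export
structural_coverage <- function(store, clusters = NULL,
                                annotated_structured = NULL,
                                criteria = NULL) {
  stopifnot(inherits(store, "cazy_store"))
  view <- protein_view(store)
  view <- view[matches(view, criteria), , drop = FALSE]
  has_pdb <- lengths(view$pdbs) > 0
  long <- tibble::tibble(accession = view$accession,
                         has_pdb = has_pdb,
                         family = view$families) |>
    tidyr::unnest("family")
  parsed <- parse_family_label(long$family)
  long$family <- format_family_label(parsed$class_code, parsed$family_number)
  families <- long |>
    dplyr::distinct(.data$family, .data$accession, .data$has_pdb) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_members = dplyr::n_distinct(.data$accession),
                     n_with_pdb = dplyr::n_distinct(
                       .data$accession[.data$has_pdb]),
                     .groups = "drop") |>
    dplyr::arrange(.data$family)
  totals <- tibble::tibble(n_members = sum(families$n_members),
                           n_with_pdb = sum(families$n_with_pdb))
  cluster_report <- NULL
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "cluster_set"))
    structured <- view$accession[has_pdb]
    cluster_report <- clusters |>
      dplyr::group_by(.data$cluster, .data$representative) |>
      dplyr::summarise(size = dplyr::n(),
                       has_structure = any(.data$accession %in% structured),
                       .groups = "drop")
  }
  out <- list(families = families, totals = totals, clusters = cluster_report)
  if (!is.null(annotated_structured)) {
    with_links <- view$accession[has_pdb]
    out$annotated_not_in_pdb_links <-
      stringr::str_sort(setdiff(annotated_structured, with_links),
                        locale = "C")
    out$pdb_links_not_annotated <-
      stringr::str_sort(setdiff(with_links, annotated_structured),
                        locale = "C")
  }
  structure(out, class = "structural_coverage")
}

#' @export
print.structural_coverage <- function(x, ...) {
  cat(sprintf("<structural_coverage> %d families, %d members, %d with PDB\n",
              nrow(x$families), x$totals$n_members, x$totals$n_with_pdb))
  if (!is.null(x$clusters)) {
    cat(sprintf("  clusters: %d (%d with structure)\n", nrow(x$clusters),
                sum(x$clusters$has_structure)))
  }
  invisible(x)
}
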