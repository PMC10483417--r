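# Pairwise alignment primitives behind the BSR matrix and the greedy
# clusterer. Smith-Waterman / Needleman-Wunsch come from Biostrings; the
# scoring conventions here (BLOSUM62, gap open 11 / extend 1) mirror the
# blastp defaults so raw-score ratios are comparable to BLAST-style BSRs.

#' Built-in local-alignment scorer
#'
#' Returns the raw Smith-Waterman score of the best local alignment of two
#' amino-acid sequences under BLOSUM62 with affine gaps (open 11,
#' extend 1). With these penalties the expected score of unrelated
#' sequences is non-positive, which keeps score ratios in [0, 1].
#'
#' @param a,b Amino-acid strings.
#' @return Numeric raw alignment score.
#' @export
local_alignment_score <- function(a, b) {
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)))
}

# Global (Needleman-Wunsch) alignment statistics used by the clusterer:
#  identity  = matches / alignment columns
#  coverage  = mutually aligned columns (both residues) / sequence length,
#              one value per sequence. A strict end-to-end span would be
#              identically 1 under a global alignment, making the coverage
#              threshold inert; the mutually-aligned definition penalises
#              length mismatch the way fragment-vs-full-length comparisons
#              should be.
global_alignment_stats <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- sum(pat != "-" & sub != "-")
  list(
    identity = Biostrings::nmatch(aln) / length(pat),
    coverage_a = both / nchar(a),
    coverage_b = both / nchar(b)
  )
}

# Coerce a named character vector / AAStringSet / tibble(accession,
# sequence) into a named character vector of sequences.
as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "AAStringSet")) {
    out <- as.character(sequences)
  } else if (is.data.frame(sequences)) {
    stopifnot(all(c("accession", "sequence") %in% names(sequences)))
    out <- setNames(sequences$sequence, sequences$accession)
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    abort("Sequences must be a named character vector, a tibble with
           accession/sequence columns, or an AAStringSet.")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    abort("Every sequence needs a name (its accession).")
  }
  if (any(is.na(out) | !nzchar(out))) {
    abort("Empty sequences are not allowed.")
  }
  out
}
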