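#' Build an affine-gap scoring scheme
#'
#' Defaults are the conventional match +1, mismatch -1, gap open -2,
#' gap extend -0.5. A gap of length L costs `gapOpen + L * gapExtend`.
#'
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; gap penalties
#'   must be <= 0 and the match reward >= 0.
#' @return a [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(match = 1, mismatch = -1,
                          gapOpen = -2, gapExtend = -0.5) {
  methods::new("ScoringScheme", match = as.numeric(match),
               mismatch = as.numeric(mismatch), gapOpen = as.numeric(gapOpen),
               gapExtend = as.numeric(gapExtend))
}

.asSeqString <- function(x, what = "sequence") {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single sequence string or XString")
  x <- toupper(x)
  if (!nzchar(x)) stop(what, " must be non-empty")
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A, C, G, T, N}")
  x
}

#' Optimal global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap penalties and
#' deterministic tie-breaking (match/mismatch preferred over gaps, gap in
#' `b` preferred over gap in `a`). `N` never matches anything, including
#' another `N`; this is deliberately conservative for identity thresholds
#' in the 99.9% range.
#'
#' @param a,b nucleotide sequences (character or `DNAString`) over
#'   \{A, C, G, T, N\}.
#' @param scheme a [ScoringScheme-class]; see [scoringScheme()].
#' @param band optional non-negative integer restricting the alignment to a
#'   diagonal band of that half-width; `NULL` (default) runs the full
#'   dynamic program. Only use a band when the expected indel offset is
#'   smaller than the half-width (e.g. equal-length, high-identity pairs).
#' @return an [AlignmentResult-class].
#' @examples
#' aln <- globalAlign("ACGTACGTAC", "ACGTACGTAC")
#' percentIdentity(aln)
#' @export
globalAlign <- function(a, b, scheme = scoringScheme(), band = NULL) {
  a <- .asSeqString(a, "a")
  b <- .asSeqString(b, "b")
  # canonical argument order: equal-score alignments can differ in gap
  # placement, so aligning in a fixed order makes every column count (and
  # hence identity) exactly symmetric in the inputs
  swap <- a > b
  res <- if (swap)
    .align_affine_cpp(b, a, scheme@match, scheme@mismatch,
                      scheme@gapOpen, scheme@gapExtend,
                      FALSE, if (is.null(band)) -1L else as.integer(band))
  else
    .align_affine_cpp(a, b, scheme@match, scheme@mismatch,
                      scheme@gapOpen, scheme@gapExtend,
                      FALSE, if (is.null(band)) -1L else as.integer(band))
  methods::new("AlignmentResult",
               alignedA = if (swap) res$aligned_b else res$aligned_a,
               alignedB = if (swap) res$aligned_a else res$aligned_b,
               matches = res$matches, mismatches = res$mismatches,
               gapOpenings = res$gap_openings, gapColumns = res$gap_columns,
               score = res$score)
}

#' Percent identity of an alignment
#'
#' Defined as `100 * matches / (matches + mismatches + gapColumns)`: the
#' denominator is the full alignment length, so every gap column counts
#' once and indels reduce identity.
#'
#' @param aln an [AlignmentResult-class].
#' @return identity in percent, in \[0, 100\].
#' @export
percentIdentity <- function(aln) {
  stopifnot(methods::is(aln, "AlignmentResult"))
  len <- aln@matches + aln@mismatches + aln@gapColumns
  if (len == 0L) stop("zero-length alignment")
  100 * aln@matches / len
}

#' Mismatches + gap openings of an alignment
#'
#' The variant-separation metric used by the intragenomic variant catalog:
#' a contiguous indel counts as one event regardless of its length.
#'
#' @param aln an [AlignmentResult-class].
#' @return integer count of mismatches plus gap openings.
#' @export
alignmentDistance <- function(aln) {
  stopifnot(methods::is(aln, "AlignmentResult"))
  aln@mismatches + aln@gapOpenings
}

#' Jukes-Cantor nucleotide distance
#'
#' Maximum-likelihood substitutions/site under the equal-rates nucleotide
#' model: `-(3/4) * log(1 - 4p/3)`.
#'
#' @param p proportion(s) of differing sites, `0 <= p < 0.75`.
#' @return substitutions per site (vectorized over `p`).
#' @examples
#' jcDistance(0.10)
#' @export
jcDistance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 0.75))
    stop("saturation: Jukes-Cantor distance is undefined for p >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' Poisson-corrected amino-acid distance
#'
#' Maximum-likelihood substitutions/site under the equal-rates 20-state
#' model: `-(19/20) * log(1 - 20p/19)`.
#'
#' @param p proportion(s) of differing residues, `0 <= p < 0.95`.
#' @return substitutions per site (vectorized over `p`).
#' @export
poissonAaDistance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 0.95))
    stop("saturation: Poisson amino-acid distance is undefined for p >= 19/20")
  -(19 / 20) * log(1 - 20 * p / 19)
}
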