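#' Global edit-distance similarity percent
#'
#' The single similarity measure used throughout the sorter:
#' `100 * (1 - D / L)` where `D` is the global (Needleman-Wunsch, unit-cost)
#' edit distance between the two sequences and `L` the length of the longer
#' one. Symmetric and bounded to `[0, 100]`. `N` never matches anything
#' (including another `N`). The denominator choice makes the similarity
#' thresholds and the relative length gates mutually consistent: two sequences
#' differing by more than x% in length can never reach `100 - x`% similarity.
#'
#' @param a,b non-empty DNA strings over `A`, `C`, `G`, `T`, `N`.
#' @return similarity percent (double, not rounded).
#' @seealso [oriented_similarity()], [length_compatible()]
#' @export
#' @examples
#' similarity("AAAA", "AATA")      # 75: one substitution over length 4
#' similarity("ACGTACGT", "ACGT")  # 50: four edits over length 8
similarity <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("similarity() requires two non-empty sequences")
  }
  d <- edit_dist_cpp(a, b)
  100 * (1 - d / max(nchar(a), nchar(b)))
}

#' Read-length compatibility gate
#'
#' Two lengths are compatible when their difference, relative to the longer
#' one, is strictly below `max_frac`. Used with 5% for read-read and
#' read-consensus comparisons and 8% for consensus-consensus comparisons.
#'
#' @param len_a,len_b positive sequence lengths (vectorised).
#' @param max_frac maximum allowed relative difference, in (0, 1), exclusive.
#' @return logical.
#' @export
#' @examples
#' length_compatible(700, 666, 0.05)  # TRUE  (34/700 < 5%)
#' length_compatible(700, 664, 0.05)  # FALSE (36/700 >= 5%)
length_compatible <- function(len_a, len_b, max_frac) {
  stopifnot(all(len_a > 0), all(len_b > 0),
            max_frac > 0, max_frac < 1)
  abs(len_a - len_b) / pmax(len_a, len_b) < max_frac
}

#' Similarity with reverse-complement rescue
#'
#' Computes same-strand similarity first; only when it falls below
#' `rc_trigger` (default 50%) is the reverse complement of the second sequence
#' also tried, and the better of the two orientations returned (ties go to
#' same-strand). Amplicon pools contain reads from both strands, so a pair of
#' reads from the same molecule can look unrelated until one is flipped.
#'
#' @param a,b DNA strings.
#' @param rc_trigger similarity percent below which the reverse complement is
#'   consulted.
#' @return a list with `similarity` (percent) and `orientation`
#'   (`"same"` or `"opposite"`).
#' @export
#' @examples
#' x <- oriented_similarity("ACGGTTAACCA", reverse_complement("ACGGTTAACCA"))
#' x$orientation
oriented_similarity <- function(a, b, rc_trigger = 50) {
  stopifnot(rc_trigger > 0, rc_trigger < 100)
  s1 <- similarity(a, b)
  if (s1 >= rc_trigger) {
    return(list(similarity = s1, orientation = "same"))
  }
  s2 <- similarity(a, reverse_complement(b))
  if (s2 > s1) {
    list(similarity = s2, orientation = "opposite")
  } else {
    list(similarity = s1, orientation = "same")
  }
}

#' Similarity between two consensus sequences
#'
#' Convenience wrapper around [oriented_similarity()] returning just the
#' percent; used when comparing gene-group or species-group consensuses.
#'
#' @param c1,c2 consensus DNA strings.
#' @return similarity percent.
#' @export
consensus_similarity <- function(c1, c2) {
  oriented_similarity(c1, c2)$similarity
}

#' Reverse complement
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`. Only
#' `A`, `C`, `G`, `T`, `N` are accepted (case-insensitive): other IUPAC
#' ambiguity codes are rejected because the similarity measure scores any
#' non-ACGT symbol as a mismatch anyway, and silently accepting them would
#' hide upstream problems.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements (uppercase).
#' @export
#' @examples
#' reverse_complement("AAACCC")  # "GGGTTT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (length(seq) == 0L) return(character(0))
  up <- toupper(seq)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("sequence ", which(bad)[1],
         " contains characters other than A/C/G/T/N")
  }
  as.character(reverseComplement(DNAStringSet(up)))
}
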