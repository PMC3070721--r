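#' Homopolymer-insensitive global alignment distance
#'
#' Computes the minimum, over all global alignments of `a` and `b`, of the
#' number of counted-difference columns. A substitution column counts 1; an
#' indel column counts 0 if and only if the inserted/deleted base equals the
#' most recently aligned base of the opposite sequence, i.e. the indel only
#' lengthens or shortens a homopolymer run shared by both sequences at that
#' point. Indels before any opposite base has been aligned always count 1.
#'
#' This distance treats 454-style homopolymer run-length miscalls as free:
#' `hp_distance("ATGTGGGGTAT", "ATGTGGGTAT")` is 0 even though the strings
#' differ, because the extra G only lengthens a shared G run.
#'
#' @param a,b DNA strings over A, C, G, T. May be empty.
#' @param alignment if `TRUE`, also return one minimum-cost alignment as a
#'   pair of gapped strings (ties between alignments are broken arbitrarily;
#'   only the distance is contractual).
#' @return A list with `distance` (non-negative integer) and, if requested,
#'   `alignment` (character vector of length 2).
#' @seealso [within_k()], [hp_distance_oracle()]
#' @export
#' @examples
#' hp_distance("ATGTGGGGTAT", "ATGTGGGTAT")$distance  # 0
#' hp_distance("ACGT", "ACGA")$distance               # 1
hp_distance <- function(a, b, alignment = FALSE) {
  .hp_distance_cpp(a, b, alignment)
}

#' Exhaustive-alignment oracle for the homopolymer distance
#'
#' Enumerates every global alignment path of two short sequences and returns
#' the minimum counted-difference total under the same column-costing rule as
#' [hp_distance()]. Exponential in sequence length; intended only as an
#' independent check of the dynamic program in tests.
#'
#' @param a,b DNA strings.
#' @param max_len refuse sequences longer than this (default 12).
#' @return Integer distance.
#' @export
hp_distance_oracle <- function(a, b, max_len = 12L) {
  .hp_oracle_cpp(a, b, max_len)
}

#' Test whether two sequences are within k counted differences
#'
#' Equivalent to `hp_distance(a, b)$distance <= k` but abandons the dynamic
#' program as soon as every continuation must exceed `k`, which makes the
#' all-against-seeds comparisons of greedy clustering fast.
#'
#' @param a,b DNA strings.
#' @param k non-negative integer radius (the study default is 3).
#' @return Logical.
#' @export
within_k <- function(a, b, k) {
  .hp_bounded_cpp(a, b, as.integer(k)) <= k
}

#' Global alignment identity fraction
#'
#' Matches divided by alignment columns of a unit-cost global alignment; used
#' by [resolution_profile()] when clustering reference sequences at a
#' percent-similarity level.
#'
#' @param a,b DNA strings.
#' @return Fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  r <- .nw_identity_cpp(a, b)
  r$matches / r$columns
}
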