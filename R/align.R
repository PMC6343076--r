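#' Levenshtein (unit-cost edit) distance
#'
#' Standard dynamic-programming edit distance between nucleotide strings,
#' used by the abundance-skew denoiser. Delegates to the C implementation
#' behind [utils::adist()].
#'
#' @param a,b character vectors; distances are computed between all pairs.
#' @return integer matrix of distances (`length(a)` x `length(b)`), or a
#'   single integer when both inputs are scalars.
#' @examples
#' levenshteinDist("ACGT", "ACGA")
#' @export
levenshteinDist <- function(a, b) {
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  if (length(a) == 1L && length(b) == 1L) d[1L, 1L] else d
}

#' Pairwise sequence identity under end-gap-free alignment
#'
#' Globally aligns two sequences with free terminal gaps (overlap
#' alignment) under unit scoring (match +1, mismatch -1, gap -1), breaking
#' score ties toward more matches, and returns
#' `matches / alignment columns` with terminal gap columns excluded. This
#' single identity convention is used everywhere: OTU clustering, read
#' mapping, and ZOTU-to-OTU mapping.
#'
#' @param a,b non-empty nucleotide strings.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity(strrep("A", 100), paste0(strrep("A", 97), "CCC"))
#' @export
pairwiseIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  overlap_identity_cpp(a, b)
}

## Identities of one query against many references, exact at/above
## min_identity (banded search; see src/alignment.cpp).
.identities_vs <- function(query, refs, min_identity) {
  banded_identity_cpp(query, refs, min_identity)
}

## Pick the best reference index for a query under the shared tie rules:
## highest identity, then larger `size`, then earlier position.
## Returns 0 when nothing reaches min_identity.
.best_hit <- function(idents, sizes, min_identity) {
  ok <- which(idents >= min_identity - 1e-12)
  if (!length(ok)) return(0L)
  best <- ok[idents[ok] >= max(idents[ok]) - 1e-12]
  if (length(best) > 1L) best <- best[sizes[best] == max(sizes[best])]
  best[1L]
}
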