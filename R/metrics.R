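#' Biodiversity metrics on abundance vectors
#'
#' The three community metrics tracked by the simulations, computed on a
#' per-species abundance vector (typically a MaxN vector):
#' * `total_abundance()` - the sum of species abundances;
#' * `species_richness()` - the number of species with abundance > 0;
#' * `hill_shannon()` - the Hill number of order 1,
#'   `exp(-sum(p_i * log(p_i)))` with natural logarithm, where `p_i` is the
#'   relative abundance of species `i` among species present. It equals the
#'   effective number of equally-abundant species and satisfies
#'   `1 <= hill_shannon(v) <= species_richness(v)`, with equality to
#'   richness exactly at perfectly even abundances.
#'
#' An all-zero vector has diversity 0 by convention (the entropy of an empty
#' community is undefined; the convention only arises in degenerate
#' pipeline configurations and is signalled with a warning).
#'
#' @param v Non-negative numeric abundance vector.
#' @return A single number.
#' @examples
#' v <- c(20, 2, 2, 2, 8, 8, 8, 8, rep(1, 7))
#' total_abundance(v)  # 65
#' species_richness(v) # 15
#' hill_shannon(v)     # 8.71
#' @export
total_abundance <- function(v) {
  stopifnot(all(v >= 0))
  sum(v)
}

#' @rdname total_abundance
#' @export
species_richness <- function(v) {
  stopifnot(all(v >= 0))
  sum(v > 0)
}

#' @rdname total_abundance
#' @export
hill_shannon <- function(v) {
  stopifnot(all(v >= 0))
  tot <- sum(v)
  if (tot == 0) {
    warning("empty community: Hill-Shannon diversity set to 0")
    return(0)
  }
  p <- v[v > 0] / tot
  exp(-sum(p * log(p)))
}

#' Jaccard similarity between two species sets
#'
#' The number of shared species divided by the total number of distinct
#' species across both sets. Two empty sets are identical by convention
#' (similarity 1, with a warning).
#'
#' @param a,b Vectors of species identifiers (sets).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard(1:15, 1:30) # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both species sets empty: Jaccard similarity set to 1")
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Bray-Curtis similarity between two abundance vectors
#'
#' `2 * sum(pmin(a, b)) / sum(a + b)` over a shared species index: 1 when
#' both communities have identical abundances, 0 when they share no
#' species. Two all-zero vectors are identical by convention (similarity 1,
#' with a warning).
#'
#' @param a,b Non-negative numeric vectors over the same species index.
#' @return Similarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(2, 0, 1), c(1, 1, 1)) # 2/3
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  denom <- sum(a + b)
  if (denom == 0) {
    warning("both abundance vectors empty: Bray-Curtis similarity set to 1")
    return(1)
  }
  2 * sum(pmin(a, b)) / denom
}
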