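# Cluster-quality measures: adjusted Rand index and a silhouette
# coefficient with great-circle (arc length) distances.

#' Adjusted Rand index
#'
#' Chance-corrected pairwise agreement between two partitions of the same
#' observations, computed from the contingency table under the
#' permutation model. Equals 1 iff the partitions are identical up to
#' relabelling and has expected value 0 under independent random
#' labelling. The noise cluster is compared as an ordinary label.
#'
#' @param a,b vectors of cluster labels of equal length (any comparable
#'   type).
#' @return scalar ARI, at most 1.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have equal length")
  if (length(a) < 2L)
    stop("at least two observations are required")
  tab <- table(a, b)
  sumNij <- sum(choose(tab, 2))
  sumAi <- sum(choose(rowSums(tab), 2))
  sumBj <- sum(choose(colSums(tab), 2))
  nPairs <- choose(length(a), 2)
  expected <- sumAi * sumBj / nPairs
  maxIndex <- (sumAi + sumBj) / 2
  if (maxIndex == expected) return(1)      # both partitions trivial
  (sumNij - expected) / (maxIndex - expected)
}

#' Spherical silhouette coefficient
#'
#' Silhouette coefficient for directional data: the distance between two
#' observations is the arc length along the unit sphere,
#' \eqn{d(x, y) = \arccos(x'y)} (the inner product is clipped to [-1, 1]
#' so rounding cannot leave the domain). For observation i with
#' within-cluster mean distance a and smallest other-cluster mean
#' distance b, the silhouette is \eqn{(b - a)/\max(a, b)}; members of
#' singleton clusters score 0 (Rousseeuw's convention). Returns the mean
#' silhouette over all observations; noise-labelled observations are
#' included as an ordinary cluster.
#'
#' @param x a \linkS4class{DirectionalSet} or matrix of unit rows.
#' @param labels cluster labels, one per row; at least two distinct.
#' @return scalar mean silhouette in [-1, 1].
#' @export
sphericalSilhouette <- function(x, labels) {
  x <- .asUnitMatrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("'labels' must have one entry per observation")
  lev <- unique(labels)
  if (length(lev) < 2L)
    stop("silhouette is undefined for a single cluster")
  D <- acos(pmin(pmax(x %*% t(x), -1), 1))
  diag(D) <- 0                  # guard against acos(1 - eps) round-off
  n <- nrow(x)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, labels == own]) / (sizes[[own]] - 1L)
    b <- min(vapply(setdiff(lev, own),
                    function(l) mean(D[i, labels == l]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
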