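# End-to-end pipeline: summary statistics -> standardise -> project to
# the sphere -> fit -> assign; plus scenario replication for the
# simulation study.

#' Cluster variants from summary statistics
#'
#' The complete directional-clustering pipeline: standardise the
#' association estimates with \eqn{\hat\Sigma_j^{-1/2}\hat\beta_{j\cdot}}
#' (diagonal covariances unless a trait correlation is supplied), project
#' each standardised vector onto the unit sphere, and fit the
#' noise-augmented vMF mixture with BIC selection of the number of
#' clusters.
#'
#' @param assoc an \linkS4class{AssociationSet}.
#' @param traitCorr optional m x m trait correlation matrix.
#' @param ... further arguments passed to \code{\link{fitNAvMix}}
#'   (e.g. \code{k}, \code{nRestarts}, \code{tol}, \code{seed}).
#' @return An \linkS4class{NAvMixFit}.
#' @export
clusterAssociations <- function(assoc, traitCorr = NULL, ...) {
  z <- standardizeAssociations(assoc, corr = traitCorr)
  fitNAvMix(normalizeToUnit(z), ...)
}

#' Replicate a simulation scenario
#'
#' Runs the full pipeline — simulate genotypes and traits, estimate
#' associations by OLS, standardise (optionally with the trait
#' correlation estimated from the simulated individual-level data),
#' project to the sphere, fit with BIC selection, assign by maximum
#' membership probability — for \code{nReps} independent replicates of
#' one scenario, and reports per replicate the selected number of
#' clusters, the number of observations allocated to the noise cluster,
#' the adjusted Rand index against the true labels, and the spherical
#' silhouette of the estimated partition. Per-replicate seeds derive
#' deterministically from \code{seed}.
#'
#' @param m number of traits (2 or 9 for the default scenario grid).
#' @param K true number of clusters (1, 2 or 4 by default).
#' @param gamma confounding proportion (0, 0.4 or 0.8 in the study grid).
#' @param nReps number of replicates.
#' @param seed master seed.
#' @param useCor logical: supply the empirical trait correlation of the
#'   simulated traits to the covariance construction.
#' @param N individuals per replicate (default 20000).
#' @param filterGws logical: filter to genome-wide significant variants
#'   before clustering.
#' @param perTraitN logical: per-trait subsamples of differing size.
#' @param ... further arguments passed to \code{\link{fitNAvMix}}.
#' @return data.frame with columns \code{rep}, \code{seed}, \code{kHat},
#'   \code{noiseSize}, \code{ari}, \code{silhouette}.
#' @examples
#' replicateScenario(m = 2, K = 1, gamma = 0, nReps = 1, seed = 1, N = 2000)
#' @export
replicateScenario <- function(m, K, gamma, nReps, seed = 1L,
                              useCor = FALSE, N = 20000L,
                              filterGws = FALSE, perTraitN = FALSE, ...) {
  config <- simulationConfig(m = m, K = K, gamma = gamma, N = N,
                             perTraitN = perTraitN,
                             filterGws = filterGws)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReps)
  out <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    sim <- simulateGwas(config, seed = repSeeds[r])
    corr <- if (useCor) sim@traitCorrelation else NULL
    fit <- clusterAssociations(sim@assoc, traitCorr = corr,
                               seed = repSeeds[r], ...)
    asg <- assignClusters(fit)
    truth <- sim@trueLabels[rownames(fit@data@unitVectors)]
    sil <- if (length(unique(asg@labels)) >= 2L)
      sphericalSilhouette(fit@data, asg@labels) else NA_real_
    out[[r]] <- data.frame(
      rep = r, seed = repSeeds[r], kHat = fit@model@K,
      noiseSize = sum(asg@labels == "noise"),
      ari = adjustedRandIndex(truth, asg@labels),
      silhouette = sil)
  }
  do.call(rbind, out)
}

#' Summarise replicated scenario runs
#'
#' Means of the selected number of clusters and noise-cluster size,
#' median adjusted Rand index and mean silhouette across replicates,
#' with Monte Carlo standard errors of the means (NA for a single
#' replicate).
#'
#' @param reps data.frame from \code{\link{replicateScenario}}.
#' @return one-row data.frame of summaries.
#' @export
summarizeScenario <- function(reps) {
  mcse <- function(v) if (nrow(reps) > 1L) stats::sd(v) / sqrt(length(v))
                      else NA_real_
  data.frame(
    nReps = nrow(reps),
    meanK = mean(reps$kHat), seK = mcse(reps$kHat),
    meanNoise = mean(reps$noiseSize), seNoise = mcse(reps$noiseSize),
    medianARI = stats::median(reps$ari),
    meanSilhouette = mean(reps$silhouette, na.rm = TRUE))
}
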