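#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif rbinom cor pnorm
#' @importFrom utils read.table write.table
NULL

#' AssociationSet: per-variant, per-trait GWAS association estimates
#'
#' An \linkS4class{AssociationSet} holds the effect estimates
#' \eqn{\hat\beta_{jl}} and standard errors \eqn{se(\hat\beta_{jl})} of
#' \eqn{n} genetic variants (rows) on \eqn{m} traits (columns), the raw
#' material for directional clustering. It extends
#' \linkS4class{SummarizedExperiment} with two assays, \code{"beta"} and
#' \code{"se"}. An optional \code{rowData} column \code{primaryBeta} carries
#' the associations with the primary (selection) trait, used only to orient
#' effect alleles.
#'
#' @param beta numeric n x m matrix of association estimates (trait units).
#' @param se numeric n x m matrix of positive standard errors.
#' @param variantIds character vector of unique variant identifiers
#'   (defaults to \code{rownames(beta)}).
#' @param traitNames character vector of trait names (defaults to
#'   \code{colnames(beta)}).
#' @param primaryBeta optional numeric vector of length n: associations with
#'   the primary trait, used by \code{\link{orientToPrimaryTrait}}.
#'
#' @return An \code{AssociationSet}.
#' @seealso \code{\link{readAssociationTable}}, \code{\link{standardizeAssociations}}
#' @examples
#' beta <- matrix(c(0.05, -0.02, 0.03, 0.04), 2, 2,
#'                dimnames = list(c("rs1", "rs2"), c("bmi", "sbp")))
#' se <- matrix(0.01, 2, 2, dimnames = dimnames(beta))
#' AssociationSet(beta, se)
#' @export
AssociationSet <- function(beta, se, variantIds = rownames(beta),
                           traitNames = colnames(beta), primaryBeta = NULL) {
  beta <- as.matrix(beta)
  se <- as.matrix(se)
  if (is.null(variantIds))
    variantIds <- paste0("v", seq_len(nrow(beta)))
  if (is.null(traitNames))
    traitNames <- paste0("trait", seq_len(ncol(beta)))
  dimnames(beta) <- dimnames(se) <- list(variantIds, traitNames)
  rd <- S4Vectors::DataFrame(row.names = variantIds)
  if (!is.null(primaryBeta))
    rd$primaryBeta <- primaryBeta
  se0 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta, se = se), rowData = rd)
  new("AssociationSet", se0)
}

#' @rdname AssociationSet
#' @export
setClass("AssociationSet", contains = "SummarizedExperiment")

setValidity("AssociationSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("beta", "se") %in% a))
    return("assays 'beta' and 'se' are required")
  beta <- SummarizedExperiment::assay(object, "beta")
  se <- SummarizedExperiment::assay(object, "se")
  if (!identical(dim(beta), dim(se)))
    return("'beta' and 'se' must have identical dimensions")
  if (nrow(beta) < 1L)
    return("at least one variant is required")
  if (ncol(beta) < 2L)
    return("at least two traits are required for directional clustering")
  if (!all(is.finite(beta)))
    return("all 'beta' entries must be finite")
  if (!all(is.finite(se)) || any(se <= 0))
    return("all 'se' entries must be finite and strictly positive")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids))
    return("variant identifiers must be present and unique")
  pb <- SummarizedExperiment::rowData(object)$primaryBeta
  if (!is.null(pb) && (!is.numeric(pb) || !all(is.finite(pb))))
    return("'primaryBeta' must be finite numeric")
  TRUE
})

#' DirectionalSet: unit-norm association directions
#'
#' Holds the matrix of proportional association vectors \eqn{x_j}
#' (one unit row vector per variant) that the mixture model clusters.
#' Rows must have Euclidean norm 1; construct with
#' \code{\link{normalizeToUnit}}.
#'
#' @slot unitVectors numeric n x m matrix with unit-norm rows; dimnames are
#'   variant ids and trait names.
#' @seealso \code{\link{normalizeToUnit}}, \code{\link{fitNAvMix}}
#' @export
setClass("DirectionalSet", representation(unitVectors = "matrix"))

setValidity("DirectionalSet", function(object) {
  x <- object@unitVectors
  if (!is.numeric(x) || !all(is.finite(x)))
    return("unit vectors must be finite numeric")
  if (ncol(x) < 2L)
    return("at least two coordinates are required")
  nrm <- sqrt(rowSums(x^2))
  if (any(abs(nrm - 1) > 1e-10))
    return("every row must have Euclidean norm 1 (within 1e-10)")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    return("rownames (variant ids) must be present and unique")
  TRUE
})

#' von Mises-Fisher component parameters
#'
#' Mean direction \eqn{\mu} (a unit vector) and concentration \eqn{\kappa
#' \ge 0} of one von Mises-Fisher component. \eqn{\kappa = 0} is the uniform
#' distribution on the sphere; large \eqn{\kappa} concentrates mass around
#' \eqn{\mu}.
#'
#' @slot mu numeric unit vector.
#' @slot kappa non-negative scalar concentration.
#' @param mu,kappa see slots.
#' @return A \code{VMFParams} object.
#' @examples
#' VMFParams(c(1, 0, 0), kappa = 10)
#' @export
setClass("VMFParams", representation(mu = "numeric", kappa = "numeric"))

setValidity("VMFParams", function(object) {
  if (length(object@mu) < 2L)
    return("'mu' must have length >= 2")
  if (!all(is.finite(object@mu)))
    return("'mu' must be finite")
  if (abs(sqrt(sum(object@mu^2)) - 1) > 1e-10)
    return("'mu' must be a unit vector (within 1e-10)")
  if (length(object@kappa) != 1L || !is.finite(object@kappa) ||
      object@kappa < 0)
    return("'kappa' must be a single non-negative finite number")
  TRUE
})

#' @rdname VMFParams-class
#' @export
VMFParams <- function(mu, kappa) {
  new("VMFParams", mu = as.numeric(mu), kappa = as.numeric(kappa))
}

#' Fitted noise-augmented von Mises-Fisher mixture model
#'
#' Parameters of the (K+1)-component mixture: K von Mises-Fisher clusters
#' (rows of \code{mu}, entries of \code{kappa}) plus a fixed near-uniform
#' noise component whose mean direction is the global sample mean direction
#' and whose concentration \code{noiseKappa} is held at a value close to
#' zero so that it is effectively uniform on the sphere. Mixing proportions
#' \code{pi} have length K+1; the last entry is the noise proportion.
#'
#' @slot K integer, number of non-noise components.
#' @slot mu K x m matrix of unit mean directions.
#' @slot kappa length-K non-negative concentrations.
#' @slot noiseMu unit vector, fixed mean direction of the noise component.
#' @slot noiseKappa small positive scalar (default 1e-4), never updated.
#' @slot pi length-(K+1) mixing proportions summing to 1.
#' @export
setClass("NAvMixModel", representation(
  K = "integer", mu = "matrix", kappa = "numeric",
  noiseMu = "numeric", noiseKappa = "numeric", pi = "numeric"))

setValidity("NAvMixModel", function(object) {
  K <- object@K
  if (length(K) != 1L || K < 1L)
    return("'K' must be a single positive integer")
  if (nrow(object@mu) != K || length(object@kappa) != K)
    return("'mu' must have K rows and 'kappa' length K")
  if (length(object@noiseMu) != ncol(object@mu))
    return("'noiseMu' must match the dimension of 'mu'")
  nrm <- sqrt(rowSums(object@mu^2))
  if (any(abs(nrm - 1) > 1e-8))
    return("rows of 'mu' must be unit vectors")
  if (abs(sqrt(sum(object@noiseMu^2)) - 1) > 1e-8)
    return("'noiseMu' must be a unit vector")
  if (any(object@kappa < 0))
    return("'kappa' must be non-negative")
  if (length(object@noiseKappa) != 1L || object@noiseKappa <= 0)
    return("'noiseKappa' must be a single positive number")
  if (length(object@pi) != K + 1L)
    return("'pi' must have length K + 1")
  if (any(object@pi < -1e-12) || abs(sum(object@pi) - 1) > 1e-10)
    return("'pi' must be non-negative and sum to 1 (within 1e-10)")
  TRUE
})

#' EM fit of the noise-augmented vMF mixture
#'
#' Result of \code{\link{fitNAvMix}}: the converged model, the n x (K+1)
#' responsibility matrix \eqn{\gamma_{jk}} (posterior membership
#' probabilities, noise in the last column), the per-iteration log-likelihood
#' trace of the winning restart, and the BIC
#' \eqn{\phi_m(K) = -2 l_K(\hat\Theta) + ((m+2)K + m)\log n}.
#' When the fit came from BIC selection over K, \code{kEvaluated} and
#' \code{bicEvaluated} record the search path.
#'
#' @slot model the fitted \linkS4class{NAvMixModel}.
#' @slot gamma responsibility matrix, rows summing to 1.
#' @slot loglikTrace log-likelihood after each E step of the best restart.
#' @slot logLik final log-likelihood.
#' @slot bic BIC value of the fit.
#' @slot nIter iterations used by the best restart.
#' @slot converged logical, whether the best restart met the tolerance.
#' @slot nRestartsUsed number of initialisations attempted.
#' @slot seed the master seed used.
#' @slot data the \linkS4class{DirectionalSet} that was fitted.
#' @slot kEvaluated,bicEvaluated BIC search path (empty for fixed-K fits).
#' @export
setClass("NAvMixFit", representation(
  model = "NAvMixModel", gamma = "matrix", loglikTrace = "numeric",
  logLik = "numeric", bic = "numeric", nIter = "integer",
  converged = "logical", nRestartsUsed = "integer", seed = "integer",
  data = "DirectionalSet", kEvaluated = "integer", bicEvaluated = "numeric"))

setValidity("NAvMixFit", function(object) {
  g <- object@gamma
  if (ncol(g) != object@model@K + 1L)
    return("'gamma' must have K + 1 columns")
  if (any(g < -1e-10) || any(g > 1 + 1e-10))
    return("'gamma' entries must lie in [0, 1]")
  if (any(abs(rowSums(g) - 1) > 1e-8))
    return("'gamma' rows must sum to 1 (within 1e-8)")
  TRUE
})

#' Cluster assignment derived from membership probabilities
#'
#' Hard, thresholded or soft cluster membership computed from the
#' responsibility matrix of a fit (see \code{\link{assignClusters}}).
#' Labels are \code{"1"}..\code{"K"}, \code{"noise"}, or \code{"unassigned"}
#' (threshold mode only). In soft mode \code{softSets} lists, per variant,
#' every cluster whose membership probability reaches the threshold.
#'
#' @slot labels character vector of per-variant labels.
#' @slot probs the n x (K+1) membership probability matrix.
#' @slot mode one of \code{"hard"}, \code{"threshold"}, \code{"soft"}.
#' @slot threshold the probability threshold used (NA for hard mode).
#' @slot softSets list of character vectors (empty unless soft mode).
#' @export
setClass("ClusterAssignment", representation(
  labels = "character", probs = "matrix", mode = "character",
  threshold = "numeric", softSets = "list"))

#' Simulation configuration for the latent-factor GWAS generator
#'
#' Defines one scenario of the genotype-trait simulation: \code{N}
#' individuals; \code{sum(clusterSizes)} variants acting on K latent
#' factors, which load on the m traits through the K x m matrix
#' \code{delta}; \code{nNoise} further variants acting directly on every
#' trait; and a shared standard-normal confounder contributing a proportion
#' \code{gamma} of each trait's non-genetic standard deviation, which
#' induces residual trait correlation \code{gamma^2}.
#'
#' @slot N number of individuals.
#' @slot m number of traits.
#' @slot K number of true clusters.
#' @slot gamma confounding proportion in [0, 1].
#' @slot clusterSizes integer vector of K cluster sizes.
#' @slot nNoise number of noise variants.
#' @slot delta K x m loading matrix of latent factors on traits.
#' @slot perTraitN logical: estimate each trait's associations on an
#'   independent subsample of random size between 10000 and 50000.
#' @slot filterGws logical: drop variants not genome-wide significant for
#'   any trait before clustering.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateGwas}}
#' @export
setClass("SimulationConfig", representation(
  N = "integer", m = "integer", K = "integer", gamma = "numeric",
  clusterSizes = "integer", nNoise = "integer", delta = "matrix",
  perTraitN = "logical", filterGws = "logical"))

setValidity("SimulationConfig", function(object) {
  if (object@N < 10L) return("'N' is implausibly small")
  if (object@m < 2L) return("'m' must be at least 2")
  if (object@K < 1L) return("'K' must be at least 1")
  if (object@gamma < 0 || object@gamma > 1)
    return("'gamma' must lie in [0, 1]")
  if (length(object@clusterSizes) != object@K ||
      any(object@clusterSizes < 1L))
    return("'clusterSizes' must be K positive integers")
  if (!identical(dim(object@delta), c(object@K, object@m)))
    return("'delta' must be a K x m matrix")
  if (object@nNoise < 0L) return("'nNoise' must be non-negative")
  if (object@perTraitN && object@N < 50000L)
    return("perTraitN subsampling draws sizes up to 50000; set N >= 50000")
  TRUE
})

#' Simulated genotype-trait dataset
#'
#' Output of \code{\link{simulateGwas}}: genotype dosages, trait values,
#' the true cluster labels of the variants, the regression-estimated
#' \linkS4class{AssociationSet}, the empirical trait correlation matrix,
#' and the matrix of true per-variant total effects on each trait
#' (\code{effects}), useful for checking the generator.
#'
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot genotypes N x n matrix of dosages in {0, 1, 2}.
#' @slot traits N x m matrix of trait values.
#' @slot trueLabels length-n character vector ("1".."K", "noise").
#' @slot assoc the estimated \linkS4class{AssociationSet}.
#' @slot traitCorrelation empirical m x m correlation of the traits.
#' @slot effects n x m matrix of true total effects of variant j on trait l.
#' @slot seed the seed used.
#' @export
setClass("GwasSimulation", representation(
  config = "SimulationConfig", genotypes = "matrix", traits = "matrix",
  trueLabels = "character", assoc = "AssociationSet",
  traitCorrelation = "matrix", effects = "matrix", seed = "integer"))
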