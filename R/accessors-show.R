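# Accessors and show methods.

#' @describeIn AssociationSet the matrix of effect estimates.
#' @param object an \code{AssociationSet}.
#' @export
betaValues <- function(object) {
  SummarizedExperiment::assay(object, "beta")
}

#' @describeIn AssociationSet the matrix of standard errors.
#' @export
seValues <- function(object) {
  SummarizedExperiment::assay(object, "se")
}

#' @describeIn AssociationSet the variant identifiers.
#' @export
variantIds <- function(object) rownames(object)

#' @describeIn AssociationSet the trait names.
#' @export
traitNames <- function(object) {
  if (is(object, "DirectionalSet")) colnames(object@unitVectors)
  else colnames(object)
}

#' @rdname NAvMixFit-class
#' @param object an \code{NAvMixFit} (or, for accessors documented here,
#'   the object named in the description).
#' @export
setGeneric("responsibilities", function(object)
  standardGeneric("responsibilities"))

#' @describeIn NAvMixFit-class the n x (K+1) membership-probability
#'   matrix (noise last column).
#' @export
setMethod("responsibilities", "NAvMixFit", function(object) {
  g <- object@gamma
  dimnames(g) <- list(rownames(object@data@unitVectors),
                      c(as.character(seq_len(object@model@K)), "noise"))
  g
})

#' @rdname NAvMixModel-class
#' @param object an \code{NAvMixModel} or \code{NAvMixFit}.
#' @export
setGeneric("meanDirections", function(object)
  standardGeneric("meanDirections"))

#' @describeIn NAvMixModel-class K x m matrix of fitted mean directions.
#' @export
setMethod("meanDirections", "NAvMixModel", function(object) object@mu)

setMethod("meanDirections", "NAvMixFit",
          function(object) object@model@mu)

#' @rdname NAvMixModel-class
#' @export
setGeneric("concentrations", function(object)
  standardGeneric("concentrations"))

#' @describeIn NAvMixModel-class length-K vector of fitted
#'   concentrations.
#' @export
setMethod("concentrations", "NAvMixModel", function(object) object@kappa)

setMethod("concentrations", "NAvMixFit",
          function(object) object@model@kappa)

#' @rdname NAvMixModel-class
#' @export
setGeneric("mixingProportions", function(object)
  standardGeneric("mixingProportions"))

#' @describeIn NAvMixModel-class length-(K+1) mixing proportions, noise
#'   last.
#' @export
setMethod("mixingProportions", "NAvMixModel", function(object) object@pi)

setMethod("mixingProportions", "NAvMixFit",
          function(object) object@model@pi)

#' @describeIn NAvMixFit-class number of non-noise clusters of the fit.
#' @export
setGeneric("numberOfClusters", function(object)
  standardGeneric("numberOfClusters"))

setMethod("numberOfClusters", "NAvMixModel", function(object) object@K)

#' @rdname NAvMixFit-class
#' @export
setMethod("numberOfClusters", "NAvMixFit",
          function(object) object@model@K)

#' @describeIn NAvMixFit-class BIC value of the returned fit.
#' @export
bicValue <- function(object) {
  stopifnot(is(object, "NAvMixFit"))
  object@bic
}

#' @describeIn ClusterAssignment-class per-variant labels.
#' @param object a \code{ClusterAssignment}.
#' @export
clusterLabels <- function(object) {
  stopifnot(is(object, "ClusterAssignment"))
  object@labels
}

#' @describeIn GwasSimulation-class true cluster labels of the simulated
#'   variants.
#' @param object a \code{GwasSimulation}.
#' @export
trueLabels <- function(object) {
  stopifnot(is(object, "GwasSimulation"))
  object@trueLabels
}

#' @describeIn GwasSimulation-class the regression-estimated
#'   \linkS4class{AssociationSet}.
#' @export
associations <- function(object) {
  stopifnot(is(object, "GwasSimulation"))
  object@assoc
}

setMethod("show", "DirectionalSet", function(object) {
  x <- object@unitVectors
  cat("DirectionalSet:", nrow(x), "unit vectors in", ncol(x),
      "dimensions\n")
  cat("traits:", paste(colnames(x), collapse = ", "), "\n")
})

setMethod("show", "VMFParams", function(object) {
  cat("von Mises-Fisher parameters (m =", length(object@mu), ")\n")
  cat("  mu:", format(object@mu, digits = 4), "\n")
  cat("  kappa:", format(object@kappa, digits = 4), "\n")
})

setMethod("show", "NAvMixModel", function(object) {
  cat("NAvMix model:", object@K, "vMF cluster(s) + noise\n")
  cat("  kappa:", format(object@kappa, digits = 4), "\n")
  cat("  pi:", format(object@pi, digits = 3),
      "(last = noise, kappa =", format(object@noiseKappa), ")\n")
})

setMethod("show", "NAvMixFit", function(object) {
  cat("NAvMix fit: K =", object@model@K, "clusters + noise, n =",
      nrow(object@gamma), "\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      " BIC:", format(object@bic, digits = 8), "\n")
  cat("  iterations:", object@nIter,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (length(object@kEvaluated))
    cat("  BIC over K =", paste(object@kEvaluated, collapse = ", "),
        ":", paste(format(object@bicEvaluated, digits = 7),
                   collapse = ", "), "\n")
  hard <- max.col(object@gamma, ties.method = "first")
  sizes <- tabulate(hard, nbins = object@model@K + 1L)
  cat("  hard sizes:",
      paste(sizes[seq_len(object@model@K)], collapse = ", "),
      "+", sizes[object@model@K + 1L], "noise\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment (", object@mode, " mode",
      if (!is.na(object@threshold))
        paste0(", threshold ", object@threshold), "):\n", sep = "")
  print(table(object@labels))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: N =", object@N, ", m =", object@m,
      ", K =", object@K, ", gamma =", object@gamma, "\n")
  cat("  cluster sizes:", paste(object@clusterSizes, collapse = "/"),
      "+", object@nNoise, "noise variants\n")
})

setMethod("show", "GwasSimulation", function(object) {
  cat("GwasSimulation:", nrow(object@effects), "variants,",
      ncol(object@traits), "traits,", nrow(object@traits),
      "individuals (seed", object@seed, ")\n")
})
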