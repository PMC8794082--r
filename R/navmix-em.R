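# Fitting machinery for the noise-augmented vMF mixture: spherical k-means
# initialisation, E and M steps, restarts, and BIC selection of K.

# The EM hot path works on a plain-list model
# (K, mu K x m, kappa, noiseMu, noiseKappa, pi) to avoid S4 construction
# costs per iteration; the exported API converts at the boundary.
.modelAsList <- function(model) {
  list(K = model@K, mu = model@mu, kappa = model@kappa,
       noiseMu = model@noiseMu, noiseKappa = model@noiseKappa,
       pi = model@pi)
}

.modelFromList <- function(mod) {
  new("NAvMixModel", K = as.integer(mod$K), mu = mod$mu,
      kappa = as.numeric(mod$kappa), noiseMu = as.numeric(mod$noiseMu),
      noiseKappa = mod$noiseKappa, pi = as.numeric(mod$pi))
}

# log pi_k + log f(x_j | mu_k, kappa_k) for all j, k (noise last column)
.logWeightedDensities <- function(x, mod) {
  m <- ncol(x)
  kap <- c(mod$kappa, mod$noiseKappa)
  proj <- x %*% cbind(t(mod$mu), mod$noiseMu)  # n x (K+1), mu' x
  lc <- vmfLogConst(m, kap)
  lp <- log(mod$pi)
  lp[mod$pi == 0] <- -Inf
  proj * rep(kap, each = nrow(x)) +
    rep(lc + lp, each = nrow(x))
}

# responsibilities and observed-data log-likelihood in one pass,
# computed in log space with max-subtraction
.eStepInternal <- function(x, mod) {
  lwd <- .logWeightedDensities(x, mod)
  mx <- lwd[cbind(seq_len(nrow(lwd)), max.col(lwd, ties.method = "first"))]
  w <- exp(lwd - mx)
  rs <- rowSums(w)
  list(gamma = w / rs, logLik = sum(log(rs) + mx))
}

#' E step: posterior membership probabilities
#'
#' Computes the responsibility matrix
#' \eqn{\gamma_{jk} = \pi_k f(x_j \mid \mu_k, \kappa_k) /
#' \sum_l \pi_l f(x_j \mid \mu_l, \kappa_l)} for all observations and all
#' K+1 components (noise last). Evaluated in log space with row-max
#' subtraction for numerical stability.
#'
#' @param x a \linkS4class{DirectionalSet} (or matrix of unit rows).
#' @param model a \linkS4class{NAvMixModel}.
#' @return n x (K+1) matrix with rows summing to 1.
#' @export
eStep <- function(x, model) {
  x <- .asUnitMatrix(x)
  stopifnot(is(model, "NAvMixModel"))
  if (ncol(x) != ncol(model@mu))
    stop("dimension of data does not match the model")
  .eStepInternal(x, .modelAsList(model))$gamma
}

#' Observed-data log-likelihood of a model
#'
#' \eqn{l_K(\Theta) = \sum_j \log \sum_k \pi_k f(x_j \mid \mu_k,
#' \kappa_k)}, the quantity whose convergence the EM iteration monitors.
#'
#' @inheritParams eStep
#' @return scalar log-likelihood.
#' @export
navmixLogLik <- function(x, model) {
  stopifnot(is(model, "NAvMixModel"))
  x <- .asUnitMatrix(x)
  .eStepInternal(x, .modelAsList(model))$logLik
}

.asUnitMatrix <- function(x) {
  if (is(x, "DirectionalSet")) return(x@unitVectors)
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("rows must be unit vectors; use normalizeToUnit() first")
  x
}

# condition signalled when a non-noise component loses all responsibility
.emptyComponent <- function(k) {
  stop(structure(class = c("navmixEmptyComponent", "error", "condition"),
                 list(message = paste0("component ", k,
                                       " received (near-)zero total weight"),
                      call = NULL)))
}

#' M step: update mixture parameters from responsibilities
#'
#' Given responsibilities \eqn{\gamma_{jk}}, sets for each non-noise
#' component \eqn{\hat\mu_k = \sum_j \gamma_{jk} x_j / \lVert \sum_j
#' \gamma_{jk} x_j \rVert}, \eqn{\bar r_k = \lVert \sum_j \gamma_{jk} x_j
#' \rVert / \sum_j \gamma_{jk}}, \eqn{\hat\kappa_k =}
#' \code{estimateKappa(rBar, m)}, and for all K+1 components
#' \eqn{\hat\pi_k = n^{-1} \sum_j \gamma_{jk}}. The noise component's mean
#' direction and concentration are never updated; only its mixing
#' proportion is.
#'
#' @param x a \linkS4class{DirectionalSet} or matrix of unit rows.
#' @param gamma n x (K+1) responsibility matrix, noise last column.
#' @param noiseMu unit vector: fixed noise mean direction.
#' @param noiseKappa fixed noise concentration (default 1e-4).
#' @param kappaCap cap on concentration estimates (default 500).
#' @param kappaMethod concentration update: \code{"banerjee"} (closed-form
#'   approximation, the default) or \code{"newton"} (exact inversion of the
#'   Bessel ratio; with it the M step is the exact conditional maximiser
#'   and the EM log-likelihood is strictly non-decreasing).
#' @return an updated \linkS4class{NAvMixModel}.
#' @export
mStep <- function(x, gamma, noiseMu, noiseKappa = 1e-4, kappaCap = 500,
                  kappaMethod = "banerjee") {
  x <- .asUnitMatrix(x)
  .modelFromList(.mStepRaw(x, gamma, noiseMu, noiseKappa, kappaCap,
                           kappaMethod))
}

.mStepRaw <- function(x, gamma, noiseMu, noiseKappa, kappaCap,
                      kappaMethod = "banerjee") {
  n <- nrow(x); m <- ncol(x)
  K <- ncol(gamma) - 1L
  if (K < 1L) stop("'gamma' must have at least 2 columns (K >= 1)")
  w <- colSums(gamma)
  low <- which(w[seq_len(K)] < 1e-8 * n)
  if (length(low)) .emptyComponent(low[1L])
  S <- crossprod(gamma[, seq_len(K), drop = FALSE], x)   # K x m
  r <- sqrt(rowSums(S^2))
  mu <- S / r
  rBar <- pmin(r / w[seq_len(K)], 1 - 1e-12)
  kappa <- estimateKappa(rBar, m, kappaCap = kappaCap,
                         method = kappaMethod)
  list(K = K, mu = mu, kappa = as.numeric(kappa),
       noiseMu = as.numeric(noiseMu), noiseKappa = noiseKappa,
       pi = as.numeric(w / n))
}

#' Spherical k-means
#'
#' k-means on the unit sphere: observations are assigned to the centroid
#' of greatest cosine similarity and centroids are the unit-normalised
#' mean of their members. Initial centroids are K distinct observation
#' rows drawn at random; an emptied cluster is reseeded with the
#' observation least similar to every current centroid. Iterates to a
#' local optimum (stable assignments).
#'
#' @param x a \linkS4class{DirectionalSet} or matrix of unit rows.
#' @param K number of clusters, \code{1 <= K <= n}.
#' @param seed optional integer seed for the random initial centroids.
#' @param maxIter iteration cap (default 100).
#' @return list with \code{cluster} (length-n integer assignments) and
#'   \code{centers} (K x m unit matrix).
#' @export
sphericalKMeans <- function(x, K, seed = NULL, maxIter = 100L) {
  x <- .asUnitMatrix(x)
  n <- nrow(x)
  if (K < 1L || K > n) stop("'K' must lie between 1 and the number of rows")
  if (!is.null(seed)) set.seed(seed)
  centers <- x[sample.int(n, K), , drop = FALSE]
  assign <- rep(0L, n)
  for (it in seq_len(maxIter)) {
    sim <- x %*% t(centers)
    newAssign <- max.col(sim, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(newAssign == k)) {
        # reseed an empty cluster with the worst-covered observation
        far <- which.min(apply(sim, 1, max))
        newAssign[far] <- k
      }
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (k in seq_len(K)) {
      s <- colSums(x[assign == k, , drop = FALSE])
      nrm <- sqrt(sum(s^2))
      if (nrm > 0) centers[k, ] <- s / nrm
    }
  }
  list(cluster = assign, centers = centers)
}

#' Initial responsibilities from spherical k-means
#'
#' Runs spherical k-means and converts the hard assignments into initial
#' responsibilities: \eqn{\gamma_{ik} = 1 - \pi^{(0)}_{K+1}} for the
#' assigned cluster, 0 for the other non-noise clusters, and
#' \eqn{\pi^{(0)}_{K+1}} (the initial noise proportion, default 0.05) for
#' the noise column. The EM iteration then starts at the M step.
#'
#' @inheritParams sphericalKMeans
#' @param noiseProp initial noise-cluster proportion in (0, 1).
#' @return n x (K+1) responsibility matrix.
#' @export
initResponsibilities <- function(x, K, noiseProp = 0.05, seed = NULL) {
  if (noiseProp <= 0 || noiseProp >= 1)
    stop("'noiseProp' must lie strictly between 0 and 1")
  x <- .asUnitMatrix(x)
  km <- sphericalKMeans(x, K, seed = seed)
  gamma <- matrix(0, nrow(x), K + 1L)
  gamma[cbind(seq_len(nrow(x)), km$cluster)] <- 1 - noiseProp
  gamma[, K + 1L] <- noiseProp
  gamma
}

# one complete EM run from one initialisation; signals
# navmixEmptyComponent if a component collapses
.emRun <- function(x, K, seed, tol, maxIter, noiseProp, kappaCap,
                   noiseMu, noiseKappa, kappaMethod) {
  gamma <- initResponsibilities(x, K, noiseProp = noiseProp, seed = seed)
  trace <- numeric(0)
  llPrev <- NA_real_
  converged <- FALSE
  model <- NULL
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    model <- .mStepRaw(x, gamma, noiseMu = noiseMu,
                       noiseKappa = noiseKappa, kappaCap = kappaCap,
                       kappaMethod = kappaMethod)
    es <- .eStepInternal(x, model)
    gamma <- es$gamma
    trace <- c(trace, es$logLik)
    if (!is.na(llPrev) && abs(es$logLik - llPrev) < tol) {
      converged <- TRUE
      break
    }
    llPrev <- es$logLik
  }
  list(model = model, gamma = gamma, trace = trace,
       logLik = trace[length(trace)], nIter = it, converged = converged)
}

# fit at fixed K with restarts; keeps the restart with greatest final
# log-likelihood
.fitFixedK <- function(x, K, nRestarts, tol, maxIter, noiseProp,
                       kappaCap, noiseKappa, seed,
                       kappaMethod = "banerjee") {
  n <- nrow(x)
  s <- colSums(x)
  noiseMu <- s / sqrt(sum(s^2))            # global sample mean direction
  set.seed(seed)
  seedPool <- sample.int(.Machine$integer.max - 1L, nRestarts * 4L)
  best <- NULL
  used <- 0L
  ptr <- 0L
  for (r in seq_len(nRestarts)) {
    run <- NULL
    for (attempt in 0:3) {                 # up to 3 re-initialisations
      ptr <- ptr + 1L
      run <- tryCatch(
        .emRun(x, K, seed = seedPool[ptr], tol = tol, maxIter = maxIter,
               noiseProp = noiseProp, kappaCap = kappaCap,
               noiseMu = noiseMu, noiseKappa = noiseKappa,
               kappaMethod = kappaMethod),
        navmixEmptyComponent = function(e) NULL)
      if (!is.null(run)) break
    }
    if (is.null(run)) next
    used <- used + 1L
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  if (is.null(best))
    stop("all restarts collapsed to an empty component at K = ", K,
         "; the data cannot support this many clusters")
  if (!best$converged)
    warning("EM did not reach the convergence threshold within ",
            maxIter, " iterations at K = ", K)
  m <- ncol(x)
  bic <- -2 * best$logLik + ((m + 2) * K + m) * log(n)
  new("NAvMixFit", model = .modelFromList(best$model), gamma = best$gamma,
      loglikTrace = best$trace, logLik = best$logLik, bic = bic,
      nIter = best$nIter, converged = best$converged,
      nRestartsUsed = used, seed = as.integer(seed),
      data = new("DirectionalSet", unitVectors = x),
      kEvaluated = integer(0), bicEvaluated = numeric(0))
}

#' Fit the noise-augmented von Mises-Fisher mixture
#'
#' Fits the (K+1)-component mixture of von Mises-Fisher distributions —
#' K directional clusters plus a fixed near-uniform noise component — by
#' EM with spherical k-means initialisation and multiple restarts,
#' keeping the restart that attains the greatest log-likelihood. When
#' \code{k} is NULL (the default) the number of clusters is chosen by
#' BIC, \eqn{\phi_m(K) = -2 l_K(\hat\Theta) + ((m+2)K + m)\log n}:
#' successive K are fitted from \code{kMin} upward and the search stops
#' once \eqn{\phi_m} has exceeded its running minimum for
#' \code{patience} consecutive values of K (or \code{kMax} is reached);
#' the fit minimising \eqn{\phi_m(K)} is returned.
#'
#' All randomness (k-means seeding, restart order) derives
#' deterministically from \code{seed}.
#'
#' @param x a \linkS4class{DirectionalSet}, or a numeric matrix whose rows
#'   are normalised to unit length first.
#' @param k fixed number of clusters; NULL (default) selects K by BIC.
#' @param kMin,kMax search range for K (defaults 1 and 10).
#' @param nRestarts number of EM initialisations per K (default 5).
#' @param tol absolute log-likelihood convergence threshold (default 1e-4).
#' @param maxIter iteration cap per EM run (default 500).
#' @param noiseProp initial noise-cluster proportion (default 0.05).
#' @param kappaCap cap on fitted concentrations (default 500).
#' @param noiseKappa fixed noise concentration (default 1e-4).
#' @param patience number of consecutive BIC increases over the running
#'   minimum before the K search stops (default 2, i.e. the search ends
#'   once \eqn{\phi_m} has risen above its running minimum for two K
#'   values in a row; set 1 to stop at the first increase).
#' @param seed master seed (default 1).
#' @param kappaMethod concentration update, \code{"banerjee"} (closed-form
#'   approximation, as published) or \code{"newton"} (exact Bessel-ratio
#'   inversion, guaranteeing a non-decreasing log-likelihood trace).
#' @return An \linkS4class{NAvMixFit}.
#' @examples
#' set.seed(7)
#' ang <- c(rnorm(30, 0, 0.1), rnorm(30, pi, 0.1))
#' x <- normalizeToUnit(cbind(cos(ang), sin(ang)))
#' fit <- fitNAvMix(x, seed = 2)
#' fit
#' @export
setGeneric("fitNAvMix", function(x, ...) standardGeneric("fitNAvMix"))

#' @rdname fitNAvMix
#' @param ... passed to the DirectionalSet method.
#' @export
setMethod("fitNAvMix", "matrix", function(x, ...) {
  fitNAvMix(normalizeToUnit(x), ...)
})

#' @rdname fitNAvMix
#' @export
setMethod("fitNAvMix", "DirectionalSet", function(x, k = NULL, kMin = 1L,
    kMax = 10L, nRestarts = 5L, tol = 1e-4, maxIter = 500L,
    noiseProp = 0.05, kappaCap = 500, noiseKappa = 1e-4, patience = 2L,
    seed = 1L, kappaMethod = c("banerjee", "newton")) {
  kappaMethod <- match.arg(kappaMethod)
  xm <- x@unitVectors
  if (!is.null(k)) {
    if (k < 1L || k > nrow(xm)) stop("'k' must lie between 1 and n")
    return(.fitFixedK(xm, as.integer(k), nRestarts, tol, maxIter,
                      noiseProp, kappaCap, noiseKappa, seed,
                      kappaMethod))
  }
  if (kMin < 1L) stop("'kMin' must be at least 1")
  set.seed(seed)
  kSeeds <- sample.int(.Machine$integer.max - 1L, kMax)
  fits <- list()
  bics <- numeric(0)
  ks <- integer(0)
  runMin <- Inf
  streak <- 0L
  for (K in seq(kMin, kMax)) {
    fit <- .fitFixedK(xm, K, nRestarts, tol, maxIter, noiseProp,
                      kappaCap, noiseKappa, kSeeds[K], kappaMethod)
    ks <- c(ks, K)
    bics <- c(bics, fit@bic)
    fits[[length(fits) + 1L]] <- fit
    if (fit@bic > runMin) {
      streak <- streak + 1L
      if (streak >= patience) break
    } else {
      runMin <- fit@bic
      streak <- 0L
    }
  }
  best <- fits[[which.min(bics)]]
  best@kEvaluated <- ks
  best@bicEvaluated <- bics
  best@seed <- as.integer(seed)
  best
})

#' Assign observations to clusters
#'
#' Converts the responsibility matrix of a fit into cluster memberships.
#' \code{"hard"} assigns each observation to the component of greatest
#' membership probability (ties broken toward the lowest cluster index;
#' the noise component competes like any other and yields the label
#' \code{"noise"}). \code{"threshold"} additionally requires that maximum
#' probability to reach \code{threshold}, else the observation is
#' \code{"unassigned"}. \code{"soft"} lists every cluster whose
#' probability reaches \code{threshold}, so an observation may belong to
#' several.
#'
#' @param fit an \linkS4class{NAvMixFit}.
#' @param mode \code{"hard"} (default), \code{"threshold"} or \code{"soft"}.
#' @param threshold probability threshold in (0, 1]; required unless
#'   \code{mode = "hard"}.
#' @return A \linkS4class{ClusterAssignment}.
#' @export
assignClusters <- function(fit, mode = c("hard", "threshold", "soft"),
                           threshold = NULL) {
  stopifnot(is(fit, "NAvMixFit"))
  mode <- match.arg(mode)
  gamma <- fit@gamma
  K <- fit@model@K
  compLabels <- c(as.character(seq_len(K)), "noise")
  top <- max.col(gamma, ties.method = "first")
  labels <- compLabels[top]
  softSets <- list()
  thr <- NA_real_
  if (mode != "hard") {
    if (is.null(threshold) || length(threshold) != 1L ||
        !is.finite(threshold) || threshold <= 0 || threshold > 1)
      stop("'threshold' in (0, 1] is required for mode '", mode, "'")
    thr <- threshold
    if (mode == "threshold") {
      labels[gamma[cbind(seq_len(nrow(gamma)), top)] < thr] <- "unassigned"
    } else {
      softSets <- apply(gamma, 1, function(g) compLabels[g >= thr],
                        simplify = FALSE)
    }
  }
  names(labels) <- rownames(gamma) <- rownames(fit@data@unitVectors)
  new("ClusterAssignment", labels = labels, probs = gamma, mode = mode,
      threshold = thr, softSets = softSets)
}

#' Write a fit as delimited text plus a YAML sidecar
#'
#' Writes \code{membership.tsv} (variant id, hard label, and the K+1
#' membership probabilities) and \code{model.yaml} (mean directions,
#' concentrations, mixing proportions, noise parameters, seed, BIC search
#' path) into \code{dir}.
#'
#' @param fit an \linkS4class{NAvMixFit}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeNAvMixFit <- function(fit, dir) {
  stopifnot(is(fit, "NAvMixFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  asg <- assignClusters(fit)
  K <- fit@model@K
  probs <- fit@gamma
  colnames(probs) <- c(paste0("cluster", seq_len(K)), "noise")
  df <- data.frame(variant = rownames(fit@data@unitVectors),
                   label = as.character(asg@labels), probs,
                   check.names = FALSE)
  write.table(df, file.path(dir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sidecar <- list(
    K = K,
    mu = lapply(seq_len(K), function(k) as.numeric(fit@model@mu[k, ])),
    kappa = as.numeric(fit@model@kappa),
    pi = as.numeric(fit@model@pi),
    noiseMu = as.numeric(fit@model@noiseMu),
    noiseKappa = fit@model@noiseKappa,
    logLik = fit@logLik, bic = fit@bic, nIter = fit@nIter,
    converged = fit@converged, seed = fit@seed,
    kEvaluated = as.integer(fit@kEvaluated),
    bicEvaluated = as.numeric(fit@bicEvaluated))
  yaml::write_yaml(sidecar, file.path(dir, "model.yaml"),
                   precision = 15L)
  invisible(dir)
}
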