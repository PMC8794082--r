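# Latent-factor generator of genotype-trait data for evaluating
# directional clustering, plus vectorised per-variant OLS association
# estimation and genome-wide significance filtering.

# default latent-factor loading matrices delta (K x m) for the supported
# scenario grid: m in {2, 9}, K in {1, 2, 4}
.defaultDelta <- function(m, K) {
  key <- paste(m, K, sep = "x")
  tab <- list(
    "2x1" = matrix(c(1, 1), 1, 2, byrow = TRUE),
    "2x2" = matrix(c(1, 1,
                     1, -1), 2, 2, byrow = TRUE),
    "2x4" = matrix(c(1, 1,
                     1, -1,
                     -1, 1,
                     -1, -1), 4, 2, byrow = TRUE),
    "9x1" = matrix(1, 1, 9),
    "9x2" = matrix(c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                     1, -1, -1, 0.5, 0.5, 0.5, 0.5, -0.5, -0.5),
                   2, 9, byrow = TRUE),
    "9x4" = matrix(c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                     1, 1, 1, 1, 1, 0, 0, 0, 0,
                     -1, -1, -1, 0.5, 0.5, 0.5, 0.5, -0.5, -0.5,
                     -1, -1, -1, -1, -1, 0, 0, 0, 0),
                   4, 9, byrow = TRUE))
  tab[[key]]
}

# default split of the 80 clustered variants
.defaultClusterSizes <- function(K) {
  switch(as.character(K),
         "1" = 80L, "2" = c(40L, 40L), "4" = c(30L, 20L, 20L, 10L),
         stop("no default cluster sizes for K = ", K,
              "; supply 'clusterSizes'"))
}

#' Build a simulation configuration
#'
#' Assembles and validates a \linkS4class{SimulationConfig} for the
#' latent-factor generator (see \code{\link{simulateGwas}} for the model).
#' Defaults reproduce the evaluation scenarios: 20000 individuals, 80
#' clustered variants split into K clusters (80; 40/40; 30/20/20/10),
#' 20 noise variants, and the fixed loading matrices \eqn{\delta} for
#' each (m, K) in \{2, 9\} x \{1, 2, 4\}. Other (m, K) combinations
#' require an explicit \code{delta}.
#'
#' @param m number of traits.
#' @param K number of true clusters.
#' @param gamma confounding proportion in [0, 1]: the shared confounder
#'   contributes \eqn{\gamma U_i} and the idiosyncratic noise
#'   \eqn{\sqrt{1-\gamma^2}\,\epsilon_{il}} to each trait, so the residual
#'   correlation between any two traits is \eqn{\gamma^2}.
#' @param N number of individuals (default 20000).
#' @param clusterSizes K cluster sizes (defaults as above).
#' @param nNoise number of directly-acting noise variants (default 20).
#' @param delta K x m latent-factor loading matrix (defaults as above).
#' @param perTraitN logical: estimate each trait on an independent random
#'   subsample of size uniform on 10000..50000 (requires N >= 50000).
#' @param filterGws logical: apply \code{\link{filterGenomeWide}} to the
#'   estimated associations.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(m = 2L, K = 1L, gamma = 0, N = 20000L,
                             clusterSizes = NULL, nNoise = 20L,
                             delta = NULL, perTraitN = FALSE,
                             filterGws = FALSE) {
  if (is.null(clusterSizes)) clusterSizes <- .defaultClusterSizes(K)
  if (is.null(delta)) {
    delta <- .defaultDelta(m, K)
    if (is.null(delta))
      stop("no default delta matrix for m = ", m, ", K = ", K,
           "; supply 'delta'")
  }
  new("SimulationConfig", N = as.integer(N), m = as.integer(m),
      K = as.integer(K), gamma = as.numeric(gamma),
      clusterSizes = as.integer(clusterSizes), nNoise = as.integer(nNoise),
      delta = as.matrix(delta), perTraitN = perTraitN,
      filterGws = filterGws)
}

#' Simulate genotypes, traits and estimated associations
#'
#' Generates, for \eqn{N} individuals and \eqn{n} independent variants:
#' \deqn{maf_j \sim U(0.01, 0.5),\quad G_{ij} \sim Binomial(2, maf_j),}
#' latent factors \eqn{L_{ik} = \sum_{j \in n^{(k)}} \beta_j \tilde
#' G_{ij}}, and traits
#' \deqn{X_{il} = \sum_k \delta_{kl} L_{ik} + \sum_{j \in noise}
#' \alpha_{jl} \tilde G_{ij} + \gamma U_i +
#' \sqrt{1-\gamma^2}\,\epsilon_{il}}
#' with \eqn{U_i, \epsilon_{il} \sim N(0,1)} independent and \eqn{\tilde
#' G} the column-standardised dosages, so each variant's association
#' strength is frequency-independent (a weak variant's expected z-statistic
#' is \eqn{\beta\sqrt{N}} on its own latent factor's traits). Per cluster k a
#' mixing weight \eqn{\phi_k \sim U(0.05, 0.2)} is drawn once; each of its
#' variants gets \eqn{\beta_j \sim U(0.03, 0.06)} with probability
#' \eqn{1-\phi_k} and \eqn{\beta_j \sim N(0.1, 0.02^2)} otherwise, so most
#' effects are weak and a few strong. Noise-variant effects are
#' \eqn{\alpha_j \sim U(-0.1, 0.1)}, identical across traits. Associations
#' are then estimated by simple linear regression of each trait on each
#' variant in turn (\code{\link{estimateAssociations}}); with
#' \code{perTraitN} each trait uses an independent subsample. The output
#' is bit-reproducible given \code{seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return A \linkS4class{GwasSimulation}.
#' @examples
#' sim <- simulateGwas(simulationConfig(m = 2, K = 2, N = 500), seed = 1)
#' table(trueLabels(sim))
#' @export
simulateGwas <- function(config, seed = 1L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(seed)
  N <- config@N; m <- config@m; K <- config@K
  sizes <- config@clusterSizes
  nC <- sum(sizes); nN <- config@nNoise; n <- nC + nN
  maf <- runif(n, 0.01, 0.5)
  G <- matrix(rbinom(N * n, 2L, rep(maf, each = N)), N, n)
  # genetic effects act on the standardised dosage scale, so a variant's
  # association strength is independent of its allele frequency and the
  # weak effects U(0.03, 0.06) average genome-wide significance at
  # N = 20000 (z = beta * sqrt(N))
  Gs <- scale(G)
  Gs[, attr(Gs, "scaled:scale") == 0] <- 0
  clusterOf <- rep(seq_len(K), sizes)             # variants 1..nC
  phi <- runif(K, 0.05, 0.2)
  strong <- rbinom(nC, 1L, phi[clusterOf]) == 1L
  beta <- runif(nC, 0.03, 0.06)
  beta[strong] <- rnorm(sum(strong), 0.1, 0.02)
  # direct effects of noise variants, drawn independently per trait so a
  # noise variant's direction carries no shared structure
  alpha <- matrix(runif(nN * m, -0.1, 0.1), nN, m)
  L <- matrix(0, N, K)
  for (k in seq_len(K)) {
    idx <- which(clusterOf == k)
    L[, k] <- Gs[, idx, drop = FALSE] %*% beta[idx]
  }
  U <- rnorm(N)
  E <- matrix(rnorm(N * m), N, m)
  X <- L %*% config@delta + config@gamma * U +
    sqrt(1 - config@gamma^2) * E
  if (nN > 0)
    X <- X + Gs[, nC + seq_len(nN), drop = FALSE] %*% alpha
  # true total effect of variant j on trait l, per standardised dosage:
  # the genetic component of X is scale(G) %*% B
  B <- matrix(0, n, m)
  B[seq_len(nC), ] <- beta * config@delta[clusterOf, , drop = FALSE]
  if (nN > 0)
    B[nC + seq_len(nN), ] <- alpha
  ids <- paste0("v", seq_len(n))
  traitNames <- paste0("trait", seq_len(m))
  dimnames(G) <- list(NULL, ids)
  dimnames(X) <- list(NULL, traitNames)
  perTraitRows <- NULL
  if (config@perTraitN) {
    sizesN <- sample(10000:50000, m, replace = TRUE)
    perTraitRows <- lapply(sizesN, function(s) sample.int(N, s))
  }
  assoc <- estimateAssociations(G, X, perTraitRows = perTraitRows)
  if (config@filterGws) assoc <- filterGenomeWide(assoc)
  labels <- c(as.character(clusterOf), rep("noise", nN))
  names(labels) <- ids
  new("GwasSimulation", config = config, genotypes = G, traits = X,
      trueLabels = labels, assoc = assoc, traitCorrelation = cor(X),
      effects = B, seed = as.integer(seed))
}

#' Per-variant, per-trait OLS association estimates
#'
#' Regresses each trait on each genotype column in turn (simple linear
#' regression with intercept) and returns the slopes and their standard
#' errors. Vectorised over variants via centred cross-products; agrees
#' with \code{lm()} to numerical precision. Variants with a constant
#' genotype column (undefined slope) are dropped with a warning.
#'
#' @param genotypes N x n numeric matrix of genotype dosages.
#' @param traits N x m numeric matrix of trait values.
#' @param perTraitRows optional list of m integer vectors: the rows
#'   (individuals) used for each trait, for differing per-trait samples.
#' @return An \linkS4class{AssociationSet}.
#' @export
estimateAssociations <- function(genotypes, traits, perTraitRows = NULL) {
  G <- as.matrix(genotypes)
  X <- as.matrix(traits)
  if (nrow(G) != nrow(X)) stop("genotypes and traits must have equal rows")
  n <- ncol(G); m <- ncol(X)
  beta <- se <- matrix(NA_real_, n, m)
  for (l in seq_len(m)) {
    rows <- if (is.null(perTraitRows)) seq_len(nrow(G)) else perTraitRows[[l]]
    g <- G[rows, , drop = FALSE]
    y <- X[rows, l]
    Nl <- length(rows)
    gc <- sweep(g, 2, colMeans(g))
    yc <- y - mean(y)
    Sxx <- colSums(gc^2)
    Sxy <- drop(crossprod(gc, yc))
    ok <- Sxx > 0
    slope <- Sxy[ok] / Sxx[ok]
    ssRes <- sum(yc^2) - slope^2 * Sxx[ok]
    beta[ok, l] <- slope
    se[ok, l] <- sqrt(pmax(ssRes, 0) / (Nl - 2) / Sxx[ok])
  }
  keep <- apply(is.finite(beta) & is.finite(se) & se > 0, 1, all)
  if (!all(keep))
    warning("dropped ", sum(!keep),
            " variant(s) with undefined association estimates")
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  tn <- colnames(X)
  if (is.null(tn)) tn <- paste0("trait", seq_len(m))
  AssociationSet(beta[keep, , drop = FALSE], se[keep, , drop = FALSE],
                 variantIds = ids[keep], traitNames = tn)
}

#' Filter to genome-wide significant variants
#'
#' Retains variants whose two-sided normal p-value from
#' \eqn{|\hat\beta / se|} falls below \code{alpha} for at least one trait.
#'
#' @param assoc an \linkS4class{AssociationSet}.
#' @param alpha significance threshold (default 5e-8, genome-wide).
#' @return the filtered \code{AssociationSet}.
#' @export
filterGenomeWide <- function(assoc, alpha = 5e-8) {
  stopifnot(is(assoc, "AssociationSet"))
  z <- abs(SummarizedExperiment::assay(assoc, "beta") /
             SummarizedExperiment::assay(assoc, "se"))
  p <- 2 * pnorm(-z)
  keep <- apply(p < alpha, 1, any)
  if (!any(keep))
    stop("no variant reaches genome-wide significance at alpha = ", alpha)
  assoc[keep, ]
}
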