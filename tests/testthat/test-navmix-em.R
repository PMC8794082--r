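# EM machinery: E/M steps, spherical k-means initialisation, restarts,
# BIC selection, assignment.

makeModel <- function(mu, kappa, pi, noiseMu = NULL, noiseKappa = 1e-4) {
  mu <- rbind(mu)
  if (is.null(noiseMu)) noiseMu <- c(1, rep(0, ncol(mu) - 1))
  new("NAvMixModel", K = nrow(mu), mu = mu, kappa = kappa,
      noiseMu = noiseMu, noiseKappa = noiseKappa, pi = pi)
}

test_that("E step: symmetry, concentration limit, uniform split", {
  # two mirror components, observation on the axis of symmetry
  model <- makeModel(rbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2)),
                     kappa = c(5, 5), pi = c(0.45, 0.45, 0.1))
  g <- eStep(rbind(c(1, 0)), model)
  expect_equal(g[1, 1], g[1, 2], tolerance = 1e-12)
  expect_equal(rowSums(g), 1, ignore_attr = TRUE, tolerance = 1e-12)

  # growing concentration at the observation: responsibility -> 1
  # (on the circle the modal density grows like sqrt(kappa), so the
  # limit is approached, not hit, below the cap)
  gAt <- vapply(c(4, 40, 400), function(k) {
    m2 <- makeModel(rbind(c(0, 1), c(1, 0)), kappa = c(k, 1),
                    pi = c(0.3, 0.3, 0.4))
    eStep(rbind(c(0, 1)), m2)[1, 1]
  }, 0)
  expect_true(all(diff(gAt) > 0))
  expect_gt(gAt[3], 0.95)

  # uniform component vs near-uniform noise at equal weight: ~50/50
  model3 <- makeModel(rbind(c(1, 0)), kappa = 0, pi = c(0.5, 0.5))
  g3 <- eStep(rbind(c(0, 1)), model3)
  expect_equal(unname(g3[1, ]), c(0.5, 0.5), tolerance = 1e-4)
  expect_error(eStep(rbind(c(1, 0, 0)), model3), "dimension")
})

test_that("M step recovers mean directions, caps kappa, skips noise", {
  x <- rbind(c(1, 0), c(0, 1))
  g <- cbind(c(0.5, 0.5), c(0.5, 0.5))     # one component + noise
  mod <- mStep(x, g, noiseMu = c(1, 0))
  expect_equal(unname(mod@mu[1, ]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(mod@pi, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(mod@noiseMu), c(1, 0))   # untouched

  # identical observations: rBar = 1 (clipped), kappa at the cap
  xx <- matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE)
  gg <- cbind(rep(0.9, 5), rep(0.1, 5))
  mod2 <- mStep(xx, gg, noiseMu = c(1, 0, 0))
  expect_equal(mod2@kappa, 500)
  expect_equal(unname(mod2@mu[1, ]), c(0, 0, 1), tolerance = 1e-12)

  # uniform sample with uniform responsibilities: kappa near 0
  set.seed(31)
  xu <- rUnitSphere(1000, 2)
  gu <- cbind(rep(0.7, 1000), rep(0.3, 1000))
  mod3 <- mStep(xu, gu, noiseMu = c(1, 0))
  expect_lt(mod3@kappa, 0.25)

  # a component with zero weight is an error condition
  g0 <- cbind(rep(0, 2), rep(0.5, 2), rep(0.5, 2))
  expect_error(mStep(x, g0, noiseMu = c(1, 0)), "zero total weight")
})

test_that("spherical k-means separates antipodal groups and is exact on ties", {
  set.seed(5)
  a <- rVMF(25, c(1, 0, 0), 100)
  b <- rVMF(25, c(-1, 0, 0), 100)
  x <- rbind(a, b)
  truth <- rep(1:2, each = 25)
  for (s in 1:5) {
    km <- sphericalKMeans(x, 2, seed = s)
    expect_equal(abs(adjustedRandIndex(km$cluster, truth)), 1)
  }
  # all identical observations, K = 1: centroid equals the common point
  same <- matrix(rep(c(0, 1), 4), 4, 2, byrow = TRUE)
  km1 <- sphericalKMeans(same, 1, seed = 1)
  expect_equal(unname(km1$centers[1, ]), c(0, 1), tolerance = 1e-12)
  expect_error(sphericalKMeans(same, 9, seed = 1), "between 1")
})

test_that("initial responsibilities encode the noise proportion", {
  set.seed(8)
  x <- rUnitSphere(30, 3)
  g <- initResponsibilities(x, 3, noiseProp = 0.05, seed = 2)
  expect_equal(dim(g), c(30L, 4L))
  expect_equal(rowSums(g), rep(1, 30), tolerance = 1e-12)
  expect_true(all(g[, 4] == 0.05))
  expect_true(all(g[, 1:3] %in% c(0, 0.95)))
  expect_error(initResponsibilities(x, 2, noiseProp = 1.2), "noiseProp")
})

test_that("log-likelihood is monotone over EM iterations on random problems", {
  set.seed(101)
  for (r in 1:15) {
    n <- sample(30:70, 1)
    m <- sample(2:4, 1)
    K <- sample(1:3, 1)
    x <- normalizeToUnit(rUnitSphere(n, m))
    # exact concentration update: the EM guarantee holds strictly
    fit <- fitNAvMix(x, k = K, nRestarts = 2, seed = r,
                     kappaMethod = "newton")
    expect_true(all(diff(fit@loglikTrace) >= -1e-8))
    # closed-form approximate update: monotone up to the scale of the
    # approximation error near the optimum
    fitB <- fitNAvMix(x, k = K, nRestarts = 2, seed = r)
    expect_true(all(diff(fitB@loglikTrace) >= -1e-2))
  }
})

test_that("fits are rotation equivariant and label-permutation invariant", {
  set.seed(21)
  x <- rbind(rVMF(40, c(1, 0, 0), 30), rVMF(40, c(0, 1, 0), 30))
  # tight tolerance so a rounding-induced extra iteration cannot move
  # the final log-likelihood measurably
  fit <- fitNAvMix(normalizeToUnit(x), k = 2, seed = 3, tol = 1e-9)
  Q <- randomRotation(3)
  fitR <- fitNAvMix(normalizeToUnit(x %*% t(Q)), k = 2, seed = 3,
                    tol = 1e-9)
  expect_equal(fitR@logLik, fit@logLik, tolerance = 1e-8)
  expect_equal(sort(mixingProportions(fitR)), sort(mixingProportions(fit)),
               tolerance = 1e-8)
  expect_equal(sort(concentrations(fitR)), sort(concentrations(fit)),
               tolerance = 1e-6)
  # mean directions rotate with the data (match up to component order)
  muR <- meanDirections(fitR)
  muQ <- meanDirections(fit) %*% t(Q)
  perm <- apply(muQ %*% t(muR), 1, which.max)
  expect_equal(sort(perm), 1:2)
  expect_equal(muR[perm, ], muQ, tolerance = 1e-6, ignore_attr = TRUE)

  # permuting component order leaves the likelihood unchanged
  model <- fit@model
  permuted <- new("NAvMixModel", K = 2L, mu = model@mu[2:1, ],
                  kappa = model@kappa[2:1], noiseMu = model@noiseMu,
                  noiseKappa = model@noiseKappa,
                  pi = model@pi[c(2, 1, 3)])
  expect_equal(navmixLogLik(fit@data, permuted),
               navmixLogLik(fit@data, model), tolerance = 1e-10)
})

test_that("restarts keep the best likelihood and fits are deterministic", {
  set.seed(33)
  x <- rbind(rVMF(30, c(1, 0, 0), 40), rVMF(30, c(0, 0, 1), 40))
  ds <- normalizeToUnit(x)
  multi <- fitNAvMix(ds, k = 2, nRestarts = 5, seed = 9)
  for (s in 1:4) {
    single <- fitNAvMix(ds, k = 2, nRestarts = 1, seed = s)
    expect_gte(multi@logLik, single@logLik - 1e-6)
  }
  again <- fitNAvMix(ds, k = 2, nRestarts = 5, seed = 9)
  expect_equal(again@logLik, multi@logLik)
  expect_equal(again@model@mu, multi@model@mu)
  expect_identical(again@nIter, multi@nIter)
})

test_that("a single tight cluster is recovered with small noise share", {
  set.seed(44)
  mu <- c(0, 0, 1)
  x <- rVMF(200, mu, 60)
  fit <- fitNAvMix(normalizeToUnit(x), k = 1, seed = 5)
  expect_lt(angleDeg(meanDirections(fit)[1, ], mu), 2)
  expect_lt(mixingProportions(fit)[2], 0.1)
})

test_that("parameters of a two-component mixture are recovered", {
  set.seed(55)
  mu1 <- c(1, 0, 0); mu2 <- c(0, 1, 0)
  x <- rbind(rVMF(250, mu1, 50), rVMF(250, mu2, 50))
  fit <- fitNAvMix(normalizeToUnit(x), k = 2, seed = 6)
  mu <- meanDirections(fit)
  expect_lt(angleDeg(mu[which.max(mu %*% mu1), ], mu1), 2)
  expect_lt(angleDeg(mu[which.max(mu %*% mu2), ], mu2), 2)
  expect_lt(max(abs(concentrations(fit) - 50) / 50), 0.15)
})

test_that("uniform outliers collect in the noise component", {
  set.seed(66)
  x <- rbind(rVMF(80, c(0, 0, 1), 80), rUnitSphere(20, 3))
  fit <- fitNAvMix(normalizeToUnit(x), k = 1, seed = 7)
  noiseTop <- max.col(fit@gamma, ties.method = "first") == 2L
  expect_gte(sum(noiseTop[81:100]), 16)   # >= 80% of planted outliers
  expect_lte(sum(noiseTop[1:80]), 8)
})

test_that("BIC uses the printed parameter count and selection takes the argmin", {
  set.seed(77)
  x <- rbind(rVMF(60, c(1, rep(0, 8)), 80),
             rVMF(60, c(0, 1, rep(0, 7)), 80))
  fit <- fitNAvMix(normalizeToUnit(x), k = 4, nRestarts = 2, seed = 8)
  # r_m(K) = (m + 2) K + m: m = 9, K = 4 -> 53 parameters
  expect_equal((fit@bic + 2 * fit@logLik) / log(120), 53, tolerance = 1e-8)

  sel <- fitNAvMix(normalizeToUnit(x), seed = 8, nRestarts = 3)
  expect_identical(numberOfClusters(sel), 2L)
  expect_identical(sel@kEvaluated[which.min(sel@bicEvaluated)], 2L)
  expect_equal(min(sel@bicEvaluated), sel@bic)
  # patience = 1 stops at the first increase over the running minimum
  sel1 <- fitNAvMix(normalizeToUnit(x), seed = 8, nRestarts = 3,
                    patience = 1)
  firstUp <- which(sel1@bicEvaluated > cummin(sel1@bicEvaluated))[1]
  expect_identical(length(sel1@kEvaluated), firstUp)
})

test_that("assignment implements hard, threshold and soft rules", {
  gamma <- rbind(c(0.7, 0.2, 0.1),
                 c(0.4, 0.35, 0.25),
                 c(0.45, 0.35, 0.20),
                 c(0.4, 0.4, 0.2))
  x <- rUnitSphere(4, 3)
  rownames(x) <- rownames(gamma) <- paste0("v", 1:4)
  fit <- new("NAvMixFit",
             model = makeModel(rbind(c(1, 0, 0), c(0, 1, 0)),
                               kappa = c(5, 5), pi = c(0.4, 0.4, 0.2),
                               noiseMu = c(0, 0, 1)),
             gamma = gamma, loglikTrace = 0, logLik = 0, bic = 0,
             nIter = 1L, converged = TRUE, nRestartsUsed = 1L,
             seed = 1L, data = normalizeToUnit(x),
             kEvaluated = integer(0), bicEvaluated = numeric(0))
  hard <- assignClusters(fit)
  expect_identical(unname(clusterLabels(hard)), c("1", "1", "1", "1"))
  # ties break to the lowest index (row 4: 0.4 vs 0.4)
  thr <- assignClusters(fit, mode = "threshold", threshold = 0.5)
  expect_identical(unname(clusterLabels(thr)),
                   c("1", "unassigned", "unassigned", "unassigned"))
  soft <- assignClusters(fit, mode = "soft", threshold = 0.3)
  expect_identical(soft@softSets[[3]], c("1", "2"))
  expect_identical(soft@softSets[[1]], "1")
  expect_error(assignClusters(fit, mode = "soft"), "threshold")
  expect_error(assignClusters(fit, mode = "threshold", threshold = 2),
               "threshold")
})

test_that("fit serialisation writes memberships and a model sidecar", {
  set.seed(88)
  x <- rbind(rVMF(30, c(1, 0), 40), rVMF(30, c(0, 1), 40))
  fit <- fitNAvMix(normalizeToUnit(x), k = 2, seed = 2)
  dir <- withr::local_tempdir()
  writeNAvMixFit(fit, dir)
  mem <- read.table(file.path(dir, "membership.tsv"), header = TRUE,
                    sep = "\t")
  expect_identical(nrow(mem), 60L)
  expect_equal(rowSums(mem[, 3:5]), rep(1, 60), tolerance = 1e-8)
  side <- yaml::read_yaml(file.path(dir, "model.yaml"))
  expect_identical(side$K, 2L)
  expect_equal(side$logLik, fit@logLik, tolerance = 1e-10)
  expect_length(side$pi, 3L)
})
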