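# Reading summary statistics, covariance construction, standardisation
# and projection to the unit sphere.

cmap <- list(bmi = c(beta = "bmi_beta", se = "bmi_se"),
             sbp = c(beta = "sbp_beta", se = "sbp_se"))

test_that("association tables parse from TSV and CSV with row filtering", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- writeAssocFixture(tsv)
  at <- readAssociationTable(tsv, cmap)
  expect_s4_class(at, "AssociationSet")
  expect_identical(dim(at), c(3L, 2L))
  expect_identical(variantIds(at), c("rs1", "rs2", "rs3"))
  expect_identical(traitNames(at), c("bmi", "sbp"))
  expect_equal(unname(betaValues(at)[, 1]), df$bmi_beta)
  expect_equal(unname(seValues(at)[, 2]), df$sbp_se)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeAssocFixture(csv, sep = ",")
  expect_identical(betaValues(readAssociationTable(csv, cmap)),
                   betaValues(at))

  # invalid rows are dropped with a message
  bad <- read.table(tsv, header = TRUE)
  bad$bmi_se[2] <- 0
  bad$sbp_beta[3] <- NA
  f2 <- withr::local_tempfile()
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(at2 <- readAssociationTable(f2, cmap), "dropped 2")
  expect_identical(variantIds(at2), "rs1")

  expect_error(readAssociationTable(tsv, list(
    bmi = c(beta = "bmi_beta", se = "nope"),
    sbp = c(beta = "sbp_beta", se = "sbp_se"))), "nope")
  bad$bmi_se <- 0
  bad$sbp_beta <- NA
  f3 <- withr::local_tempfile()
  write.table(bad, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readAssociationTable(f3, cmap)),
               "no usable")
})

test_that("allele orientation flips whole rows and is idempotent", {
  at <- AssociationSet(beta = rbind(c(0.1, -0.3), c(0.2, 0.1)),
                       se = matrix(0.05, 2, 2),
                       variantIds = c("a", "b"),
                       traitNames = c("t1", "t2"),
                       primaryBeta = c(-0.02, 0.02))
  or1 <- orientToPrimaryTrait(at)
  expect_equal(unname(betaValues(or1)[1, ]), c(-0.1, 0.3))   # flipped
  expect_equal(unname(betaValues(or1)[2, ]), c(0.2, 0.1))    # unchanged
  expect_identical(seValues(or1), seValues(at))
  expect_equal(abs(betaValues(or1)), abs(betaValues(at)))
  or2 <- orientToPrimaryTrait(or1)
  expect_identical(betaValues(or2), betaValues(or1))
  noPb <- AssociationSet(betaValues(at), seValues(at))
  expect_error(orientToPrimaryTrait(noPb), "primaryBeta")
})

test_that("covariance construction follows se_k se_l cor_kl", {
  expect_equal(buildCovariance(c(0.1, 0.2)), diag(c(0.01, 0.04)))
  corr <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  sig <- buildCovariance(c(0.1, 0.2), corr)
  expect_equal(sig[1, 2], 0.1 * 0.2 * 0.5)
  expect_equal(sig[1, 1], 0.01)
  expect_equal(buildCovariance(c(0.3, 0.4), diag(2)),
               buildCovariance(c(0.3, 0.4)))
  # symmetric PSD output for random PSD correlations
  set.seed(4)
  for (r in 1:10) {
    m <- sample(2:5, 1)
    a <- matrix(rnorm(m * m), m)
    corr <- cov2cor(crossprod(a) + diag(m) * 0.1)
    sig <- buildCovariance(runif(m, 0.01, 1), corr)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    expect_gte(min(eigen(sig, symmetric = TRUE)$values), -1e-12)
  }
  badCorr <- matrix(c(1, 2, 2, 1), 2, 2)   # not PSD, entries out of range
  expect_error(buildCovariance(c(0.1, 0.1), badCorr))
  expect_error(buildCovariance(c(0, 0.1)), "positive")
})

test_that("standardisation reduces to z-scores without correlation", {
  at <- AssociationSet(beta = rbind(c(0.05, -0.02)),
                       se = rbind(c(0.01, 0.01)))
  expect_equal(unname(standardizeAssociations(at)[1, ]), c(5, -2))
  set.seed(9)
  beta <- matrix(rnorm(30), 10, 3)
  se <- matrix(runif(30, 0.01, 0.2), 10, 3)
  at2 <- AssociationSet(beta, se)
  expect_lt(max(abs(standardizeAssociations(at2) - beta / se)), 1e-12)
  expect_lt(max(abs(standardizeAssociations(at2, diag(3)) - beta / se)),
            1e-12)
})

test_that("full-covariance standardisation matches the 2x2 eigen oracle", {
  rho <- 0.6
  # closed form for the symmetric inverse root of [[1, rho], [rho, 1]]:
  # eigenvectors (1,1)/sqrt(2), (1,-1)/sqrt(2), eigenvalues 1+rho, 1-rho
  at <- AssociationSet(beta = rbind(c(1, 1), c(0.3, -0.7)),
                       se = rbind(c(1, 1), c(2, 0.5)))
  corr <- matrix(c(1, rho, rho, 1), 2, 2)
  z <- standardizeAssociations(at, corr)
  oracle <- function(betaRow, seRow) {
    # explicit 2x2 eigendecomposition: quadratic formula + rotation angle
    sig <- outer(seRow, seRow) * corr
    tr <- sum(diag(sig)); det0 <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
    lam <- c((tr + sqrt(tr^2 - 4 * det0)) / 2,
             (tr - sqrt(tr^2 - 4 * det0)) / 2)
    th <- 0.5 * atan2(2 * sig[1, 2], sig[1, 1] - sig[2, 2])
    v <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    isq <- v %*% diag(1 / sqrt(lam)) %*% t(v)
    drop(isq %*% betaRow)
  }
  expect_equal(unname(z[1, ]), oracle(c(1, 1), c(1, 1)), tolerance = 1e-10)
  expect_equal(unname(z[2, ]), oracle(c(0.3, -0.7), c(2, 0.5)),
               tolerance = 1e-10)
  # perfectly correlated traits give a singular covariance
  corr1 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(standardizeAssociations(at, corr1), "singular|v1")
})

test_that("unit projection preserves direction and rejects zero rows", {
  ds <- normalizeToUnit(rbind(c(3, 4), c(-1, 0)))
  expect_s4_class(ds, "DirectionalSet")
  expect_equal(unname(unitVectors(ds)[1, ]), c(0.6, 0.8))
  expect_equal(unname(unitVectors(ds)[2, ]), c(-1, 0))
  set.seed(2)
  z <- matrix(rnorm(60), 20, 3)
  x1 <- unitVectors(normalizeToUnit(z))
  expect_equal(unname(sqrt(rowSums(x1^2))), rep(1, 20),
               tolerance = 1e-10)
  # scale invariance and preserved cosine
  for (c0 in c(7, 0.001, 1e6)) {
    expect_equal(unitVectors(normalizeToUnit(c0 * z)), x1,
                 tolerance = 1e-12)
  }
  cosines <- unname(rowSums(z * x1) / sqrt(rowSums(z^2)))
  expect_equal(cosines, rep(1, 20), tolerance = 1e-12)
  zbad <- rbind(c(1, 1), c(0, 0))
  rownames(zbad) <- c("ok", "degenerate")
  expect_error(normalizeToUnit(zbad), "degenerate")
})

test_that("directional data round-trips through delimited text", {
  ds <- normalizeToUnit(matrix(rnorm(12), 4, 3),
                        variantIds = paste0("rs", 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDirectionalSet(ds, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(back$variant, paste0("rs", 1:4))
  expect_equal(as.matrix(back[, -1]), unitVectors(ds),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("trait correlation files are validated on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  corr <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  write.csv(as.data.frame(corr), f)
  expect_equal(unname(readTraitCorrelation(f)), unname(corr))
  bad <- corr; bad[1, 2] <- 0.9            # asymmetric
  write.csv(as.data.frame(bad), f)
  expect_error(readTraitCorrelation(f), "symmetric")
})
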