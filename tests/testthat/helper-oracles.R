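# Brute-force oracles, deliberately naive implementations used only to
# check the package's vectorised code paths.

# pair-counting adjusted Rand index: enumerate all C(n,2) pairs
ariPairCounting <- function(a, b) {
  n <- length(a)
  sameA <- sameB <- both <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + 1
      ia <- a[i] == a[j]
      ib <- b[i] == b[j]
      sameA <- sameA + ia
      sameB <- sameB + ib
      both <- both + (ia && ib)
    }
  }
  expected <- sameA * sameB / total
  maxIndex <- (sameA + sameB) / 2
  if (maxIndex == expected) return(1)
  (both - expected) / (maxIndex - expected)
}

# all set partitions of seq_len(n) as label vectors (Bell(6) = 203)
allPartitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- allPartitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (k in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, k)
    }
  }
  out
}

# silhouette with explicit loops and arc-length distances
silhouetteEnumerated <- function(x, labels) {
  n <- nrow(x)
  d <- function(i, j) acos(min(max(sum(x[i, ] * x[j, ]), -1), 1))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(vapply(mates, function(j) d(i, j), 0))
    b <- Inf
    for (l in setdiff(unique(labels), own)) {
      members <- which(labels == l)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# textbook OLS of y on (1, g) via the normal equations
olsOracle <- function(g, y) {
  X <- cbind(1, g)
  xtxInv <- solve(t(X) %*% X)
  coefs <- xtxInv %*% t(X) %*% y
  resid <- y - X %*% coefs
  sigma2 <- sum(resid^2) / (length(y) - 2)
  list(slope = coefs[2], se = sqrt(sigma2 * xtxInv[2, 2]))
}

# small wide association table for IO tests
writeAssocFixture <- function(path, sep = "\t") {
  df <- data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    bmi_beta = c(0.05, -0.02, 0.031),
    bmi_se = c(0.01, 0.012, 0.009),
    sbp_beta = c(-0.02, 0.015, 0.008),
    sbp_se = c(0.01, 0.011, 0.01))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  df
}
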