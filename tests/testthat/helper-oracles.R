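# Independent brute-force oracles. Everything here recomputes the target
# quantities with explicit loops and textbook formulas, deliberately
# avoiding the package's own code paths.

# Random grouped Ct table for property tests.
randomCtTable <- function(k = 7, n = 10, seed = 1, twoGroups = TRUE) {
  set.seed(seed)
  ct <- matrix(runif(k * n, 15, 35), k, n,
               dimnames = list(paste0("c", seq_len(k)),
                               paste0("s", seq_len(n))))
  group <- if (twoGroups) rep(c("g1", "g2"), c(ceiling(n / 2), floor(n / 2)))
  else rep("all", n)
  CtTable(ct, group = group, condition = "test")
}

# Two-pass sample SD.
oracleSD <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Pairwise Ct-difference SD matrix by explicit double loop.
oraclePairwiseSD <- function(ct) {
  k <- nrow(ct)
  out <- matrix(0, k, k, dimnames = list(rownames(ct), rownames(ct)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) out[i, j] <- oracleSD(ct[i, ] - ct[j, ])
  }
  out
}

# Comparative delta-Ct: mean of each row of the oracle pair-SD matrix.
oracleDeltaCt <- function(ct) {
  sdm <- oraclePairwiseSD(ct)
  k <- nrow(ct)
  vals <- numeric(k)
  for (i in seq_len(k)) vals[i] <- sum(sdm[i, -i]) / (k - 1)
  names(vals) <- rownames(ct)
  vals
}

# Stepwise geNorm by exhaustive recomputation at every step.
oracleGeNormTrace <- function(ct) {
  current <- sort(rownames(ct))
  exclusion <- character(0)
  mRec <- setNames(numeric(nrow(ct)), rownames(ct))
  while (length(current) > 2) {
    m <- setNames(numeric(length(current)), current)
    for (i in current) {
      others <- setdiff(current, i)
      m[i] <- mean(vapply(others, function(j) oracleSD(ct[i, ] - ct[j, ]),
                          numeric(1)))
    }
    worst <- sort(names(m)[m >= max(m) - 1e-12])[1]
    mRec[worst] <- m[worst]
    exclusion <- c(exclusion, worst)
    current <- setdiff(current, worst)
  }
  mRec[current] <- oracleSD(ct[current[1], ] - ct[current[2], ])
  list(exclusionOrder = exclusion, finalPair = current, m = mRec)
}

# BestKeeper descriptives by loops.
oracleBestKeeper <- function(ct) {
  k <- nrow(ct); n <- ncol(ct)
  mad <- cv <- geo <- numeric(k)
  for (i in seq_len(k)) {
    m <- mean(ct[i, ])
    mad[i] <- mean(abs(ct[i, ] - m))
    cv[i] <- 100 * mad[i] / m
    geo[i] <- prod(ct[i, ])^(1 / n)
  }
  idx <- numeric(n)
  for (s in seq_len(n)) idx[s] <- prod(ct[, s])^(1 / k)
  list(mad = setNames(mad, rownames(ct)), cv = setNames(cv, rownames(ct)),
       geo = setNames(geo, rownames(ct)), index = setNames(idx, colnames(ct)))
}

# NormFinder decomposition, step by step with explicit loops.
oracleNormFinder <- function(ct, group) {
  k <- nrow(ct)
  groups <- unique(group)
  G <- length(groups)
  yc <- ct
  for (i in seq_len(k)) yc[i, ] <- ct[i, ] - mean(ct[i, ])
  x <- yc
  for (s in seq_len(ncol(ct))) x[, s] <- yc[, s] - mean(yc[, s])
  dHat <- s2 <- sigma2 <- matrix(0, k, G,
                                 dimnames = list(rownames(ct), groups))
  nG <- setNames(integer(G), groups)
  for (g in groups) {
    cols <- which(group == g)
    nG[g] <- length(cols)
    for (i in seq_len(k)) {
      xi <- x[i, cols]
      dHat[i, g] <- mean(xi)
      s2[i, g] <- sum((xi - mean(xi))^2) / (length(xi) - 1)
    }
  }
  for (g in groups) {
    Sg <- sum(s2[, g])
    for (i in seq_len(k))
      sigma2[i, g] <- max(0, (k / (k - 2)) * (s2[i, g] - Sg / (k * (k - 1))))
  }
  sampVar <- sigma2
  for (g in groups) sampVar[, g] <- sigma2[, g] / nG[g]
  dAll <- as.vector(dHat)
  gamma2 <- max(0, sum((dAll - mean(dAll))^2) / (length(dAll) - 1) -
                  mean(sampVar))
  dTilde <- dHat
  for (g in groups) for (i in seq_len(k))
    dTilde[i, g] <- if (gamma2 == 0) 0 else
      dHat[i, g] * gamma2 / (gamma2 + sigma2[i, g] / nG[g])
  rho <- setNames(numeric(k), rownames(ct))
  for (i in seq_len(k))
    rho[i] <- mean(abs(dTilde[i, ]) + sqrt(sigma2[i, ] / nG))
  list(s2 = s2, sigma2 = sigma2, dHat = dHat, dTilde = dTilde,
       gamma2 = gamma2, rho = rho)
}

# Geometric mean of integer ranks by direct product.
oracleGeomeanRank <- function(ranks) prod(ranks)^(1 / length(ranks))
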