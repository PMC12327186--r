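nfToy <- function() {
  ct <- rbind(A = c(20.0, 20.5, 19.8, 22.1, 22.4, 21.9),
              B = c(25.2, 25.0, 25.4, 25.1, 25.3, 24.9),
              C = c(18.1, 18.9, 18.4, 19.6, 20.2, 19.9))
  colnames(ct) <- paste0("s", 1:6)
  CtTable(ct, group = rep(c("g1", "g2"), each = 3))
}

test_that("a zero-noise table decomposes to all-zero components", {
  ct <- matrix(rep(c(20, 25, 30), 6), 3, 6,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:6)))
  tab <- CtTable(ct, group = rep(c("g1", "g2"), each = 3))
  dec <- normFinderDecompose(tab)
  expect_equal(unname(dec@sigma2), matrix(0, 3, 2))
  expect_equal(unname(dec@dHat), matrix(0, 3, 2))
  expect_equal(dec@gamma2, 0)
  expect_equal(unname(stabilityValues(normFinderStability(dec))),
               rep(0, 3))
  expect_equal(unname(stabilityValues(normFinderSingleGroup(tab))),
               rep(0, 3))
})

test_that("the decomposition reproduces a step-by-step computation on a toy", {
  dec <- normFinderDecompose(nfToy())
  # frozen values from the independent step-by-step oracle
  expect_equal(dec@gamma2, 0.219388888888889, tolerance = 1e-9)
  rho <- stabilityValues(normFinderStability(dec))
  expect_equal(rho[["A"]], 0.498060565903953, tolerance = 1e-9)
  expect_equal(rho[["B"]], 0.690556440405768, tolerance = 1e-9)
  expect_equal(rho[["C"]], 0.267543914078403, tolerance = 1e-9)

  oracle <- oracleNormFinder(ctValues(nfToy()), sampleGroups(nfToy()))
  expect_equal(dec@s2, oracle$s2, tolerance = 1e-12)
  expect_equal(dec@sigma2, oracle$sigma2, tolerance = 1e-12)
  expect_equal(dec@dHat, oracle$dHat, tolerance = 1e-12)
  expect_equal(dec@dTilde, oracle$dTilde, tolerance = 1e-12)
  expect_equal(rho, oracle$rho, tolerance = 1e-12)
})

test_that("the decomposition matches the oracle on random grouped tables", {
  for (seed in 41:46) {
    tab <- randomCtTable(k = sample(3:8, 1), n = 10, seed = seed)
    dec <- normFinderDecompose(tab)
    oracle <- oracleNormFinder(ctValues(tab), sampleGroups(tab))
    expect_equal(dec@sigma2, oracle$sigma2, tolerance = 1e-9)
    expect_equal(dec@dHat, oracle$dHat, tolerance = 1e-9)
    expect_equal(dec@dTilde, oracle$dTilde, tolerance = 1e-9)
    expect_equal(dec@gamma2, oracle$gamma2, tolerance = 1e-9)
    expect_equal(stabilityValues(normFinderStability(dec)), oracle$rho,
                 tolerance = 1e-9)
    # structural invariants
    expect_equal(unname(colSums(dec@dHat)), c(0, 0), tolerance = 1e-9)
    expect_true(all(abs(dec@dTilde) <= abs(dec@dHat) + 1e-12))
    expect_true(all(dec@sigma2 >= 0))
    expect_gte(dec@gamma2, 0)
  }
})

test_that("contract errors: too few candidates, single group", {
  ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 26, 27, 28))
  colnames(ct) <- paste0("s", 1:4)
  expect_error(normFinderDecompose(CtTable(ct, group = c("g1", "g1", "g2", "g2"))),
               class = "ctsContractError")
  tab1g <- randomCtTable(k = 5, n = 8, seed = 1, twoGroups = FALSE)
  expect_error(normFinderDecompose(tab1g), "normFinderSingleGroup",
               class = "ctsContractError")
  expect_error(normFinderSingleGroup(CtTable(ct[, 1:2, drop = FALSE] + 0,
                                             group = NULL)),
               class = "ctsContractError")
})

test_that("a group-shifted candidate shows the largest intergroup deviation", {
  hits <- vapply(1:100, function(seed) {
    spec <- SimSpec(sigma = rep(0.3, 7), delta = c(2, rep(0, 6)),
                    tau = 0.8, nReplicates = 1L, seed = seed)
    dec <- normFinderDecompose(simulateCt(spec))
    maxDev <- apply(abs(dec@dHat), 1, max)
    names(which.max(maxDev)) == "cand1"
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("single-group stability ranks an inflated-noise candidate last", {
  hits <- vapply(1:100, function(seed) {
    spec <- SimSpec(sigma = c(rep(0.3, 6), 1.5), delta = rep(0, 7),
                    nPerGroup = c(all = 10L), tau = 0.8,
                    nReplicates = 1L, seed = seed + 200)
    rho <- stabilityValues(normFinderSingleGroup(simulateCt(spec)))
    names(which.max(rho)) == "cand7"
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("a shared per-sample loading leaves the decomposition unchanged", {
  tab <- randomCtTable(k = 7, n = 10, seed = 51)
  ct <- ctValues(tab)
  shifted <- sweep(ct, 2L, seq(-3, 3, length.out = ncol(ct)), "+")
  dec1 <- normFinderDecompose(tab)
  dec2 <- normFinderDecompose(CtTable(shifted, group = sampleGroups(tab)))
  expect_equal(dec1@sigma2, dec2@sigma2, tolerance = 1e-12)
  expect_equal(dec1@dHat, dec2@dHat, tolerance = 1e-12)
  expect_equal(dec1@gamma2, dec2@gamma2, tolerance = 1e-12)
})

test_that("the stability ranking recovers the true disorder ordering", {
  spec <- SimSpec(sigma = seq(0.1, 1.5, length.out = 7),
                  delta = c(0, 0, 0, 0, 0.8, 0, 1.6), tau = 0.8,
                  nReplicates = 1L)
  truth <- trueDisorder(spec)
  nRep <- 200L
  sumRank <- setNames(numeric(7), spec@candidates)
  for (seed in seq_len(nRep)) {
    rspec <- spec
    rspec@seed <- 5000L + seed
    rho <- stabilityValues(normFinderStability(
      normFinderDecompose(simulateCt(rspec))))
    sumRank <- sumRank + rank(rho)
  }
  expect_gte(cor(rank(truth), sumRank / nRep, method = "spearman"), 0.9)
})
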