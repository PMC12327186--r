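toyTable <- function() {
  ct <- rbind(A = c(20, 21, 22, 23),
              B = c(25, 26, 27, 28),
              C = c(20, 22, 21, 24))
  colnames(ct) <- paste0("s", 1:4)
  CtTable(ct, group = c("g1", "g1", "g2", "g2"))
}

test_that("pairwise SD matches hand values and the brute-force oracle", {
  sdm <- pairwiseSD(toyTable())
  # B is A plus a constant: zero pairwise SD
  expect_equal(sdm["A", "B"], 0)
  # differences A - C = (0, -1, 1, -1): SD 0.9574 by hand
  expect_equal(sdm["A", "C"], 0.957427107756338, tolerance = 1e-12)
  expect_equal(sdm["A", "C"], oracleSD(c(0, -1, 1, -1)), tolerance = 1e-14)
  # symmetry, zero diagonal, non-negativity
  expect_equal(sdm, t(sdm))
  expect_equal(diag(sdm), setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(all(sdm >= 0))

  for (seed in 1:5) {
    tab <- randomCtTable(k = 6, n = 9, seed = seed)
    expect_equal(pairwiseSD(tab), oraclePairwiseSD(ctValues(tab)),
                 tolerance = 1e-12)
  }
})

test_that("pairwise SD is invariant to per-sample and per-candidate constants", {
  tab <- randomCtTable(k = 5, n = 8, seed = 31)
  base <- pairwiseSD(tab)
  ct <- ctValues(tab)
  perSample <- sweep(ct, 2L, seq(-2, 2, length.out = ncol(ct)), "+")
  perCand <- ct + seq(-1, 3, length.out = nrow(ct))
  expect_equal(pairwiseSD(CtTable(perSample, group = sampleGroups(tab))),
               base, tolerance = 1e-12)
  expect_equal(pairwiseSD(CtTable(perCand, group = sampleGroups(tab))),
               base, tolerance = 1e-12)
})

test_that("delta-Ct stability equals mean pairwise SD per candidate", {
  vals <- stabilityValues(deltaCtStability(toyTable()))
  expect_equal(vals[["A"]], 0.957427107756338 / 2, tolerance = 1e-12)
  expect_equal(vals[["B"]], vals[["A"]], tolerance = 1e-14)
  expect_equal(vals[["C"]], 0.957427107756338, tolerance = 1e-12)

  # two duplicated candidates only -> both zero
  dup <- CtTable(rbind(X = c(20, 21, 22), Y = c(20, 21, 22)),
                 group = NULL)
  expect_equal(unname(stabilityValues(deltaCtStability(dup))), c(0, 0))

  for (seed in 6:10) {
    tab <- randomCtTable(k = 7, n = 10, seed = seed)
    expect_equal(stabilityValues(deltaCtStability(tab)),
                 oracleDeltaCt(ctValues(tab)), tolerance = 1e-12)
  }
})

test_that("geNorm M on the full panel is exactly the delta-Ct stability", {
  for (seed in 11:20) {
    tab <- randomCtTable(k = 7, n = 10, seed = seed)
    expect_equal(stabilityValues(geNormM(tab)),
                 stabilityValues(deltaCtStability(tab)), tolerance = 1e-12)
  }
})

test_that("geNorm M on subsets matches the pair SDs", {
  tab <- toyTable()
  mAB <- stabilityValues(geNormM(tab, c("A", "B")))
  expect_equal(unname(mAB), c(0, 0))
  mAC <- stabilityValues(geNormM(tab, c("A", "C")))
  expect_equal(unname(mAC), rep(0.957427107756338, 2), tolerance = 1e-12)
  expect_error(geNormM(tab, "A"), class = "ctsContractError")
})

test_that("stepwise geNorm excludes the least stable candidate first", {
  tr <- geNormRank(toyTable())
  expect_identical(tr@exclusionOrder, "C")
  expect_identical(sort(tr@finalPair), c("A", "B"))
  expect_equal(tr@mAtExclusion[["C"]], 0.957427107756338, tolerance = 1e-12)
  expect_equal(tr@mAtExclusion[["A"]], 0)
  rv <- rankValues(geNormRankVector(tr))
  expect_equal(rv[["A"]], 1L)
  expect_equal(rv[["B"]], 1L)
  expect_equal(rv[["C"]], 3L)
})

test_that("stepwise geNorm matches exhaustive recomputation on random tables", {
  for (seed in 21:26) {
    tab <- randomCtTable(k = 7, n = 10, seed = seed)
    tr <- geNormRank(tab)
    oracle <- oracleGeNormTrace(ctValues(tab))
    expect_identical(tr@exclusionOrder, oracle$exclusionOrder)
    expect_identical(sort(tr@finalPair), sort(oracle$finalPair))
    expect_equal(tr@mAtExclusion, oracle$m[names(tr@mAtExclusion)],
                 tolerance = 1e-12)
  }
})

test_that("a candidate duplicated up to a constant always forms the final pair", {
  set.seed(5)
  ct <- matrix(runif(5 * 8, 18, 32), 5, 8,
               dimnames = list(paste0("c", 1:5), paste0("s", 1:8)))
  ct[4, ] <- ct[2, ] + 3.5
  tr <- geNormRank(CtTable(ct))
  expect_identical(sort(tr@finalPair), c("c2", "c4"))
})

test_that("the geNorm final pair recovers a planted stable pair", {
  # stepwise exclusion does not in general guarantee that the final pair
  # minimises the pairwise SD (a member of the best pair can carry the
  # worst M early on), but when one pair is distinctly tighter than every
  # other relation it must survive to the end
  for (seed in 27:34) {
    set.seed(seed)
    k <- sample(5:8, 1)
    ct <- matrix(runif(k * 10, 15, 35), k, 10,
                 dimnames = list(paste0("c", seq_len(k)), paste0("s", 1:10)))
    ct[2, ] <- ct[1, ] + 2 + rnorm(10, 0, 0.05)  # tight pair (c1, c2)
    tab <- CtTable(ct)
    tr <- geNormRank(tab)
    expect_identical(sort(tr@finalPair), c("c1", "c2"))
    sdm <- pairwiseSD(tab)
    expect_equal(sdm["c1", "c2"], min(sdm[upper.tri(sdm)]),
                 tolerance = 1e-12)
  }
})

test_that("geNorm V is zero for proportional factors and matches brute force", {
  # third candidate equal to a retained candidate plus a constant:
  # both normalization factors are proportional, so V = 0
  set.seed(9)
  ct <- matrix(runif(2 * 6, 20, 30), 2, 6,
               dimnames = list(c("a1", "a2"), paste0("s", 1:6)))
  ct <- rbind(ct, a3 = ct["a1", ] + 2)
  # a1/a3 are the zero-SD pair (final pair); a2 enters at n = 3... but with
  # k = 3 only n = 2 is valid, comparing NF2 (final pair) to NF3.
  tabProp <- CtTable(rbind(ct[c("a1", "a3"), ], dup = ct["a1", ] + 1))
  trProp <- geNormRank(tabProp)
  expect_equal(geNormV(trProp, tabProp, 2), 0, tolerance = 1e-12)

  tab <- toyTable()
  tr <- geNormRank(tab)
  v <- geNormV(tr, tab, 2)
  # direct recomputation: ranking is (A, B) then C
  ctv <- ctValues(tab)[c("A", "B", "C"), ]
  q <- 2^(apply(ctv, 1, min) - ctv)
  nf2 <- apply(q[1:2, ], 2, function(x) prod(x)^(1 / 2))
  nf3 <- apply(q, 2, function(x) prod(x)^(1 / 3))
  expect_equal(v, oracleSD(log2(nf2 / nf3)), tolerance = 1e-12)
  expect_gte(v, 0)
  expect_error(geNormV(tr, tab, 3), class = "ctsContractError")
})
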