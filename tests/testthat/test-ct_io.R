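test_that("well-formed wide input round-trips through read and write", {
  tab <- randomCtTable(k = 7, n = 10, seed = 11)
  ctf <- withr::local_tempfile(fileext = ".csv")
  mdf <- withr::local_tempfile(fileext = ".csv")
  writeCtTable(tab, ctf, mdf)
  back <- readCtTable(ctf, mdf)
  expect_equal(ctValues(back), ctValues(tab), tolerance = 1e-7)
  expect_identical(candidateNames(back), candidateNames(tab))
  expect_identical(unname(sampleGroups(back)), unname(sampleGroups(tab)))
  expect_identical(conditionLabel(back), "test")
})

test_that("reader rejects malformed input with informative errors", {
  ctf <- withr::local_tempfile(fileext = ".csv")
  mdf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2"), group = c("g1", "g2"),
                       condition = "x"), mdf, row.names = FALSE)

  # non-numeric cell named in the error
  write.csv(data.frame(candidate = c("A", "B"), s1 = c("20", "Undetermined"),
                       s2 = c("21", "26")), ctf, row.names = FALSE)
  expect_error(readCtTable(ctf, mdf), "Undetermined", class = "ctsParseError")

  # Ct outside (0, 45]
  write.csv(data.frame(candidate = c("A", "B"), s1 = c(20, 99),
                       s2 = c(21, 26)), ctf, row.names = FALSE)
  expect_error(readCtTable(ctf, mdf), "(0, 45]", fixed = TRUE)

  # duplicate candidate ids
  write.csv(data.frame(candidate = c("A", "A"), s1 = c(20, 22),
                       s2 = c(21, 26)), ctf, row.names = FALSE)
  expect_error(readCtTable(ctf, mdf), "duplicate",
               class = "ctsValidationError")

  # metadata missing a sample, named in the error
  write.csv(data.frame(candidate = c("A", "B"), s1 = c(20, 25),
                       s2 = c(21, 26), s3 = c(22, 27)), ctf,
            row.names = FALSE)
  expect_error(readCtTable(ctf, mdf), "s3", class = "ctsValidationError")
})

test_that("long dialect collapses replicates and carries QC flags", {
  ctf <- withr::local_tempfile(fileext = ".csv")
  mdf <- withr::local_tempfile(fileext = ".csv")
  long <- expand.grid(sample = c("s1", "s2"), candidate = c("A", "B"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  long$ct <- 20 + seq_len(nrow(long)) * 0.01
  long$ct[long$sample == "s1" & long$candidate == "A"] <- c(20, 20.2, 20.4)
  write.csv(long, ctf, row.names = FALSE)
  write.csv(data.frame(sample = c("s1", "s2"), group = c("g1", "g2"),
                       condition = "x"), mdf, row.names = FALSE)
  tab <- readCtTable(ctf, mdf, dialect = "long", spreadThreshold = 0.3)
  expect_equal(ctValues(tab)["A", "s1"], 20.2)
  qc <- S4Vectors::metadata(tab)$replicateQC
  expect_true(qc$flagged[qc$candidate == "A" & qc$sample == "s1"])
})

test_that("replicate collapse is the arithmetic mean, flags wide spreads, keeps singletons", {
  raw <- data.frame(sample = "s1", candidate = "A", ct = c(20.0, 20.2, 20.4))
  out <- collapseReplicates(raw)
  expect_equal(out$ct["A", "s1"], 20.2)
  expect_false(out$qc$flagged)

  single <- collapseReplicates(data.frame(sample = "s1", candidate = "A",
                                          ct = 25.0))
  expect_equal(single$ct["A", "s1"], 25.0)
  expect_false(single$qc$flagged)

  wide <- collapseReplicates(data.frame(sample = "s1", candidate = "A",
                                        ct = c(20, 21)),
                             spreadThreshold = 0.5)
  expect_equal(wide$ct["A", "s1"], 20.5)
  expect_true(wide$qc$flagged)

  expect_error(collapseReplicates(data.frame(sample = character(0),
                                             candidate = character(0),
                                             ct = numeric(0))),
               class = "ctsValidationError")
})

test_that("replicate collapse is invariant to replicate order", {
  set.seed(3)
  raw <- data.frame(sample = rep(c("s1", "s2"), each = 6),
                    candidate = rep(rep(c("A", "B"), each = 3), 2),
                    ct = runif(12, 18, 30))
  perm <- raw[sample(nrow(raw)), ]
  ref <- collapseReplicates(raw)$ct
  got <- collapseReplicates(perm)$ct[rownames(ref), colnames(ref)]
  expect_equal(got, ref)
})

test_that("group summaries match a brute-force two-pass computation", {
  tab <- randomCtTable(k = 7, n = 10, seed = 21)
  summ <- summarizeGroupCt(tab)
  ct <- ctValues(tab)
  g <- sampleGroups(tab)
  for (r in seq_len(nrow(summ))) {
    x <- ct[summ$candidate[r], g == summ$group[r]]
    expect_equal(summ$n[r], length(x))
    expect_equal(summ$mean[r], sum(x) / length(x), tolerance = 1e-12)
    expect_equal(summ$sd[r], oracleSD(x), tolerance = 1e-12)
    expect_equal(summ$sem[r], oracleSD(x) / sqrt(length(x)),
                 tolerance = 1e-12)
  }
  # degenerate cases: constant group and two-point formula
  ct2 <- rbind(A = c(22, 22, 20, 22), B = c(25, 26, 27, 28))
  colnames(ct2) <- paste0("s", 1:4)
  s2 <- summarizeGroupCt(CtTable(ct2, group = c("g1", "g1", "g2", "g2")))
  constRow <- s2[s2$candidate == "A" & s2$group == "g1", ]
  expect_equal(constRow$mean, 22)
  expect_equal(constRow$sd, 0)
  expect_equal(constRow$sem, 0)
  twoPt <- summarizeGroupCt(CtTable(
    rbind(A = c(20, 22, 21, 23), B = c(25, 26, 27, 28)),
    group = c("g1", "g1", "g2", "g2")))
  aRow <- twoPt[twoPt$candidate == "A" & twoPt$group == "g1", ]
  expect_equal(aRow$mean, 21)
  expect_equal(aRow$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(aRow$sem, 1, tolerance = 1e-12)
})

test_that("two-group t-test behaves at the null, detects shifts, holds its size", {
  # degenerate null: identical groups
  ct <- rbind(A = c(20, 21, 20, 21), B = c(25, 26, 25, 26))
  colnames(ct) <- paste0("s", 1:4)
  tab <- CtTable(ct, group = c("g1", "g1", "g2", "g2"))
  res <- compareGroupCt(tab)
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
  expect_false(any(res$significant))

  # clear separation with symmetric within-group jitter
  ct2 <- rbind(A = c(10, 10.1, 9.9, 20, 20.1, 19.9))
  ct2 <- rbind(ct2, B = ct2[1, ] + 5)
  colnames(ct2) <- paste0("s", 1:6)
  res2 <- compareGroupCt(CtTable(ct2, group = rep(c("g1", "g2"), each = 3)))
  expect_true(all(res2$significant))

  # contract: exactly two groups
  expect_error(compareGroupCt(randomCtTable(twoGroups = FALSE)),
               class = "ctsContractError")

  # Monte-Carlo type-I error for a stable candidate, sigma 0.3, n = 5+5
  rejections <- vapply(seq_len(500), function(s) {
    set.seed(s)
    x <- matrix(rnorm(20, 22, 0.3), 2, 10,
                dimnames = list(c("A", "B"), paste0("s", 1:10)))
    t <- CtTable(x, group = rep(c("g1", "g2"), each = 5))
    compareGroupCt(t)$significant[1]
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("panel validation enforces alphabets and non-emptiness", {
  panel <- loadCandidatePanel()
  report <- validatePanel(panel)
  expect_true(all(report$valid))
  let7 <- panel[panel$assay_name == "hsa-let-7c-5p", ]
  expect_identical(let7$mature_sequence, "UGAGGUAGUAGGUUGUAUGGUU")
  expect_equal(report$length[report$assay_name == "hsa-let-7c-5p"], 22L)

  bad <- data.frame(assay_name = c("m1", "m2"),
                    assay_id = c("1_mir", "2_mir"),
                    mature_sequence = c("ACGT", ""))
  rep2 <- validatePanel(bad)
  expect_false(any(rep2$valid))
  expect_match(rep2$problem[1], "T")
  expect_match(rep2$problem[2], "empty")
})
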