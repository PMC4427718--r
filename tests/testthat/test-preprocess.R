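test_that("normexp correction handles degenerate and identical arrays", {
  m <- cbind(a = rep(50, 20), b = rep(50, 20))
  out <- normexpCorrect(m, offset = 10)
  expect_true(all(out == 10))

  set.seed(1)
  x <- rexp(200, 1 / 500) + rnorm(200, 100, 20)
  m2 <- cbind(a = x, b = x)
  out2 <- normexpCorrect(pmax(m2, 0))
  expect_identical(out2[, "a"], out2[, "b"])
  expect_true(all(out2 > 0))

  m3 <- m2; m3[5, 2] <- NA
  expect_error(normexpCorrect(m3), "b")
})

test_that("normexp correction is monotone and asymptotically linear", {
  set.seed(7)
  x <- sort(rexp(500, 1 / 1000) + rnorm(500, 80, 15))
  x <- pmax(x, 0)
  out <- normexpCorrect(cbind(a = x), offset = 10)[, 1]
  expect_true(all(diff(out) >= -1e-9))
  ## far above background the correction approaches x - mu + offset
  par <- limma::normexp.fit(x, method = "saddle")$par
  mu <- par[1]
  top <- which(x > mu + 20 * exp(par[2]))
  expect_equal(out[top], x[top] - mu + 10, tolerance = 0.02)
})

test_that("normexp corrected values match the conditional-expectation
           integral evaluated numerically", {
  set.seed(11)
  x <- pmax(rexp(300, 1 / 800) + rnorm(300, 100, 25), 0)
  par <- limma::normexp.fit(x, method = "saddle")$par
  mu <- par[1]; sigma <- exp(par[2]); alpha <- exp(par[3])
  analytic <- limma::normexp.signal(par, x)
  numeric <- normexpExpectedSignal(x, mu, sigma, alpha)
  expect_equal(analytic, numeric, tolerance = 1e-6)
})

test_that("quantile normalization equalizes sorted columns", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantileNormalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  ## defining property on arbitrary input, exact
  set.seed(3)
  r <- matrix(rnorm(600), 100, 6)
  q <- quantileNormalize(r)
  sorted <- apply(q, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  ## rank order preserved within columns
  expect_identical(apply(q, 2L, order), apply(r, 2L, order))

  ## idempotent once distributions agree
  expect_equal(quantileNormalize(q), q, tolerance = 1e-12)
  ## single column untouched
  one <- matrix(rnorm(10), 10, 1)
  expect_identical(quantileNormalize(one), one)
})

test_that("median polish reproduces additive structure and matches the
           iterative oracle", {
  ## exactly additive probe x sample block
  a <- c(0.5, -0.2, 0.1)
  b <- c(10, 11, 9, 12)
  block <- outer(a, b, `+`)
  rownames(block) <- paste0("f1_p", 1:3)
  out <- medianPolishSummarize(block, rep("f1", 3))
  expect_equal(diff(range(out[1, ] - b)), 0, tolerance = 1e-9)

  ## single-probe feature passes through
  single <- matrix(rnorm(4), 1, 4, dimnames = list("f2_p1", NULL))
  expect_equal(unname(medianPolishSummarize(single, "f2")[1, ]),
               unname(single[1, ]))

  ## random blocks, including an outlier cell, against the oracle
  set.seed(21)
  for (i in 1:8) {
    blk <- matrix(rnorm(30), 5, 6)
    if (i %% 2 == 0) blk[2, 3] <- blk[2, 3] + 50
    rownames(blk) <- paste0("g_p", 1:5)
    got <- medianPolishSummarize(blk, rep("g", 5))[1, ]
    want <- with(oracleMedianPolish(blk), overall + col)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("median summarization takes per-feature medians", {
  m <- rbind(c(3, 3), c(5, 5), c(9, 9))
  rownames(m) <- paste0("x_p", 1:3)
  expect_equal(unname(medianSummarize(m, rep("x", 3))[1, ]), c(5, 5))
  expect_equal(unname(medianSummarize(m[1:2, ], rep("x", 2))[1, ]),
               c(4, 4))
  ## probe order is irrelevant
  perm <- m[c(3, 1, 2), ]
  expect_equal(medianSummarize(perm, rep("x", 3)),
               medianSummarize(m, rep("x", 3)))
})

test_that("detection calls threshold at the per-array percentile", {
  set.seed(5)
  m <- matrix(sample(1:1000, 200), 100, 2)
  calls <- detectionCalls(m, percentile = 0.05)
  expect_equal(unname(colSums(!detectionMatrix(calls))), c(5L, 5L))

  flat <- matrix(7, 10, 2)
  expect_true(all(!detectionMatrix(detectionCalls(flat))))  # ties -> absent

  expect_true(all(!detectionMatrix(detectionCalls(m, percentile = 1))))
  expect_error(detectionCalls(m, percentile = 0), "percentile")
  expect_error(detectionCalls(m, percentile = 1.2), "percentile")
})

test_that("presence filtering keeps features present in half of a group", {
  groups <- rep(c("sham", "L", "M", "H"), each = 10)
  mk <- function(perGroup) {
    calls <- matrix(FALSE, 1, 40)
    for (g in seq_along(perGroup))
      calls[1, (g - 1) * 10 + seq_len(perGroup[g])] <- TRUE
    calls
  }
  cm <- rbind(mk(c(5, 0, 0, 0)),   # half of sham: kept
              mk(c(0, 0, 0, 0)),   # absent everywhere: dropped
              mk(c(4, 4, 4, 4)))   # under half in all groups: dropped
  rownames(cm) <- c("keep", "none", "weak")
  calls <- new("DetectionCalls", calls = cm,
               thresholds = rep(0, 40), percentile = 0.05)
  expect_identical(filterPresent(calls, groups), "keep")
  expect_error(filterPresent(calls, replace(groups, 3, NA)), "group")
})

test_that("between-array correlation QC flags the permuted array only", {
  set.seed(9)
  base <- rnorm(300, 8, 2)
  m <- sapply(1:6, function(i) base + rnorm(300, 0, 0.3))
  m <- cbind(m, sample(base))          # array 7: permuted copy
  colnames(m) <- paste0("a", 1:7)
  qc <- detectOutlierArrays(m)
  expect_identical(excludedArrays(qc), "a7")

  ## identical arrays: nothing flagged
  same <- matrix(rep(rnorm(50), 4), 50, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  expect_length(excludedArrays(detectOutlierArrays(same)), 0L)

  ## flag set invariant to array ordering
  perm <- m[, c(7, 3, 1, 6, 2, 5, 4)]
  expect_setequal(excludedArrays(detectOutlierArrays(perm)), "a7")

  ## too few arrays: no flagging, note recorded
  small <- detectOutlierArrays(m[, 1:2])
  expect_length(excludedArrays(small), 0L)
  expect_match(small@note, "fewer than 3")
})

test_that("RLE summaries behave as location diagnostics", {
  m <- matrix(rep(rnorm(80), 5), 80, 5,
              dimnames = list(NULL, paste0("a", 1:5)))
  r <- rleReport(m)
  expect_true(all(abs(qcTable(r)$rle_median) < 1e-12))

  shifted <- m
  shifted[, 3] <- shifted[, 3] + 1
  r2 <- qcTable(rleReport(shifted))
  expect_equal(r2$rle_median[3], 1, tolerance = 0.05)

  set.seed(15)
  sym <- matrix(rnorm(100 * 6), 100, 6)
  expect_lt(abs(sum(qcTable(rleReport(sym))$rle_median)), 0.5)
})

test_that("the default miRNA pipeline yields the 260 x 70 filtered matrix", {
  se <- simulateMirnaExperiment(mirnaSimConfig(seed = 31L))
  pp <- preprocessMirna(se)
  expect_equal(dim(SummarizedExperiment::assay(pp, "exprs")), c(260L, 70L))
  expect_identical(S4Vectors::metadata(pp)$excluded,
                   sampleSheet(se)$sample_id[sampleSheet(se)$planted_outlier])
  truth <- S4Vectors::metadata(pp)$truth
  expect_false(any(truth$true_class == "absent"))
})
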