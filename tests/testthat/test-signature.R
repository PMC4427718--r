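makeTwoClass <- function(nFeatures = 200, nSignal = 10, n1 = 8, n2 = 9,
                         effect = 2, sd = 0.25, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nFeatures * (n1 + n2), 8, sd), nFeatures, n1 + n2)
  m[seq_len(nSignal), seq_len(n1)] <-
    m[seq_len(nSignal), seq_len(n1)] + effect
  dimnames(m) <- list(sprintf("g%04d", seq_len(nFeatures)),
                      sprintf("s%02d", seq_len(n1 + n2)))
  list(m = m, labels = factor(rep(c("sham", "H"), c(n1, n2)),
                              levels = c("sham", "H")),
       signal = rownames(m)[seq_len(nSignal)])
}

test_that("the SAM d-statistic matches its definition", {
  dat <- makeTwoClass(nFeatures = 50, nSignal = 5, seed = 3)
  d <- samStatistic(dat$m, dat$labels)
  s0 <- attr(d, "s0")
  expect_equal(as.numeric(d), unname(oracleSamD(dat$m, dat$labels, s0)),
               tolerance = 1e-12)
  ## ranking identical to the oracle's
  expect_identical(order(-abs(d)),
                   order(-abs(oracleSamD(dat$m, dat$labels, s0))))

  ## equal class means give d = 0
  flat <- matrix(rep(c(1, 2, 3, 4), 5), 5, 4, byrow = TRUE)
  labs <- c("a", "a", "b", "b")
  ## symmetric groups: means equal
  flat2 <- cbind(flat[, c(1, 2)], flat[, c(1, 2)])
  expect_equal(as.numeric(samStatistic(flat2, labs, s0 = 1)), rep(0, 5))

  ## s0 = 0 reduces to the pooled two-sample t statistic
  d0 <- samStatistic(dat$m, dat$labels, s0 = 0)
  tt <- apply(dat$m, 1, function(x)
    t.test(x[dat$labels == "sham"], x[dat$labels == "H"],
           var.equal = TRUE)$statistic)
  expect_equal(as.numeric(d0), unname(tt), tolerance = 1e-9)

  expect_error(samStatistic(dat$m[, 1:3], dat$labels[1:3]), "class")
})

test_that("stratified splits have the stated sizes and partition the
           samples", {
  labels <- rep(c("x", "y"), each = 10)
  sp <- splitTrainTest(labels, 0.2, seed = 5)
  expect_equal(sum(labels[sp$train] == "x"), 2L)
  expect_equal(sum(labels[sp$train] == "y"), 2L)
  expect_length(sp$test, 16L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, splitTrainTest(labels, 0.2, seed = 5))
  expect_error(splitTrainTest(c("x", "y", "y", "y"), 0.9), "too small")
})

test_that("the SVM wrapper is deterministic and separates separable data", {
  dat <- makeTwoClass(nFeatures = 30, nSignal = 30, effect = 3, seed = 7)
  x <- t(dat$m)
  fit <- trainClassifier(x, dat$labels)
  expect_equal(evaluateClassifier(fit, x, dat$labels), 0)
  fit2 <- trainClassifier(x, dat$labels)
  expect_identical(as.character(predict(fit, x)),
                   as.character(predict(fit2, x)))
  expect_error(trainClassifier(x, rep("one", nrow(x))), "one class")
})

test_that("misclassification fractions span the unit interval", {
  stub <- structure(list(), class = "constantClassifier")
  assign("predict.constantClassifier",
         function(object, newdata, ...) rep("a", nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.constantClassifier", envir = globalenv()))
  x <- matrix(0, 4, 2)
  expect_equal(evaluateClassifier(stub, x, rep("a", 4)), 0)
  expect_equal(evaluateClassifier(stub, x, rep("b", 4)), 1)
  expect_equal(evaluateClassifier(stub, x, c("a", "a", "b", "b")), 0.5)
  expect_error(evaluateClassifier(stub, x[0, ], character()), "empty")
})

test_that("genSigPred recovers a planted separable signature with zero
           error", {
  dat <- makeTwoClass(nFeatures = 300, nSignal = 10, effect = 3, seed = 11)
  res <- genSigPred(dat$m, dat$labels, N = 10L, R = 20L, seed = 17L)
  expect_setequal(consensusGenes(res), dat$signal)
  expect_equal(perError(res), 0)
  expect_equal(perError(res), mean(iterationErrors(res)))

  ## same master seed, same everything
  res2 <- genSigPred(dat$m, dat$labels, N = 10L, R = 20L, seed = 17L)
  expect_identical(consensusGenes(res), consensusGenes(res2))
  expect_identical(iterationErrors(res), iterationErrors(res2))
})

test_that("with N equal to the pool size every gene is always selected", {
  dat <- makeTwoClass(nFeatures = 20, nSignal = 5, seed = 13)
  res <- genSigPred(dat$m, dat$labels, N = 20L, R = 5L, seed = 1L)
  expect_setequal(consensusGenes(res), rownames(dat$m))
  expect_true(all(selectionFrequency(res) == 1))
})

test_that("label permutation drives the error to chance", {
  dat <- makeTwoClass(nFeatures = 300, nSignal = 10, effect = 3, seed = 19)
  set.seed(23)
  perm <- sample(dat$labels)
  res <- genSigPred(dat$m, perm, N = 10L, R = 50L, seed = 29L)
  expect_lt(abs(perError(res) - 0.5), 0.15)
})

test_that("signature-size selection minimizes Per(N), smallest N on ties", {
  dat <- makeTwoClass(nFeatures = 100, nSignal = 10, effect = 3, seed = 31)
  one <- selectSignatureSize(dat$m, dat$labels, candidates = 25L,
                             R = 10L, seed = 3L)
  expect_equal(one$N, 25L)
  ## separable data: several N reach Per = 0; the smallest is chosen
  sel <- selectSignatureSize(dat$m, dat$labels,
                             candidates = c(10L, 25L, 50L),
                             R = 10L, seed = 3L)
  expect_equal(min(sel$perCurve), 0)
  expect_equal(sel$N, as.integer(names(which(sel$perCurve == 0))[1]))
})
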