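test_that("identical configurations yield bit-identical datasets", {
  cfg <- mrnaSimConfig(nFeatures = 150L, nInteractionL = 0L,
                       nInteractionM = 0L, nInteractionH = 10L, seed = 42L)
  a <- simulateMrnaExperiment(cfg)
  b <- simulateMrnaExperiment(cfg)
  expect_identical(SummarizedExperiment::assay(a, "exprs"),
                   SummarizedExperiment::assay(b, "exprs"))
  cfg2 <- mrnaSimConfig(nFeatures = 150L, nInteractionL = 0L,
                        nInteractionM = 0L, nInteractionH = 10L, seed = 43L)
  c <- simulateMrnaExperiment(cfg2)
  expect_false(identical(SummarizedExperiment::assay(a, "exprs"),
                         SummarizedExperiment::assay(c, "exprs")))

  mcfg <- mirnaSimConfig(nFeatures = 60L,
                         figure8Counts = c("tumor-only" = 4L), seed = 5L)
  expect_identical(
    SummarizedExperiment::assay(simulateMirnaExperiment(mcfg), "raw"),
    SummarizedExperiment::assay(simulateMirnaExperiment(mcfg), "raw"))
})

test_that("default designs reproduce the study sample counts", {
  sheet <- table1Sheet()
  expect_equal(sum(sheet$tissue == "P"), 14L)
  expect_equal(sum(sheet$tissue == "T"), 31L)
  expect_equal(nrow(sheet), 45L)
  expect_equal(unname(table(sheet$dose[sheet$tissue == "P"])[c(
    "sham", "L", "M", "H")]), c(2L, 2L, 5L, 5L), ignore_attr = TRUE)

  se <- simulateMirnaExperiment(mirnaSimConfig(seed = 2L))
  ms <- sampleSheet(se)
  expect_equal(nrow(ms), 71L)  # 70 design arrays + 1 planted outlier
  expect_equal(sum(ms$planted_outlier), 1L)
  real <- ms[!ms$planted_outlier, ]
  expect_equal(sum(real$tissue == "P"), 40L)
  expect_equal(sum(real$tissue == "T"), 30L)
  expect_equal(unname(table(real$dose[real$tissue == "T"])[c(
    "sham", "L", "M", "H")]), c(8L, 7L, 6L, 9L), ignore_attr = TRUE)
  ## parenchyma groups reach 10 arrays through technical replicates
  expect_true(all(tapply(real$is_replicate, paste(real$tissue, real$dose),
                         sum)[sprintf("P %s", c("H", "L", "M", "sham"))]
                  == 2L))
})

test_that("null configuration with vanishing noise gives flat cell means", {
  cfg <- mrnaSimConfig(nFeatures = 20L, nInteractionL = 0L,
                       nInteractionM = 0L, nInteractionH = 0L,
                       residualSd = 1e-9, seed = 3L)
  se <- simulateMrnaExperiment(cfg)
  m <- SummarizedExperiment::assay(se, "exprs")
  expect_lt(max(apply(m, 1L, function(x) diff(range(x)))), 1e-7)
})

test_that("planted coefficients are recovered by the downstream fit", {
  ## exact interpolation as noise vanishes
  cfg0 <- mrnaSimConfig(nFeatures = 60L, nInteractionH = 12L,
                        effectSize = 1.5, residualSd = 1e-9, seed = 8L)
  se0 <- simulateMrnaExperiment(cfg0)
  fit0 <- fitInteractionModel(se0)
  truth0 <- as.matrix(truthTable(se0)[, sprintf("beta%d", 0:7)])
  expect_equal(unname(coef(fit0)), unname(truth0), tolerance = 1e-6)

  ## beta7 = 4 at residual SD 0.1: every planted feature within 3 SE
  cfg <- mrnaSimConfig(nFeatures = 200L, nInteractionL = 0L,
                       nInteractionM = 0L, nInteractionH = 10L,
                       effectSize = 4, residualSd = 0.1, seed = 9L)
  se <- simulateMrnaExperiment(cfg)
  fit <- fitInteractionModel(se)
  planted <- truthTable(se)$true_class == "interaction-H"
  err <- abs(coef(fit)[planted, "CeT:doH"] -
               truthTable(se)$beta7[planted])
  expect_true(all(err <= 3 * fit@stderr[planted, "CeT:doH"]))
})

test_that("invalid configurations are rejected", {
  expect_error(mrnaSimConfig(nFeatures = 10L, nInteractionH = 50L),
               "exceed")
  gs <- smokeSig:::.mrnaGroupSizes()
  gs$n[gs$tissue == "P" & gs$dose == "sham"] <- 0L
  expect_error(simulateMrnaExperiment(mrnaSimConfig(nFeatures = 10L,
                                                    nInteractionH = 0L,
                                                    nInteractionM = 0L,
                                                    nInteractionL = 0L,
                                                    groupSizes = gs)),
               "empty design cell")
  expect_error(mirnaSimConfig(nFeatures = 50L,
                              figure8Counts = c("tumor-only" = 1L),
                              absentFraction = 1.5),
               "absentFraction")
  expect_error(mirnaSimConfig(figure8Counts = c("no-such-category" = 3L)))
})

test_that("planted absent features sit below every detection threshold", {
  se <- simulateMirnaExperiment(mirnaSimConfig(seed = 21L))
  truth <- truthTable(se)
  raw <- SummarizedExperiment::assay(se, "raw")
  fid <- SummarizedExperiment::rowData(se)$feature_id
  keepArrays <- !sampleSheet(se)$planted_outlier
  rawSum <- medianSummarize(raw, fid)[, keepArrays, drop = FALSE]
  calls <- detectionCalls(rawSum)
  kept <- filterPresent(calls, sampleSheet(se)$dose[keepArrays])
  expect_setequal(kept, truth$feature_id[truth$true_class != "absent"])
  expect_equal(length(kept), 260L)
})

test_that("an absent fraction of zero passes the presence filter intact", {
  ## flat baselines: per-array bottom-percentile membership rotates with
  ## noise, so every feature is present in at least half of some group
  se <- simulateMirnaExperiment(mirnaDirectConfig(seed = 4L,
                                                  nFeatures = 40L,
                                                  baselineRange = c(8, 8),
                                                  figure8Counts =
                                                    c("tumor-only" = 2L)))
  raw <- SummarizedExperiment::assay(se, "raw")
  rownames(raw) <- SummarizedExperiment::rowData(se)$feature_id
  kept <- filterPresent(detectionCalls(raw), sampleSheet(se)$dose)
  expect_equal(length(kept), 40L)
})

test_that("the planted outlier array is the one flagged by QC", {
  se <- simulateMirnaExperiment(mirnaSimConfig(seed = 13L))
  raw <- SummarizedExperiment::assay(se, "raw")
  fid <- SummarizedExperiment::rowData(se)$feature_id
  ex <- log2(medianSummarize(quantileNormalize(normexpCorrect(raw)), fid))
  qc <- detectOutlierArrays(ex)
  expect_identical(excludedArrays(qc),
                   sampleSheet(se)$sample_id[sampleSheet(se)$planted_outlier])
})
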