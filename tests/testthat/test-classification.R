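test_that("ROC/AUC reproduces hand-counted cases", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9),
                      c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  # 2 concordant of 4 pairs
  sc <- c(0.8, 0.1, 0.2, 0.9); y <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(concordantPairAuc(sc, y), 0.5)
  expect_equal(rocAuc(sc, y)$auc, 0.5)
  # all tied scores: AUC 1/2 by the tie convention
  expect_equal(rocAuc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(rocAuc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUC equals the concordant-pair statistic
          exactly", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(rocAuc(sc, y)$auc, concordantPairAuc(sc, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(18)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(sc, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC and ROC are invariant to monotone score transforms", {
  set.seed(9)
  sc <- rnorm(60); y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  r <- rocAuc(sc, y)
  expect_equal(rocAuc(exp(sc), y)$auc, r$auc)
  expect_equal(rocAuc(atan(sc), y)$points, r$points)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(10)
  r <- rocAuc(rnorm(50), sample(c(TRUE, FALSE), 50, replace = TRUE))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("out-of-fold scores separate separable data and are null on
          permuted labels", {
  set.seed(12)
  n <- 100
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n), ncol = 1) + 5 * y
  for (k in c("linear", "rbf")) {
    sc <- crossValidatedScores(x, y, kernel = k, seed = 2)
    expect_equal(rocAuc(sc, y)$auc, 1.0)
  }
  yp <- sample(y)    # permuted labels: chance-level AUC
  scp <- crossValidatedScores(matrix(rnorm(n * 4), n, 4), yp, "rbf",
                              seed = 3)
  expect_gte(rocAuc(scp, yp)$auc, 0.35)
  expect_lte(rocAuc(scp, yp)$auc, 0.65)
  expect_error(crossValidatedScores(x, c(rep(TRUE, 3), rep(FALSE, 97)),
                                    "rbf"), "fewer")
})

test_that("fold assignment depends only on seed and subject order", {
  set.seed(14)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c(TRUE, FALSE), n / 2)
  f1 <- attr(crossValidatedScores(x, y, "linear", seed = 5), "folds")
  f2 <- attr(crossValidatedScores(x[, 6:1], y, "linear", seed = 5),
             "folds")
  expect_identical(f1, f2)
})

test_that("bootstrap AUC intervals behave at the extremes", {
  y <- rep(c(FALSE, TRUE), each = 15)
  sc <- c(rnorm(15, 0), rnorm(15, 10))
  ci <- aucConfidenceInterval(sc, y, nBoot = 200, seed = 1)
  expect_equal(ci[2], 1.0)
  # nBoot = 1: degenerate interval at the single resample's AUC
  ci1 <- aucConfidenceInterval(sc, y, nBoot = 1, seed = 2)
  expect_equal(ci1[1], ci1[2])
  # null scores: the interval covers 1/2 in nearly all repeats
  set.seed(4)
  cover <- 0
  for (i in 1:15) {
    scn <- rnorm(60); yn <- rep(c(TRUE, FALSE), 30)
    cin <- aucConfidenceInterval(scn, yn, nBoot = 200, seed = i)
    cover <- cover + (cin[1] <= 0.5 && 0.5 <= cin[2])
  }
  expect_gte(cover, 12)
})

test_that("Youden-threshold metrics follow the confusion-matrix
          formulas", {
  # chosen operating point: TP=2 FP=1 FN=0 TN=2
  sc <- c(0.9, 0.8, 0.85, 0.2, 0.1)
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  tm <- thresholdMetrics(sc, y)
  expect_equal(tm$sensitivity, 1.0)
  expect_equal(tm$specificity, 2 / 3)
  expect_equal(tm$f1, 0.8)
  expect_equal(tm$accuracy, 4 / 5)

  # perfect classifier: everything 1
  tmp <- thresholdMetrics(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unlist(tmp[c("accuracy", "sensitivity", "specificity",
                            "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 f1 = 1))

  # random scores: accuracy near chance, slightly inflated by the
  # Youden choice
  set.seed(15)
  tr <- thresholdMetrics(rnorm(1000), rep(c(TRUE, FALSE), 500))
  expect_gte(tr$accuracy, 0.45)
  expect_lte(tr$accuracy, 0.60)
})

test_that("kernel comparison is paired and ranks geometry correctly", {
  set.seed(16)
  n <- 120
  # concentric rings: radius encodes the class
  r <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  th <- runif(n, 0, 2 * pi)
  x <- cbind(r * cos(th), r * sin(th))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  cmp <- compareKernels(x, y, kernels = c("linear", "rbf"), seed = 6,
                        nBoot = 50)
  expect_gt(cmp$rbf$auc, cmp$linear$auc + 0.2)

  cmp2 <- compareKernels(x, y, kernels = c("linear", "rbf"), seed = 6,
                         nBoot = 50)
  expect_identical(cmp$rbf$auc, cmp2$rbf$auc)
  expect_identical(cmp$linear$rocPoints, cmp2$linear$rocPoints)
})

test_that("severity contrasts order as expected at reference cohort
          scale", {
  # ground-truth parameters + age for 88 subjects: the age gap makes
  # normal-vs-advanced the easiest contrast, mild-vs-advanced harder
  co <- generateCohort(cohortSpec(regionShape = c(8, 8, 4), seed = 3))
  tr <- co$truth
  pw <- reshape(tr[, c("subject_id", "region", "bvtv", "tb_th_mm",
                       "tb_sp_mm", "tb_n_per_mm")],
                idvar = "subject_id", timevar = "region",
                direction = "wide")
  grp <- tr$group[match(pw$subject_id, tr$subject_id)]
  age <- tr$age[match(pw$subject_id, tr$subject_id)]
  x <- cbind(as.matrix(pw[, -1]), age = age)
  aucOf <- function(task) {
    td <- taskDefinitions()[[task]]
    keep <- grp %in% td$groups
    y <- grp[keep] %in% td$positive
    rocAuc(crossValidatedScores(x[keep, ], y, "rbf", seed = 5), y)$auc
  }
  aNA <- aucOf("normal_vs_advanced")
  aMA <- aucOf("mild_vs_advanced")
  expect_gt(aNA, 0.8)        # materially above chance
  expect_gt(aNA, aMA)        # and the hardest contrast stays hardest
})

test_that("model comparison ranks informative over noise features", {
  set.seed(17)
  n <- 60
  y <- rep(c(FALSE, TRUE), each = n / 2)
  good <- matrix(rnorm(n * 2), n, 2) + 3 * y
  noise <- matrix(rnorm(n * 4), n, 4)
  rg <- classifierReport(good, y, "demo", "rbf", seed = 4, nBoot = 50)
  rn <- classifierReport(noise, y, "demo", "rbf", seed = 4, nBoot = 50)
  panel <- compareModels(rg, rn)
  expect_gt(panel$radiomics[panel$metric == "auc"],
            panel$trabecular[panel$metric == "auc"])
  same <- compareModels(rg, rg)
  expect_equal(same$radiomics, same$trabecular)
  expect_error(compareModels(rg, classifierReport(noise[1:40, ],
                                                  y[1:40], "x", "rbf",
                                                  seed = 1,
                                                  nBoot = 10)),
               "different subject sets")
})
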