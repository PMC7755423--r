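test_that("amino-acid frequency differences hit the analytic extremes", {
  rec <- makeRecords(20, cdr1h = c(rep("LLLL", 10), rep("FFFF", 10)),
                     reactivity = rep(c(5L, 0L), each = 10))
  rec <- assignPolyreactivityLabels(rec, "parsed")
  em <- encodeRepertoire(rec)
  fd <- aaFrequencyDifference(em)
  row <- "cdr1h:0"
  expect_equal(unname(fd$delta[row, "L"]), 1)
  expect_equal(unname(fd$delta[row, "F"]), -1)
  # per-column sums vanish (frequencies sum to 1 in both classes)
  expect_lt(max(abs(rowSums(fd$delta))), 1e-12)
  expect_true(all(fd$delta >= -1 & fd$delta <= 1))
  # threshold rule: a 0.08 difference is absent from the filtered view
  rec2 <- makeRecords(50, reactivity = rep(c(5L, 0L), each = 25))
  rec2$cdr1h <- c(rep("LFTF", 12), rep("GFTF", 13),
                  rep("LFTF", 10), rep("GFTF", 15))
  rec2 <- assignPolyreactivityLabels(rec2, "parsed")
  fd2 <- aaFrequencyDifference(encodeRepertoire(rec2))
  expect_equal(unname(fd2$delta["cdr1h:0", "L"]), 0.08)
  expect_true(is.na(fd2$filtered["cdr1h:0", "L"]))
  # identical classes -> all zeros
  rec3 <- rec
  rec3[rec3$label == "non_polyreactive", LOOPS] <-
    rec3[rec3$label == "polyreactive", LOOPS]
  expect_true(all(aaFrequencyDifference(encodeRepertoire(rec3))$delta == 0))
})

test_that("PCA projection is orthonormal, sign-fixed and rank-faithful", {
  set.seed(30)
  # collinear cloud: PC1 explains nearly everything
  t <- rnorm(100)
  cloud <- cbind(t, 2 * t + rnorm(100, sd = 1e-4), -t + rnorm(100, sd = 1e-4))
  pc <- pcaProject(cloud, nComponents = 2, standardize = FALSE)
  expect_gt(pc$explainedVariance[1], 0.999)
  # orthonormal rotation
  g <- crossprod(pc$rotation)
  expect_lt(max(abs(g - diag(2))), 1e-9)
  # sign fix: largest-magnitude loading positive
  for (j in 1:2)
    expect_gt(pc$rotation[which.max(abs(pc$rotation[, j])), j], 0)
  # rank-k data: projections preserve pairwise distances at k components
  U <- matrix(rnorm(40), 20, 2)
  V <- matrix(rnorm(10), 5, 2)
  X <- U %*% t(V)
  pk <- pcaProject(X, nComponents = 2, standardize = FALSE)
  dOrig <- dist(scale(X, scale = FALSE))
  dProj <- dist(pk$projections)
  expect_lt(max(abs(dOrig - dProj)), 1e-9)
  expect_error(pcaProject(matrix(1, 5, 3), 2), "constant")
})

test_that("feature selection ranks signal first and filters duplicates", {
  set.seed(31)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  signal <- ifelse(y == "a", 1, -1) + rnorm(n, sd = 0.1)
  noise <- matrix(rnorm(n * 8), n)
  feat <- cbind(sig = signal, noise)
  colnames(feat) <- c("sig", paste0("n", 1:8))
  sel <- selectFeatures(feat, y, k = 3)
  expect_identical(sel$selected[1], "sig")
  # duplicated feature columns (r = 1): one survives
  feat2 <- cbind(feat, sig2 = signal)
  sel2 <- selectFeatures(feat2, y, k = ncol(feat2) - 1,
                         correlationThreshold = 0.99)
  expect_identical(sum(c("sig", "sig2") %in% sel2$selected), 1L)
  # identity bounds: k = count, threshold 1 -> everything kept
  sel3 <- selectFeatures(feat, y, k = ncol(feat),
                         correlationThreshold = 1)
  expect_setequal(sel3$selected, colnames(feat))
  expect_error(selectFeatures(feat, y, k = 0), "positive")
  expect_error(selectFeatures(feat, y, k = 100), "exceeds")
  # pca mode returns k components
  sel4 <- selectFeatures(feat, y, method = "pca", k = 2)
  expect_identical(ncol(sel4$features), 2L)
})

test_that("the linear discriminant separates blobs and matches MASS::lda", {
  set.seed(32)
  n <- 50
  a <- cbind(rnorm(n) + 4, rnorm(n) - 4)
  b <- cbind(rnorm(n) - 4, rnorm(n) + 4)
  x <- rbind(a, b); colnames(x) <- c("f1", "f2")
  y <- rep(c("pos", "neg"), each = n)
  fit <- ldaFitProject(x, y)
  expect_identical(fit$accuracy, 1)
  # orientation: class A (first label) projects high
  expect_gt(mean(fit$scores[y == "pos"]), fit$threshold)
  # independent cross-check: projection direction agrees with MASS
  ml <- MASS::lda(x, grouping = factor(y))
  proj <- drop(x %*% ml$scaling)
  expect_gt(abs(cor(proj, fit$scores)), 0.999)
  # random labels on one blob: accuracy near chance
  set.seed(33)
  blob <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  yr <- sample(rep(c("pos", "neg"), each = 100))
  fr <- ldaFitProject(blob, yr)
  expect_gte(fr$accuracy, 0.5)  # orientation guarantees >= 0.5
  expect_lt(fr$accuracy, 0.65)  # within the null band
  # contract of the weight table
  tw <- topWeights(fit, k = 10)
  expect_identical(nrow(tw), 2L)
  expect_gte(abs(tw$weight[1]), abs(tw$weight[2]))
  expect_error(ldaFitProject(matrix(rnorm(12), 3), c("a", "a", "b")),
               "at least 2")
})

test_that("ridge regularization engages on singular scatter", {
  x <- cbind(f1 = c(1, 1, 2, 2), f2 = c(2, 2, 4, 4))  # collinear
  y <- c("a", "a", "b", "b")
  expect_message(fit <- ldaFitProject(x, y), "ridge")
  expect_true(all(is.finite(fit$weights)))
})

test_that("LOOCV reports are deterministic and leakage-free", {
  gen <- strongSignalFixture(nPerClass = 15, delta = 1, seed = 7)
  em <- encodeRepertoire(gen$records)
  feat <- buildFeatureMatrix(em, "charge", standardize = FALSE)
  lab <- rowLabels(em)
  r1 <- svmLoocv(feat, lab, k = 10, seed = 1)
  r2 <- svmLoocv(feat, lab, k = 10, seed = 1)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$n, 30L)
  expect_gte(r1$accuracy, 0.8)  # overwhelming per-record signal
  # no leakage: inflating one held-out row leaves its fold's selection
  feat2 <- feat
  feat2[5, ] <- feat2[5, ] + 1e6
  r3 <- svmLoocv(feat2, lab, k = 10, seed = 1)
  expect_identical(r1$selectedPerFold[[5]], r3$selectedPerFold[[5]])
  few <- c(1:3, 16:18)  # both classes present but under the size floor
  expect_error(svmLoocv(feat[few, ], lab[few], k = 3), "at least 10")
})

test_that("scrambled labels drive accuracy to chance", {
  gen <- strongSignalFixture(nPerClass = 15, delta = 1, seed = 8)
  em <- encodeRepertoire(gen$records)
  feat <- buildFeatureMatrix(em, "charge", standardize = FALSE)
  sc <- scrambledControl(feat, rowLabels(em), repeats = 3, seed = 9,
                         k = 10)
  expect_identical(length(sc$accuracies), 3L)
  expect_gt(sc$mean, 0.2)
  expect_lt(sc$mean, 0.8)
  expect_error(scrambledControl(feat, rowLabels(em), repeats = 0),
               "at least 1")
})
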