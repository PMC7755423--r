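test_that("column entropy reproduces analytic values", {
  expect_identical(columnEntropy(rep("A", 30)), 0)
  expect_equal(columnEntropy(rep(c("A", "G"), 15)), 1)
  expect_equal(columnEntropy(rep(1:20, 3)), log2(20), tolerance = 1e-12)
  expect_error(columnEntropy(character()), "non-empty")
})

test_that("conditional entropy matches brute-force enumeration", {
  x <- c("a", "a", "a", "b"); y <- c("a", "a", "b", "b")
  # joint counts {(a,a):2, (a,b):1, (b,b):1} -> H(X|Y) = 0.5 bits
  expect_equal(conditionalEntropy(x, y), bruteCondEntropy(x, y))
  expect_equal(conditionalEntropy(x, y), 0.5)
  # X = Y -> 0; Y constant -> H(X)
  z <- rep(1:4, 5)
  expect_equal(conditionalEntropy(z, z), 0)
  expect_equal(conditionalEntropy(z, rep(1, 20)), columnEntropy(z))
  expect_error(conditionalEntropy(1:3, 1:4), "equal length")
  set.seed(77)
  for (i in 1:20) {
    a <- sample(1:5, 40, replace = TRUE)
    b <- sample(letters[1:4], 40, replace = TRUE)
    expect_equal(conditionalEntropy(a, b), bruteCondEntropy(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mutual information equals the joint-histogram KL form", {
  # conserved column -> 0 with any partner
  set.seed(13)
  other <- sample(1:6, 40, replace = TRUE)
  expect_identical(mutualInformation(rep(3, 40), other), 0)
  expect_identical(mutualInformation(other, rep(3, 40)), 0)
  # I(X;X) = H(X)
  expect_equal(mutualInformation(other, other), columnEntropy(other))
  # uniform k-symbol self-MI = log2 k
  u <- rep(1:8, 5)
  expect_equal(mutualInformation(u, u), 3)
  # oracle equivalence over random instances, n <= 50, alphabet <= 6
  for (i in 1:30) {
    n <- sample(5:50, 1)
    k <- sample(2:6, 1)
    a <- sample(seq_len(k), n, replace = TRUE)
    b <- sample(letters[seq_len(k)], n, replace = TRUE)
    expect_equal(mutualInformation(a, b), bruteMI(a, b),
                 tolerance = 1e-12)
    # symmetry and bounds
    expect_equal(mutualInformation(a, b), mutualInformation(b, a),
                 tolerance = 1e-12)
    expect_lte(mutualInformation(a, b),
               min(columnEntropy(a), columnEntropy(b)) + 1e-12)
    expect_gte(mutualInformation(a, b), 0)
  }
})

test_that("bijective relabeling leaves H and I unchanged", {
  set.seed(21)
  a <- sample(1:5, 60, replace = TRUE)
  b <- sample(1:5, 60, replace = TRUE)
  perm <- sample(1:5)
  expect_equal(columnEntropy(perm[a]), columnEntropy(a))
  expect_equal(mutualInformation(perm[a], b), mutualInformation(a, b),
               tolerance = 1e-12)
})

test_that("MI matrices are symmetric with entropy on the diagonal", {
  gen <- generateRepertoire(fixtureSpec(nPoly = 30, nNon = 30), seed = 2)
  em <- encodeRepertoire(gen$records)
  res <- miMatrix(em)
  expect_lt(max(abs(res$mi - t(res$mi))), 1e-12)
  expect_equal(unname(diag(res$mi)), unname(res$entropy))
  expect_true(all(res$mi >= 0))
  v <- encodedValues(em)
  j <- which(colnames(res$mi) == "cdr2h:3")
  expect_equal(res$entropy[[j]], columnEntropy(v[, j]))
  # identical rows -> all-zero MI and entropy
  rec <- makeRecords(6, reactivity = rep(c(5L, 0L), 3))
  rec <- assignPolyreactivityLabels(rec, "parsed")
  emc <- encodeRepertoire(rec)
  resc <- miMatrix(emc)
  expect_true(all(resc$mi == 0))
  # per-class restriction and errors
  expect_identical(miMatrix(em, class = "polyreactive")$n, 30L)
  expect_error(miMatrix(em, class = "missing_label"), "no rows")
})

test_that("gap exclusion restricts estimation to residue-bearing rows", {
  rec <- makeRecords(40, cdr3h = rep(c("ARDY", "ARDYGS"), 20),
                     reactivity = rep(c(5L, 0L), each = 20))
  rec <- assignPolyreactivityLabels(rec, "parsed")
  em <- encodeRepertoire(rec)
  inc <- miMatrix(em, gapMode = "include")
  exc <- miMatrix(em, gapMode = "exclude")
  # edge columns carry length information only under inclusion
  edge <- which(colnames(inc$mi) == "cdr3h:0")
  expect_gt(inc$entropy[[edge]], 0)
  expect_identical(exc$entropy[[edge]], 0)
})

test_that("class MI differences are antisymmetric and calibrated at null", {
  ll <- list(cdr1l = 6L, cdr2l = 4L, cdr3l = 4L, cdr1h = 6L,
             cdr2h = 4L, cdr3h = 6L)
  spec <- fixtureSpec(nPoly = 60, nNon = 60, loopLengths = ll,
                      background = c(A = 1, G = 1, S = 1, Y = 1))
  gen <- generateRepertoire(spec, seed = 14)
  em <- encodeRepertoire(gen$records, layout = fixtureLayout(spec))
  cols <- 0:5  # first loop only, keeps the permutation loop quick
  fwd <- miDifferenceWithSignificance(
    em, classes = c("polyreactive", "non_polyreactive"), R = 99,
    seed = 15, columns = cols)
  rev <- miDifferenceWithSignificance(
    em, classes = c("non_polyreactive", "polyreactive"), R = 99,
    seed = 15, columns = cols)
  expect_equal(fwd$deltaMI, -rev$deltaMI)
  expect_true(all(fwd$p >= 1 / 100 & fwd$p <= 1))
  # null data: few pairs significant at 0.05
  off <- fwd$p[upper.tri(fwd$p)]
  expect_lte(mean(off <= 0.05), 0.25)
})

test_that("an implanted coupling appears as a class MI difference", {
  ll <- list(cdr1l = 6L, cdr2l = 4L, cdr3l = 4L, cdr1h = 8L,
             cdr2h = 4L, cdr3h = 6L)
  bg <- c(A = 1, G = 1, S = 1, Y = 1)
  lay <- fixtureLayout(fixtureSpec(loopLengths = ll, background = bg))
  sp <- segmentSpans(lay)
  i <- sp["cdr1h", 1] + 1L; j <- sp["cdr1h", 1] + 5L
  spec <- fixtureSpec(nPoly = 150, nNon = 150, loopLengths = ll,
                      background = bg,
                      couplings = list(list(i = i, j = j, strength = 1,
                                            class = "polyreactive")))
  gen <- generateRepertoire(spec, seed = 16)
  em <- encodeRepertoire(gen$records, layout = fixtureLayout(spec))
  cols <- sp["cdr1h", 1]:(sp["cdr1h", 2] - 1)
  dm <- miDifferenceWithSignificance(
    em, classes = c("polyreactive", "non_polyreactive"), R = 99,
    seed = 17, columns = cols)
  ki <- "cdr1h:1"; kj <- "cdr1h:5"
  expect_gt(dm$deltaMI[ki, kj], 1)
  expect_identical(dm$p[ki, kj], 1 / 100)
})
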