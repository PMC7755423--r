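.twoClassIndicator <- function(labels, classes = NULL) {
  lab <- as.character(labels)
  if (is.null(classes)) classes <- unique(lab)[1:2]
  if (length(classes) != 2L || any(is.na(classes)))
    stop("two classes are required")
  keep <- lab %in% classes
  list(keep = keep, y = lab[keep] == classes[1], classes = classes)
}

#' Per-position amino-acid frequency difference map
#'
#' For every matrix column and residue code 1..21 computes the
#' within-class residue frequency (among non-gap rows of that class) and
#' the difference class A minus class B. A filtered view drops entries
#' with \code{|difference| <= displayThreshold} (default 0.10, the
#' 10-percent display rule).
#'
#' @param em an [EncodedMatrix-class].
#' @param classes two labels (default first two present).
#' @param displayThreshold display cutoff for the filtered map.
#' @return list with \code{delta} (L x 21 matrix, rows named
#'   \code{"segment:offset"}, columns by residue letter), \code{filtered}
#'   (same with sub-threshold entries set NA), and the per-class
#'   frequency arrays.
#' @export
aaFrequencyDifference <- function(em, classes = NULL,
                                  displayThreshold = 0.10) {
  tc <- .twoClassIndicator(em@rowLabels, classes)
  m <- em@values[tc$keep, , drop = FALSE]
  y <- tc$y
  if (sum(y) == 0L || sum(!y) == 0L) stop("both classes must be non-empty")
  freqOf <- function(sub) {
    apply(sub, 2L, function(col) {
      col <- col[col != 0L]
      if (length(col) == 0L) return(numeric(21L))
      tabulate(col, 21L) / length(col)
    })
  }
  fA <- t(freqOf(m[y, , drop = FALSE]))
  fB <- t(freqOf(m[!y, , drop = FALSE]))
  segs <- columnSegments(em@layout)
  offs <- stats::ave(seq_along(segs), segs, FUN = seq_along) - 1L
  rn <- sprintf("%s:%d", segs, offs)
  colnames(fA) <- colnames(fB) <- c(.AA_ORDER, "X")
  rownames(fA) <- rownames(fB) <- rn
  delta <- fA - fB
  filtered <- delta
  filtered[abs(filtered) <= displayThreshold] <- NA_real_
  list(delta = delta, filtered = filtered, freq_A = fA, freq_B = fB,
       classes = tc$classes, displayThreshold = displayThreshold)
}

#' Principal component projection of a feature matrix
#'
#' Standard PCA on z-scored features. Component signs are fixed
#' deterministically by making each component's largest-magnitude
#' loading positive.
#'
#' @param features numeric matrix (rows = sequences).
#' @param nComponents number of components to keep.
#' @param standardize z-score columns first (default TRUE).
#' @return list with \code{projections}, \code{rotation},
#'   \code{explainedVariance} (fractions).
#' @export
pcaProject <- function(features, nComponents = 2L, standardize = TRUE) {
  if (nrow(features) <= nComponents)
    stop("need more rows than components")
  x <- if (standardize) standardizeColumns(features)$x else features
  keep <- apply(x, 2L, function(v) stats::sd(v) > 0)
  if (!any(keep)) stop("all features are constant")
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = !standardize,
                      scale. = FALSE)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k),
                 function(j) sign(rot[which.max(abs(rot[, j])), j]),
                 numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  proj <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  list(projections = proj, rotation = rot,
       explainedVariance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       keptFeatures = colnames(features)[keep])
}

#' Select discriminative features
#'
#' \code{method = "top_diff"}: features (z-scored) are ranked by the
#' absolute difference of class means; before truncation the
#' lower-ranked member of every pair with \code{|Pearson r| >
#' correlationThreshold} is greedily dropped; the top \code{k} survivors
#' are kept. \code{method = "pca"}: the first \code{k} principal
#' components replace the features.
#'
#' @param features numeric matrix (rows = sequences), ideally already
#'   z-scored.
#' @param labels class labels per row.
#' @param method \code{"top_diff"} or \code{"pca"}.
#' @param k number of features/components to keep (default 75).
#' @param correlationThreshold Pearson cutoff for the greedy filter
#'   (default 0.75).
#' @param classes two labels (default first two present).
#' @return list with \code{features} (reduced matrix), \code{selected}
#'   (names), \code{method}, \code{provenance} (ranking/PCA details).
#' @export
selectFeatures <- function(features, labels,
                           method = c("top_diff", "pca"), k = 75L,
                           correlationThreshold = 0.75, classes = NULL) {
  method <- match.arg(method)
  if (k <= 0L) stop("k must be positive")
  if (k > ncol(features)) stop("k exceeds feature count")
  if (method == "pca") {
    pc <- pcaProject(features, nComponents = k)
    return(list(features = pc$projections,
                selected = colnames(pc$projections), method = method,
                provenance = list(explainedVariance = pc$explainedVariance,
                                  rotation = pc$rotation)))
  }
  tc <- .twoClassIndicator(labels, classes)
  x <- standardizeColumns(features)$x
  xs <- x[tc$keep, , drop = FALSE]
  y <- tc$y
  diffs <- abs(colMeans(xs[y, , drop = FALSE]) -
               colMeans(xs[!y, , drop = FALSE]))
  diffs[!is.finite(diffs)] <- 0
  ord <- order(diffs, decreasing = TRUE)
  keep <- logical(ncol(xs))
  if (correlationThreshold < 1) {
    cm <- suppressWarnings(abs(stats::cor(xs)))
    cm[!is.finite(cm)] <- 0
    for (j in ord) {
      if (!any(keep & cm[j, ] > correlationThreshold)) keep[j] <- TRUE
    }
  } else keep[ord] <- TRUE
  survivors <- ord[ord %in% which(keep)]
  sel <- survivors[seq_len(min(k, length(survivors)))]
  list(features = features[, sel, drop = FALSE],
       selected = colnames(features)[sel], method = method,
       provenance = list(rankedDiff = diffs[sel],
                         correlationThreshold = correlationThreshold,
                         k = k))
}

#' Two-class linear discriminant: fit, project, separate
#'
#' Fisher's linear discriminant on all supplied data ("mode 1"):
#' \code{w = Sw^{-1} (mu_A - mu_B)} with the pooled within-class scatter
#' \code{Sw}; a ridge term (epsilon = 1e-6 on the diagonal) is added if
#' the scatter is singular, with a message. Scores are oriented so class
#' A projects high. Separation accuracy is the fraction of sequences on
#' the correct side of the midpoint between the projected class means.
#'
#' @param features numeric matrix, with fewer columns than rows
#'   (overfit guard; reduce with [selectFeatures()] first).
#' @param labels class labels per row.
#' @param classes two labels (default first two present).
#' @param ridge ridge constant used when the scatter matrix is singular.
#' @return list with \code{weights} (named), \code{scores},
#'   \code{threshold}, \code{accuracy}, \code{classes},
#'   \code{predicted}.
#' @export
ldaFitProject <- function(features, labels, classes = NULL,
                          ridge = 1e-6) {
  tc <- .twoClassIndicator(labels, classes)
  x <- features[tc$keep, , drop = FALSE]
  y <- tc$y
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("each class needs at least 2 sequences")
  if (ncol(x) >= nrow(x))
    stop("feature count must be below sequence count; ",
         "reduce with selectFeatures()")
  muA <- colMeans(x[y, , drop = FALSE])
  muB <- colMeans(x[!y, , drop = FALSE])
  cA <- sweep(x[y, , drop = FALSE], 2L, muA)
  cB <- sweep(x[!y, , drop = FALSE], 2L, muB)
  Sw <- crossprod(cA) + crossprod(cB)
  w <- tryCatch(solve(Sw, muA - muB), error = function(e) {
    message("singular within-class scatter; ridge epsilon = ", ridge)
    solve(Sw + diag(ridge, ncol(Sw)), muA - muB)
  })
  names(w) <- colnames(x)
  scores <- drop(x %*% w)
  mA <- mean(scores[y]); mB <- mean(scores[!y])
  if (mA < mB) { w <- -w; scores <- -scores; tmp <- mA; mA <- mB; mB <- tmp }
  thr <- (mA + mB) / 2
  predicted <- ifelse(scores > thr, tc$classes[1], tc$classes[2])
  truth <- ifelse(y, tc$classes[1], tc$classes[2])
  accuracy <- mean(predicted == truth)
  if (accuracy < 0.5) {
    # orientation is chosen toward class A; flip if the midpoint rule
    # still sides the majority wrong, so training accuracy >= 0.5 holds
    w <- -w; scores <- -scores; thr <- -thr
    predicted <- ifelse(scores > thr, tc$classes[1], tc$classes[2])
    accuracy <- mean(predicted == truth)
  }
  list(weights = w, scores = scores, threshold = thr,
       accuracy = accuracy, classes = tc$classes, predicted = predicted)
}

#' Largest-magnitude discriminant weights
#'
#' @param fit result of [ldaFitProject()].
#' @param k number of weights to report (default 10).
#' @return data.frame of the top-k features sorted by |weight|.
#' @export
topWeights <- function(fit, k = 10L) {
  w <- fit$weights
  ord <- order(abs(w), decreasing = TRUE)[seq_len(min(k, length(w)))]
  data.frame(feature = names(w)[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Linear-kernel SVM with leave-one-out cross-validation
#'
#' For each fold the held-out sequence is removed, the column
#' standardization and the feature selection are refit on the remaining
#' N-1 rows only (no leakage), a linear-kernel SVM (unit cost,
#' class-balanced weights) is trained, and the held-out sequence is
#' predicted. Accuracy is the fraction of correct fold predictions.
#'
#' @param features raw (unstandardized) numeric feature matrix.
#' @param labels class labels per row.
#' @param classes two labels (default first two present).
#' @param k features kept per fold (default 75, capped at the
#'   available/overfit-safe count).
#' @param correlationThreshold greedy correlation cutoff (default 0.75).
#' @param standardize z-score per fold (default TRUE).
#' @param cost SVM regularization constant (default 1).
#' @param seed optional RNG seed (recorded; LOOCV itself is
#'   deterministic given the data).
#' @return a classifier report: list with \code{accuracy},
#'   \code{predictions} (per fold), \code{selectedPerFold},
#'   \code{settings}, \code{seed}.
#' @export
svmLoocv <- function(features, labels, classes = NULL, k = 75L,
                     correlationThreshold = 0.75, standardize = TRUE,
                     cost = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- .twoClassIndicator(labels, classes)
  x <- features[tc$keep, , drop = FALSE]
  y <- factor(ifelse(tc$y, tc$classes[1], tc$classes[2]),
              levels = tc$classes)
  n <- nrow(x)
  if (n < 10L) stop("at least 10 sequences are required")
  preds <- rep(NA_character_, n)
  selected <- vector("list", n)
  wts <- c(1, 1); names(wts) <- tc$classes
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    if (nlevels(droplevels(yt)) < 2L) {
      warning("fold ", i, " skipped: a class is absent from training")
      next
    }
    std <- standardizeColumns(xt)
    xtz <- if (standardize) std$x else xt
    kf <- min(k, ncol(xtz), nrow(xtz) - 2L)
    sel <- selectFeatures(xtz, yt, method = "top_diff", k = kf,
                          correlationThreshold = correlationThreshold,
                          classes = tc$classes)
    selected[[i]] <- sel$selected
    xheld <- x[i, , drop = FALSE]
    if (standardize)
      xheld <- standardizeColumns(xheld, center = std$center,
                                  scale = std$scale)$x
    cw <- table(yt); cw <- as.numeric(sum(cw) / (2 * cw))
    names(cw) <- levels(yt)
    fit <- e1071::svm(sel$features, yt, kernel = "linear", cost = cost,
                      class.weights = cw, scale = FALSE)
    preds[i] <- as.character(stats::predict(
      fit, xheld[, sel$selected, drop = FALSE]))
  }
  ok <- !is.na(preds)
  list(accuracy = mean(preds[ok] == as.character(y)[ok]),
       predictions = data.frame(id = rownames(x) %||% as.character(seq_len(n)),
                                truth = as.character(y),
                                predicted = preds,
                                stringsAsFactors = FALSE),
       selectedPerFold = selected,
       settings = list(method = "top_diff", k = k,
                       correlationThreshold = correlationThreshold,
                       standardize = standardize, cost = cost),
       classes = tc$classes, seed = seed, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scrambled-label control distribution of LOOCV accuracies
#'
#' Repeats [svmLoocv()] with class labels randomly permuted; for balanced
#' classes the expected accuracy is 0.5, the null against which real
#' classifier accuracy is judged.
#'
#' @param features raw feature matrix.
#' @param labels true labels (permuted per repeat).
#' @param repeats number of scrambles (must be >= 1).
#' @param seed RNG seed for the permutations.
#' @param ... passed to [svmLoocv()].
#' @return list with \code{accuracies}, \code{mean}, \code{sd}.
#' @export
scrambledControl <- function(features, labels, repeats = 20L,
                             seed = NULL, ...) {
  if (repeats < 1L) stop("repeats must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(seq_len(repeats), function(r) {
    svmLoocv(features, sample(labels), ...)$accuracy
  }, numeric(1))
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc))
}

#' Nearest-centroid classification in PCA space
#'
#' Projects held-out sequences onto the principal components of the
#' training features and assigns each to the training class with the
#' nearest centroid in that space. Used for the platform-domain test
#' classes.
#'
#' @param trainFeatures,trainLabels training data.
#' @param testFeatures held-out rows (same columns).
#' @param nComponents PCA dimensionality (default 2).
#' @return list with \code{assigned} (character), \code{trainProjections},
#'   \code{testProjections}, \code{explainedVariance}.
#' @export
pcaClassify <- function(trainFeatures, trainLabels, testFeatures,
                        nComponents = 2L) {
  std <- standardizeColumns(trainFeatures)
  pc <- pcaProject(std$x, nComponents = nComponents, standardize = FALSE)
  rot <- pc$rotation
  testz <- standardizeColumns(testFeatures, center = std$center,
                              scale = std$scale)$x
  testProj <- testz[, rownames(rot), drop = FALSE] %*% rot
  trainProj <- pc$projections
  cent <- vapply(unique(as.character(trainLabels)), function(cl)
    colMeans(trainProj[trainLabels == cl, , drop = FALSE]),
    numeric(ncol(trainProj)))
  d2 <- vapply(seq_len(ncol(cent)), function(j)
    rowSums(sweep(testProj, 2L, cent[, j])^2),
    numeric(nrow(testProj)))
  if (nrow(testProj) == 1L) d2 <- matrix(d2, nrow = 1L)
  assigned <- colnames(cent)[apply(d2, 1L, which.min)]
  list(assigned = assigned, trainProjections = trainProj,
       testProjections = testProj,
       explainedVariance = pc$explainedVariance)
}
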