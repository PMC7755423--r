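.colVars <- function(m) {
  n <- nrow(m)
  (colSums(m * m) - n * colMeans(m)^2) / (n - 1)
}

.studentize <- function(num, den) {
  z <- num / den
  z[den == 0 & num == 0] <- 0
  z[den == 0 & num != 0] <- Inf
  z
}

#' Per-column class means with bootstrap standard errors
#'
#' For every matrix column, computes the within-class means of a masked
#' matrix and their bootstrap standard errors: the standard deviation of
#' the column mean over \code{iterations} resamples drawn with
#' replacement within each class (the empirical, not the null,
#' distribution). Columns that are all-zero in both classes (pure buffer)
#' are reported as not testable.
#'
#' @param masked a [MaskedMatrix-class] whose labels contain the two
#'   classes.
#' @param classes the two labels to compare (defaults to the first two
#'   label levels present).
#' @param iterations bootstrap resamples (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame: column (0-based), segment, mean/se/n per class,
#'   \code{testable}.
#' @export
positionMeanProfile <- function(masked, classes = NULL, iterations = 1000L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(masked@rowLabels)
  if (is.null(classes)) classes <- unique(lab)[1:2]
  if (any(is.na(classes)) || length(classes) != 2L)
    stop("two classes are required")
  m1 <- masked@values[lab == classes[1], , drop = FALSE]
  m2 <- masked@values[lab == classes[2], , drop = FALSE]
  if (nrow(m1) < 2L || nrow(m2) < 2L)
    stop("each class needs at least 2 members")
  bootSE <- function(m) {
    n <- nrow(m)
    reps <- vapply(seq_len(iterations),
                   function(i) colMeans(m[sample.int(n, n, TRUE), ,
                                          drop = FALSE]),
                   numeric(ncol(m)))
    if (ncol(m) == 1L) reps <- matrix(reps, nrow = 1L)
    apply(reps, 1L, stats::sd)
  }
  testable <- colSums(abs(m1)) + colSums(abs(m2)) > 0
  out <- data.frame(
    column = seq_len(ncol(masked@values)) - 1L,
    segment = columnSegments(masked@layout),
    mean_A = colMeans(m1), mean_B = colMeans(m2),
    se_A = bootSE(m1), se_B = bootSE(m2),
    n_A = nrow(m1), n_B = nrow(m2),
    testable = testable)
  rownames(out) <- NULL
  attr(out, "classes") <- classes
  out
}

#' Two-sample nonparametric Studentized bootstrap test
#'
#' The empirical statistic is the Studentized mean difference
#' \code{z0 = (mean(b) - mean(a)) / sqrt(var(b)/n2 + var(a)/n1)} (sample
#' variances, n-1 denominator). Null replicates pool both groups without
#' labels and draw n1 and n2 samples with replacement from the pool
#' (\code{mode = "pool"}, the default) or randomly partition the pooled
#' values into the two group sizes (\code{mode = "partition"}). The
#' two-sided p-value counts squared null statistics at least as large as
#' the squared empirical one: \code{p = (1 + #(z^2 >= z0^2)) / (R + 1)},
#' so p is never 0 and its floor is exactly \code{1/(R + 1)}.
#'
#' Degenerate inputs: when both groups have zero variance, equal means
#' give \code{z0 = 0, p = 1}; unequal means are treated as exceeding all
#' finite null statistics, \code{p = 1/(R + 1)}.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param R bootstrap iterations (default 1000).
#' @param seed optional RNG seed.
#' @param mode null-resampling mode, \code{"pool"} or \code{"partition"}.
#' @return list with \code{z0}, \code{R}, \code{exceed_count}, \code{p}.
#' @export
studentizedBootstrapTest <- function(a, b, R = 1000L, seed = NULL,
                                     mode = c("pool", "partition")) {
  mode <- match.arg(mode)
  if (R < 1L) stop("R must be at least 1")
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  if (!is.null(seed)) set.seed(seed)
  v1 <- stats::var(a); v2 <- stats::var(b)
  num0 <- mean(b) - mean(a)
  den0 <- sqrt(v2 / n2 + v1 / n1)
  if (den0 == 0 && num0 == 0)
    return(list(z0 = 0, R = R, exceed_count = R, p = 1))
  if (den0 == 0)
    return(list(z0 = Inf, R = R, exceed_count = 0L, p = 1 / (R + 1)))
  z0 <- num0 / den0
  pool <- c(a, b)
  if (mode == "pool") {
    A <- matrix(sample(pool, n1 * R, replace = TRUE), n1, R)
    B <- matrix(sample(pool, n2 * R, replace = TRUE), n2, R)
  } else {
    idx <- vapply(seq_len(R), function(i) sample.int(n1 + n2),
                  integer(n1 + n2))
    A <- matrix(pool[idx[seq_len(n1), ]], n1, R)
    B <- matrix(pool[idx[n1 + seq_len(n2), ]], n2, R)
  }
  num <- colMeans(B) - colMeans(A)
  den <- sqrt(.colVars(B) / n2 + .colVars(A) / n1)
  z <- .studentize(num, den)
  exceed <- sum(z * z >= z0 * z0)
  list(z0 = z0, R = R, exceed_count = exceed, p = (1 + exceed) / (R + 1))
}

#' Contiguous runs of significant columns
#'
#' @param flagged integer vector of flagged column indices (0-based).
#' @return two-column matrix of half-open intervals \code{[start, end)}.
#' @examples
#' significantRuns(c(3, 4, 5, 9))  # [3,6) and [9,10)
#' @export
significantRuns <- function(flagged) {
  if (length(flagged) == 0L)
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("start", "end"))))
  flagged <- sort(unique(as.integer(flagged)))
  brk <- which(diff(flagged) > 1L)
  starts <- flagged[c(1L, brk + 1L)]
  ends <- flagged[c(brk, length(flagged))] + 1L
  cbind(start = starts, end = ends)
}

#' Position-wise significance profile with Bonferroni correction
#'
#' Runs the Studentized bootstrap test on every testable matrix column
#' (columns all-zero in both classes are skipped as "not testable"),
#' applies the Bonferroni correction \code{p_adj = min(1, m * p)}, flags
#' columns at \code{p_adj <= alpha}, and reports contiguous runs of
#' significant columns as half-open column intervals.
#'
#' @param masked a [MaskedMatrix-class].
#' @param classes two labels to compare (default first two present).
#' @param R bootstrap iterations per column (default 1000).
#' @param alpha significance level (default 0.05).
#' @param bonferroniM number of tests for the correction; default the
#'   number of testable columns.
#' @param seed optional RNG seed.
#' @param mode null-resampling mode, passed to
#'   [studentizedBootstrapTest()].
#' @return data.frame (one row per column) with means, p_raw, p_adj and
#'   significance flags; attribute \code{"runs"} holds the interval
#'   matrix.
#' @export
profileSignificance <- function(masked, classes = NULL, R = 1000L,
                                alpha = 0.05, bonferroniM = NULL,
                                seed = NULL, mode = "pool") {
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(masked@rowLabels)
  if (is.null(classes)) classes <- unique(lab)[1:2]
  m1 <- masked@values[lab == classes[1], , drop = FALSE]
  m2 <- masked@values[lab == classes[2], , drop = FALSE]
  testable <- colSums(abs(m1)) + colSums(abs(m2)) > 0
  if (is.null(bonferroniM)) bonferroniM <- sum(testable)
  p <- rep(NA_real_, ncol(m1))
  for (j in which(testable))
    p[j] <- studentizedBootstrapTest(m1[, j], m2[, j], R = R,
                                     mode = mode)$p
  out <- data.frame(
    column = seq_len(ncol(m1)) - 1L,
    segment = columnSegments(masked@layout),
    mean_A = colMeans(m1), mean_B = colMeans(m2),
    p_raw = p,
    p_adj = pmin(1, bonferroniM * p),
    testable = testable)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  rownames(out) <- NULL
  attr(out, "runs") <- significantRuns(out$column[out$significant])
  attr(out, "classes") <- classes
  out
}

#' Two-sample permutation test
#'
#' Randomly permutes the pooled observations into two bins of the
#' original group sizes and counts the permutations where the permuted
#' statistic is at least as large as the empirical one:
#' \code{p = (1 + #(t >= t0)) / (R + 1)}. The default statistic is the
#' simple difference of means \code{mean(a) - mean(b)}; pass e.g. an
#' absolute-difference statistic for a two-sided test.
#'
#' @param a,b numeric vectors (pooled size >= 4).
#' @param statistic function of two vectors returning a scalar; NULL
#'   selects the fast difference-of-means path.
#' @param R permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list with \code{t0}, \code{R}, \code{exceed_count}, \code{p}.
#' @export
permutationTest <- function(a, b, statistic = NULL, R = 1000L,
                            seed = NULL) {
  if (R < 1L) stop("R must be at least 1")
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 < 4L) stop("pooled size must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  pool <- c(a, b)
  if (is.null(statistic)) {
    t0 <- mean(a) - mean(b)
    tot <- sum(pool)
    idx <- matrix(0L, n1, R)
    for (r in seq_len(R)) idx[, r] <- sample.int(n1 + n2, n1)
    sumA <- colSums(matrix(pool[idx], n1, R))
    tperm <- sumA / n1 - (tot - sumA) / n2
  } else {
    t0 <- statistic(a, b)
    tperm <- vapply(seq_len(R), function(r) {
      i <- sample.int(n1 + n2, n1)
      statistic(pool[i], pool[-i])
    }, numeric(1))
  }
  exceed <- sum(tperm >= t0)
  list(t0 = t0, R = R, exceed_count = exceed, p = (1 + exceed) / (R + 1))
}

#' Write a tidy position-profile CSV
#'
#' @param profile data.frame from [profileSignificance()] or
#'   [positionMeanProfile()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
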