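.asIntCodes <- function(x) {
  # map an arbitrary symbol vector onto 1..K integer codes
  ux <- sort(unique(x))
  list(codes = match(x, ux), K = length(ux))
}

.entropyFromCounts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  log2(n) - sum(counts * log2(counts)) / n
}

#' Shannon entropy of one alignment column
#'
#' Plug-in (maximum-likelihood) estimate
#' \code{H(X) = -sum_x p(x) log2 p(x)} in bits, where p(x) is the
#' occurrence frequency of each symbol in the column; 0 log 0 terms
#' contribute 0.
#'
#' @param column atomic vector of symbols (residue codes, letters, ...).
#' @return entropy in bits.
#' @examples
#' columnEntropy(rep(c("A", "B"), 10))  # 1 bit
#' @export
columnEntropy <- function(column) {
  if (length(column) == 0L) stop("column must be non-empty")
  .entropyFromCounts(as.integer(table(column)))
}

#' Conditional Shannon entropy H(X | Y)
#'
#' Plug-in estimate
#' \code{H(X|Y) = -sum_y p(y) sum_x p(x|y) log2 p(x|y)} in bits, computed
#' from the joint histogram of the two equally long columns.
#'
#' @param x,y equal-length symbol vectors.
#' @return conditional entropy in bits.
#' @export
conditionalEntropy <- function(x, y) {
  if (length(x) != length(y)) stop("columns must have equal length")
  cx <- .asIntCodes(x); cy <- .asIntCodes(y)
  .condEntropyCodes(cx$codes, cy$codes, cx$K, cy$K)
}

.condEntropyCodes <- function(xi, yi, Kx, Ky) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * Ky + yi, Kx * Ky)
  cy <- tabulate(yi, Ky)
  nz <- joint > 0
  jv <- joint[nz]
  # p(x|y) = c_xy / c_y; sum over cells of (c_xy/n) log2(c_y/c_xy)
  yOfCell <- ((which(nz) - 1L) %% Ky) + 1L
  sum(jv * (log2(cy[yOfCell]) - log2(jv))) / n
}

#' Mutual information between two alignment columns
#'
#' \code{I(X;Y) = H(X) - H(X|Y)} in bits, via [columnEntropy()] and
#' [conditionalEntropy()]; tiny negative floating-point residue is
#' clipped at 0. A conserved (constant) column has I = 0 with any
#' partner.
#'
#' @param x,y equal-length symbol vectors.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("columns must have equal length")
  cx <- .asIntCodes(x); cy <- .asIntCodes(y)
  mi <- .entropyFromCounts(tabulate(cx$codes, cx$K)) -
    .condEntropyCodes(cx$codes, cy$codes, cx$K, cy$K)
  max(mi, 0)
}

.miMatrixCodes <- function(m, K) {
  # m: integer matrix with entries 1..K; returns LxL plug-in MI in bits
  L <- ncol(m)
  H <- vapply(seq_len(L),
              function(j) .entropyFromCounts(tabulate(m[, j], K)),
              numeric(1))
  mi <- diag(H, L)
  if (L > 1L)
    for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
      v <- max(H[i] - .condEntropyCodes(m[, i], m[, j], K, K), 0)
      mi[i, j] <- v; mi[j, i] <- v
    }
  list(mi = mi, entropy = H)
}

#' Entropy profile and mutual-information matrix of an encoded matrix
#'
#' Computes the per-column Shannon entropy and the L x L matrix of
#' pairwise mutual information (bits) across all matrix columns of one
#' class, in the spatial segment order of the layout. The diagonal holds
#' the per-column entropy (I(X;X) = H(X)). The buffer/gap code 0 is
#' treated as an ordinary symbol by default (\code{gapMode =
#' "include"}); \code{gapMode = "exclude"} estimates each pair from the
#' rows where both columns are non-gap.
#'
#' @param em an [EncodedMatrix-class].
#' @param class optional label selecting the rows of one class; default
#'   all rows.
#' @param gapMode \code{"include"} or \code{"exclude"}.
#' @return list with \code{mi} (L x L matrix, dimnames
#'   \code{"segment:offset"}), \code{entropy} (length-L vector) and
#'   \code{n} (rows used).
#' @export
miMatrix <- function(em, class = NULL, gapMode = c("include", "exclude")) {
  gapMode <- match.arg(gapMode)
  m <- em@values
  if (!is.null(class)) {
    m <- m[as.character(em@rowLabels) == class, , drop = FALSE]
    if (nrow(m) == 0L) stop("no rows with label '", class, "'")
  }
  if (nrow(m) < 2L) stop("at least 2 rows are required")
  segs <- columnSegments(em@layout)
  offs <- stats::ave(seq_along(segs), segs, FUN = seq_along) - 1L
  cn <- sprintf("%s:%d", segs, offs)
  if (gapMode == "include") {
    res <- .miMatrixCodes(m + 1L, 22L)
    mi <- res$mi; H <- res$entropy
  } else {
    L <- ncol(m)
    H <- vapply(seq_len(L), function(j) {
      v <- m[m[, j] != 0L, j]
      if (length(v)) columnEntropy(v) else 0
    }, numeric(1))
    mi <- diag(H, L)
    if (L > 1L)
      for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
        keep <- m[, i] != 0L & m[, j] != 0L
        v <- if (sum(keep) >= 2L)
          mutualInformation(m[keep, i], m[keep, j]) else 0
        mi[i, j] <- v; mi[j, i] <- v
      }
  }
  dimnames(mi) <- list(cn, cn)
  names(H) <- cn
  list(mi = mi, entropy = H, n = nrow(m))
}

#' Class difference in mutual information, with permutation significance
#'
#' Computes \code{deltaMI = MI(class A) - MI(class B)} for every column
#' pair and attaches a per-pair permutation p-value: class labels are
#' shuffled (group sizes preserved) and the two-sided statistic
#' \code{|MI_A - MI_B|} of each shuffle is compared against the empirical
#' one using the count rule \code{p = (1 + #(t >= t0)) / (R + 1)}.
#'
#' @param em an [EncodedMatrix-class] whose labels contain the two
#'   classes.
#' @param classes two labels (default first two present).
#' @param R permutations (default 1000).
#' @param alpha significance level for the mask (default 0.05).
#' @param seed optional RNG seed.
#' @param columns optional integer vector of 0-based matrix columns to
#'   restrict the analysis to (all pairwise combinations of these).
#' @return list with matrices \code{deltaMI}, \code{p},
#'   \code{significant}, plus \code{classes} and \code{R}.
#' @export
miDifferenceWithSignificance <- function(em, classes = NULL, R = 1000L,
                                         alpha = 0.05, seed = NULL,
                                         columns = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(em@rowLabels)
  if (is.null(classes)) classes <- unique(lab)[1:2]
  keep <- lab %in% classes
  m <- em@values[keep, , drop = FALSE] + 1L
  lab <- lab[keep]
  segs <- columnSegments(em@layout)
  offs <- stats::ave(seq_along(segs), segs, FUN = seq_along) - 1L
  cn <- sprintf("%s:%d", segs, offs)
  if (!is.null(columns)) {
    m <- m[, columns + 1L, drop = FALSE]
    cn <- cn[columns + 1L]
  }
  isA <- lab == classes[1]
  nA <- sum(isA); nTot <- length(lab)
  if (nA < 2L || nTot - nA < 2L) stop("each class needs at least 2 rows")
  L <- ncol(m); K <- 22L
  miOf <- function(rows) .miMatrixCodes(m[rows, , drop = FALSE], K)$mi
  miA <- miOf(isA)
  miB <- miOf(!isA)
  delta <- miA - miB
  t0 <- abs(delta)
  exceed <- matrix(0L, L, L)
  for (r in seq_len(R)) {
    permA <- logical(nTot)
    permA[sample.int(nTot, nA)] <- TRUE
    tperm <- abs(miOf(permA) - miOf(!permA))
    exceed <- exceed + (tperm >= t0)
  }
  p <- (1 + exceed) / (R + 1)
  dimnames(delta) <- dimnames(p) <- list(cn, cn)
  list(deltaMI = delta, p = p, significant = p <= alpha,
       classes = classes, R = R)
}

#' Write a square MI or delta-MI matrix as CSV
#'
#' @param m square matrix with \code{"segment:offset"} dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMIMatrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
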