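# Approximate background residue frequencies of antibody CDR loops
# (enriched in serine/glycine/tyrosine), used by the "natural" preset.
.NATURAL_CDR_FREQ <- c(
  S = 0.13, G = 0.12, Y = 0.09, A = 0.07, T = 0.07, D = 0.06,
  R = 0.055, N = 0.05, F = 0.045, L = 0.045, V = 0.04, I = 0.035,
  P = 0.035, E = 0.03, K = 0.03, W = 0.025, Q = 0.025, H = 0.02,
  M = 0.015, C = 0.01)

# CDR2H is nearly constant-length in natural repertoires; the other
# loops vary, CDR3H most of all.
.DEFAULT_LOOP_LENGTHS <- list(
  cdr1l = 10:17, cdr2l = 7:8, cdr3l = 8:11,
  cdr1h = 8:10, cdr2h = 8L, cdr3h = 10:22)

#' Specify a two-class synthetic repertoire
#'
#' Collects the generator's study conditions: class sizes, per-loop
#' length distributions, background residue frequencies, implanted
#' signals and label noise. Defaults mirror the aggregate dataset the
#' pipeline was designed around (529 polyreactive / 524 non-polyreactive
#' records) with realistic loop-length ranges (CDR3H 10-22) and a
#' uniform residue background.
#'
#' @param nPoly,nNon class sizes.
#' @param loopLengths named list; each entry the vector of allowed
#'   lengths for that loop (sampled uniformly).
#' @param background \code{"uniform"}, \code{"natural"} (CDR-like
#'   frequencies), or a named numeric vector of residue probabilities.
#' @param shifts list of property-shift signals, each a list with
#'   \code{loop}, \code{positions} (0-based offsets within the loop
#'   span), \code{residues}, \code{delta}, \code{class}.
#' @param couplings list of coupling signals, each a list with
#'   \code{i}, \code{j} (0-based matrix columns), \code{strength},
#'   \code{class} (NULL = both).
#' @param labelNoise fraction of labels flipped after implantation.
#' @param bufferWidth buffer used for the layout in which signal
#'   coordinates are interpreted.
#' @param source dataset tag recorded on every record.
#' @return a validated \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(nPoly = 529L, nNon = 524L,
                        loopLengths = .DEFAULT_LOOP_LENGTHS,
                        background = "uniform",
                        shifts = list(), couplings = list(),
                        labelNoise = 0, bufferWidth = 3L,
                        source = "synthetic") {
  ll <- utils::modifyList(.DEFAULT_LOOP_LENGTHS, loopLengths)
  spec <- structure(list(nPoly = as.integer(nPoly), nNon = as.integer(nNon),
                         loopLengths = ll[.LOOP_NAMES],
                         background = background, shifts = shifts,
                         couplings = couplings, labelNoise = labelNoise,
                         bufferWidth = as.integer(bufferWidth),
                         source = source),
                    class = "FixtureSpec")
  if (spec$nPoly < 1L || spec$nNon < 1L) stop("class sizes must be positive")
  if (labelNoise < 0 || labelNoise > 1) stop("labelNoise must be in [0,1]")
  for (s in shifts) {
    if (length(s$residues %||% character()) == 0L)
      stop("property shift needs a non-empty residue set")
    if ((s$delta %||% -1) < 0 || s$delta > 1)
      stop("shift probability delta must be in [0,1]")
  }
  for (cp in couplings)
    if ((cp$strength %||% -1) < 0 || cp$strength > 1)
      stop("coupling strength must be in [0,1]")
  spec
}

.backgroundProbs <- function(background) {
  if (is.character(background) && length(background) == 1L) {
    if (background == "uniform")
      return(stats::setNames(rep(1 / 20, 20), .AA_ORDER))
    if (background == "natural")
      return(.NATURAL_CDR_FREQ[.AA_ORDER] /
             sum(.NATURAL_CDR_FREQ[.AA_ORDER]))
    stop("unknown background preset: ", background)
  }
  # a named vector over any subset of the alphabet; unnamed residues get 0
  if (is.null(names(background)) ||
      !all(names(background) %in% .AA_ORDER) || any(background < 0))
    stop("invalid background frequencies")
  p <- stats::setNames(rep(0, 20), .AA_ORDER)
  p[names(background)] <- background
  if (sum(p) <= 0) stop("background frequencies must sum to a positive value")
  p / sum(p)
}

#' The layout a fixture's signal coordinates refer to
#'
#' Signals in a [fixtureSpec()] are declared in matrix coordinates;
#' those coordinates are interpreted in this layout, whose span widths
#' are the maximum allowed length of each loop.
#'
#' @param spec a FixtureSpec.
#' @return a [MatrixLayout-class].
#' @export
fixtureLayout <- function(spec) {
  widths <- vapply(spec$loopLengths, max, integer(1))
  makeLayout(widths, spec$bufferWidth)
}

#' Generate a deterministic two-class synthetic repertoire
#'
#' Draws loop lengths and residues per record, synthesizes reactivity
#' counts consistent with the class (polyreactive from 4-7 panel
#' ligands, non-polyreactive 0, mirroring the parsed labeling scheme),
#' applies the spec's implanted signals, then the label noise. Fully
#' reproducible from (spec, seed).
#'
#' @param spec a [fixtureSpec()].
#' @param seed RNG seed (required for reproducibility).
#' @return list with \code{records} (a repertoire data.frame that passes
#'   [validateRepertoire()]) and \code{truth} (implanted-signal registry,
#'   per-record true class, seed).
#' @export
generateRepertoire <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(seed)
  probs <- .backgroundProbs(spec$background)
  n <- spec$nPoly + spec$nNon
  trueClass <- rep(c("polyreactive", "non_polyreactive"),
                   c(spec$nPoly, spec$nNon))
  rec <- data.frame(
    id = sprintf("syn%05d", seq_len(n)), stringsAsFactors = FALSE)
  for (lp in .LOOP_NAMES) {
    allowed <- spec$loopLengths[[lp]]
    # guard the scalar case: sample(8) would draw from 1:8
    lens <- if (length(allowed) == 1L) rep(allowed, n)
            else sample(allowed, n, replace = TRUE)
    rec[[lp]] <- vapply(lens, function(l)
      paste(sample(names(probs), l, replace = TRUE, prob = probs),
            collapse = ""), character(1))
  }
  rec$reactivity_count <- ifelse(trueClass == "polyreactive",
                                 sample(4:7, n, replace = TRUE), 0L)
  rec$source <- spec$source
  for (g in c("v_gene_h", "v_gene_l", "j_gene_h", "j_gene_l"))
    rec[[g]] <- NA_character_
  rec$label <- factor(trueClass, levels = .LABEL_LEVELS)
  layout <- fixtureLayout(spec)
  for (s in spec$shifts)
    rec <- implantPropertyShift(rec, s$loop, s$positions, s$residues,
                                s$delta, s$class %||% NULL, layout)
  for (cp in spec$couplings)
    rec <- implantCoupling(rec, cp$i, cp$j, cp$strength,
                           cp$class %||% NULL, layout)
  if (spec$labelNoise > 0) {
    flip <- which(stats::runif(n) < spec$labelNoise)
    lv <- as.character(rec$label[flip])
    rec$label[flip] <- ifelse(lv == "polyreactive",
                              "non_polyreactive", "polyreactive")
  }
  validateRepertoire(rec)
  list(records = rec,
       truth = list(trueClass = trueClass, shifts = spec$shifts,
                    couplings = spec$couplings, seed = seed,
                    layout = layout))
}

# map a matrix column (0-based) to its segment and 0-based offset
.columnToSegment <- function(layout, column) {
  spans <- segmentSpans(layout)
  k <- which(column >= spans[, 1L] & column < spans[, 2L])
  if (length(k) != 1L)
    stop("column ", column, " is not inside any segment span")
  list(segment = layout@segmentNames[k], offset = column - spans[k, 1L],
       width = layout@segmentWidths[k])
}

# string index (1-based) of a span offset for a sequence of length len
# center-aligned in a span of the given width; NA when the offset falls
# in the padding
.offsetToStringIndex <- function(width, len, offset) {
  left <- (width - len) %/% 2L
  idx <- offset - left + 1L
  ifelse(idx >= 1L & idx <= len, idx, NA_integer_)
}

.replaceChar <- function(s, i, ch) {
  substr(s, i, i) <- ch
  s
}

#' Implant a biophysical property shift
#'
#' With probability \code{delta}, the residue of a class's records at
#' the given within-loop span offsets is replaced by a uniform draw from
#' \code{residues} (e.g. \code{c("R", "K")} to shift charge). Offsets
#' falling into a record's center-alignment padding are skipped.
#'
#' @param records repertoire data.frame.
#' @param loop loop name (e.g. \code{"cdr2h"}).
#' @param positions 0-based offsets within the loop's span.
#' @param residues non-empty residue set drawn from uniformly.
#' @param delta per-position replacement probability.
#' @param class restrict to records with this label (NULL = all).
#' @param layout the [MatrixLayout-class] fixing the span widths
#'   (default: widths of the observed maxima, buffer 3).
#' @return modified records.
#' @export
implantPropertyShift <- function(records, loop, positions, residues,
                                 delta, class = NULL, layout = NULL) {
  if (length(residues) == 0L) stop("residue set must be non-empty")
  if (delta < 0 || delta > 1) stop("delta must be in [0,1]")
  loop <- match.arg(loop, .LOOP_NAMES)
  if (is.null(layout)) {
    widths <- vapply(.LOOP_NAMES,
                     function(lp) max(nchar(records[[lp]]), 1L), integer(1))
    layout <- makeLayout(widths, 3L)
  }
  w <- layout@segmentWidths[layout@segmentNames == loop]
  if (any(positions < 0L | positions >= w))
    stop("positions must lie within the loop span [0, ", w, ")")
  target <- if (is.null(class)) seq_len(nrow(records))
            else which(as.character(records$label) == class)
  for (i in target) {
    s <- records[[loop]][i]
    len <- nchar(s)
    for (pos in positions) {
      idx <- .offsetToStringIndex(w, len, pos)
      if (!is.na(idx) && stats::runif(1) < delta)
        s <- .replaceChar(s, idx, sample(residues, 1L))
    }
    records[[loop]][i] <- s
  }
  records
}

#' Implant a positional coupling between two matrix columns
#'
#' With probability \code{strength}, the residue of a record at column
#' \code{j} is set equal to its residue at column \code{i} (creating
#' "crosstalk" detectable as mutual information). Records where either
#' column falls into padding are left unchanged.
#'
#' @param records repertoire data.frame.
#' @param i,j 0-based matrix columns; both must lie inside loop spans of
#'   \code{layout}.
#' @param strength coupling probability in [0,1]; 0 is a no-op.
#' @param class restrict to records with this label (NULL = all).
#' @param layout the [MatrixLayout-class] fixing the coordinates
#'   (default: observed maxima, buffer 3).
#' @return modified records.
#' @export
implantCoupling <- function(records, i, j, strength, class = NULL,
                            layout = NULL) {
  if (strength < 0 || strength > 1) stop("strength must be in [0,1]")
  if (strength == 0) return(records)
  if (is.null(layout)) {
    widths <- vapply(.LOOP_NAMES,
                     function(lp) max(nchar(records[[lp]]), 1L), integer(1))
    layout <- makeLayout(widths, 3L)
  }
  segI <- .columnToSegment(layout, i)
  segJ <- .columnToSegment(layout, j)
  target <- if (is.null(class)) seq_len(nrow(records))
            else which(as.character(records$label) == class)
  for (r in target) {
    sI <- records[[segI$segment]][r]
    sJ <- records[[segJ$segment]][r]
    idxI <- .offsetToStringIndex(segI$width, nchar(sI), segI$offset)
    idxJ <- .offsetToStringIndex(segJ$width, nchar(sJ), segJ$offset)
    if (is.na(idxI) || is.na(idxJ)) next
    if (stats::runif(1) < strength) {
      sJ <- .replaceChar(sJ, idxJ, substr(sI, idxI, idxI))
      records[[segJ$segment]][r] <- sJ
    }
  }
  records
}

#' Generate synthetic platform-domain classes
#'
#' Builds two aligned platform-domain classes whose residue composition
#' differs in hydrophobicity -- a "lipid-like" class drawing
#' preferentially from hydrophobic residues and a "peptide-like" class
#' drawing preferentially from polar ones -- plus held-out test members
#' generated from each class. Emulates the MHC-versus-CD1 platform
#' comparison at desk scale.
#'
#' @param nTrain training members per class.
#' @param nTest test members per class.
#' @param bias probability mass placed on the class's preferred residue
#'   set (default 0.7).
#' @param seed RNG seed.
#' @return list with \code{classes} (train classes + one "test" class,
#'   in the [loadPlatformClasses()] structure), \code{boundaries}
#'   (feature data.frame) and \code{truth} (generating class of each
#'   test member).
#' @export
generatePlatformClasses <- function(nTrain = 15L, nTest = 5L, bias = 0.7,
                                    seed = 1L) {
  set.seed(seed)
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C")
  polar <- c("S", "T", "Y", "N", "Q", "D", "E", "K", "R", "H", "G", "P")
  # platform domains run ~180 residues: two beta-strand floors and two
  # alpha-helices
  boundaries <- data.frame(
    name = c("strand1", "helix1", "strand2", "helix2"),
    start = c(0L, 45L, 90L, 135L), end = c(45L, 90L, 135L, 180L),
    stringsAsFactors = FALSE)
  width <- max(boundaries$end)
  drawSeq <- function(pref, alt) {
    fromPref <- stats::runif(width) < bias
    paste(ifelse(fromPref, sample(pref, width, replace = TRUE),
                 sample(alt, width, replace = TRUE)), collapse = "")
  }
  mk <- function(n, pref, alt, prefix) {
    s <- vapply(seq_len(n), function(k) drawSeq(pref, alt), character(1))
    names(s) <- sprintf("%s%02d", prefix, seq_len(n))
    s
  }
  lipidTrain <- mk(nTrain, hydrophobic, polar, "lip")
  peptTrain <- mk(nTrain, polar, hydrophobic, "pep")
  lipidTest <- mk(nTest, hydrophobic, polar, "lipT")
  peptTest <- mk(nTest, polar, hydrophobic, "pepT")
  classes <- list(
    `lipid-like` = list(name = "lipid-like", sequences = lipidTrain,
                        width = width, role = "train"),
    `peptide-like` = list(name = "peptide-like", sequences = peptTrain,
                          width = width, role = "train"),
    test = list(name = "test", sequences = c(lipidTest, peptTest),
                width = width, role = "test"))
  truth <- c(rep("lipid-like", nTest), rep("peptide-like", nTest))
  names(truth) <- c(names(lipidTest), names(peptTest))
  list(classes = classes, boundaries = boundaries, truth = truth)
}
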