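#' Load aligned platform-domain sequence classes from FASTA
#'
#' Each class (e.g. "MHC-I", "CD1") is one aligned FASTA file: all
#' members must share the alignment length (gaps \code{"-"}); ragged
#' input is rejected with an instruction to align first.
#'
#' @param fastaPaths named character vector, one aligned FASTA per
#'   class; names become the class labels.
#' @param roles character vector ("train"/"test") per class, recycled.
#' @return list of platform classes: each a list with \code{name},
#'   \code{sequences} (uppercase character vector, named by record),
#'   \code{width}, \code{role}.
#' @export
loadPlatformClasses <- function(fastaPaths, roles = "train") {
  if (is.null(names(fastaPaths)) || any(names(fastaPaths) == ""))
    stop("fastaPaths must be named by class")
  roles <- rep_len(roles, length(fastaPaths))
  out <- vector("list", length(fastaPaths))
  for (i in seq_along(fastaPaths)) {
    aas <- Biostrings::readAAStringSet(fastaPaths[[i]])
    if (length(aas) == 0L)
      stop("empty FASTA for class '", names(fastaPaths)[i], "'")
    widths <- Biostrings::width(aas)
    if (length(unique(widths)) != 1L)
      stop("ragged sequences in class '", names(fastaPaths)[i],
           "' (lengths ", paste(unique(widths), collapse = ", "),
           "); align the sequences first")
    out[[i]] <- list(name = names(fastaPaths)[i],
                     sequences = toupper(as.character(aas)),
                     width = widths[1], role = roles[i])
  }
  names(out) <- names(fastaPaths)
  out
}

#' Read or validate structural feature boundaries
#'
#' Boundaries declare the platform-domain features (beta-strands and
#' alpha-helices) as 0-based half-open \code{[start, end)} intervals in
#' alignment coordinates. Accepts a YAML/JSON file (a list of
#' \code{{name, start, end}}) or a data.frame.
#'
#' @param x path to a YAML/JSON file, or a data.frame with columns
#'   \code{name}, \code{start}, \code{end}.
#' @param alignmentWidth optional alignment length used to validate the
#'   intervals.
#' @return validated data.frame with columns name, start, end.
#' @export
readFeatureBoundaries <- function(x, alignmentWidth = NULL) {
  if (is.character(x)) {
    raw <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
    if (is.data.frame(raw)) b <- raw
    else b <- do.call(rbind, lapply(raw, function(f)
      data.frame(name = f$name, start = f$start, end = f$end,
                 stringsAsFactors = FALSE)))
  } else b <- as.data.frame(x)
  need <- c("name", "start", "end")
  if (!all(need %in% names(b)))
    stop("boundaries need columns name, start, end")
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  if (any(b$end <= b$start)) stop("feature intervals must be non-empty")
  if (anyDuplicated(b$name)) stop("feature names must be unique")
  ord <- order(b$start)
  b <- b[ord, , drop = FALSE]
  if (any(utils::head(b$end, -1L) > utils::tail(b$start, -1L)))
    stop("feature intervals must be disjoint and increasing")
  if (!is.null(alignmentWidth) && any(b$end > alignmentWidth))
    stop("feature boundary beyond alignment length ", alignmentWidth)
  rownames(b) <- NULL
  b
}

#' Encode platform-domain classes into a segment matrix
#'
#' Extracts each declared structural feature from the alignment,
#' optionally strips in-segment gap characters, and center-aligns every
#' segment into its own span (width = longest observed segment across
#' all classes), with zero buffers between spans -- the same coordinate
#' construction as the antibody path, so every downstream module (masks,
#' position statistics, entropy/MI, PCA/LDA/SVM) applies unchanged.
#' Row labels are the class names; a segment that is all gaps in one
#' member yields an all-zero span for that row.
#'
#' @param classes list from [loadPlatformClasses()].
#' @param boundaries feature boundaries (path or data.frame; see
#'   [readFeatureBoundaries()]).
#' @param bufferWidth buffer columns between segments (default 3).
#' @param stripGaps drop gap characters inside each segment before
#'   center alignment (default TRUE); FALSE preserves gap columns,
#'   encoding gaps as 0 is not possible mid-span, so gaps become code 21
#'   only when FALSE is combined with non-'-' characters.
#' @param roles restrict to classes with these roles (default all).
#' @return an [EncodedMatrix-class].
#' @export
encodePlatform <- function(classes, boundaries, bufferWidth = 3L,
                           stripGaps = TRUE, roles = NULL) {
  if (!is.null(roles))
    classes <- Filter(function(cl) cl$role %in% roles, classes)
  if (length(classes) == 0L) stop("no classes to encode")
  aw <- unique(vapply(classes, `[[`, integer(1), "width"))
  if (length(aw) != 1L)
    stop("all classes must share one alignment length; got ",
         paste(aw, collapse = ", "))
  b <- readFeatureBoundaries(boundaries, alignmentWidth = aw)
  segOf <- function(seqs, k) {
    sub <- substr(seqs, b$start[k] + 1L, b$end[k])
    if (stripGaps) gsub("-", "", sub) else sub
  }
  allSeqs <- unlist(lapply(classes, `[[`, "sequences"), use.names = FALSE)
  widths <- vapply(seq_len(nrow(b)), function(k)
    max(nchar(segOf(allSeqs, k)), 1L), integer(1))
  names(widths) <- b$name
  layout <- makeLayout(widths, bufferWidth)
  spans <- segmentSpans(layout)
  ids <- unlist(lapply(classes, function(cl) names(cl$sequences)),
                use.names = FALSE)
  labs <- unlist(lapply(classes, function(cl)
    rep(cl$name, length(cl$sequences))), use.names = FALSE)
  values <- matrix(0L, length(allSeqs), totalLength(layout))
  for (k in seq_len(nrow(b))) {
    segs <- segOf(allSeqs, k)
    if (!stripGaps) segs <- gsub("-", "X", segs)
    cols <- (spans[k, 1L] + 1L):spans[k, 2L]
    values[, cols] <- t(vapply(seq_along(segs),
      function(i) centerAlignSegment(segs[i], widths[k], id = ids[i]),
      integer(widths[k])))
  }
  new("EncodedMatrix", values = values, layout = layout,
      rowIds = as.character(ids),
      rowLabels = factor(labs, levels = unique(labs)))
}
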