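#' @import methods
NULL

#' Layout of a position-sensitive segment matrix
#'
#' A \code{MatrixLayout} describes how variable-length sequence segments
#' (the six CDR loops of an antibody, or the structural features of an
#' MHC platform domain) are placed into a fixed-width matrix: one span of
#' columns per segment, separated by buffer columns that always hold the
#' code 0.
#'
#' @slot segmentNames character vector naming each segment, in matrix order.
#' @slot segmentWidths integer vector of span widths, one per segment; each
#'   width must be at least the longest sequence placed in that span.
#' @slot bufferWidth single non-negative integer, the number of zero
#'   columns inserted between consecutive segments.
#'
#' @seealso [segmentSpans()], [totalLength()], [encodeRepertoire()]
#' @export
setClass("MatrixLayout",
  representation(
    segmentNames  = "character",
    segmentWidths = "integer",
    bufferWidth   = "integer"
  )
)

setValidity("MatrixLayout", function(object) {
  msg <- character()
  if (length(object@segmentNames) != length(object@segmentWidths))
    msg <- c(msg, "segmentNames and segmentWidths must have equal length")
  if (length(object@segmentWidths) < 1L)
    msg <- c(msg, "layout needs at least one segment")
  if (any(object@segmentWidths < 1L))
    msg <- c(msg, "segment widths must be positive")
  if (length(object@bufferWidth) != 1L || object@bufferWidth < 0L)
    msg <- c(msg, "bufferWidth must be a single non-negative integer")
  if (anyDuplicated(object@segmentNames))
    msg <- c(msg, "segment names must be unique")
  if (length(msg)) msg else TRUE
})

#' Position-sensitive integer encoding of a repertoire
#'
#' An \code{EncodedMatrix} holds one row per sequence record. Each residue
#' is encoded as an integer 1-21 (20 standard residues plus code 21 for
#' X/non-standard); 0 marks buffer columns and the padding around
#' center-aligned segments.
#'
#' @slot values integer matrix, N rows by [totalLength()] columns, entries
#'   in 0..21.
#' @slot layout the [MatrixLayout-class] shared by every row.
#' @slot rowIds character vector of record identifiers.
#' @slot rowLabels factor of class labels, one per row.
#'
#' @seealso [encodeRepertoire()], [applyMask()], [miMatrix()]
#' @export
setClass("EncodedMatrix",
  representation(
    values    = "matrix",
    layout    = "MatrixLayout",
    rowIds    = "character",
    rowLabels = "factor"
  )
)

setValidity("EncodedMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (ncol(v) != totalLength(object@layout))
    msg <- c(msg, "column count does not match layout total length")
  if (nrow(v) != length(object@rowIds) || nrow(v) != length(object@rowLabels))
    msg <- c(msg, "rowIds/rowLabels length must equal row count")
  if (length(v) && (any(v < 0) || any(v > 21) || any(v != round(v))))
    msg <- c(msg, "entries must be integers in 0..21")
  spans <- segmentSpans(object@layout)
  inSpan <- logical(ncol(v))
  for (k in seq_len(nrow(spans)))
    inSpan[(spans[k, 1L] + 1L):spans[k, 2L]] <- TRUE
  if (length(v) && any(v[, !inSpan, drop = FALSE] != 0))
    msg <- c(msg, "buffer columns must be all zero")
  if (length(msg)) msg else TRUE
})

#' Property-masked repertoire matrix
#'
#' The result of replacing the 1-21 residue codes of an
#' [EncodedMatrix-class] by the per-residue values of one biophysical
#' property ("mask"). Buffer/padding zeros stay exactly 0.
#'
#' @slot values numeric matrix with the same shape as the source encoding.
#' @slot property name of the applied property.
#' @slot layout the shared [MatrixLayout-class].
#' @slot rowIds,rowLabels carried over from the source matrix.
#'
#' @seealso [applyMask()], [positionMeanProfile()]
#' @export
setClass("MaskedMatrix",
  representation(
    values    = "matrix",
    property  = "character",
    layout    = "MatrixLayout",
    rowIds    = "character",
    rowLabels = "factor"
  )
)

setValidity("MaskedMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != totalLength(object@layout))
    msg <- c(msg, "column count does not match layout total length")
  if (nrow(object@values) != length(object@rowLabels))
    msg <- c(msg, "rowLabels length must equal row count")
  if (length(object@property) != 1L)
    msg <- c(msg, "property must be a single name")
  if (length(msg)) msg else TRUE
})

#' Table of per-residue biophysical property masks
#'
#' Rows correspond to residue codes 1..21 (see [residueAlphabet()]); each
#' column is one named property. Code 21 (X / non-standard residue) is
#' assigned 0 for every mask, a neutral imputation.
#'
#' @slot values 21 x P numeric matrix; rownames are the residue letters
#'   (with "X" last), colnames the property names.
#' @slot metadata data.frame with one row per property: \code{property},
#'   \code{category} (basic / kidera / hotspot / custom), \code{description}.
#'
#' @seealso [defaultPropertySet()], [loadPropertyTable()], [applyMask()]
#' @export
setClass("PropertySet",
  representation(
    values   = "matrix",
    metadata = "data.frame"
  )
)

setValidity("PropertySet", function(object) {
  msg <- character()
  if (nrow(object@values) != 21L)
    msg <- c(msg, "values must have 21 rows (codes 1..21)")
  if (is.null(colnames(object@values)) || anyDuplicated(colnames(object@values)))
    msg <- c(msg, "properties must have unique names")
  if (any(!is.finite(object@values[1:20, ])))
    msg <- c(msg, "all properties must be defined for the 20 standard residues")
  if (nrow(object@metadata) != ncol(object@values))
    msg <- c(msg, "metadata must have one row per property")
  if (length(msg)) msg else TRUE
})

## ---- generics ----

#' @rdname MatrixLayout-class
#' @param object,x a MatrixLayout (or an object carrying one)
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname MatrixLayout-class
#' @export
setGeneric("segmentSpans", function(x) standardGeneric("segmentSpans"))

#' @rdname EncodedMatrix-class
#' @export
setGeneric("encodedValues", function(x) standardGeneric("encodedValues"))

#' @rdname EncodedMatrix-class
#' @export
setGeneric("matrixLayout", function(x) standardGeneric("matrixLayout"))

#' @rdname EncodedMatrix-class
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @rdname EncodedMatrix-class
#' @export
setGeneric("rowLabels", function(x) standardGeneric("rowLabels"))

#' @rdname PropertySet-class
#' @export
setGeneric("propertyNames", function(x) standardGeneric("propertyNames"))

#' @rdname PropertySet-class
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

## ---- methods ----

#' @describeIn MatrixLayout-class total number of matrix columns
#'   (sum of segment widths plus buffers between segments).
#' @export
setMethod("totalLength", "MatrixLayout", function(x) {
  sum(x@segmentWidths) + (length(x@segmentWidths) - 1L) * x@bufferWidth
})

#' @describeIn MatrixLayout-class 0-based half-open column interval
#'   of each segment, as a two-column matrix \code{[start, end)} with one
#'   row per segment.
#' @export
setMethod("segmentSpans", "MatrixLayout", function(x) {
  w <- x@segmentWidths
  starts <- cumsum(c(0L, head(w, -1L) + x@bufferWidth))
  out <- cbind(start = starts, end = starts + w)
  rownames(out) <- x@segmentNames
  out
})

#' @export
setMethod("totalLength", "EncodedMatrix", function(x) totalLength(x@layout))

#' @describeIn EncodedMatrix-class the integer value matrix.
#' @export
setMethod("encodedValues", "EncodedMatrix", function(x) x@values)

#' @export
setMethod("encodedValues", "MaskedMatrix", function(x) x@values)

#' @describeIn EncodedMatrix-class the shared layout.
#' @export
setMethod("matrixLayout", "EncodedMatrix", function(x) x@layout)

#' @export
setMethod("matrixLayout", "MaskedMatrix", function(x) x@layout)

#' @describeIn EncodedMatrix-class record identifiers.
#' @export
setMethod("rowIds", "EncodedMatrix", function(x) x@rowIds)

#' @export
setMethod("rowIds", "MaskedMatrix", function(x) x@rowIds)

#' @describeIn EncodedMatrix-class class labels.
#' @export
setMethod("rowLabels", "EncodedMatrix", function(x) x@rowLabels)

#' @export
setMethod("rowLabels", "MaskedMatrix", function(x) x@rowLabels)

#' @describeIn PropertySet-class names of the available masks.
#' @export
setMethod("propertyNames", "PropertySet", function(x) colnames(x@values))

#' @describeIn PropertySet-class the 21 x P value matrix.
#' @export
setMethod("propertyValues", "PropertySet", function(x) x@values)

#' @export
setMethod("dim", "EncodedMatrix", function(x) dim(x@values))

#' @export
setMethod("dim", "MaskedMatrix", function(x) dim(x@values))

setMethod("show", "MatrixLayout", function(object) {
  cat("MatrixLayout:", length(object@segmentWidths), "segments,",
      "buffer", object@bufferWidth, "->", totalLength(object), "columns\n")
  sp <- segmentSpans(object)
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-8s width %2d  span [%d, %d)\n",
                object@segmentNames[i], object@segmentWidths[i],
                sp[i, 1L], sp[i, 2L]))
})

setMethod("show", "EncodedMatrix", function(object) {
  cat("EncodedMatrix:", nrow(object@values), "sequences x",
      ncol(object@values), "positions\n")
  tab <- table(object@rowLabels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  show(object@layout)
})

setMethod("show", "MaskedMatrix", function(object) {
  cat("MaskedMatrix ('", object@property, "'): ",
      nrow(object@values), " sequences x ", ncol(object@values),
      " positions\n", sep = "")
})

setMethod("show", "PropertySet", function(object) {
  cat("PropertySet:", ncol(object@values), "properties\n")
  print(table(object@metadata$category))
})
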