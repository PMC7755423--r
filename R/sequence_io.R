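# Residue alphabet. Only three assignments are fixed by the published
# worked example (L=3, H=16, R=17); the remaining order groups residues
# by biophysical character (hydrophobic, polar, charged) subject to those
# constraints. Code 21 is reserved for X / non-standard residues.
.AA_ORDER <- c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C",
               "S", "T", "Y", "N", "Q", "H", "R", "K", "D", "E")

.LOOP_NAMES <- c("cdr1l", "cdr2l", "cdr3l", "cdr1h", "cdr2h", "cdr3h")

.LABEL_LEVELS <- c("polyreactive", "non_polyreactive", "excluded", "unknown")

#' The residue alphabet and integer codes
#'
#' Returns the 21-letter alphabet used by the encoder: the 20 standard
#' residues in a fixed order (leucine = 3, histidine = 16, arginine = 17)
#' followed by \code{"X"}, the catch-all code 21 for non-standard letters.
#'
#' @return named integer vector mapping residue letter to code 1..21.
#' @examples
#' residueAlphabet()[c("L", "H", "R", "X")]
#' @export
residueAlphabet <- function() {
  stats::setNames(seq_len(21L), c(.AA_ORDER, "X"))
}

#' Encode residues as integer codes
#'
#' @param residue character vector of single-letter residues (vectorised;
#'   a single multi-letter string is split into its letters).
#' @return integer codes in 1..21; \code{"X"} and any non-standard letter
#'   map to 21.
#' @examples
#' encodeResidue(c("L", "H", "R"))  # 3 16 17
#' @export
encodeResidue <- function(residue) {
  if (length(residue) == 1L && nchar(residue) > 1L)
    residue <- strsplit(residue, "")[[1]]
  residue <- toupper(residue)
  bad <- !grepl("^[A-Z]$", residue)
  if (any(bad))
    stop("non-alphabet character(s) in residue input: ",
         paste(unique(residue[bad]), collapse = ", "))
  code <- match(residue, .AA_ORDER)
  code[is.na(code)] <- 21L
  as.integer(code)
}

#' Decode integer codes back to residue letters
#'
#' @param code integer vector in 0..21; 0 decodes to \code{""} (buffer).
#' @return character vector of letters (code 21 decodes to \code{"X"}).
#' @export
decodeResidue <- function(code) {
  if (any(code < 0 | code > 21))
    stop("codes must lie in 0..21")
  out <- c("", .AA_ORDER, "X")[code + 1L]
  out
}

#' Center-align one segment into a fixed-width span
#'
#' Pads a residue string symmetrically with zeros into a span of
#' \code{width} columns: the left pad is \code{floor((width - len)/2)}
#' and any odd slack goes to the right. An empty sequence yields all
#' zeros.
#'
#' @param sequence residue string (possibly empty).
#' @param width span width; must be >= \code{nchar(sequence)}.
#' @param id optional record id used in the error message.
#' @return integer vector of length \code{width}.
#' @examples
#' centerAlignSegment("CAR", 5)
#' @export
centerAlignSegment <- function(sequence, width, id = NULL) {
  n <- nchar(sequence)
  if (n > width)
    stop("sequence of length ", n, " does not fit span width ", width,
         if (!is.null(id)) paste0(" (record ", id, ")") else "")
  out <- integer(width)
  if (n > 0L) {
    left <- (width - n) %/% 2L
    out[left + seq_len(n)] <- encodeResidue(sequence)
  }
  out
}

#' Construct a segment-matrix layout
#'
#' @param segmentWidths named integer vector (or list) of span widths.
#' @param bufferWidth number of zero columns between consecutive segments
#'   (default 3).
#' @return a [MatrixLayout-class].
#' @export
makeLayout <- function(segmentWidths, bufferWidth = 3L) {
  new("MatrixLayout",
      segmentNames  = names(segmentWidths),
      segmentWidths = as.integer(unlist(segmentWidths)),
      bufferWidth   = as.integer(bufferWidth))
}

#' Read a repertoire of CDR-loop records from CSV
#'
#' The expected schema has columns \code{id}, the six loop columns
#' \code{cdr1l, cdr2l, cdr3l, cdr1h, cdr2h, cdr3h}, and optionally
#' \code{reactivity_count}, \code{source} and gene-call columns
#' (\code{v_gene_h}, \code{v_gene_l}, \code{j_gene_h}, \code{j_gene_l}).
#' Loop strings are upper-cased; letters outside the supported alphabet
#' are replaced by \code{X} with a warning.
#'
#' @param path CSV file path.
#' @param schema optional named character vector remapping expected column
#'   names to the names actually present in the file, e.g.
#'   \code{c(cdr3h = "CDRH3_AA")}.
#' @return data.frame with one row per record, loop columns normalised,
#'   a \code{label} column initialised to \code{"unknown"}.
#' @export
readRepertoire <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("input file is empty: ", path)
  if (!is.null(schema))
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        stop("schema column '", schema[[std]], "' not found in ", path)
      names(df)[names(df) == schema[[std]]] <- std
    }
  required <- c("id", .LOOP_NAMES)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  rec <- data.frame(id = df$id, stringsAsFactors = FALSE)
  replaced <- character()
  for (lp in .LOOP_NAMES) {
    s <- toupper(ifelse(is.na(df[[lp]]), "", df[[lp]]))
    nonstd <- grepl(sprintf("[^%sX]", paste(.AA_ORDER, collapse = "")), s)
    if (any(nonstd)) {
      replaced <- c(replaced, paste0(lp, ":", df$id[nonstd]))
      s <- vapply(s, function(x) {
        letters <- strsplit(x, "")[[1]]
        letters[!letters %in% c(.AA_ORDER, "X")] <- "X"
        paste(letters, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    rec[[lp]] <- s
  }
  if (length(replaced))
    warning("non-standard residues mapped to X in: ",
            paste(replaced, collapse = "; "))
  rec$reactivity_count <- if ("reactivity_count" %in% names(df))
    as.integer(df$reactivity_count) else NA_integer_
  rec$source <- if ("source" %in% names(df)) df$source else NA_character_
  for (g in c("v_gene_h", "v_gene_l", "j_gene_h", "j_gene_l"))
    rec[[g]] <- if (g %in% names(df)) df[[g]] else NA_character_
  rec$label <- factor(rep("unknown", nrow(rec)), levels = .LABEL_LEVELS)
  validateRepertoire(rec)
  rec
}

#' Validate a repertoire data.frame
#'
#' Checks the loop alphabet, reactivity-count range (0-7 ELISA panel) and
#' label levels. Called by the readers and the synthetic generator.
#'
#' @param records repertoire data.frame.
#' @return the records, invisibly, or an error.
#' @export
validateRepertoire <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(c("id", .LOOP_NAMES), names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  pat <- sprintf("^[%sX]*$", paste(.AA_ORDER, collapse = ""))
  for (lp in .LOOP_NAMES)
    if (!all(grepl(pat, records[[lp]])))
      stop("loop ", lp, " contains letters outside the supported alphabet")
  rc <- records$reactivity_count
  if (!is.null(rc) && any(!is.na(rc) & (rc < 0L | rc > 7L)))
    stop("reactivity_count outside the 0-7 panel range")
  invisible(records)
}

#' Assign polyreactivity labels from ELISA reactivity counts
#'
#' Two schemes: \code{"full"} labels a record polyreactive when it binds
#' two or more panel ligands, otherwise non-polyreactive; \code{"parsed"}
#' keeps only the strong phenotypes (4-7 ligands = polyreactive, 0 =
#' non-polyreactive) and marks counts 1-3 \code{excluded}.
#'
#' @param records repertoire data.frame with \code{reactivity_count} set.
#' @param scheme \code{"full"} or \code{"parsed"}.
#' @return records with the \code{label} factor filled in.
#' @export
assignPolyreactivityLabels <- function(records,
                                       scheme = c("full", "parsed")) {
  scheme <- match.arg(scheme)
  rc <- records$reactivity_count
  if (any(is.na(rc)))
    stop("reactivity_count must be set on every record")
  if (any(rc < 0L | rc > 7L))
    stop("reactivity_count outside the 0-7 panel range")
  lab <- if (scheme == "full") {
    ifelse(rc >= 2L, "polyreactive", "non_polyreactive")
  } else {
    ifelse(rc >= 4L, "polyreactive",
           ifelse(rc == 0L, "non_polyreactive", "excluded"))
  }
  records$label <- factor(lab, levels = .LABEL_LEVELS)
  records
}

#' Build the position-sensitive integer matrix for a repertoire
#'
#' Each record's six CDR loops are center-aligned into per-loop spans and
#' concatenated with zero buffers between spans. With \code{layout =
#' NULL} the span widths are set automatically to the longest observed
#' loop in each slot across \emph{all} records (both classes share one
#' coordinate system). Rows are ordered polyreactive block first, then
#' non-polyreactive, then any remaining labels.
#'
#' @param records repertoire data.frame (see [readRepertoire()]).
#' @param layout optional [MatrixLayout-class]; default auto.
#' @param bufferWidth buffer columns between loops when auto-building the
#'   layout (default 3).
#' @param dropExcluded drop records labeled \code{"excluded"} (default
#'   TRUE, matching the parsed-scheme convention).
#' @return an [EncodedMatrix-class].
#' @export
encodeRepertoire <- function(records, layout = NULL, bufferWidth = 3L,
                             dropExcluded = TRUE) {
  validateRepertoire(records)
  if (dropExcluded && "label" %in% names(records))
    records <- records[records$label != "excluded", , drop = FALSE]
  if (nrow(records) == 0L) stop("no records to encode")
  if (is.null(layout)) {
    widths <- vapply(.LOOP_NAMES,
                     function(lp) max(nchar(records[[lp]]), 1L), integer(1))
    layout <- makeLayout(widths, bufferWidth)
  }
  if (!identical(layout@segmentNames, .LOOP_NAMES) &&
      !setequal(layout@segmentNames, .LOOP_NAMES))
    stop("layout segments must be the six CDR loops")
  lab <- if ("label" %in% names(records))
    as.character(records$label) else rep("unknown", nrow(records))
  ord <- order(match(lab, .LABEL_LEVELS), seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  lab <- lab[ord]
  spans <- segmentSpans(layout)
  L <- totalLength(layout)
  values <- matrix(0L, nrow(records), L)
  for (k in seq_along(layout@segmentNames)) {
    lp <- layout@segmentNames[k]
    w <- layout@segmentWidths[k]
    cols <- (spans[k, 1L] + 1L):spans[k, 2L]
    seqs <- records[[lp]]
    values[, cols] <- t(vapply(seq_along(seqs),
      function(i) centerAlignSegment(seqs[i], w, id = records$id[i]),
      integer(w)))
  }
  new("EncodedMatrix",
      values = values, layout = layout,
      rowIds = as.character(records$id),
      rowLabels = factor(lab, levels = unique(c(.LABEL_LEVELS, lab))))
}

#' Decode an encoded matrix back to loop strings
#'
#' Inverse of [encodeRepertoire()] for records without non-standard
#' residues: strips the zero padding of each span and decodes codes back
#' to letters.
#'
#' @param em an [EncodedMatrix-class].
#' @return data.frame with \code{id} and one column per segment.
#' @export
decodeRepertoire <- function(em) {
  spans <- segmentSpans(em@layout)
  out <- data.frame(id = em@rowIds, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(spans))) {
    cols <- (spans[k, 1L] + 1L):spans[k, 2L]
    out[[em@layout@segmentNames[k]]] <- apply(
      em@values[, cols, drop = FALSE], 1L,
      function(r) paste(decodeResidue(r[r != 0L]), collapse = ""))
  }
  out
}

#' Map matrix columns to their segment
#'
#' @param layout a [MatrixLayout-class].
#' @return character vector of length [totalLength()] giving the segment
#'   name of each column, or \code{"buffer"}.
#' @export
columnSegments <- function(layout) {
  out <- rep("buffer", totalLength(layout))
  spans <- segmentSpans(layout)
  for (k in seq_len(nrow(spans)))
    out[(spans[k, 1L] + 1L):spans[k, 2L]] <- layout@segmentNames[k]
  out
}

#' Attach V/J gene calls from an AIRR-C rearrangement TSV
#'
#' Reads a community-standard rearrangement table (columns
#' \code{sequence_id}, \code{v_call}, \code{j_call}) and merges the calls
#' into the repertoire by record id. Chain is selected with
#' \code{chain = "heavy"} or \code{"light"}.
#'
#' @param records repertoire data.frame.
#' @param path AIRR TSV path.
#' @param chain which chain the rearrangement file describes.
#' @return records with \code{v_gene_h/j_gene_h} (or \code{_l}) filled.
#' @export
readAirrGeneCalls <- function(records, path, chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  if (!file.exists(path)) stop("AIRR file not found: ", path)
  airr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "v_call", "j_call")
  missing <- setdiff(need, names(airr))
  if (length(missing))
    stop("AIRR file lacks column(s): ", paste(missing, collapse = ", "))
  idx <- match(records$id, airr$sequence_id)
  suff <- if (chain == "heavy") "h" else "l"
  records[[paste0("v_gene_", suff)]] <- airr$v_call[idx]
  records[[paste0("j_gene_", suff)]] <- airr$j_call[idx]
  records
}

#' Gene-usage table per class, with frequency differences
#'
#' Tabulates gene calls within each of two classes, computes per-gene
#' frequencies (fraction of the class) and their difference, and flags
#' genes that appear in one class but stay below a display threshold
#' (default 2 percent) in the other.
#'
#' @param records labeled repertoire data.frame.
#' @param gene which gene-call column to tabulate (default
#'   \code{"v_gene_h"}).
#' @param classes the two labels to compare.
#' @param threshold display threshold as a fraction (default 0.02).
#' @return data.frame: gene, count/frequency per class, \code{freq_diff}
#'   (class A minus class B), and \code{below_threshold_in} flag.
#' @export
geneUsageTable <- function(records, gene = "v_gene_h",
                           classes = c("polyreactive", "non_polyreactive"),
                           threshold = 0.02) {
  calls <- records[[gene]]
  if (is.null(calls) || all(is.na(calls)))
    stop("no gene calls in column '", gene,
         "'; attach them with readAirrGeneCalls() from an AIRR-C TSV")
  keep <- records$label %in% classes & !is.na(calls)
  records <- records[keep, , drop = FALSE]
  calls <- calls[keep]
  genes <- sort(unique(calls))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  freqs <- list()
  for (cl in classes) {
    sub <- calls[records$label == cl]
    if (length(sub) == 0L) stop("class '", cl, "' has no gene calls")
    cnt <- as.integer(table(factor(sub, levels = genes)))
    out[[paste0("count_", cl)]] <- cnt
    freqs[[cl]] <- cnt / length(sub)
    out[[paste0("freq_", cl)]] <- freqs[[cl]]
  }
  out$freq_diff <- freqs[[classes[1]]] - freqs[[classes[2]]]
  out$below_threshold_in <- ifelse(
    freqs[[classes[1]]] > 0 & freqs[[classes[2]]] < threshold, classes[2],
    ifelse(freqs[[classes[2]]] > 0 & freqs[[classes[1]]] < threshold,
           classes[1], ""))
  out
}

#' Write an encoded matrix as CSV plus a JSON layout sidecar
#'
#' @param em an [EncodedMatrix-class].
#' @param csvPath output CSV of integer codes (one row per sequence).
#' @param jsonPath output JSON with layout, row ids and labels; default
#'   replaces the CSV extension.
#' @return invisibly, the two paths.
#' @export
writeEncodedMatrix <- function(em, csvPath,
                               jsonPath = sub("\\.csv$", ".json", csvPath)) {
  m <- em@values
  colnames(m) <- sprintf("%s:%d", columnSegments(em@layout),
                         seq_len(ncol(m)) - 1L)
  utils::write.csv(data.frame(id = em@rowIds, m, check.names = FALSE),
                   csvPath, row.names = FALSE)
  side <- list(
    segment_names  = em@layout@segmentNames,
    segment_widths = em@layout@segmentWidths,
    buffer_width   = em@layout@bufferWidth,
    row_ids        = em@rowIds,
    row_labels     = as.character(em@rowLabels))
  jsonlite::write_json(side, jsonPath, auto_unbox = FALSE, digits = NA)
  invisible(c(csvPath, jsonPath))
}

#' Read single-chain loop sequences from FASTA
#'
#' Convenience reader for single-loop lists (e.g. a CDR3H-only FASTA):
#' builds a repertoire data.frame with the chosen loop filled and the
#' other five empty.
#'
#' @param path FASTA file.
#' @param loop which loop the sequences represent (default
#'   \code{"cdr3h"}).
#' @return repertoire data.frame.
#' @export
readLoopFasta <- function(path, loop = "cdr3h") {
  loop <- match.arg(loop, .LOOP_NAMES)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA: ", path)
  rec <- data.frame(id = names(aas), stringsAsFactors = FALSE)
  for (lp in .LOOP_NAMES) rec[[lp]] <- ""
  rec[[loop]] <- toupper(as.character(aas))
  rec$reactivity_count <- NA_integer_
  rec$source <- "fasta"
  for (g in c("v_gene_h", "v_gene_l", "j_gene_h", "j_gene_l"))
    rec[[g]] <- NA_character_
  rec$label <- factor(rep("unknown", nrow(rec)), levels = .LABEL_LEVELS)
  validateRepertoire(rec)
  rec
}
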