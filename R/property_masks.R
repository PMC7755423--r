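# Ten Kidera factors (Kidera et al. 1985): orthogonal, standardized
# statistical descriptors of amino-acid physicochemical properties, as
# commonly redistributed. Rows in the package alphabet order are built
# from this letter-keyed table.
.KIDERA <- matrix(c(
  # kf1    kf2    kf3    kf4    kf5    kf6    kf7    kf8    kf9    kf10
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48, # A
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93, # R
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73, # N
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70, # D
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10, # C
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33, # Q
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12, # E
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46, # G
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63, # H
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78, # I
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93, # L
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60, # K
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27, # M
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44, # F
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28, # P
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23, # S
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19, # T
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60, # W
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53, # Y
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65  # V
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  paste0("kidera", 1:10)))

# Structural-propensity ("hotspot") masks, reconstructed from AAindex
# scales shipped with seqinr. hotspot6 is an alpha-helix propensity
# (Chou-Fasman), matching the role that variable plays in the default
# mask set.
.HOTSPOT_ACCESSIONS <- c(
  "BEGF750101", "BEGF750102", "BEGF750103", "BURA740101", "CHAM830101",
  "CHOP780201", "CHOP780202", "CHOP780203", "CHOP780101", "CHOP780204",
  "CHOP780205", "CHOP780208", "CHOP780209", "CRAJ730101", "CRAJ730102",
  "CRAJ730103", "GEIM800101", "GEIM800102", "GEIM800103", "GEIM800104",
  "ISOY800101", "ISOY800103", "ISOY800104", "ISOY800105", "ISOY800106",
  "ISOY800107", "ISOY800108", "KANM800101", "KANM800102", "KANM800103",
  "KANM800104", "LEVM780101", "LEVM780102", "LEVM780103", "LEVM780104",
  "LEVM780105", "LEVM780106", "LEWP710101", "LIFS790101", "LIFS790102",
  "LIFS790103", "MAXF760101", "NAGK730101", "NAGK730103", "PALJ810101",
  "PALJ810102", "PALJ810103")

.DEFAULT_PKA <- c(D = 3.65, E = 4.25, H = 6.0, C = 8.3,
                  Y = 10.07, K = 10.53, R = 12.48)

.pkgCache <- new.env(parent = emptyenv())

#' Fractional side-chain charge at a given pH
#'
#' Henderson-Hasselbalch fractional protonation of the ionizable side
#' chains: basic residues (H, K, R) carry \code{+1/(1 + 10^(pH - pKa))},
#' acidic/deprotonatable residues (D, E, C, Y) carry
#' \code{-1/(1 + 10^(pKa - pH))}, all others 0. With the default pKa
#' table at pH 7 this reproduces the anchor values 0.00 (L), 0.091 (H)
#' and 1.00 (R) after 3-decimal rounding.
#'
#' @param residue character vector of one-letter residues.
#' @param pH solution pH (default 7.0).
#' @param pKaTable named numeric vector of side-chain pKa values.
#' @return signed fractional charge per residue.
#' @examples
#' round(chargeAtPH(c("L", "H", "R")), 3)
#' @export
chargeAtPH <- function(residue, pH = 7.0, pKaTable = .DEFAULT_PKA) {
  residue <- toupper(residue)
  unknown <- !residue %in% c(.AA_ORDER, "X")
  if (any(unknown))
    stop("unknown residue(s): ", paste(unique(residue[unknown]),
                                       collapse = ", "))
  out <- numeric(length(residue))
  basic <- intersect(names(pKaTable), c("H", "K", "R"))
  acidic <- setdiff(names(pKaTable), basic)
  ib <- residue %in% basic
  out[ib] <- 1 / (1 + 10^(pH - pKaTable[residue[ib]]))
  ia <- residue %in% acidic
  out[ia] <- -1 / (1 + 10^(pKaTable[residue[ia]] - pH))
  out
}

.aaindexScale <- function(accession) {
  if (is.null(.pkgCache$aaindex)) {
    env <- new.env()
    utils::data("aaindex", package = "seqinr", envir = env)
    .pkgCache$aaindex <- env$aaindex
  }
  entry <- .pkgCache$aaindex[[accession]]
  if (is.null(entry)) stop("AAindex accession not found: ", accession)
  v <- entry$I
  names(v) <- vapply(names(v), seqinr::a, character(1))
  v[.AA_ORDER]
}

.rescaleUnit <- function(v) 2 * (v - min(v)) / (max(v) - min(v)) - 1

.zscore20 <- function(v) (v - mean(v)) / stats::sd(v)

#' The default 62-mask biophysical property set
#'
#' Builds the default [PropertySet-class] of 62 masks: five basic
#' properties (\code{hydrophobicity1}: Kyte-Doolittle hydropathy rescaled
#' to [-1, 1]; \code{charge}: Henderson-Hasselbalch fractional charge at
#' pH 7 (see [chargeAtPH()]); \code{hydrophobicity2}: Eisenberg consensus
#' hydrophobicity rescaled to [-1, 1]; \code{flexibility}: Vihinen
#' normalized B-value flexibility; \code{bulk}: Zimmerman bulkiness), the
#' ten published Kidera factors, and 47 structural-propensity "hotspot"
#' masks (helix/sheet/turn propensity scales, z-scored over the 20
#' residues); \code{hotspot6} is Chou-Fasman alpha-helix propensity.
#' Code 21 (X) is 0 under every mask.
#'
#' @return a [PropertySet-class] with 62 properties.
#' @examples
#' length(propertyNames(defaultPropertySet()))
#' @export
defaultPropertySet <- function() {
  if (!is.null(.pkgCache$defaultProps)) return(.pkgCache$defaultProps)
  basic <- cbind(
    hydrophobicity1 = .rescaleUnit(.aaindexScale("KYTJ820101")),
    charge          = chargeAtPH(.AA_ORDER),
    hydrophobicity2 = .rescaleUnit(.aaindexScale("EISD840101")),
    flexibility     = .aaindexScale("VINM940101"),
    bulk            = .aaindexScale("ZIMJ680102"))
  kidera <- .KIDERA[.AA_ORDER, ]
  hotspot <- vapply(.HOTSPOT_ACCESSIONS,
                    function(a) .zscore20(.aaindexScale(a)), numeric(20))
  colnames(hotspot) <- paste0("hotspot", seq_along(.HOTSPOT_ACCESSIONS))
  vals20 <- cbind(basic, kidera, hotspot)
  values <- rbind(vals20, X = 0)
  rownames(values) <- c(.AA_ORDER, "X")
  meta <- data.frame(
    property = colnames(values),
    category = c(rep("basic", 5), rep("kidera", 10),
                 rep("hotspot", length(.HOTSPOT_ACCESSIONS))),
    description = c(
      "Kyte-Doolittle hydropathy, rescaled to [-1,1]",
      "Henderson-Hasselbalch fractional side-chain charge at pH 7",
      "Eisenberg consensus hydrophobicity, rescaled to [-1,1]",
      "Vihinen normalized flexibility (B-values)",
      "Zimmerman bulkiness",
      paste("Kidera factor", 1:10),
      paste0("structural propensity (AAindex ", .HOTSPOT_ACCESSIONS,
             "), z-scored")),
    stringsAsFactors = FALSE)
  ps <- new("PropertySet", values = values, metadata = meta)
  .pkgCache$defaultProps <- ps
  ps
}

#' Load a custom property table from CSV
#'
#' The CSV's first column holds the one-letter residue; every remaining
#' column is one property. All 20 standard residues must be present; an
#' \code{X} row is optional (0 is imputed when absent).
#'
#' @param path CSV file path.
#' @param category category recorded in the metadata (default
#'   \code{"custom"}).
#' @return a [PropertySet-class].
#' @export
loadPropertyTable <- function(path, category = "custom") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  res <- toupper(df[[1]])
  missing <- setdiff(.AA_ORDER, res)
  if (length(missing))
    stop("property table lacks residue row(s): ",
         paste(missing, collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- res
  out <- matrix(0, 21L, ncol(vals),
                dimnames = list(c(.AA_ORDER, "X"), colnames(vals)))
  out[res[res %in% rownames(out)], ] <- vals[res[res %in% rownames(out)], ]
  meta <- data.frame(property = colnames(out),
                     category = category,
                     description = paste("loaded from", basename(path)),
                     stringsAsFactors = FALSE)
  new("PropertySet", values = out, metadata = meta)
}

#' Apply a biophysical property mask to an encoded matrix
#'
#' Replaces every residue code by the property value of that residue;
#' buffer/padding zeros stay 0. If any code-21 (X) entries are present a
#' message notes the neutral imputation.
#'
#' @param em an [EncodedMatrix-class].
#' @param property property name.
#' @param table a [PropertySet-class] (default [defaultPropertySet()]).
#' @return a [MaskedMatrix-class].
#' @examples
#' # a row encoding L, H, R under the charge mask -> 0.00, 0.091, 1.00
#' @export
applyMask <- function(em, property, table = defaultPropertySet()) {
  avail <- propertyNames(table)
  if (!property %in% avail)
    stop("unknown property '", property, "'; available: ",
         paste(avail, collapse = ", "))
  if (any(em@values == 21L))
    message("code-21 (X) residues present; value 0 imputed under mask '",
            property, "'")
  lut <- c(0, propertyValues(table)[, property])
  masked <- matrix(lut[em@values + 1L], nrow(em@values), ncol(em@values))
  new("MaskedMatrix", values = masked, property = property,
      layout = em@layout, rowIds = em@rowIds, rowLabels = em@rowLabels)
}

#' Build a flattened position-by-property feature matrix
#'
#' Concatenates the masked matrices of the chosen properties column-wise,
#' giving one feature per (property, matrix column) pair, named
#' \code{"property@column"} (0-based column index). With
#' \code{standardize = TRUE} every column is z-scored (constant columns
#' map to 0); the standardization parameters are stored as attributes
#' \code{"center"} and \code{"scale"}.
#'
#' @param em an [EncodedMatrix-class].
#' @param properties character vector of property names.
#' @param table a [PropertySet-class].
#' @param standardize z-score columns (default TRUE).
#' @return numeric matrix N x (L * P) with attribute \code{"labels"}
#'   carrying the row labels.
#' @export
buildFeatureMatrix <- function(em, properties, table = defaultPropertySet(),
                               standardize = TRUE) {
  if (length(properties) < 1L) stop("at least one property required")
  blocks <- lapply(properties, function(p) {
    mm <- applyMask(em, p, table)@values
    colnames(mm) <- paste0(p, "@", seq_len(ncol(mm)) - 1L)
    mm
  })
  feat <- do.call(cbind, blocks)
  rownames(feat) <- em@rowIds
  if (standardize) {
    std <- standardizeColumns(feat)
    feat <- std$x
    attr(feat, "center") <- std$center
    attr(feat, "scale") <- std$scale
  }
  attr(feat, "labels") <- em@rowLabels
  feat
}

#' Z-score the columns of a matrix
#'
#' Constant columns are mapped to 0 (their scale is recorded as 1).
#'
#' @param x numeric matrix.
#' @param center,scale optional pre-computed parameters (used to apply a
#'   training-set standardization to held-out rows).
#' @return list with \code{x}, \code{center}, \code{scale}.
#' @export
standardizeColumns <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  list(x = z, center = center, scale = scale)
}
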