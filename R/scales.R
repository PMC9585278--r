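## Amino-acid property scales shipped with the package. Values are from
## the primary literature for each scale:
##   ECI  electronic charge index (Collantes & Dunn, 1995)
##   GVO  residue molecular volume, A^3 (Zamyatnin, 1972)
##   HWH  Hopp-Woods hydrophilicity (Hopp & Woods, 1981)
##   KDH  Kyte-Doolittle hydropathy (Kyte & Doolittle, 1982)
## Additional scales can be supplied as named 20-vectors.

.CODES20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")

.SCALES <- list(
  ECI = c(ALA = 0.05, ARG = 1.69, ASN = 1.31, ASP = 1.25, CYS = 0.15,
          GLN = 1.36, GLU = 1.31, GLY = 0.02, HIS = 0.56, ILE = 0.09,
          LEU = 0.10, LYS = 0.53, MET = 0.34, PHE = 0.14, PRO = 0.16,
          SER = 0.56, THR = 0.65, TRP = 1.08, TYR = 0.72, VAL = 0.05),
  GVO = c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
          GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
          LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
          SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0),
  HWH = c(ALA = -0.5, ARG = 3.0, ASN = 0.2, ASP = 3.0, CYS = -1.0,
          GLN = 0.2, GLU = 3.0, GLY = 0.0, HIS = -0.5, ILE = -1.8,
          LEU = -1.8, LYS = 3.0, MET = -1.3, PHE = -2.5, PRO = 0.0,
          SER = 0.3, THR = -0.4, TRP = -3.4, TYR = -2.3, VAL = -1.5),
  KDH = c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
          GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
          LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
          SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2))

## property-token aliases seen in published descriptor names
.SCALE_ALIASES <- c(KDS = "KDH")

#' Shipped amino-acid property scales
#'
#' Four scales are bundled: \code{ECI} (electronic charge index),
#' \code{GVO} (residue molecular volume, cubic Angstrom), \code{HWH}
#' (Hopp-Woods hydrophilicity) and \code{KDH} (Kyte-Doolittle hydropathy;
#' token \code{KDS} is accepted as an alias). Each is a named numeric
#' vector over the 20 standard 3-letter residue codes.
#'
#' @param scaleId optional id; if missing, the full list is returned.
#' @return a named numeric 20-vector, or the list of all scales.
#' @export
#' @examples
#' propertyScales("KDH")[["TRP"]]
propertyScales <- function(scaleId) {
  if (missing(scaleId)) return(.SCALES)
  scaleId <- toupper(scaleId)
  if (scaleId %in% names(.SCALE_ALIASES)) scaleId <- .SCALE_ALIASES[[scaleId]]
  if (!scaleId %in% names(.SCALES))
    stop("unknown property scale '", scaleId, "'")
  .SCALES[[scaleId]]
}

#' Build a per-residue property vector
#'
#' Looks each residue code up in a property scale. Common modified codes
#' (e.g. MSE) map to their standard parent before lookup.
#'
#' @param residueCodes character vector of 3-letter codes.
#' @param scale a scale id (see \code{\link{propertyScales}}) or a named
#'   numeric vector covering the 20 standard codes.
#' @return numeric vector, one value per residue.
#' @export
propertyVector <- function(residueCodes, scale = "ECI") {
  if (is.character(scale) && length(scale) == 1L)
    scale <- propertyScales(scale)
  if (!is.numeric(scale) || length(scale) != 20L ||
      !all(.CODES20 %in% names(scale)) || any(!is.finite(scale)))
    stop("scale must be a finite named numeric vector over the 20 codes")
  unname(scale[.standardizeCode(residueCodes)])
}
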