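#' @import methods
NULL

#' ResiduePointSet: one 3D point per residue
#'
#' A protein reduced to a single coordinate per residue under one of the
#' four spatial representations: \code{"CA"} (alpha carbon), \code{"CB"}
#' (beta carbon, alpha carbon for glycine), \code{"AB"} (backbone amide-bond
#' midpoint) or \code{"AVG"} (heavy-atom centroid).
#'
#' @slot coords numeric matrix, n x 3, coordinates in Angstrom.
#' @slot residueIds data.frame with columns \code{chain}, \code{resno},
#'   \code{resid} (3-letter code), one row per residue in chain order then
#'   ascending sequence position.
#' @slot representation character scalar, one of CA/CB/AB/AVG.
#'
#' @exportClass ResiduePointSet
setClass("ResiduePointSet",
  representation(coords = "matrix",
                 residueIds = "data.frame",
                 representation = "character"))

setValidity("ResiduePointSet", function(object) {
  msg <- NULL
  n <- nrow(object@coords)
  if (n < 2L) msg <- c(msg, "need at least 2 residues")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (any(!is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  if (nrow(object@residueIds) != n)
    msg <- c(msg, "residueIds rows must match coords rows")
  if (!all(c("chain", "resno", "resid") %in% names(object@residueIds)))
    msg <- c(msg, "residueIds needs chain, resno, resid columns")
  if (length(object@representation) != 1L ||
      !object@representation %in% c("CA", "CB", "AB", "AVG"))
    msg <- c(msg, "representation must be one of CA, CB, AB, AVG")
  if (is.null(msg)) TRUE else msg
})

#' SphericalFrame: the sphere a protein is embedded in
#'
#' Geometric centre (arithmetic mean of the residue points), per-residue
#' Euclidean distances to that centre, and the spherical radius R (the
#' distance of the outermost residue).
#'
#' @slot center numeric length-3 coordinate of the geometric centre.
#' @slot radius numeric scalar, max of \code{centerDistances}.
#' @slot centerDistances numeric vector of per-residue distances (Angstrom).
#'
#' @exportClass SphericalFrame
setClass("SphericalFrame",
  representation(center = "numeric",
                 radius = "numeric",
                 centerDistances = "numeric"))

setValidity("SphericalFrame", function(object) {
  msg <- NULL
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (any(object@centerDistances < 0))
    msg <- c(msg, "negative center distance")
  if (length(object@centerDistances) &&
      !isTRUE(all.equal(object@radius, max(object@centerDistances))))
    msg <- c(msg, "radius must equal max(centerDistances)")
  if (is.null(msg)) TRUE else msg
})

#' TruncationSpec: a truncation function bound to a distance interval
#'
#' Identifies one of the 16 truncation functions (13 fuzzy membership
#' functions + 3 molecular-dynamics smoothing functions) or \code{"NONE"},
#' the (r_on, r_off) interval as fractions of the spherical radius, and the
#' fusion rule combining the memberships of the residues in a tuple.
#'
#' @slot functionId character, see \code{\link{truncationFunctions}}.
#' @slot rOn,rOff numeric fractions of R, 0 <= rOn < rOff <= 1.
#' @slot fusion one of \code{"ARITHMETIC_MEAN"}, \code{"MIN"}, \code{"MAX"}.
#'
#' @exportClass TruncationSpec
setClass("TruncationSpec",
  representation(functionId = "character",
                 rOn = "numeric",
                 rOff = "numeric",
                 fusion = "character"),
  prototype(functionId = "NONE", rOn = 0, rOff = 1,
            fusion = "ARITHMETIC_MEAN"))

setValidity("TruncationSpec", function(object) {
  msg <- NULL
  if (!object@functionId %in% c(truncationFunctions(), "NONE"))
    msg <- c(msg, paste0("unknown truncation function '",
                         object@functionId, "'"))
  if (object@rOn < 0 || object@rOn >= 1) msg <- c(msg, "rOn must be in [0,1)")
  if (object@rOff <= 0 || object@rOff > 1) msg <- c(msg, "rOff must be in (0,1]")
  if (object@rOn >= object@rOff) msg <- c(msg, "rOn must be < rOff")
  if (!object@fusion %in% c("ARITHMETIC_MEAN", "MIN", "MAX"))
    msg <- c(msg, "fusion must be ARITHMETIC_MEAN, MIN or MAX")
  if (is.null(msg)) TRUE else msg
})

#' SimilarityTensor: two- or three-tuple inter-residue (dis)similarity array
#'
#' Holds an n x n matrix (order 2) or n x n x n array (order 3) of
#' (dis)similarity coefficients z_ij / z_ijl together with provenance: the
#' metric, the Hadamard exponent k, the normalization scheme and the ordered
#' list of filters already applied (truncation, lag, group).
#'
#' @slot values numeric array, n^order entries.
#' @slot order integer, 2 or 3 (tuple size).
#' @slot k integer Hadamard exponent (may be negative).
#' @slot normalization one of \code{"NS"}, \code{"SS"}, \code{"MP"}.
#' @slot metricId character id of the metric/multi-metric.
#' @slot filters list of provenance records, in application order.
#'
#' @exportClass SimilarityTensor
setClass("SimilarityTensor",
  representation(values = "array",
                 order = "integer",
                 k = "integer",
                 normalization = "character",
                 metricId = "character",
                 filters = "list"))

setValidity("SimilarityTensor", function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (!object@order %in% c(2L, 3L)) msg <- c(msg, "order must be 2 or 3")
  if (length(d) != object@order || length(unique(d)) != 1L)
    msg <- c(msg, "values must be a square array of dimension = order")
  if (!object@normalization %in% c("NS", "SS", "MP"))
    msg <- c(msg, "normalization must be NS, SS or MP")
  if (is.null(msg)) TRUE else msg
})

#' DescriptorTable: proteins x named descriptors
#'
#' @slot values numeric matrix, rows = proteins, columns = descriptors with
#'   names generated by the deterministic naming grammar.
#' @slot metadata list (configuration digest, package version, notes).
#'
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(values = "matrix", metadata = "list"),
  prototype(metadata = list()))

setValidity("DescriptorTable", function(object) {
  if (is.null(colnames(object@values)))
    "descriptor columns must be named" else TRUE
})
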