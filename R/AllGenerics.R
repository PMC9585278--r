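#' Accessors for ProtSphere classes
#'
#' Small accessor generics: \code{coords} and \code{residueIds} on a
#' \linkS4class{ResiduePointSet}; \code{sphereCenter}, \code{sphereRadius}
#' and \code{centerDistances} on a \linkS4class{SphericalFrame};
#' \code{tensorValues} and \code{tensorOrder} on a
#' \linkS4class{SimilarityTensor}; \code{descriptorValues} on a
#' \linkS4class{DescriptorTable}.
#'
#' @param x object to access.
#' @return The slot contents (matrix, data.frame or numeric, as documented
#'   on each class).
#' @name accessors
#' @aliases coords residueIds nResidues representation2 sphereCenter
#'   sphereRadius centerDistances tensorValues tensorOrder descriptorValues
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("pointRepresentation",
           function(x) standardGeneric("pointRepresentation"))
#' @rdname accessors
#' @export
setGeneric("sphereCenter", function(x) standardGeneric("sphereCenter"))
#' @rdname accessors
#' @export
setGeneric("sphereRadius", function(x) standardGeneric("sphereRadius"))
#' @rdname accessors
#' @export
setGeneric("centerDistances", function(x) standardGeneric("centerDistances"))
#' @rdname accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))
#' @rdname accessors
#' @export
setGeneric("tensorOrder", function(x) standardGeneric("tensorOrder"))
#' @rdname accessors
#' @export
setGeneric("descriptorValues",
           function(x) standardGeneric("descriptorValues"))

#' @rdname accessors
setMethod("coords", "ResiduePointSet", function(x) x@coords)
#' @rdname accessors
setMethod("residueIds", "ResiduePointSet", function(x) x@residueIds)
#' @rdname accessors
setMethod("nResidues", "ResiduePointSet", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("pointRepresentation", "ResiduePointSet",
          function(x) x@representation)
#' @rdname accessors
setMethod("sphereCenter", "SphericalFrame", function(x) x@center)
#' @rdname accessors
setMethod("sphereRadius", "SphericalFrame", function(x) x@radius)
#' @rdname accessors
setMethod("centerDistances", "SphericalFrame", function(x) x@centerDistances)
#' @rdname accessors
setMethod("tensorValues", "SimilarityTensor", function(x) x@values)
#' @rdname accessors
setMethod("tensorOrder", "SimilarityTensor", function(x) x@order)
#' @rdname accessors
setMethod("descriptorValues", "DescriptorTable", function(x) x@values)

setMethod("show", "ResiduePointSet", function(object) {
  cat("ResiduePointSet:", nrow(object@coords), "residues,",
      object@representation, "representation\n")
  cat("  chains:", paste(unique(object@residueIds$chain), collapse = " "),
      "\n")
})

setMethod("show", "SphericalFrame", function(object) {
  cat(sprintf("SphericalFrame: center (%.3f, %.3f, %.3f), R = %.3f A, %d residues\n",
              object@center[1], object@center[2], object@center[3],
              object@radius, length(object@centerDistances)))
})

setMethod("show", "TruncationSpec", function(object) {
  cat(sprintf("TruncationSpec: %s[%g-%g], fusion %s\n", object@functionId,
              object@rOn, object@rOff, object@fusion))
})

setMethod("show", "SimilarityTensor", function(object) {
  cat(sprintf("SimilarityTensor: order %d, n = %d, metric %s, k = %d, %s\n",
              object@order, dim(object@values)[1], object@metricId,
              object@k, object@normalization))
  if (length(object@filters))
    cat("  filters:", paste(vapply(object@filters, `[[`, "", "type"),
                            collapse = " -> "), "\n")
})

setMethod("show", "DescriptorTable", function(object) {
  cat("DescriptorTable:", nrow(object@values), "proteins x",
      ncol(object@values), "descriptors\n")
})
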