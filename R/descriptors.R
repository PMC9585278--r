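## Amino-acid-level bilinear/trilinear algebraic forms weighted by
## property vectors, the per-spec descriptor pipeline, and the global
## descriptor table.

#' DescriptorSpec: the full recipe for one descriptor family
#'
#' @slot representation one of CA/CB/AB/AVG.
#' @slot form \code{"Q"} (two-linear, order-2 tensor) or \code{"T"}
#'   (three-linear, order-3 tensor).
#' @slot metricId metric (form Q) or multi-metric (form T) id.
#' @slot normalization NS, SS or MP.
#' @slot k integer Hadamard exponent.
#' @slot truncation a \linkS4class{TruncationSpec}.
#' @slot lagTopological,lagGeometric inclusive lag windows (length-2
#'   numeric, or length-0 when absent).
#' @slot group group id or explicit residue codes (length-0 = total).
#' @slot properties property-scale ids for the x, y (and p, form T)
#'   weight vectors.
#' @slot aggregations operator ids, one descriptor column each.
#' @slot flags opaque name tokens carried through parsing (e.g. "o").
#'
#' @exportClass DescriptorSpec
setClass("DescriptorSpec",
  representation(representation = "character", form = "character",
                 metricId = "character", normalization = "character",
                 k = "integer", truncation = "TruncationSpec",
                 lagTopological = "numeric", lagGeometric = "numeric",
                 group = "character", properties = "character",
                 aggregations = "character", flags = "character"))

setValidity("DescriptorSpec", function(object) {
  msg <- NULL
  if (!object@representation %in% c("CA", "CB", "AB", "AVG"))
    msg <- c(msg, "bad representation")
  if (!object@form %in% c("Q", "T")) msg <- c(msg, "form must be Q or T")
  if (!object@normalization %in% c("NS", "SS", "MP"))
    msg <- c(msg, "bad normalization")
  need <- if (object@form == "Q") 2L else 3L
  if (length(object@properties) != need)
    msg <- c(msg, sprintf("form %s needs %d property ids", object@form,
                          need))
  if (length(object@aggregations) == 0L ||
      !all(object@aggregations %in% .AGG_IDS))
    msg <- c(msg, "unknown aggregation operator")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DescriptorSpec
#'
#' @param representation spatial representation (CA/CB/AB/AVG).
#' @param form "Q" for two-linear (pairwise tensor), "T" for three-linear.
#' @param metric metric or multi-metric id (see \code{\link{metricIds}}).
#' @param normalization NS, SS or MP.
#' @param k integer Hadamard exponent.
#' @param truncation a \linkS4class{TruncationSpec} (default: no
#'   truncation).
#' @param lagTopological,lagGeometric optional inclusive lag windows.
#' @param group optional group id or residue-code vector.
#' @param properties property-scale ids for x, y (and p when form = "T");
#'   a single id is recycled.
#' @param aggregations aggregation operator ids.
#' @param flags opaque name tokens (carried, not interpreted).
#' @return a \linkS4class{DescriptorSpec}.
#' @export
descriptorSpec <- function(representation = "CA", form = "Q",
                           metric = "EUCLIDEAN", normalization = "NS",
                           k = 1L, truncation = truncationSpec(),
                           lagTopological = NULL, lagGeometric = NULL,
                           group = NULL, properties = "ECI",
                           aggregations = "N1", flags = character(0)) {
  need <- if (form == "Q") 2L else 3L
  if (length(properties) == 1L) properties <- rep(properties, need)
  properties <- toupper(properties)
  hit <- properties %in% names(.SCALE_ALIASES)
  properties[hit] <- .SCALE_ALIASES[properties[hit]]
  new("DescriptorSpec", representation = representation, form = form,
      metricId = .resolveMetric(metric, if (form == "Q") 2 else 3),
      normalization = normalization, k = as.integer(k),
      truncation = truncation,
      lagTopological = as.numeric(lagTopological %||% numeric(0)),
      lagGeometric = as.numeric(lagGeometric %||% numeric(0)),
      group = as.character(group %||% character(0)),
      properties = toupper(properties),
      aggregations = toupper(aggregations), flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinear form of an aa-level matrix
#'
#' Computes the two-linear algebraic map sum_ij Z[i,j] x_i y_j.
#'
#' @param Z numeric n x n matrix.
#' @param x,y numeric property vectors of length n.
#' @return scalar.
#' @export
bilinearForm <- function(Z, x, y) {
  if (!is.matrix(Z) || nrow(Z) != ncol(Z))
    stop("Z must be a square matrix")
  if (length(x) != nrow(Z) || length(y) != nrow(Z))
    stop("dimension mismatch between Z and property vectors")
  as.numeric(crossprod(x, Z %*% y))
}

#' Trilinear form of an aa-level tensor
#'
#' Computes the three-linear algebraic map sum_ijl Z[i,j,l] x_i y_j p_l.
#'
#' @param Z numeric n x n x n array.
#' @param x,y,p numeric property vectors of length n.
#' @return scalar.
#' @export
trilinearForm <- function(Z, x, y, p) {
  d <- dim(Z)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("Z must be a cubic array")
  n <- d[1]
  if (length(x) != n || length(y) != n || length(p) != n)
    stop("dimension mismatch between Z and property vectors")
  ## contract the third index first, then the remaining matrix
  M <- matrix(as.numeric(Z), n * n, n) %*% p
  as.numeric(crossprod(x, matrix(M, n, n) %*% y))
}

## run one DescriptorSpec on one structure record -> named descriptor
## values (one per aggregation operator)
.computeOne <- function(structure, spec) {
  pts <- projectRepresentation(structure, spec@representation)
  frame <- sphericalFrame(pts)
  tensor <- if (spec@form == "Q") twoTupleTensor(pts, spec@metricId)
            else threeTupleTensor(pts, spec@metricId)
  tensor <- applySphericalTruncation(tensor, frame, spec@truncation)
  if (length(spec@lagTopological) || length(spec@lagGeometric))
    tensor <- applyLagFilter(tensor, pts,
      topological = if (length(spec@lagTopological)) spec@lagTopological,
      geometric = if (length(spec@lagGeometric)) spec@lagGeometric)
  if (length(spec@group))
    tensor <- groupRestrict(tensor, spec@group, residueIds(pts)$resid)
  tensor <- normalizeTensor(tensor, spec@normalization)
  tensor <- hadamardPower(tensor, spec@k)

  codes <- residueIds(pts)$resid
  pv <- lapply(spec@properties, function(s) propertyVector(codes, s))
  n <- nResidues(pts)
  lai <- vapply(seq_len(n), function(a) {
    Za <- tensorValues(aaLevelTensor(tensor, a))
    if (spec@form == "Q") bilinearForm(Za, pv[[1]], pv[[2]])
    else trilinearForm(Za, pv[[1]], pv[[2]], pv[[3]])
  }, numeric(1))
  vapply(spec@aggregations, function(op)
    suppressWarnings(aggregateLAI(lai, op)), numeric(1))
}

#' Compute a descriptor table
#'
#' Runs every \linkS4class{DescriptorSpec} on every structure through the
#' fixed pipeline (representation projection, spherical frame, order-1
#' tensor, spherical truncation, lag filter, group restriction,
#' normalization, Hadamard power, per-residue forms, aggregation) and
#' assembles the proteins x descriptors matrix. A failure on an individual
#' protein produces NA cells for that protein (with a warning), not an
#' abort. Columns are named by the deterministic grammar of
#' \code{\link{descriptorName}} and ordered spec by spec; reruns on the
#' same input are bit-identical.
#'
#' @param structures named list of structure records from
#'   \code{\link{readStructure}} (or character paths to PDB files, read on
#'   the fly).
#' @param specs a \linkS4class{DescriptorSpec}, a list of them, or a
#'   project configuration list from \code{\link{readProjectConfig}}.
#' @return a \linkS4class{DescriptorTable}.
#' @export
computeDescriptors <- function(structures, specs) {
  if (is(specs, "DescriptorSpec")) specs <- list(specs)
  if (!is.list(structures) || is.null(names(structures)) ||
      !length(structures))
    stop("structures must be a non-empty named list")
  structures <- lapply(structures, function(s)
    if (is.character(s)) readStructure(s) else s)
  colNames <- unlist(lapply(specs, function(sp)
    vapply(sp@aggregations, function(op)
      descriptorName(sp, aggregation = op), character(1))))
  if (anyDuplicated(colNames))
    stop("duplicate descriptor names in configuration")
  vals <- matrix(NA_real_, length(structures), length(colNames),
                 dimnames = list(names(structures), colNames))
  for (q in seq_along(structures)) {
    col <- 1L
    for (sp in specs) {
      nagg <- length(sp@aggregations)
      res <- tryCatch(.computeOne(structures[[q]], sp), error = function(e) {
        warning("protein '", names(structures)[q], "': ",
                conditionMessage(e), " (cells set to NA)")
        rep(NA_real_, nagg)
      })
      vals[q, col:(col + nagg - 1L)] <- res
      col <- col + nagg
    }
  }
  new("DescriptorTable", values = vals,
      metadata = list(package = "ProtSphere",
                      version = as.character(utils::packageVersion("ProtSphere")),
                      nSpecs = length(specs)))
}

#' Write a descriptor table to CSV/TSV
#'
#' Prepends a commented metadata block (package version, spec count) and
#' writes proteins as rows.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param file output path.
#' @param sep \code{","} or \code{"\t"}.
#' @export
writeDescriptorTable <- function(table, file, sep = ",") {
  stopifnot(is(table, "DescriptorTable"))
  meta <- sprintf("# %s = %s", names(table@metadata),
                  unlist(table@metadata))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- data.frame(protein = rownames(table@values), table@values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}
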