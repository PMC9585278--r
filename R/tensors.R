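## Two-tuple and three-tuple spatial (dis)similarity tensors and their
## transformations: spherical truncation, lag and group filters,
## NS/SS/MP normalization, Hadamard powers, and the per-residue split.
##
## Fixed pipeline order (enforced, not rearranged): order-1 tensor ->
## spherical truncation -> lag filter -> group restriction ->
## normalization -> Hadamard power.

.METRICS <- c("EUCLIDEAN", "MANHATTAN", "CHEBYSHEV", "MINKOWSKI",
              "CANBERRA", "BRAY_CURTIS", "COSINE", "TANIMOTO")
.MULTIMETRICS <- c("AREA", "PERIMETER", "BOND_ANGLE", "DIST_SUM")

## numeric-code aliases for the metric tokens found in descriptor names;
## user-extensible through the alias argument of parseDescriptorName
.METRIC_ALIASES <- c(M1 = "EUCLIDEAN", M2 = "MANHATTAN", M3 = "CHEBYSHEV",
                     M4 = "MINKOWSKI", M5 = "CANBERRA", M6 = "BRAY_CURTIS",
                     M7 = "COSINE", M8 = "TANIMOTO",
                     M24 = "EUCLIDEAN", M32 = "AREA")

#' Implemented (multi-)metrics
#'
#' @param order 2 for pairwise metrics on two 3D coordinates, 3 for
#'   multi-metrics on coordinate triples.
#' @return character vector of stable metric ids.
#' @export
metricIds <- function(order = 2) {
  if (order == 2) .METRICS else if (order == 3) .MULTIMETRICS
  else stop("order must be 2 or 3")
}

.pairMetric <- function(id, p = 2) {
  switch(id,
    EUCLIDEAN = function(u, v) sqrt(sum((u - v)^2)),
    MANHATTAN = function(u, v) sum(abs(u - v)),
    CHEBYSHEV = function(u, v) max(abs(u - v)),
    MINKOWSKI = function(u, v) sum(abs(u - v)^p)^(1 / p),
    CANBERRA  = function(u, v) {
      den <- abs(u) + abs(v)
      num <- abs(u - v)
      sum(ifelse(den == 0, 0, num / den))
    },
    BRAY_CURTIS = function(u, v) {
      den <- sum(abs(u + v))
      if (den == 0) 0 else sum(abs(u - v)) / den
    },
    COSINE = function(u, v) {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) 0 else 1 - sum(u * v) / (nu * nv)
    },
    TANIMOTO = function(u, v) {
      den <- sum(u^2) + sum(v^2) - sum(u * v)
      if (den == 0) 0 else 1 - sum(u * v) / den
    },
    stop("unknown metric '", id, "'"))
}

.tripleMetric <- function(id) {
  switch(id,
    AREA = function(u, v, w)
      0.5 * sqrt(sum(.cross3(v - u, w - u)^2)),
    PERIMETER = function(u, v, w)
      sqrt(sum((u - v)^2)) + sqrt(sum((v - w)^2)) + sqrt(sum((w - u)^2)),
    BOND_ANGLE = function(u, v, w) {   # angle at the middle vertex, radians
      a <- u - v; b <- w - v
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0
      else acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1))
    },
    DIST_SUM = function(u, v, w)
      sqrt(sum((u - v)^2)) + sqrt(sum((v - w)^2)) + sqrt(sum((w - u)^2)),
    stop("unknown multi-metric '", id, "'"))
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

.newTensor <- function(values, order, metricId, k = 1L,
                       normalization = "NS", filters = list())
  new("SimilarityTensor", values = values, order = as.integer(order),
      k = as.integer(k), normalization = normalization,
      metricId = metricId, filters = filters)

#' Two-tuple (dis)similarity tensor of order 1
#'
#' Builds the n x n matrix z_ij = metric(coord_i, coord_j) over all residue
#' pairs (diagonal included: metric(x, x)).
#'
#' @param points a \linkS4class{ResiduePointSet}.
#' @param metricId one of \code{metricIds(2)} (or an M-number alias).
#' @param p Minkowski exponent, used only by \code{"MINKOWSKI"}.
#' @return a \linkS4class{SimilarityTensor} of order 2, k = 1, NS.
#' @export
twoTupleTensor <- function(points, metricId = "EUCLIDEAN", p = 3) {
  metricId <- .resolveMetric(metricId, 2)
  xyz <- coords(points)
  n <- nrow(xyz)
  z <- matrix(0, n, n)
  if (metricId == "EUCLIDEAN") {
    z <- as.matrix(stats::dist(xyz))
    dimnames(z) <- NULL
  } else {
    f <- .pairMetric(metricId, p)
    for (i in seq_len(n)) for (j in seq_len(n))
      z[i, j] <- f(xyz[i, ], xyz[j, ])
  }
  .newTensor(z, 2, metricId)
}

#' Three-tuple (dis)similarity tensor of order 1
#'
#' Builds the n x n x n array z_ijl = multimetric(coord_i, coord_j,
#' coord_l) over residue triples. Entries with any repeated index are 0.
#'
#' @param points a \linkS4class{ResiduePointSet} with n >= 3.
#' @param multimetricId one of \code{metricIds(3)}: triangle \code{"AREA"},
#'   \code{"PERIMETER"}, \code{"BOND_ANGLE"} (at the middle index, radians)
#'   or \code{"DIST_SUM"}.
#' @return a \linkS4class{SimilarityTensor} of order 3, k = 1, NS.
#' @export
threeTupleTensor <- function(points, multimetricId = "AREA") {
  multimetricId <- .resolveMetric(multimetricId, 3)
  xyz <- coords(points)
  n <- nrow(xyz)
  if (n < 3L) stop("three-tuple tensors need at least 3 residues")
  f <- .tripleMetric(multimetricId)
  z <- array(0, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
    if (i == j || j == l || i == l) next
    z[i, j, l] <- f(xyz[i, ], xyz[j, ], xyz[l, ])
  }
  .newTensor(z, 3, multimetricId)
}

.resolveMetric <- function(id, order, aliases = .METRIC_ALIASES) {
  id <- toupper(id)
  if (id %in% names(aliases)) id <- aliases[[id]]
  valid <- if (order == 2) .METRICS else .MULTIMETRICS
  if (!id %in% valid)
    stop("unknown ", if (order == 3) "multi-", "metric '", id, "'")
  id
}

## index tuples of a tensor as a matrix (rows = entries)
.tupleIndex <- function(tensor) {
  n <- dim(tensor@values)[1]
  if (tensor@order == 2L)
    cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  else
    cbind(rep(seq_len(n), n * n),
          rep(rep(seq_len(n), each = n), n),
          rep(seq_len(n), each = n * n))
}

#' Apply fuzzy spherical truncation to an order-1 tensor
#'
#' Every entry r = z_i.. is replaced by r * F(W), where W holds the
#' membership degrees of the entry's index residues in the spec's fuzzy
#' set on the residue-to-centre distance, and F is the spec's fusion rule.
#' Truncation is defined only for tensors of order k = 1 (it precedes
#' normalization and powering in the pipeline).
#'
#' @param tensor a \linkS4class{SimilarityTensor} with \code{k == 1}.
#' @param frame the structure's \linkS4class{SphericalFrame}.
#' @param spec a \linkS4class{TruncationSpec}; \code{"NONE"} returns the
#'   tensor unchanged (bit-identical values).
#' @return the truncated \linkS4class{SimilarityTensor}.
#' @export
applySphericalTruncation <- function(tensor, frame, spec) {
  stopifnot(is(tensor, "SimilarityTensor"))
  if (tensor@k != 1L)
    stop("spherical truncation applies to order-1 (k = 1) tensors only")
  filt <- c(tensor@filters,
            list(list(type = "truncation", functionId = spec@functionId,
                      rOn = spec@rOn, rOff = spec@rOff,
                      fusion = spec@fusion)))
  if (spec@functionId == "NONE") {
    tensor@filters <- filt
    return(tensor)
  }
  w <- membershipVector(frame, spec)
  idx <- .tupleIndex(tensor)
  wm <- matrix(w[idx], nrow(idx), ncol(idx))
  fw <- switch(spec@fusion,
               ARITHMETIC_MEAN = rowMeans(wm),
               MIN = do.call(pmin, as.data.frame(wm)),
               MAX = do.call(pmax, as.data.frame(wm)))
  v <- tensor@values
  v[] <- as.numeric(v) * fw
  tensor@values <- v
  tensor@filters <- filt
  tensor
}

#' Restrict a tensor to a lag window
#'
#' Zeroes entries whose index tuple violates a topological window (the
#' sequence separation |i - j| of every constituent pair must lie inside
#' \code{topological}) or a geometric window (the Euclidean inter-residue
#' distance of every pair must lie inside \code{geometric}, in Angstrom).
#' Both windows are inclusive; \code{NULL} disables a window.
#'
#' @param tensor a \linkS4class{SimilarityTensor}.
#' @param points the \linkS4class{ResiduePointSet} the tensor came from
#'   (needed for the geometric window).
#' @param topological length-2 numeric range on sequence separation, or
#'   NULL.
#' @param geometric length-2 numeric range in Angstrom, or NULL.
#' @return the filtered \linkS4class{SimilarityTensor}.
#' @export
applyLagFilter <- function(tensor, points, topological = NULL,
                           geometric = NULL) {
  stopifnot(is(tensor, "SimilarityTensor"))
  if (is.null(topological) && is.null(geometric)) return(tensor)
  .checkRange <- function(r, what) {
    if (length(r) != 2L || any(r < 0) || r[1] > r[2])
      stop("invalid ", what, " lag range")
  }
  idx <- .tupleIndex(tensor)
  pairs <- if (tensor@order == 2L) list(c(1, 2))
           else list(c(1, 2), c(2, 3), c(1, 3))
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(topological)) {
    .checkRange(topological, "topological")
    for (pr in pairs) {
      sep <- abs(idx[, pr[1]] - idx[, pr[2]])
      keep <- keep & sep >= topological[1] & sep <= topological[2]
    }
  }
  if (!is.null(geometric)) {
    .checkRange(geometric, "geometric")
    dm <- as.matrix(stats::dist(coords(points)))
    for (pr in pairs) {
      dd <- dm[idx[, c(pr[1], pr[2]), drop = FALSE]]
      keep <- keep & dd >= geometric[1] & dd <= geometric[2]
    }
  }
  v <- tensor@values
  v[!keep] <- 0
  tensor@values <- v
  tensor@filters <- c(tensor@filters,
                      list(list(type = "lag", topological = topological,
                                geometric = geometric)))
  tensor
}

#' Shipped residue groups
#'
#' \code{"FBS"} (beta-sheet favouring: VAL, ILE, TYR, CYS, TRP, PHE, THR)
#' is shipped; \code{"PBS"} and \code{"PAH"} are placeholders that must be
#' defined by the user before use.
#'
#' @return named list of residue-code sets.
#' @export
residueGroups <- function()
  list(FBS = c("VAL", "ILE", "TYR", "CYS", "TRP", "PHE", "THR"),
       PBS = character(0), PAH = character(0))

#' Restrict a tensor to a residue group
#'
#' Zeroes entries whose index residues are not all members of the group.
#'
#' @param tensor a \linkS4class{SimilarityTensor}.
#' @param group a group id from \code{\link{residueGroups}} or an explicit
#'   character vector of 3-letter residue codes.
#' @param residueCodes character vector of the structure's residue codes in
#'   tensor index order.
#' @return the restricted \linkS4class{SimilarityTensor}.
#' @export
groupRestrict <- function(tensor, group, residueCodes) {
  stopifnot(is(tensor, "SimilarityTensor"))
  gid <- NA_character_
  if (length(group) == 1L && group %in% names(residueGroups())) {
    gid <- group
    group <- residueGroups()[[group]]
    if (length(group) == 0L)
      stop("group '", gid, "' has no shipped definition; supply codes")
  }
  group <- toupper(group)
  bad <- !group %in% .STANDARD_AA
  if (any(bad)) stop("non-standard codes in group: ",
                     paste(group[bad], collapse = ", "))
  inG <- residueCodes %in% group
  idx <- .tupleIndex(tensor)
  keep <- rowSums(!matrix(inG[idx], nrow(idx), ncol(idx))) == 0
  v <- tensor@values
  v[!keep] <- 0
  tensor@values <- v
  tensor@filters <- c(tensor@filters,
                      list(list(type = "group", groupId = gid,
                                codes = group)))
  tensor
}

#' Normalize a tensor
#'
#' \code{"NS"} (non-stochastic) leaves the tensor unchanged; \code{"SS"}
#' (simple stochastic) divides each row (order 2) or each i-slice (order 3)
#' by its sum, leaving all-zero rows untouched; \code{"MP"} (mutual
#' probability) divides every entry by the grand sum.
#'
#' @param tensor a \linkS4class{SimilarityTensor}.
#' @param scheme \code{"NS"}, \code{"SS"} or \code{"MP"}.
#' @return the normalized \linkS4class{SimilarityTensor}.
#' @export
normalizeTensor <- function(tensor, scheme = "NS") {
  stopifnot(is(tensor, "SimilarityTensor"),
            scheme %in% c("NS", "SS", "MP"))
  v <- tensor@values
  if (scheme != "NS" && sum(abs(v)) == 0)
    stop("cannot ", scheme, "-normalize an all-zero tensor")
  if (scheme == "SS") {
    if (tensor@order == 2L) {
      rs <- rowSums(v)
      nz <- rs != 0
      v[nz, ] <- v[nz, , drop = FALSE] / rs[nz]
    } else {
      for (i in seq_len(dim(v)[1])) {
        s <- sum(v[i, , ])
        if (s != 0) v[i, , ] <- v[i, , ] / s
      }
    }
  } else if (scheme == "MP") {
    v <- v / sum(v)
  }
  tensor@values <- v
  tensor@normalization <- scheme
  tensor
}

#' Hadamard (element-wise) power of a tensor
#'
#' Raises every entry to the integer power k. Negative powers model
#' gravitational-like (k = -1) and Coulombic-like (k = -2) decay; zero
#' entries are mapped to 0 under negative powers rather than infinity, so
#' diagonals and filtered entries stay finite.
#'
#' @param tensor a \linkS4class{SimilarityTensor}.
#' @param k integer exponent.
#' @return the powered \linkS4class{SimilarityTensor} with slot
#'   \code{k} updated.
#' @export
hadamardPower <- function(tensor, k = 1L) {
  stopifnot(is(tensor, "SimilarityTensor"))
  k <- as.integer(k)
  v <- tensor@values
  if (k != 1L) {
    if (k < 0L) {
      nz <- v != 0
      v[nz] <- v[nz]^k
      v[!nz] <- 0
    } else v <- v^k
  }
  tensor@values <- v
  tensor@k <- k
  tensor
}

#' Per-residue split of a tensor
#'
#' The amino-acid-level tensor of residue \code{a} keeps each entry whose
#' index tuple contains \code{a}, scaled by m/N where m is the multiplicity
#' of \code{a} in the tuple and N the tuple size, and zeroes the rest.
#' This equal-share split guarantees the partition property: the aa-level
#' tensors of all residues sum to the total tensor.
#'
#' @param tensor a \linkS4class{SimilarityTensor}.
#' @param a residue index, 1-based.
#' @return the aa-level \linkS4class{SimilarityTensor}.
#' @export
aaLevelTensor <- function(tensor, a) {
  stopifnot(is(tensor, "SimilarityTensor"))
  n <- dim(tensor@values)[1]
  if (a < 1L || a > n) stop("residue index out of range")
  idx <- .tupleIndex(tensor)
  mult <- rowSums(matrix(idx == a, nrow(idx), ncol(idx)))
  v <- tensor@values
  v[] <- as.numeric(v) * (mult / tensor@order)
  tensor@values <- v
  tensor
}
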