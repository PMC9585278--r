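## Exploratory statistics over membership degrees and descriptor tables:
## distance-bin distributions, membership summaries, Ward clustering of
## truncation functions, Shannon-entropy variability, and varimax-rotated
## PCA loadings.

#' Residue counts per spherical-radius bin
#'
#' Each protein's radius is divided into \code{nBins} equal fractions
#' ([0,10), ..., [90,100] percent for the default 10); residue p of
#' protein q falls in bin \code{floor(nBins * d_pq / R_q)}, with d = R
#' assigned to the last bin. Counts are pooled over proteins.
#'
#' @param frames list of \linkS4class{SphericalFrame} objects.
#' @param nBins number of bins (default 10).
#' @return named integer vector of per-bin residue counts.
#' @export
distanceBinFrequencies <- function(frames, nBins = 10L) {
  if (is(frames, "SphericalFrame")) frames <- list(frames)
  if (!length(frames)) stop("no frames supplied")
  counts <- integer(nBins)
  for (fr in frames) {
    b <- pmin(floor(nBins * fr@centerDistances / fr@radius), nBins - 1L)
    counts <- counts + tabulate(b + 1L, nBins)
  }
  lo <- round(100 * (seq_len(nBins) - 1L) / nBins)
  hi <- round(100 * seq_len(nBins) / nBins)
  names(counts) <- sprintf("[%d,%d%s", lo, hi,
                           c(rep(")", nBins - 1L), "]"))
  counts
}

#' Pooled membership matrix over proteins and truncation functions
#'
#' Evaluates every truncation function on the interval [0, R] (fractions
#' \code{rOn = 0}, \code{rOff = 1}) for every residue of every frame and
#' stacks the degrees into a rows = residues, columns = functions matrix.
#'
#' @param frames list of \linkS4class{SphericalFrame} objects.
#' @param functionIds truncation functions to evaluate (default: all 16).
#' @param rOn,rOff interval fractions shared by all functions.
#' @return numeric matrix with one column per function.
#' @export
membershipMatrix <- function(frames, functionIds = truncationFunctions(),
                             rOn = 0, rOff = 1) {
  if (is(frames, "SphericalFrame")) frames <- list(frames)
  cols <- lapply(functionIds, function(fn) {
    spec <- truncationSpec(fn, rOn, rOff)
    unlist(lapply(frames, membershipVector, spec = spec))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- functionIds
  m
}

#' Column-wise descriptive statistics of a membership matrix
#'
#' Minimum, maximum, arithmetic mean and sample (n-1) standard deviation
#' of the membership degrees of each truncation function.
#'
#' @param m membership matrix (rows = residues, columns = functions).
#' @return data.frame with columns \code{fun}, \code{min}, \code{max},
#'   \code{mean}, \code{sd}.
#' @export
membershipStatistics <- function(m) {
  m <- as.matrix(m)
  if (!nrow(m)) stop("empty membership matrix")
  data.frame(fun = colnames(m) %||% paste0("F", seq_len(ncol(m))),
             min = apply(m, 2, min), max = apply(m, 2, max),
             mean = colMeans(m), sd = apply(m, 2, stats::sd),
             row.names = NULL)
}

#' Ward clustering of truncation functions
#'
#' Builds the function x function matrix of Euclidean distances between
#' membership columns, applies Ward agglomeration, and cuts the tree at a
#' height expressed as a fraction of the maximum linkage distance.
#'
#' @param m membership matrix (columns = truncation functions).
#' @param cutoffFraction flat-cluster cutoff as a fraction of the maximum
#'   linkage height (default 0.2).
#' @return list with \code{hclust} (the tree), \code{distances} (the
#'   \code{dist} object) and \code{clusters} (named integer memberships).
#' @export
functionDendrogram <- function(m, cutoffFraction = 0.2) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least two truncation functions")
  d <- stats::dist(t(m), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, h = cutoffFraction * max(hc$height))
  list(hclust = hc, distances = d, clusters = cl)
}

#' Shannon entropy of a descriptor column
#'
#' Bins the values into \code{nBins} equal-width bins spanning the
#' observed range and returns \code{-sum(p_b log2 p_b)} over non-empty
#' bins. A constant column (zero-width range) has zero entropy. The upper
#' bound is \code{log2(nBins)}, attained by a uniform occupation.
#'
#' @param x numeric vector of descriptor values.
#' @param nBins number of equal-width bins (convention: the number of
#'   proteins in the dataset).
#' @return entropy in bits.
#' @export
#' @examples
#' shannonEntropy(seq_len(152), 152)  # log2(152) = 7.24 bits
shannonEntropy <- function(x, nBins) {
  if (any(!is.finite(x))) stop("descriptor column must be finite")
  if (nBins < 2L) stop("need at least 2 bins")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  b <- pmin(floor(nBins * (x - rng[1]) / (rng[2] - rng[1])), nBins - 1L)
  p <- tabulate(b + 1L, nBins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based variability ranking of a descriptor table
#'
#' @param table a \linkS4class{DescriptorTable} or numeric matrix
#'   (rows = proteins).
#' @param nBins bins per column; defaults to the number of proteins.
#' @return data.frame with columns \code{descriptor}, \code{entropy}
#'   (bits), \code{maxEntropy}, sorted by decreasing entropy.
#' @export
entropyRanking <- function(table, nBins = NULL) {
  v <- if (is(table, "DescriptorTable")) table@values else as.matrix(table)
  if (is.null(nBins)) nBins <- nrow(v)
  se <- apply(v, 2, shannonEntropy, nBins = nBins)
  out <- data.frame(descriptor = colnames(v), entropy = se,
                    maxEntropy = log2(nBins), row.names = NULL)
  out[order(-out$entropy), ]
}

#' PCA loadings of a descriptor table
#'
#' Mean-centres and unit-scales the columns, extracts principal
#' components, and reports loadings as component-variable correlations.
#' With \code{rotation = "varimax"} the loadings of the leading
#' \code{nComponents} are rotated with the normalized varimax criterion
#' (rows divided by the square roots of their communalities before
#' rotation). Descriptors with |loading| >= \code{threshold} on a
#' component are tagged as strongly loaded there.
#'
#' @param table a \linkS4class{DescriptorTable} or numeric matrix
#'   (rows = proteins, >= 3; columns = descriptors, >= 2).
#' @param rotation \code{"none"} or \code{"varimax"}.
#' @param nComponents components to keep (default: all with positive
#'   variance, capped at min(n-1, p)).
#' @param threshold strong-loading cutoff (default 0.7).
#' @return list with \code{loadings} (variables x components),
#'   \code{explainedVariance} (percent per component),
#'   \code{stronglyLoaded} (list of descriptor names per component) and
#'   \code{rotation}.
#' @export
pcaLoadings <- function(table, rotation = c("none", "varimax"),
                        nComponents = NULL, threshold = 0.7) {
  rotation <- match.arg(rotation)
  v <- if (is(table, "DescriptorTable")) table@values else as.matrix(table)
  if (nrow(v) < 3L || ncol(v) < 2L)
    stop("need at least 3 proteins and 2 descriptors")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  pos <- pc$sdev > sqrt(.Machine$double.eps)
  kmax <- sum(pos)
  k <- min(nComponents %||% kmax, kmax)
  ## correlation loadings: eigenvector * component sd (columns scaled)
  L <- pc$rotation[, seq_len(k), drop = FALSE] *
    rep(pc$sdev[seq_len(k)], each = ncol(v))
  expl <- 100 * pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  if (rotation == "varimax" && k >= 2L) {
    vr <- stats::varimax(L, normalize = TRUE)
    L <- L %*% vr$rotmat
    ## variance explained by a rotated factor = its sum of squared
    ## correlation loadings; total variance of standardized data = p
    expl <- 100 * colSums(L^2) / sum(pc$sdev^2)
  }
  colnames(L) <- paste0("PC", seq_len(k))
  strong <- apply(L, 2, function(col)
    rownames(L)[abs(col) >= threshold], simplify = FALSE)
  list(loadings = L, explainedVariance = expl, stronglyLoaded = strong,
       rotation = rotation)
}
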