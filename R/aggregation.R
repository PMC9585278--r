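## Aggregation operators collapsing a vector of per-residue Local Amino
## acid Invariants (LAIs) into one global descriptor value.

.AGG_IDS <- c("N1",    # sum
              "AM",    # arithmetic mean
              "Q1",    # quadratic mean (RMS)
              "GM",    # geometric mean (non-negative entries)
              "HM",    # harmonic mean (nonzero entries)
              "N2",    # Euclidean norm
              "VAR",   # sample variance
              "SD",    # sample standard deviation
              "SK",    # skewness (moment formula)
              "KU",    # excess kurtosis
              "MN", "MX", "RA",   # minimum, maximum, range
              "I50",   # median (50th percentile)
              "TA")    # total of absolute values

#' Aggregation operators
#'
#' Stable ids of the operators turning an LAI vector into a global
#' descriptor: \code{N1} sum, \code{AM} arithmetic mean, \code{Q1}
#' quadratic mean, \code{GM} geometric mean, \code{HM} harmonic mean,
#' \code{N2} Euclidean norm, \code{VAR}/\code{SD} sample variance and
#' standard deviation, \code{SK} skewness, \code{KU} excess kurtosis,
#' \code{MN}/\code{MX}/\code{RA} extremes and range, \code{I50} median,
#' \code{TA} sum of absolute values.
#'
#' @return character vector of operator ids.
#' @export
aggregationOperators <- function() .AGG_IDS

#' Aggregate an LAI vector into a scalar descriptor
#'
#' Degenerate cases keep tables dense rather than propagating NaN: the
#' geometric mean requires non-negative entries (negative input errors);
#' skewness and kurtosis of a (near-)constant or too-short vector return 0
#' with a warning; the harmonic mean of a vector containing zero returns 0.
#'
#' @param lai numeric vector of per-residue invariants.
#' @param operatorId one of \code{\link{aggregationOperators}()}.
#' @return a single numeric value.
#' @export
#' @examples
#' aggregateLAI(c(3, 4), "N2")  # 5
aggregateLAI <- function(lai, operatorId = "N1") {
  if (!is.numeric(lai) || length(lai) == 0L || any(!is.finite(lai)))
    stop("lai must be a non-empty finite numeric vector")
  n <- length(lai)
  m <- mean(lai)
  .moment <- function(r) mean((lai - m)^r)
  s2 <- .moment(2)
  switch(operatorId,
    N1 = sum(lai),
    AM = m,
    Q1 = sqrt(mean(lai^2)),
    GM = {
      if (any(lai < 0)) stop("geometric mean needs non-negative entries")
      if (any(lai == 0)) 0 else exp(mean(log(lai)))
    },
    HM = if (any(lai == 0)) {
      warning("harmonic mean undefined with zero entries; returning 0")
      0
    } else n / sum(1 / lai),
    N2 = sqrt(sum(lai^2)),
    VAR = if (n < 2L) 0 else stats::var(lai),
    SD = if (n < 2L) 0 else stats::sd(lai),
    SK = if (n < 3L || s2 <= .Machine$double.eps * max(1, m^2)) {
      warning("skewness undefined (constant or too-short vector); returning 0")
      0
    } else .moment(3) / s2^1.5,
    KU = if (n < 3L || s2 <= .Machine$double.eps * max(1, m^2)) {
      warning("kurtosis undefined (constant or too-short vector); returning 0")
      0
    } else .moment(4) / s2^2 - 3,
    MN = min(lai),
    MX = max(lai),
    RA = max(lai) - min(lai),
    I50 = stats::median(lai),
    TA = sum(abs(lai)),
    stop("unknown aggregation operator '", operatorId, "'"))
}
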