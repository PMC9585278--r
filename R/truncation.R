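## Fuzzy membership and smoothing functions of the residue-to-centre
## distance, interval resolution against the spherical radius, and the
## fusion rule producing the truncation value S(r) = r * F(W).

.FMF_IDS <- c("S_SHAPED", "Z_SHAPED", "PI_SHAPED", "TRIANGULAR",
              "TRAPEZOIDAL", "D_SIGMOID", "A_SIGMOID", "D_GAUSSIAN",
              "C_GAUSSIAN", "A_GAUSSIAN", "D_BELL", "C_BELL", "A_BELL")
.TF_IDS <- c("SHIFTING1", "SHIFTING2", "SWITCHING")

## regime each function favours on [d_on, d_off]:
## "c" near the lower boundary, "m" the middle region, "s" the upper boundary
.REGIME <- c(S_SHAPED = "s", Z_SHAPED = "c", PI_SHAPED = "m",
             TRIANGULAR = "m", TRAPEZOIDAL = "m",
             D_SIGMOID = "c", A_SIGMOID = "s",
             D_GAUSSIAN = "c", C_GAUSSIAN = "m", A_GAUSSIAN = "s",
             D_BELL = "c", C_BELL = "m", A_BELL = "s",
             SHIFTING1 = "c", SHIFTING2 = "c", SWITCHING = "c")

#' Available truncation functions
#'
#' The 13 fuzzy membership functions (S/Z/PI-shaped, triangular,
#' trapezoidal, descending/ascending sigmoid, descending/centralized/
#' ascending Gaussian and generalized Bell) and the 3 molecular-dynamics
#' smoothing functions (two shifting forms and one switching form).
#' \code{"NONE"} (accepted by \code{\link{truncationSpec}}) disables
#' truncation entirely.
#'
#' @param regimes logical; if TRUE return a named character vector giving
#'   each function's bias regime: \code{"c"} (near the lower boundary /
#'   protein centre), \code{"m"} (middle region) or \code{"s"} (upper
#'   boundary / surface).
#' @return character vector of function ids, or the named regime vector.
#' @export
#' @examples
#' truncationFunctions()
truncationFunctions <- function(regimes = FALSE) {
  if (regimes) .REGIME else c(.FMF_IDS, .TF_IDS)
}

#' Construct a TruncationSpec
#'
#' @param functionId one of \code{\link{truncationFunctions}()} or
#'   \code{"NONE"}.
#' @param rOn,rOff lower/upper interval boundary as fractions of the
#'   spherical radius R; \code{0 <= rOn < rOff <= 1}.
#' @param fusion rule fusing the memberships of a tuple's residues:
#'   \code{"ARITHMETIC_MEAN"} (the default used throughout),
#'   \code{"MIN"} or \code{"MAX"}.
#' @return a \linkS4class{TruncationSpec}.
#' @export
#' @examples
#' truncationSpec("Z_SHAPED", 0.2, 1)
truncationSpec <- function(functionId = "NONE", rOn = 0, rOff = 1,
                           fusion = "ARITHMETIC_MEAN") {
  new("TruncationSpec", functionId = functionId, rOn = rOn, rOff = rOff,
      fusion = fusion)
}

#' Resolve a fractional interval against a spherical radius
#'
#' Interval boundaries are stored as fractions of R so the same spec applies
#' to proteins of different size: \code{d_on = R * rOn},
#' \code{d_off = R * rOff}.
#'
#' @param spec a \linkS4class{TruncationSpec}.
#' @param radius spherical radius R in Angstrom, > 0.
#' @return named numeric c(dOn, dOff) in Angstrom.
#' @export
#' @examples
#' resolveInterval(truncationSpec("S_SHAPED", 0.2, 0.8), 10)
resolveInterval <- function(spec, radius) {
  stopifnot(is(spec, "TruncationSpec"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number")
  c(dOn = radius * spec@rOn, dOff = radius * spec@rOff)
}

## piecewise S-shaped rise from 0 at a to 1 at b (MATLAB smf)
.smf <- function(x, a, b) {
  m <- (a + b) / 2
  ifelse(x <= a, 0,
  ifelse(x <= m, 2 * ((x - a) / (b - a))^2,
  ifelse(x <= b, 1 - 2 * ((x - b) / (b - a))^2, 1)))
}

## Z-shaped fall from 1 at a to 0 at b (MATLAB zmf); complement of .smf
.zmf <- function(x, a, b) 1 - .smf(x, a, b)

#' Evaluate a truncation function
#'
#' Computes the membership degree mu_A(x) of a residue-to-centre distance x
#' in the fuzzy set A = [dOn, dOff]. Parameter bindings follow the standard
#' conventions: S/Z-shaped use (a, b) = (dOn, dOff); PI-shaped and
#' trapezoidal put their shoulders at 0.45 and 0.55 of (dOn + dOff);
#' triangular peaks at the midpoint; sigmoids use slope a = -1 (descending)
#' or +1 (ascending) per Angstrom about the midpoint; Gaussians use width
#' a = (dOff - dOn)/2 centred at dOn (descending), width (dOff - dOn)/4 at
#' the midpoint (centralized), or width (dOff - dOn)/2 at dOff (ascending);
#' generalized Bell curves use the same three (a, c) bindings with slope
#' exponent b = 2. The smoothing functions are the molecular-dynamics
#' forms: Shifting1 (1 - (x/dOff)^2)^2 and Shifting2 (1 - x/dOff)^2 on
#' [0, dOff], and Switching, 1 below dOn, a quintic-type decay on
#' (dOn, dOff) and 0 beyond. Values x outside [dOn, dOff] are legal (the
#' functions extend naturally); results are clamped to [0, 1].
#'
#' @param functionId one of \code{\link{truncationFunctions}()} or
#'   \code{"NONE"} (always 1).
#' @param x distance(s) to the geometric centre, in Angstrom, >= 0
#'   (vectorized).
#' @param dOn,dOff resolved interval boundaries in Angstrom, dOn < dOff.
#' @return membership degree(s) in [0, 1].
#' @export
#' @examples
#' membership("S_SHAPED", 2.83, 0, 4.056)  # 0.817
#' membership("Z_SHAPED", 2.83, 0, 4.056)  # 0.183
membership <- function(functionId, x, dOn, dOff) {
  if (dOn >= dOff) stop("dOn must be < dOff")
  if (any(x < 0)) stop("distances must be non-negative")
  a <- dOn; d <- dOff
  mid <- (a + d) / 2
  mu <- switch(functionId,
    NONE        = rep(1, length(x)),
    S_SHAPED    = .smf(x, a, d),
    Z_SHAPED    = .zmf(x, a, d),
    PI_SHAPED   = .smf(x, a, (a + d) * 0.45) * .zmf(x, (a + d) * 0.55, d),
    TRIANGULAR  = {
      b <- mid
      ifelse(x <= a | x >= d, 0,
      ifelse(x <= b, (x - a) / (b - a), (d - x) / (d - b)))
    },
    TRAPEZOIDAL = {
      b <- (a + d) * 0.45; cc <- (a + d) * 0.55
      ifelse(x <= a | x >= d, 0,
      ifelse(x <= b, (x - a) / (b - a),
      ifelse(x <= cc, 1, (d - x) / (d - cc))))
    },
    D_SIGMOID   = 1 / (1 + exp(-(-1) * (x - mid))),
    A_SIGMOID   = 1 / (1 + exp(-(+1) * (x - mid))),
    D_GAUSSIAN  = exp(-(x - a)^2 / (2 * ((d - a) * 0.5)^2)),
    C_GAUSSIAN  = exp(-(x - mid)^2 / (2 * ((d - a) * 0.25)^2)),
    A_GAUSSIAN  = exp(-(x - d)^2 / (2 * ((d - a) * 0.5)^2)),
    D_BELL      = 1 / (1 + abs((x - a) / ((d - a) * 0.5))^4),
    C_BELL      = 1 / (1 + abs((x - mid) / ((d - a) * 0.25))^4),
    A_BELL      = 1 / (1 + abs((x - d) / ((d - a) * 0.5))^4),
    SHIFTING1   = ifelse(x <= d, (1 - (x / d)^2)^2, 0),
    SHIFTING2   = ifelse(x <= d, (1 - x / d)^2, 0),
    SWITCHING   = ifelse(x <= a, 1,
                  ifelse(x >= d, 0,
                    (d^2 - x^2)^2 * (d^2 + 2 * x^2 - 3 * a^2) /
                      (d^2 - a^2)^3)),
    stop("unknown truncation function '", functionId, "'")
  )
  pmin(pmax(mu, 0), 1)
}

#' Membership degrees of every residue in a spherical frame
#'
#' Evaluates w_po = mu_A(d_po) for every residue p, where d_po is the
#' residue's distance to the geometric centre o and A is the spec's
#' interval resolved against the frame's radius.
#'
#' @param frame a \linkS4class{SphericalFrame}.
#' @param spec a \linkS4class{TruncationSpec}.
#' @return numeric vector of membership degrees in [0, 1], one per residue.
#' @export
membershipVector <- function(frame, spec) {
  stopifnot(is(frame, "SphericalFrame"), is(spec, "TruncationSpec"))
  iv <- resolveInterval(spec, frame@radius)
  membership(spec@functionId, frame@centerDistances, iv[["dOn"]],
             iv[["dOff"]])
}

#' Fuse membership degrees into a truncation value
#'
#' The truncation value F(W) applied to a tensor entry is a fusion of the
#' membership degrees of the 2 or 3 residues participating in the entry's
#' index tuple. The arithmetic mean is the conventional choice.
#'
#' @param degrees numeric vector of 2 or 3 membership degrees.
#' @param fusion \code{"ARITHMETIC_MEAN"}, \code{"MIN"} or \code{"MAX"}.
#' @return a single degree in [0, 1].
#' @export
#' @examples
#' truncationValue(c(1, 0.816))  # 0.908
truncationValue <- function(degrees, fusion = "ARITHMETIC_MEAN") {
  if (length(degrees) == 0L) stop("empty degree list")
  switch(fusion,
         ARITHMETIC_MEAN = mean(degrees),
         MIN = min(degrees),
         MAX = max(degrees),
         stop("unknown fusion rule '", fusion, "'"))
}
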