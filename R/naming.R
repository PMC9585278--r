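## Deterministic descriptor naming grammar. Underscore-joined tokens in
## fixed order:
##   representation _ aggregation _ form _ metric _ normalization-k
##   [_ flags] [_ group] [_ LGP[a-b]] [_ LGL[a-b]]
##   [_ LGST(function)[rOn-rOff]] _ property
## Omitted filters omit their token; names round-trip through
## parseDescriptorName().

## compact function tokens used inside LGST(...) name fragments
.FN_TOKENS <- c(S_SHAPED = "S", Z_SHAPED = "Z", PI_SHAPED = "PI",
                TRIANGULAR = "TRIANGULAR", TRAPEZOIDAL = "TRAPEZOIDAL",
                D_SIGMOID = "DSIGMOID", A_SIGMOID = "ASIGMOID",
                D_GAUSSIAN = "DGAUSSIAN", C_GAUSSIAN = "CGAUSSIAN",
                A_GAUSSIAN = "AGAUSSIAN", D_BELL = "DBELL",
                C_BELL = "CBELL", A_BELL = "ABELL",
                SHIFTING1 = "SHIFTING1", SHIFTING2 = "SHIFTING2",
                SWITCHING = "SWITCHING")

.num <- function(x) vapply(x, function(v) format(v, trim = TRUE,
                                                 scientific = FALSE),
                           character(1))
.range <- function(r) paste0("[", .num(r[1]), "-", .num(r[2]), "]")

#' Generate a descriptor name
#'
#' Serializes a \linkS4class{DescriptorSpec} (with one chosen aggregation
#' operator) into its canonical token string, e.g.
#' \code{"AVG_N1_Q_EUCLIDEAN_SS-6_FBS_LGST(Z)[0.2-1]_ECI"}. Interval
#' boundaries are printed as fractions of the spherical radius. The name
#' parses back to an equivalent spec via \code{\link{parseDescriptorName}}.
#'
#' @param spec a \linkS4class{DescriptorSpec}.
#' @param aggregation which of the spec's aggregation operators to name
#'   (default: the first).
#' @return a character scalar.
#' @export
descriptorName <- function(spec, aggregation = spec@aggregations[1]) {
  stopifnot(is(spec, "DescriptorSpec"),
            aggregation %in% .AGG_IDS)
  toks <- c(spec@representation, aggregation, spec@form, spec@metricId,
            paste0(spec@normalization, "-", spec@k))
  if (length(spec@flags)) toks <- c(toks, spec@flags)
  if (length(spec@group)) {
    g <- if (length(spec@group) == 1L &&
             spec@group %in% names(residueGroups())) spec@group
         else paste0("G[", paste(spec@group, collapse = "."), "]")
    toks <- c(toks, g)
  }
  if (length(spec@lagTopological))
    toks <- c(toks, paste0("LGP", .range(spec@lagTopological)))
  if (length(spec@lagGeometric))
    toks <- c(toks, paste0("LGL", .range(spec@lagGeometric)))
  tr <- spec@truncation
  if (tr@functionId != "NONE")
    toks <- c(toks, paste0("LGST(", .FN_TOKENS[[tr@functionId]], ")",
                           .range(c(tr@rOn, tr@rOff))))
  prop <- if (length(unique(spec@properties)) == 1L) spec@properties[1]
          else paste(spec@properties, collapse = ".")
  paste(c(toks, prop), collapse = "_")
}

.parseRange <- function(tok) {
  m <- regmatches(tok, regexec("\\[([-0-9.eE+]+)-([0-9.eE+]+)\\]$", tok))[[1]]
  if (length(m) != 3L) stop("cannot parse interval in token '", tok, "'")
  as.numeric(m[2:3])
}

#' Parse a descriptor name back into its spec
#'
#' Inverse of \code{\link{descriptorName}}. Accepts the compact truncation
#' function tokens (Z, S, PI, AGAUSSIAN, ...) and numeric metric aliases
#' (M7, M24, ...) in addition to the stable ids. Tokens that are neither a
#' known grammar element nor the final property token (e.g. the opaque
#' "o" flag seen in published names) are preserved in the spec's
#' \code{flags} slot and ignored by computation.
#'
#' @param name a descriptor name string.
#' @param aliases named character vector extending the metric alias table.
#' @return a \linkS4class{DescriptorSpec} with a single aggregation.
#' @export
parseDescriptorName <- function(name, aliases = character(0)) {
  toks <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(toks) < 6L) stop("descriptor name has too few tokens")
  rep_ <- toks[1]; agg <- toks[2]; form <- toks[3]; metric <- toks[4]
  normk <- regmatches(toks[5],
                      regexec("^(NS|SS|MP)-(-?[0-9]+)$", toks[5]))[[1]]
  if (length(normk) != 3L) stop("cannot parse normalization token '",
                                toks[5], "'")
  prop <- toks[length(toks)]
  mid <- toks[setdiff(seq_along(toks), c(1:5, length(toks)))]

  trunc <- truncationSpec()
  lgp <- NULL; lgl <- NULL; group <- character(0); flags <- character(0)
  for (tok in mid) {
    if (startsWith(tok, "LGP")) lgp <- .parseRange(tok)
    else if (startsWith(tok, "LGL")) lgl <- .parseRange(tok)
    else if (startsWith(tok, "LGST(")) {
      fn <- sub("^LGST\\(([^)]+)\\).*$", "\\1", tok)
      fid <- if (fn %in% .FN_TOKENS) names(.FN_TOKENS)[.FN_TOKENS == fn]
             else if (fn %in% names(.FN_TOKENS)) fn
             else stop("unknown truncation function token '", fn, "'")
      rng <- .parseRange(tok)
      trunc <- truncationSpec(fid, rng[1], rng[2])
    }
    else if (tok %in% names(residueGroups())) group <- tok
    else if (startsWith(tok, "G[") && endsWith(tok, "]"))
      group <- strsplit(substr(tok, 3, nchar(tok) - 1), ".",
                        fixed = TRUE)[[1]]
    else flags <- c(flags, tok)
  }
  props <- strsplit(prop, ".", fixed = TRUE)[[1]]
  descriptorSpec(representation = rep_, form = form,
                 metric = .resolveMetric(metric,
                                         if (form == "Q") 2 else 3,
                                         c(.METRIC_ALIASES, aliases)),
                 normalization = normk[2], k = as.integer(normk[3]),
                 truncation = trunc, lagTopological = lgp,
                 lagGeometric = lgl,
                 group = if (length(group)) group else NULL,
                 properties = props, aggregations = agg, flags = flags)
}
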