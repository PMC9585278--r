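## Declarative "project" configuration: a JSON document enumerating
## descriptor specifications, mirroring the descriptor-name tokens.

#' Read a project configuration
#'
#' A project is a JSON object with a \code{descriptors} array; each element
#' either has a \code{name} field (a full descriptor name, parsed by
#' \code{\link{parseDescriptorName}}) or the explicit fields
#' \code{representation}, \code{form}, \code{metric}, \code{normalization},
#' \code{k}, \code{truncation} (object with \code{function}, \code{rOn},
#' \code{rOff}, optional \code{fusion}), \code{lagTopological},
#' \code{lagGeometric}, \code{group}, \code{properties},
#' \code{aggregations}.
#'
#' @param path path to a JSON project file (or a JSON string).
#' @return list of \linkS4class{DescriptorSpec} objects.
#' @export
readProjectConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  if (is.null(cfg$descriptors) || !length(cfg$descriptors))
    stop("project configuration has no 'descriptors' array")
  lapply(cfg$descriptors, function(d) {
    if (!is.null(d$name)) return(parseDescriptorName(d$name))
    tr <- if (is.null(d$truncation)) truncationSpec()
          else truncationSpec(
            functionId = d$truncation[["function"]] %||% "NONE",
            rOn = d$truncation$rOn %||% 0,
            rOff = d$truncation$rOff %||% 1,
            fusion = d$truncation$fusion %||% "ARITHMETIC_MEAN")
    descriptorSpec(
      representation = d$representation %||% "CA",
      form = d$form %||% "Q",
      metric = d$metric %||% "EUCLIDEAN",
      normalization = d$normalization %||% "NS",
      k = d$k %||% 1L,
      truncation = tr,
      lagTopological = d$lagTopological,
      lagGeometric = d$lagGeometric,
      group = d$group,
      properties = d$properties %||% "ECI",
      aggregations = d$aggregations %||% "N1")
  })
}

#' Validate a project configuration
#'
#' Parses the project and reports per-descriptor problems without
#' stopping at the first one.
#'
#' @param path path to a JSON project file.
#' @return invisibly, the list of specs if valid; otherwise stops with a
#'   summary of all problems found.
#' @export
validateProjectConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  if (is.null(cfg$descriptors) || !length(cfg$descriptors))
    stop("project configuration has no 'descriptors' array")
  probs <- character(0)
  specs <- vector("list", length(cfg$descriptors))
  for (i in seq_along(cfg$descriptors)) {
    specs[[i]] <- tryCatch(
      readProjectConfig(jsonlite::toJSON(
        list(descriptors = cfg$descriptors[i]), auto_unbox = TRUE))[[1]],
      error = function(e) {
        probs <<- c(probs, sprintf("descriptor %d: %s", i,
                                   conditionMessage(e)))
        NULL
      })
  }
  if (length(probs)) stop("invalid project:\n  ",
                          paste(probs, collapse = "\n  "))
  invisible(specs)
}
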