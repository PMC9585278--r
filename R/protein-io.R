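## PDB structure input: parse with bio3d, keep standard amino-acid
## residues, resolve altlocs by occupancy, then project to one 3D point
## per residue under the CA / CB / AB / AVG representations.

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

## residues commonly deposited under modified names, mapped for property
## lookup only (coordinates are used as-is)
.AA_ALIASES <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HSD = "HIS",
                 HSE = "HIS", HSP = "HIS")

#' Read a PDB structure
#'
#' Parses a PDB file (or raw PDB text) through \pkg{bio3d}, keeps ATOM
#' records of standard amino-acid residues only (waters and hetero groups
#' are dropped), selects one model, optionally filters chains, and resolves
#' alternate locations by highest occupancy (ties broken by first altloc
#' label). Hydrogens are excluded; every retained atom is a heavy atom.
#'
#' @param pdbSource path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or multiple elements is treated as
#'   text).
#' @param modelIndex 1-based model to use for multi-model files.
#' @param chainFilter optional character vector of chain ids to keep.
#' @return a structure record: list with element \code{atoms}, a data.frame
#'   with columns chain, resno, insert, resid, elety, x, y, z; rows in file
#'   order, grouped by residue.
#' @export
readStructure <- function(pdbSource, modelIndex = 1L, chainFilter = NULL) {
  src <- pdbSource
  istext <- length(src) > 1L || grepl("\n", src[1]) ||
    grepl("^(ATOM|HETATM|MODEL|HEADER)", src[1])
  if (istext) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(unlist(strsplit(src, "\n")), tf)
    src <- tf
  } else if (!file.exists(src)) {
    stop("cannot read PDB source: ", src)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(src, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB source: ", conditionMessage(e)))

  at <- pdb$atom
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (modelIndex < 1L || modelIndex > nmodels)
    stop("modelIndex ", modelIndex, " out of range (", nmodels, " models)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[modelIndex, ] else as.numeric(pdb$xyz)
  at$x <- xyz[seq(1, length(xyz), 3)]
  at$y <- xyz[seq(2, length(xyz), 3)]
  at$z <- xyz[seq(3, length(xyz), 3)]

  keep <- at$type == "ATOM" & at$resid %in% .STANDARD_AA
  ## element symbol if present, else first letter of atom name
  ele <- at$elesy
  if (is.null(ele)) ele <- NA_character_
  ele[is.na(ele) | ele == ""] <- substr(gsub("[0-9]", "",
                                             at$elety[is.na(ele) | ele == ""]),
                                        1, 1)
  keep <- keep & toupper(ele) != "H"
  if (!is.null(chainFilter)) keep <- keep & at$chain %in% chainFilter
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no standard residues",
         if (!is.null(chainFilter)) " after chain filtering" else "")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc resolution: per residue+atom name, keep highest occupancy,
  ## ties -> first altloc label in file order
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(akey, unique(akey)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  nres <- length(unique(rkey))
  if (nres < 2L) stop("structure has fewer than 2 standard residues")
  list(atoms = at[, c("chain", "resno", "insert", "resid", "elety",
                      "x", "y", "z")])
}

#' Project a structure to one point per residue
#'
#' Four spatial representations are supported: \code{"CA"} the alpha
#' carbon; \code{"CB"} the beta carbon, falling back to the alpha carbon
#' for glycine; \code{"AB"} the backbone amide-bond midpoint between C(i)
#' and N(i+1) (the chain-terminal residue uses its backbone C-O midpoint);
#' \code{"AVG"} the unweighted centroid of the residue's heavy atoms.
#'
#' @param structure a record from \code{\link{readStructure}}.
#' @param representation one of \code{"CA"}, \code{"CB"}, \code{"AB"},
#'   \code{"AVG"}.
#' @return a \linkS4class{ResiduePointSet}.
#' @export
projectRepresentation <- function(structure, representation = "CA") {
  stopifnot(representation %in% c("CA", "CB", "AB", "AVG"))
  at <- structure$atoms
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ukeys <- unique(rkey)
  n <- length(ukeys)
  ids <- at[match(ukeys, rkey), c("chain", "resno", "resid")]
  rownames(ids) <- NULL

  getAtom <- function(rows, name) {
    hit <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(hit) == 0L) NULL else as.numeric(hit[1, c("x", "y", "z")])
  }
  byres <- split(seq_len(nrow(at)), factor(rkey, levels = ukeys))
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    rows <- at[byres[[i]], , drop = FALSE]
    label <- paste0(ids$resid[i], ids$resno[i])
    p <- switch(representation,
      CA = getAtom(rows, "CA"),
      CB = if (ids$resid[i] == "GLY") getAtom(rows, "CA")
           else getAtom(rows, "CB"),
      AVG = colMeans(rows[, c("x", "y", "z")]),
      AB = {
        ci <- getAtom(rows, "C")
        nxt <- if (i < n && ids$chain[i + 1] == ids$chain[i])
          getAtom(at[byres[[i + 1]], , drop = FALSE], "N") else NULL
        if (!is.null(ci) && !is.null(nxt)) (ci + nxt) / 2
        else {
          oi <- getAtom(rows, "O")
          if (!is.null(ci) && !is.null(oi)) (ci + oi) / 2 else NULL
        }
      })
    if (is.null(p) || any(!is.finite(p)))
      stop("residue ", label, ": missing atom for representation ",
           representation)
    pts[i, ] <- p
  }
  new("ResiduePointSet", coords = pts, residueIds = ids,
      representation = representation)
}

#' Spherical frame of a residue point set
#'
#' The geometric centre o is the arithmetic mean of the residue points;
#' each residue's centre distance d_po is its Euclidean distance to o; the
#' spherical radius R is the distance of the outermost residue,
#' \code{R = max(d_po)}.
#'
#' @param points a \linkS4class{ResiduePointSet}, or an n x 3 coordinate
#'   matrix.
#' @return a \linkS4class{SphericalFrame}.
#' @export
sphericalFrame <- function(points) {
  xyz <- if (is(points, "ResiduePointSet")) points@coords else as.matrix(points)
  ctr <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  new("SphericalFrame", center = as.numeric(ctr), radius = max(d),
      centerDistances = d)
}

## map possibly-modified residue codes to the 20 standard ones
.standardizeCode <- function(codes) {
  out <- toupper(codes)
  hit <- out %in% names(.AA_ALIASES)
  out[hit] <- .AA_ALIASES[out[hit]]
  bad <- !out %in% .STANDARD_AA
  if (any(bad))
    stop("unmappable residue code(s): ", paste(unique(out[bad]),
                                               collapse = ", "))
  out
}
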