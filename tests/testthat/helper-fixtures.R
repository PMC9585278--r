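## Shared fixtures: hand-formatted PDB text, random point sets, structure
## records built in code, rigid motions, and brute-force oracles.

pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, b = 0, alt = "", icode = "",
                        record = "ATOM", ele = substr(name, 1, 1)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, icode,
          x, y, z, occ, b, ele)
}

writePdbText <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

## a 3-residue peptide with full backbones (plus CB where applicable),
## hand-placed so AB midpoints and AVG centroids are easy to verify
backbonePdb <- function() {
  c(pdbAtomLine(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, ele = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(3, "CB", "ALA", "A", 1, 1.0, 1.0, 0.0, ele = "C"),
    pdbAtomLine(4, "C",  "ALA", "A", 1, 2.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(5, "O",  "ALA", "A", 1, 2.0, -1.0, 0.0, ele = "O"),
    pdbAtomLine(6, "N",  "GLY", "A", 2, 3.0, 0.0, 0.0, ele = "N"),
    pdbAtomLine(7, "CA", "GLY", "A", 2, 4.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(8, "C",  "GLY", "A", 2, 5.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(9, "O",  "GLY", "A", 2, 5.0, -1.0, 0.0, ele = "O"),
    pdbAtomLine(10, "N",  "VAL", "A", 3, 6.0, 0.0, 0.0, ele = "N"),
    pdbAtomLine(11, "CA", "VAL", "A", 3, 7.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(12, "CB", "VAL", "A", 3, 7.0, 1.5, 0.0, ele = "C"),
    pdbAtomLine(13, "C",  "VAL", "A", 3, 8.0, 0.0, 0.0, ele = "C"),
    pdbAtomLine(14, "O",  "VAL", "A", 3, 8.0, -1.0, 0.0, ele = "O"))
}

## random residue point set; sequence cycles the 20 standard codes
randomPointSet <- function(n, seed = 1, scale = 8) {
  set.seed(seed)
  codes <- rep_len(c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                     "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                     "PRO", "SER", "THR", "TRP", "TYR", "VAL"), n)
  new("ResiduePointSet",
      coords = matrix(stats::runif(3 * n, -scale, scale), n, 3),
      residueIds = data.frame(chain = "A", resno = seq_len(n),
                              resid = codes, stringsAsFactors = FALSE),
      representation = "CA")
}

## a structure record (the readStructure output shape) with one CA
## pseudo-atom per residue, built directly from a point set
structureRecord <- function(points) {
  ids <- residueIds(points)
  xyz <- coords(points)
  list(atoms = data.frame(chain = ids$chain, resno = ids$resno,
                          insert = "", resid = ids$resid, elety = "CA",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE))
}

## random proper rotation + translation
rigidMotion <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::runif(3, -20, 20))
}

applyMotion <- function(points, motion) {
  pts <- points
  pts@coords <- coords(points) %*% t(motion$R) +
    matrix(motion$t, nResidues(points), 3, byrow = TRUE)
  pts
}

## brute-force oracles ------------------------------------------------

loopBilinear <- function(Z, x, y) {
  s <- 0
  for (i in seq_len(nrow(Z))) for (j in seq_len(ncol(Z)))
    s <- s + Z[i, j] * x[i] * y[j]
  s
}

loopTrilinear <- function(Z, x, y, p) {
  n <- dim(Z)[1]
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n))
    s <- s + Z[i, j, l] * x[i] * y[j] * p[l]
  s
}

loopEuclidean <- function(xyz) {
  n <- nrow(xyz)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    z[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  z
}
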