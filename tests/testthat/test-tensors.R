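test_that("two-tuple tensors match brute-force metric loops", {
  pts <- randomPointSet(2, seed = 9)
  pts@coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  z <- tensorValues(twoTupleTensor(pts, "EUCLIDEAN"))
  expect_equal(z, matrix(c(0, 2, 2, 0), 2))

  pts5 <- randomPointSet(5, seed = 10)
  z5 <- tensorValues(twoTupleTensor(pts5, "EUCLIDEAN"))
  expect_equal(z5, loopEuclidean(coords(pts5)), tolerance = 1e-12)
  ## symmetry for all shipped symmetric metrics
  for (m in metricIds(2)) {
    zm <- tensorValues(twoTupleTensor(pts5, m))
    expect_equal(zm, t(zm), info = m)
  }
  expect_error(twoTupleTensor(pts5, "NOPE"), "unknown metric")
})

test_that("three-tuple tensors match closed forms and loops", {
  pts <- randomPointSet(3, seed = 2)
  pts@coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  A <- tensorValues(threeTupleTensor(pts, "AREA"))
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1)))
    expect_equal(A[p[1], p[2], p[3]], 0.5)
  expect_equal(A[1, 1, 2], 0)   # repeated index

  col <- randomPointSet(3, seed = 2)
  col@coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(tensorValues(threeTupleTensor(col, "AREA"))[1, 2, 3], 0)

  pts5 <- randomPointSet(5, seed = 4)
  B <- tensorValues(threeTupleTensor(pts5, "BOND_ANGLE"))
  xyz <- coords(pts5)
  for (i in 1:5) for (j in 1:5) for (l in 1:5) {
    if (length(unique(c(i, j, l))) < 3) next
    a <- xyz[i, ] - xyz[j, ]; b <- xyz[l, ] - xyz[j, ]
    ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    expect_equal(B[i, j, l], ang, tolerance = 1e-12)
  }
})

test_that("spherical truncation scales entries by fused memberships", {
  pts <- randomPointSet(6, seed = 6)
  fr <- sphericalFrame(pts)
  z <- twoTupleTensor(pts, "EUCLIDEAN")
  for (fn in c("S_SHAPED", "PI_SHAPED", "Z_SHAPED")) {
    spec <- truncationSpec(fn, 0, 1)
    w <- membershipVector(fr, spec)
    zt <- tensorValues(applySphericalTruncation(z, fr, spec))
    for (i in 1:6) for (j in 1:6)
      expect_equal(zt[i, j], tensorValues(z)[i, j] * mean(c(w[i], w[j])),
                   tolerance = 1e-12)
    ## truncation never increases a non-negative entry
    expect_true(all(zt <= tensorValues(z) + 1e-12))
  }
  ## NONE is bit-identical; plateau leaves values unchanged
  expect_identical(tensorValues(applySphericalTruncation(
    z, fr, truncationSpec("NONE"))), tensorValues(z))
  ## k != 1 is rejected: truncation precedes powering
  zk <- hadamardPower(z, 2)
  expect_error(applySphericalTruncation(zk, fr, truncationSpec("Z_SHAPED")),
               "order-1")
})

test_that("three-tuple truncation fuses all three memberships", {
  pts <- randomPointSet(4, seed = 8)
  fr <- sphericalFrame(pts)
  z <- threeTupleTensor(pts, "PERIMETER")
  spec <- truncationSpec("D_GAUSSIAN", 0, 1)
  w <- membershipVector(fr, spec)
  zt <- tensorValues(applySphericalTruncation(z, fr, spec))
  expect_equal(zt[1, 2, 3],
               tensorValues(z)[1, 2, 3] * mean(w[c(1, 2, 3)]),
               tolerance = 1e-12)
})

test_that("lag filters zero exactly the out-of-window tuples", {
  pts <- randomPointSet(4, seed = 12)
  z <- twoTupleTensor(pts, "EUCLIDEAN")
  ## adjacent-only topological window
  zt <- tensorValues(applyLagFilter(z, pts, topological = c(1, 1)))
  for (i in 1:4) for (j in 1:4)
    expect_equal(zt[i, j],
                 if (abs(i - j) == 1) tensorValues(z)[i, j] else 0)
  ## an all-covering geometric window is the identity
  zg <- applyLagFilter(z, pts, geometric = c(0, Inf))
  expect_equal(tensorValues(zg), tensorValues(z))
  ## contact-shell window matches a brute-force distance check
  zs <- tensorValues(applyLagFilter(z, pts, geometric = c(4, 5.9)))
  dm <- loopEuclidean(coords(pts))
  for (i in 1:4) for (j in 1:4) {
    keep <- dm[i, j] >= 4 && dm[i, j] <= 5.9
    expect_equal(zs[i, j], if (keep) tensorValues(z)[i, j] else 0)
  }
})

test_that("group restriction keeps all-member tuples only", {
  pts <- randomPointSet(8, seed = 13)
  codes <- residueIds(pts)$resid
  z <- twoTupleTensor(pts, "MANHATTAN")
  ## all 20 codes: identity
  all20 <- unique(c(codes, residueGroups()$FBS,
                    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                      "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                      "PRO", "SER", "THR", "TRP", "TYR", "VAL")))
  expect_equal(tensorValues(groupRestrict(z, all20, codes)),
               tensorValues(z))
  ## FBS default set: brute-force membership check
  zg <- tensorValues(groupRestrict(z, "FBS", codes))
  inG <- codes %in% residueGroups()$FBS
  for (i in 1:8) for (j in 1:8)
    expect_equal(zg[i, j],
                 if (inG[i] && inG[j]) tensorValues(z)[i, j] else 0)
  ## disjoint group: zero tensor (first 8 cycled codes contain no TRP)
  expect_equal(max(abs(tensorValues(groupRestrict(z, "TRP", codes)))), 0)
  expect_error(groupRestrict(z, "PBS", codes), "no shipped definition")
})

test_that("normalization schemes satisfy their sum laws", {
  pts <- randomPointSet(7, seed = 14)
  z2 <- twoTupleTensor(pts, "EUCLIDEAN")
  ss <- tensorValues(normalizeTensor(z2, "SS"))
  rs <- rowSums(ss)
  expect_true(all(abs(rs[rs != 0] - 1) < 1e-9))
  mp <- tensorValues(normalizeTensor(z2, "MP"))
  expect_equal(sum(mp), 1, tolerance = 1e-9)
  expect_identical(tensorValues(normalizeTensor(z2, "NS")),
                   tensorValues(z2))
  ## 2x2 closed form
  z22 <- z2; z22@values <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(tensorValues(normalizeTensor(z22, "SS")),
               matrix(c(0, 1, 1, 0), 2))
  ## order-3: i-slice sums
  z3 <- threeTupleTensor(randomPointSet(5, seed = 15), "AREA")
  ss3 <- tensorValues(normalizeTensor(z3, "SS"))
  for (i in 1:5) {
    s <- sum(ss3[i, , ])
    if (s != 0) expect_equal(s, 1, tolerance = 1e-9)
  }
  ## all-zero tensors cannot be normalized
  z0 <- z2; z0@values <- matrix(0, 7, 7)
  expect_error(normalizeTensor(z0, "MP"), "all-zero")
})

test_that("Hadamard powers are element-wise with 0 -> 0 under k < 0", {
  pts <- randomPointSet(6, seed = 16)
  z <- twoTupleTensor(pts, "EUCLIDEAN")
  expect_identical(tensorValues(hadamardPower(z, 1)), tensorValues(z))
  z3 <- tensorValues(hadamardPower(z, 3))
  expect_equal(z3, tensorValues(z)^3, tolerance = 1e-12)
  zm2 <- tensorValues(hadamardPower(z, -2))
  v <- tensorValues(z)
  expect_equal(diag(zm2), rep(0, 6))         # zeros stay zero
  off <- v != 0
  expect_equal(zm2[off], v[off]^(-2), tolerance = 1e-12)
  expect_equal(hadamardPower(z, -2)@k, -2L)
  ## scalar check: entry 2 at k = -2 -> 0.25
  zs <- z; zs@values <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(tensorValues(hadamardPower(zs, -2)),
               matrix(c(0, 0.25, 0.25, 0), 2))
})

test_that("aa-level tensors partition the total tensor", {
  pts <- randomPointSet(5, seed = 17)
  for (tensor in list(twoTupleTensor(pts, "EUCLIDEAN"),
                      threeTupleTensor(pts, "DIST_SUM"))) {
    total <- array(0, dim(tensorValues(tensor)))
    for (a in 1:5)
      total <- total + tensorValues(aaLevelTensor(tensor, a))
    expect_equal(total, tensorValues(tensor), tolerance = 1e-12)
  }
  ## 2-residue system: each residue holds half of each off-diagonal entry
  p2 <- randomPointSet(2, seed = 18)
  z2 <- twoTupleTensor(p2, "EUCLIDEAN")
  a1 <- tensorValues(aaLevelTensor(z2, 1))
  expect_equal(a1[1, 2], tensorValues(z2)[1, 2] / 2)
  expect_error(aaLevelTensor(z2, 3), "out of range")
})

test_that("tensors are rigid-motion invariant", {
  pts <- randomPointSet(6, seed = 19)
  z <- tensorValues(twoTupleTensor(pts, "EUCLIDEAN"))
  a <- tensorValues(threeTupleTensor(pts, "AREA"))
  for (s in 1:3) {
    moved <- applyMotion(pts, rigidMotion(100 + s))
    expect_lt(max(abs(tensorValues(twoTupleTensor(moved, "EUCLIDEAN")) - z)),
              1e-9)
    expect_lt(max(abs(tensorValues(threeTupleTensor(moved, "AREA")) - a)),
              1e-9)
  }
})
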