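test_that("property vectors are table lookups with alias mapping", {
  expect_equal(propertyVector(rep("ALA", 6), "KDH"), rep(1.8, 6))
  expect_error(propertyVector(c("ALA", "XYZ"), "ECI"), "unmappable")
  expect_equal(propertyVector("MSE", "KDH"), propertyVector("MET", "KDH"))
  codes <- c("TRP", "GLY", "VAL", "HIS")
  eci <- propertyScales("ECI")
  expect_equal(propertyVector(codes, "ECI"),
               vapply(codes, function(cc) eci[[cc]], numeric(1),
                      USE.NAMES = FALSE))
  expect_error(propertyScales("NOPE"), "unknown property scale")
})

test_that("bilinear and trilinear forms equal explicit loops", {
  expect_equal(bilinearForm(diag(4), rep(1, 4), rep(1, 4)), 4)
  expect_equal(bilinearForm(matrix(0, 3, 3), runif(3), runif(3)), 0)
  set.seed(21)
  Z <- matrix(rnorm(25), 5)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(bilinearForm(Z, x, y), loopBilinear(Z, x, y),
               tolerance = 1e-12)
  expect_error(bilinearForm(Z, x, y[1:3]), "dimension mismatch")

  Z3 <- array(0, c(4, 4, 4)); Z3[1, 2, 3] <- 2
  expect_equal(trilinearForm(Z3, rep(1, 4), rep(1, 4), rep(1, 4)), 2)
  Z3r <- array(rnorm(64), c(4, 4, 4))
  x4 <- rnorm(4); y4 <- rnorm(4); p4 <- rnorm(4)
  expect_equal(trilinearForm(Z3r, x4, y4, p4),
               loopTrilinear(Z3r, x4, y4, p4), tolerance = 1e-12)
  expect_equal(trilinearForm(Z3r, x4, y4, rep(0, 4)), 0)
})

test_that("aa-level additivity carries to the bilinear forms", {
  pts <- randomPointSet(6, seed = 22)
  z <- normalizeTensor(twoTupleTensor(pts, "EUCLIDEAN"), "SS")
  x <- propertyVector(residueIds(pts)$resid, "ECI")
  y <- propertyVector(residueIds(pts)$resid, "KDH")
  perRes <- vapply(1:6, function(a)
    bilinearForm(tensorValues(aaLevelTensor(z, a)), x, y), numeric(1))
  expect_equal(sum(perRes), bilinearForm(tensorValues(z), x, y),
               tolerance = 1e-12)
})

test_that("aggregation operators match their defining formulas", {
  expect_equal(aggregateLAI(rep(3.5, 7), "AM"), 3.5)
  expect_equal(aggregateLAI(c(3, 4), "N2"), 5)
  set.seed(24)
  v <- rnorm(11)
  m <- mean(v)
  expect_equal(aggregateLAI(v, "SK"),
               mean((v - m)^3) / mean((v - m)^2)^1.5, tolerance = 1e-12)
  expect_equal(aggregateLAI(v, "KU"),
               mean((v - m)^4) / mean((v - m)^2)^2 - 3, tolerance = 1e-12)
  expect_equal(aggregateLAI(v, "Q1"), sqrt(mean(v^2)))
  expect_equal(aggregateLAI(abs(v), "GM"), exp(mean(log(abs(v)))))
  expect_equal(aggregateLAI(v, "RA"), max(v) - min(v))
  expect_equal(aggregateLAI(v, "I50"), median(v))
  expect_equal(aggregateLAI(v, "TA"), sum(abs(v)))
  ## degenerate moments return 0 with a warning, not NaN
  expect_warning(s <- aggregateLAI(rep(2, 5), "SK"), "undefined")
  expect_equal(s, 0)
  expect_error(aggregateLAI(c(-1, 2), "GM"), "non-negative")
  expect_error(aggregateLAI(v, "NOPE"), "unknown aggregation")
})

test_that("the descriptor pipeline yields the expected table shape", {
  s1 <- structureRecord(makeSyntheticPeptide(8, "uniform-ball", seed = 31))
  s2 <- structureRecord(makeSyntheticPeptide(8, "uniform-ball", seed = 32))
  spec <- descriptorSpec("CA", "Q", "EUCLIDEAN", "NS", 1,
                         properties = "ECI", aggregations = "N1")
  tab <- computeDescriptors(list(p1 = s1, p2 = s2), spec)
  expect_equal(dim(descriptorValues(tab)), c(2L, 1L))
  expect_equal(rownames(descriptorValues(tab)), c("p1", "p2"))
})

test_that("truncated quadratic descriptors never exceed untruncated ones", {
  s <- structureRecord(makeSyntheticPeptide(9, "uniform-ball", seed = 33))
  base <- descriptorSpec("CA", "Q", "EUCLIDEAN", "NS", 1,
                         properties = "GVO", aggregations = "N1")
  v0 <- descriptorValues(computeDescriptors(list(p = s), base))[1, 1]
  for (fn in c("S_SHAPED", "PI_SHAPED", "Z_SHAPED")) {
    spTr <- descriptorSpec("CA", "Q", "EUCLIDEAN", "NS", 1,
                           truncation = truncationSpec(fn, 0, 1),
                           properties = "GVO", aggregations = "N1")
    vt <- descriptorValues(computeDescriptors(list(p = s), spTr))[1, 1]
    expect_lte(vt, v0 + 1e-12)
    expect_gte(vt, 0)
  }
})

test_that("rigid-motion copies produce identical descriptor rows", {
  pep <- makeSyntheticPeptide(7, "uniform-ball", seed = 34)
  specs <- list(
    descriptorSpec("CA", "Q", "EUCLIDEAN", "SS", 2,
                   truncation = truncationSpec("Z_SHAPED", 0.2, 1),
                   properties = c("ECI", "KDH"),
                   aggregations = c("N1", "Q1", "SD")),
    descriptorSpec("CA", "T", "AREA", "MP", 1,
                   truncation = truncationSpec("PI_SHAPED", 0, 1),
                   properties = "GVO", aggregations = c("AM", "N2")))
  structs <- list(orig = structureRecord(pep))
  for (s in 1:3)
    structs[[paste0("mv", s)]] <-
      structureRecord(applyMotion(pep, rigidMotion(200 + s)))
  tab <- descriptorValues(computeDescriptors(structs, specs))
  for (r in 2:nrow(tab))
    expect_equal(tab[r, ], tab[1, ], tolerance = 1e-9)
})

test_that("failures on one protein give NA cells, not aborts", {
  good <- structureRecord(makeSyntheticPeptide(6, seed = 35))
  bad <- good
  bad$atoms$elety <- "CB"   # no CA atoms -> projection fails
  spec <- descriptorSpec("CA", "Q", "EUCLIDEAN")
  expect_warning(tab <- computeDescriptors(list(a = good, b = bad), spec),
                 "cells set to NA")
  v <- descriptorValues(tab)
  expect_false(anyNA(v["a", ]))
  expect_true(all(is.na(v["b", ])))
})

test_that("descriptor names round-trip and separate distinct specs", {
  spec <- descriptorSpec("AVG", "Q", "EUCLIDEAN", "SS", 6,
                         truncation = truncationSpec("Z_SHAPED", 0.2, 1),
                         group = "FBS", properties = "ECI",
                         aggregations = "N1")
  nm <- descriptorName(spec)
  expect_match(nm, "LGST(Z)[0.2-1]", fixed = TRUE)
  reparsed <- parseDescriptorName(nm)
  expect_equal(descriptorName(reparsed), nm)
  expect_equal(reparsed@truncation@rOff, 1)
  expect_equal(reparsed@group, "FBS")

  spec2 <- descriptorSpec("AVG", "Q", "EUCLIDEAN", "SS", 6,
                          truncation = truncationSpec("Z_SHAPED", 0.2, 0.8),
                          group = "FBS", properties = "ECI",
                          aggregations = "N1")
  expect_false(descriptorName(spec) == descriptorName(spec2))

  ## published-style name with lag windows, numeric metric alias and the
  ## opaque "o" flag
  full <- "AB_Q1_T_M32_SS-1_o_LGP[1-12]_LGL[4-5.9]_LGST(AGAUSSIAN)[0-0.8]_KDS"
  sp <- parseDescriptorName(full)
  expect_equal(sp@metricId, "AREA")
  expect_equal(sp@truncation@functionId, "A_GAUSSIAN")
  expect_equal(sp@lagGeometric, c(4, 5.9))
  expect_equal(sp@flags, "o")
  expect_equal(descriptorName(sp),
    "AB_Q1_T_AREA_SS-1_o_LGP[1-12]_LGL[4-5.9]_LGST(AGAUSSIAN)[0-0.8]_KDH")
})

test_that("project configurations parse, validate and drive computation", {
  cfg <- '{
    "descriptors": [
      {"representation": "CA", "form": "Q", "metric": "EUCLIDEAN",
       "normalization": "SS", "k": 2,
       "truncation": {"function": "Z_SHAPED", "rOn": 0.2, "rOff": 1},
       "properties": ["ECI"], "aggregations": ["N1", "AM"]},
      {"name": "CA_N2_Q_MANHATTAN_MP-1_KDH"}
    ]
  }'
  tf <- tempfile(fileext = ".json")
  writeLines(cfg, tf)
  specs <- readProjectConfig(tf)
  expect_length(specs, 2)
  expect_equal(specs[[1]]@truncation@functionId, "Z_SHAPED")
  expect_equal(specs[[2]]@metricId, "MANHATTAN")
  expect_silent(validateProjectConfig(tf))
  s <- structureRecord(makeSyntheticPeptide(6, seed = 36))
  tab <- computeDescriptors(list(p = s), specs)
  expect_equal(ncol(descriptorValues(tab)), 3L)

  bad <- '{"descriptors": [{"form": "Q", "metric": "NOPE"}]}'
  tf2 <- tempfile(fileext = ".json")
  writeLines(bad, tf2)
  expect_error(validateProjectConfig(tf2), "descriptor 1")
})

test_that("descriptor tables are deterministic and serializable", {
  s <- structureRecord(makeSyntheticPeptide(6, seed = 37))
  spec <- descriptorSpec("CA", "Q", "EUCLIDEAN", "SS", 2,
                         truncation = truncationSpec("C_GAUSSIAN", 0, 1),
                         aggregations = c("N1", "SK"))
  t1 <- computeDescriptors(list(p = s), spec)
  t2 <- computeDescriptors(list(p = s), spec)
  expect_identical(descriptorValues(t1), descriptorValues(t2))
  out <- tempfile(fileext = ".csv")
  writeDescriptorTable(t1, out)
  back <- read.csv(out, comment.char = "#", check.names = FALSE)
  expect_equal(unlist(back[1, -1], use.names = FALSE),
               unname(descriptorValues(t1)[1, ]))
})
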