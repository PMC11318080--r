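test_that("fingerprint registry has 14 kinds with the documented dimensions", {
  reg <- fingerprintKinds()
  expect_equal(nrow(reg), 14L)
  expect_equal(reg$dim[reg$kind == "MACCS"], 167L)
  expect_true(all(reg$dim[reg$kind != "MACCS"] == 1024L))
  expect_equal(sum(reg$type == "circular"), 7L)
  expect_equal(sum(reg$type == "path"), 5L)
  expect_equal(sum(reg$type == "substructure"), 2L)
})

test_that("computeFingerprints returns registry-dimension bit matrices", {
  fps <- computeFingerprints(c("CCO", "c1ccccc1O"),
                             c("MACCS", "ECFP0", "ECFP4", "RDK5"))
  expect_equal(dim(fps$MACCS), c(2L, 167L))
  expect_equal(dim(fps$ECFP0), c(2L, 1024L))
  expect_equal(dim(fps$ECFP4), c(2L, 1024L))
  expect_true(all(fps$ECFP4 %in% c(0, 1)))
  # determinism
  again <- computeFingerprints(c("CCO", "c1ccccc1O"), "ECFP4")$ECFP4
  expect_identical(fps$ECFP4, again)
  # radius ordering: ECFP0 bits are a subset of atom environments, ethanol
  # has fewer distinct environments at radius 0 than radius 2
  expect_lte(sum(fps$ECFP0[1L, ]), sum(fps$ECFP4[1L, ]))
  expect_error(computeFingerprints("CCO", "ECFP8"), "unknown fingerprint")
  expect_error(computeFingerprints("not_a_smiles", "ECFP4"), "invalid SMILES")
})

test_that("PCA reducer centers, projects to 100 dims and zero-pads", {
  smiles <- moleculeSmiles(tinyBench()$molSet)
  fp <- computeFingerprints(smiles, "ECFP4")$ECFP4
  red <- fitReducer(fp)
  at <- applyReducer(fp, red, kind = "ECFP4")
  expect_equal(dim(attrValues(at)), c(length(smiles), 100L))
  expect_equal(attrName(at), "ecfp4")
  # the column-mean row projects to the zero vector (centering)
  mid <- applyReducer(matrix(colMeans(fp), 1L), red)
  expect_lt(max(abs(attrValues(mid))), 1e-8)
  # MACCS (167-d input) reduces to 100-d like the 1024-d kinds
  maccs <- computeFingerprints(smiles, "MACCS")$MACCS
  atm <- applyReducer(maccs, fitReducer(maccs), kind = "MACCS")
  expect_equal(ncol(attrValues(atm)), 100L)
  # fewer rows than target dim -> zero-padded to 100
  small <- fitReducer(fp[1:5, ])
  proj <- attrValues(applyReducer(fp[1:5, ], small))
  expect_equal(ncol(proj), 100L)
  expect_true(all(proj[, 5:100] == 0))
  expect_error(fitReducer(fp[1L, , drop = FALSE]), "fewer than 2 rows")
  expect_error(applyReducer(fp[, 1:50], red), "dimension")
})

test_that("rank-deficient input is reconstructed exactly from the basis", {
  # rank-5 synthetic matrix: PCA with 100 components must reconstruct it
  set.seed(42)
  B <- matrix(rnorm(5 * 60), 5, 60)
  W <- matrix(rnorm(40 * 5), 40, 5)
  X <- W %*% B
  red <- fitReducer(X)
  proj <- attrValues(applyReducer(X, red))
  recon <- proj[, seq_len(ncol(red$rotation)), drop = FALSE] %*%
    t(red$rotation)
  recon <- sweep(recon, 2L, red$center, "+")
  # independent oracle: base svd reconstruction with 5 components
  sv <- svd(sweep(X, 2L, colMeans(X)))
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5]) %*% t(sv$v[, 1:5])
  oracle <- sweep(oracle, 2L, colMeans(X), "+")
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_lt(max(abs(recon - oracle)), 1e-8)
})

test_that("projection is row-order independent and batch independent", {
  smiles <- moleculeSmiles(tinyBench()$molSet)[1:30]
  fp <- computeFingerprints(smiles, "ECFP2")$ECFP2
  red <- fitReducer(fp)
  all <- attrValues(applyReducer(fp, red))
  perm <- rev(seq_len(nrow(fp)))
  permuted <- attrValues(applyReducer(fp[perm, ], red))
  expect_equal(permuted, all[perm, ], tolerance = 1e-12)
  one <- attrValues(applyReducer(fp[3L, , drop = FALSE], red))
  expect_equal(drop(one), all[3L, ], tolerance = 1e-12)
})

test_that("combineAttributes forms dual/triplet attributes", {
  a <- tinyAttrs("ECFP4")
  b <- tinyAttrs("RDK5")
  add <- combineAttributes(list(a, b), "addition")
  expect_equal(attrName(add), "ecfp4_rdk5")
  expect_equal(ncol(attrValues(add)), 100L)
  expect_equal(attrValues(add), attrValues(a) + attrValues(b))
  # addition is commutative
  add2 <- combineAttributes(list(b, a), "addition")
  expect_equal(attrValues(add2), attrValues(add))
  # all-zero part is the additive identity
  zero <- a
  zero@values <- zero@values * 0
  expect_equal(attrValues(combineAttributes(list(a, zero), "addition")),
               attrValues(a))
  cat2 <- combineAttributes(list(a, b), "concatenation")
  expect_equal(ncol(attrValues(cat2)), 200L)
  tri <- combineAttributes(list(a, b, tinyAttrs("MACCS")), "concatenation")
  expect_equal(ncol(attrValues(tri)), 300L)
  expect_equal(attrName(tri), "ecfp4_rdk5_maccs")
  expect_error(combineAttributes(list(a), "addition"), "2 or 3")
  short <- a
  short@values <- short@values[1:10, ]
  expect_error(combineAttributes(list(a, short), "addition"), "row counts")
})

test_that("deep fingerprints are ingested by canonical-SMILES join", {
  ms <- tinyBench()$molSet
  n <- nMolecules(ms)
  set.seed(9)
  emb <- matrix(rnorm(n * 8), n)
  tab <- data.frame(smiles = moleculeSmiles(ms), emb)
  names(tab) <- c("smiles", paste0("v", 0:7))
  perm <- sample(n)
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab[perm, ], tmp, row.names = FALSE)
  m <- loadDeepFingerprints(tmp, ms, tag = "toy")
  expect_equal(dim(m), c(n, 8L))
  expect_equal(attr(m, "kind"), "DEEP:toy")
  # keyed join: permuted table rows give the same matrix
  m2 <- m
  attr(m2, "kind") <- NULL
  expect_equal(unname(m2), unname(emb), tolerance = 1e-12)
  # reduces like any fingerprint
  at <- applyReducer(m, fitReducer(m), kind = "deep_toy")
  expect_equal(ncol(attrValues(at)), 100L)
  # a missing molecule is a fatal, named error
  write.csv(tab[-1L, ], tmp, row.names = FALSE)
  expect_error(loadDeepFingerprints(tmp, ms), moleculeSmiles(ms)[1L],
               fixed = TRUE)
  unlink(tmp)
})

test_that("relationship taxonomy follows the strict-inequality tie rule", {
  # published triplet-attribute example: combined 0.8352 vs 0.8254/0.8221
  r <- classifyRelationship(0.8352, 0.8254, 0.8221)
  expect_equal(r$relation, "R1")
  expect_equal(r$heatmap, 1.0)
  expect_equal(classifyRelationship(0.5, 0.6, 0.7)$relation, "R3")
  expect_equal(classifyRelationship(0.5, 0.6, 0.7)$heatmap, 0.0)
  # tie with one single and above the other -> R2
  expect_equal(classifyRelationship(0.6, 0.6, 0.5)$relation, "R2")
  expect_equal(classifyRelationship(0.6, 0.6, 0.5)$heatmap, 0.5)
  expect_equal(classifyRelationship(0.65, 0.6, 0.7)$relation, "R2")
})
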