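test_that("attributions are exact for linear scorers at any step count", {
  set.seed(8)
  n <- 8
  w <- rnorm(16 * n^3)
  sc <- linearScorer(w, bias = 2.5, size = n)
  vals <- array(runif(16 * n^3), c(n, n, n, 16))
  g <- makeGrid(n = n, values = vals)
  for (steps in c(1, 3, 100)) {
    ag <- integratedGradients(sc, g, steps = steps)
    expect_equal(as.numeric(gridValues(ag)), w * as.numeric(vals),
                 tolerance = 1e-12)
    expect_lte(completenessGap(ag), 1e-9)
  }
  # recomputation from forward passes agrees with the recorded gap
  ag <- integratedGradients(sc, g, steps = 10)
  expect_equal(completenessGap(ag, sc, g), completenessGap(ag),
               tolerance = 1e-9)
})

test_that("a constant scorer yields zero attributions everywhere", {
  n <- 8
  sc <- linearScorer(numeric(16 * n^3), bias = 5, size = n)
  g <- makeGrid(n = n, values = array(runif(16 * n^3), c(n, n, n, 16)))
  ag <- integratedGradients(sc, g, steps = 10)
  expect_true(all(gridValues(ag) == 0))
  expect_equal(completenessGap(ag), 0)
})

test_that("input equal to the baseline gives zero attributions and zero gap", {
  n <- 8
  sc <- buildScorer("clash", seed = 2, size = n)
  g <- makeGrid(n = n)  # all-zero grid = default baseline
  ag <- integratedGradients(sc, g, steps = 5)
  expect_true(all(gridValues(ag) == 0))
  expect_equal(completenessGap(ag), 0, tolerance = 1e-12)
})

test_that("completeness gap is small and non-increasing as steps double", {
  cx <- makeTinyComplex(seed = 6)
  g <- voxelize(cx, size = 8)
  sc <- buildScorer("clash", seed = 6, size = 8)
  dF <- abs(scorerForward(sc, g) -
            scorerForward(sc, numeric(16 * 8^3)))
  gaps <- vapply(c(100, 200, 400, 800), function(s)
    completenessGap(integratedGradients(sc, g, steps = s)), numeric(1))
  expect_lte(gaps[1], max(1e-6, 0.01 * dF))
  expect_true(all(diff(gaps) <= 1e-8))
})

test_that("steps must be >= 1 and baselines must match shapes", {
  g <- makeGrid(n = 8)
  sc <- buildScorer("clash", seed = 1, size = 8)
  expect_error(integratedGradients(sc, g, steps = 0), "steps")
  bad <- makeGrid(n = 8)
  bad@values <- array(0, c(4, 4, 4, 16))
  expect_error(integratedGradients(sc, g, baseline = bad), "shape")
})

test_that("top regions match a brute-force scan over every voxel", {
  set.seed(17)
  for (rep in 1:3) {
    vals <- array(rnorm(6^3 * 16), c(6, 6, 6, 16))
    ag <- makeAttr(vals)
    tr <- topRegions(ag)
    oracle <- bruteTopScan(vals)
    expect_equal(tr@perChannel$i, oracle$perChannel$i)
    expect_equal(tr@perChannel$j, oracle$perChannel$j)
    expect_equal(tr@perChannel$k, oracle$perChannel$k)
    expect_equal(tr@perChannel$value, oracle$perChannel$value)
    expect_identical(tr@selectedChannels, oracle$selectedChannels)
  }
})

test_that("top-region edge cases: ties, corners, single voxel, all-zero", {
  n <- 6
  vals <- array(0, c(n, n, n, 16))
  vals[2, 3, 4, 5] <- -0.7
  tr <- topRegions(makeAttr(vals))
  expect_identical(tr@selectedChannels, 5L)
  expect_equal(unlist(tr@perChannel[5, c("i", "j", "k")], use.names = FALSE),
               c(2, 3, 4))
  expect_equal(tr@perChannel$value[5], -0.7)

  # two equal |maxima|: the lower linear index wins
  vals2 <- array(0, c(n, n, n, 16))
  vals2[4, 1, 1, 1] <- 0.5
  vals2[1, 1, 2, 1] <- -0.5  # higher linear index
  tr2 <- topRegions(makeAttr(vals2))
  expect_equal(unlist(tr2@perChannel[1, c("i", "j", "k")], use.names = FALSE),
               c(4, 1, 1))

  # corner top voxel: in-bounds Chebyshev-1 neighborhood has 7 voxels
  vals3 <- array(0, c(n, n, n, 16))
  vals3[1, 1, 1, 3] <- 1
  tr3 <- topRegions(makeAttr(vals3))
  expect_equal(nrow(tr3@neighbors[[3]]), 7)
  # interior top voxel: 26 neighbors
  vals4 <- array(0, c(n, n, n, 16))
  vals4[3, 3, 3, 3] <- 1
  expect_equal(nrow(topRegions(makeAttr(vals4))@neighbors[[3]]), 26)

  tr0 <- topRegions(makeAttr(array(0, c(n, n, n, 16))))
  expect_true(tr0@empty)
  expect_identical(tr0@selectedChannels, integer(0))
})

test_that("atom attribution assigns voxels to the nearest flagged atom", {
  # single-atom ligand: always the ligand top atom
  lig <- atomRecord("C", 0, 0, 0, source = "ligand", hydrophobic = TRUE)
  prot <- atomRecord("N", 5, 0, 0, source = "protein", donor = TRUE)
  cx <- ComplexStructure(prot, lig, id = "aa")
  g <- voxelize(cx, size = 8)
  ag <- integratedGradients(linearScorer(rep(1, 16 * 8^3), size = 8), g,
                            steps = 1)
  res <- atomAttribution(ag, cx)
  expect_identical(res$topLigandAtom, 1L)
  expect_identical(res$topProteinAtom, 1L)
  expect_true(all(res$scores$score >= 0))

  # atom exactly at a top-voxel center is selected; ties go to lower index
  vals <- array(0, c(8, 8, 8, 16))
  vals[4, 4, 4, 16] <- 1     # ligand occupancy channel top voxel
  ag2 <- makeAttr(vals)
  ctr <- voxelCenter(ag2, c(4L, 4L, 4L))
  lig3 <- atomRecord(c("C", "C"), ctr[1] + c(0.5, -0.5), ctr[2], ctr[3],
                     source = "ligand", hydrophobic = TRUE)
  cx3 <- ComplexStructure(prot, lig3, id = "tie")
  res3 <- atomAttribution(ag2, cx3)
  expect_identical(res3$topLigandAtom, 1L)  # equidistant: lower index
  expect_true(res3$channelTop$assigned[16])

  # no property-matched atom within 3 A: unassigned marker
  vals4 <- array(0, c(8, 8, 8, 16))
  vals4[1, 1, 1, 16] <- 1
  ag4 <- makeAttr(vals4)
  far <- voxelCenter(ag4, c(8L, 8L, 8L))
  lig4 <- atomRecord("C", far[1], far[2], far[3], source = "ligand",
                     hydrophobic = TRUE)
  cx4 <- ComplexStructure(prot, lig4, id = "far")
  expect_message(res4 <- atomAttribution(ag4, cx4), "unassigned")
  expect_false(res4$channelTop$assigned[16])
})
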