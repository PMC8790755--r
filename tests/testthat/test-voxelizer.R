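test_that("kernel hits its closed-form values at r = 0 and r = rvdw", {
  # two-carbon ligand whose geometric center (0.5, 0.5, 0.5) puts atom 1 at
  # (0,0,0) exactly on a voxel center of the even-sided box
  lig <- atomRecord("C", c(0, 1), c(0, 1), c(0, 1), source = "ligand",
                    hydrophobic = TRUE)
  cx <- ComplexStructure(atomRecord("C", 7, 0, 0, source = "protein",
                                    hydrophobic = TRUE), lig, id = "k")
  g <- voxelize(cx, size = 8)
  ctr <- nearestVoxel(g, c(0, 0, 0))
  expect_equal(voxelCenter(g, ctr), c(0, 0, 0))
  v <- gridValues(g)
  expect_equal(v[ctr[1], ctr[2], ctr[3], 9], 1, tolerance = 1e-6)  # lig hydrophobic
  expect_equal(v[ctr[1], ctr[2], ctr[3], 16], 1, tolerance = 1e-6) # lig occupancy

  # voxel center at distance exactly rvdw: value 1 - exp(-1)
  rv <- vdwRadius("C") # 1.7
  expect_equal(occupancyKernel(rv, rv), 1 - exp(-1), tolerance = 1e-12)
  # the grid reproduces the max-aggregated kernel at an off-center voxel
  at <- voxelCenter(g, ctr + c(3L, 0L, 0L))
  expected <- max(occupancyKernel(sqrt(sum(at^2)), rv),
                  occupancyKernel(sqrt(sum((at - c(1, 1, 1))^2)), rv))
  expect_equal(v[ctr[1] + 3, ctr[2], ctr[3], 16], expected, tolerance = 1e-12)
})

test_that("channels without carriers are identically zero", {
  cx <- makeTinyComplex(seed = 3)
  expect_false(any(ligandAtoms(cx)$metal))
  expect_false(any(proteinAtoms(cx)$metal))
  v <- gridValues(voxelize(cx, size = 12))
  expect_true(all(v[, , , 7] == 0))   # protein metal
  expect_true(all(v[, , , 15] == 0))  # ligand metal
  expect_true(max(v) <= 1 && min(v) >= 0)
})

test_that("voxelize matches the brute-force atom-by-voxel oracle exactly", {
  for (seed in 1:3) {
    cx <- generateComplex(seed = seed, pocketRadius = 5, ligandSize = 4,
                          nShellAtoms = 12, pairingFraction = 0.5)
    g <- voxelize(cx, size = 8)
    oracle <- bruteVoxelize(cx, size = 8)
    expect_identical(gridOrigin(g), oracle$origin)
    expect_equal(gridValues(g), oracle$values, tolerance = 1e-14)
  }
})

test_that("the grid is translation-equivariant (box follows the ligand)", {
  cx <- makeTinyComplex(seed = 5)
  shift <- c(3.7, -2.1, 11.4)
  shiftAtoms <- function(a) { a$x <- a$x + shift[1]; a$y <- a$y + shift[2]
    a$z <- a$z + shift[3]; a }
  cx2 <- ComplexStructure(shiftAtoms(proteinAtoms(cx)),
                          shiftAtoms(ligandAtoms(cx)), id = "shifted")
  g1 <- voxelize(cx, size = 12)
  g2 <- voxelize(cx2, size = 12)
  expect_equal(gridValues(g1), gridValues(g2), tolerance = 1e-12)
  expect_equal(gridOrigin(g2) - gridOrigin(g1), shift, tolerance = 1e-12)
})

test_that("kernel decreases monotonically with distance beyond r = 0", {
  r <- seq(0.05, 6, by = 0.05)
  v <- occupancyKernel(r, 1.7)
  expect_true(all(diff(v) <= 0))
  # strictly decreasing wherever 1 - v is representable (the kernel
  # saturates to exactly 1.0 in double precision for r << rvdw)
  strict <- r >= 1.3
  expect_true(all(diff(v[strict]) < 0))
  expect_true(all(v > 0 & v <= 1))
})

test_that("max aggregation keeps values at most 1 under dense atoms", {
  # many overlapping flagged atoms in a small box
  lig <- atomRecord("C", runif(20, -1, 1), runif(20, -1, 1), runif(20, -1, 1),
                    source = "ligand", hydrophobic = TRUE)
  prot <- atomRecord("C", 4, 0, 0, source = "protein", hydrophobic = TRUE)
  g <- voxelize(ComplexStructure(prot, lig, id = "dense"), size = 8)
  expect_lte(max(gridValues(g)), 1)
})

test_that("grid-world mapping is mutually consistent", {
  g <- makeGrid(n = 8, spacing = 1)
  for (idx in list(c(1L, 1L, 1L), c(3L, 5L, 8L), c(8L, 8L, 8L))) {
    expect_identical(nearestVoxel(g, voxelCenter(g, idx)), idx)
  }
  # origin (0,0,0), spacing 1: voxel_center(3,1,1) = (2,0,0)
  g2 <- new("VoxelGrid", values = array(0, c(8, 8, 8, 16)),
            origin = c(0, 0, 0), spacing = 1,
            channels = channelScheme()$name, sourceId = "m")
  expect_equal(voxelCenter(g2, c(3L, 1L, 1L)), c(2, 0, 0))
  # a point 0.4 A from a center rounds to that center
  expect_identical(nearestVoxel(g2, c(2.4, 0, 0)), c(3L, 1L, 1L))
  expect_error(nearestVoxel(g2, c(50, 0, 0)), "outside")
  expect_error(voxelCenter(g2, c(9L, 1L, 1L)), "out of range")
})

test_that("voxelize warns when ligand atoms leave the box", {
  lig <- atomRecord("C", c(0, 30), c(0, 0), c(0, 0), source = "ligand",
                    hydrophobic = TRUE)
  prot <- atomRecord("C", 5, 0, 0, source = "protein", hydrophobic = TRUE)
  expect_warning(voxelize(ComplexStructure(prot, lig, id = "oob"), size = 8),
                 "outside")
})
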