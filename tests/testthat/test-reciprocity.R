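test_that("pair distances follow the grid geometry", {
  n <- 8
  pairs <- channelPairs()
  occ <- pairs[pairs$pair == "occupancy", ]

  vals <- array(0, c(n, n, n, 16))
  vals[3, 3, 3, occ$proteinChannel] <- 0.9
  vals[3, 3, 3, occ$ligandChannel] <- -0.4
  d <- pairDistance(makeAttr(vals), occ)
  expect_equal(as.numeric(d), 0)                    # same voxel
  expect_equal(attr(d, "magnitude"), 1.3)           # |0.9| + |-0.4|

  vals[3, 3, 3, occ$ligandChannel] <- 0
  vals[4, 3, 3, occ$ligandChannel] <- 1
  expect_equal(as.numeric(pairDistance(makeAttr(vals), occ)), 1)  # adjacent

  vals[4, 3, 3, occ$ligandChannel] <- 0
  vals[4, 4, 3, occ$ligandChannel] <- 1                  # face+edge diagonal
  expect_equal(as.numeric(pairDistance(makeAttr(vals), occ)), sqrt(2),
               tolerance = 1e-12)

  # identically-zero channel: undefined with a warning
  vals[, , , occ$ligandChannel] <- 0
  expect_warning(d0 <- pairDistance(makeAttr(vals), occ), "identically zero")
  expect_true(is.na(d0))
})

test_that("the random baseline draws only voxels above the 0.75 gate", {
  n <- 8
  pairs <- channelPairs()
  occ <- pairs[pairs$pair == "occupancy", ]
  vals <- array(0, c(n, n, n, 16))
  vals[2, 2, 2, occ$proteinChannel] <- 0.80   # only qualifying protein voxel
  vals[5, 2, 2, occ$proteinChannel] <- 0.70   # below the gate: not selectable
  vals[2, 5, 2, occ$ligandChannel] <- 0.76    # only qualifying ligand voxel
  g <- makeGrid(n = n, values = vals)
  # forced choice: distance is deterministic regardless of the seed
  for (seed in 1:5)
    expect_equal(baselinePairDistance(g, occ, seed = seed), 3)

  # same seed -> same draw with many candidates
  vals[, , , occ$proteinChannel] <- 0.9
  vals[, , , occ$ligandChannel] <- 0.9
  g2 <- makeGrid(n = n, values = vals)
  expect_equal(baselinePairDistance(g2, occ, seed = 4),
               baselinePairDistance(g2, occ, seed = 4))

  # exactly at the threshold does not qualify (strictly greater)
  vals2 <- array(0, c(n, n, n, 16))
  vals2[1, 1, 1, occ$proteinChannel] <- 0.75
  vals2[1, 1, 1, occ$ligandChannel] <- 0.9
  expect_warning(
    b <- baselinePairDistance(makeGrid(n = n, values = vals2), occ, seed = 1),
    "no voxel above")
  expect_true(is.na(b))
})

test_that("Mann-Whitney U and exact p match hand cases and the permutation oracle", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)   # complete separation: no x above any y
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)  # 2 of 6 assignments as extreme

  # identical samples: p = 1 under exact enumeration
  expect_equal(mannWhitneyU(c(5, 5, 5), c(5, 5, 5))$p, 1)
  x <- c(1.2, 3.4, 2.2); expect_equal(mannWhitneyU(x, x)$p, 1)

  set.seed(5)
  for (rep in 1:8) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(m, mean = 0.5), 1)  # rounding forces occasional ties
    got <- mannWhitneyU(x, y)
    oracle <- brutePermutation(x, y)
    expect_equal(got$U, oracle$U, tolerance = 1e-12)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }

  # no ties: agree with the independent exact implementation in stats
  set.seed(6)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mannWhitneyU(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # large samples: normal approximation close to the stats reference
  set.seed(7)
  x <- rnorm(60); y <- rnorm(80, 0.3)
  expect_equal(mannWhitneyU(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("magnitude-distance correlation handles the degenerate cases", {
  rec <- data.frame(magnitude = c(3, 2, 1), distance = c(1, 2, 3))
  expect_equal(magnitudeDistanceCorrelation(rec), -1)
  # duplicating every record leaves r unchanged
  expect_equal(magnitudeDistanceCorrelation(rbind(rec, rec)), -1)
  rec2 <- data.frame(magnitude = c(1, 1, 1), distance = c(1, 2, 3))
  expect_warning(r2 <- magnitudeDistanceCorrelation(rec2), "constant")
  expect_true(is.na(r2))
  expect_warning(r3 <- magnitudeDistanceCorrelation(rec[1:2, ]), "fewer than 3")
  expect_true(is.na(r3))
})

test_that("pair distance is invariant under an exact 90-degree rotation", {
  cx <- makeTinyComplex(seed = 14)
  rot90 <- function(atoms) {
    lig <- ligandAtoms(cx)
    ctr <- colMeans(as.matrix(lig[lig$heavy, c("x", "y", "z")]))
    xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, ctr)
    xyz <- cbind(-xyz[, 2], xyz[, 1], xyz[, 3])  # 90 deg about z
    atoms$x <- xyz[, 1] + ctr[1]; atoms$y <- xyz[, 2] + ctr[2]
    atoms$z <- xyz[, 3] + ctr[3]
    atoms
  }
  cxR <- ComplexStructure(rot90(proteinAtoms(cx)), rot90(ligandAtoms(cx)),
                          id = "rot90")
  # a 90-degree axis rotation about the ligand center permutes voxels
  # exactly; the scorer must be rotation-invariant for the attribution to
  # permute along. Channel-constant weights are invariant but leave ties
  # (occupancy saturates at exactly 1), so weight voxels by a radial profile:
  # still rotation-invariant, but argmaxes become unique.
  n <- 12
  offs <- (seq_len(n) - 1) - (n - 1) / 2
  r2 <- outer(outer(offs^2, offs^2, "+"), offs^2, "+")
  w <- array(0, c(n, n, n, 16))
  pairs <- channelPairs()
  occ <- pairs[pairs$pair == "occupancy", ]
  w[, , , occ$proteinChannel] <- exp(-r2 / 30)
  w[, , , occ$ligandChannel] <- exp(-r2 / 30)
  lin <- linearScorer(as.numeric(w), size = n)
  d1 <- pairDistance(integratedGradients(lin, voxelize(cx, size = n),
                                         steps = 1), occ)
  d2 <- pairDistance(integratedGradients(lin, voxelize(cxR, size = n),
                                         steps = 1), occ)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
})

test_that("consistency study: degenerate scorer repeats, uniform baseline is ~1-2", {
  cx <- generateComplex(seed = 23, ligandSize = 20)  # >= 20 ligand atoms
  lig <- ligandAtoms(cx)
  # exactly one donor atom forces a degenerate, perfectly consistent ligand
  # top atom under the donor-channel linear scorer
  lig$donor <- FALSE; lig$donor[3] <- TRUE
  lig$acceptor <- FALSE
  cx <- ComplexStructure(proteinAtoms(cx), lig, id = "cons")
  n <- 12
  w <- array(0, c(n, n, n, 16))
  w[, , , 11] <- 1   # ligand donor channel
  lin <- linearScorer(as.numeric(w), size = n)
  res <- consistencyStudy(cx, lin, nVariants = 6, mode = "rotation",
                          seed = 31, steps = 1)
  expect_equal(res$ligand$maxRepeat, 6)
  # uniform-random choice among >= 20 atoms, 10 draws: modal count near 1-2
  expect_gte(res$ligand$randomBaseline, 1)
  expect_lte(res$ligand$randomBaseline, 2.5)
  expect_identical(res$nFailed, 0L)

  expect_error(consistencyStudy(cx, lin, nVariants = 1), "nVariants")
})
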