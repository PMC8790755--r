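test_that("complex generation is deterministic and respects clearances", {
  a <- generateComplex(seed = 11)
  b <- generateComplex(seed = 11)
  expect_identical(ligandAtoms(a), ligandAtoms(b))
  expect_identical(proteinAtoms(a), proteinAtoms(b))

  for (seed in 1:5) {
    cx <- generateComplex(seed = seed)
    expect_gte(minContactDistance(cx), 2.4)
    expect_gte(nrow(ligandAtoms(cx)), 4)
  }
  expect_error(generateComplex(seed = 1, ligandSize = 3), "ligand size")
  expect_error(generateComplex(seed = 1, pocketRadius = 3), "infeasible")
})

test_that("full pairing places a complementary partner near every donor", {
  cx <- generateComplex(seed = 21, pairingFraction = 1.0)
  lig <- ligandAtoms(cx)
  prot <- proteinAtoms(cx)
  donors <- which(lig$donor)
  if (length(donors) > 0) {
    acc <- prot[prot$acceptor, c("x", "y", "z")]
    nNear <- sum(vapply(donors, function(i) {
      d <- sqrt((acc$x - lig$x[i])^2 + (acc$y - lig$y[i])^2 +
                (acc$z - lig$z[i])^2)
      any(d <= 3.4 + 1e-9)
    }, logical(1)))
    expect_gte(nNear, length(donors))
  }
  expect_gte(cx@metadata$nContacts, 1)
})

test_that("clashed poses breach 1.5 A while leaving the protein untouched", {
  for (seed in 1:5) {
    cx <- generateComplex(seed = 100 + seed)
    cl <- makeClashedPose(cx, seed = seed)
    expect_lt(poseMinContact(cl$label), 1.5)
    expect_identical(proteinAtoms(cl$complex), proteinAtoms(cx))
    expect_equal(poseKind(cl$label), "clashed")
  }
  cx <- generateComplex(seed = 200)
  c1 <- makeClashedPose(cx, seed = 9)
  c2 <- makeClashedPose(cx, seed = 9)
  expect_identical(ligandAtoms(c1$complex), ligandAtoms(c2$complex))
})

test_that("clashed and crystal-like poses are disjoint in min contact", {
  # separability that makes the clash task learnable
  for (seed in 1:10) {
    cx <- generateComplex(seed = 300 + seed)
    expect_gte(minContactDistance(cx), 2.4)
    cl <- makeClashedPose(cx, seed = seed)
    expect_lt(minContactDistance(cl$complex), 1.5)
  }
})

test_that("perturbed poses hit the target RMSD within tolerance", {
  cx <- generateComplex(seed = 42)
  p0 <- makePerturbedPose(cx, 0, seed = 1)
  expect_equal(poseRmsdLabel(p0$label), 0)
  expect_identical(ligandAtoms(p0$complex), ligandAtoms(cx))

  for (target in c(0.5, 2.0, 4.5)) {
    p <- makePerturbedPose(cx, target, seed = 7)
    achieved <- poseRMSD(cx, p$complex)
    expect_lte(abs(achieved - target), max(0.05, 0.05 * target) + 1e-9)
    expect_equal(achieved, poseRmsdLabel(p$label), tolerance = 1e-12)
  }
  # pose labels satisfy their class invariants by construction
  set <- syntheticPoseSet("pose", nComplexes = 5, seed = 5,
                          pocketRadius = 6, ligandSize = 6, nShellAtoms = 60)
  for (k in seq_along(set$poseLabels)) {
    lab <- set$poseLabels[[k]]
    expect_true(validObject(lab, test = TRUE))
    if (set$labels[k] == 1) expect_lte(poseRmsdLabel(lab), 2.0)
    else expect_gte(poseRmsdLabel(lab), 4.0)
  }
})

test_that("RMSD matches uniform-translation and hand-computed cases", {
  cx <- generateComplex(seed = 55)
  lig <- ligandAtoms(cx)
  expect_equal(poseRMSD(lig, lig), 0)

  moved <- lig; moved$z <- moved$z + 4
  expect_equal(poseRMSD(lig, moved), 4)

  # 2 atoms, displacements 0 and 2: sqrt((0 + 4)/2) = sqrt(2)
  a <- atomRecord(c("C", "C"), c(0, 3), 0, 0)
  b <- a; b$x[2] <- b$x[2] + 2
  expect_equal(poseRMSD(a, b), sqrt(2), tolerance = 1e-12)

  expect_error(poseRMSD(a, a[1, ]), "differ")

  # brute-force per-atom oracle on random 5-atom poses
  set.seed(99)
  for (rep in 1:5) {
    p1 <- atomRecord(rep("C", 5), rnorm(5), rnorm(5), rnorm(5))
    p2 <- atomRecord(rep("C", 5), rnorm(5), rnorm(5), rnorm(5))
    manual <- sqrt(sum((p1$x - p2$x)^2 + (p1$y - p2$y)^2 +
                       (p1$z - p2$z)^2) / 5)
    expect_equal(poseRMSD(p1, p2), manual, tolerance = 1e-9)
  }
})

test_that("random rotation is rigid and centered on the ligand", {
  cx <- generateComplex(seed = 77)
  rot <- randomRotation(cx, seed = 3)
  allA <- rbind(as.matrix(proteinAtoms(cx)[, c("x", "y", "z")]),
                as.matrix(ligandAtoms(cx)[, c("x", "y", "z")]))
  allB <- rbind(as.matrix(proteinAtoms(rot)[, c("x", "y", "z")]),
                as.matrix(ligandAtoms(rot)[, c("x", "y", "z")]))
  expect_equal(as.numeric(dist(allA)), as.numeric(dist(allB)),
               tolerance = 1e-9)
  ligC <- ligandAtoms(cx); ligR <- ligandAtoms(rot)
  expect_equal(colMeans(as.matrix(ligC[ligC$heavy, c("x", "y", "z")])),
               colMeans(as.matrix(ligR[ligR$heavy, c("x", "y", "z")])),
               tolerance = 1e-9)
  rot2 <- randomRotation(cx, seed = 3)
  expect_identical(ligandAtoms(rot), ligandAtoms(rot2))
})
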