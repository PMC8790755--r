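test_that("a minimal PDB with one CA carbon parses to a single flagged record", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(path, pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"))
  atoms <- readProtein(path)
  expect_equal(nrow(atoms), 1)
  expect_equal(atoms$element, "C")
  expect_equal(atoms$vdw, 1.7)
  expect_equal(atoms$source, "protein")
})

test_that("non-polar hydrogens are dropped, polar hydrogens kept as flagless records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(path, c(
    pdbLine(1, "N", "SER", "A", 1, 0, 0, 0, "N"),
    pdbLine(2, "CA", "SER", "A", 1, 1.5, 0, 0, "C"),
    pdbLine(3, "CB", "SER", "A", 1, 2.2, 1.2, 0, "C"),
    pdbLine(4, "H", "SER", "A", 1, -0.9, 0.4, 0, "H"),    # polar (on N)
    pdbLine(5, "HA", "SER", "A", 1, 1.9, -1.0, 0, "H")))  # non-polar (on CA)
  atoms <- readProtein(path)
  expect_equal(nrow(atoms), 4)  # 3 heavy + 1 polar H
  expect_equal(sum(atoms$heavy), 3)
  h <- atoms[!atoms$heavy, ]
  expect_false(any(unlist(h[, c("hydrophobic", "aromatic", "donor",
                                "acceptor")])))
})

test_that("a waters-only PDB raises the empty-structure error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(path, c(
    pdbLine(1, "O", "HOH", "A", 1, 0, 0, 0, "O", record = "HETATM"),
    pdbLine(2, "O", "HOH", "A", 2, 3, 0, 0, "O", record = "HETATM")))
  expect_error(readProtein(path), "retained")
})

test_that("metal ion HETATM records survive the HETATM filter", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(path, c(
    pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdbLine(2, "ZN", "ZN", "A", 2, 4, 0, 0, "ZN", record = "HETATM"),
    pdbLine(3, "C1", "LIG", "A", 3, 8, 0, 0, "C", record = "HETATM")))
  atoms <- readProtein(path)
  expect_equal(nrow(atoms), 2)  # GLY CA + ZN; organic HETATM dropped
  expect_true(any(atoms$metal))
})

test_that("SDF records parse in order with connectivity-derived flags", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(benzeneRecord(), acetateRecord(), ethylamineRecord()), path)
  ligs <- readLigands(path)
  expect_length(ligs, 3)
  # order preserved: benzene (6 C), acetate (4), ethylamine (3)
  expect_equal(vapply(ligs, nrow, integer(1)), c(6L, 4L, 3L))
  expect_true(all(ligs[[1]]$aromatic) && all(ligs[[1]]$hydrophobic))
  expect_true(all(ligs[[2]]$negative_ionizable[3:4]))  # M CHG honored
  expect_true(ligs[[3]]$positive_ionizable[3])
  expect_true(all(vapply(ligs, function(l) all(l$source == "ligand"),
                         logical(1))))
})

test_that("more than 100 SDF records is a limit error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(unlist(replicate(101, ethylamineRecord(), simplify = FALSE)),
             path)
  expect_error(readLigands(path), "100 ligands")
  # exactly 100 is fine and order is preserved
  path2 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(unlist(replicate(100, ethylamineRecord(), simplify = FALSE)),
             path2)
  expect_length(readLigands(path2), 100)
})

test_that("bundled demo files load into complexes", {
  pdb <- system.file("extdata", "synthetic_pocket.pdb", package = "voxattrib")
  sdf <- system.file("extdata", "synthetic_ligands.sdf", package = "voxattrib")
  cxs <- readComplexes(pdb, sdf)
  expect_gte(length(cxs), 2)
  expect_s4_class(cxs[[1]], "ComplexStructure")
  g <- voxelize(cxs[[1]], size = 16)
  expect_gte(max(gridValues(g)), 0.9)
})

test_that("cube files round-trip origin, spacing, shape and values", {
  set.seed(42)
  vals <- array(0, c(8, 8, 8, 16))
  vals[, , , 16] <- array(runif(512), c(8, 8, 8))
  g <- makeAttr(vals * 2 - 0.5)  # signed values
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(g, 16, path)
  rt <- readCube(path)
  expect_equal(rt$n, 8)
  expect_equal(rt$origin, gridOrigin(g), tolerance = 1e-6)
  expect_equal(rt$spacing, gridSpacing(g), tolerance = 1e-6)
  # values to at least 6 significant figures
  expect_equal(rt$values, gridValues(g)[, , , 16], tolerance = 1e-6)
})

test_that("cube header converts Angstrom to Bohr (zero origin stays zero)", {
  vals <- array(0, c(8, 8, 8, 16)); vals[1, 1, 1, 1] <- 1
  g <- new("AttributionGrid", values = vals, origin = c(0, 0, 0), spacing = 1,
           channels = channelScheme()$name, sourceId = "t",
           baselineId = "zero", steps = 1L, completenessGap = 0)
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(g, 1, path)
  hdr <- readLines(path, n = 4)
  expect_match(hdr[3], "^\\s*0\\s+0\\.0+\\s+0\\.0+\\s+0\\.0+")
  ax <- as.numeric(strsplit(trimws(hdr[4]), "\\s+")[[1]])
  expect_equal(ax[1], 8)                      # voxel count in the header
  expect_equal(ax[2], 1.8897259886, tolerance = 1e-9)  # 1 A in Bohr
})

test_that("cube atom block contains the ligand and boxed protein atoms", {
  cx <- makeTinyComplex(seed = 2)
  g <- voxelize(cx, size = 12)
  ag <- integratedGradients(linearScorer(rep(1, 16 * 12^3), size = 12), g,
                            steps = 1)
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(ag, 16, path, complex = cx)
  rt <- readCube(path)
  expect_gte(nrow(rt$atoms), nrow(ligandAtoms(cx)))
  expect_lte(nrow(rt$atoms),
             nrow(ligandAtoms(cx)) + nrow(proteinAtoms(cx)))
})
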