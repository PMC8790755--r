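#' @include utils.R
NULL

#' The fixed 16-channel scheme
#'
#' Eight pharmacophore properties (hydrophobic, aromatic, donor, acceptor,
#' positive ionizable, negative ionizable, metal, occupancy/excluded volume)
#' for each of protein and ligand: the protein block (channels 1-8) followed
#' by the ligand block (channels 9-16).
#'
#' @return data.frame with columns channel, entity, property, name.
#' @export
channelScheme <- function() {
  data.frame(
    channel = 1:16,
    entity = rep(c("protein", "ligand"), each = 8),
    property = rep(.PHARMA_PROPERTIES, 2),
    name = paste(rep(c("protein", "ligand"), each = 8),
                 rep(.PHARMA_PROPERTIES, 2), sep = "."),
    stringsAsFactors = FALSE)
}

# Fingerprint tying a scorer to the grid geometry + channel order it was
# trained on.
schemeFingerprint <- function(channels, side, spacing) {
  paste0(paste(channels, collapse = "|"), "@", side, "x", format(spacing))
}

# Atom flag matrix (natoms x 8) in property order; occupancy = heavy.
.propertyFlags <- function(atoms) {
  cbind(hydrophobic = atoms$hydrophobic, aromatic = atoms$aromatic,
        donor = atoms$donor, acceptor = atoms$acceptor,
        positive_ionizable = atoms$positive_ionizable,
        negative_ionizable = atoms$negative_ionizable,
        metal = atoms$metal, occupancy = atoms$heavy)
}

#' @describeIn voxelize Voxelize a ComplexStructure.
#'
#' The cubic box is centered at the ligand's geometric center (heavy atoms).
#' For every flagged atom, each voxel within `cutoff` of the atom
#' accumulates the kernel value `n(r) = 1 - exp(-(rvdw/r)^12)` into every
#' channel whose property the atom carries; per voxel, contributions are
#' aggregated by maximum, keeping all values in [0, 1]. Protein and ligand
#' atoms fill the protein (1-8) and ligand (9-16) channel blocks.
#'
#' @param size integer, voxels per side (default 24).
#' @param spacing Angstrom per voxel (default 1.0).
#' @param cutoff kernel cutoff distance in Angstrom (default 5.0).
#' @export
setMethod("voxelize", "ComplexStructure",
function(x, size = 24L, spacing = 1.0, cutoff = 5.0) {
  lig <- ligandAtoms(x)
  if (nrow(lig) == 0) stop("ligand is empty")
  ligHeavy <- lig[lig$heavy, , drop = FALSE]
  center <- colMeans(.coords(ligHeavy))
  size <- as.integer(size)
  origin <- center - spacing * (size - 1) / 2

  halfBox <- spacing * (size - 1) / 2 + spacing / 2
  off <- sweep(.coords(ligHeavy), 2, center)
  if (any(abs(off) > halfBox))
    warning("ligand atoms fall outside the voxelization box; ",
            "their out-of-box contributions are clipped")

  scheme <- channelScheme()
  vals <- numeric(size^3 * 16)

  for (entity in c("protein", "ligand")) {
    atoms <- if (entity == "protein") proteinAtoms(x) else lig
    if (nrow(atoms) == 0) next
    flags <- .propertyFlags(atoms)
    block <- if (entity == "protein") 0L else 8L
    contrib <- voxelize_cpp(.coords(atoms), atoms$vdw,
                            matrix(as.logical(flags), nrow = nrow(atoms)),
                            size, origin, spacing, cutoff)
    idx <- seq.int(block * size^3 + 1L, length.out = 8L * size^3)
    vals[idx] <- pmax(vals[idx], contrib)
  }

  new("VoxelGrid",
      values = array(vals, dim = c(size, size, size, 16)),
      origin = as.numeric(origin), spacing = spacing,
      channels = scheme$name, sourceId = complexId(x))
})

#' World coordinates of a voxel center
#'
#' @param grid a [VolumeGrid].
#' @param index integer vector (i, j, k), 1-based, or a 3-column matrix.
#' @return numeric(3) point in Angstrom (or matrix of points).
#' @export
voxelCenter <- function(grid, index) {
  if (is.matrix(index)) {
    .checkIndex(grid, index)
    return(sweep((index - 1) * gridSpacing(grid), 2, gridOrigin(grid), "+"))
  }
  .checkIndex(grid, matrix(index, nrow = 1))
  gridOrigin(grid) + gridSpacing(grid) * (index - 1)
}

.checkIndex <- function(grid, idx) {
  n <- gridSide(grid)
  if (any(idx < 1 | idx > n)) stop("voxel index out of range")
  invisible(TRUE)
}

#' Nearest voxel index for a world point
#'
#' Inverse of [voxelCenter()]; errors for points outside the box (beyond the
#' half-voxel margin around the outermost centers).
#'
#' @param grid a [VolumeGrid].
#' @param point numeric(3), Angstrom.
#' @return integer(3) 1-based voxel index.
#' @export
nearestVoxel <- function(grid, point) {
  rel <- (point - gridOrigin(grid)) / gridSpacing(grid)
  idx <- as.integer(round(rel)) + 1L
  n <- gridSide(grid)
  if (any(rel < -0.5 | rel > n - 0.5)) stop("point outside the grid box")
  pmin(pmax(idx, 1L), n)
}

#' Occupancy kernel
#'
#' `n(r) = 1 - exp(-(rvdw/r)^12)`, the distance-decaying kernel each atom
#' paints into its channels; equals 1 at r = 0 and 1 - exp(-1) at r = rvdw.
#'
#' @param r distance(s) in Angstrom.
#' @param rvdw van der Waals radius in Angstrom.
#' @export
occupancyKernel <- function(r, rvdw) {
  ifelse(r == 0, 1, 1 - exp(-(rvdw / r)^12))
}
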