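#' @include voxattrib-package.R
NULL

# Atom tables used throughout: data.frame with columns
#   element (character), x, y, z (numeric, Angstrom), vdw (numeric, > 0),
#   source ("protein"/"ligand"), and the 8 logical pharmacophore flags
#   hydrophobic, aromatic, donor, acceptor, positive_ionizable,
#   negative_ionizable, metal, heavy.

.PHARMA_PROPERTIES <- c("hydrophobic", "aromatic", "donor", "acceptor",
                        "positive_ionizable", "negative_ionizable",
                        "metal", "occupancy")

.ATOM_FLAGS <- c("hydrophobic", "aromatic", "donor", "acceptor",
                 "positive_ionizable", "negative_ionizable", "metal", "heavy")

.ATOM_COLS <- c("element", "x", "y", "z", "vdw", "source", .ATOM_FLAGS)

.validAtomTable <- function(df, source, allowEmpty = FALSE) {
  if (!is.data.frame(df)) return("atom table must be a data.frame")
  missing <- setdiff(.ATOM_COLS, names(df))
  if (length(missing))
    return(paste("atom table missing columns:", paste(missing, collapse = ", ")))
  if (!allowEmpty && nrow(df) == 0) return("atom table is empty")
  if (nrow(df) == 0) return(TRUE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(pos))) return("atom positions must be finite")
  if (!all(df$vdw > 0)) return("vdw radii must be positive")
  if (!all(df$source == source))
    return(sprintf("all atoms must have source '%s'", source))
  for (fl in .ATOM_FLAGS)
    if (!is.logical(df[[fl]])) return(sprintf("flag '%s' must be logical", fl))
  bad <- df$metal & (df$donor | df$acceptor | df$aromatic)
  if (any(bad)) return("metal atoms cannot be donor/acceptor/aromatic")
  TRUE
}

#' ComplexStructure: a protein-ligand complex as flagged atom records
#'
#' Holds protein and ligand atom tables (coordinates in Angstrom, van der
#' Waals radii, and the 8 pharmacophore flags per atom) plus an identifier
#' and free-form metadata (e.g. the number of engineered complementary
#' contacts for synthetic complexes).
#'
#' @slot proteinAtoms data.frame of protein atom records.
#' @slot ligandAtoms data.frame of ligand atom records (never empty).
#' @slot id character(1) label.
#' @slot metadata list of optional annotations.
#' @export
setClass("ComplexStructure",
  representation(proteinAtoms = "data.frame", ligandAtoms = "data.frame",
                 id = "character", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msgs <- character()
    v <- .validAtomTable(object@proteinAtoms, "protein", allowEmpty = TRUE)
    if (!isTRUE(v)) msgs <- c(msgs, paste("protein:", v))
    v <- .validAtomTable(object@ligandAtoms, "ligand", allowEmpty = FALSE)
    if (!isTRUE(v)) msgs <- c(msgs, paste("ligand:", v))
    if (length(object@id) != 1L) msgs <- c(msgs, "id must be a single string")
    if (length(msgs)) msgs else TRUE
  })

#' VolumeGrid: shared geometry of voxel-indexed volumes (virtual)
#'
#' @slot values 4-d array, dim c(N, N, N, 16); spatial axes then channel.
#' @slot origin numeric(3), Angstrom; world position of the center of voxel
#'   (1,1,1).
#' @slot spacing numeric(1), Angstrom per voxel.
#' @slot channels character(16) channel names, fixed protein-block then
#'   ligand-block order.
#' @slot sourceId character(1), id of the complex the volume came from.
#' @export
setClass("VolumeGrid",
  representation("VIRTUAL", values = "array", origin = "numeric",
                 spacing = "numeric", channels = "character",
                 sourceId = "character"))

.validVolumeGeometry <- function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 4L) msgs <- c(msgs, "values must be a 4-d array")
  else {
    if (d[1] != d[2] || d[2] != d[3]) msgs <- c(msgs, "grid must be cubic")
    if (d[4] != length(object@channels))
      msgs <- c(msgs, "4th dimension must match number of channels")
  }
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite numbers")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msgs <- c(msgs, "spacing must be a single positive number")
  msgs
}

#' VoxelGrid: 16-channel pharmacophore feature grid (model input)
#'
#' Values lie in [0, 1]: each voxel/channel holds the maximum over
#' contributing atoms of the vdW occupancy kernel
#' n(r) = 1 - exp(-(rvdw/r)^12).
#'
#' @export
setClass("VoxelGrid", contains = "VolumeGrid",
  validity = function(object) {
    msgs <- .validVolumeGeometry(object)
    rng <- suppressWarnings(range(object@values))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msgs <- c(msgs, "feature values must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
  })

#' AttributionGrid: signed per-voxel Integrated Gradients attributions
#'
#' Shares the geometry of the VoxelGrid it was computed for. Records the
#' baseline description, the number of path steps, and the completeness gap
#' |sum(attributions) - (F(x) - F(baseline))| measured from two extra
#' forward passes.
#'
#' @slot baselineId character(1) description of the baseline input.
#' @slot steps integer(1) number of path-integral steps.
#' @slot completenessGap numeric(1), >= 0.
#' @export
setClass("AttributionGrid", contains = "VolumeGrid",
  representation(baselineId = "character", steps = "integer",
                 completenessGap = "numeric"),
  validity = function(object) {
    msgs <- .validVolumeGeometry(object)
    if (!all(is.finite(object@values)))
      msgs <- c(msgs, "attributions must be finite")
    if (length(object@steps) != 1L || object@steps < 1L)
      msgs <- c(msgs, "steps must be a positive integer")
    if (length(object@completenessGap) != 1L ||
        !is.finite(object@completenessGap) || object@completenessGap < 0)
      msgs <- c(msgs, "completenessGap must be a single non-negative number")
    if (length(msgs)) msgs else TRUE
  })

#' TrainedScorer: differentiable grid-to-scalar scoring function
#'
#' Wraps either the package's compact 3D CNN ("cnn" kind) or a linear model
#' ("linear" kind, mainly for exactness checks of the attribution
#' machinery). Classifier forward passes return the pre-sigmoid logit.
#'
#' @slot task one of "clash", "pose", "regression".
#' @slot kind "cnn" or "linear".
#' @slot params numeric parameter vector (flattened weights).
#' @slot arch list describing the architecture (grid size, channels, ...).
#' @slot trainConfig list of training hyperparameters incl. seed.
#' @slot metrics list of held-out metrics (accuracy/precision or pearson_r).
#' @slot fingerprint character(1) channel-scheme + geometry fingerprint;
#'   attribution refuses grids whose fingerprint mismatches.
#' @slot trained logical(1).
#' @export
setClass("TrainedScorer",
  representation(task = "character", kind = "character", params = "numeric",
                 arch = "list", trainConfig = "list", metrics = "list",
                 fingerprint = "character", trained = "logical"),
  prototype(trainConfig = list(), metrics = list(), trained = FALSE),
  validity = function(object) {
    msgs <- character()
    if (!object@task %in% c("clash", "pose", "regression"))
      msgs <- c(msgs, "task must be clash, pose or regression")
    if (!object@kind %in% c("cnn", "linear"))
      msgs <- c(msgs, "kind must be cnn or linear")
    if (!all(is.finite(object@params)))
      msgs <- c(msgs, "parameters must be finite")
    if (length(msgs)) msgs else TRUE
  })

#' PoseLabel: provenance label of a generated ligand pose
#'
#' @slot kind "crystal_like", "good_pose", "bad_pose", "clashed" or
#'   "ambiguous" (RMSD in the excluded (2, 4) Angstrom band).
#' @slot rmsd numeric(1), heavy-atom RMSD to the reference pose (Angstrom).
#' @slot minContact numeric(1), minimum protein-ligand heavy-atom distance.
#' @export
setClass("PoseLabel",
  representation(kind = "character", rmsd = "numeric", minContact = "numeric"),
  validity = function(object) {
    msgs <- character()
    kinds <- c("crystal_like", "good_pose", "bad_pose", "clashed", "ambiguous")
    if (!object@kind %in% kinds)
      msgs <- c(msgs, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@rmsd < 0) msgs <- c(msgs, "rmsd must be >= 0")
    if (object@kind == "clashed" && object@minContact >= 1.5)
      msgs <- c(msgs, "clashed pose must have minContact < 1.5 A")
    if (object@kind == "good_pose" && object@rmsd > 2.0 + 1e-9)
      msgs <- c(msgs, "good pose must have rmsd <= 2 A")
    if (object@kind == "bad_pose" && object@rmsd < 4.0 - 1e-9)
      msgs <- c(msgs, "bad pose must have rmsd >= 4 A")
    if (length(msgs)) msgs else TRUE
  })

#' RegionSummary: most-contributing attribution regions
#'
#' Per channel, the voxel with the highest absolute attribution and its
#' in-bounds Chebyshev-1 neighborhood; plus the channels owning the 5
#' globally largest absolute attributions.
#'
#' @slot perChannel data.frame: channel, name, i, j, k (1-based voxel
#'   index), value (signed attribution at the top voxel).
#' @slot neighbors list of integer matrices (one per channel) of in-bounds
#'   neighbor voxel indices around the top voxel (excluding it).
#' @slot selectedChannels integer vector (length <= 5).
#' @slot empty logical(1): TRUE when the attribution grid is identically 0.
#' @export
setClass("RegionSummary",
  representation(perChannel = "data.frame", neighbors = "list",
                 selectedChannels = "integer", empty = "logical"))

#' DistanceStudyResult: reciprocity analysis of complementary channels
#'
#' @slot records data.frame with one row per complex x channel pair:
#'   complexId, pair, distance (A), baselineDistance (A), magnitude
#'   (summed |attribution| of the two top voxels).
#' @slot tests data.frame with one row per pair: pair, U, p (two-sided
#'   Mann-Whitney vs baseline), r (Pearson magnitude-distance), n.
#' @export
setClass("DistanceStudyResult",
  representation(records = "data.frame", tests = "data.frame"))
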