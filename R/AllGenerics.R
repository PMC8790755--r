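#' @include AllClasses.R
NULL

#' @export
setGeneric("proteinAtoms", function(x) standardGeneric("proteinAtoms"))
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @export
setGeneric("gridChannels", function(x) standardGeneric("gridChannels"))
#' @export
setGeneric("gridSourceId", function(x) standardGeneric("gridSourceId"))
#' @export
setGeneric("gridSide", function(x) standardGeneric("gridSide"))

#' Voxelize a complex into the 16-channel pharmacophore grid
#'
#' @param x a [ComplexStructure].
#' @param ... passed to methods; see the ComplexStructure method.
#' @return a [VoxelGrid].
#' @export
setGeneric("voxelize", function(x, ...) standardGeneric("voxelize"))

#' Evaluate a scorer on a voxel grid
#'
#' Returns the scalar model output: the pre-sigmoid logit for classifiers,
#' the predicted value for regression.
#'
#' @param scorer a [TrainedScorer].
#' @param grid a [VoxelGrid], [AttributionGrid] (values used as-is) or a
#'   numeric vector/array of matching length.
#' @export
setGeneric("scorerForward", function(scorer, grid) standardGeneric("scorerForward"))

#' Gradient of the scorer output with respect to every input voxel
#'
#' @inheritParams scorerForward
#' @return numeric vector of length 16 * N^3 (channels-last layout, matching
#'   `as.vector(gridValues(grid))`).
#' @export
setGeneric("scorerInputGradient",
           function(scorer, grid) standardGeneric("scorerInputGradient"))
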