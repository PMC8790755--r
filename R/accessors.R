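#' @include AllGenerics.R
NULL

#' Construct a ComplexStructure
#'
#' @param proteinAtoms,ligandAtoms atom data.frames (see [atomRecord()]).
#' @param id character(1) label.
#' @param metadata optional list of annotations.
#' @return a validated [ComplexStructure].
#' @export
ComplexStructure <- function(proteinAtoms, ligandAtoms, id = "complex",
                             metadata = list()) {
  new("ComplexStructure", proteinAtoms = proteinAtoms,
      ligandAtoms = ligandAtoms, id = id, metadata = metadata)
}

#' Build an atom record table
#'
#' Helper to assemble one or more atom records with sane defaults: vdW radius
#' looked up from the element, all pharmacophore flags FALSE except `heavy`,
#' which is TRUE for non-hydrogens.
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinates (Angstrom).
#' @param source "protein" or "ligand".
#' @param ... named logical flag overrides (hydrophobic, aromatic, donor,
#'   acceptor, positive_ionizable, negative_ionizable, metal, heavy).
#' @return data.frame of atom records.
#' @export
atomRecord <- function(element, x, y, z, source = "ligand", ...) {
  n <- length(element)
  df <- data.frame(element = element, x = x, y = y, z = z,
                   vdw = vdwRadius(element), source = source,
                   stringsAsFactors = FALSE)
  for (fl in .ATOM_FLAGS) df[[fl]] <- rep(FALSE, n)
  df$heavy <- toupper(element) != "H"
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% .ATOM_FLAGS) stop("unknown flag: ", nm)
    df[[nm]] <- rep_len(as.logical(dots[[nm]]), n)
  }
  df
}

#' Van der Waals radii (Angstrom)
#'
#' Bondi-style values; metals 2.0, unknown elements 1.5.
#' @param element character vector of element symbols.
#' @export
vdwRadius <- function(element) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  el <- toupper(element)
  r <- unname(tab[el])
  r[el %in% .METALS] <- 2.0
  r[is.na(r)] <- 1.5
  r
}

.METALS <- c("ZN", "MG", "MN", "CA", "FE", "NI", "CU", "CO", "NA", "K")

#' @describeIn ComplexStructure protein atom table
#' @param x a ComplexStructure.
#' @export
setMethod("proteinAtoms", "ComplexStructure", function(x) x@proteinAtoms)

#' @describeIn ComplexStructure ligand atom table
#' @export
setMethod("ligandAtoms", "ComplexStructure", function(x) x@ligandAtoms)

#' @describeIn ComplexStructure identifier
#' @export
setMethod("complexId", "ComplexStructure", function(x) x@id)

#' @export
setMethod("gridValues", "VolumeGrid", function(x) x@values)
#' @export
setMethod("gridOrigin", "VolumeGrid", function(x) x@origin)
#' @export
setMethod("gridSpacing", "VolumeGrid", function(x) x@spacing)
#' @export
setMethod("gridChannels", "VolumeGrid", function(x) x@channels)
#' @export
setMethod("gridSourceId", "VolumeGrid", function(x) x@sourceId)
#' @export
setMethod("gridSide", "VolumeGrid", function(x) dim(x@values)[1])

#' Number of Integrated Gradients path steps used for an attribution
#' @param attr an [AttributionGrid].
#' @export
igSteps <- function(attr) {
  stopifnot(is(attr, "AttributionGrid"))
  attr@steps
}

#' Baseline description of an attribution
#' @param attr an [AttributionGrid].
#' @export
igBaselineId <- function(attr) {
  stopifnot(is(attr, "AttributionGrid"))
  attr@baselineId
}

#' Task, metrics and training configuration of a scorer
#' @param scorer a [TrainedScorer].
#' @export
scorerTask <- function(scorer) scorer@task

#' @rdname scorerTask
#' @export
scorerMetrics <- function(scorer) scorer@metrics

#' @rdname scorerTask
#' @export
scorerTrainConfig <- function(scorer) scorer@trainConfig

#' @rdname scorerTask
#' @export
isTrained <- function(scorer) scorer@trained

#' Pose label accessors
#' @param label a [PoseLabel].
#' @export
poseKind <- function(label) label@kind

#' @rdname poseKind
#' @export
poseRmsdLabel <- function(label) label@rmsd

#' @rdname poseKind
#' @export
poseMinContact <- function(label) label@minContact

#' Records and per-pair tests of a distance study
#' @param x a [DistanceStudyResult].
#' @export
studyRecords <- function(x) x@records

#' @rdname studyRecords
#' @export
studyTests <- function(x) x@tests

setMethod("show", "ComplexStructure", function(object) {
  cat("ComplexStructure '", object@id, "': ",
      nrow(object@proteinAtoms), " protein atoms, ",
      nrow(object@ligandAtoms), " ligand atoms\n", sep = "")
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid %dx%dx%dx%d (spacing %.2f A, source '%s')\n",
              d[1], d[2], d[3], d[4], object@spacing, object@sourceId))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; value range [%.3f, %.3f]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "AttributionGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("AttributionGrid %dx%dx%dx%d (source '%s')\n",
              d[1], d[2], d[3], d[4], object@sourceId))
  cat(sprintf("  baseline '%s', %d steps, completeness gap %.3g\n",
              object@baselineId, object@steps, object@completenessGap))
})

setMethod("show", "TrainedScorer", function(object) {
  cat(sprintf("TrainedScorer (%s, %s)%s\n", object@task, object@kind,
              if (object@trained) ", trained" else ", untrained"))
  if (length(object@metrics)) {
    m <- vapply(object@metrics, function(v)
      if (is.numeric(v)) sprintf("%.4g", v) else as.character(v), "")
    cat("  metrics:", paste(names(m), m, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "PoseLabel", function(object) {
  cat(sprintf("PoseLabel: %s (rmsd %.3f A, min contact %.3f A)\n",
              object@kind, object@rmsd, object@minContact))
})

setMethod("show", "RegionSummary", function(object) {
  if (object@empty) {
    cat("RegionSummary: all-zero attribution grid\n")
  } else {
    cat("RegionSummary:", nrow(object@perChannel), "channel maxima; selected channels:",
        paste(object@selectedChannels, collapse = ", "), "\n")
  }
})

setMethod("show", "DistanceStudyResult", function(object) {
  cat("DistanceStudyResult:", nrow(object@records), "records over",
      nrow(object@tests), "channel pairs\n")
  if (nrow(object@tests)) print(object@tests)
})
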