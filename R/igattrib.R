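#' @include scorers.R
NULL

#' Integrated Gradients attribution over a voxel grid
#'
#' Computes, for each input voxel i, the attribution
#' `(x_i - x'_i) * mean_alpha dF/dx_i (x' + alpha (x - x'))`
#' with the path scalar alpha taken at midpoint nodes of a uniform partition
#' of (0, 1). F is the scorer forward pass: the pre-sigmoid logit for
#' classifiers (attributing the logit avoids the sigmoid-extreme saturation
#' the path integral is meant to mitigate). The default baseline x' is the
#' all-zero grid. The completeness gap
#' `|sum(attributions) - (F(x) - F(x'))|` is measured from two extra forward
#' passes and recorded on the result; for a linear scorer the quadrature is
#' exact and the gap vanishes.
#'
#' @param scorer a [TrainedScorer] (differentiable; cnn or linear kind).
#' @param grid the [VoxelGrid] to attribute.
#' @param steps number of path steps (>= 1; default 100).
#' @param baseline optional [VoxelGrid] of identical shape (default: zeros).
#' @return an [AttributionGrid] sharing the grid's geometry.
#' @export
integratedGradients <- function(scorer, grid, steps = 100L, baseline = NULL) {
  stopifnot(is(scorer, "TrainedScorer"), is(grid, "VoxelGrid"))
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  .checkGridCompat(scorer, grid)
  x <- .gridVector(grid)
  if (is.null(baseline)) {
    xb <- numeric(length(x))
    baselineId <- "zero"
  } else {
    if (!identical(dim(gridValues(baseline)), dim(gridValues(grid))))
      stop("baseline shape does not match the input grid")
    xb <- .gridVector(baseline)
    baselineId <- paste0("custom:", gridSourceId(baseline))
  }

  if (scorer@kind == "cnn") {
    pg <- cnn_path_grad_cpp(x, xb, scorer@params, scorer@arch$n,
                            scorer@arch$conv, scorer@arch$hidden, steps)
    meanGrad <- pg$meanGrad
  } else {
    alphas <- (seq_len(steps) - 0.5) / steps
    acc <- numeric(length(x))
    for (a in alphas)
      acc <- acc + scorerInputGradient(scorer, xb + a * (x - xb))
    meanGrad <- acc / steps
  }
  attrVals <- (x - xb) * meanGrad

  fx <- scorerForward(scorer, grid)
  fb <- if (is.null(baseline)) scorerForward(scorer, xb) else
    scorerForward(scorer, baseline)
  gap <- abs(sum(attrVals) - (fx - fb))

  new("AttributionGrid",
      values = array(attrVals, dim = dim(gridValues(grid))),
      origin = gridOrigin(grid), spacing = gridSpacing(grid),
      channels = gridChannels(grid), sourceId = gridSourceId(grid),
      baselineId = baselineId, steps = steps, completenessGap = gap)
}

#' Completeness gap of an attribution
#'
#' With only `attr`, returns the gap recorded when the attribution was
#' computed. With `scorer` and `grid`, recomputes
#' `|sum(attributions) - (F(grid) - F(baseline))|` from fresh forward
#' passes.
#'
#' @param attr an [AttributionGrid].
#' @param scorer,grid,baseline optionally, the scorer/input/baseline the
#'   attribution was produced for.
#' @return non-negative number.
#' @export
completenessGap <- function(attr, scorer = NULL, grid = NULL, baseline = NULL) {
  stopifnot(is(attr, "AttributionGrid"))
  if (is.null(scorer)) return(attr@completenessGap)
  stopifnot(!is.null(grid))
  fx <- scorerForward(scorer, grid)
  fb <- scorerForward(scorer, if (is.null(baseline))
    numeric(length(.gridVector(grid))) else baseline)
  abs(sum(gridValues(attr)) - (fx - fb))
}

# per-channel argmax of |values|; ties broken by lowest linear index
# (x fastest, then y, z). Returns 1-based (i, j, k) and the signed value.
.channelArgmax <- function(vals) {
  n <- dim(vals)[1]
  nchan <- dim(vals)[4]
  out <- data.frame(channel = seq_len(nchan), i = NA_integer_,
                    j = NA_integer_, k = NA_integer_, value = NA_real_)
  for (c in seq_len(nchan)) {
    v <- vals[, , , c]
    lin <- which.max(abs(v))
    idx <- arrayInd(lin, dim(v))
    out$i[c] <- idx[1]; out$j[c] <- idx[2]; out$k[c] <- idx[3]
    out$value[c] <- v[lin]
  }
  out
}

#' Most-contributing regions of an attribution grid
#'
#' For each of the 16 channels, finds the voxel with the highest absolute
#' attribution (ties: lowest linear index, channel-major then x, y, z) and
#' its in-bounds Chebyshev-radius-`neighborRadius` neighborhood
#' (26-connectivity at radius 1). The selected channels are those owning the
#' `nBest` globally largest absolute attributions.
#'
#' @param attr an [AttributionGrid].
#' @param nBest number of globally best voxels defining the selected
#'   channels (default 5).
#' @param neighborRadius Chebyshev neighborhood radius in voxels (default 1).
#' @return a [RegionSummary]; `empty` is TRUE for an all-zero grid.
#' @export
topRegions <- function(attr, nBest = 5L, neighborRadius = 1L) {
  stopifnot(is(attr, "AttributionGrid"))
  vals <- gridValues(attr)
  if (!all(is.finite(vals))) stop("attributions must be finite")
  n <- dim(vals)[1]
  if (all(vals == 0)) {
    return(new("RegionSummary", perChannel = data.frame(), neighbors = list(),
               selectedChannels = integer(0), empty = TRUE))
  }
  pc <- .channelArgmax(vals)
  pc$name <- gridChannels(attr)[pc$channel]

  nb <- lapply(seq_len(nrow(pc)), function(c) {
    ctr <- c(pc$i[c], pc$j[c], pc$k[c])
    rng <- lapply(ctr, function(v)
      max(1L, v - neighborRadius):min(n, v + neighborRadius))
    g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    g[!(g[, 1] == ctr[1] & g[, 2] == ctr[2] & g[, 3] == ctr[3]), ,
      drop = FALSE]
  })

  absv <- abs(as.numeric(vals))
  ord <- order(-absv)[seq_len(min(nBest, length(absv)))]
  ord <- ord[absv[ord] > 0]  # zero attribution never selects a channel
  voxPerChan <- n^3
  sel <- unique(as.integer((ord - 1) %/% voxPerChan) + 1L)

  new("RegionSummary", perChannel = pc, neighbors = nb,
      selectedChannels = sel, empty = FALSE)
}

#' Map voxel attributions onto atoms
#'
#' Every voxel with a nonzero attribution in a channel is assigned to the
#' nearest atom (Euclidean) among the atoms of that channel's entity that
#' carry the channel's property; the atom's score accumulates the voxel's
#' absolute attribution. The top atom per entity is the score argmax
#' (ties: lowest atom index). Each channel's top voxel with no
#' property-matched atom within `maxAssign` of it is reported unassigned.
#'
#' @param attr an [AttributionGrid].
#' @param complex the [ComplexStructure] the grid was voxelized from.
#' @param maxAssign top-voxel assignment cutoff in Angstrom (default 3).
#' @return list: `scores` (data.frame entity, atomIndex, score),
#'   `topLigandAtom`, `topProteinAtom` (indices into the respective atom
#'   tables, NA when the entity has no scored atom), and `channelTop`
#'   (data.frame: channel, atomIndex, distance, assigned).
#' @export
atomAttribution <- function(attr, complex, maxAssign = 3.0) {
  stopifnot(is(attr, "AttributionGrid"), is(complex, "ComplexStructure"))
  vals <- gridValues(attr)
  scheme <- channelScheme()
  pc <- if (all(vals == 0)) NULL else .channelArgmax(vals)

  pScore <- numeric(nrow(proteinAtoms(complex)))
  lScore <- numeric(nrow(ligandAtoms(complex)))
  chTop <- data.frame(channel = scheme$channel, atomIndex = NA_integer_,
                      distance = NA_real_, assigned = FALSE)

  for (c in seq_len(16)) {
    entity <- scheme$entity[c]
    prop <- scheme$property[c]
    atoms <- if (entity == "protein") proteinAtoms(complex) else
      ligandAtoms(complex)
    match <- if (prop == "occupancy") atoms$heavy else atoms[[prop]]
    mi <- which(match)
    if (length(mi) == 0) next
    axyz <- .coords(atoms[mi, , drop = FALSE])

    v <- vals[, , , c]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    idx <- arrayInd(nz, dim(v))
    centers <- voxelCenter(attr, idx)
    d2 <- outer(rowSums(centers^2), rowSums(axyz^2), "+") -
      2 * centers %*% t(axyz)
    nearest <- max.col(-d2, ties.method = "first")
    contrib <- abs(v[nz])
    sc <- vapply(seq_along(mi), function(a)
      sum(contrib[nearest == a]), numeric(1))
    if (entity == "protein") pScore[mi] <- pScore[mi] + sc
    else lScore[mi] <- lScore[mi] + sc

    if (!is.null(pc)) {
      tv <- voxelCenter(attr, c(pc$i[c], pc$j[c], pc$k[c]))
      dt <- sqrt(rowSums(sweep(axyz, 2, tv)^2))
      a <- which.min(dt)
      chTop$distance[c] <- dt[a]
      if (dt[a] <= maxAssign) {
        chTop$atomIndex[c] <- mi[a]
        chTop$assigned[c] <- TRUE
      } else {
        message("channel ", c, " top voxel has no ", entity, " ", prop,
                " atom within ", maxAssign, " A; unassigned")
      }
    }
  }

  topOf <- function(s) if (length(s) == 0 || all(s == 0)) NA_integer_ else
    which.max(s)
  scores <- rbind(
    data.frame(entity = "protein", atomIndex = seq_along(pScore),
               score = pScore),
    data.frame(entity = "ligand", atomIndex = seq_along(lScore),
               score = lScore))
  list(scores = scores, topProteinAtom = topOf(pScore),
       topLigandAtom = topOf(lScore), channelTop = chTop)
}
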