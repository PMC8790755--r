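#' @include igattrib.R
NULL

#' The five complementary channel pairs
#'
#' Protein/ligand channel pairs expected to show attribution reciprocity:
#' hydrophobic-hydrophobic, aromatic-aromatic (pi-stacking), protein
#' acceptor-ligand donor and protein donor-ligand acceptor (hydrogen
#' bonds), occupancy-occupancy (steric component).
#'
#' @return data.frame with columns pair, proteinChannel, ligandChannel.
#' @export
channelPairs <- function() {
  data.frame(
    pair = c("hydrophobic", "aromatic", "acceptor_donor", "donor_acceptor",
             "occupancy"),
    proteinChannel = c(1L, 2L, 4L, 3L, 8L),
    ligandChannel = c(9L, 10L, 11L, 12L, 16L),
    stringsAsFactors = FALSE)
}

# top-|value| voxel of one channel; NULL when the channel is identically 0
.topVoxel <- function(vals, channel) {
  v <- vals[, , , channel]
  if (all(v == 0)) return(NULL)
  lin <- which.max(abs(v))
  idx <- arrayInd(lin, dim(v))
  list(idx = as.integer(idx), value = v[lin])
}

#' Distance between the top-attribution voxels of a channel pair
#'
#' Euclidean distance (Angstrom) between the voxel centers of the per-channel
#' argmax-|attribution| voxels (ties: lowest linear index).
#'
#' @param attr an [AttributionGrid].
#' @param pair one row of [channelPairs()] (or a list with proteinChannel
#'   and ligandChannel).
#' @return distance in Angstrom, or NA (with a warning) when a channel is
#'   identically zero; the attribute "magnitude" carries the summed
#'   |attribution| of the two top voxels.
#' @export
pairDistance <- function(attr, pair) {
  stopifnot(is(attr, "AttributionGrid"))
  vals <- gridValues(attr)
  a <- .topVoxel(vals, pair$proteinChannel)
  b <- .topVoxel(vals, pair$ligandChannel)
  if (is.null(a) || is.null(b)) {
    warning("channel identically zero for pair '", pair$pair,
            "'; distance undefined")
    return(structure(NA_real_, magnitude = NA_real_))
  }
  d <- sqrt(sum((voxelCenter(attr, a$idx) - voxelCenter(attr, b$idx))^2))
  structure(d, magnitude = abs(a$value) + abs(b$value))
}

#' Random-baseline distance for a channel pair
#'
#' Distance between two voxels drawn uniformly at random from the pair's
#' channels among voxels whose feature value exceeds `threshold` (0.75),
#' evaluated on the voxelized feature grid -- the gate guarantees an atom is
#' nearby. Deterministic given `seed`.
#'
#' @param grid the feature [VoxelGrid] of the complex (not the attribution).
#' @param pair one row of [channelPairs()].
#' @param seed integer seed.
#' @param threshold feature-value gate (default 0.75, strict).
#' @return distance in Angstrom, or NA (with a warning) when a channel has
#'   no qualifying voxel.
#' @export
baselinePairDistance <- function(grid, pair, seed = NULL, threshold = 0.75) {
  stopifnot(is(grid, "VoxelGrid"))
  vals <- gridValues(grid)
  pick <- function(channel) {
    v <- vals[, , , channel]
    ok <- which(v > threshold)
    if (length(ok) == 0) return(NULL)
    lin <- if (length(ok) == 1) ok else ok[sample.int(length(ok), 1)]
    arrayInd(lin, dim(v))
  }
  .withSeed(seed, {
    a <- pick(pair$proteinChannel)
    b <- pick(pair$ligandChannel)
    if (is.null(a) || is.null(b)) {
      warning("no voxel above ", threshold, " for pair '", pair$pair,
              "'; baseline undefined")
      return(NA_real_)
    }
    sqrt(sum((voxelCenter(grid, as.integer(a)) -
              voxelCenter(grid, as.integer(b)))^2))
  })
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs with x above y (ties at half weight; U = rank-sum of x
#' minus n(n+1)/2). For min(n, m) <= 8 the two-sided p-value is computed by
#' exhaustive enumeration of all group assignments of the midranks (exact
#' also under ties); otherwise by the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force/disable exact enumeration (default: automatic).
#' @return list with `U` (for the first sample), `p` (two-sided, in (0, 1])
#'   and `method`.
#' @export
mannWhitneyU <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2

  if (is.null(exact)) exact <- min(n, m) <= 8
  if (exact && choose(n + m, n) <= 3e6) {
    dev <- abs(U - mu)
    sets <- combn(n + m, n)
    base <- n * (n + 1) / 2
    Us <- colSums(matrix(r[sets], nrow = n)) - base
    p <- mean(abs(Us - mu) >= dev - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }

  N <- n + m
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p = p, method = "normal approximation")
}

#' Pearson correlation between attribution magnitude and top-voxel distance
#'
#' @param records data.frame with columns `magnitude` (summed |attribution|
#'   of the two top voxels) and `distance` (Angstrom); needs >= 3 complete
#'   records and non-constant variables.
#' @return Pearson r, or NA (with a warning) for degenerate input.
#' @export
magnitudeDistanceCorrelation <- function(records) {
  ok <- stats::complete.cases(records[, c("magnitude", "distance")])
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 3) {
    warning("fewer than 3 complete records; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(rec$magnitude) == 0 || stats::sd(rec$distance) == 0) {
    warning("constant variable; correlation undefined")
    return(NA_real_)
  }
  stats::cor(rec$magnitude, rec$distance)
}

#' Reciprocity distance study over a set of complexes
#'
#' For each complex: voxelize, attribute with Integrated Gradients, and for
#' each complementary channel pair record the top-voxel distance, the summed
#' magnitude of the two top voxels, and one random occupancy-gated baseline
#' distance. Per pair, runs the two-sided Mann-Whitney U test of the
#' attribution distances against the baseline distances and the Pearson
#' magnitude-distance correlation.
#'
#' @param complexes list of [ComplexStructure].
#' @param scorer a trained [TrainedScorer].
#' @param pairs subset of [channelPairs()] (default: all five).
#' @param steps Integrated Gradients steps (default 100).
#' @param seed seed for the baseline draws.
#' @param verbose print progress every 25 complexes.
#' @return a [DistanceStudyResult].
#' @export
distanceStudy <- function(complexes, scorer, pairs = channelPairs(),
                          steps = 100L, seed = 1, verbose = FALSE) {
  recs <- vector("list", length(complexes))
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    grid <- voxelize(cx, size = scorer@arch$n, spacing = scorer@arch$spacing)
    ag <- integratedGradients(scorer, grid, steps = steps)
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      pr <- pairs[k, ]
      d <- suppressWarnings(pairDistance(ag, pr))
      b <- suppressWarnings(baselinePairDistance(
        grid, pr, seed = childSeed(seed, i * nrow(pairs) + k)))
      data.frame(complexId = complexId(cx), pair = pr$pair,
                 distance = as.numeric(d),
                 baselineDistance = b,
                 magnitude = attr(d, "magnitude") %||% NA_real_,
                 stringsAsFactors = FALSE)
    })
    recs[[i]] <- do.call(rbind, rows)
    if (verbose && i %% 25 == 0)
      message("attributed ", i, "/", length(complexes), " complexes")
  }
  records <- do.call(rbind, recs)

  tests <- do.call(rbind, lapply(split(records, records$pair), function(rr) {
    dd <- rr$distance[!is.na(rr$distance)]
    bb <- rr$baselineDistance[!is.na(rr$baselineDistance)]
    if (length(dd) == 0 || length(bb) == 0)
      return(data.frame(pair = rr$pair[1], U = NA_real_, p = NA_real_,
                        r = NA_real_, n = length(dd)))
    mw <- mannWhitneyU(dd, bb)
    r <- suppressWarnings(magnitudeDistanceCorrelation(rr))
    data.frame(pair = rr$pair[1], U = mw$U, p = mw$p, r = r, n = length(dd),
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  new("DistanceStudyResult", records = records, tests = tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consistency of top-attributed atoms under input variation
#'
#' Generates `nVariants` variants of the complex (uniform random rotations,
#' or rigid pose perturbations at 0.5 A target RMSD), attributes each with
#' the scorer, takes the top-scoring atom per entity via
#' [atomAttribution()], and reports the modal atom's repeat count. The
#' random baseline is the expected modal count when atoms are drawn
#' uniformly at random among the entity's heavy atoms, estimated by
#' simulation from the same seed stream.
#'
#' @param complex a [ComplexStructure].
#' @param scorer a trained [TrainedScorer].
#' @param nVariants number of input variants (>= 2; default 10).
#' @param mode "rotation" or "pose_perturbation".
#' @param seed integer seed.
#' @param steps Integrated Gradients steps (default 100).
#' @param nBaselineSim simulation draws for the baseline (default 200).
#' @return list with, per entity, `maxRepeat` (modal count over variants)
#'   and `randomBaseline` (expected modal count under uniform choice), plus
#'   `nFailed`.
#' @export
consistencyStudy <- function(complex, scorer, nVariants = 10L,
                             mode = c("rotation", "pose_perturbation"),
                             seed = 1, steps = 100L, nBaselineSim = 200L) {
  mode <- match.arg(mode)
  nVariants <- as.integer(nVariants)
  if (nVariants < 2L) stop("nVariants must be >= 2")
  topL <- integer(0); topP <- integer(0); failed <- 0L
  for (v in seq_len(nVariants)) {
    sv <- childSeed(seed, v)
    res <- tryCatch({
      var <- if (mode == "rotation") randomRotation(complex, seed = sv) else
        makePerturbedPose(complex, 0.5, seed = sv)$complex
      grid <- voxelize(var, size = scorer@arch$n, spacing = scorer@arch$spacing)
      attr <- integratedGradients(scorer, grid, steps = steps)
      suppressMessages(atomAttribution(attr, var))
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    if (!is.na(res$topLigandAtom)) topL <- c(topL, res$topLigandAtom)
    if (!is.na(res$topProteinAtom)) topP <- c(topP, res$topProteinAtom)
  }
  if (failed > nVariants / 2)
    stop("attribution failed on more than half of the variants (", failed,
         "/", nVariants, ")")

  modal <- function(v) if (length(v) == 0) 0L else max(table(v))
  baseline <- function(nAtoms) {
    if (nAtoms < 1) return(NA_real_)
    sims <- vapply(seq_len(nBaselineSim), function(s)
      modal(sample.int(nAtoms, nVariants, replace = TRUE)), numeric(1))
    mean(sims)
  }
  .withSeed(childSeed(seed, 0L), {
    list(
      ligand = list(maxRepeat = modal(topL),
                    randomBaseline = baseline(sum(ligandAtoms(complex)$heavy))),
      protein = list(maxRepeat = modal(topP),
                     randomBaseline = baseline(sum(proteinAtoms(complex)$heavy))),
      nFailed = failed)
  })
}
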