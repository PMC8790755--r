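#' @include structio.R
NULL

# Synthetic protein-ligand complexes at desk scale: a spherical-shell pocket
# of pseudo-residue atoms around a cavity, a connected random-walk ligand
# inside it, engineered complementary pharmacophore contacts, plus pose
# manipulations (clashes, RMSD-controlled rigid perturbations, rotations).
# All geometry is deterministic given the seed.

.LIGAND_ATOM_TYPES <- data.frame(
  element = c("C", "C", "N", "O", "O"),
  hydrophobic = c(TRUE, TRUE, FALSE, FALSE, FALSE),
  aromatic = c(FALSE, TRUE, FALSE, FALSE, FALSE),
  donor = c(FALSE, FALSE, TRUE, FALSE, TRUE),
  acceptor = c(FALSE, FALSE, FALSE, TRUE, TRUE),
  prob = c(0.40, 0.15, 0.17, 0.17, 0.11),
  stringsAsFactors = FALSE)

.PROTEIN_ATOM_TYPES <- data.frame(
  element = c("C", "C", "N", "O"),
  hydrophobic = c(TRUE, TRUE, FALSE, FALSE),
  aromatic = c(FALSE, TRUE, FALSE, FALSE),
  donor = c(FALSE, FALSE, TRUE, FALSE),
  acceptor = c(FALSE, FALSE, FALSE, TRUE),
  prob = c(0.45, 0.12, 0.21, 0.22),
  stringsAsFactors = FALSE)

.syntheticAtom <- function(type, xyz, source) {
  atomRecord(type$element, xyz[1], xyz[2], xyz[3], source = source,
             hydrophobic = type$hydrophobic, aromatic = type$aromatic,
             donor = type$donor, acceptor = type$acceptor)
}

# vectorized variant: one atom table from a type-table row index vector and
# a coordinate matrix
.syntheticAtoms <- function(types, typeIdx, xyz, source) {
  tt <- types[typeIdx, , drop = FALSE]
  atomRecord(tt$element, xyz[, 1], xyz[, 2], xyz[, 3], source = source,
             hydrophobic = tt$hydrophobic, aromatic = tt$aromatic,
             donor = tt$donor, acceptor = tt$acceptor)
}

#' Generate a synthetic protein-ligand complex
#'
#' Builds a binding pocket as a spherical shell of pseudo-residue atoms
#' around a cavity, grows a connected random-walk heavy-atom ligand inside
#' it, and places a stated fraction of flagged ligand atoms 2.6-3.4 A from a
#' complementary protein partner (donor-acceptor, aromatic-aromatic,
#' hydrophobic-hydrophobic). The minimum protein-ligand heavy-atom distance
#' is >= 2.4 A by construction. Deterministic given `seed`.
#'
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param pocketRadius cavity radius in Angstrom (default 8).
#' @param ligandSize number of ligand heavy atoms (>= 4, default 12).
#' @param pairingFraction fraction of flagged ligand atoms given an
#'   engineered complementary protein contact (default 0.6).
#' @param nShellAtoms number of pocket-wall atoms (default 160).
#' @param id complex label.
#' @return a [ComplexStructure]; `metadata$nContacts` counts the engineered
#'   contacts and `metadata$pkd` maps them onto a pKd-like 2-12 scale.
#' @export
generateComplex <- function(seed = NULL, pocketRadius = 8, ligandSize = 12,
                            pairingFraction = 0.6, nShellAtoms = 160,
                            id = NULL) {
  if (ligandSize < 4) stop("ligand size must be >= 4 atoms")
  if (pocketRadius - 3 < 1.6)
    stop("infeasible parameters: cavity too small for any ligand")
  if (is.null(id))
    id <- sprintf("synth_%s", if (is.null(seed)) "r" else seed)
  .withSeed(seed, {
    lig <- .growLigand(ligandSize, maxRadius = pocketRadius - 3)
    prot <- .growShell(nShellAtoms, pocketRadius, lig)
    paired <- .placeContacts(lig, prot, pairingFraction)
    prot <- paired$prot
    nContacts <- paired$nContacts
    eligible <- max(1L, paired$nEligible)
    ComplexStructure(prot, lig, id = id,
                     metadata = list(nContacts = nContacts,
                                     nEligible = paired$nEligible,
                                     pkd = 2 + 10 * nContacts / eligible,
                                     pocketRadius = pocketRadius))
  })
}

.growLigand <- function(ligandSize, maxRadius, bond = 1.5, minSep = 1.4) {
  xyz <- matrix(0, nrow = ligandSize, ncol = 3)
  placed <- 1L
  tries <- 0L
  while (placed < ligandSize) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop("infeasible parameters: ligand does not fit in the cavity")
    parent <- sample.int(placed, 1)
    cand <- xyz[parent, ] + bond * .randomUnitVector()
    if (sqrt(sum(cand^2)) > maxRadius) next
    d <- sqrt(rowSums(sweep(xyz[seq_len(placed), , drop = FALSE], 2, cand)^2))
    d[parent] <- Inf
    if (any(d < minSep)) next
    placed <- placed + 1L
    xyz[placed, ] <- cand
  }
  typeIdx <- sample.int(nrow(.LIGAND_ATOM_TYPES), ligandSize, replace = TRUE,
                        prob = .LIGAND_ATOM_TYPES$prob)
  .syntheticAtoms(.LIGAND_ATOM_TYPES, typeIdx, xyz, "ligand")
}

.growShell <- function(nShellAtoms, pocketRadius, lig, minClearance = 2.4,
                       minPack = 1.8) {
  ligXyz <- .coords(lig)
  center <- colMeans(ligXyz)
  xyz <- matrix(NA_real_, nrow = nShellAtoms, ncol = 3)
  placed <- 0L
  tries <- 0L
  while (placed < nShellAtoms && tries < nShellAtoms * 60L) {
    tries <- tries + 1L
    u <- .randomUnitVector()
    r <- runif(1, pocketRadius, pocketRadius + 3)
    cand <- center + r * u
    if (min(sqrt(rowSums(sweep(ligXyz, 2, cand)^2))) < minClearance) next
    if (placed > 0 &&
        min(sqrt(rowSums(sweep(xyz[seq_len(placed), , drop = FALSE], 2,
                               cand)^2))) < minPack) next
    placed <- placed + 1L
    xyz[placed, ] <- cand
  }
  xyz <- xyz[seq_len(placed), , drop = FALSE]
  typeIdx <- sample.int(nrow(.PROTEIN_ATOM_TYPES), placed, replace = TRUE,
                        prob = .PROTEIN_ATOM_TYPES$prob)
  .syntheticAtoms(.PROTEIN_ATOM_TYPES, typeIdx, xyz, "protein")
}

# complementary partner type for an eligible ligand atom
.partnerType <- function(ligRow) {
  if (ligRow$donor) {
    data.frame(element = "O", hydrophobic = FALSE, aromatic = FALSE,
               donor = FALSE, acceptor = TRUE)
  } else if (ligRow$acceptor) {
    data.frame(element = "N", hydrophobic = FALSE, aromatic = FALSE,
               donor = TRUE, acceptor = FALSE)
  } else if (ligRow$aromatic) {
    data.frame(element = "C", hydrophobic = TRUE, aromatic = TRUE,
               donor = FALSE, acceptor = FALSE)
  } else {
    data.frame(element = "C", hydrophobic = TRUE, aromatic = FALSE,
               donor = FALSE, acceptor = FALSE)
  }
}

.placeContacts <- function(lig, prot, pairingFraction, minClearance = 2.4) {
  flagged <- which(lig$donor | lig$acceptor | lig$aromatic | lig$hydrophobic)
  nEligible <- length(flagged)
  nPair <- round(pairingFraction * nEligible)
  if (nPair == 0) return(list(prot = prot, nContacts = 0L, nEligible = nEligible))
  chosen <- if (nPair >= nEligible) flagged else sample(flagged, nPair)
  ligXyz <- .coords(lig)
  center <- colMeans(ligXyz)
  protXyz <- .coords(prot)
  newXyz <- matrix(numeric(0), ncol = 3)
  partnerOf <- integer(0)
  for (i in chosen) {
    outward <- ligXyz[i, ] - center
    no <- sqrt(sum(outward^2))
    outward <- if (no > 1e-9) outward / no else .randomUnitVector()
    for (try in 1:200) {
      u <- outward + 0.6 * rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- ligXyz[i, ] + runif(1, 2.6, 3.4) * u
      dl2 <- rowSums(ligXyz^2) - 2 * ligXyz %*% cand + sum(cand^2)
      dl2[i] <- Inf
      if (any(dl2 < minClearance^2)) next
      dp2 <- protXyz^2 %*% c(1, 1, 1) - 2 * protXyz %*% cand + sum(cand^2)
      if (min(dp2) < 1.5^2) next
      if (nrow(newXyz) > 0 &&
          min(rowSums(sweep(newXyz, 2, cand)^2)) < 1.5^2) next
      newXyz <- rbind(newXyz, as.numeric(cand))
      partnerOf <- c(partnerOf, i)
      break
    }
  }
  placedContacts <- length(partnerOf)
  if (placedContacts > 0) {
    partners <- do.call(rbind, lapply(seq_along(partnerOf), function(k)
      .syntheticAtom(.partnerType(lig[partnerOf[k], ]), newXyz[k, ],
                     "protein")))
    prot <- rbind(prot, partners)
  }
  rownames(prot) <- NULL
  list(prot = prot, nContacts = placedContacts, nEligible = nEligible)
}

#' Heavy-atom RMSD between two matched ligand poses
#'
#' Root-mean-square deviation over heavy atoms, without re-superposition
#' (poses share the protein frame, as in docking practice).
#'
#' @param poseA,poseB matched atom data.frames (same atoms, same order) or
#'   [ComplexStructure] objects (their ligands are compared).
#' @return RMSD in Angstrom.
#' @export
poseRMSD <- function(poseA, poseB) {
  if (is(poseA, "ComplexStructure")) poseA <- ligandAtoms(poseA)
  if (is(poseB, "ComplexStructure")) poseB <- ligandAtoms(poseB)
  a <- poseA[poseA$heavy, , drop = FALSE]
  b <- poseB[poseB$heavy, , drop = FALSE]
  if (nrow(a) != nrow(b))
    stop("pose atom counts differ (", nrow(a), " vs ", nrow(b), ")")
  d <- .coords(a) - .coords(b)
  sqrt(mean(rowSums(d^2)))
}

#' Translate the ligand into the pocket wall to create a clashed pose
#'
#' The ligand is rigidly translated along a random direction until the
#' minimum protein-ligand heavy-atom distance falls below 1.5 A (the clash
#' threshold); the protein is unchanged. The achieved minimum contact is
#' sampled in (0.6, 1.45) A for variety across seeds.
#'
#' @param complex a [ComplexStructure].
#' @param seed integer seed.
#' @return list with `complex` (the clashed [ComplexStructure]) and `label`
#'   (a [PoseLabel] of kind "clashed").
#' @export
makeClashedPose <- function(complex, seed = NULL) {
  .withSeed(seed, {
    lig <- ligandAtoms(complex)
    prot <- proteinAtoms(complex)
    pXyz <- .coords(prot[prot$heavy, , drop = FALSE])
    lXyz <- .coords(lig[lig$heavy, , drop = FALSE])
    target <- runif(1, 0.6, 1.45)
    sol <- NULL
    for (attempt in 1:20) {
      u <- .randomUnitVector()
      mind <- function(t) .minPairDist(pXyz, sweep(lXyz, 2, t * u, "+"))
      tHi <- NA
      for (t in seq(0.5, 40, by = 0.5)) {
        if (mind(t) < target) { tHi <- t; break }
      }
      if (is.na(tHi)) next
      tLo <- tHi - 0.5
      for (k in 1:50) {
        tm <- (tLo + tHi) / 2
        if (mind(tm) < target) tHi <- tm else tLo <- tm
      }
      sol <- tHi * u
      break
    }
    if (is.null(sol))
      stop("could not reach a clash within the search bounds")
    newLig <- .setCoords(lig, sweep(.coords(lig), 2, sol, "+"))
    out <- ComplexStructure(prot, newLig, id = paste0(complexId(complex), "_clash"),
                            metadata = complex@metadata)
    mc <- minContactDistance(out)
    list(complex = out,
         label = new("PoseLabel", kind = "clashed",
                     rmsd = poseRMSD(lig, newLig), minContact = mc))
  })
}

#' Random rigid perturbation of the ligand with a target RMSD
#'
#' Applies a random rigid rotation (about the ligand centroid) plus
#' translation whose magnitude is tuned by bisection until the achieved
#' heavy-atom RMSD is within 5% of `targetRmsd` (0.05 A absolute for small
#' targets). Target 0 returns the pose unchanged.
#'
#' @param complex a [ComplexStructure].
#' @param targetRmsd target RMSD in Angstrom (>= 0).
#' @param seed integer seed.
#' @return list with `complex` and `label` (a [PoseLabel]; kind follows the
#'   RMSD bands: good <= 2 A, bad >= 4 A, "ambiguous" in between, clashed
#'   when the move created a < 1.5 A contact).
#' @export
makePerturbedPose <- function(complex, targetRmsd, seed = NULL) {
  if (targetRmsd < 0) stop("targetRmsd must be >= 0")
  lig <- ligandAtoms(complex)
  if (targetRmsd == 0) {
    return(list(complex = complex,
                label = new("PoseLabel", kind = "crystal_like", rmsd = 0,
                            minContact = minContactDistance(complex))))
  }
  .withSeed(seed, {
    axis <- .randomUnitVector()
    tdir <- .randomUnitVector()
    xyz <- .coords(lig)
    centroid <- colMeans(xyz[lig$heavy, , drop = FALSE])
    pose <- function(m) {
      R <- .axisAngleMatrix(axis, min(m * 0.35, pi))
      moved <- sweep(sweep(xyz, 2, centroid) %*% t(R), 2,
                     centroid + m * tdir, "+")
      .setCoords(lig, moved)
    }
    achieved <- function(m) poseRMSD(lig, pose(m))
    tol <- max(0.05, 0.05 * targetRmsd)
    lo <- 0; hi <- max(2 * targetRmsd, 1)
    it <- 0
    while (achieved(hi) < targetRmsd) {
      hi <- hi * 2; it <- it + 1
      if (it > 30) stop("perturbation did not reach the target RMSD")
    }
    m <- NA
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      r <- achieved(mid)
      if (abs(r - targetRmsd) <= tol) { m <- mid; break }
      if (r < targetRmsd) lo <- mid else hi <- mid
    }
    if (is.na(m)) stop("bisection on the perturbation magnitude did not converge")
    newLig <- pose(m)
    out <- ComplexStructure(proteinAtoms(complex), newLig,
                            id = paste0(complexId(complex), "_pert"),
                            metadata = complex@metadata)
    rm <- poseRMSD(lig, newLig)
    mc <- minContactDistance(out)
    kind <- if (mc < 1.5) "clashed"
            else if (rm <= 2) "good_pose"
            else if (rm >= 4) "bad_pose"
            else "ambiguous"
    list(complex = out,
         label = new("PoseLabel", kind = kind, rmsd = rm, minContact = mc))
  })
}

#' Uniform random rotation of the whole complex
#'
#' Rotates protein and ligand jointly about the ligand geometric center
#' (heavy atoms); all pairwise distances are preserved.
#'
#' @param complex a [ComplexStructure].
#' @param seed integer seed.
#' @return the rotated [ComplexStructure].
#' @export
randomRotation <- function(complex, seed = NULL) {
  .withSeed(seed, {
    R <- .randomRotationMatrix()
    lig <- ligandAtoms(complex)
    center <- colMeans(.coords(lig[lig$heavy, , drop = FALSE]))
    rot <- function(atoms)
      .setCoords(atoms, sweep(sweep(.coords(atoms), 2, center) %*% t(R),
                              2, center, "+"))
    ComplexStructure(rot(proteinAtoms(complex)), rot(lig),
                     id = complexId(complex), metadata = complex@metadata)
  })
}

#' Generate a labelled synthetic training set
#'
#' For task "clash": each complex contributes its crystal-like pose
#' (label 0) and one clashed variant (label 1). For task "pose": one good
#' pose (target RMSD in (0.3, 1.9) A, label 1) and one bad pose (target RMSD
#' in (4.3, 6) A, label 0) per complex; the bands are pulled in by the 5%
#' bisection tolerance so achieved RMSDs stay inside the good (<= 2 A) /
#' bad (>= 4 A) definitions. For task "regression": one pose per
#' complex labelled with its synthetic pKd.
#'
#' @param task "clash", "pose" or "regression".
#' @param nComplexes number of base complexes.
#' @param seed integer seed.
#' @param ... passed to [generateComplex()].
#' @return list with `complexes` (list of [ComplexStructure]), `labels`
#'   (numeric vector) and `poseLabels` (list of [PoseLabel] or NULL).
#' @export
syntheticPoseSet <- function(task = c("clash", "pose", "regression"),
                             nComplexes = 500, seed = 1, ...) {
  task <- match.arg(task)
  complexes <- list()
  labels <- numeric(0)
  poseLabels <- list()
  for (i in seq_len(nComplexes)) {
    base <- generateComplex(seed = childSeed(seed, i),
                            id = sprintf("synth_%04d", i), ...)
    if (task == "clash") {
      cl <- makeClashedPose(base, seed = childSeed(seed, i) + 1L)
      complexes <- c(complexes, list(base, cl$complex))
      labels <- c(labels, 0, 1)
      poseLabels <- c(poseLabels, list(
        new("PoseLabel", kind = "crystal_like", rmsd = 0,
            minContact = minContactDistance(base)), cl$label))
    } else if (task == "pose") {
      gSeed <- childSeed(seed, i) + 1L
      good <- makePerturbedPose(base, .withSeed(gSeed, runif(1, 0.3, 1.9)),
                                seed = gSeed + 1L)
      bad <- makePerturbedPose(base, .withSeed(gSeed + 2L, runif(1, 4.3, 6.0)),
                               seed = gSeed + 3L)
      complexes <- c(complexes, list(good$complex, bad$complex))
      labels <- c(labels, 1, 0)
      poseLabels <- c(poseLabels, list(good$label, bad$label))
    } else {
      complexes <- c(complexes, list(base))
      labels <- c(labels, base@metadata$pkd)
      poseLabels <- c(poseLabels, list(NULL))
    }
  }
  list(complexes = complexes, labels = labels, poseLabels = poseLabels,
       task = task)
}
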