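#' @include pharmacophore.R
NULL

.WATER_RES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "TIP4", "SOL", "H2O")

.ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15,
                S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27,
                NI = 28, CU = 29, ZN = 30, BR = 35, I = 53)

.elementZ <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  z <- unname(.ELEMENT_Z[el])
  z[is.na(z)] <- 0
  z
}

# Element inference from a PDB atom name when the element column is absent.
.elementFromName <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "FE", "MN", "CU", "NI", "CO"),
         two, substr(nm, 1, 1))
}

#' Read a protonated protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (first model, first alternate location).
#' Crystallographic waters and organic HETATM groups are dropped; single-atom
#' metal ions are retained so the metal channel stays live. Non-polar
#' hydrogens are discarded; polar hydrogens (within 1.25 A of an N/O/S) are
#' kept as records but carry no pharmacophore flags themselves -- they only
#' confirm the donor flag of their heavy parent. Pharmacophore flags are
#' assigned with [assignProteinFlags()].
#'
#' @param path PDB file path.
#' @return atom data.frame (source = "protein") with pharmacophore flags.
#' @export
readProtein <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no ATOM/HETATM records in '", path, "'")

  # first altloc only
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A", "1"), , drop = FALSE]

  el <- toupper(trimws(at$elesy))
  noEl <- is.na(el) | el == ""
  el[noEl] <- .elementFromName(at$elety[noEl])

  resid <- toupper(at$resid)
  isWater <- resid %in% .WATER_RES
  isMetalIon <- at$type == "HETATM" & el %in% .METALS
  aaRes <- resid %in% c(bio3d::aa.table$aa3, .HIS_NAMES) |
    at$type == "ATOM"
  keep <- !isWater & (aaRes & at$type == "ATOM" | isMetalIon)
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(at) == 0)
    stop("no protein atoms retained from '", path,
         "' (waters and non-protein HETATM are dropped)")

  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      vdw = vdwRadius(el), source = "protein",
                      resid = toupper(at$resid), elety = toupper(at$elety),
                      resno = at$resno, chain = at$chain,
                      stringsAsFactors = FALSE)
  for (fl in .ATOM_FLAGS) atoms[[fl]] <- FALSE
  atoms <- assignProteinFlags(atoms)

  # drop non-polar hydrogens: keep H only when within 1.25 A of N/O/S
  isH <- atoms$element == "H"
  if (any(isH)) {
    pol <- atoms$element %in% c("N", "O", "S")
    keepH <- rep(FALSE, sum(isH))
    if (any(pol)) {
      hxyz <- .coords(atoms[isH, , drop = FALSE])
      pxyz <- .coords(atoms[pol, , drop = FALSE])
      d2 <- outer(rowSums(hxyz^2), rowSums(pxyz^2), "+") - 2 * hxyz %*% t(pxyz)
      keepH <- apply(d2 < 1.25^2, 1, any)
    }
    atoms <- atoms[!isH | replace(logical(nrow(atoms)), which(isH), keepH), ,
                   drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no protein atoms retained from '", path, "'")
  rownames(atoms) <- NULL
  atoms
}

# Formal charges from the "M  CHG" property lines of each SDF record
# (ChemmineR's atom block does not carry them).
.sdfCharges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recEnd <- grep("^\\$\\$\\$\\$", lines)
  recStart <- c(1L, head(recEnd, -1) + 1L)
  lapply(seq_along(recStart), function(i) {
    rec <- lines[recStart[i]:recEnd[i]]
    chgLines <- grep("^M  CHG", rec, value = TRUE)
    out <- list()
    for (cl in chgLines) {
      toks <- as.integer(strsplit(trimws(substring(cl, 7)), "\\s+")[[1]])
      nent <- toks[1]
      for (k in seq_len(nent))
        out[[as.character(toks[2 * k])]] <- toks[2 * k + 1]
    }
    out
  })
}

#' Read ligand records from an SDF file
#'
#' One atom table per molecule record, in file order, with pharmacophore
#' flags assigned from the record's connectivity (aromatic = order-4 bonds)
#' and formal charges (M CHG) via [assignPharmacophoreFlags()]. At most 100
#' records are accepted per file. Unreadable records are skipped with a
#' warning; an error is raised only if every record fails.
#'
#' @param path SDF file path.
#' @param limit maximum number of records (default 100).
#' @return list of ligand atom data.frames (source = "ligand").
#' @export
readLigands <- function(path, limit = 100L) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("failed to parse SDF file '", path,
                                           "': ", conditionMessage(e)))
  nrec <- length(sdf)
  if (nrec == 0) stop("no molecule records in '", path, "'")
  if (nrec > limit)
    stop("SDF contains ", nrec, " records; only ", limit,
         " ligands are allowed per job")
  charges <- tryCatch(.sdfCharges(path), error = function(e) NULL)

  out <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    out[[i]] <- tryCatch({
      ab <- ChemmineR::atomblock(sdf[[i]])
      bb <- ChemmineR::bondblock(sdf[[i]])
      el <- sub("_.*$", "", rownames(ab))
      natoms <- nrow(ab)
      chg <- numeric(natoms)
      if (!is.null(charges) && length(charges) >= i) {
        for (nm in names(charges[[i]]))
          chg[as.integer(nm)] <- charges[[i]][[nm]]
      }
      atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                          vdw = vdwRadius(el), source = "ligand",
                          stringsAsFactors = FALSE)
      for (fl in .ATOM_FLAGS) atoms[[fl]] <- FALSE
      bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
      atoms <- assignPharmacophoreFlags(atoms, bonds, chg)
      # drop explicit hydrogens (heavy-atom featurization; implied-H donor
      # typing has already consumed them)
      atoms <- atoms[atoms$element != "H", , drop = FALSE]
      if (nrow(atoms) == 0) stop("record has no heavy atoms")
      rownames(atoms) <- NULL
      atoms
    }, error = function(e) {
      warning("skipping SDF record ", i, ": ", conditionMessage(e))
      NULL
    })
  }
  ok <- !vapply(out, is.null, logical(1))
  if (!any(ok)) stop("all SDF records failed to parse in '", path, "'")
  out[ok]
}

#' Read a protein plus an SDF of ligand poses into ComplexStructures
#'
#' @param proteinPath PDB file.
#' @param ligandPath SDF file (<= 100 records).
#' @param id label prefix for the complexes.
#' @return list of [ComplexStructure], one per ligand record, in file order.
#' @export
readComplexes <- function(proteinPath, ligandPath, id = NULL) {
  prot <- readProtein(proteinPath)
  ligs <- readLigands(ligandPath)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(ligandPath))
  lapply(seq_along(ligs), function(i)
    ComplexStructure(prot, ligs[[i]], id = sprintf("%s_%03d", id, i)))
}

.BOHR_PER_ANGSTROM <- 1.8897259886

#' Write one channel of a volume as a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and origin (Bohr);
#' three axis records; the atom block (ligand atoms plus protein atoms
#' inside the box, when a complex is supplied); voxel values in z-fastest
#' nesting. The stored origin is the center of the first voxel.
#'
#' @param attr an [AttributionGrid] or [VoxelGrid].
#' @param channel channel index, 1-16.
#' @param path output file.
#' @param complex optional [ComplexStructure] for the atom block.
#' @export
writeCube <- function(attr, channel, path, complex = NULL) {
  stopifnot(is(attr, "VolumeGrid"))
  channel <- as.integer(channel)
  nchan <- length(gridChannels(attr))
  if (channel < 1 || channel > nchan) stop("channel index out of range")

  n <- gridSide(attr)
  sp <- gridSpacing(attr) * .BOHR_PER_ANGSTROM
  org <- gridOrigin(attr) * .BOHR_PER_ANGSTROM

  atoms <- NULL
  if (!is.null(complex)) {
    all <- rbind(proteinAtoms(complex)[, .ATOM_COLS],
                 ligandAtoms(complex)[, .ATOM_COLS])
    lo <- gridOrigin(attr) - gridSpacing(attr) / 2
    hi <- gridOrigin(attr) + gridSpacing(attr) * (n - 0.5)
    inBox <- all$x >= lo[1] & all$x <= hi[1] &
             all$y >= lo[2] & all$y <= hi[2] &
             all$z >= lo[3] & all$z <= hi[3]
    atoms <- all[all$source == "ligand" | inBox, , drop = FALSE]
  }
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("voxattrib volume: channel %s",
                       gridChannels(attr)[channel]),
               sprintf("source %s; lengths in Bohr; z-fastest", gridSourceId(attr))),
             con)
  writeLines(sprintf("%5d%16.9f%16.9f%16.9f", natoms, org[1], org[2], org[3]), con)
  writeLines(sprintf("%5d%16.9f%16.9f%16.9f", n, sp, 0, 0), con)
  writeLines(sprintf("%5d%16.9f%16.9f%16.9f", n, 0, sp, 0), con)
  writeLines(sprintf("%5d%16.9f%16.9f%16.9f", n, 0, 0, sp), con)
  if (natoms > 0) {
    z <- .elementZ(atoms$element)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", z, z,
                       atoms$x * .BOHR_PER_ANGSTROM,
                       atoms$y * .BOHR_PER_ANGSTROM,
                       atoms$z * .BOHR_PER_ANGSTROM), con)
  }

  v <- gridValues(attr)[, , , channel]
  lines <- character(n * n)
  k <- 1L
  for (ix in seq_len(n)) {
    for (iy in seq_len(n)) {
      row <- sprintf("%14.6E", v[ix, iy, ])
      lines[k] <- paste(vapply(split(row, ceiling(seq_along(row) / 6)),
                               paste, "", collapse = ""), collapse = "\n")
      k <- k + 1L
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Counterpart of [writeCube()] for round-trip checks and downstream use.
#'
#' @param path cube file.
#' @return list with `values` (N x N x N array), `origin` (Angstrom, center
#'   of the first voxel), `spacing` (Angstrom), `n`, and `atoms`
#'   (data.frame: z, x, y, z coordinates in Angstrom).
#' @export
readCube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(l) as.numeric(strsplit(trimws(lines[l]), "\\s+")[[1]])
  h3 <- hdr(3)
  natoms <- as.integer(h3[1])
  origin <- h3[2:4] / .BOHR_PER_ANGSTROM
  ax <- lapply(4:6, hdr)
  n <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  if (length(unique(n)) != 1) stop("only cubic grids are supported")
  spacing <- ax[[1]][2] / .BOHR_PER_ANGSTROM
  atoms <- NULL
  if (natoms > 0) {
    am <- do.call(rbind, lapply(7:(6 + natoms), hdr))
    atoms <- data.frame(atomicNumber = as.integer(am[, 1]),
                        x = am[, 3] / .BOHR_PER_ANGSTROM,
                        y = am[, 4] / .BOHR_PER_ANGSTROM,
                        z = am[, 5] / .BOHR_PER_ANGSTROM)
  }
  dataLines <- lines[(7 + natoms):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(dataLines), "\\s+")))
  n <- n[1]
  if (length(vals) != n^3) stop("unexpected number of voxel values")
  arr <- aperm(array(vals, dim = c(n, n, n)), c(3, 2, 1)) # z-fastest on disk
  list(values = arr, origin = origin, spacing = spacing, n = n, atoms = atoms)
}
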