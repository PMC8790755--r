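# Shared fixtures: all inputs are generated in code at test time.

# A VoxelGrid with prescribed values (defaults: all zero, 8^3 x 16, box
# centered at the world origin).
makeGrid <- function(n = 8L, values = NULL, spacing = 1, sourceId = "fixture") {
  if (is.null(values)) values <- array(0, dim = c(n, n, n, 16))
  new("VoxelGrid", values = values, spacing = spacing,
      origin = rep(-spacing * (n - 1) / 2, 3),
      channels = channelScheme()$name, sourceId = sourceId)
}

# Attribution grid wrapper around raw values (geometry as makeGrid).
makeAttr <- function(values, spacing = 1, steps = 1L, gap = 0) {
  n <- dim(values)[1]
  new("AttributionGrid", values = values, spacing = spacing,
      origin = rep(-spacing * (n - 1) / 2, 3),
      channels = channelScheme()$name, sourceId = "fixture",
      baselineId = "zero", steps = as.integer(steps), completenessGap = gap)
}

# Small synthetic complex for unit tests (fits an 8 A-scale box budget).
makeTinyComplex <- function(seed = 1, ...) {
  generateComplex(seed = seed, pocketRadius = 6, ligandSize = 6,
                  nShellAtoms = 60, ...)
}

# Brute-force voxelizer: double loop over atoms x voxels, identical kernel
# and box conventions; the oracle for the C++ implementation.
bruteVoxelize <- function(cx, size = 8L, spacing = 1, cutoff = 5) {
  scheme <- channelScheme()
  lig <- ligandAtoms(cx)
  ligH <- lig[lig$heavy, , drop = FALSE]
  center <- unname(colMeans(as.matrix(ligH[, c("x", "y", "z")])))
  origin <- center - spacing * (size - 1) / 2
  arr <- array(0, dim = c(size, size, size, 16))
  for (ch in 1:16) {
    atoms <- if (scheme$entity[ch] == "protein") proteinAtoms(cx) else lig
    flag <- if (scheme$property[ch] == "occupancy") atoms$heavy
            else atoms[[scheme$property[ch]]]
    atoms <- atoms[flag, , drop = FALSE]
    for (a in seq_len(nrow(atoms))) {
      pos <- c(atoms$x[a], atoms$y[a], atoms$z[a])
      for (i in 1:size) for (j in 1:size) for (k in 1:size) {
        ctr <- origin + spacing * (c(i, j, k) - 1)
        r <- sqrt(sum((ctr - pos)^2))
        if (r > cutoff) next
        v <- if (r == 0) 1 else 1 - exp(-(atoms$vdw[a] / r)^12)
        arr[i, j, k, ch] <- max(arr[i, j, k, ch], v)
      }
    }
  }
  list(values = arr, origin = origin)
}

# Exhaustive permutation oracle for the Mann-Whitney test: U from direct
# pair counting, p from the full enumeration of group assignments.
brutePermutation <- function(x, y) {
  n <- length(x); m <- length(y)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- ustat(x, y)
  mu <- n * m / 2
  pool <- c(x, y)
  sets <- combn(n + m, n)
  us <- apply(sets, 2, function(s) ustat(pool[s], pool[-s]))
  list(U = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-9))
}

# Full-scan oracle for topRegions: per-channel argmax of |values| with
# first-index tie-break, global best-nBest channels.
bruteTopScan <- function(values, nBest = 5) {
  nchan <- dim(values)[4]
  per <- data.frame(channel = seq_len(nchan), i = NA, j = NA, k = NA,
                    value = NA)
  for (c in seq_len(nchan)) {
    v <- values[, , , c]
    best <- -1; bidx <- NULL
    for (k in seq_len(dim(v)[3])) for (j in seq_len(dim(v)[2]))
      for (i in seq_len(dim(v)[1])) {
        if (abs(v[i, j, k]) > best) { best <- abs(v[i, j, k]); bidx <- c(i, j, k) }
      }
    per[c, c("i", "j", "k")] <- bidx
    per$value[c] <- v[bidx[1], bidx[2], bidx[3]]
  }
  absv <- abs(as.numeric(values))
  ord <- order(-absv)[seq_len(min(nBest, length(absv)))]
  ord <- ord[absv[ord] > 0]
  sel <- unique(as.integer((ord - 1) %/% prod(dim(values)[1:3])) + 1L)
  list(perChannel = per, selectedChannels = sel)
}

# Minimal hand-written PDB fixtures
pdbLine <- function(serial, name, resid, chain, resno, x, y, z, element,
                    record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, "", resid, chain, resno, "", x, y, z, 1, 0,
          element)
}

writeTinyPDB <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

sdfRecord <- function(title, atoms, bonds, chg = NULL) {
  # atoms: data.frame(element, x, y, z); bonds: data.frame(a1, a2, order)
  c(title, "  voxattrib-test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(atoms), nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            atoms$x, atoms$y, atoms$z, atoms$element),
    sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$order),
    if (!is.null(chg)) sprintf("M  CHG%3d%s", nrow(chg),
      paste(sprintf("%4d%4d", chg$atom, chg$charge), collapse = "")),
    "M  END", "$$$$")
}

benzeneRecord <- function() {
  ang <- (0:5) * pi / 3
  sdfRecord("benzene",
            data.frame(element = "C", x = 1.396 * cos(ang),
                       y = 1.396 * sin(ang), z = 0),
            data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4))
}

acetateRecord <- function() {
  sdfRecord("acetate",
            data.frame(element = c("C", "C", "O", "O"),
                       x = c(0, 1.52, 2.15, 2.15), y = c(0, 0, 1.05, -1.05),
                       z = 0),
            data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1, 2, 1)),
            chg = data.frame(atom = 4, charge = -1))
}

ethylamineRecord <- function() {
  sdfRecord("ethylamine",
            data.frame(element = c("C", "C", "N"), x = c(0, 1.5, 2.2),
                       y = c(0, 0, 1.2), z = 0),
            data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
}
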