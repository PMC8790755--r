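#' @include voxelizer.R
NULL

# Deterministic, connectivity-based pharmacophore typing. The 8 properties
# are assigned from elements, bonds and formal charges:
#   hydrophobic        C/S with no bonded N/O and not ionizable
#   aromatic           atom participating in an aromatic (order-4) bond
#   donor              N/O/S bearing a (explicit or implied) polar hydrogen
#   acceptor           N/O with a lone pair (formal charge <= 0)
#   positive_ionizable amine/guanidinium/amidinium N or formal charge > 0
#   negative_ionizable carboxylate/phosphate/sulfonate O or formal charge < 0
#   metal              Zn/Mg/Mn/Ca/Fe/Ni/Cu/Co/Na/K (never donor/acceptor/
#                      aromatic)
#   heavy              any non-hydrogen (feeds the occupancy channel)

#' Assign pharmacophore flags from connectivity
#'
#' Applies the deterministic rule set above to an atom table with bond
#' connectivity (as parsed from an SDF record). Unknown elements get the
#' default vdW radius and only the heavy flag, with a warning.
#'
#' @param atoms atom data.frame (at least element, x, y, z columns; flag
#'   columns are (re)computed).
#' @param bonds data.frame/matrix with columns a1, a2 (1-based atom indices)
#'   and order (1, 2, 3, or 4 = aromatic).
#' @param charges optional numeric vector of formal charges (default 0).
#' @return the atom table with the 8 flags and vdw filled in.
#' @export
assignPharmacophoreFlags <- function(atoms, bonds, charges = NULL) {
  n <- nrow(atoms)
  el <- toupper(atoms$element)
  if (is.null(charges)) charges <- numeric(n)
  bonds <- as.data.frame(bonds)
  names(bonds)[1:3] <- c("a1", "a2", "order")

  known <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", .METALS)
  unknown <- !(el %in% known)
  if (any(unknown))
    warning("unknown element(s): ", paste(unique(atoms$element[unknown]),
            collapse = ", "), "; heavy flag only")

  nbrs <- lapply(seq_len(n), function(i) integer(0))
  ords <- lapply(seq_len(n), function(i) numeric(0))
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]; o <- bonds$order[b]
    nbrs[[a1]] <- c(nbrs[[a1]], a2); ords[[a1]] <- c(ords[[a1]], o)
    nbrs[[a2]] <- c(nbrs[[a2]], a1); ords[[a2]] <- c(ords[[a2]], o)
  }

  heavy <- el != "H"
  aromatic <- vapply(seq_len(n), function(i) any(ords[[i]] == 4), logical(1))
  metal <- el %in% .METALS

  explicitH <- vapply(seq_len(n), function(i)
    sum(el[nbrs[[i]]] == "H"), numeric(1))
  valence <- vapply(seq_len(n), function(i) {
    o <- ords[[i]]; o[o == 4] <- 1.5
    sum(o)
  }, numeric(1))
  stdVal <- c(N = 3, O = 2, S = 2)[el]
  impliedH <- pmax(0, round(stdVal + pmax(charges, -stdVal) - valence))
  impliedH[is.na(impliedH)] <- 0
  hasH <- explicitH > 0 | impliedH > 0

  donor <- el %in% c("N", "O", "S") & hasH & !metal
  acceptor <- el %in% c("N", "O") & charges <= 0 & !metal

  hasNO <- vapply(seq_len(n), function(i)
    any(el[nbrs[[i]]] %in% c("N", "O")), logical(1))

  # guanidinium/amidinium: N bonded to a C that carries >= 2 N neighbors and
  # a double bond to one of them
  amidineC <- vapply(seq_len(n), function(i) {
    if (el[i] != "C") return(FALSE)
    nn <- nbrs[[i]]; oo <- ords[[i]]
    isN <- el[nn] == "N"
    sum(isN) >= 2 && any(isN & oo == 2)
  }, logical(1))
  carbonylC <- vapply(seq_len(n), function(i) {
    if (el[i] != "C") return(FALSE)
    any(el[nbrs[[i]]] == "O" & ords[[i]] == 2)
  }, logical(1))
  amineN <- vapply(seq_len(n), function(i) {
    if (el[i] != "N") return(FALSE)
    all(ords[[i]] %in% c(0, 1)) && hasH[i] &&
      !any(carbonylC[nbrs[[i]]] | amidineC[nbrs[[i]]])
  }, logical(1))
  guanidN <- vapply(seq_len(n), function(i) {
    el[i] == "N" && any(amidineC[nbrs[[i]]])
  }, logical(1))
  positive <- (amineN | guanidN | charges > 0) & el == "N" & !metal
  positive <- positive | (charges > 0 & el %in% c("N", "O", "S"))

  # carboxylate/phosphate/sulfonate oxygens: terminal O on a C/P/S center
  # that carries >= 2 terminal oxygens
  degree <- vapply(seq_len(n), function(i) sum(el[nbrs[[i]]] != "H"), numeric(1))
  acidO <- vapply(seq_len(n), function(i) {
    if (el[i] != "O" || degree[i] != 1) return(FALSE)
    x <- nbrs[[i]][el[nbrs[[i]]] != "H"]
    if (length(x) != 1 || !el[x] %in% c("C", "P", "S")) return(FALSE)
    oNbrs <- nbrs[[x]][el[nbrs[[x]]] == "O"]
    sum(degree[oNbrs] == 1) >= 2
  }, logical(1))
  negative <- (acidO | charges < 0) & el %in% c("O", "S") & !metal

  hydrophobic <- el %in% c("C", "S") & !hasNO & !positive & !negative

  atoms$vdw <- vdwRadius(atoms$element)
  atoms$hydrophobic <- hydrophobic & !unknown
  atoms$aromatic <- aromatic & !metal & !unknown
  atoms$donor <- donor & !unknown
  atoms$acceptor <- acceptor & !unknown
  atoms$positive_ionizable <- positive & !unknown
  atoms$negative_ionizable <- negative & !unknown
  atoms$metal <- metal
  atoms$heavy <- heavy
  atoms
}

# Aromatic side-chain ring atoms per residue
.AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.PROT_DONOR <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1", HIS = c("ND1", "NE2"))

.PROT_ACCEPTOR <- list(
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = character(0))

.PROT_POSITIVE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

.PROT_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# side-chain C/S atoms with no bonded N/O
.PROT_HYDROPHOBIC <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1", "CD"), MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = "CB", PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"), THR = "CG2", GLU = c("CB", "CG"), ASP = "CB",
  ASN = "CB", GLN = c("CB", "CG"), CYS = c("CB", "SG"))

.HIS_NAMES <- c("HIS", "HID", "HIE", "HIP", "HSD", "HSE", "HSP")

#' Assign pharmacophore flags to protein atoms by residue/atom-name rules
#'
#' Standard amino-acid typing: aromatic ring atoms of Phe/Tyr/Trp/His,
#' backbone N donor (except Pro) and carbonyl O acceptor, side-chain
#' donors/acceptors, Lys/Arg positive ionizable, Asp/Glu (and OXT) negative
#' ionizable, aliphatic C/S hydrophobic, metal ions by element. If hydrogen
#' records are present, any N/O/S with an H within `hBondMax` is
#' additionally flagged as donor.
#'
#' @param atoms atom data.frame with element, x, y, z, resid and elety
#'   (PDB atom name) columns.
#' @param hBondMax covalent N/O/S-H distance cutoff in Angstrom.
#' @return the atom table with flags filled in.
#' @export
assignProteinFlags <- function(atoms, hBondMax = 1.25) {
  n <- nrow(atoms)
  el <- toupper(atoms$element)
  res <- toupper(atoms$resid)
  res[res %in% .HIS_NAMES] <- "HIS"
  name <- toupper(atoms$elety)

  inList <- function(tab) {
    hit <- logical(n)
    for (r in names(tab)) hit <- hit | (res == r & name %in% tab[[r]])
    hit
  }

  metal <- el %in% .METALS
  aromatic <- inList(.AROMATIC_RING) & !metal
  donor <- (name == "N" & res != "PRO" & el == "N") | inList(.PROT_DONOR)
  acceptor <- (name %in% c("O", "OXT") & el == "O") | inList(.PROT_ACCEPTOR)
  positive <- inList(.PROT_POSITIVE)
  negative <- inList(.PROT_NEGATIVE) | (name == "OXT" & el == "O")
  hydrophobic <- inList(.PROT_HYDROPHOBIC) & el %in% c("C", "S")

  # polar hydrogens confirm donors on their heavy parent
  isH <- el == "H"
  if (any(isH)) {
    hxyz <- .coords(atoms[isH, , drop = FALSE])
    pol <- el %in% c("N", "O", "S")
    if (any(pol)) {
      pxyz <- .coords(atoms[pol, , drop = FALSE])
      d2 <- outer(rowSums(pxyz^2), rowSums(hxyz^2), "+") - 2 * pxyz %*% t(hxyz)
      donor[pol] <- donor[pol] | apply(d2 < hBondMax^2, 1, any)
    }
  }

  atoms$vdw <- vdwRadius(atoms$element)
  atoms$hydrophobic <- hydrophobic
  atoms$aromatic <- aromatic
  atoms$donor <- donor & !metal
  atoms$acceptor <- acceptor & !metal
  atoms$positive_ionizable <- positive & !metal
  atoms$negative_ionizable <- negative & !metal
  atoms$metal <- metal
  atoms$heavy <- !isH
  atoms
}
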