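# Residue-level chemical data: one/three-letter codes, heavy-atom topology,
# ideal side-chain internal coordinates (measured once from ideal residue
# geometries), a minimal backbone-independent rotamer set, van der Waals
# radii, coarse partial charges and hydrogen-bond donor/acceptor roles.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @return converted codes.
#' @keywords internal
aa_three <- function(x) {
  out <- AA3[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid code: ", paste(x[is.na(out)], collapse = ","))
  unname(out)
}

aa_one <- function(x) {
  out <- AA1[toupper(x)]
  if (anyNA(out)) stop("unknown residue name: ", paste(x[is.na(out)], collapse = ","))
  unname(out)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Ideal side-chain internal coordinates. Each atom is placed by NeRF from
# reference atoms (r1, r2, r3) with the given bond/angle; the dihedral is
# chi_k + doff when chi > 0, or the fixed value doff when chi == 0.
SC_TOPO <- data.frame(
  resid = c("ALA","ARG","ARG","ARG","ARG","ARG","ARG","ARG","ASN","ASN","ASN","ASN","ASP","ASP","ASP","ASP","CYS","CYS","GLN","GLN","GLN","GLN","GLN","GLU","GLU","GLU","GLU","GLU","HIS","HIS","HIS","HIS","HIS","HIS","ILE","ILE","ILE","ILE","LEU","LEU","LEU","LEU","LYS","LYS","LYS","LYS","LYS","MET","MET","MET","MET","PHE","PHE","PHE","PHE","PHE","PHE","PHE","PRO","PRO","PRO","SER","SER","THR","THR","THR","TRP","TRP","TRP","TRP","TRP","TRP","TRP","TRP","TRP","TRP","TYR","TYR","TYR","TYR","TYR","TYR","TYR","TYR","VAL","VAL","VAL"),
  atom  = c("CB","CB","CG","CD","NE","CZ","NH1","NH2","CB","CG","OD1","ND2","CB","CG","OD1","OD2","CB","SG","CB","CG","CD","OE1","NE2","CB","CG","CD","OE1","OE2","CB","CG","ND1","CD2","CE1","NE2","CB","CG1","CG2","CD1","CB","CG","CD1","CD2","CB","CG","CD","CE","NZ","CB","CG","SD","CE","CB","CG","CD1","CD2","CE1","CE2","CZ","CB","CG","CD","CB","OG","CB","OG1","CG2","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2","CB","CG","CD1","CD2","CE1","CE2","CZ","OH","CB","CG1","CG2"),
  r1    = c("C","C","N","CA","CB","CG","CD","CD","C","N","CA","CA","C","N","CA","CA","C","N","C","N","CA","CB","CB","C","N","CA","CB","CB","C","N","CA","CA","CB","CG","C","N","N","CA","C","N","CA","CA","C","N","CA","CB","CG","C","N","CA","CB","C","N","CA","CA","CB","CB","CG","C","N","CA","C","N","C","N","N","C","N","CA","CA","CB","CB","CB","CG","CG","CD2","C","N","CA","CA","CB","CB","CG","CD1","C","N","N"),
  r2    = c("N","N","CA","CB","CG","CD","NE","NE","N","CA","CB","CB","N","CA","CB","CB","N","CA","N","CA","CB","CG","CG","N","CA","CB","CG","CG","N","CA","CB","CB","CG","ND1","N","CA","CA","CB","N","CA","CB","CB","N","CA","CB","CG","CD","N","CA","CB","CG","N","CA","CB","CB","CG","CG","CD1","N","CA","CB","N","CA","N","CA","CA","N","CA","CB","CB","CG","CG","CG","CD2","CD2","CE2","N","CA","CB","CB","CG","CG","CD1","CE1","N","CA","CA"),
  r3    = c("CA","CA","CB","CG","CD","NE","CZ","CZ","CA","CB","CG","CG","CA","CB","CG","CG","CA","CB","CA","CB","CG","CD","CD","CA","CB","CG","CD","CD","CA","CB","CG","CG","ND1","CE1","CA","CB","CB","CG1","CA","CB","CG","CG","CA","CB","CG","CD","CE","CA","CB","CG","SD","CA","CB","CG","CG","CD1","CD2","CE1","CA","CB","CG","CA","CB","CA","CB","CB","CA","CB","CG","CG","CD1","CD2","CD2","CE2","CE3","CZ2","CA","CB","CG","CG","CD1","CD2","CE1","CZ","CA","CB","CB"),
  bond  = c(1.529,1.536,1.537,1.527,1.444,1.406,1.391,1.391,1.531,1.507,1.213,1.348,1.530,1.508,1.208,1.341,1.528,1.814,1.529,1.528,1.507,1.212,1.347,1.530,1.531,1.508,1.208,1.343,1.534,1.510,1.351,1.338,1.337,1.337,1.529,1.529,1.530,1.529,1.529,1.530,1.530,1.529,1.530,1.531,1.531,1.529,1.469,1.529,1.528,1.814,1.814,1.529,1.505,1.382,1.383,1.382,1.382,1.381,1.543,1.543,1.544,1.529,1.428,1.529,1.428,1.530,1.529,1.507,1.343,1.464,1.369,1.407,1.396,1.391,1.366,1.377,1.529,1.506,1.382,1.383,1.381,1.381,1.387,1.358,1.529,1.530,1.529),
  angle = c(109.46,111.55,114.54,112.42,111.02,123.00,121.00,119.81,109.45,109.48,119.97,120.01,109.48,109.46,119.96,120.00,109.50,109.50,109.46,109.53,109.54,119.94,120.09,109.48,109.40,109.43,120.00,120.00,111.13,112.98,120.33,129.93,107.86,107.62,109.43,109.55,109.46,109.55,109.42,109.49,109.50,109.50,109.45,109.42,109.44,109.46,109.50,109.43,109.54,109.51,100.03,109.47,109.52,120.06,120.00,120.03,119.98,120.05,104.72,105.06,105.06,109.47,109.51,109.41,109.51,109.53,109.52,109.44,126.50,126.51,109.93,106.08,134.05,119.35,119.80,119.81,109.47,109.50,119.95,119.94,120.07,120.02,119.98,120.13,109.45,109.51,109.49),
  chi   = c(0,0,1,2,3,4,0,0,0,1,2,2,0,1,2,2,0,1,0,1,2,3,3,0,1,2,3,3,0,1,2,2,0,0,0,1,1,2,0,1,2,2,0,1,2,3,4,0,1,2,3,0,1,2,2,0,0,0,0,1,2,0,1,0,1,1,0,1,2,2,0,0,0,0,0,0,0,1,2,2,0,0,0,0,0,1,1),
  doff  = c(120.00,123.56,0.00,0.00,0.00,0.00,-179.99,0.01,120.00,0.00,0.00,179.93,120.01,0.00,0.00,179.94,120.01,0.00,120.07,0.00,0.00,0.00,179.96,119.96,0.00,0.00,0.00,179.94,122.78,0.00,0.00,-179.85,-179.90,0.04,120.07,0.00,119.97,0.00,119.97,0.00,0.00,-120.09,119.97,0.00,0.00,0.00,0.00,120.04,0.00,0.00,0.00,120.09,0.00,0.00,-179.76,-179.99,-179.84,0.05,118.84,0.00,0.00,120.02,0.00,120.00,0.00,120.03,120.03,0.00,0.00,-179.62,-179.94,-179.96,-0.78,179.83,-179.64,-0.22,120.04,0.00,0.00,-179.69,179.98,-179.77,0.10,179.97,120.00,0.00,-120.03),
  stringsAsFactors = FALSE)

SC_TOPO_BY_RES <- split(SC_TOPO, SC_TOPO$resid)

# Minimal backbone-independent rotamer set: the most frequent chi
# combinations per residue type (degrees). One row per rotamer.
ROTAMERS <- list(
  ALA = matrix(numeric(0), nrow = 1),
  GLY = matrix(numeric(0), nrow = 1),
  SER = cbind(c(-65, 180, 62)),
  CYS = cbind(c(-65, 180, 62)),
  THR = cbind(c(62, -60, 180)),
  VAL = cbind(c(180, -60, 62)),
  ILE = cbind(c(-60, -60, 180, 62), c(170, -60, 165, 100)),
  LEU = cbind(c(-60, 180, -85), c(175, 65, 65)),
  ASP = cbind(c(-70, 180, 62), c(-15, 15, 0)),
  ASN = cbind(c(-65, 180, 62), c(-20, 30, -75)),
  HIS = cbind(c(-65, 180, 62), c(-70, 60, 80)),
  PHE = cbind(c(-65, 180, 62), c(90, 80, 90)),
  TYR = cbind(c(-65, 180, 62), c(90, 80, 90)),
  TRP = cbind(c(-65, 180, 62), c(95, -105, -90)),
  PRO = cbind(23.8, -0.03),
  MET = cbind(c(-65, -65, 180, 62), c(180, 180, 180, 180), c(75, 180, 180, 75)),
  GLU = cbind(c(-65, 180, 62), c(180, 180, 180), c(-10, 0, 0)),
  GLN = cbind(c(-65, 180, 62), c(180, 180, 180), c(-25, 0, 20)),
  LYS = cbind(c(-65, 180, 62), c(180, 180, 180), c(180, 180, 180), c(180, 180, 180)),
  ARG = cbind(c(-65, 180, -65, 62), c(180, 180, 180, 180), c(180, 180, 65, 180), c(180, 180, 85, 180))
)

# heavy atoms expected per residue type (backbone + side chain)
expected_atoms <- function(resid) {
  sc <- SC_TOPO_BY_RES[[resid]]
  c(BACKBONE_ATOMS, if (!is.null(sc)) sc$atom)
}

# van der Waals radii by element (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

element_of <- function(elety) {
  e <- sub("^[0-9]*", "", toupper(elety))
  e <- substr(e, 1L, 1L)
  ifelse(e %in% c("C", "N", "O", "S", "H", "P"), e, "C")
}

vdw_radius <- function(elem) {
  r <- VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Coarse heavy-atom partial charges (electron units): formal charges spread
# over the terminal atoms of ionisable groups plus amide-dipole backbone
# charges. Used by the screened-Coulomb terms.
atom_charge <- function(resid, atom) {
  q <- numeric(length(atom))
  q[atom == "N"] <- 0.35
  q[atom == "O"] <- -0.35
  q[resid == "ASP" & atom %in% c("OD1", "OD2")] <- -0.5
  q[resid == "GLU" & atom %in% c("OE1", "OE2")] <- -0.5
  q[resid == "LYS" & atom == "NZ"] <- 1.0
  q[resid == "ARG" & atom %in% c("NH1", "NH2")] <- 0.4
  q[resid == "ARG" & atom == "NE"] <- 0.2
  q[resid == "ASN" & atom == "OD1"] <- -0.3
  q[resid == "ASN" & atom == "ND2"] <- 0.3
  q[resid == "GLN" & atom == "OE1"] <- -0.3
  q[resid == "GLN" & atom == "NE2"] <- 0.3
  # hydroxyls are neutral dipoles in a heavy-atom model (their polarity is
  # carried by the hydrogen-bond term); charging the O alone would give
  # Ser/Thr/Tyr-rich chains spurious net charge
  q
}

# hydrogen-bond roles for heavy atoms (hydrogens are implicit)
hb_role <- function(resid, atom) {
  don <- (atom == "N" & resid != "PRO") |
    (resid == "ARG" & atom %in% c("NE", "NH1", "NH2")) |
    (resid == "LYS" & atom == "NZ") |
    (resid == "ASN" & atom == "ND2") |
    (resid == "GLN" & atom == "NE2") |
    (resid == "TRP" & atom == "NE1") |
    (resid == "HIS" & atom %in% c("ND1", "NE2")) |
    (resid == "SER" & atom == "OG") |
    (resid == "THR" & atom == "OG1") |
    (resid == "TYR" & atom == "OH")
  acc <- (atom == "O") |
    (resid == "ASP" & atom %in% c("OD1", "OD2")) |
    (resid == "GLU" & atom %in% c("OE1", "OE2")) |
    (resid == "ASN" & atom == "OD1") |
    (resid == "GLN" & atom == "OE1") |
    (resid == "HIS" & atom %in% c("ND1", "NE2")) |
    (resid == "SER" & atom == "OG") |
    (resid == "THR" & atom == "OG1") |
    (resid == "TYR" & atom == "OH")
  ifelse(don & acc, "both", ifelse(don, "donor", ifelse(acc, "acceptor", "none")))
}

# charged side-chain atoms used by the buried-charge curation check
is_charged_sc_atom <- function(resid, atom) {
  (resid == "LYS" & atom == "NZ") |
    (resid == "ARG" & atom %in% c("NE", "NH1", "NH2")) |
    (resid == "ASP" & atom %in% c("OD1", "OD2")) |
    (resid == "GLU" & atom %in% c("OE1", "OE2"))
}

charge_sign_sc <- function(resid) {
  ifelse(resid %in% c("LYS", "ARG"), 1L, ifelse(resid %in% c("ASP", "GLU"), -1L, 0L))
}

#' Build ideal side-chain coordinates for one residue
#'
#' Places side-chain heavy atoms by NeRF from the residue's backbone using the
#' ideal internal-coordinate table and a chi vector.
#'
#' @param resid 3-letter residue name.
#' @param bb named list/matrix with rows N, CA, C (3-vectors).
#' @param chi numeric chi vector (missing values fall back to the first
#'   rotamer of the type).
#' @return matrix of side-chain coordinates with atom-name rownames
#'   (0-row matrix for GLY).
#' @keywords internal
build_sidechain <- function(resid, bb, chi = NULL) {
  sc <- SC_TOPO_BY_RES[[resid]]
  if (is.null(sc) || nrow(sc) == 0L)
    return(matrix(numeric(0), ncol = 3L, dimnames = list(NULL, NULL)))
  rot <- ROTAMERS[[resid]]
  nchi <- if (is.matrix(rot)) ncol(rot) else 0L
  if (is.null(chi)) chi <- if (nchi > 0L) rot[1L, ] else numeric(0)
  pos <- list(N = bb[["N"]], CA = bb[["CA"]], C = bb[["C"]])
  out <- matrix(NA_real_, nrow = nrow(sc), ncol = 3L,
                dimnames = list(sc$atom, NULL))
  for (i in seq_len(nrow(sc))) {
    row <- sc[i, ]
    dih <- if (row$chi > 0L) {
      ch <- if (row$chi <= length(chi)) chi[row$chi] else 0
      ch + row$doff
    } else row$doff
    p <- place_atom(pos[[row$r1]], pos[[row$r2]], pos[[row$r3]],
                    row$bond, row$angle, dih)
    pos[[row$atom]] <- p
    out[i, ] <- p
  }
  out
}
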