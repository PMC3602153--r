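#' Amino-acid alphabet used for all sparse encodings
#'
#' The 20 standard amino acids ordered alphabetically by one-letter code.
#' This order fixes the bit layout of [encode_peptide()] and the row order
#' of every [build_pwm()] matrix.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# reverse map 3-letter -> 1-letter
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Van der Waals radii (Bondi), by element
#'
#' Used by [shrake_rupley()]. Values in Angstroms.
#'
#' @format Named numeric vector.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)

#' Reference maximal accessible surface areas (Gly-X-Gly, theoretical)
#'
#' Tien et al. (2013) theoretical maxima, in square Angstroms; used to turn
#' absolute per-residue areas into relative accessibilities.
#'
#' @format Named numeric vector (names are 1-letter codes).
#' @export
MAX_ASA <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
             H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
             P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
             W = 285, Y = 263)

#' Kyte-Doolittle hydropathy scale
#'
#' @format Named numeric vector (names are 1-letter codes).
#' @export
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                   G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                   M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Formal residue charges (sum over side chain at physiological pH).
RESIDUE_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5)

# Canonical charge-bearing side-chain atoms; the formal charge is split
# evenly over the atoms present.  When none of these atoms exist in a
# charged residue (e.g. reduced pseudo-atom side chains), the whole charge
# is placed on the side-chain atom farthest from CA.
CHARGED_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  LYS = "NZ",
  ARG = c("NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

# Side-chain hydrogen-bond donor atoms per residue.
SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

# Side-chain hydrogen-bond acceptor atoms per residue.
SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
  TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

# Covalent antecedent of common polar atoms (used for the no-hydrogen
# donor angle criterion); anything absent falls back to the nearest atom
# of the same residue.
ANTECEDENTS <- c(N = "CA", O = "C", OXT = "C",
                 OG = "CB", OG1 = "CB", SG = "CB", OH = "CZ",
                 ND2 = "CG", NE2 = "CD", OD1 = "CG", OE1 = "CD",
                 NZ = "CE", NE = "CD", NH1 = "CZ", NH2 = "CZ",
                 ND1 = "CG", NE1 = "CD1", OD2 = "CG", OE2 = "CD",
                 SD = "CG")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
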