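# Atom typing tables shared by the SASA and interaction-fingerprint code.
# All assignments are the standard biochemistry ones for the 20 canonical
# residues; they are deliberately data, not logic, so a user can override them
# (see the `typing` arguments of the detectors).

#' Bondi van der Waals radii (Angstrom) by element symbol
#'
#' Used by [shrake_rupley_sasa()]. Elements not listed raise an error unless a
#' `default_radius` is supplied.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

# Hydrogen-bond donor / acceptor heavy atoms. Backbone N donates (except PRO),
# backbone O (and OXT) accepts, for every residue type. Sulfur is excluded
# from both roles. Hydroxyls (SER/THR/TYR) and HIS ring nitrogens play both.
.hbond_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH"
)
.hbond_acceptors <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)

# Residues counted as apolar for hydrophobic contacts (TYR included per the
# interaction-calculator convention; its hydroxyl still h-bonds).
.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")

# Aromatic ring definitions: list of (residue -> list of ring atom-name sets).
.aromatic_rings <- list(
  PHE = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(five = c("CG", "CD1", "CD2", "NE1", "CE2"),
             six  = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(five = c("CG", "ND1", "CD2", "CE1", "NE2"))
)

# Side-chain charged groups at pH 7. HIS is excluded from the cationic set by
# default (configurable via `include_his`).
.cationic_groups <- function(include_his = FALSE) {
  g <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
  if (include_his) g$HIS <- c("ND1", "NE2")
  g
}
.anionic_groups <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Sulfur atoms eligible for aromatic-sulphur contacts.
.sulphur_atoms <- list(CYS = "SG", MET = "SD")

.is_mainchain <- function(name) name %in% .backbone_names
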