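# Built-in chemistry templates for standard amino acids and water.
#
# Each entry gives, by PDB v3 atom name: intra-residue bonds, hydrogen-bond
# donors (heavy atom -> attached polar hydrogens), acceptors, aromatic rings
# (ordered), and formally charged groups at physiological pH. Only polar
# hydrogens are required to be present; topologies may omit nonpolar ones.
# Hydrophobic carbons are not listed: they are derived from the bond graph
# (carbon with no bonded N or O).

.backbone_template <- list(
  bonds     = list(c("N", "H"), c("N", "CA"), c("CA", "C"), c("C", "O")),
  donors    = list(N = "H"),
  acceptors = "O"
)

.sidechain_templates <- list(
  ALA = list(bonds = list(c("CA", "CB"))),
  ARG = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
                 c("NE", "HE"), c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2"),
                 c("NH1", "HH11"), c("NH1", "HH12"), c("NH2", "HH21"), c("NH2", "HH22")),
    donors = list(NE = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
    charged = list(list(atoms = c("NE", "CZ", "NH1", "NH2"), sign = 1L))
  ),
  ASN = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2"),
                 c("ND2", "HD21"), c("ND2", "HD22")),
    donors = list(ND2 = c("HD21", "HD22")), acceptors = "OD1"
  ),
  ASP = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
    acceptors = c("OD1", "OD2"),
    charged = list(list(atoms = c("CG", "OD1", "OD2"), sign = -1L))
  ),
  CYS = list(bonds = list(c("CA", "CB"), c("CB", "SG"))),
  GLN = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                 c("CD", "NE2"), c("NE2", "HE21"), c("NE2", "HE22")),
    donors = list(NE2 = c("HE21", "HE22")), acceptors = "OE1"
  ),
  GLU = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                 c("CD", "OE2")),
    acceptors = c("OE1", "OE2"),
    charged = list(list(atoms = c("CD", "OE1", "OE2"), sign = -1L))
  ),
  GLY = list(),
  HIS = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("ND1", "CE1"),
                 c("CE1", "NE2"), c("NE2", "CD2"), c("CD2", "CG"), c("ND1", "HD1")),
    donors = list(ND1 = "HD1"), acceptors = "NE2",
    rings = list(c("CG", "ND1", "CE1", "NE2", "CD2"))
  ),
  ILE = list(bonds = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1"))),
  LEU = list(bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"))),
  LYS = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
                 c("CE", "NZ"), c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")),
    donors = list(NZ = c("HZ1", "HZ2", "HZ3")),
    charged = list(list(atoms = "NZ", sign = 1L))
  ),
  MET = list(bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE"))),
  PHE = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CD1", "CE1"),
                 c("CE1", "CZ"), c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG")),
    rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  ),
  PRO = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
    no_backbone_nh = TRUE
  ),
  SER = list(
    bonds = list(c("CA", "CB"), c("CB", "OG"), c("OG", "HG")),
    donors = list(OG = "HG"), acceptors = "OG"
  ),
  THR = list(
    bonds = list(c("CA", "CB"), c("CB", "OG1"), c("OG1", "HG1"), c("CB", "CG2")),
    donors = list(OG1 = "HG1"), acceptors = "OG1"
  ),
  TRP = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CD1", "NE1"),
                 c("NE1", "CE2"), c("CE2", "CD2"), c("CD2", "CG"), c("NE1", "HE1"),
                 c("CD2", "CE3"), c("CE3", "CZ3"), c("CZ3", "CH2"), c("CH2", "CZ2"),
                 c("CZ2", "CE2")),
    donors = list(NE1 = "HE1"),
    rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                 c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
  ),
  TYR = list(
    bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CD1", "CE1"),
                 c("CE1", "CZ"), c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG"),
                 c("CZ", "OH"), c("OH", "HH")),
    donors = list(OH = "HH"), acceptors = "OH",
    rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  ),
  VAL = list(bonds = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")))
)

.water_resnames <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL", "H2O")

.water_template <- list(
  oxygen    = c("O", "OW", "OH2"),
  hydrogens = c("H1", "H2", "HW1", "HW2", "HT1", "HT2")
)

is_standard_resname <- function(resname) resname %in% names(.sidechain_templates)

is_water_resname <- function(resname) resname %in% .water_resnames
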