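# Fixtures built in code: a fixed micro topology whose coordinates each test
# assigns, plus small PDB writers for the reader tests.

# Micro system: four annotated protein residues (donor/acceptor, carboxylate,
# ammonium, aromatic), a ligand with amine donor (+1), acceptor, ring and
# nonpolar carbon, and five waters. Geometry is supplied per test.
micro_topology <- function(reverse_waters = FALSE) {
  res <- function(resname, resno, names) {
    tibble::tibble(name = names, element = substr(gsub("[0-9]", "", names), 1, 1),
                   resname = resname, resno = resno, chain = "A")
  }
  protein <- dplyr::bind_rows(
    res("SER", 10L, c("N", "H", "CA", "C", "O", "CB", "OG", "HG")),
    res("ASP", 20L, c("N", "H", "CA", "C", "O", "CB", "CG", "OD1", "OD2")),
    res("LYS", 30L, c("N", "H", "CA", "C", "O", "CB", "CG", "CD", "CE",
                      "NZ", "HZ1", "HZ2", "HZ3")),
    res("TYR", 40L, c("N", "H", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                      "CE1", "CE2", "CZ", "OH", "HH")))
  lig_names <- c("N1", "H1A", "H1B", "C1", "C2", "O1",
                 "CR1", "CR2", "CR3", "CR4", "CR5", "CR6", "C9")
  ligand <- tibble::tibble(
    name = lig_names,
    element = c("N", "H", "H", "C", "C", "O", rep("C", 7)),
    resname = "LIG", resno = 1L, chain = "L")
  wseq <- if (reverse_waters) 5:1 else 1:5
  waters <- dplyr::bind_rows(lapply(wseq, function(i) {
    tibble::tibble(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                   resname = "HOH", resno = as.integer(i), chain = "W")
  }))
  atoms <- dplyr::bind_rows(protein, ligand, waters)
  off <- nrow(protein)
  li <- function(nm) off + match(nm, lig_names)
  lig_bonds <- rbind(
    c(li("N1"), li("H1A")), c(li("N1"), li("H1B")), c(li("N1"), li("C1")),
    c(li("C1"), li("C2")), c(li("C2"), li("O1")), c(li("C1"), li("CR1")),
    c(li("CR1"), li("CR2")), c(li("CR2"), li("CR3")), c(li("CR3"), li("CR4")),
    c(li("CR4"), li("CR5")), c(li("CR5"), li("CR6")), c(li("CR6"), li("CR1")),
    c(li("C9"), li("CR1")))
  sidecar <- list(ligand = list(
    resname = "LIG",
    donors = list(list(heavy = "N1", hydrogens = list("H1A", "H1B"))),
    acceptors = list("O1"),
    rings = list(list("CR1", "CR2", "CR3", "CR4", "CR5", "CR6")),
    charged = list(list(atoms = list("N1"), sign = 1))))
  topology(atoms, bonds = lig_bonds, ligand_template = sidecar)
}

# Default coordinates: every atom isolated on a remote line so that only the
# atoms a test positions can interact.
base_coords <- function(top) {
  n <- nrow(top$atoms)
  cbind(1000 + 10 * seq_len(n), rep(0, n), rep(0, n))
}

atom_row <- function(top, chain, resno, name) {
  i <- which(top$atoms$chain == chain & top$atoms$resno == resno &
               top$atoms$name == name)
  stopifnot(length(i) == 1L)
  i
}

# place: named list "chain/resno/name" -> coordinates
place_atoms <- function(top, place, xyz = base_coords(top)) {
  for (key in names(place)) {
    parts <- strsplit(key, "/")[[1]]
    xyz[atom_row(top, parts[1], as.integer(parts[2]), parts[3]), ] <- place[[key]]
  }
  xyz
}

# Fully random micro frame in a 12 Angstrom cube (dense enough for chance
# contacts of every type).
random_micro_frame <- function(top) {
  matrix(runif(nrow(top$atoms) * 3, 0, 12), ncol = 3)
}

hexagon <- function(center, radius = 1.39, start_deg = 0) {
  ang <- (start_deg + (0:5) * 60) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang), center[3])
}

# minimal fixed-width PDB writer for reader tests (independent of the package)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, het = FALSE) {
  sprintf("%s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          if (het) "HETATM" else "ATOM  ", serial, name, resname, chain, resno,
          x, y, z, element)
}

# long straight poly-glycine chain for selection-grammar tests
make_chain_topology <- function(n_res = 169) {
  atoms <- dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
    tibble::tibble(name = c("N", "H", "CA", "C", "O"),
                   element = c("N", "H", "C", "C", "O"),
                   resname = "GLY", resno = as.integer(i), chain = "A")
  }))
  topology(atoms)
}

# trajectory with engineered ligand basins over a rigid protein
basin_trajectory <- function(top, populations = c(20, 15, 10), jitter = 0.03,
                             seed = 61) {
  set.seed(seed)
  ref <- base_coords(top)
  prot <- select_atoms(top, "protein")
  lig <- select_atoms(top, "ligand")
  ref[prot, ] <- matrix(rnorm(length(prot) * 3, sd = 3), ncol = 3)
  ref[lig, ] <- matrix(rnorm(length(lig) * 3, sd = 1.5), ncol = 3)
  shifts <- list(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  assignment <- rep(seq_along(populations), populations)
  frames <- lapply(assignment, function(bi) {
    xyz <- ref
    xyz[lig, ] <- sweep(xyz[lig, , drop = FALSE], 2, shifts[[bi]], `+`) +
      matrix(rnorm(length(lig) * 3, sd = jitter), ncol = 3)
    xyz
  })
  coords <- array(NA_real_, dim = c(nrow(top$atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(traj = trajectory(coords, seq_along(frames) - 1), assignment = assignment,
       prot = prot, lig = lig)
}

event_keys <- function(ev, top) {
  wres <- rep(NA_integer_, nrow(ev))
  if (any(!is.na(ev$water_id))) {
    map <- match(ev$water_id, top$atoms$molid)
    wres <- top$atoms$resno[map]
  }
  sort(paste(ev$type, ev$resno, ev$chain, ev$ligand_atoms, wres))
}
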