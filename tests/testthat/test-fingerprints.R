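# Interaction detectors under the geometric criteria, and fraction
# aggregation.

test_that("an ideal hydrogen bond is detected and a long one is not", {
  top <- micro_topology()
  # SER10 OG-HG donates to ligand O1 (acceptor angle via C2 at 150 deg)
  xyz <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "L/1/O1" = c(0, 0, 2.9), "L/1/C2" = c(0.7, 0, 4.11)))
  ev <- detect_hbonds(xyz, top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resno, 10L)
  expect_equal(ev$type, "hbond")
  expect_equal(ev$direction, "protein")
  expect_equal(ev$residue_part, "sidechain")
  # H...A = 3.5 Angstrom: no event
  xyz2 <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "L/1/O1" = c(0, 0, 4.5), "L/1/C2" = c(0.7, 0, 5.7)))
  expect_equal(nrow(detect_hbonds(xyz2, top)), 0L)
})

test_that("donor and acceptor angle criteria both gate the hydrogen bond", {
  top <- micro_topology()
  # donor angle ~100 deg (< 120): H displaced sideways
  xyz <- place_atoms(top, list(
    "A/10/OG" = c(0.98, 0, 1.17), "A/10/HG" = c(0, 0, 1.0),
    "L/1/O1" = c(0, 0, 2.9), "L/1/C2" = c(0.7, 0, 4.11)))
  expect_equal(nrow(detect_hbonds(xyz, top)), 0L)
  # acceptor angle ~60 deg (< 90): C2 pulled toward H
  xyz2 <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "L/1/O1" = c(0, 0, 2.9), "L/1/C2" = c(1.21, 0, 2.2)))
  expect_equal(nrow(detect_hbonds(xyz2, top)), 0L)
  # ligand-donor direction: N1-H1A donates to ASP20 OD1
  xyz3 <- place_atoms(top, list(
    "L/1/N1" = c(0, 0, 0), "L/1/H1A" = c(0, 0, 1.0),
    "A/20/OD1" = c(0, 0, 2.9), "A/20/CG" = c(0.7, 0, 4.11)))
  ev <- detect_hbonds(xyz3, top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resno, 20L)
  expect_equal(ev$direction, "ligand")
})

test_that("a single water bridging protein and ligand yields one event", {
  top <- micro_topology()
  # SER10 OG-HG -> water O; water H1 -> ligand O1
  xyz <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "W/1/O" = c(0, 0, 2.9), "W/1/H1" = c(0.96, 0, 2.9), "W/1/H2" = c(-0.3, -0.8, 3.3),
    "L/1/O1" = c(2.85, 0, 2.9), "L/1/C2" = c(3.8, 0.9, 2.9)))
  ev <- detect_water_bridges(xyz, top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "water_bridge")
  expect_equal(ev$resno, 10L)
  expect_equal(ev$ligand_atoms, "O1")
  expect_equal(ev$water_id, top$atoms$molid[atom_row(top, "W", 1, "O")])
  # water bonded to protein only: no bridge
  xyz2 <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "W/1/O" = c(0, 0, 2.9), "W/1/H1" = c(0.96, 0, 2.9), "W/1/H2" = c(-0.3, -0.8, 3.3)))
  expect_equal(nrow(detect_water_bridges(xyz2, top)), 0L)
})

test_that("pi stacking: parallel rings are face-to-face, perpendicular are edge-to-face", {
  top <- micro_topology()
  ring_p <- hexagon(c(0, 0, 0))
  place <- list()
  tyr_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (i in 1:6) place[[paste0("A/40/", tyr_names[i])]] <- ring_p[i, ]
  ring_l <- hexagon(c(0, 0, 3.8), start_deg = 30)
  for (i in 1:6) place[[paste0("L/1/CR", i)]] <- ring_l[i, ]
  ev <- detect_pi_interactions(place_atoms(top, place), top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "pi_pi")
  expect_equal(ev$direction, "face_to_face")
  expect_equal(ev$resno, 40L)
  # perpendicular ligand ring, centroids 5.0 apart
  ring_perp <- hexagon(c(0, 0, 0), start_deg = 0)
  place2 <- place
  for (i in 1:6) {
    place2[[paste0("L/1/CR", i)]] <- c(ring_perp[i, 1] + 5.0, 0, ring_perp[i, 2])
  }
  ev2 <- detect_pi_interactions(place_atoms(top, place2), top)
  expect_equal(ev2$direction, "edge_to_face")
})

test_that("pi-cation fires within 4.5 Angstrom in both directions", {
  top <- micro_topology()
  ring_p <- hexagon(c(0, 0, 0))
  place <- list("L/1/N1" = c(0, 0, 4.0))
  tyr_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (i in 1:6) place[[paste0("A/40/", tyr_names[i])]] <- ring_p[i, ]
  ev <- detect_pi_interactions(place_atoms(top, place), top)
  expect_true(any(ev$type == "pi_cation" & ev$direction == "ligand" & ev$resno == 40))
  # protein ammonium over the ligand ring
  ring_l <- hexagon(c(50, 0, 0))
  place2 <- list("A/30/NZ" = c(50, 0, 4.4))
  for (i in 1:6) place2[[paste0("L/1/CR", i)]] <- ring_l[i, ]
  ev2 <- detect_pi_interactions(place_atoms(top, place2), top)
  expect_true(any(ev2$type == "pi_cation" & ev2$direction == "protein" & ev2$resno == 30))
})

test_that("hydrophobic and ionic contacts follow their cutoffs", {
  top <- micro_topology()
  xyz <- place_atoms(top, list("A/30/CD" = c(0, 0, 0), "L/1/C9" = c(3.5, 0, 0)))
  ev <- detect_nonpolar_and_ionic(xyz, top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "hydrophobic")
  expect_equal(ev$resno, 30L)
  # carboxylate 10 Angstrom from the amine: nothing
  xyz2 <- place_atoms(top, list(
    "A/20/OD1" = c(0, 0, 0), "A/20/OD2" = c(1, 1, 0), "A/20/CG" = c(0.6, 0.5, 0.6),
    "L/1/N1" = c(10, 0, 0)))
  expect_equal(nrow(detect_nonpolar_and_ionic(xyz2, top)), 0L)
  # at 3.5 Angstrom closest-atom: ionic event
  xyz3 <- place_atoms(top, list(
    "A/20/OD1" = c(0, 0, 0), "A/20/OD2" = c(1, 1, 0), "A/20/CG" = c(0.6, 0.5, 0.6),
    "L/1/N1" = c(3.5, 0, 0)))
  ev3 <- detect_nonpolar_and_ionic(xyz3, top)
  expect_equal(ev3$type, "ionic")
})

test_that("loosening any threshold never removes an event (monotonicity)", {
  top <- micro_topology()
  tight <- interaction_criteria()
  loose <- interaction_criteria(
    hbond_distance = 3.0, hbond_donor_angle_min = 110, hbond_acceptor_angle_min = 80,
    wbridge_distance = 3.3, wbridge_donor_angle_min = 100, wbridge_acceptor_angle_min = 80,
    pication_distance = 5.0, pipi_f2f_centroid_max = 4.9, pipi_e2f_centroid_max = 6.0,
    pipi_f2f_plane_angle_max = 40, pipi_e2f_plane_angle_window = c(50, 130),
    hydrophobic_distance = 4.1, ionic_distance = 4.2)
  # aggregated ligand-atom lists can grow when thresholds loosen, so the
  # monotone quantity is the (type, residue, water) identity of the events
  contact_ids <- function(xyz, crit) {
    ev <- dplyr::bind_rows(
      detect_hbonds(xyz, top, crit),
      detect_water_bridges(xyz, top, crit),
      detect_pi_interactions(xyz, top, crit),
      detect_nonpolar_and_ionic(xyz, top, crit))
    unique(paste(ev$type, ev$resno, ev$chain, ev$water_id))
  }
  set.seed(31)
  for (i in 1:15) {
    xyz <- random_micro_frame(top)
    expect_true(all(contact_ids(xyz, tight) %in% contact_ids(xyz, loose)))
  }
})

test_that("detection is stable under water reordering in the topology", {
  top1 <- micro_topology()
  top2 <- micro_topology(reverse_waters = TRUE)
  set.seed(32)
  for (i in 1:5) {
    xyz1 <- random_micro_frame(top1)
    # same geometry mapped onto the reordered topology by atom identity
    key1 <- paste(top1$atoms$chain, top1$atoms$resno, top1$atoms$name)
    key2 <- paste(top2$atoms$chain, top2$atoms$resno, top2$atoms$name)
    xyz2 <- xyz1[match(key2, key1), ]
    expect_identical(detector_events(xyz1, top1), detector_events(xyz2, top2))
  }
})

test_that("fractions binarize per frame and flag displayed/key by strict thresholds", {
  top <- micro_topology()
  # two simultaneous hydrogen bonds from SER10 in one frame count once
  xyz <- place_atoms(top, list(
    "A/10/OG" = c(0, 0, 0), "A/10/HG" = c(0, 0, 1.0),
    "A/10/N" = c(1.7, 0, 0.9), "A/10/H" = c(1.2, 0, 1.7),
    "L/1/O1" = c(0, 0, 2.9), "L/1/C2" = c(0.7, 0, 4.11)))
  ev <- detect_hbonds(xyz, top)
  expect_equal(nrow(ev), 2L)
  ev$frame <- 1L; ev$replica <- 1L
  fr <- aggregate_fractions(ev, 1)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$fraction, 1.0)

  # strict key rule: 0.51 -> key, 0.50 -> not key
  mk <- function(resno, k) {
    tibble::tibble(replica = 1L, frame = seq_len(k), type = "hbond",
                   resno = resno, resname = "XXX", chain = "A",
                   residue_part = "sidechain", ligand_atoms = "O1",
                   water_id = NA_integer_, direction = "protein")
  }
  fr2 <- aggregate_fractions(dplyr::bind_rows(mk(1L, 51), mk(2L, 50), mk(3L, 20)), 100)
  expect_true(fr2$key[fr2$resno == 1])
  expect_false(fr2$key[fr2$resno == 2])
  expect_true(fr2$displayed[fr2$resno == 2])
  expect_false(fr2$displayed[fr2$resno == 3])   # 0.20 is not > 0.2
  expect_error(aggregate_fractions(mk(1L, 5), 0), class = "bindmode_statistics_error")
})

test_that("missing donor hydrogens are an annotation error for H-bond analysis", {
  atoms <- dplyr::bind_rows(
    tibble::tibble(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                   resname = "GLY", resno = 1L, chain = "A"),
    tibble::tibble(name = c("C1", "O1"), element = c("C", "O"),
                   resname = "LIG", resno = 1L, chain = "L"))
  top <- topology(atoms, bonds = matrix(c(5L, 6L), ncol = 2),
                  ligand_template = list(ligand = list(acceptors = list("O1"))))
  xyz <- matrix(0, nrow = 6, ncol = 3); xyz[, 1] <- 1:6
  expect_error(detect_hbonds(xyz, top), class = "bindmode_annotation_error")
})
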