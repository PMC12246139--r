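# Topology reading, chemistry annotation, selection grammar and trajectory I/O.

test_that("a single-water PDB is annotated from the water template", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "O", "HOH", "W", 1, 0, 0, 0, "O", het = TRUE),
    pdb_atom_line(2, "H1", "HOH", "W", 1, 0.96, 0, 0, "H", het = TRUE),
    pdb_atom_line(3, "H2", "HOH", "W", 1, -0.24, 0.93, 0, "H", het = TRUE),
    "CONECT    1    2",
    "CONECT    1    3",
    "END"), path)
  top <- read_topology(path)
  expect_equal(nrow(top$atoms), 3L)
  expect_equal(sum(top$atoms$is_water), 3L)
  o <- which(top$atoms$name == "O")
  expect_true(o %in% top$acceptors)
  expect_setequal(top$donors$hydrogen, which(top$atoms$element == "H"))
  expect_equal(unique(top$donors$heavy), o)
})

test_that("a Gly-Thr-Asp tripeptide gets template chemistry", {
  path <- withr::local_tempfile(fileext = ".pdb")
  gly <- list(N = c(0, 0, 0), H = c(-0.6, 0.8, 0), CA = c(1.45, 0, 0),
              C = c(2.2, 1.1, 0), O = c(2.0, 2.3, 0))
  thr <- list(N = c(3.5, 0.9, 0), H = c(3.6, -0.1, 0), CA = c(4.7, 1.7, 0),
              C = c(6.0, 0.9, 0), O = c(6.0, -0.3, 0), CB = c(4.8, 3.0, 0.9),
              OG1 = c(4.0, 4.1, 0.5), HG1 = c(4.1, 4.9, 1.05), CG2 = c(6.2, 3.5, 1.1))
  asp <- list(N = c(7.1, 1.6, 0), H = c(7.0, 2.6, 0), CA = c(8.4, 1.0, 0),
              C = c(9.5, 2.0, 0), O = c(9.3, 3.2, 0), CB = c(8.7, 0, 1.1),
              CG = c(9.9, -0.9, 1.2), OD1 = c(10.9, -0.6, 1.9),
              OD2 = c(9.9, -1.95, 0.55))
  lines <- character(); serial <- 0
  for (r in list(list("GLY", 1, gly), list("THR", 2, thr), list("ASP", 3, asp))) {
    for (nm in names(r[[3]])) {
      serial <- serial + 1
      p <- r[[3]][[nm]]
      lines <- c(lines, pdb_atom_line(serial, nm, r[[1]], "A", r[[2]],
                                      p[1], p[2], p[3],
                                      substr(gsub("[0-9]", "", nm), 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  top <- read_topology(path)
  og1 <- atom_row(top, "A", 2, "OG1")
  expect_true(og1 %in% top$acceptors)
  expect_true(og1 %in% top$donors$heavy)
  expect_length(top$charged_groups, 1L)
  grp <- top$charged_groups[[1]]
  expect_equal(grp$sign, -1L)
  expect_true(all(c(atom_row(top, "A", 3, "OD1"), atom_row(top, "A", 3, "OD2"))
                  %in% grp$atoms))
  # peptide bond Gly1(C)-Thr2(N) present
  c1 <- atom_row(top, "A", 1, "C"); n2 <- atom_row(top, "A", 2, "N")
  expect_true(any((top$bonds[, 1] == c1 & top$bonds[, 2] == n2) |
                  (top$bonds[, 2] == c1 & top$bonds[, 1] == n2)))
})

test_that("ligand sidecar declares the benzene ring verbatim", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  yml <- withr::local_tempfile(fileext = ".yaml")
  hx <- hexagon(c(0, 0, 0))
  lines <- sapply(1:6, function(i) {
    pdb_atom_line(i, paste0("C", i), "BNZ", "L", 1, hx[i, 1], hx[i, 2], hx[i, 3],
                  "C", het = TRUE)
  })
  conect <- sprintf("CONECT%5d%5d", 1:6, c(2:6, 1))
  writeLines(c(lines, conect, "END"), pdb)
  yaml::write_yaml(list(ligand = list(
    resname = "BNZ",
    rings = list(list("C1", "C2", "C3", "C4", "C5", "C6")))), yml)
  top <- read_topology(pdb, ligand_template = yml)
  expect_length(top$rings, 1L)
  expect_equal(top$atoms$name[top$rings[[1]]], paste0("C", 1:6))
})

test_that("unknown-element atoms are rejected with the atom named", {
  atoms <- tibble::tibble(name = "X1", element = "", resname = "LIG",
                          resno = 1L, chain = "L")
  expect_error(topology(atoms), class = "bindmode_annotation_error")
})

test_that("trajectory stride is applied by time, not index", {
  top <- micro_topology()
  nf <- 10
  coords <- array(rep(base_coords(top), nf), dim = c(nrow(top$atoms), 3, nf))
  for (f in seq_len(nf)) coords[1, 1, f] <- f   # make frames distinct
  traj <- trajectory(coords, times = 0:(nf - 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, top, path)
  t1 <- read_trajectory(top, path, stride_ns = 1)
  expect_equal(n_frames(t1), 10L)
  t2 <- read_trajectory(top, path, stride_ns = 2)
  expect_equal(n_frames(t2), 5L)
  expect_equal(t2$times, c(0, 2, 4, 6, 8))
  expect_equal(t2$coords[1, 1, ], c(1, 3, 5, 7, 9), tolerance = 1e-3)
})

test_that("multi-model PDB round-trips within format precision", {
  top <- micro_topology()
  set.seed(4)
  coords <- array(runif(nrow(top$atoms) * 3 * 3, 0, 50), dim = c(nrow(top$atoms), 3, 3))
  traj <- trajectory(coords, times = 0:2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, top, path)
  back <- read_trajectory(top, path)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
})

test_that("DCD round-trips within float precision", {
  top <- micro_topology()
  set.seed(5)
  coords <- array(runif(nrow(top$atoms) * 3 * 4, -30, 30), dim = c(nrow(top$atoms), 3, 4))
  traj <- trajectory(coords, times = 0:3)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory_dcd(traj, top, path)
  back <- read_trajectory(top, path)
  expect_equal(n_frames(back), 4L)
  expect_equal(back$coords, traj$coords, tolerance = 1e-4)
})

test_that("format and count errors are classed", {
  top <- micro_topology()
  expect_error(read_trajectory(top, "nope.xtc"), class = "bindmode_format_error")
  expect_error(read_topology("missing_file.pdb"), class = "bindmode_format_error")
  small <- make_chain_topology(2)
  coords <- array(0, dim = c(nrow(small$atoms), 3, 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(trajectory(coords, 0), small, path)
  expect_error(read_trajectory(top, path), class = "bindmode_topology_error")
})

test_that("selection grammar counts, enumerates and errors as specified", {
  chain <- make_chain_topology(169)
  expect_length(select_atoms(chain, "calpha and residue 10-20"), 11L)
  top <- micro_topology()
  expect_length(select_atoms(top, "water"), 15L)
  bb <- select_atoms(top, "backbone and residue 10")
  manual <- sapply(c("N", "CA", "C", "O"), function(nm) atom_row(top, "A", 10, nm))
  expect_equal(as.integer(bb), sort(as.integer(manual)))
  expect_error(select_atoms(top, "residue !!"), class = "bindmode_parse_error")
  expect_error(select_atoms(top, "froboz"), class = "bindmode_parse_error")
  empty <- select_atoms(top, "resname XYZ")
  expect_length(empty, 0L)
})

test_that("selection algebra: and is intersection, or is union, not is complement", {
  top <- micro_topology()
  terms <- c("protein", "ligand", "water", "backbone", "calpha", "element C",
             "residue 10-30", "name CA,CB", "chain L")
  set.seed(11)
  for (i in 1:25) {
    a <- sample(terms, 1); b <- sample(terms, 1)
    expect_equal(as.integer(select_atoms(top, paste(a, "and", b))),
                 intersect(as.integer(select_atoms(top, a)),
                           as.integer(select_atoms(top, b))))
    expect_equal(as.integer(select_atoms(top, paste(a, "or", b))),
                 sort(union(as.integer(select_atoms(top, a)),
                            as.integer(select_atoms(top, b)))))
    expect_equal(as.integer(select_atoms(top, paste("not", a))),
                 setdiff(seq_len(nrow(top$atoms)), as.integer(select_atoms(top, a))))
  }
})
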