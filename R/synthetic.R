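# Synthetic trajectory generator with planted, ledgered ground truth.
#
# The generator emulates the statistical structure of a pocket-binding study:
# a KRAS-like mini receptor with named pocket residues, a ligand carrying
# donors, acceptors, an aromatic ring and a charged amine, explicit waters
# exchanging through a conserved site between Thr58 and Gly10, and multiple
# independent replicas sampled at 1 ns intervals. Planted contacts are placed
# far inside (or far outside) their geometric criteria so that detection is
# noise-proof and ledger comparisons can be exact; probabilistic realism is
# carried by Bernoulli/Markov schedules, not by borderline geometry.

#' Configuration for the synthetic-trajectory generator
#'
#' Defaults mirror the study design being emulated: 20 independent replicas
#' sampled at 1 ns, planted hydrogen-bond occupancies of 1.0 (Asp69), 0.7
#' (Glu63 backbone) and 0.2 (His95), a conserved-water-site occupancy of 0.8
#' with persistent (Markov) dynamics tuned to roughly 30 distinct site waters
#' per replica from a 100-water pool, and a 70% native side-chain state for
#' Thr58.
#'
#' @param n_replicas,n_frames Replica count and frames per replica.
#' @param frame_spacing_ns Time between frames (ns).
#' @param hbond_occupancy_targets Named vector of per-contact Bernoulli
#'   probabilities; names must be a subset of `c("ASP69", "GLU63", "HIS95")`.
#' @param water_site_occupancy Stationary site occupancy probability.
#' @param water_stay_prob Markov persistence P(occupied -> occupied); the
#'   vacant->occupied rate is derived to match the stationary occupancy.
#' @param water_exchange_prob Probability per occupied frame that the
#'   occupant is swapped for another water without vacating the site.
#' @param occupancy_by_state Optional named vector `c(native=, flipped=)`; when
#'   given, per-frame occupancy is an independent Bernoulli conditioned on the
#'   side-chain state (couples water occupancy to the flip state; exchange
#'   statistics are then not Markovian).
#' @param n_waters Water pool size.
#' @param state_native_fraction Stationary fraction of the native state.
#' @param state_stay_prob Markov persistence P(native -> native).
#' @param noise_sigma Gaussian positional noise s.d. per coordinate (Angstrom),
#'   clamped at 4 sigma; must pass the boundary-margin audit.
#' @param seed Master seed; per-replica sub-seeds are derived by a fixed rule.
#' @return A list of class `bindmode_generator_config`.
#' @export
generator_config <- function(n_replicas = 20,
                             n_frames = 1000,
                             frame_spacing_ns = 1,
                             hbond_occupancy_targets = c(ASP69 = 1.0, GLU63 = 0.7, HIS95 = 0.2),
                             water_site_occupancy = 0.8,
                             water_stay_prob = 0.95,
                             water_exchange_prob = 0,
                             occupancy_by_state = NULL,
                             n_waters = 100,
                             state_native_fraction = 0.7,
                             state_stay_prob = 0.95,
                             noise_sigma = 0.02,
                             seed = 1) {
  cfg <- list(n_replicas = as.integer(n_replicas), n_frames = as.integer(n_frames),
              frame_spacing_ns = frame_spacing_ns,
              hbond_occupancy_targets = hbond_occupancy_targets,
              water_site_occupancy = water_site_occupancy,
              water_stay_prob = water_stay_prob,
              water_exchange_prob = water_exchange_prob,
              occupancy_by_state = occupancy_by_state,
              n_waters = as.integer(n_waters),
              state_native_fraction = state_native_fraction,
              state_stay_prob = state_stay_prob,
              state_distance_max = 4,
              state_angle_window = c(60, 180),
              site_radius = 3,
              noise_sigma = noise_sigma,
              seed = as.integer(seed))
  probs <- c(cfg$hbond_occupancy_targets, cfg$water_site_occupancy,
             cfg$water_stay_prob, cfg$water_exchange_prob,
             cfg$state_native_fraction, cfg$state_stay_prob, cfg$occupancy_by_state)
  if (any(probs < 0 | probs > 1)) {
    stop_bindmode("all generator probabilities must lie in [0, 1]", "bindmode_config_error")
  }
  if (cfg$n_replicas < 1L || cfg$n_frames < 1L || cfg$n_waters < 2L) {
    stop_bindmode("replica, frame and water counts must be positive", "bindmode_config_error")
  }
  if (cfg$noise_sigma < 0) {
    stop_bindmode("noise_sigma must be non-negative", "bindmode_config_error")
  }
  bad <- setdiff(names(cfg$hbond_occupancy_targets), c("ASP69", "GLU63", "HIS95"))
  if (length(bad) > 0L) {
    stop_bindmode(paste0("unknown planted contact(s): ", paste(bad, collapse = ", ")),
                  "bindmode_config_error")
  }
  # vacant -> occupied rate matching the stationary occupancy
  occ <- cfg$water_site_occupancy
  entry <- occ * (1 - cfg$water_stay_prob) / max(1e-12, 1 - occ)
  if (is.null(cfg$occupancy_by_state) && entry > 1) {
    stop_bindmode("water_stay_prob is too low for the requested stationary occupancy",
                  "bindmode_config_error")
  }
  cfg$water_entry_prob <- min(1, entry)
  nat <- cfg$state_native_fraction
  entry_s <- nat * (1 - cfg$state_stay_prob) / max(1e-12, 1 - nat)
  if (entry_s > 1) {
    stop_bindmode("state_stay_prob is too low for the requested native fraction",
                  "bindmode_config_error")
  }
  cfg$state_entry_prob <- min(1, entry_s)
  structure(cfg, class = "bindmode_generator_config")
}

# Regular polygon in a z = const plane, returned in ring order.
polygon_ring <- function(center, n, radius, start_deg = 0) {
  ang <- (start_deg + (0:(n - 1)) * 360 / n) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        rep(center[3], n))
}

# Atom rows (name, element, coords) for one residue from explicit coordinates.
res_atoms <- function(resname, resno, coords) {
  nm <- names(coords)
  tibble(name = nm,
         element = guess_element(nm),
         resname = resname, resno = as.integer(resno), chain = "A",
         x = vapply(coords, `[`, numeric(1), 1),
         y = vapply(coords, `[`, numeric(1), 2),
         z = vapply(coords, `[`, numeric(1), 3))
}

# Filler residue: standard backbone plus a template-complete side chain laid
# out locally; only used far from all planted interactions.
filler_residue <- function(resname, resno, origin) {
  off <- list(N = c(0, 0, 0), H = c(-0.58, 0.77, 0), CA = c(1.45, 0, 0),
              C = c(2.2, 1.1, 0), O = c(2.0, 2.3, 0))
  side <- switch(resname,
    ALA = list(CB = c(1.9, -1.3, 0.5)),
    CYS = list(CB = c(1.9, -1.3, 0.5), SG = c(2.7, -2.5, 1.2)),
    LYS = list(CB = c(1.9, -1.3, 0.5), CG = c(2.7, -2.5, 1.2),
               CD = c(3.5, -3.7, 1.9), CE = c(4.3, -4.9, 2.6),
               NZ = c(5.1, -6.1, 3.3), HZ1 = c(5.76, -6.75, 3.05),
               HZ2 = c(4.62, -6.68, 3.94), HZ3 = c(5.63, -5.62, 3.95)),
    GLU = list(CB = c(1.9, -1.3, 0.5), CG = c(2.7, -2.5, 1.2),
               CD = c(3.5, -3.7, 1.9), OE1 = c(4.6, -3.7, 2.5),
               OE2 = c(3.0, -4.8, 1.9)),
    TYR = {
      ring <- polygon_ring(c(4.1, -3.4, 1.2), 6, 1.39, start_deg = 210)
      oh_dir <- (ring[4, ] - c(4.1, -3.4, 1.2)) / 1.39
      s <- list(CB = c(1.9, -1.3, 0.5))
      for (k in seq_along(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))) {
        s[[c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[k]]] <- ring[k, ] - origin * 0
      }
      s$OH <- s$CZ + 1.38 * oh_dir
      s$HH <- s$OH + 0.96 * oh_dir
      s
    },
    stop_bindmode(sprintf("no filler layout for residue %s", resname), "bindmode_config_error"))
  coords <- c(off, side)
  coords <- lapply(coords, function(p) p + origin)
  res_atoms(resname, resno, coords)
}

#' Build the synthetic receptor-ligand-water system
#'
#' Constructs a mini receptor (Ala5, Gly10, Cys12, Lys16, Thr58, Glu62,
#' Glu63, Tyr64, Asp69, His95, Tyr96 with conventional atom names), a ligand
#' with an annotated charged amine, two additional donors, two acceptors and
#' an aromatic ring, and a pool of explicit waters; plus the placement plan
#' for every planted interaction. Deterministic for a fixed configuration.
#' The boundary-margin audit runs at build time: a noise level that could move
#' any planted geometry across a detection criterion is a configuration error.
#'
#' @param config A [generator_config()].
#' @return An object of class `bindmode_system`: list with `topology`,
#'   `reference` (coordinate matrix), `plan` (placement plan), `site`
#'   (the [water_site()] used for occupancy), `sidecar` (ligand annotation
#'   list), `config`.
#' @export
build_system <- function(config = generator_config()) {
  stopifnot(inherits(config, "bindmode_generator_config"))

  gly10 <- res_atoms("GLY", 10, list(
    N = c(0, 0, 0), H = c(0, 0, 1.0), CA = c(1.45, 0, 0),
    C = c(2.2, 1.0, 0), O = c(2.0, 2.2, 0)))
  # Thr58 side chain: CB is 3.3 Angstrom from the Gly10 amide hydrogen; the
  # native OG1 sits perpendicular to the CB->H arm (angle 90 deg, distance
  # ~3.6), the flipped OG1 points away (angle 180 deg, distance ~4.7, outside
  # the 4 Angstrom native bound).
  thr58 <- res_atoms("THR", 58, list(
    N = c(-4.284, 3.214, 3.231), H = c(-5.052, 3.790, 3.231),
    CA = c(-3.124, 2.344, 3.260),
    C = c(-3.428, 3.256, 2.090), O = c(-3.428, 3.933, 1.063),
    CB = c(-1.908, 1.432, 3.290), OG1 = c(-2.748, 0.312, 3.290),
    HG1 = c(-3.693, 0.420, 3.424), CG2 = c(-2.752, 2.064, 2.191)))
  glu63 <- res_atoms("GLU", 63, list(
    N = c(-20.89, 2.01, 4.73), H = c(-21.47, 2.78, 4.73), CA = c(-19.58, 1.37, 4.73),
    C = c(-19.58, 0, 4.06), O = c(-20, 0, 2.9),
    CB = c(-19.58, 2.04, 6.10), CG = c(-19.58, 3.06, 7.22),
    CD = c(-19.58, 4.43, 7.89), OE1 = c(-18.70, 5.31, 8.07), OE2 = c(-20.46, 5.31, 8.07)))
  asp69 <- res_atoms("ASP", 69, list(
    N = c(18.10, 3.36, 5.71), H = c(17.43, 4.03, 5.84), CA = c(19.11, 2.35, 5.41),
    C = c(20.48, 2.96, 5.71), O = c(20.98, 4.08, 5.71),
    CB = c(19.57, 0.97, 4.95), CG = c(20.48, 0, 4.22),
    OD1 = c(20, 0, 2.9), OD2 = c(21.66, 0, 4.65)))
  # imidazole in the z = 0 plane with ND1 at (40, 0, 0), pointing its H up at
  # the ligand acceptor N5
  his_ring <- polygon_ring(c(40, -1.17, 0), 5, 1.17, start_deg = 90)
  his95 <- res_atoms("HIS", 95, list(
    N = c(43.3, -4.3, -0.4), H = c(43.9, -5.0, -0.4), CA = c(42.9, -2.9, -0.4),
    C = c(44.1, -2.0, -0.6), O = c(44.0, -0.9, -1.2),
    CB = c(42.0, -2.3, 0.6),
    CG = his_ring[5, ], ND1 = his_ring[1, ], CE1 = his_ring[2, ],
    NE2 = his_ring[3, ], CD2 = his_ring[4, ], HD1 = c(40, 0, 1.0)))
  tyr_ring <- polygon_ring(c(0, -15, 0), 6, 1.39, start_deg = 0)
  tyr96 <- res_atoms("TYR", 96, list(
    N = c(4.91, -13.03, 0), H = c(5.59, -12.36, 0), CA = c(4.27, -14.33, 0),
    C = c(5.64, -15.0, 0), O = c(6.18, -16.11, 0),
    CB = c(2.90, -15, 0),
    CG = tyr_ring[1, ], CD1 = tyr_ring[2, ], CE1 = tyr_ring[3, ],
    CZ = tyr_ring[4, ], CE2 = tyr_ring[5, ], CD2 = tyr_ring[6, ],
    OH = c(-2.77, -15, 0), HH = c(-3.45, -14.33, 0)))
  fillers <- bind_rows(
    filler_residue("ALA", 5, c(0, 40, 0)),
    filler_residue("CYS", 12, c(10, 40, 0)),
    filler_residue("LYS", 16, c(20, 40, 0)),
    filler_residue("GLU", 62, c(-20, 40, 0)),
    filler_residue("TYR", 64, c(30, 40, 0)))

  protein <- bind_rows(fillers, gly10, thr58, glu63, asp69, his95, tyr96) %>%
    arrange(.data$resno)

  lig_ring <- polygon_ring(c(0, -15, 4.0), 6, 1.39, start_deg = 30)
  lig_coords <- list(
    N1 = c(20, 0, 0), H11 = c(20, 0, 1.0), H12 = c(20.90, 0, -0.33),
    C1 = c(18.62, 0, -0.50),
    N3 = c(-20, 0, 0), H31 = c(-20, 0, 1.0), C3 = c(-20, -0.50, -1.38),
    N5 = c(40, 0, 2.9), C5 = c(40.46, 0, 4.17),
    O6 = c(2.85, 0, 2.9), C6 = c(4.166, 0.479, 2.9),
    C11 = lig_ring[1, ], C12 = lig_ring[2, ], C13 = lig_ring[3, ],
    C14 = lig_ring[4, ], C15 = lig_ring[5, ], C16 = lig_ring[6, ])
  ligand <- res_atoms("LIG", 1, lig_coords)
  ligand$chain <- "L"
  ligand$element <- c("N", "H", "H", "C", "N", "H", "C", "N", "C", "O", "C",
                      rep("C", 6))

  # water pool on a remote lattice; one designated site position
  nw <- config$n_waters
  k <- 0:(nw - 1)
  homes <- cbind(60 + 4 * (k %% 5), 20 + 4 * ((k %/% 5) %% 5), 4 * (k %/% 25))
  waters <- bind_rows(lapply(seq_len(nw), function(i) {
    p <- homes[i, ]
    tibble(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
           resname = "HOH", resno = as.integer(i), chain = "W",
           x = p[1] + c(0, 0.96, -0.24), y = p[2] + c(0, 0, 0.93), z = p[3])
  }))

  atoms <- bind_rows(protein, ligand, waters)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  atom_tbl <- atoms[, c("name", "element", "resname", "resno", "chain")]

  # ligand bonds by atom name
  lig_bond_names <- list(
    c("N1", "H11"), c("N1", "H12"), c("N1", "C1"), c("C1", "C3"),
    c("N3", "H31"), c("N3", "C3"), c("C3", "C5"), c("N5", "C5"), c("C5", "C6"),
    c("O6", "C6"), c("C6", "C11"),
    c("C11", "C12"), c("C12", "C13"), c("C13", "C14"), c("C14", "C15"),
    c("C15", "C16"), c("C16", "C11"))
  lig_offset <- nrow(protein)
  lig_name_idx <- function(nm) lig_offset + match(nm, ligand$name)
  lig_bonds <- do.call(rbind, lapply(lig_bond_names, function(b) {
    c(lig_name_idx(b[1]), lig_name_idx(b[2]))
  }))

  sidecar <- list(ligand = list(
    resname = "LIG",
    donors = list(list(heavy = "N1", hydrogens = list("H11", "H12")),
                  list(heavy = "N3", hydrogens = list("H31"))),
    acceptors = list("N5", "O6"),
    rings = list(list("C11", "C12", "C13", "C14", "C15", "C16")),
    charged = list(list(atoms = list("N1"), sign = 1))))

  top <- topology(atom_tbl, bonds = lig_bonds, xyz = xyz, ligand_template = sidecar)

  idx_of <- function(resno, name, chain = "A") {
    which(top$atoms$resno == resno & top$atoms$name == name & top$atoms$chain == chain)
  }
  lig_idx <- function(name) which(top$atoms$chain == "L" & top$atoms$name == name)
  water_atoms <- lapply(seq_len(nw), function(i) {
    which(top$atoms$chain == "W" & top$atoms$resno == i)[match(c("O", "H1", "H2"),
      top$atoms$name[top$atoms$chain == "W" & top$atoms$resno == i])]
  })

  plan <- list(
    contacts = list(
      ASP69 = list(atoms = c(idx_of(69, "CB"), idx_of(69, "CG"),
                             idx_of(69, "OD1"), idx_of(69, "OD2")),
                   off_shift = c(0, 8, 0)),
      GLU63 = list(atoms = c(lig_idx("N3"), lig_idx("H31")),
                   off_shift = c(0, -8, 0)),
      HIS95 = list(atoms = c(lig_idx("N5"), lig_idx("C5")),
                   off_shift = c(0, 8, 0))),
    state = list(
      atoms = c(idx_of(58, "OG1"), idx_of(58, "HG1")),
      native = rbind(c(-2.748, 0.312, 3.290), c(-3.693, 0.420, 3.424)),
      flipped = rbind(c(-2.717, 2.039, 4.262), c(-3.430, 2.574, 4.619))),
    site_water_pos = rbind(c(0, 0, 2.9), c(0.96, 0, 2.9), c(0.733, -0.548, 3.189)),
    water_atoms = water_atoms,
    water_molids = vapply(water_atoms, function(a) top$atoms$molid[a[1]], integer(1)),
    water_homes = homes
  )

  site <- water_site(anchors = list(sidechain_or_ca(top, 58), sidechain_or_ca(top, 10)),
                     radius = config$site_radius)

  system <- structure(list(topology = top, reference = xyz, plan = plan,
                           site = site, sidecar = sidecar, config = config),
                      class = "bindmode_system")
  audit_margins(system)
  system
}

# Archetype coordinates: exact (noise-free) frame for one combination of
# planted-contact flags, state label and site occupancy.
archetype_coords <- function(system, contact_on, state, occupied,
                             occupant = 1L) {
  xyz <- system$reference
  plan <- system$plan
  for (nm in names(plan$contacts)) {
    if (!isTRUE(contact_on[[nm]])) {
      ct <- plan$contacts[[nm]]
      xyz[ct$atoms, ] <- sweep(xyz[ct$atoms, , drop = FALSE], 2, ct$off_shift, `+`)
    }
  }
  xyz[plan$state$atoms, ] <- if (state == "native") plan$state$native else plan$state$flipped
  if (occupied) {
    xyz[plan$water_atoms[[occupant]], ] <- plan$site_water_pos
  }
  xyz
}

# Boundary-margin audit: with 4-sigma-clamped noise each atom moves at most
# r = 4*sigma*sqrt(3); pair distances change at most 2r, angles at most a
# conservative bound based on a 1 Angstrom worst arm (ring-plane normals use
# the ring radius instead). Every archetypal configuration must yield
# identical detector output under criteria tightened and loosened by these
# bounds; otherwise noise could cross a criterion boundary and the
# configuration is rejected, keeping the ground-truth ledger exact.
audit_margins <- function(system) {
  cfg <- system$config
  r <- 4 * cfg$noise_sigma * sqrt(3)
  dd <- 2 * r + 0.02
  da <- 2 * asin(min(1, 2 * r / 1.0)) * 180 / pi + 1
  dring <- 2 * asin(min(1, r / 1.39)) * 180 / pi + 1
  # state angle arms are CB-OG1 (1.4) and CB-H (>= 3), hence a tighter bound
  da_state <- 2 * asin(min(1, 2 * r / 1.4)) * 180 / pi + 1
  shift <- function(s) {
    interaction_criteria(
      hbond_distance = 2.5 + s * dd,
      hbond_donor_angle_min = max(1e-6, 120 - s * da),
      hbond_acceptor_angle_min = max(1e-6, 90 - s * da),
      wbridge_distance = 2.8 + s * dd,
      wbridge_donor_angle_min = max(1e-6, 110 - s * da),
      wbridge_acceptor_angle_min = max(1e-6, 90 - s * da),
      pication_distance = 4.5 + s * dd,
      pipi_f2f_centroid_max = 4.4 + s * dd,
      pipi_e2f_centroid_max = 5.5 + s * dd,
      pipi_f2f_plane_angle_max = max(1e-6, 30 + s * dring),
      pipi_e2f_plane_angle_window = c(60 - s * dring, min(180, 120 + s * dring)),
      hydrophobic_distance = 3.6 + s * dd,
      ionic_distance = 3.7 + s * dd)
  }
  crit_tight <- shift(-1)
  crit_loose <- shift(+1)
  top <- system$topology
  ctx <- interaction_context(top)
  anchor_idx <- unlist(lapply(system$site$anchors, as.integer))
  occupant <- 1L
  event_key <- function(xyz, crit) {
    ev <- bind_rows(
      detect_hbonds(xyz, top, crit, context = ctx),
      detect_water_bridges(xyz, top, crit, context = ctx),
      detect_pi_interactions(xyz, top, crit, context = ctx),
      detect_nonpolar_and_ionic(xyz, top, crit, context = ctx))
    sort(paste(ev$type, ev$resno, ev$chain, ev$ligand_atoms, ev$water_id))
  }
  combos <- expand.grid(ASP69 = c(TRUE, FALSE), GLU63 = c(TRUE, FALSE),
                        HIS95 = c(TRUE, FALSE), state = c("native", "flipped"),
                        occupied = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    xyz <- archetype_coords(system, as.list(cb[1:3]), cb$state, cb$occupied, occupant)
    if (!identical(event_key(xyz, crit_tight), event_key(xyz, crit_loose))) {
      stop_bindmode("noise level could cross an interaction criterion boundary; lower noise_sigma",
                    "bindmode_config_error")
    }
    # site occupancy margin
    ctr <- colMeans(xyz[anchor_idx, , drop = FALSE])
    dw <- sqrt(colSums((t(xyz[vapply(system$plan$water_atoms, `[`, integer(1), 1), ]) - ctr)^2))
    if (!identical(dw <= cfg$site_radius - dd, dw <= cfg$site_radius + dd)) {
      stop_bindmode("noise level could cross the water-site radius; lower noise_sigma",
                    "bindmode_config_error")
    }
    # state-boundary margin
    og <- xyz[system$plan$state$atoms[1], ]
    cb58 <- xyz[which(top$atoms$resno == 58 & top$atoms$name == "CB" & top$atoms$chain == "A"), ]
    hh <- xyz[which(top$atoms$resno == 10 & top$atoms$name == "H" & top$atoms$chain == "A"), ]
    d <- vnorm(og - hh); ang <- vec_angle(og, cb58, hh)
    lab <- function(dmax, w) d <= dmax && ang >= w[1] && ang <= w[2]
    if (lab(cfg$state_distance_max - dd, cfg$state_angle_window + c(da_state, -da_state)) !=
        lab(cfg$state_distance_max + dd, cfg$state_angle_window + c(-da_state, da_state))) {
      stop_bindmode("noise level could cross the state-classification boundary; lower noise_sigma",
                    "bindmode_config_error")
    }
  }
  invisible(TRUE)
}

#' Simulate one synthetic replica
#'
#' Per frame, each planted contact is switched on/off by an independent
#' Bernoulli draw at its target probability; the site water follows a Markov
#' on/off chain matching the stationary occupancy, with the occupant replaced
#' on re-entry (and, optionally, swapped in place at `water_exchange_prob`);
#' the Thr58-type side chain follows its two-state Markov schedule; clamped
#' Gaussian noise is added to every coordinate. The returned ledger records
#' the exact planted truth per frame.
#'
#' @param system A [build_system()] result.
#' @param replica Replica number (drives the derived sub-seed).
#' @return List with `trajectory` (a [trajectory()]) and `ledger` (tibble with
#'   per-frame contact flags, `occupied`, `site_water`, `state`).
#' @export
simulate_trajectory <- function(system, replica = 1L) {
  cfg <- system$config
  plan <- system$plan
  nf <- cfg$n_frames
  set.seed(replica_seed(cfg$seed, replica))

  contact_names <- names(plan$contacts)
  targets <- cfg$hbond_occupancy_targets[contact_names]
  targets[is.na(targets)] <- 0
  flags <- matrix(FALSE, nf, length(contact_names),
                  dimnames = list(NULL, contact_names))
  for (j in seq_along(contact_names)) {
    flags[, j] <- runif(nf) < targets[j]
  }

  # two-state Markov schedule
  state <- character(nf)
  cur <- if (runif(1) < cfg$state_native_fraction) "native" else "flipped"
  for (f in seq_len(nf)) {
    state[f] <- cur
    p_stay <- if (cur == "native") cfg$state_stay_prob else 1 - cfg$state_entry_prob
    if (runif(1) >= p_stay) cur <- if (cur == "native") "flipped" else "native"
  }

  # site occupancy: Markov chain (or state-conditioned Bernoulli)
  occupied <- logical(nf)
  occupant <- rep(NA_integer_, nf)
  pick_new <- function(exclude) {
    pool <- seq_len(cfg$n_waters)
    if (!is.na(exclude)) pool <- pool[pool != exclude]
    pool[sample.int(length(pool), 1L)]
  }
  if (is.null(cfg$occupancy_by_state)) {
    occ <- runif(1) < cfg$water_site_occupancy
    cur_w <- if (occ) pick_new(NA_integer_) else NA_integer_
    for (f in seq_len(nf)) {
      occupied[f] <- occ
      occupant[f] <- if (occ) cur_w else NA_integer_
      if (occ && cfg$water_exchange_prob > 0 && runif(1) < cfg$water_exchange_prob) {
        cur_w <- pick_new(cur_w)
        # exchange applies from the next frame on
      }
      if (occ) {
        if (runif(1) >= cfg$water_stay_prob) {
          occ <- FALSE
        }
      } else {
        if (runif(1) < cfg$water_entry_prob) {
          occ <- TRUE
          cur_w <- pick_new(cur_w)
        }
      }
    }
  } else {
    p <- cfg$occupancy_by_state
    last_w <- NA_integer_
    for (f in seq_len(nf)) {
      occupied[f] <- runif(1) < p[[state[f]]]
      if (occupied[f]) {
        last_w <- pick_new(last_w)
        occupant[f] <- last_w
      }
    }
  }

  n_at <- nrow(system$reference)
  coords <- array(NA_real_, dim = c(n_at, 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- system$reference
    for (j in seq_along(contact_names)) {
      if (!flags[f, j]) {
        ct <- plan$contacts[[j]]
        xyz[ct$atoms, ] <- sweep(xyz[ct$atoms, , drop = FALSE], 2, ct$off_shift, `+`)
      }
    }
    xyz[plan$state$atoms, ] <- if (state[f] == "native") plan$state$native else plan$state$flipped
    if (occupied[f]) {
      xyz[plan$water_atoms[[occupant[f]]], ] <- plan$site_water_pos
    }
    if (cfg$noise_sigma > 0) {
      noise <- matrix(rnorm(n_at * 3L, sd = cfg$noise_sigma), n_at, 3L)
      lim <- 4 * cfg$noise_sigma
      noise <- pmin(pmax(noise, -lim), lim)
      xyz <- xyz + noise
    }
    coords[, , f] <- xyz
  }
  times <- (seq_len(nf) - 1L) * cfg$frame_spacing_ns
  ledger <- tibble(replica = as.integer(replica), frame = seq_len(nf), time_ns = times,
                   ASP69 = flags[, "ASP69"], GLU63 = flags[, "GLU63"],
                   HIS95 = flags[, "HIS95"],
                   occupied = occupied, site_water = occupant, state = state)
  list(trajectory = trajectory(coords, times), ledger = ledger)
}

#' Run the full synthetic study
#'
#' Builds the system and simulates all replicas, returning the trajectories
#' and the pooled ground-truth ledger.
#'
#' @param config A [generator_config()].
#' @return List with `system`, `trajectories` (list, one per replica),
#'   `ledger` (pooled tibble).
#' @export
synthetic_study <- function(config = generator_config()) {
  system <- build_system(config)
  runs <- lapply(seq_len(config$n_replicas), function(r) simulate_trajectory(system, r))
  list(system = system,
       trajectories = lapply(runs, `[[`, "trajectory"),
       ledger = bind_rows(lapply(runs, `[[`, "ledger")))
}

#' Exact realized values of a ground-truth ledger
#'
#' @param ledger Ledger tibble from [simulate_trajectory()] or
#'   [synthetic_study()].
#' @return List with `contact_fractions` (realized planted-contact fractions),
#'   `occupancy_fraction`, `unique_waters` (per-replica tibble), `median_unique`,
#'   `state_fractions`, `conditional_occupancy` (tibble by state).
#' @export
ledger_summary <- function(ledger) {
  per <- ledger %>%
    group_by(.data$replica) %>%
    summarise(n_unique = n_distinct(.data$site_water[!is.na(.data$site_water)]),
              .groups = "drop")
  cond <- ledger %>%
    group_by(.data$state) %>%
    summarise(fraction = mean(.data$occupied), n_frames = n(), .groups = "drop")
  list(
    contact_fractions = c(ASP69 = mean(ledger$ASP69), GLU63 = mean(ledger$GLU63),
                          HIS95 = mean(ledger$HIS95)),
    occupancy_fraction = mean(ledger$occupied),
    unique_waters = per,
    median_unique = median(per$n_unique),
    state_fractions = c(native = mean(ledger$state == "native"),
                        flipped = mean(ledger$state == "flipped")),
    conditional_occupancy = cond
  )
}

#' Write a synthetic system and trajectories to files
#'
#' Exports the topology as a PDB with CONECT records, the ligand sidecar as
#' YAML, trajectories as multi-model PDB or DCD, and the ledger as JSON.
#'
#' @param study A [synthetic_study()] result.
#' @param dir Output directory (created if needed).
#' @param format `"dcd"` (default) or `"pdb"` for the trajectories.
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir, format = c("dcd", "pdb")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top <- study$system$topology
  ref <- trajectory(array(study$system$reference,
                          dim = c(nrow(study$system$reference), 3L, 1L)), times = 0)
  write_trajectory_pdb(ref, top, file.path(dir, "topology.pdb"))
  yaml::write_yaml(study$system$sidecar, file.path(dir, "ligand.yaml"))
  for (r in seq_along(study$trajectories)) {
    path <- file.path(dir, sprintf("replica_%02d.%s", r, format))
    if (format == "dcd") {
      write_trajectory_dcd(study$trajectories[[r]], top, path)
    } else {
      write_trajectory_pdb(study$trajectories[[r]], top, path)
    }
  }
  jsonlite::write_json(as.data.frame(study$ledger), file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
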