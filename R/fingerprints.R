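# Per-frame protein-ligand interaction detection and aggregation into
# interaction fractions.

# Precompute everything the per-frame detectors need from the topology.
interaction_context <- function(top) {
  atoms <- top$atoms
  seg <- atoms$segment
  donors <- top$donors
  donor_seg <- seg[donors$heavy]
  acc_seg <- seg[top$acceptors]

  # bonded heavy neighbors of each acceptor (for the H...A-X acceptor angle)
  el <- atoms$element
  nb <- vector("list", nrow(atoms))
  if (nrow(top$bonds) > 0L) {
    for (k in seq_len(nrow(top$bonds))) {
      a <- top$bonds[k, 1]; b <- top$bonds[k, 2]
      if (el[b] != "H") nb[[a]] <- c(nb[[a]], b)
      if (el[a] != "H") nb[[b]] <- c(nb[[b]], a)
    }
  }

  ring_seg <- vapply(top$rings, function(r) seg[r[1]], character(1))
  grp_seg <- vapply(top$charged_groups, function(g) seg[g$atoms[1]], character(1))
  water_o <- which(atoms$is_water & el == "O")

  list(
    atoms = atoms,
    backbone_names = c("N", "CA", "C", "O", "H", "HN", "HA", "HA2", "HA3"),
    donors_protein = donors[donor_seg == "protein", ],
    donors_ligand = donors[donor_seg == "ligand", ],
    donors_water = donors[donor_seg == "water", ],
    acceptors_protein = top$acceptors[acc_seg == "protein"],
    acceptors_ligand = top$acceptors[acc_seg == "ligand"],
    water_oxygens = water_o,
    acceptor_neighbors = nb,
    rings_protein = top$rings[ring_seg == "protein"],
    rings_ligand = top$rings[ring_seg == "ligand"],
    charged_protein = top$charged_groups[grp_seg == "protein"],
    charged_ligand = top$charged_groups[grp_seg == "ligand"],
    hydrophobic_protein = top$hydrophobic[seg[top$hydrophobic] == "protein"],
    hydrophobic_ligand = top$hydrophobic[seg[top$hydrophobic] == "ligand"],
    missing_h = top$missing_hydrogens[seg[top$missing_hydrogens] %in% c("protein", "ligand")]
  )
}

# Vectorized hydrogen-bond geometry test. Returns logical vector over pairs.
# Distances honor the periodic box; angles use the unwrapped coordinates
# (systems are assumed whole/wrapped per molecule). Acceptors without bonded
# heavy atoms (water oxygens) satisfy the acceptor-angle criterion trivially.
hbond_geometry_ok <- function(xyz, donor, hydrogen, acceptor, nb, box,
                              dist_max, donor_angle_min, acceptor_angle_min) {
  if (length(hydrogen) == 0L) return(logical(0))
  ok <- pbc_distance(xyz[hydrogen, , drop = FALSE], xyz[acceptor, , drop = FALSE], box) <= dist_max
  idx <- which(ok)
  if (length(idx) == 0L) return(ok)
  dang <- vec_angle_rows(xyz[donor[idx], , drop = FALSE],
                         xyz[hydrogen[idx], , drop = FALSE],
                         xyz[acceptor[idx], , drop = FALSE])
  ok[idx] <- dang >= donor_angle_min
  idx <- which(ok)
  if (length(idx) == 0L) return(ok)
  for (i in idx) {
    xs <- nb[[acceptor[i]]]
    if (length(xs) == 0L) next
    aang <- vapply(xs, function(x) {
      vec_angle(xyz[hydrogen[i], ], xyz[acceptor[i], ], xyz[x, ])
    }, numeric(1))
    if (max(aang) < acceptor_angle_min) ok[i] <- FALSE
  }
  ok
}

empty_events <- function() {
  tibble::new_tibble(list(
    type = character(), resno = integer(), resname = character(),
    chain = character(), residue_part = character(),
    ligand_atoms = character(), water_id = integer(), direction = character()),
    nrow = 0L)
}

event_rows <- function(ctx, type, protein_atom, ligand_atoms, water_id, direction) {
  a <- ctx$atoms
  n <- length(protein_atom)
  part <- ifelse(a$name[protein_atom] %in% ctx$backbone_names, "backbone", "sidechain")
  tibble::new_tibble(list(
    type = rep_len(type, n),
    resno = a$resno[protein_atom], resname = a$resname[protein_atom],
    chain = a$chain[protein_atom], residue_part = part,
    ligand_atoms = rep_len(ligand_atoms, n),
    water_id = rep_len(as.integer(water_id), n),
    direction = rep_len(direction, n)), nrow = n)
}

#' Detect protein-ligand hydrogen bonds in one frame
#'
#' An event is recorded when the hydrogen-acceptor distance is at most
#' `hbond_distance`, the donor angle D-H...A is at least
#' `hbond_donor_angle_min`, and the acceptor angle H...A-X (maximized over the
#' acceptor's bonded heavy atoms X) is at least `hbond_acceptor_angle_min`.
#' Both donor directions (protein donor and ligand donor) are scanned.
#'
#' @param xyz `n_atoms x 3` frame coordinates (Angstrom).
#' @param topology A [topology()] object with hydrogens on all donors.
#' @param criteria An [interaction_criteria()] list.
#' @param box Optional periodic box (3x3 row-vector matrix).
#' @param context Internal precomputed context (for repeated calls).
#' @return Tibble of events (`type`, `resno`, `resname`, `chain`,
#'   `residue_part`, `ligand_atoms`, `water_id`, `direction`).
#' @export
detect_hbonds <- function(xyz, topology, criteria = interaction_criteria(),
                          box = NULL, context = NULL) {
  ctx <- context %||% interaction_context(topology)
  if (length(ctx$missing_h) > 0L) {
    a <- ctx$atoms[ctx$missing_h[1], ]
    stop_bindmode(sprintf("donor %s of %s%d has no attached hydrogen; hydrogens are required for H-bond analysis",
                          a$name, a$resname, a$resno), "bindmode_annotation_error")
  }
  out <- list()
  # protein donor -> ligand acceptor
  dp <- ctx$donors_protein; al <- ctx$acceptors_ligand
  if (nrow(dp) > 0L && length(al) > 0L) {
    D <- rep(dp$heavy, times = length(al)); H <- rep(dp$hydrogen, times = length(al))
    A <- rep(al, each = nrow(dp))
    ok <- hbond_geometry_ok(xyz, D, H, A, ctx$acceptor_neighbors, box,
                            criteria$hbond_distance, criteria$hbond_donor_angle_min,
                            criteria$hbond_acceptor_angle_min)
    if (any(ok)) {
      out[[length(out) + 1L]] <- event_rows(ctx, "hbond", D[ok],
                                            ctx$atoms$name[A[ok]], NA_integer_, "protein")
    }
  }
  # ligand donor -> protein acceptor
  dl <- ctx$donors_ligand; ap <- ctx$acceptors_protein
  if (nrow(dl) > 0L && length(ap) > 0L) {
    D <- rep(dl$heavy, times = length(ap)); H <- rep(dl$hydrogen, times = length(ap))
    A <- rep(ap, each = nrow(dl))
    ok <- hbond_geometry_ok(xyz, D, H, A, ctx$acceptor_neighbors, box,
                            criteria$hbond_distance, criteria$hbond_donor_angle_min,
                            criteria$hbond_acceptor_angle_min)
    if (any(ok)) {
      out[[length(out) + 1L]] <- event_rows(ctx, "hbond", A[ok],
                                            ctx$atoms$name[D[ok]], NA_integer_, "ligand")
    }
  }
  if (length(out) == 0L) empty_events() else bind_rows(out)
}

# One leg of a water bridge: all water<->partner hydrogen bonds under the
# water-bridge thresholds. Returns tibble(water (O index), partner (heavy
# protein/ligand atom), donor_side ("water" or "partner")).
water_legs <- function(xyz, ctx, criteria, box, partner_donors, partner_acceptors,
                       water_donors = NULL, water_oxygens = NULL) {
  legs <- list()
  dw <- water_donors %||% ctx$donors_water
  # water donates to partner acceptor
  if (nrow(dw) > 0L && length(partner_acceptors) > 0L) {
    D <- rep(dw$heavy, times = length(partner_acceptors))
    H <- rep(dw$hydrogen, times = length(partner_acceptors))
    A <- rep(partner_acceptors, each = nrow(dw))
    ok <- hbond_geometry_ok(xyz, D, H, A, ctx$acceptor_neighbors, box,
                            criteria$wbridge_distance, criteria$wbridge_donor_angle_min,
                            criteria$wbridge_acceptor_angle_min)
    if (any(ok)) {
      legs[[length(legs) + 1L]] <- tibble::new_tibble(
        list(water = D[ok], partner = A[ok],
             donor_side = rep_len("water", sum(ok))), nrow = sum(ok))
    }
  }
  # partner donates to water oxygen
  wo <- water_oxygens %||% ctx$water_oxygens
  if (nrow(partner_donors) > 0L && length(wo) > 0L) {
    D <- rep(partner_donors$heavy, times = length(wo))
    H <- rep(partner_donors$hydrogen, times = length(wo))
    A <- rep(wo, each = nrow(partner_donors))
    ok <- hbond_geometry_ok(xyz, D, H, A, ctx$acceptor_neighbors, box,
                            criteria$wbridge_distance, criteria$wbridge_donor_angle_min,
                            criteria$wbridge_acceptor_angle_min)
    if (any(ok)) {
      legs[[length(legs) + 1L]] <- tibble::new_tibble(
        list(water = A[ok], partner = D[ok],
             donor_side = rep_len("partner", sum(ok))), nrow = sum(ok))
    }
  }
  if (length(legs) == 0L) {
    tibble::new_tibble(list(water = integer(), partner = integer(),
                            donor_side = character()), nrow = 0L)
  } else {
    bind_rows(legs)
  }
}

#' Detect water-bridged protein-ligand interactions in one frame
#'
#' A single water simultaneously hydrogen-bonded (under the water-bridge
#' thresholds) to a protein residue and to a ligand atom produces one event
#' per (residue, water, ligand atom). Only single-water bridges are
#' considered. The `direction` field records the donor of the protein leg
#' (`"protein"` or `"water"`).
#'
#' @inheritParams detect_hbonds
#' @return Tibble of events; `water_id` is the molecule id of the bridging
#'   water.
#' @export
detect_water_bridges <- function(xyz, topology, criteria = interaction_criteria(),
                                 box = NULL, context = NULL) {
  ctx <- context %||% interaction_context(topology)
  if (length(ctx$water_oxygens) == 0L) {
    stop_bindmode("topology contains no annotated waters", "bindmode_annotation_error")
  }
  # A bridging water needs one of its atoms within the H...A cutoff of a
  # ligand polar atom (water H near a ligand acceptor, or water O near a
  # ligand donor hydrogen); prefiltering on that condition is an exact
  # superset of the candidates and prunes the bulk solvent.
  lig_polar <- unique(c(ctx$acceptors_ligand, ctx$donors_ligand$heavy,
                        ctx$donors_ligand$hydrogen))
  if (length(lig_polar) == 0L) return(empty_events())
  wo <- ctx$water_oxygens
  watoms <- c(wo, ctx$donors_water$hydrogen)
  owner <- c(wo, ctx$donors_water$heavy)   # owning oxygen of each water atom
  reach <- criteria$wbridge_distance + 1e-9
  near_o <- integer()
  for (a in lig_polar) {
    d <- pbc_distance(xyz[watoms, , drop = FALSE],
                      matrix(xyz[a, ], length(watoms), 3L, byrow = TRUE), box)
    near_o <- c(near_o, owner[d <= reach])
  }
  if (length(near_o) == 0L) return(empty_events())
  wo_near <- intersect(wo, unique(near_o))
  dw_near <- ctx$donors_water[ctx$donors_water$heavy %in% wo_near, ]
  lig <- water_legs(xyz, ctx, criteria, box, ctx$donors_ligand, ctx$acceptors_ligand,
                    water_donors = dw_near, water_oxygens = wo_near)
  if (nrow(lig) == 0L) return(empty_events())
  prot <- water_legs(xyz, ctx, criteria, box, ctx$donors_protein, ctx$acceptors_protein,
                     water_donors = dw_near, water_oxygens = wo_near)
  if (nrow(prot) == 0L) return(empty_events())
  joined <- dplyr::inner_join(prot, lig, by = "water", suffix = c("_prot", "_lig"),
                              relationship = "many-to-many")
  if (nrow(joined) == 0L) return(empty_events())
  joined <- distinct(joined, .data$water, .data$partner_prot, .data$partner_lig,
                     .keep_all = TRUE)
  mol <- ctx$atoms$molid
  event_rows(ctx, "water_bridge", joined$partner_prot,
             ctx$atoms$name[joined$partner_lig], mol[joined$water],
             ifelse(joined$donor_side_prot == "water", "water", "protein"))
}

ring_centroid_normal <- function(xyz, ring) {
  pts <- xyz[ring, , drop = FALSE]
  centroid <- colMeans(pts)
  sv <- svd(sweep(pts, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

# Interplanar angle folded into [0, 90] (ring normals have no sign).
plane_angle <- function(n1, n2) {
  ang <- acos(max(-1, min(1, abs(sum(n1 * n2)) / (vnorm(n1) * vnorm(n2))))) * 180 / pi
  ang
}

#' Detect pi-pi and pi-cation interactions in one frame
#'
#' A pi-cation event requires a charged-group centroid within
#' `pication_distance` of an aromatic ring centroid on the opposite molecule.
#' A pi-pi event requires two ring centroids within the face-to-face cutoff
#' with a folded interplanar angle at most `pipi_f2f_plane_angle_max`, or
#' within the edge-to-face cutoff with the angle inside the edge window. Ring
#' normals come from the SVD of the centered ring coordinates.
#'
#' @inheritParams detect_hbonds
#' @return Tibble of events (`type` is `"pi_pi"` or `"pi_cation"`).
#' @export
detect_pi_interactions <- function(xyz, topology, criteria = interaction_criteria(),
                                   box = NULL, context = NULL) {
  ctx <- context %||% interaction_context(topology)
  for (ring in c(ctx$rings_protein, ctx$rings_ligand)) {
    if (length(ring) < 5L) {
      stop_bindmode("aromatic ring with fewer than 5 atoms", "bindmode_annotation_error")
    }
  }
  out <- list()
  prot_rings <- lapply(ctx$rings_protein, ring_centroid_normal, xyz = xyz)
  lig_rings <- lapply(ctx$rings_ligand, ring_centroid_normal, xyz = xyz)
  # pi-pi: protein ring x ligand ring
  e2f_min <- min(criteria$pipi_e2f_plane_angle_window)
  e2f_max <- max(criteria$pipi_e2f_plane_angle_window)
  for (i in seq_along(prot_rings)) {
    for (j in seq_along(lig_rings)) {
      d <- pbc_distance(prot_rings[[i]]$centroid, lig_rings[[j]]$centroid, box)
      phi <- plane_angle(prot_rings[[i]]$normal, lig_rings[[j]]$normal)
      f2f <- d <= criteria$pipi_f2f_centroid_max && phi <= criteria$pipi_f2f_plane_angle_max
      e2f <- d <= criteria$pipi_e2f_centroid_max && phi >= e2f_min && phi <= e2f_max
      if (f2f || e2f) {
        ring_atom <- ctx$rings_protein[[i]][1]
        lig_names <- paste(ctx$atoms$name[ctx$rings_ligand[[j]]], collapse = ",")
        out[[length(out) + 1L]] <- event_rows(ctx, "pi_pi", ring_atom, lig_names,
                                              NA_integer_,
                                              if (f2f) "face_to_face" else "edge_to_face")
      }
    }
  }
  # pi-cation: both directions
  group_centroid <- function(g) colMeans(xyz[g$atoms, , drop = FALSE])
  for (g in ctx$charged_protein) {
    if (g$sign <= 0) next
    gc <- group_centroid(g)
    for (j in seq_along(lig_rings)) {
      if (pbc_distance(gc, lig_rings[[j]]$centroid, box) <= criteria$pication_distance) {
        lig_names <- paste(ctx$atoms$name[ctx$rings_ligand[[j]]], collapse = ",")
        out[[length(out) + 1L]] <- event_rows(ctx, "pi_cation", g$atoms[1], lig_names,
                                              NA_integer_, "protein")
      }
    }
  }
  for (g in ctx$charged_ligand) {
    if (g$sign <= 0) next
    gc <- group_centroid(g)
    for (i in seq_along(prot_rings)) {
      if (pbc_distance(gc, prot_rings[[i]]$centroid, box) <= criteria$pication_distance) {
        lig_names <- paste(ctx$atoms$name[g$atoms], collapse = ",")
        out[[length(out) + 1L]] <- event_rows(ctx, "pi_cation", ctx$rings_protein[[i]][1],
                                              lig_names, NA_integer_, "ligand")
      }
    }
  }
  if (length(out) == 0L) empty_events() else bind_rows(out)
}

#' Detect hydrophobic and ionic contacts in one frame
#'
#' A hydrophobic event is recorded per protein residue whose flagged nonpolar
#' carbons come within `hydrophobic_distance` of a flagged nonpolar ligand
#' carbon. An ionic event is recorded per pair of oppositely charged groups
#' whose closest atoms are within `ionic_distance`.
#'
#' @inheritParams detect_hbonds
#' @return Tibble of events (`type` is `"hydrophobic"` or `"ionic"`).
#' @export
detect_nonpolar_and_ionic <- function(xyz, topology, criteria = interaction_criteria(),
                                      box = NULL, context = NULL) {
  ctx <- context %||% interaction_context(topology)
  out <- list()
  hp <- ctx$hydrophobic_protein; hl <- ctx$hydrophobic_ligand
  if (length(hp) > 0L && length(hl) > 0L) {
    P <- rep(hp, times = length(hl)); L <- rep(hl, each = length(hp))
    d <- pbc_distance(xyz[P, , drop = FALSE], xyz[L, , drop = FALSE], box)
    hit <- d <= criteria$hydrophobic_distance
    if (any(hit)) {
      df <- tibble(p = P[hit], l = L[hit],
                   res = paste(ctx$atoms$chain[P[hit]], ctx$atoms$resno[P[hit]]))
      per_res <- df %>%
        group_by(.data$res) %>%
        summarise(p = .data$p[1],
                  lig = paste(sort(unique(ctx$atoms$name[.data$l])), collapse = ","),
                  .groups = "drop")
      out[[length(out) + 1L]] <- event_rows(ctx, "hydrophobic", per_res$p, per_res$lig,
                                            NA_integer_, "none")
    }
  }
  for (gp in ctx$charged_protein) {
    for (gl in ctx$charged_ligand) {
      if (gp$sign * gl$sign >= 0) next
      P <- rep(gp$atoms, times = length(gl$atoms))
      L <- rep(gl$atoms, each = length(gp$atoms))
      dmin <- min(pbc_distance(xyz[P, , drop = FALSE], xyz[L, , drop = FALSE], box))
      if (dmin <= criteria$ionic_distance) {
        lig_names <- paste(ctx$atoms$name[gl$atoms], collapse = ",")
        out[[length(out) + 1L]] <- event_rows(ctx, "ionic", gp$atoms[1], lig_names,
                                              NA_integer_, "none")
      }
    }
  }
  if (length(out) == 0L) empty_events() else bind_rows(out)
}

#' Detect all protein-ligand interactions over a trajectory
#'
#' Runs the hydrogen-bond, water-bridge, pi and nonpolar/ionic detectors on
#' every frame and returns the pooled event table.
#'
#' @param traj A [trajectory()] object.
#' @param topology The matching [topology()].
#' @param criteria An [interaction_criteria()] list.
#' @param replica Integer replica id recorded on every event (default 1).
#' @param types Character subset of
#'   `c("hbond", "water_bridge", "pi", "nonpolar_ionic")` to run.
#' @return Tibble of events with columns `replica`, `frame`, `time_ns`,
#'   `type`, `resno`, `resname`, `chain`, `residue_part`, `ligand_atoms`,
#'   `water_id`, `direction`; class `bindmode_events`.
#' @export
detect_interactions <- function(traj, topology, criteria = interaction_criteria(),
                                replica = 1L,
                                types = c("hbond", "water_bridge", "pi", "nonpolar_ionic")) {
  types <- match.arg(types, several.ok = TRUE)
  ctx <- interaction_context(topology)
  nf <- n_frames(traj)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    ev <- list()
    if ("hbond" %in% types) {
      ev[[length(ev) + 1L]] <- detect_hbonds(xyz, topology, criteria, traj$box, ctx)
    }
    if ("water_bridge" %in% types && length(ctx$water_oxygens) > 0L) {
      ev[[length(ev) + 1L]] <- detect_water_bridges(xyz, topology, criteria, traj$box, ctx)
    }
    if ("pi" %in% types) {
      ev[[length(ev) + 1L]] <- detect_pi_interactions(xyz, topology, criteria, traj$box, ctx)
    }
    if ("nonpolar_ionic" %in% types) {
      ev[[length(ev) + 1L]] <- detect_nonpolar_and_ionic(xyz, topology, criteria, traj$box, ctx)
    }
    ev <- bind_rows(ev)
    if (nrow(ev) > 0L) {
      ev$frame <- f
      ev$time_ns <- traj$times[f]
      out[[f]] <- ev
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- empty_events()
    res$frame <- integer()
    res$time_ns <- numeric()
  }
  res$replica <- as.integer(replica)
  res <- res[, c("replica", "frame", "time_ns", "type", "resno", "resname", "chain",
                 "residue_part", "ligand_atoms", "water_id", "direction")]
  class(res) <- c("bindmode_events", class(res))
  res
}

#' Aggregate interaction events into per-residue fractions
#'
#' Per (residue, interaction type), the fraction is the number of analyzed
#' frames (pooled over replicas) with at least one event of that type divided
#' by `frames_analyzed` (per-frame binarization: multiple same-type contacts
#' between one residue and the ligand in one frame count once). The
#' per-residue total is the sum over types and may exceed 1. Residues with
#' total fraction above 0.2 are flagged `displayed`, above 0.5 `key` (strict
#' inequalities).
#'
#' @param events Event tibble from [detect_interactions()] (replicas pooled
#'   with [dplyr::bind_rows()]).
#' @param frames_analyzed Total number of frames analyzed across replicas.
#' @return Tibble with columns `resno`, `resname`, `chain`, `type`,
#'   `fraction`, `total`, `displayed`, `key`; class `bindmode_fractions`.
#' @export
aggregate_fractions <- function(events, frames_analyzed) {
  if (!is_scalar_number(frames_analyzed) || frames_analyzed <= 0) {
    stop_bindmode("frames_analyzed must be a positive number", "bindmode_statistics_error")
  }
  per_type <- events %>%
    distinct(.data$replica, .data$frame, .data$resno, .data$resname, .data$chain,
             .data$type) %>%
    count(.data$resno, .data$resname, .data$chain, .data$type, name = "n_frames") %>%
    mutate(fraction = .data$n_frames / frames_analyzed) %>%
    select(-"n_frames")
  totals <- per_type %>%
    group_by(.data$resno, .data$resname, .data$chain) %>%
    summarise(total = sum(.data$fraction), .groups = "drop")
  out <- per_type %>%
    left_join(totals, by = c("resno", "resname", "chain")) %>%
    mutate(displayed = .data$total > 0.2, key = .data$total > 0.5) %>%
    arrange(desc(.data$total), .data$resno, .data$type)
  class(out) <- c("bindmode_fractions", class(out))
  attr(out, "frames_analyzed") <- frames_analyzed
  out
}

#' Write a fraction table as CSV
#' @param fractions A [aggregate_fractions()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fractions_csv <- function(fractions, path) {
  write.csv(as.data.frame(fractions), path, row.names = FALSE)
  invisible(path)
}

#' Write interaction events as JSON lines
#' @param events A [detect_interactions()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(events) > 0L) {
    jsonlite::stream_out(as.data.frame(events), con, verbose = FALSE)
  }
  invisible(path)
}
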