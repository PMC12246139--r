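# Literal brute-force oracles for the geometric interaction criteria,
# written as plain loops with their own formulas, independent of the
# detector implementations.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# heavy (non-H) neighbors of an atom under the topology bonds
o_neighbors <- function(top, i) {
  b <- top$bonds
  nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  nb[top$atoms$element[nb] != "H"]
}

o_hbond_ok <- function(xyz, top, D, H, A, dmax, amin_d, amin_a) {
  if (o_dist(xyz[H, ], xyz[A, ]) > dmax) return(FALSE)
  if (o_angle(xyz[D, ], xyz[H, ], xyz[A, ]) < amin_d) return(FALSE)
  xs <- o_neighbors(top, A)
  if (length(xs) == 0L) return(TRUE)
  any(sapply(xs, function(x) o_angle(xyz[H, ], xyz[A, ], xyz[x, ])) >= amin_a)
}

o_water_resno <- function(top, o_atom) top$atoms$resno[o_atom]

# plane normal by eigen-decomposition of the covariance (independent route)
o_ring_normal <- function(xyz, ring) {
  pts <- xyz[ring, , drop = FALSE]
  cc <- colMeans(pts)
  ev <- eigen(crossprod(sweep(pts, 2, cc)))
  list(centroid = cc, normal = ev$vectors[, 3])
}

# All events of all types, as sorted key strings
# "type resno chain ligand_atoms water_resno".
oracle_events <- function(xyz, top, crit = interaction_criteria()) {
  atoms <- top$atoms
  seg <- atoms$segment
  donors <- top$donors
  keys <- character()
  push <- function(type, prot_atom, lig, wat = NA) {
    keys <<- c(keys, paste(type, atoms$resno[prot_atom], atoms$chain[prot_atom],
                           lig, wat))
  }
  # --- hydrogen bonds, both directions
  for (k in seq_len(nrow(donors))) {
    D <- donors$heavy[k]; H <- donors$hydrogen[k]
    if (seg[D] == "protein") {
      for (A in top$acceptors[seg[top$acceptors] == "ligand"]) {
        if (o_hbond_ok(xyz, top, D, H, A, crit$hbond_distance,
                       crit$hbond_donor_angle_min, crit$hbond_acceptor_angle_min)) {
          push("hbond", D, atoms$name[A])
        }
      }
    } else if (seg[D] == "ligand") {
      for (A in top$acceptors[seg[top$acceptors] == "protein"]) {
        if (o_hbond_ok(xyz, top, D, H, A, crit$hbond_distance,
                       crit$hbond_donor_angle_min, crit$hbond_acceptor_angle_min)) {
          push("hbond", A, atoms$name[D])
        }
      }
    }
  }
  # --- water bridges: per water, legs to protein and ligand
  w_ok <- function(D, H, A) o_hbond_ok(xyz, top, D, H, A, crit$wbridge_distance,
                                       crit$wbridge_donor_angle_min,
                                       crit$wbridge_acceptor_angle_min)
  waters <- which(atoms$is_water & atoms$element == "O")
  for (wo in waters) {
    whs <- donors$hydrogen[donors$heavy == wo]
    legs_to <- function(side) {
      partners <- integer()
      for (h in whs) {
        for (A in top$acceptors[seg[top$acceptors] == side]) {
          if (w_ok(wo, h, A)) partners <- c(partners, A)
        }
      }
      dns <- donors[seg[donors$heavy] == side, ]
      for (k in seq_len(nrow(dns))) {
        if (w_ok(dns$heavy[k], dns$hydrogen[k], wo)) {
          partners <- c(partners, dns$heavy[k])
        }
      }
      unique(partners)
    }
    pp <- legs_to("protein")
    if (length(pp) == 0L) next
    pl <- legs_to("ligand")
    for (a in pp) for (b in pl) {
      push("water_bridge", a, atoms$name[b], o_water_resno(top, wo))
    }
  }
  # --- pi-pi and pi-cation
  ring_seg <- sapply(top$rings, function(r) seg[r[1]])
  pr <- top$rings[ring_seg == "protein"]; lr <- top$rings[ring_seg == "ligand"]
  for (ri in pr) for (rj in lr) {
    a <- o_ring_normal(xyz, ri); b <- o_ring_normal(xyz, rj)
    d <- o_dist(a$centroid, b$centroid)
    cosphi <- abs(sum(a$normal * b$normal)) /
      sqrt(sum(a$normal^2) * sum(b$normal^2))
    phi <- acos(min(1, cosphi)) * 180 / pi
    f2f <- d <= crit$pipi_f2f_centroid_max && phi <= crit$pipi_f2f_plane_angle_max
    e2f <- d <= crit$pipi_e2f_centroid_max &&
      phi >= min(crit$pipi_e2f_plane_angle_window) &&
      phi <= max(crit$pipi_e2f_plane_angle_window)
    if (f2f || e2f) {
      push("pi_pi", ri[1], paste(atoms$name[rj], collapse = ","))
    }
  }
  grp_seg <- sapply(top$charged_groups, function(g) seg[g$atoms[1]])
  pg <- top$charged_groups[grp_seg == "protein"]
  lg <- top$charged_groups[grp_seg == "ligand"]
  for (g in pg) {
    if (g$sign <= 0) next
    gc <- colMeans(xyz[g$atoms, , drop = FALSE])
    for (rj in lr) {
      if (o_dist(gc, colMeans(xyz[rj, , drop = FALSE])) <= crit$pication_distance) {
        push("pi_cation", g$atoms[1], paste(atoms$name[rj], collapse = ","))
      }
    }
  }
  for (g in lg) {
    if (g$sign <= 0) next
    gc <- colMeans(xyz[g$atoms, , drop = FALSE])
    for (ri in pr) {
      if (o_dist(gc, colMeans(xyz[ri, , drop = FALSE])) <= crit$pication_distance) {
        push("pi_cation", ri[1], paste(atoms$name[g$atoms], collapse = ","))
      }
    }
  }
  # --- hydrophobic (per residue) and ionic (per group pair)
  hp <- top$hydrophobic[seg[top$hydrophobic] == "protein"]
  hl <- top$hydrophobic[seg[top$hydrophobic] == "ligand"]
  if (length(hp) > 0L && length(hl) > 0L) {
    res_ids <- unique(paste(atoms$chain[hp], atoms$resno[hp]))
    for (rid in res_ids) {
      pa <- hp[paste(atoms$chain[hp], atoms$resno[hp]) == rid]
      partners <- character()
      for (p in pa) for (l in hl) {
        if (o_dist(xyz[p, ], xyz[l, ]) <= crit$hydrophobic_distance) {
          partners <- c(partners, atoms$name[l])
        }
      }
      if (length(partners) > 0L) {
        push("hydrophobic", pa[1], paste(sort(unique(partners)), collapse = ","))
      }
    }
  }
  for (gp in pg) for (gl in lg) {
    if (gp$sign * gl$sign >= 0) next
    dmin <- Inf
    for (p in gp$atoms) for (l in gl$atoms) {
      dmin <- min(dmin, o_dist(xyz[p, ], xyz[l, ]))
    }
    if (dmin <= crit$ionic_distance) {
      push("ionic", gp$atoms[1], paste(atoms$name[gl$atoms], collapse = ","))
    }
  }
  sort(keys)
}

# detector-side events for one frame, as the same key strings
detector_events <- function(xyz, top, crit = interaction_criteria()) {
  ev <- dplyr::bind_rows(
    detect_hbonds(xyz, top, crit),
    detect_water_bridges(xyz, top, crit),
    detect_pi_interactions(xyz, top, crit),
    detect_nonpolar_and_ionic(xyz, top, crit))
  event_keys(ev, top)
}
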