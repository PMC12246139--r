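#' Molecular topology with chemistry annotations
#'
#' A `bindmode_topology` bundles the atom table, the bond list and the
#' hydrogen-bonding/aromatic/charge annotations that the interaction detectors
#' need. Standard amino acids and waters are annotated from a built-in template
#' table; ligand chemistry comes from a YAML sidecar (preferred) or from a
#' simple rule-based perception of the bond graph.
#'
#' @param atoms Tibble with columns `name`, `element`, `resname`, `resno`,
#'   `chain`. Atoms are indexed by row (1-based).
#' @param bonds Two-column integer matrix of atom indices (may be empty).
#' @param xyz Optional n x 3 matrix of reference coordinates (Angstrom).
#' @param ligand_template Optional ligand annotation list (see
#'   [read_ligand_sidecar()]); when `NULL` ligand chemistry is perceived from
#'   the bond graph.
#'
#' @return An object of class `bindmode_topology`: a list with elements
#'   `atoms` (tibble, with derived columns `is_water`, `segment`, `molid`),
#'   `bonds`, `donors` (tibble `heavy`,`hydrogen`), `acceptors` (indices),
#'   `rings` (list of ordered index vectors), `charged_groups` (list of
#'   `list(atoms, sign)`), `hydrophobic` (indices), `missing_hydrogens`
#'   (donor heavy atoms whose template hydrogens are absent) and `xyz`.
#' @export
topology <- function(atoms, bonds = NULL, xyz = NULL, ligand_template = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("name", "element", "resname", "resno", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop_bindmode(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")),
                  "bindmode_format_error")
  }
  n <- nrow(atoms)
  bad <- which(is.na(atoms$element) | atoms$element == "")
  if (length(bad) > 0L) {
    stop_bindmode(sprintf("atom %d (%s %s%s) has unknown element", bad[1],
                          atoms$name[bad[1]], atoms$resname[bad[1]], atoms$resno[bad[1]]),
                  "bindmode_annotation_error")
  }
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L && (min(bonds) < 1L || max(bonds) > n)) {
    stop_bindmode("bond references an atom index outside the topology",
                  "bindmode_format_error")
  }
  atoms$is_water <- is_water_resname(atoms$resname)
  atoms$segment <- atom_segments(atoms)

  top <- structure(list(atoms = atoms, bonds = bonds, xyz = xyz),
                   class = "bindmode_topology")
  top <- annotate_chemistry(top, ligand_template)
  top$atoms$molid <- molecule_ids(nrow(top$atoms), top$bonds)
  validate_topology(top)
  top
}

atom_segments <- function(atoms) {
  ions <- c("K", "NA", "CL", "MG", "ZN", "CA2", "SOD", "CLA", "POT")
  dplyr::case_when(
    is_water_resname(atoms$resname) ~ "water",
    is_standard_resname(atoms$resname) ~ "protein",
    atoms$resname %in% ions ~ "other",
    TRUE ~ "ligand"
  )
}

# Connected components of the bond graph via union-find; bond-less atoms of the
# same residue are merged so that un-bonded waters still form one molecule each.
molecule_ids <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- find(bonds[k, 1]); b <- find(bonds[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

validate_topology <- function(top) {
  atoms <- top$atoms
  # every water molecule has exactly one oxygen
  w <- which(atoms$is_water)
  if (length(w) > 0L) {
    per_mol <- tapply(atoms$element[w] == "O", interaction(atoms$chain[w], atoms$resno[w], drop = TRUE), sum)
    if (any(per_mol != 1L)) {
      stop_bindmode("a water molecule does not have exactly one oxygen atom",
                    "bindmode_format_error")
    }
  }
  for (ring in top$rings) {
    if (length(ring) < 5L) {
      stop_bindmode("aromatic ring has fewer than 5 atoms", "bindmode_annotation_error")
    }
    if (!ring_is_cyclic(ring, top$bonds)) {
      stop_bindmode("aromatic ring atom list is not cyclic under the bond list",
                    "bindmode_annotation_error")
    }
  }
  ann <- c(top$acceptors, top$donors$heavy, top$donors$hydrogen,
           unlist(top$rings), unlist(lapply(top$charged_groups, `[[`, "atoms")),
           top$hydrophobic)
  if (length(ann) > 0L && (min(ann) < 1L || max(ann) > nrow(atoms))) {
    stop_bindmode("annotation references an atom index outside the topology",
                  "bindmode_format_error")
  }
  invisible(top)
}

ring_is_cyclic <- function(ring, bonds) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  have <- key(bonds[, 1], bonds[, 2])
  m <- length(ring)
  edges <- key(ring, ring[c(2:m, 1)])
  all(edges %in% have)
}

# ---- chemistry annotation ----------------------------------------------------

annotate_chemistry <- function(top, ligand_template = NULL) {
  atoms <- top$atoms
  n <- nrow(atoms)
  donors_heavy <- integer(); donors_h <- integer()
  acceptors <- integer(); rings <- list(); charged <- list()
  missing_h <- integer()
  extra_bonds <- list()

  find_atom <- function(rows, nm) rows[atoms$name[rows] %in% nm]

  residues <- atoms %>%
    mutate(.row = dplyr::row_number()) %>%
    group_by(.data$chain, .data$resno, .data$resname) %>%
    summarise(rows = list(.data$.row), .groups = "drop") %>%
    arrange(.data$chain, .data$resno)

  for (i in seq_len(nrow(residues))) {
    resname <- residues$resname[i]
    rows <- residues$rows[[i]]
    if (is_water_resname(resname)) {
      o <- find_atom(rows, .water_template$oxygen)
      hs <- find_atom(rows, .water_template$hydrogens)
      if (length(o) == 1L) {
        acceptors <- c(acceptors, o)
        for (h in hs) {
          donors_heavy <- c(donors_heavy, o); donors_h <- c(donors_h, h)
          extra_bonds[[length(extra_bonds) + 1L]] <- c(o, h)
        }
      }
      next
    }
    if (!is_standard_resname(resname)) next
    tpl <- .sidechain_templates[[resname]]
    # backbone
    if (is.null(tpl$no_backbone_nh)) {
      nb <- find_atom(rows, "N"); hb <- find_atom(rows, c("H", "HN"))
      if (length(nb) == 1L) {
        if (length(hb) >= 1L) {
          donors_heavy <- c(donors_heavy, nb); donors_h <- c(donors_h, hb[1])
        } else {
          missing_h <- c(missing_h, nb)
        }
      }
    }
    ob <- find_atom(rows, "O")
    if (length(ob) == 1L) acceptors <- c(acceptors, ob)
    for (bp in c(.backbone_template$bonds, tpl$bonds %||% list())) {
      a <- find_atom(rows, bp[1]); b <- find_atom(rows, bp[2])
      if (length(a) == 1L && length(b) == 1L) {
        extra_bonds[[length(extra_bonds) + 1L]] <- c(a, b)
      }
    }
    for (heavy_name in names(tpl$donors %||% list())) {
      heavy <- find_atom(rows, heavy_name)
      if (length(heavy) != 1L) next
      hs <- find_atom(rows, tpl$donors[[heavy_name]])
      if (length(hs) == 0L) {
        missing_h <- c(missing_h, heavy)
      } else {
        donors_heavy <- c(donors_heavy, rep(heavy, length(hs)))
        donors_h <- c(donors_h, hs)
      }
    }
    for (acc_name in tpl$acceptors %||% character()) {
      a <- find_atom(rows, acc_name)
      if (length(a) == 1L) acceptors <- c(acceptors, a)
    }
    for (ring_names in tpl$rings %||% list()) {
      idx <- vapply(ring_names, function(nm) {
        a <- find_atom(rows, nm)
        if (length(a) == 1L) a else NA_integer_
      }, integer(1))
      if (!anyNA(idx)) rings[[length(rings) + 1L]] <- unname(idx)
    }
    for (grp in tpl$charged %||% list()) {
      idx <- find_atom(rows, grp$atoms)
      if (length(idx) > 0L) {
        charged[[length(charged) + 1L]] <- list(atoms = idx, sign = grp$sign)
      }
    }
  }

  # peptide bonds between sequence-adjacent residues of a chain
  prot <- residues[vapply(residues$resname, is_standard_resname, logical(1)), ]
  if (nrow(prot) > 1L) {
    for (i in seq_len(nrow(prot) - 1L)) {
      if (prot$chain[i] == prot$chain[i + 1L] && prot$resno[i + 1L] - prot$resno[i] == 1L) {
        ci <- find_atom(prot$rows[[i]], "C"); nj <- find_atom(prot$rows[[i + 1L]], "N")
        if (length(ci) == 1L && length(nj) == 1L) {
          extra_bonds[[length(extra_bonds) + 1L]] <- c(ci, nj)
        }
      }
    }
  }

  bonds <- top$bonds
  if (length(extra_bonds) > 0L) {
    bonds <- rbind(bonds, do.call(rbind, extra_bonds))
  }
  if (nrow(bonds) > 0L) {
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- bonds[!duplicated(key), , drop = FALSE]
  }
  top$bonds <- bonds

  # ligand chemistry: sidecar wins; perception is the fallback
  lig_rows <- which(atoms$segment == "ligand")
  if (length(lig_rows) > 0L) {
    lig <- if (!is.null(ligand_template)) {
      apply_ligand_sidecar(atoms, bonds, lig_rows, ligand_template)
    } else {
      perceive_ligand(atoms, bonds, lig_rows)
    }
    donors_heavy <- c(donors_heavy, lig$donors$heavy)
    donors_h <- c(donors_h, lig$donors$hydrogen)
    acceptors <- c(acceptors, lig$acceptors)
    rings <- c(rings, lig$rings)
    charged <- c(charged, lig$charged)
    missing_h <- c(missing_h, lig$missing_h)
    if (length(lig$bonds) > 0L) {
      top$bonds <- rbind(top$bonds, do.call(rbind, lig$bonds))
      key <- paste(pmin(top$bonds[, 1], top$bonds[, 2]), pmax(top$bonds[, 1], top$bonds[, 2]))
      top$bonds <- top$bonds[!duplicated(key), , drop = FALSE]
    }
  }

  top$donors <- tibble(heavy = as.integer(donors_heavy), hydrogen = as.integer(donors_h))
  top$acceptors <- sort(unique(as.integer(acceptors)))
  top$rings <- rings
  top$charged_groups <- charged
  top$missing_hydrogens <- sort(unique(as.integer(missing_h)))
  top$hydrophobic <- derive_hydrophobic(top$atoms, top$bonds)
  top
}

# Nonpolar carbon: element C with no bonded N or O.
derive_hydrophobic <- function(atoms, bonds) {
  n <- nrow(atoms)
  polar_neighbor <- rep(FALSE, n)
  if (nrow(bonds) > 0L) {
    el <- atoms$element
    pol1 <- el[bonds[, 2]] %in% c("N", "O")
    pol2 <- el[bonds[, 1]] %in% c("N", "O")
    polar_neighbor[bonds[pol1, 1]] <- TRUE
    polar_neighbor[bonds[pol2, 2]] <- TRUE
  }
  which(atoms$element == "C" & !polar_neighbor)
}

apply_ligand_sidecar <- function(atoms, bonds, lig_rows, sidecar) {
  sc <- sidecar$ligand %||% sidecar
  if (!is.null(sc$resname)) {
    lig_rows <- lig_rows[atoms$resname[lig_rows] == sc$resname]
  }
  find_named <- function(nm) {
    hit <- lig_rows[atoms$name[lig_rows] == nm]
    if (length(hit) != 1L) {
      stop_bindmode(sprintf("ligand sidecar names atom '%s' not found uniquely in the topology", nm),
                    "bindmode_annotation_error")
    }
    hit
  }
  donors_heavy <- integer(); donors_h <- integer(); missing_h <- integer()
  for (d in sc$donors %||% list()) {
    heavy <- find_named(d$heavy)
    hs <- vapply(d$hydrogens %||% character(), find_named, integer(1))
    if (length(hs) == 0L) missing_h <- c(missing_h, heavy)
    donors_heavy <- c(donors_heavy, rep(heavy, length(hs)))
    donors_h <- c(donors_h, hs)
  }
  rings <- lapply(sc$rings %||% list(), function(r) vapply(unlist(r), find_named, integer(1)))
  charged <- lapply(sc$charged %||% list(), function(g) {
    list(atoms = vapply(unlist(g$atoms), find_named, integer(1)), sign = as.integer(g$sign))
  })
  extra_bonds <- lapply(sc$bonds %||% list(), function(b) {
    c(find_named(b[[1]]), find_named(b[[2]]))
  })
  list(donors = tibble(heavy = donors_heavy, hydrogen = donors_h),
       acceptors = vapply(sc$acceptors %||% character(), find_named, integer(1)),
       rings = rings, charged = charged, missing_h = missing_h, bonds = extra_bonds)
}

# Rule-based fallback when no sidecar is given: polar heavy atoms with a bonded
# hydrogen are donors; O always accepts, N accepts when its heavy-atom degree
# is at most 2; rings of size 5-6 made of C/N are taken as aromatic. Formal
# charges are not perceived (a sidecar is required for charged groups).
perceive_ligand <- function(atoms, bonds, lig_rows) {
  el <- atoms$element
  adj <- vector("list", nrow(atoms))
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  donors_heavy <- integer(); donors_h <- integer(); acceptors <- integer()
  for (i in lig_rows) {
    if (!el[i] %in% c("N", "O")) next
    hs <- adj[[i]][el[adj[[i]]] == "H"]
    heavy_deg <- sum(el[adj[[i]]] != "H")
    donors_heavy <- c(donors_heavy, rep(i, length(hs)))
    donors_h <- c(donors_h, hs)
    if (el[i] == "O" || heavy_deg <= 2L) acceptors <- c(acceptors, i)
  }
  rings <- perceive_rings(lig_rows, adj, el)
  list(donors = tibble(heavy = donors_heavy, hydrogen = donors_h),
       acceptors = acceptors, rings = rings, charged = list(),
       missing_h = integer(), bonds = list())
}

# Smallest cycle through each bond (BFS), kept when 5-6 atoms, all C/N.
perceive_rings <- function(lig_rows, adj, el) {
  in_lig <- rep(FALSE, length(adj)); in_lig[lig_rows] <- TRUE
  rings <- list(); seen <- character()
  for (a in lig_rows) {
    for (b in adj[[a]]) {
      if (b <= a || !in_lig[b]) next
      # BFS from a to b avoiding the direct edge
      prev <- rep(NA_integer_, length(adj))
      prev[a] <- a
      queue <- a
      while (length(queue) > 0L) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (!in_lig[w] || el[w] == "H") next
          if (v == a && w == b) next
          if (is.na(prev[w])) {
            prev[w] <- v
            queue <- c(queue, w)
          }
        }
      }
      if (is.na(prev[b])) next
      path <- b
      while (path[1] != a) path <- c(prev[path[1]], path)
      if (length(path) %in% 5:6 && all(el[path] %in% c("C", "N"))) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <- c(seen, key)
          rings[[length(rings) + 1L]] <- path
        }
      }
    }
  }
  rings
}

#' @export
print.bindmode_topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<bindmode_topology> %d atoms, %d bonds\n", nrow(a), nrow(x$bonds)))
  cat(sprintf("  protein: %d atoms (%d residues) | ligand: %d | waters: %d molecules | other: %d\n",
              sum(a$segment == "protein"),
              nrow(distinct(a[a$segment == "protein", c("chain", "resno")])),
              sum(a$segment == "ligand"),
              length(unique(a$molid[a$is_water])),
              sum(a$segment == "other")))
  cat(sprintf("  donors: %d H | acceptors: %d | rings: %d | charged groups: %d | nonpolar C: %d\n",
              nrow(x$donors), length(x$acceptors), length(x$rings),
              length(x$charged_groups), length(x$hydrophobic)))
  invisible(x)
}
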