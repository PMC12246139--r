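#' Read a topology from a PDB file
#'
#' Reads atoms (first model), CONECT connectivity and, when present, the
#' CRYST1 box from a PDB file, then annotates chemistry: standard residues and
#' waters from the built-in template table, the ligand from the YAML sidecar
#' (preferred) or rule-based perception of the bond graph.
#'
#' @param path Path to a PDB file (CONECT records honored).
#' @param ligand_template Optional path to a ligand sidecar YAML file, or an
#'   already-parsed annotation list (see [read_ligand_sidecar()]).
#' @return A [topology()] object; reference coordinates are kept in `$xyz`.
#' @export
read_topology <- function(path, ligand_template = NULL) {
  if (!file.exists(path)) {
    stop_bindmode(sprintf("cannot read topology file '%s'", path), "bindmode_format_error")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop_bindmode(sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)),
                                      "bindmode_format_error"))
  at <- pdb$atom
  element <- trimws(at$elesy %||% "")
  element[is.na(element)] <- ""
  guess <- guess_element(at$elety)
  element <- ifelse(element == "", guess, toupper(element))
  atoms <- tibble(
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain)
  )
  bonds <- parse_conect(path, serials = as.integer(at$eleno))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  if (is.character(ligand_template)) {
    ligand_template <- read_ligand_sidecar(ligand_template)
  }
  topology(atoms, bonds = bonds, xyz = xyz, ligand_template = ligand_template)
}

guess_element <- function(name) {
  name <- toupper(trimws(name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")
  stripped <- gsub("[0-9']", "", name)
  ifelse(substr(stripped, 1, 2) %in% two, substr(stripped, 1, 2), substr(stripped, 1, 1))
}

parse_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L) return(matrix(integer(), ncol = 2L))
  out <- list()
  for (ln in lines) {
    fields <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]
    ids <- suppressWarnings(as.integer(fields))
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2L) next
    a <- match(ids[1], serials)
    for (b in match(ids[-1], serials)) {
      if (!is.na(a) && !is.na(b)) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0L) return(matrix(integer(), ncol = 2L))
  m <- do.call(rbind, out)
  key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[!duplicated(key), , drop = FALSE]
}

#' Read a ligand annotation sidecar
#'
#' The sidecar is a YAML file declaring ligand chemistry by atom name:
#' `donors` (list of `heavy` + `hydrogens`), `acceptors`, `rings` (ordered atom
#' name lists), `charged` (list of `atoms` + `sign`), and optional `bonds`.
#' Explicit declaration is the source of truth for ligand chemistry; bond-order
#' perception is only a fallback.
#'
#' @param path Path to a YAML file.
#' @return A named list suitable for the `ligand_template` argument of
#'   [read_topology()] and [topology()].
#' @export
read_ligand_sidecar <- function(path) {
  if (!file.exists(path)) {
    stop_bindmode(sprintf("cannot read ligand sidecar '%s'", path), "bindmode_format_error")
  }
  yaml::read_yaml(path)
}

# ---- trajectory container ----------------------------------------------------

#' Coordinate trajectory
#'
#' A `bindmode_trajectory` stores per-frame coordinates (Angstrom), frame
#' timestamps (ns) and an optional periodic box.
#'
#' @param coords Numeric array of dimension `n_atoms x 3 x n_frames`.
#' @param times Numeric vector of non-decreasing frame timestamps in ns.
#' @param box Optional 3x3 matrix of box vectors (rows), constant over frames.
#' @return An object of class `bindmode_trajectory`.
#' @export
trajectory <- function(coords, times, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (length(times) != dim(coords)[3]) {
    stop_bindmode("length of times does not match frame count", "bindmode_format_error")
  }
  if (any(diff(times) < 0)) {
    stop_bindmode("frame timestamps must be non-decreasing", "bindmode_format_error")
  }
  if (any(times < 0)) {
    stop_bindmode("frame timestamps must be non-negative", "bindmode_format_error")
  }
  if (!is.null(box)) check_box(box)
  structure(list(coords = coords, times = as.numeric(times), box = box),
            class = "bindmode_trajectory")
}

check_box <- function(box) {
  if (!is.matrix(box) || any(dim(box) != c(3L, 3L)) || abs(det(box)) < 1e-8) {
    stop_bindmode("periodic box vectors must form a non-degenerate 3x3 matrix",
                  "bindmode_geometry_error")
  }
  invisible(box)
}

#' @export
print.bindmode_trajectory <- function(x, ...) {
  cat(sprintf("<bindmode_trajectory> %d atoms, %d frames, %.6g-%.6g ns%s\n",
              dim(x$coords)[1], dim(x$coords)[3],
              x$times[1], x$times[length(x$times)],
              if (is.null(x$box)) ", no box" else ", periodic box"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj A [trajectory()] object.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i]

#' Read a coordinate trajectory
#'
#' Accepts multi-model PDB and DCD files. Frames are strided by time, not by
#' index: a frame is kept when its timestamp is a multiple of `stride_ns`
#' (relative to the first frame). Neither format stores timestamps explicitly,
#' so `frame_spacing_ns` declares the sampling interval of the file.
#'
#' @param topology A [topology()] object (atom counts are cross-checked).
#' @param path Path to a multi-model PDB (`.pdb`) or DCD (`.dcd`) file.
#' @param stride_ns Analysis stride in ns (default 1).
#' @param frame_spacing_ns Time between stored frames in ns (default 1).
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(topology, path, stride_ns = 1, frame_spacing_ns = 1) {
  stopifnot(stride_ns > 0, frame_spacing_ns > 0)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc") {
    stop_bindmode("XTC trajectories are not supported; convert to DCD or multi-model PDB",
                  "bindmode_format_error")
  }
  if (!file.exists(path)) {
    stop_bindmode(sprintf("cannot read trajectory file '%s'", path), "bindmode_format_error")
  }
  n_top <- nrow(topology$atoms)
  box <- NULL
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    box <- parse_cryst1(path)
  }
  n_at <- ncol(xyz) / 3L
  if (n_at != n_top) {
    stop_bindmode(sprintf("trajectory has %d atoms but topology has %d", n_at, n_top),
                  "bindmode_topology_error")
  }
  nf <- nrow(xyz)
  times <- (seq_len(nf) - 1L) * frame_spacing_ns
  keep <- which(abs((times - times[1]) / stride_ns - round((times - times[1]) / stride_ns)) < 1e-9)
  coords <- array(NA_real_, dim = c(n_at, 3L, length(keep)))
  for (k in seq_along(keep)) {
    coords[, , k] <- matrix(xyz[keep[k], ], ncol = 3L, byrow = TRUE)
  }
  trajectory(coords, times[keep], box = box)
}

parse_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0L) return(NULL)
  f <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24), substr(ln[1], 25, 33),
                    substr(ln[1], 34, 40), substr(ln[1], 41, 47), substr(ln[1], 48, 54)))
  if (anyNA(f)) return(NULL)
  box_from_cell(f[1], f[2], f[3], f[4], f[5], f[6])
}

# Cell parameters (lengths, angles in degrees) -> row-vector box matrix.
box_from_cell <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cz <- sqrt(max(0, 1 - cb^2 - ((ca - cb * cg) / sg)^2))
  v3 <- c(c * cb, c * (ca - cb * cg) / sg, c * cz)
  rbind(v1, v2, v3)
}

# ---- writers -----------------------------------------------------------------

#' Write a trajectory (or single frame) as a multi-model PDB
#'
#' Emits MODEL/ENDMDL blocks, a CRYST1 record when a box is present, and
#' CONECT records for all topology bonds.
#'
#' @param traj A [trajectory()] object, or a plain `n_atoms x 3` matrix for a
#'   single frame.
#' @param topology The matching [topology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, topology, path) {
  if (is.matrix(traj)) {
    traj <- trajectory(array(traj, dim = c(nrow(traj), 3L, 1L)), times = 0)
  }
  atoms <- topology$atoms
  n <- nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    b <- traj$box
    cell <- cell_from_box(b)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]), con)
  }
  hetatm <- atoms$segment %in% c("ligand", "water", "other")
  rectype <- ifelse(hetatm, "HETATM", "ATOM  ")
  name4 <- vapply(atoms$name, function(nm) {
    if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, character(1))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rectype, seq_len(n) %% 100000L, name4, substr(atoms$resname, 1, 3),
                       atoms$chain, atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3],
                       1, 0, atoms$element), con)
    writeLines("ENDMDL", con)
  }
  if (nrow(topology$bonds) > 0L) {
    writeLines(sprintf("CONECT%5d%5d", topology$bonds[, 1], topology$bonds[, 2]), con)
  }
  writeLines("END", con)
  invisible(path)
}

cell_from_box <- function(box) {
  a <- vnorm(box[1, ]); b <- vnorm(box[2, ]); cc <- vnorm(box[3, ])
  alpha <- acos(sum(box[2, ] * box[3, ]) / (b * cc)) * 180 / pi
  beta <- acos(sum(box[1, ] * box[3, ]) / (a * cc)) * 180 / pi
  gamma <- acos(sum(box[1, ] * box[2, ]) / (a * b)) * 180 / pi
  c(a, b, cc, alpha, beta, gamma)
}

#' Write a trajectory in DCD format
#'
#' Writes a CHARMM-style binary DCD (no unit cell record), readable by
#' standard trajectory tools.
#'
#' @inheritParams write_trajectory_pdb
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, topology, path) {
  n_at <- dim(traj$coords)[1]
  nf <- n_frames(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  # header block
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(1, con, size = 4)  # DELTA as float32
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  # title block
  title <- sprintf("%-80s", "Synthetic trajectory written by bindmode")
  writeBin(as.integer(4 + 80), con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(as.integer(4 + 80), con, size = 4)
  # natom block
  writeBin(4L, con, size = 4)
  writeBin(as.integer(n_at), con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- as.integer(4 * n_at)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (d in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(xyz[, d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}

#' Export a time series as CSV
#'
#' @param trace A tibble with columns `time_ns` and `value` (as returned by
#'   [rmsd_trace()] and [min_distance_trace()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
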