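# Conserved-water-site occupancy, exchange statistics and occupancy
# conditioned on protein conformational state.

#' Define a conserved water site
#'
#' The site is a sphere of `radius` Angstrom around the centroid of the anchor
#' atoms, recomputed every frame (the site moves with the protein). Anchors
#' are usually the side chains of pocket residues; [sidechain_or_ca()] builds
#' the conventional anchor selection (all non-backbone heavy atoms of a
#' residue, or its C-alpha when the residue has no side-chain heavy atoms,
#' as for glycine).
#'
#' @param anchors List of selections (expressions, [select_atoms()] results or
#'   index vectors), one per anchor residue.
#' @param radius Site radius in Angstrom (default 3).
#' @return An object of class `bindmode_water_site`.
#' @export
water_site <- function(anchors, radius = 3) {
  if (!is.list(anchors) || length(anchors) == 0L) {
    stop_bindmode("anchors must be a non-empty list of selections", "bindmode_selection_error")
  }
  if (!is_scalar_number(radius) || radius <= 0) {
    stop_bindmode("site radius must be positive", "bindmode_config_error")
  }
  structure(list(anchors = anchors, radius = radius), class = "bindmode_water_site")
}

#' Anchor selection: side-chain heavy atoms, or C-alpha as fallback
#'
#' Returns the indices of all non-backbone heavy atoms of a residue; when the
#' residue has none (glycine), its C-alpha is returned instead, keeping the
#' site construction total for any residue.
#'
#' @param topology A [topology()] object.
#' @param resno Residue number.
#' @param chain Optional chain id.
#' @return Integer atom indices.
#' @export
sidechain_or_ca <- function(topology, resno, chain = NULL) {
  atoms <- topology$atoms
  rows <- which(atoms$resno == resno & atoms$segment == "protein" &
                  (is.null(chain) | atoms$chain == (chain %||% "")))
  if (length(rows) == 0L) {
    stop_bindmode(sprintf("residue %d not found in topology", resno), "bindmode_selection_error")
  }
  backbone <- c("N", "CA", "C", "O", "H", "HN", "HA", "HA2", "HA3")
  side <- rows[!(atoms$name[rows] %in% backbone) & atoms$element[rows] != "H"]
  if (length(side) > 0L) return(side)
  rows[atoms$name[rows] == "CA"]
}

#' Frame-wise centroid of a water site
#'
#' Unweighted mean position of all anchor atoms in this frame.
#'
#' @param xyz `n_atoms x 3` frame coordinates.
#' @param site A [water_site()] (anchors must already be index vectors) or a
#'   plain integer vector of anchor atom indices.
#' @return Numeric length-3 point.
#' @export
site_centroid <- function(xyz, site) {
  idx <- if (inherits(site, "bindmode_water_site")) unlist(site$anchors) else site
  idx <- as.integer(idx)
  if (length(idx) == 0L) {
    stop_bindmode("empty anchor selection", "bindmode_selection_error")
  }
  colMeans(xyz[idx, , drop = FALSE])
}

#' Water-site occupancy trace
#'
#' Per frame, the site is occupied when any water oxygen lies within the site
#' radius (PBC-aware) of the frame's anchor centroid; the molecule ids of all
#' such waters are recorded. Hydrogens are ignored (occupancy is judged by the
#' oxygen position).
#'
#' @param traj A [trajectory()] object.
#' @param topology The matching [topology()].
#' @param site A [water_site()]; anchor expressions are resolved against
#'   `topology`.
#' @param replica Integer replica id recorded on every row (default 1).
#' @return Tibble with columns `replica`, `frame`, `time_ns`, `occupied`,
#'   `water_ids` (list column of molecule ids); class `bindmode_occupancy`.
#' @export
occupancy_trace <- function(traj, topology, site, replica = 1L) {
  stopifnot(inherits(site, "bindmode_water_site"))
  anchors <- lapply(site$anchors, resolve_selection, topology = topology)
  if (any(lengths(anchors) == 0L)) {
    stop_bindmode("empty anchor selection in water site", "bindmode_selection_error")
  }
  idx <- unlist(anchors)
  wo <- which(topology$atoms$is_water & topology$atoms$element == "O")
  if (length(wo) == 0L) {
    stop_bindmode("topology contains no annotated waters", "bindmode_annotation_error")
  }
  mol <- topology$atoms$molid
  nf <- n_frames(traj)
  occupied <- logical(nf)
  ids <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    d <- pbc_distance(matrix(ctr, length(wo), 3L, byrow = TRUE),
                      xyz[wo, , drop = FALSE], traj$box)
    inside <- wo[d <= site$radius]
    occupied[f] <- length(inside) > 0L
    ids[[f]] <- mol[inside]
  }
  out <- tibble(replica = as.integer(replica), frame = seq_len(nf),
                time_ns = traj$times, occupied = occupied, water_ids = ids)
  class(out) <- c("bindmode_occupancy", class(out))
  attr(out, "radius") <- site$radius
  out
}

#' Unique waters per replica and their median
#'
#' Counts, per replica, the distinct water molecules that ever occupy the
#' site, and the median across replicas (mean of the middle two for an even
#' replica count). This is an exchange-rate proxy; evaluated at the analysis
#' stride, sub-stride exchange events are not counted.
#'
#' @param occupancy Occupancy tibble from [occupancy_trace()] (replicas pooled
#'   with [dplyr::bind_rows()]).
#' @return List with `per_replica` (tibble `replica`, `n_unique`) and `median`.
#' @export
unique_waters <- function(occupancy) {
  if (nrow(occupancy) == 0L) {
    stop_bindmode("empty occupancy trace", "bindmode_statistics_error")
  }
  per <- occupancy %>%
    group_by(.data$replica) %>%
    summarise(n_unique = dplyr::n_distinct(unlist(.data$water_ids)), .groups = "drop")
  list(per_replica = per, median = median(per$n_unique))
}

#' Occupancy conditioned on conformational state
#'
#' For each state label, the fraction of that label's frames in which the
#' site is occupied. Traces must be frame-aligned (same replicas and frames).
#'
#' @param occupancy Occupancy tibble from [occupancy_trace()].
#' @param states State tibble from [classify_states()] with columns `replica`,
#'   `frame`, `state`.
#' @return Tibble with columns `state`, `fraction`, `n_frames`.
#' @export
conditional_occupancy <- function(occupancy, states) {
  if (nrow(occupancy) != nrow(states)) {
    stop_bindmode(sprintf("occupancy (%d frames) and states (%d frames) are not aligned",
                          nrow(occupancy), nrow(states)), "bindmode_alignment_error")
  }
  joined <- dplyr::inner_join(
    occupancy[, c("replica", "frame", "occupied")],
    states[, c("replica", "frame", "state")],
    by = c("replica", "frame"))
  if (nrow(joined) != nrow(occupancy)) {
    stop_bindmode("occupancy and state traces do not cover the same frames",
                  "bindmode_alignment_error")
  }
  joined %>%
    group_by(.data$state) %>%
    summarise(fraction = mean(.data$occupied), n_frames = n(), .groups = "drop")
}

#' Write an occupancy trace as CSV
#' @param occupancy An [occupancy_trace()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  df <- as.data.frame(occupancy[, c("replica", "frame", "time_ns", "occupied")])
  df$water_ids <- vapply(occupancy$water_ids, paste, character(1), collapse = ";")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
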