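# Distance-angle descriptors for side-chain flip states, two-state
# classification and masked density grids.

#' Distance-angle flip descriptors
#'
#' Per frame: the distance from the donor residue's side-chain oxygen (OG1
#' for threonine) to the reference residue's backbone amide hydrogen, and the
#' interior angle side-chain-oxygen - C-beta - amide-hydrogen (vertex at
#' C-beta). These two coordinates separate the "native" orientation of a
#' threonine-type side chain (oxygen toward the reference amide) from the
#' "flipped" one.
#'
#' @param traj A [trajectory()] object.
#' @param topology The matching [topology()].
#' @param donor_resno Residue number of the side chain under study
#'   (default 58).
#' @param reference_resno Residue number providing the backbone amide H
#'   (default 10).
#' @param replica Integer replica id recorded on every row (default 1).
#' @return Tibble with columns `replica`, `frame`, `time_ns`, `distance`
#'   (Angstrom), `angle` (degrees); class `bindmode_state_trace`.
#' @export
flip_descriptors <- function(traj, topology, donor_resno = 58, reference_resno = 10,
                             replica = 1L) {
  atoms <- topology$atoms
  need <- function(resno, name) {
    hit <- which(atoms$resno == resno & atoms$segment == "protein" & atoms$name %in% name)
    if (length(hit) == 0L) {
      stop_bindmode(sprintf("atom %s of residue %d not found", name[1], resno),
                    "bindmode_annotation_error")
    }
    hit[1]
  }
  og <- need(donor_resno, c("OG1", "OG"))
  cb <- need(donor_resno, "CB")
  hh <- need(reference_resno, c("H", "HN"))
  nf <- n_frames(traj)
  dist <- numeric(nf); ang <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    dist[f] <- pbc_distance(xyz[og, ], xyz[hh, ], traj$box)
    ang[f] <- vec_angle(xyz[og, ], xyz[cb, ], xyz[hh, ])
  }
  out <- tibble(replica = as.integer(replica), frame = seq_len(nf),
                time_ns = traj$times, distance = dist, angle = ang)
  class(out) <- c("bindmode_state_trace", class(out))
  out
}

#' Classify flip states from descriptors
#'
#' A frame is `"native"` iff its distance is at most `distance_max` and its
#' angle lies inside the closed `angle_window`; otherwise `"flipped"`. The
#' boundary is closed on the native side: a descriptor exactly on the boundary
#' is native. The partition is fully configurable; the defaults place the
#' native basin at short oxygen-amide distance with the side-chain oxygen
#' oriented toward the reference amide.
#'
#' @param trace Descriptor tibble from [flip_descriptors()].
#' @param distance_max Native distance bound in Angstrom (default 4).
#' @param angle_window Native angle window in degrees (default `c(60, 180)`).
#' @return The input tibble with a `state` column added.
#' @export
classify_states <- function(trace, distance_max = 4, angle_window = c(60, 180)) {
  stopifnot(is_scalar_number(distance_max), length(angle_window) == 2L)
  native <- trace$distance <= distance_max &
    trace$angle >= min(angle_window) & trace$angle <= max(angle_window)
  out <- mutate(trace, state = ifelse(native, "native", "flipped"))
  class(out) <- unique(c("bindmode_state_trace", class(out)))
  out
}

#' Masked 2-D density grid of the descriptor space
#'
#' Histograms the (distance, angle) descriptors into fractions of the total
#' frame count. Cells below `mask_threshold` are flagged masked and their
#' frames are returned as raw points (the conventional rendering draws masked
#' cells transparent with individual observations on top). Normalization is by
#' the total frame count, so masking does not distort the fractions.
#'
#' @param trace Descriptor tibble from [flip_descriptors()].
#' @param distance_bins,angle_bins Monotone increasing bin edge vectors.
#' @param mask_threshold Cell fraction below which a cell is masked
#'   (default 0.05).
#' @return An object of class `bindmode_density`: list with `grid` (tibble of
#'   cell edges, `fraction`, `masked`), `points` (frames in masked cells),
#'   `mask_threshold`.
#' @export
density_grid <- function(trace, distance_bins, angle_bins, mask_threshold = 0.05) {
  if (nrow(trace) == 0L) {
    stop_bindmode("density grid requires at least one frame", "bindmode_statistics_error")
  }
  if (any(diff(distance_bins) <= 0) || any(diff(angle_bins) <= 0)) {
    stop_bindmode("bin edges must be strictly increasing", "bindmode_config_error")
  }
  di <- cut(trace$distance, distance_bins, include.lowest = TRUE, labels = FALSE)
  ai <- cut(trace$angle, angle_bins, include.lowest = TRUE, labels = FALSE)
  n_total <- nrow(trace)
  grid <- tidyr::expand_grid(
    dbin = seq_len(length(distance_bins) - 1L),
    abin = seq_len(length(angle_bins) - 1L))
  counts <- tibble(dbin = di, abin = ai) %>%
    filter(!is.na(.data$dbin), !is.na(.data$abin)) %>%
    count(.data$dbin, .data$abin)
  grid <- grid %>%
    left_join(counts, by = c("dbin", "abin")) %>%
    mutate(
      fraction = ifelse(is.na(.data$n), 0, .data$n) / n_total,
      distance_lo = distance_bins[.data$dbin], distance_hi = distance_bins[.data$dbin + 1L],
      angle_lo = angle_bins[.data$abin], angle_hi = angle_bins[.data$abin + 1L],
      masked = .data$fraction < mask_threshold) %>%
    select(-"n")
  in_masked <- !is.na(di) & !is.na(ai) &
    grid$masked[match(paste(di, ai), paste(grid$dbin, grid$abin))]
  structure(list(grid = grid, points = trace[which(in_masked), ],
                 mask_threshold = mask_threshold,
                 n_frames = n_total),
            class = "bindmode_density")
}

#' @export
print.bindmode_density <- function(x, ...) {
  cat(sprintf("<bindmode_density> %d x %d cells, %d frames, %d masked cells (< %.3g)\n",
              length(unique(x$grid$dbin)), length(unique(x$grid$abin)),
              x$n_frames, sum(x$grid$masked), x$mask_threshold))
  invisible(x)
}

#' Write a density grid as JSON
#' @param density A [density_grid()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_json <- function(density, path) {
  jsonlite::write_json(list(
    mask_threshold = density$mask_threshold,
    n_frames = density$n_frames,
    grid = as.data.frame(density$grid),
    points = as.data.frame(density$points[, c("distance", "angle")])
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
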