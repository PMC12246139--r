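#' Geometric interaction criteria
#'
#' Thresholds used by the interaction detectors. The defaults follow the
#' analysis conventions of simulation-interaction fingerprinting: hydrogen
#' bonds require a hydrogen-acceptor distance of at most 2.5 Angstrom with a
#' donor angle (D-H...A) of at least 120 degrees and an acceptor angle
#' (H...A-X, maximized over the acceptor's bonded heavy atoms X) of at least
#' 90 degrees; water bridges use 2.8 Angstrom / 110 / 90 degrees on both legs;
#' pi-cation contacts use a 4.5 Angstrom centroid-centroid cutoff. The
#' distance criterion is interpreted as hydrogen-acceptor (a 2.5 Angstrom
#' donor-acceptor cutoff would reject nearly all real hydrogen bonds, whose
#' donor-acceptor separation is typically 2.8-3.2 Angstrom).
#'
#' pi-pi stacking distinguishes face-to-face (centroids within
#' `pipi_f2f_centroid_max`, interplanar angle at most
#' `pipi_f2f_plane_angle_max`) from edge-to-face (centroids within
#' `pipi_e2f_centroid_max`, interplanar angle inside
#' `pipi_e2f_plane_angle_window`). The interplanar angle between ring normals
#' is folded into \[0, 90\] degrees (ring normals have no preferred sign), so
#' the edge window `c(60, 120)` is equivalent to a folded angle of at least 60
#' degrees.
#'
#' @param hbond_distance H...A distance cutoff (Angstrom).
#' @param hbond_donor_angle_min,hbond_acceptor_angle_min H-bond angle minima
#'   (degrees).
#' @param wbridge_distance,wbridge_donor_angle_min,wbridge_acceptor_angle_min
#'   Water-bridge H-bond criteria for both legs of the bridge.
#' @param pication_distance Cation-centroid to ring-centroid cutoff (Angstrom).
#' @param pipi_f2f_centroid_max,pipi_e2f_centroid_max Ring centroid cutoffs
#'   (Angstrom).
#' @param pipi_f2f_plane_angle_max Maximum interplanar angle for face-to-face
#'   stacking (degrees).
#' @param pipi_e2f_plane_angle_window Interplanar angle window for edge-to-face
#'   stacking (degrees, length 2).
#' @param hydrophobic_distance Nonpolar carbon-carbon cutoff (Angstrom).
#' @param ionic_distance Closest-atom cutoff between oppositely charged groups
#'   (Angstrom).
#' @return A list of class `bindmode_criteria`.
#' @export
interaction_criteria <- function(hbond_distance = 2.5,
                                 hbond_donor_angle_min = 120,
                                 hbond_acceptor_angle_min = 90,
                                 wbridge_distance = 2.8,
                                 wbridge_donor_angle_min = 110,
                                 wbridge_acceptor_angle_min = 90,
                                 pication_distance = 4.5,
                                 pipi_f2f_centroid_max = 4.4,
                                 pipi_e2f_centroid_max = 5.5,
                                 pipi_f2f_plane_angle_max = 30,
                                 pipi_e2f_plane_angle_window = c(60, 120),
                                 hydrophobic_distance = 3.6,
                                 ionic_distance = 3.7) {
  crit <- list(
    hbond_distance = hbond_distance,
    hbond_donor_angle_min = hbond_donor_angle_min,
    hbond_acceptor_angle_min = hbond_acceptor_angle_min,
    wbridge_distance = wbridge_distance,
    wbridge_donor_angle_min = wbridge_donor_angle_min,
    wbridge_acceptor_angle_min = wbridge_acceptor_angle_min,
    pication_distance = pication_distance,
    pipi_f2f_centroid_max = pipi_f2f_centroid_max,
    pipi_e2f_centroid_max = pipi_e2f_centroid_max,
    pipi_f2f_plane_angle_max = pipi_f2f_plane_angle_max,
    pipi_e2f_plane_angle_window = pipi_e2f_plane_angle_window,
    hydrophobic_distance = hydrophobic_distance,
    ionic_distance = ionic_distance
  )
  dists <- crit[grepl("distance|centroid", names(crit))]
  if (any(unlist(dists) <= 0)) {
    stop_bindmode("all distance criteria must be positive", "bindmode_config_error")
  }
  angles <- unlist(crit[grepl("angle", names(crit))])
  if (any(angles <= 0 | angles > 180)) {
    stop_bindmode("all angle criteria must lie in (0, 180]", "bindmode_config_error")
  }
  structure(crit, class = "bindmode_criteria")
}
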