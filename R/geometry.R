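#' Minimum-image distance under periodic boundaries
#'
#' Computes the distance between points `a` and `b`. With a periodic box the
#' minimum-image convention is applied exactly, including for triclinic boxes:
#' the displacement is wrapped in fractional coordinates and then minimized
#' over the 27 neighboring image translations. Without a box the plain
#' Euclidean distance is returned.
#'
#' @param a,b Numeric length-3 points, or `n x 3` matrices of paired points.
#' @param box Optional 3x3 matrix whose rows are the box vectors (Angstrom).
#' @return Numeric vector of distances (Angstrom).
#' @export
pbc_distance <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- b - a
  if (is.null(box)) return(sqrt(rowSums(d^2)))
  check_box(box)
  frac <- d %*% solve(box)
  frac <- frac - round(frac)
  best <- rep(Inf, nrow(frac))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    img <- (frac + matrix(c(i, j, k), nrow(frac), 3L, byrow = TRUE)) %*% box
    best <- pmin(best, rowSums(img^2))
  }
  sqrt(best)
}

#' Interior angle at a vertex
#'
#' @param a,b,c Numeric length-3 points; the angle is measured at vertex `b`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) {
    stop_bindmode("angle is undefined for zero-length arms", "bindmode_geometry_error")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# Vectorized variant over rows; used by the interaction detectors.
vec_angle_rows <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  acos(pmax(-1, pmin(1, cosang))) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` by singular value
#' decomposition of the covariance matrix, with the reflection branch
#' excluded (determinant forced to +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices of paired points
#'   (`n >= 3`).
#' @return An object of class `bindmode_superposition`: list with `rotation`
#'   (3x3, det +1), `translation` (length 3), and `rmsd` (Angstrom). The fitted
#'   coordinates are `mobile %*% rotation + translation` (rows).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop_bindmode("mobile and reference must be n x 3 matrices of equal size",
                  "bindmode_geometry_error")
  }
  if (nrow(mobile) < 3L) {
    stop_bindmode("superposition requires at least 3 points", "bindmode_geometry_error")
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = as.numeric(rc - mc %*% R), rmsd = rmsd),
            class = "bindmode_superposition")
}

#' @export
print.bindmode_superposition <- function(x, ...) {
  cat(sprintf("<bindmode_superposition> rmsd = %.6g Angstrom\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(coords %*% sp$rotation, 2, sp$translation, `+`)
}

resolve_selection <- function(topology, sel) {
  if (inherits(sel, "bindmode_selection")) return(as.integer(sel))
  if (is.character(sel)) return(as.integer(select_atoms(topology, sel)))
  as.integer(sel)
}

#' RMSD time trace after superposition
#'
#' Per frame, the frame is superposed onto the reference over `fit_sel`, and
#' the RMSD is measured over `measure_sel` without re-fitting (the
#' "ligand RMSD after protein fit" convention). Set `refit = TRUE` to
#' additionally superpose on `measure_sel` before measuring.
#'
#' @param traj A [trajectory()] object.
#' @param topology The matching [topology()].
#' @param fit_sel,measure_sel Selections (expression strings,
#'   [select_atoms()] results, or index vectors).
#' @param reference `n_atoms x 3` reference coordinates; defaults to the first
#'   frame.
#' @param refit Superpose again on `measure_sel` before measuring
#'   (default `FALSE`).
#' @return Tibble with columns `time_ns`, `value` (Angstrom); class
#'   `bindmode_trace`.
#' @export
rmsd_trace <- function(traj, topology, fit_sel, measure_sel, reference = NULL,
                       refit = FALSE) {
  fit <- resolve_selection(topology, fit_sel)
  mea <- resolve_selection(topology, measure_sel)
  if (length(fit) == 0L || length(mea) == 0L) {
    stop_bindmode("empty selection in rmsd_trace", "bindmode_selection_error")
  }
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    sp <- superpose(xyz[fit, , drop = FALSE], reference[fit, , drop = FALSE])
    moved <- apply_superposition(xyz[mea, , drop = FALSE], sp)
    if (refit) {
      vals[f] <- superpose(moved, reference[mea, , drop = FALSE])$rmsd
    } else {
      vals[f] <- sqrt(mean(rowSums((moved - reference[mea, , drop = FALSE])^2)))
    }
  }
  new_trace(traj$times, vals, label = "RMSD", unit = "Angstrom")
}

new_trace <- function(times, values, label, unit) {
  out <- tibble(time_ns = times, value = values)
  class(out) <- c("bindmode_trace", class(out))
  attr(out, "label") <- label
  attr(out, "unit") <- unit
  out
}

#' Per-atom root-mean-square fluctuation
#'
#' Every frame is superposed over `fit_sel`; the reference is either the
#' iterated mean structure (two passes: fit to the first frame, average,
#' re-fit to the average; the default) or the first frame. RMSF is then the
#' root-mean-square deviation of each `measure_sel` atom about its mean
#' position.
#'
#' @inheritParams rmsd_trace
#' @param reference `"mean"` (two-pass iterated mean structure) or `"first"`.
#' @return Tibble with columns `atom` (index), `name`, `resname`, `resno`,
#'   `chain`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, topology, fit_sel, measure_sel, reference = c("mean", "first")) {
  reference <- match.arg(reference)
  fit <- resolve_selection(topology, fit_sel)
  mea <- resolve_selection(topology, measure_sel)
  if (length(fit) == 0L || length(mea) == 0L) {
    stop_bindmode("empty selection in rmsf", "bindmode_selection_error")
  }
  nf <- n_frames(traj)
  if (nf < 2L) {
    stop_bindmode("rmsf requires at least 2 frames", "bindmode_statistics_error")
  }
  ref_xyz <- frame_coords(traj, 1L)
  fitted <- fit_all_frames(traj, fit, mea, ref_xyz)
  if (reference == "mean") {
    mean1 <- list(fit = apply(fitted$fit, c(1, 2), mean),
                  mea = apply(fitted$mea, c(1, 2), mean))
    fitted <- fit_all_frames(traj, fit, mea, NULL, ref_fit = mean1$fit)
  }
  mean_pos <- apply(fitted$mea, c(1, 2), mean)
  dev2 <- sapply(seq_len(nf), function(f) rowSums((fitted$mea[, , f] - mean_pos)^2))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(mea))
  vals <- sqrt(rowMeans(dev2))
  atoms <- topology$atoms[mea, ]
  tibble(atom = mea, name = atoms$name, resname = atoms$resname,
         resno = atoms$resno, chain = atoms$chain, rmsf = vals)
}

fit_all_frames <- function(traj, fit, mea, ref_xyz, ref_fit = NULL) {
  if (is.null(ref_fit)) ref_fit <- ref_xyz[fit, , drop = FALSE]
  nf <- n_frames(traj)
  out_fit <- array(NA_real_, c(length(fit), 3L, nf))
  out_mea <- array(NA_real_, c(length(mea), 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    sp <- superpose(xyz[fit, , drop = FALSE], ref_fit)
    out_fit[, , f] <- apply_superposition(xyz[fit, , drop = FALSE], sp)
    out_mea[, , f] <- apply_superposition(xyz[mea, , drop = FALSE], sp)
  }
  list(fit = out_fit, mea = out_mea)
}

#' Minimum-distance time trace between two selections
#'
#' Per frame, the minimum over all pairs of the (PBC-aware) distance between
#' atoms of `sel_a` and atoms of `sel_b`.
#'
#' @inheritParams rmsd_trace
#' @param sel_a,sel_b Selections.
#' @return Tibble with columns `time_ns`, `value` (Angstrom); class
#'   `bindmode_trace`.
#' @export
min_distance_trace <- function(traj, topology, sel_a, sel_b) {
  ia <- resolve_selection(topology, sel_a)
  ib <- resolve_selection(topology, sel_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop_bindmode("empty selection in min_distance_trace", "bindmode_selection_error")
  }
  nf <- n_frames(traj)
  vals <- numeric(nf)
  pairs_a <- rep(ia, times = length(ib))
  pairs_b <- rep(ib, each = length(ia))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    vals[f] <- min(pbc_distance(xyz[pairs_a, , drop = FALSE],
                                xyz[pairs_b, , drop = FALSE], traj$box))
  }
  new_trace(traj$times, vals, label = "minimum distance", unit = "Angstrom")
}
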