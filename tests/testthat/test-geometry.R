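# Geometric primitives: minimum-image distances, angles, Kabsch
# superposition, RMSD/RMSF traces, minimum-distance traces.

test_that("pbc_distance matches the 27-image enumeration oracle", {
  expect_equal(pbc_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pbc_distance(c(0, 0, 0), c(9, 0, 0), box = diag(3) * 10), 1)
  set.seed(21)
  for (rep in 1:5) {
    # random mildly triclinic box
    box <- diag(runif(3, 8, 12))
    box[2, 1] <- runif(1, -2, 2); box[3, 1] <- runif(1, -2, 2)
    box[3, 2] <- runif(1, -2, 2)
    frac_a <- matrix(runif(200 * 3), ncol = 3)
    frac_b <- matrix(runif(200 * 3), ncol = 3)
    a <- frac_a %*% box; b <- frac_b %*% box
    got <- pbc_distance(a, b, box)
    # oracle: brute force over all 27 image translations of the displacement
    oracle <- sapply(seq_len(nrow(a)), function(i) {
      d <- b[i, ] - a[i, ]
      best <- Inf
      for (ii in -1:1) for (jj in -1:1) for (kk in -1:1) {
        img <- d + ii * box[1, ] + jj * box[2, ] + kk * box[3, ]
        best <- min(best, sqrt(sum(img^2)))
      }
      best
    })
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  expect_error(pbc_distance(c(0, 0, 0), c(1, 1, 1), box = matrix(1, 3, 3)),
               class = "bindmode_geometry_error")
})

test_that("pbc_distance is symmetric and satisfies the triangle inequality", {
  set.seed(22)
  a <- matrix(rnorm(50 * 3), ncol = 3)
  b <- matrix(rnorm(50 * 3), ncol = 3)
  c <- matrix(rnorm(50 * 3), ncol = 3)
  expect_equal(pbc_distance(a, b), pbc_distance(b, a))
  expect_true(all(pbc_distance(a, c) <= pbc_distance(a, b) + pbc_distance(b, c) + 1e-12))
})

test_that("vec_angle matches the arccos formula and handles degenerate arms", {
  expect_equal(vec_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(23)
  for (i in 1:200) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    u <- a - b; v <- c - b
    expected <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_equal(vec_angle(a, b, c), expected, tolerance = 1e-6)
  }
  expect_error(vec_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "bindmode_geometry_error")
})

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

test_that("superpose recovers exact rigid transforms and excludes reflections", {
  set.seed(24)
  X <- matrix(rnorm(30), ncol = 3)
  sp0 <- superpose(X, X)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)
  R <- rotation_matrix(0.4, -1.1, 2.0)
  Y <- X %*% R + matrix(c(1, -2, 3), nrow(X), 3, byrow = TRUE)
  sp <- superpose(X, Y)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(sp$rotation, R, tolerance = 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  # near-planar mirrored set must still come back with a proper rotation
  Z <- X; Z[, 3] <- 0
  spm <- superpose(Z, -Z)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-8)
  expect_error(superpose(X[1:2, ], Y[1:2, ]), class = "bindmode_geometry_error")
})

test_that("superpose agrees with an independent least-squares fit (bio3d)", {
  set.seed(25)
  for (i in 1:10) {
    X <- matrix(rnorm(45), ncol = 3)
    Y <- matrix(rnorm(45), ncol = 3)
    mine <- superpose(X, Y)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(Y)), as.vector(t(X)), fit = TRUE)
    expect_equal(mine, theirs, tolerance = 1e-3)
  }
})

# small helper trajectory around the micro topology
traj_from_frames <- function(frames, times = seq_along(frames) - 1) {
  coords <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(coords, times)
}

test_that("rmsd_trace: zero for identical frames, fit removes rigid motion,
           and a constructed ligand displacement is returned exactly", {
  top <- micro_topology()
  ref <- base_coords(top)
  prot <- select_atoms(top, "protein")
  lig <- select_atoms(top, "ligand")
  set.seed(26)
  ref[prot, ] <- matrix(rnorm(length(prot) * 3, sd = 3), ncol = 3)
  ref[lig, ] <- matrix(rnorm(length(lig) * 3, sd = 2), ncol = 3)

  traj0 <- traj_from_frames(list(ref, ref, ref))
  tr0 <- rmsd_trace(traj0, top, prot, lig, reference = ref)
  expect_equal(tr0$value, c(0, 0, 0), tolerance = 1e-10)

  R <- rotation_matrix(0.3, 0.5, -0.2)
  moved <- ref %*% R + matrix(c(4, 5, 6), nrow(ref), 3, byrow = TRUE)
  tr1 <- rmsd_trace(traj_from_frames(list(moved)), top, prot, prot, reference = ref)
  expect_lt(tr1$value, 1e-6)

  d <- 2.75
  displaced <- ref
  displaced[lig, 1] <- displaced[lig, 1] + d
  tr2 <- rmsd_trace(traj_from_frames(list(displaced)), top, prot, lig, reference = ref)
  expect_equal(tr2$value, d, tolerance = 1e-9)
})

test_that("rmsf: zero for static input, closed form for a two-state oscillator,
           and equal to a scripted two-pass oracle on a random walk", {
  top <- make_chain_topology(3)          # 15 atoms
  n <- nrow(top$atoms)
  set.seed(27)
  ref <- matrix(rnorm(n * 3, sd = 4), ncol = 3)
  anchors <- 1:12
  probe <- n

  static <- traj_from_frames(list(ref, ref, ref, ref))
  expect_true(all(rmsf(static, top, anchors, seq_len(n))$rmsf < 1e-12))
  expect_error(rmsf(traj_from_frames(list(ref)), top, anchors, probe),
               class = "bindmode_statistics_error")

  a <- 0.8
  up <- ref; up[probe, 1] <- ref[probe, 1] + a
  dn <- ref; dn[probe, 1] <- ref[probe, 1] - a
  osc <- traj_from_frames(list(up, dn, up, dn))
  got <- rmsf(osc, top, anchors, probe)$rmsf
  expect_equal(got, a, tolerance = 1e-9)

  # random-walk fixture vs direct two-pass computation using bio3d fits
  frames <- list(ref)
  for (f in 2:6) frames[[f]] <- frames[[f - 1]] + matrix(rnorm(n * 3, sd = 0.3), ncol = 3)
  walk <- traj_from_frames(frames)
  got <- rmsf(walk, top, anchors, seq_len(n))$rmsf
  fit_to <- function(xyz, ref_fit) {
    sp <- superpose(xyz[anchors, ], ref_fit)
    sweep(xyz %*% sp$rotation, 2, sp$translation, `+`)
  }
  pass1 <- lapply(frames, fit_to, ref_fit = ref[anchors, ])
  mean1 <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- lapply(frames, fit_to, ref_fit = mean1[anchors, ])
  mean2 <- Reduce(`+`, pass2) / length(pass2)
  oracle <- sqrt(Reduce(`+`, lapply(pass2, function(x) rowSums((x - mean2)^2))) / length(pass2))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("min_distance_trace equals the all-pairs brute force", {
  top <- micro_topology()
  set.seed(28)
  frames <- lapply(1:5, function(f) matrix(runif(nrow(top$atoms) * 3, 0, 15), ncol = 3))
  traj <- traj_from_frames(frames)
  sa <- select_atoms(top, "protein")
  sb <- select_atoms(top, "ligand or water")
  got <- min_distance_trace(traj, top, sa, sb)$value
  oracle <- sapply(frames, function(xyz) {
    best <- Inf
    for (i in sa) for (j in sb) best <- min(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    best
  })
  expect_equal(got, oracle, tolerance = 1e-12)
  # trivial cases
  two <- base_coords(top)
  two[sa[1], ] <- c(0, 0, 0); two[sb[1], ] <- c(4, 0, 0)
  tr <- min_distance_trace(traj_from_frames(list(two)), top, sa[1], sb[1])
  expect_equal(tr$value, 4)
  expect_error(min_distance_trace(traj, top, integer(), sb),
               class = "bindmode_selection_error")
})

test_that("rmsd is invariant under rigid transforms of the mobile set", {
  set.seed(29)
  X <- matrix(rnorm(36), ncol = 3)
  Y <- matrix(rnorm(36), ncol = 3)
  base <- superpose(X, Y)$rmsd
  for (i in 1:5) {
    R <- rotation_matrix(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    Xr <- X %*% R + matrix(rnorm(3, sd = 10), nrow(X), 3, byrow = TRUE)
    expect_equal(superpose(Xr, Y)$rmsd, base, tolerance = 1e-8)
  }
})
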