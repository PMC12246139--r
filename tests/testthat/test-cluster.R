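# Pairwise RMSD similarity, affinity propagation and representative-frame
# selection.

test_that("pairwise similarities are zero for identical frames and -d^2 for a
           constructed displacement", {
  top <- micro_topology()
  ref <- base_coords(top)
  prot <- select_atoms(top, "protein"); lig <- select_atoms(top, "ligand")
  set.seed(62)
  ref[prot, ] <- matrix(rnorm(length(prot) * 3, sd = 3), ncol = 3)
  coords <- array(rep(ref, 4), dim = c(nrow(top$atoms), 3, 4))
  sim0 <- pairwise_rmsd_matrix(trajectory(coords, 0:3), top, prot, lig)
  expect_true(all(abs(sim0$S) < 1e-12))
  expect_equal(sim0$S, t(sim0$S))

  d <- 3.25
  moved <- ref; moved[lig, 1] <- moved[lig, 1] + d
  coords2 <- array(NA_real_, dim = c(nrow(top$atoms), 3, 2))
  coords2[, , 1] <- ref; coords2[, , 2] <- moved
  sim <- pairwise_rmsd_matrix(trajectory(coords2, 0:1), top, prot, lig)
  expect_equal(sim$S[1, 2], -d^2, tolerance = 1e-9)
  expect_equal(max(abs(sim$S - t(sim$S))), 0)
})

test_that("affinity propagation reproduces frozen reference labels on a 2-D
           blob fixture", {
  pts <- rbind(c(0, 0), c(0.3, 0.1), c(0.1, 0.4),
               c(5, 5), c(5.2, 4.9), c(4.8, 5.3),
               c(9, 0), c(9.1, 0.2), c(8.7, 0.1))
  S <- -as.matrix(dist(pts))^2
  res <- affinity_propagation(S)
  # reference labels computed once with scikit-learn 1.9.0
  # (AffinityPropagation, precomputed affinity, damping 0.5,
  #  preference = median off-diagonal): exemplars {2, 4, 7}
  expect_equal(sort(res$exemplars), c(2L, 4L, 7L))
  expect_equal(res$labels, rep(1:3, each = 3))
  expect_true(res$converged)
})

test_that("degenerate similarities give one cluster; preference extremes move
           the cluster count the canonical way", {
  S <- matrix(0, 6, 6)
  # fully tied messages cannot settle: the contract is a warning plus the
  # single fallback exemplar, never an error
  expect_warning(res <- affinity_propagation(S), "did not converge")
  expect_false(res$converged)
  expect_equal(length(res$exemplars), 1L)
  expect_equal(res$labels, rep(1L, 6))

  top <- micro_topology()
  bt <- basin_trajectory(top, populations = c(8, 8))
  sim <- pairwise_rmsd_matrix(bt$traj, top, bt$prot, bt$lig)
  hi <- affinity_propagation(sim, preference = max(sim$S[row(sim$S) != col(sim$S)]))
  expect_gte(length(hi$exemplars), 2L)
  lo <- affinity_propagation(sim, preference = min(sim$S) * 100)
  expect_equal(length(lo$exemplars), 1L)
})

test_that("three engineered basins give three clusters with exemplars inside
           each basin, stably under frame permutation", {
  top <- micro_topology()
  bt <- basin_trajectory(top)
  sim <- pairwise_rmsd_matrix(bt$traj, top, bt$prot, bt$lig)
  res <- affinity_propagation(sim)
  expect_equal(length(res$exemplars), 3L)
  expect_true(res$converged)
  # one exemplar inside each basin; labels match the construction
  expect_setequal(bt$assignment[res$exemplars], 1:3)
  relabel <- match(res$labels, res$labels[!duplicated(bt$assignment)])
  expect_equal(dplyr::n_distinct(paste(res$labels, bt$assignment)), 3L)

  # permuting the frames yields the same partition
  perm <- sample(n_frames(bt$traj))
  coords <- bt$traj$coords[, , perm]
  simp <- pairwise_rmsd_matrix(trajectory(coords, seq_along(perm) - 1), top,
                               bt$prot, bt$lig)
  resp <- affinity_propagation(simp)
  expect_equal(length(resp$exemplars), 3L)
  same_part <- tapply(resp$labels, bt$assignment[perm], function(x) length(unique(x)))
  expect_true(all(same_part == 1))

  td <- tidy(res)
  expect_equal(nrow(td), n_frames(bt$traj))
  expect_true(all(td$cluster[td$is_exemplar] == res$labels[res$exemplars]))
  gl <- glance(res)
  expect_equal(gl$n_clusters, 3L)
})

test_that("select_representative walks the population order and falls back with
           a warning", {
  clusters <- structure(list(labels = rep(1:3, c(20, 15, 10)),
                             exemplars = c(5L, 25L, 40L),
                             exemplar_rows = c(5L, 25L, 40L),
                             populations = c(20L, 15L, 10L),
                             iterations = 10L, converged = TRUE,
                             frames = 1:45), class = "bindmode_ap")
  ev <- function(frame, resnos) {
    tibble::tibble(replica = 1L, frame = frame, type = "hbond", resno = resnos,
                   resname = "XXX", chain = "A", residue_part = "sidechain",
                   ligand_atoms = "O1", water_id = NA_integer_,
                   direction = "protein")
  }
  # largest cluster's exemplar complete
  events <- dplyr::bind_rows(ev(5L, c(10L, 20L)), ev(25L, 10L))
  res <- select_representative(clusters, events, key_residues = c(10, 20))
  expect_equal(res$frame, 5L)
  expect_true(res$complete)
  # largest incomplete, second complete
  events2 <- dplyr::bind_rows(ev(5L, 10L), ev(25L, c(10L, 20L)))
  res2 <- select_representative(clusters, events2, key_residues = c(10, 20))
  expect_equal(res2$frame, 25L)
  expect_true(res2$complete)
  # none complete: largest cluster's exemplar, with a warning
  expect_warning(
    res3 <- select_representative(clusters, ev(5L, 10L), key_residues = c(10, 20)),
    "key interactions")
  expect_equal(res3$frame, 5L)
  expect_false(res3$complete)
  expect_error(select_representative(clusters, events, integer()),
               class = "bindmode_config_error")
})

test_that("frame caps subsample evenly by time and exemplar self-membership
           holds", {
  top <- micro_topology()
  bt <- basin_trajectory(top, populations = c(30, 30))
  sim <- pairwise_rmsd_matrix(bt$traj, top, bt$prot, bt$lig, max_frames = 20)
  expect_equal(nrow(sim$S), 20L)
  expect_equal(sim$frames, unique(round(seq(1, 60, length.out = 20))))
  res <- affinity_propagation(sim)
  for (k in seq_along(res$exemplars)) {
    expect_equal(res$labels[res$exemplar_rows[k]], k)
  }
  expect_equal(sum(res$populations), 20L)
})
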