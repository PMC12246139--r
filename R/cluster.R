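# Representative binding-mode frame selection: pairwise key-residue RMSD
# matrix, affinity-propagation clustering, and interaction-complete exemplar
# choice.

#' Pairwise RMSD similarity matrix
#'
#' For every frame pair, frame j is superposed onto frame i over `fit_sel`
#' (typically the protein backbone) and the RMSD is measured over
#' `measure_sel` (typically key residues plus ligand heavy atoms) without
#' re-fitting; the similarity is the negative squared RMSD. The matrix is
#' symmetric by construction. When the trajectory exceeds `max_frames`, frames
#' are subsampled evenly by time.
#'
#' @param traj A [trajectory()] object with at least 2 frames.
#' @param topology The matching [topology()].
#' @param fit_sel,measure_sel Selections (expressions, [select_atoms()]
#'   results, or index vectors).
#' @param max_frames Cap on the number of clustered frames (default 2000).
#' @return An object of class `bindmode_similarity`: list with `S` (n x n
#'   similarity matrix, Angstrom^2, diagonal 0 until preferences are set),
#'   `frames` (original frame indices), `times`.
#' @export
pairwise_rmsd_matrix <- function(traj, topology, fit_sel, measure_sel,
                                 max_frames = 2000) {
  fit <- resolve_selection(topology, fit_sel)
  mea <- resolve_selection(topology, measure_sel)
  if (length(fit) == 0L || length(mea) == 0L) {
    stop_bindmode("empty selection in pairwise_rmsd_matrix", "bindmode_selection_error")
  }
  nf <- n_frames(traj)
  if (nf < 2L) {
    stop_bindmode("pairwise RMSD matrix requires at least 2 frames", "bindmode_statistics_error")
  }
  frames <- if (nf > max_frames) {
    unique(round(seq(1L, nf, length.out = max_frames)))
  } else {
    seq_len(nf)
  }
  n <- length(frames)
  fit_list <- vector("list", n); mea_list <- vector("list", n)
  for (k in seq_len(n)) {
    xyz <- frame_coords(traj, frames[k])
    fit_list[[k]] <- xyz[fit, , drop = FALSE]
    mea_list[[k]] <- xyz[mea, , drop = FALSE]
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sp <- superpose(fit_list[[j]], fit_list[[i]])
      moved <- apply_superposition(mea_list[[j]], sp)
      r <- sqrt(mean(rowSums((moved - mea_list[[i]])^2)))
      S[i, j] <- S[j, i] <- -r^2
    }
  }
  structure(list(S = S, frames = frames, times = traj$times[frames],
                 fit_sel = fit, measure_sel = mea),
            class = "bindmode_similarity")
}

#' Affinity-propagation clustering
#'
#' Standard responsibility/availability message passing with damping on a
#' similarity matrix. Deterministic: no random initialization, ties broken
#' toward the lower frame index. Convergence is declared when the exemplar set
#' is unchanged for `convergence_window` consecutive iterations. Near-tied
#' similarities can make the messages oscillate at light damping; when that
#' happens the pass is rerun once with damping 0.9 (the method's canonical
#' remedy), still deterministically. On final non-convergence the result is
#' returned with `converged = FALSE` and a warning (not an error). If no
#' exemplar emerges (degenerate similarity), the frame with the largest
#' similarity sum becomes the single exemplar.
#'
#' @param sim A [pairwise_rmsd_matrix()] result, or a plain symmetric
#'   similarity matrix.
#' @param preference Diagonal preference value(s); default the median of the
#'   off-diagonal similarities (the method's canonical default).
#' @param damping Message damping factor in \[0.5, 1) (default 0.5).
#' @param max_iter Maximum iterations (default 1000).
#' @param convergence_window Iterations of exemplar stability required
#'   (default 50).
#' @return An object of class `bindmode_ap`: list with `labels` (per-frame
#'   cluster id), `exemplars` (frame index per cluster, in the original
#'   trajectory indexing when `sim` carries a frame map), `populations`,
#'   `iterations`, `converged`, `frames`.
#' @export
affinity_propagation <- function(sim, preference = NULL, damping = 0.5,
                                 max_iter = 1000, convergence_window = 50) {
  if (inherits(sim, "bindmode_similarity")) {
    S <- sim$S
    frames <- sim$frames
  } else {
    S <- as.matrix(sim)
    frames <- seq_len(nrow(S))
  }
  n <- nrow(S)
  if (!all(is.finite(S))) {
    stop_bindmode("similarity matrix must be finite", "bindmode_statistics_error")
  }
  if (is.null(preference)) {
    off <- S[row(S) != col(S)]
    preference <- median(off)
  }
  diag(S) <- preference
  pass <- ap_message_passing(S, damping, max_iter, convergence_window)
  if (!pass$converged && damping < 0.9) {
    # near-tied similarities make the 0.5-damped messages oscillate; the
    # canonical remedy is stronger damping, applied deterministically
    pass <- ap_message_passing(S, 0.9, max_iter, convergence_window)
    if (pass$converged) damping <- 0.9
  }
  R <- pass$R; A <- pass$A
  converged <- pass$converged
  it <- pass$iterations
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) {
    ex <- which.max(rowSums(S))
  }
  if (!converged) {
    warn("affinity propagation did not converge; returning the current exemplar set")
  }
  # assignment: each point to the exemplar with the largest similarity,
  # exemplars to themselves (ties toward the lower frame index via which.max)
  labels <- integer(n)
  for (i in seq_len(n)) {
    labels[i] <- ex[which.max(S[i, ex])]
  }
  labels[ex] <- ex
  cluster_id <- match(labels, ex)
  populations <- tabulate(cluster_id, nbins = length(ex))
  structure(list(labels = cluster_id,
                 exemplars = frames[ex],
                 exemplar_rows = ex,
                 populations = populations,
                 iterations = it,
                 converged = converged,
                 damping = damping,
                 frames = frames),
            class = "bindmode_ap")
}

ap_message_passing <- function(S, damping, max_iter, convergence_window) {
  n <- nrow(S)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  exemplar_history <- rep(NA_character_, convergence_window)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cols <- colSums(Rp)
    Anew <- matrix(cols, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    exemplar_history <- c(exemplar_history[-1L], paste(ex, collapse = ","))
    if (it >= convergence_window && length(ex) > 0L &&
        length(unique(exemplar_history)) == 1L) {
      converged <- TRUE
      break
    }
  }
  list(R = R, A = A, converged = converged, iterations = it)
}

#' @export
print.bindmode_ap <- function(x, ...) {
  cat(sprintf("<bindmode_ap> %d clusters over %d frames (%s after %d iterations)\n",
              length(x$exemplars), length(x$labels),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.bindmode_ap <- function(x, ...) {
  tibble(frame = x$frames, cluster = x$labels,
         exemplar_frame = x$exemplars[x$labels],
         is_exemplar = x$frames %in% x$exemplars)
}

#' @export
glance.bindmode_ap <- function(x, ...) {
  tibble(n_clusters = length(x$exemplars), n_frames = length(x$labels),
         iterations = x$iterations, converged = x$converged,
         largest_population = max(x$populations))
}

#' Select the representative binding-mode frame
#'
#' Orders clusters by population (descending; ties toward the lower exemplar
#' frame) and returns the exemplar of the first cluster whose exemplar frame
#' exhibits at least one interaction event with every key residue. If no
#' cluster qualifies, the largest cluster's exemplar is returned with a
#' warning.
#'
#' @param clusters An [affinity_propagation()] result.
#' @param events Event tibble from [detect_interactions()], frame-aligned with
#'   the clustered trajectory (same frame indexing).
#' @param key_residues Integer vector of key residue numbers.
#' @return List with `frame` (the representative frame index), `cluster`,
#'   `complete` (whether all key residues interact in that frame).
#' @export
select_representative <- function(clusters, events, key_residues) {
  if (length(key_residues) == 0L) {
    stop_bindmode("key_residues must be non-empty", "bindmode_config_error")
  }
  ord <- order(-clusters$populations, clusters$exemplars)
  for (ci in ord) {
    exemplar <- clusters$exemplars[ci]
    present <- unique(events$resno[events$frame == exemplar])
    if (all(key_residues %in% present)) {
      return(list(frame = exemplar, cluster = ci, complete = TRUE))
    }
  }
  best <- ord[1]
  warn("no cluster exemplar exhibits all key interactions; returning the most populated cluster's exemplar")
  list(frame = clusters$exemplars[best], cluster = best, complete = FALSE)
}

#' Write a clustering result as JSON
#' @param clusters An [affinity_propagation()] result.
#' @param path Output file path.
#' @param representative Optional [select_representative()] result to embed.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clusters, path, representative = NULL) {
  payload <- list(
    n_clusters = length(clusters$exemplars),
    exemplars = clusters$exemplars,
    populations = clusters$populations,
    iterations = clusters$iterations,
    converged = clusters$converged,
    assignments = as.data.frame(tidy(clusters))
  )
  if (!is.null(representative)) payload$representative <- representative
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
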