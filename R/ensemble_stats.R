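# RMSD with optimal superposition, block-averaged RMSD statistics, and
# GROMOS-style conformational clustering with populations and medoid
# representatives.

#' RMSD between two coordinate sets
#'
#' With `superpose = TRUE` the moving set is first fitted onto the reference
#' by an optimal least-squares (Kabsch) superposition.
#'
#' @param a,b N x 3 coordinate matrices (equal N).
#' @param superpose fit before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("congruence error: coordinate sets differ in size")
  if (superpose) {
    # least-squares fit of a onto b, full precision
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(b)),
                                           mobile = as.vector(t(a))))
    a <- matrix(fit, ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-replicate RMSD time series against a reference structure
#'
#' Every analyzed frame is (optionally) least-squares fitted to the
#' reference over the selection, then the RMSD over the selection is
#' recorded, giving one series per replicate.
#'
#' @param ensemble a `gik_ensemble`.
#' @param selection atom indices on the topology (e.g. C-alpha atoms of the
#'   helical segments).
#' @param reference reference coordinates for the full topology (N x 3
#'   matrix) or a `gik_structure`; defaults to the topology itself.
#' @param superpose fit each frame to the reference first.
#' @param stride,discard_fraction frame policy (see [analyzed_frames()]).
#' @return list of `gik_rmsd_series`: replicate_id, values (A),
#'   frame_interval_ns.
#' @export
rmsd_series <- function(ensemble, selection, reference = NULL,
                        superpose = TRUE, stride = 1L,
                        discard_fraction = NULL) {
  ref <- if (is.null(reference)) coords(ensemble$topology)
  else if (inherits(reference, "gik_structure")) coords(reference)
  else as.matrix(reference)
  refsel <- ref[selection, , drop = FALSE]
  frames <- analyzed_frames(ensemble, stride = stride,
                            discard_fraction = discard_fraction)
  lapply(split(frames, frames$replicate), function(fr) {
    r <- fr$replicate[1]
    arr <- ensemble$replicates[[r]]
    vals <- vapply(fr$frame, function(f)
      rmsd(arr[selection, , f], refsel, superpose = superpose), numeric(1))
    base::structure(list(replicate_id = r, values = vals,
                         frame_interval_ns = ensemble$frame_interval_ns * stride),
                    class = "gik_rmsd_series")
  })
}

#' Block-averaged statistics of RMSD series
#'
#' Each series is divided into non-overlapping blocks of `block_size` frames
#' (a trailing partial block is dropped and noted). Block means within a
#' replicate give the replicate mean and SEM; across replicates, each
#' replicate mean is treated as an independent observation, giving the
#' ensemble mean and SEM (sample sd of replicate means / sqrt(R)).
#'
#' @param series_set list of `gik_rmsd_series` (or plain numeric vectors).
#' @param block_size block length in frames (e.g. 50 frames = 50 ns at
#'   1 ns/frame).
#' @return object of class `gik_block_stats`: block_size_frames,
#'   per_replicate (data.frame replicate, n_blocks, mean, sem, dropped
#'   frames), block_means (list), ensemble_mean, ensemble_sem.
#' @export
block_stats <- function(series_set, block_size) {
  block_size <- as.integer(block_size)
  if (block_size < 1) stop("parameter error: block_size must be >= 1")
  vals <- lapply(series_set, function(s)
    if (inherits(s, "gik_rmsd_series")) s$values else as.numeric(s))
  ids <- vapply(seq_along(series_set), function(i) {
    s <- series_set[[i]]
    if (inherits(s, "gik_rmsd_series")) s$replicate_id else i
  }, numeric(1))
  too_short <- vapply(vals, length, integer(1)) < block_size
  if (any(too_short))
    stop("parameter error: block_size ", block_size,
         " exceeds series length for replicate(s) ",
         paste(ids[too_short], collapse = ", "))
  block_means <- lapply(vals, function(v) {
    nb <- length(v) %/% block_size
    colMeans(matrix(v[seq_len(nb * block_size)], nrow = block_size))
  })
  per <- data.frame(
    replicate = ids,
    n_blocks = vapply(block_means, length, integer(1)),
    mean = vapply(block_means, mean, numeric(1)),
    sem = vapply(block_means, function(b)
      if (length(b) > 1) stats::sd(b) / sqrt(length(b)) else 0, numeric(1)),
    dropped_frames = vapply(vals, function(v) length(v) %% block_size, integer(1)))
  r_means <- per$mean
  base::structure(list(
    block_size_frames = block_size,
    per_replicate = per, block_means = block_means,
    ensemble_mean = mean(r_means),
    ensemble_sem = if (length(r_means) > 1)
      stats::sd(r_means) / sqrt(length(r_means)) else 0),
    class = "gik_block_stats")
}

#' @export
print.gik_block_stats <- function(x, ...) {
  cat(sprintf("<gik_block_stats: %d replicates, %d-frame blocks, ensemble %.2f +/- %.2f A>\n",
              nrow(x$per_replicate), x$block_size_frames,
              x$ensemble_mean, x$ensemble_sem))
  invisible(x)
}

# frame coordinate matrix (F x 3n) for a selection over analyzed frames
frame_matrix <- function(ensemble, selection, frames) {
  n <- length(selection)
  X <- matrix(0, nrow(frames), 3L * n)
  for (i in seq_len(nrow(frames))) {
    X[i, ] <- as.vector(ensemble$replicates[[frames$replicate[i]]][selection, , frames$frame[i]])
  }
  X
}

#' GROMOS-style conformational clustering of ensemble frames
#'
#' Neighbor-count clustering on pairwise RMSD over the selection:
#' iteratively, the frame with the most neighbors within `rmsd_cutoff`
#' becomes a cluster center (medoid); it and its neighborhood are assigned
#' and removed; repeat until all frames are assigned. Ties are broken by the
#' lowest frame index. With `superpose = FALSE` (default) frames are taken
#' as already expressed in a common receptor-aligned frame, so the metric is
#' the positional RMSD - appropriate for clustering the *position* of a
#' helix; `superpose = TRUE` switches to pairwise Kabsch-fitted RMSD.
#'
#' @param ensemble a `gik_ensemble`, or an F x 3n coordinate matrix.
#' @param selection atom indices (ignored when a matrix is given).
#' @param rmsd_cutoff neighbor cutoff in Angstrom (default 1.5).
#' @param superpose pairwise superposition before RMSD.
#' @param stride,discard_fraction frame policy for ensembles.
#' @return object of class `gik_clusters`: assignments (integer per analyzed
#'   frame), populations (data.frame cluster, count, fraction, medoid),
#'   frames (frame refs), rmsd_cutoff, superpose.
#' @export
cluster_frames <- function(ensemble, selection = NULL, rmsd_cutoff = 1.5,
                           superpose = FALSE, stride = 1L,
                           discard_fraction = NULL) {
  if (inherits(ensemble, "gik_ensemble")) {
    frames <- analyzed_frames(ensemble, stride = stride,
                              discard_fraction = discard_fraction)
    X <- frame_matrix(ensemble, selection, frames)
  } else {
    X <- as.matrix(ensemble)
    frames <- data.frame(replicate = 1L, frame = seq_len(nrow(X)))
  }
  fcount <- nrow(X)
  if (fcount < 1) stop("empty-analysis error: no frames to cluster")
  natoms <- ncol(X) / 3
  adj <- adjacency_matrix(X, natoms, rmsd_cutoff, superpose)
  assignments <- integer(fcount)
  counts <- colSums(adj)
  alive <- rep(TRUE, fcount)
  cl <- 0L
  medoids <- integer()
  while (any(alive)) {
    cl <- cl + 1L
    center <- which.max(counts)  # ties: lowest frame index
    members <- which(adj[, center] & alive)
    assignments[members] <- cl
    medoids[cl] <- center
    counts <- counts - rowSums(adj[, members, drop = FALSE])
    alive[members] <- FALSE
    counts[!alive] <- -Inf
  }
  sizes <- tabulate(assignments, nbins = cl)
  ord <- order(-sizes, medoids[seq_len(cl)])
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  assignments <- relabel[assignments]
  pops <- data.frame(cluster = seq_len(cl),
                     count = sizes[ord],
                     fraction = sizes[ord] / fcount,
                     medoid = medoids[ord])
  base::structure(list(assignments = assignments, populations = pops,
                       frames = frames, rmsd_cutoff = rmsd_cutoff,
                       superpose = superpose),
                  class = "gik_clusters")
}

adjacency_matrix <- function(X, natoms, cutoff, superpose) {
  fcount <- nrow(X)
  if (superpose) {
    adj <- matrix(FALSE, fcount, fcount)
    for (i in seq_len(fcount)) {
      adj[i, i] <- TRUE
      if (i == fcount) break
      mi <- matrix(X[i, ], natoms, 3)
      for (j in (i + 1):fcount) {
        r <- rmsd(matrix(X[j, ], natoms, 3), mi, superpose = TRUE)
        adj[i, j] <- adj[j, i] <- r <= cutoff
      }
    }
    return(adj)
  }
  # positional RMSD, vectorized in row blocks to bound memory
  thr <- natoms * cutoff^2                # compare sums of squared deviations
  sq <- rowSums(X * X)
  adj <- matrix(FALSE, fcount, fcount)
  block <- max(1L, min(fcount, as.integer(2e7 / fcount)))
  i0 <- 1L
  while (i0 <= fcount) {
    i1 <- min(fcount, i0 + block - 1L)
    d2 <- outer(sq[i0:i1], sq, "+") - 2 * tcrossprod(X[i0:i1, , drop = FALSE], X)
    adj[i0:i1, ] <- d2 <= thr
    i0 <- i1 + 1L
  }
  adj
}

#' @export
print.gik_clusters <- function(x, ...) {
  cat(sprintf("<gik_clusters: %d frames, %d clusters, cutoff %.2f A, superpose=%s>\n",
              length(x$assignments), nrow(x$populations), x$rmsd_cutoff,
              x$superpose))
  print(utils::head(x$populations, 5))
  invisible(x)
}

#' Cluster population fractions from frame counts
#'
#' Utility for population bookkeeping: converts cluster frame counts into
#' fractions of the analyzed total. When the total is unknown but one
#' cluster's count and fraction are both known (as in a published cluster
#' report), the total is inferred as `round(count / fraction)` first.
#'
#' @param counts integer frame counts per cluster.
#' @param total total analyzed frames; if NULL, inferred from
#'   `known_count` / `known_fraction`.
#' @param known_count,known_fraction one cluster's count and fraction, used
#'   to infer the total when it is not given.
#' @return data.frame count, fraction (and the total used as an attribute).
#' @export
population_fractions <- function(counts, total = NULL,
                                 known_count = NULL, known_fraction = NULL) {
  if (is.null(total)) {
    if (is.null(known_count) || is.null(known_fraction))
      stop("need either total or a (known_count, known_fraction) pair")
    total <- round(known_count / known_fraction)
  }
  out <- data.frame(count = counts, fraction = counts / total)
  attr(out, "total") <- total
  out
}

#' Medoid representative of a cluster
#'
#' The representative is the cluster center found by the neighbor-count
#' clustering, i.e. the frame with minimal mean RMSD to the members at the
#' time of selection; deterministic (ties resolved to the lowest index).
#'
#' @param clusters a `gik_clusters`.
#' @param cluster_id cluster number (1 = most populated).
#' @return one-row data.frame with the global frame index and its
#'   (replicate, frame) reference.
#' @export
representative <- function(clusters, cluster_id) {
  row <- clusters$populations[clusters$populations$cluster == cluster_id, ]
  if (nrow(row) != 1) stop("lookup error: unknown cluster id ", cluster_id)
  m <- row$medoid
  cbind(frame_index = m, clusters$frames[m, , drop = FALSE])
}
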