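# Helix-axis descriptors, membrane-frame plane projections, and inter-helix
# distance metrics. The membrane normal is assumed to be +z of the input
# frame (OPM convention); XZ and XY projections follow the input frame axes.

#' Helix axis and membrane-frame descriptor from ordered C-alpha coordinates
#'
#' The axis is the principal component of the centered coordinates,
#' sign-fixed so that it points from the N-terminal to the C-terminal half.
#' Length is the extent of the projections onto the axis. Projections of the
#' C-alpha trace onto the XZ and XY planes of the input frame are stored.
#'
#' @param ca_coords ordered n x 3 matrix of C-alpha positions (N to C), n >= 4.
#' @return object of class `gik_helix`: origin (centroid), axis (unit,
#'   N-to-C), length, projection_xz, projection_xy.
#' @export
helix_axis <- function(ca_coords) {
  ca <- as.matrix(ca_coords)
  if (nrow(ca) < 4) stop("geometry error: need at least 4 C-alpha positions")
  origin <- colMeans(ca)
  x <- sweep(ca, 2, origin)
  sv <- svd(x, nu = 0, nv = 3)
  axis <- sv$v[, 1]
  n_half <- colMeans(ca[seq_len(floor(nrow(ca) / 2)), , drop = FALSE])
  c_half <- colMeans(ca[(floor(nrow(ca) / 2) + 1):nrow(ca), , drop = FALSE])
  if (sum(axis * (c_half - n_half)) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  proj <- drop(x %*% axis)
  base::structure(list(origin = origin, axis = axis,
                       length = diff(range(proj)),
                       projection_xz = ca[, c(1, 3)],
                       projection_xy = ca[, c(1, 2)]),
                  class = "gik_helix")
}

#' @export
print.gik_helix <- function(x, ...) {
  cat(sprintf("<gik_helix: origin (%.1f, %.1f, %.1f), axis (%.3f, %.3f, %.3f), length %.1f A>\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3], x$length))
  invisible(x)
}

#' C-alpha distance between two generic positions in one frame
#'
#' The TM2-TM6 opening metric is this distance between positions 2.39 and
#' 6.33; it scales with the outward TM6 movement that distinguishes Gs- from
#' Gi-coupled receptor conformations.
#'
#' @param x a `gik_structure` (or ensemble frame).
#' @param map numbering map resolving the labels.
#' @param label_a,label_b generic labels (symmetric).
#' @return distance in Angstrom.
#' @export
tm_distance <- function(x, map, label_a, label_b) {
  get_ca <- function(lab) {
    res <- to_residue(map, lab)
    idx <- select_atoms(x, chain = res$chain, resnum = res$resnum,
                        atom = "CA")
    idx <- idx[x$atoms$icode[idx] == res$icode]
    if (length(idx) != 1)
      stop("atom-missing error: no unique CA for label ", lab)
    coords(x)[idx, ]
  }
  a <- get_ca(label_a); b <- get_ca(label_b)
  sqrt(sum((a - b)^2))
}

#' TM-opening distance series over an ensemble
#'
#' @param ensemble a `gik_ensemble`.
#' @param map numbering map on the topology.
#' @param label_a,label_b generic labels.
#' @param stride,discard_fraction frame policy (see [analyzed_frames()]).
#' @return data.frame replicate, frame, distance.
#' @export
tm_distance_series <- function(ensemble, map, label_a, label_b,
                               stride = 1L, discard_fraction = NULL) {
  res_a <- to_residue(map, label_a); res_b <- to_residue(map, label_b)
  top <- ensemble$topology
  ia <- select_atoms(top, chain = res_a$chain, resnum = res_a$resnum, atom = "CA")
  ib <- select_atoms(top, chain = res_b$chain, resnum = res_b$resnum, atom = "CA")
  if (length(ia) != 1 || length(ib) != 1)
    stop("atom-missing error: need unique CA atoms for both labels")
  frames <- analyzed_frames(ensemble, stride = stride,
                            discard_fraction = discard_fraction)
  d <- numeric(nrow(frames))
  for (i in seq_len(nrow(frames))) {
    arr <- ensemble$replicates[[frames$replicate[i]]]
    d[i] <- sqrt(sum((arr[ia, , frames$frame[i]] - arr[ib, , frames$frame[i]])^2))
  }
  cbind(frames, distance = d)
}

#' Compare a helix descriptor against a set of references
#'
#' All descriptors must be computed in a common receptor-aligned frame
#' (superpose the receptors onto one reference complex first). Angle is the
#' arc between axis vectors; offset is the origin displacement.
#'
#' @param target a `gik_helix`.
#' @param references list of `gik_helix` (optionally named).
#' @return data.frame reference, angle_deg, origin_offset.
#' @export
orientation_compare <- function(target, references) {
  if (inherits(references, "gik_helix")) references <- list(references)
  nm <- names(references)
  if (is.null(nm)) nm <- as.character(seq_along(references))
  ang <- vapply(references, function(r) {
    cosang <- sum(target$axis * r$axis)
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))
  off <- vapply(references, function(r)
    sqrt(sum((target$origin - r$origin)^2)), numeric(1))
  data.frame(reference = nm, angle_deg = unname(ang),
             origin_offset = unname(off), stringsAsFactors = FALSE)
}
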