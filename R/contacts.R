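# Residue-residue contacts and hydrogen bonds, single-frame and over
# trajectory ensembles. Heavy-atom cutoff default 4.5 A; H-bond criteria
# donor-acceptor <= 3.0 A with D-H...A within 20 degrees of linear; "polar"
# contacts are side-chain N/O pairs within 4.0 A with no angle term.

backbone_names <- c("N", "CA", "C", "O", "OXT")

# cross squared-distance matrix between two coordinate sets (vectorized;
# this is the accelerated path checked against a brute-force double loop)
cross_dist2 <- function(a, b) {
  sa <- rowSums(a * a); sb <- rowSums(b * b)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

atom_filter_for_kind <- function(atoms, idx, kind) {
  if (kind == "heavy_atom") {
    idx[atoms$element[idx] != "H"]
  } else {
    # polar / hbond distance screen: side-chain N/O/S only
    idx[atoms$element[idx] %in% c("N", "O", "S") &
          !(atoms$atom[idx] %in% backbone_names)]
  }
}

#' Residue-residue contacts between two atom groups in one structure/frame
#'
#' A residue pair is in contact iff the minimum inter-atomic distance over
#' the relevant atoms is at most `cutoff`. For `kind = "heavy_atom"` all
#' non-hydrogen atoms count; for `kind = "polar"` only side-chain N/O/S
#' atoms count (salt-bridge-like engagement, no angle term).
#'
#' @param x a `gik_structure` (or ensemble frame from [ensemble_frame()]).
#' @param group_a,group_b disjoint atom index vectors (see [select_atoms()]).
#' @param cutoff contact distance in Angstrom.
#' @param kind "heavy_atom" or "polar".
#' @param map_a,map_b optional numbering maps used to attach generic labels.
#' @return data.frame, one row per contacting residue pair, with residue keys
#'   of both sides, optional labels, and `min_distance`; sorted by keys.
#' @export
heavy_atom_contacts <- function(x, group_a, group_b, cutoff = 4.5,
                                kind = c("heavy_atom", "polar"),
                                map_a = NULL, map_b = NULL) {
  kind <- match.arg(kind)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty-selection error: both atom groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("atom groups must be disjoint")
  a <- x$atoms
  ia <- atom_filter_for_kind(a, group_a, kind)
  ib <- atom_filter_for_kind(a, group_b, kind)
  empty <- contact_frame(NULL, NULL, NULL)
  if (length(ia) == 0 || length(ib) == 0) return(empty)
  xyz <- coords(x)
  # conservative bounding-box prefilter: an atom farther than cutoff from the
  # other group's bounding box cannot be in any contacting pair
  box_keep <- function(pts, other) {
    lo <- apply(other, 2, min) - cutoff; hi <- apply(other, 2, max) + cutoff
    pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  }
  xa <- xyz[ia, , drop = FALSE]; xb <- xyz[ib, , drop = FALSE]
  ka <- box_keep(xa, xb); kb <- box_keep(xb, xa)
  ia <- ia[ka]; ib <- ib[kb]
  if (length(ia) == 0 || length(ib) == 0) return(empty)
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  ra <- factor(res_uid(a)[ia], levels = unique(res_uid(a)[ia]))
  rb <- factor(res_uid(a)[ib], levels = unique(res_uid(a)[ib]))
  # residue-pair minimum via two-stage rowsum-style reduction
  mins <- do.call(rbind, lapply(split(seq_along(ia), ra), function(rows) {
    m <- d2[rows, , drop = FALSE]
    tapply(apply(m, 2, min)[seq_along(ib)], rb, min)
  }))
  hits <- which(mins <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  key_a <- rownames(mins)[hits[, 1]]
  key_b <- colnames(mins)[hits[, 2]]
  out <- contact_frame(key_a, key_b, sqrt(mins[hits]))
  out <- attach_labels(out, a, map_a, map_b)
  out[order(out$chain_a, out$resnum_a, out$icode_a,
            out$chain_b, out$resnum_b, out$icode_b), , drop = FALSE]
}

contact_frame <- function(key_a, key_b, min_distance) {
  if (is.null(key_a)) {
    return(data.frame(chain_a = character(), resnum_a = integer(),
                      icode_a = character(), chain_b = character(),
                      resnum_b = integer(), icode_b = character(),
                      label_a = character(), label_b = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  sa <- do.call(rbind, strsplit(key_a, "|", fixed = TRUE))
  sb <- do.call(rbind, strsplit(key_b, "|", fixed = TRUE))
  pad <- function(m) if (ncol(m) == 2) cbind(m, "") else m
  sa <- pad(sa); sb <- pad(sb)
  data.frame(chain_a = sa[, 1], resnum_a = as.integer(sa[, 2]), icode_a = sa[, 3],
             chain_b = sb[, 1], resnum_b = as.integer(sb[, 2]), icode_b = sb[, 3],
             label_a = NA_character_, label_b = NA_character_,
             min_distance = as.numeric(min_distance),
             stringsAsFactors = FALSE, row.names = NULL)
}

attach_labels <- function(out, atoms, map_a, map_b) {
  lab <- function(map, chain, resnum, icode) {
    key <- paste(chain, resnum, icode)
    mk <- paste(map$pairs$chain, map$pairs$resnum, map$pairs$icode)
    map$pairs$label[match(key, mk)]
  }
  if (!is.null(map_a))
    out$label_a <- lab(map_a, out$chain_a, out$resnum_a, out$icode_a)
  if (!is.null(map_b))
    out$label_b <- lab(map_b, out$chain_b, out$resnum_b, out$icode_b)
  out
}

#' Hydrogen-bond geometry test for one donor/hydrogen/acceptor triple
#'
#' True iff the donor-acceptor distance is at most `dist_cutoff` and the
#' D-H...A angle deviates from linear (180 degrees) by at most `angle_cutoff`.
#'
#' @param x a `gik_structure`.
#' @param donor atom index of the donor heavy atom (N/O/S).
#' @param hydrogen atom index of the attached hydrogen; if `NA` an explicit
#'   error instructs use of the heavy-atom-only fallback
#'   (`kind = "polar"` in the ensemble operations).
#' @param acceptor atom index of the acceptor heavy atom (N/O/S).
#' @param dist_cutoff donor-acceptor cutoff (A).
#' @param angle_cutoff max deviation from linearity (degrees).
#' @return logical scalar; attributes `distance` and `deviation`.
#' @export
hbond_present <- function(x, donor, hydrogen, acceptor,
                          dist_cutoff = 3.0, angle_cutoff = 20) {
  a <- x$atoms
  if (is.na(hydrogen))
    stop("missing hydrogen on donor: structures without explicit hydrogens ",
         "must use the heavy-atom-only fallback (kind = 'polar')")
  if (!(a$element[donor] %in% c("N", "O", "S")))
    stop("donor must be N/O/S")
  if (!(a$element[acceptor] %in% c("N", "O", "S")))
    stop("acceptor must be N/O/S")
  xyz <- coords(x)
  d <- xyz[donor, ]; h <- xyz[hydrogen, ]; acc <- xyz[acceptor, ]
  da <- sqrt(sum((d - acc)^2))
  v1 <- d - h; v2 <- acc - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi  # angle at H
  deviation <- 180 - ang
  ok <- (da <= dist_cutoff) && (deviation <= angle_cutoff)
  attr(ok, "distance") <- da
  attr(ok, "deviation") <- deviation
  ok
}

# all hydrogen bonds between two groups in one frame: donors are H atoms
# covalently attached (< 1.25 A, same residue) to N/O/S
find_hbonds <- function(x, group_a, group_b, dist_cutoff = 3.0,
                        angle_cutoff = 20) {
  a <- x$atoms
  xyz <- coords(x)
  uid <- res_uid(a)
  pairs_dir <- function(gd, ga) {
    hyd <- gd[a$element[gd] == "H"]
    acc <- ga[a$element[ga] %in% c("N", "O", "S")]
    if (length(hyd) == 0 || length(acc) == 0) return(NULL)
    heavy <- gd[a$element[gd] %in% c("N", "O", "S")]
    if (length(heavy) == 0) return(NULL)
    axyz <- xyz[acc, , drop = FALSE]
    out <- NULL
    for (h in hyd) {
      same <- heavy[uid[heavy] == uid[h]]
      if (length(same) == 0) next
      dh <- sqrt(rowSums((xyz[same, , drop = FALSE] -
                            matrix(xyz[h, ], length(same), 3, byrow = TRUE))^2))
      if (min(dh) > 1.25) next
      don <- same[which.min(dh)]
      d <- xyz[don, ]
      da <- sqrt(rowSums(sweep(axyz, 2, d)^2))
      near <- which(da <= dist_cutoff)
      for (k in near) {
        ac <- acc[k]
        v1 <- d - xyz[h, ]; v2 <- xyz[ac, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        deviation <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (deviation <= angle_cutoff)
          out <- rbind(out, data.frame(key_a = uid[don], key_b = uid[ac],
                                       distance = da[k]))
      }
    }
    out
  }
  fwd <- pairs_dir(group_a, group_b)
  rev <- pairs_dir(group_b, group_a)
  if (!is.null(rev)) rev <- data.frame(key_a = rev$key_b, key_b = rev$key_a,
                                       distance = rev$distance)
  res <- rbind(fwd, rev)
  if (is.null(res)) return(contact_frame(NULL, NULL, NULL))
  agg <- stats::aggregate(distance ~ key_a + key_b, data = res, FUN = min)
  contact_frame(agg$key_a, agg$key_b, agg$distance)
}

#' Per-pair contact occupancy over a trajectory ensemble
#'
#' Applies the ensemble's equilibration discard, detects contacts in every
#' analyzed frame, and reports the fraction of frames in which each residue
#' pair is present. Only pairs with occupancy at least `min_occupancy` are
#' returned, sorted by decreasing occupancy (ties broken by residue keys).
#'
#' @param ensemble a `gik_ensemble`.
#' @param group_a,group_b disjoint atom index vectors on the topology.
#' @param kind "heavy_atom", "polar", or "hbond".
#' @param cutoff distance cutoff (A); defaults 4.5 / 4.0 / 3.0 by kind.
#' @param angle_cutoff H-bond linearity tolerance (degrees), hbond kind only.
#' @param min_occupancy report threshold (default 0.05).
#' @param stride frame stride after the discard.
#' @param discard_fraction override of the ensemble discard fraction.
#' @param map_a,map_b optional numbering maps for labels.
#' @return data.frame of occupancy records: residue keys, labels,
#'   frames_present, frames_total, occupancy.
#' @export
occupancy_map <- function(ensemble, group_a, group_b,
                          kind = c("heavy_atom", "polar", "hbond"),
                          cutoff = NULL, angle_cutoff = 20,
                          min_occupancy = 0.05, stride = 1L,
                          discard_fraction = NULL,
                          map_a = NULL, map_b = NULL) {
  kind <- match.arg(kind)
  if (is.null(cutoff))
    cutoff <- switch(kind, heavy_atom = 4.5, polar = 4.0, hbond = 3.0)
  frames <- analyzed_frames(ensemble, stride = stride,
                            discard_fraction = discard_fraction)
  n_total <- nrow(frames)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (i in seq_len(n_total)) {
    fr <- ensemble_frame(ensemble, frames$replicate[i], frames$frame[i])
    cc <- if (kind == "hbond")
      find_hbonds(fr, group_a, group_b, cutoff, angle_cutoff)
    else heavy_atom_contacts(fr, group_a, group_b, cutoff, kind = kind)
    if (nrow(cc) == 0) next
    keys <- paste(cc$chain_a, cc$resnum_a, cc$icode_a,
                  cc$chain_b, cc$resnum_b, cc$icode_b, sep = "|")
    for (j in seq_along(keys)) {
      k <- keys[j]
      assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L, counts)
      if (!exists(k, meta)) assign(k, cc[j, 1:6], meta)
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    out <- contact_frame(NULL, NULL, NULL)
    out$min_distance <- NULL
    out$frames_present <- integer(); out$frames_total <- integer()
    out$occupancy <- numeric()
    return(out)
  }
  np <- vapply(keys, function(k) get(k, counts), integer(1))
  out <- do.call(rbind, lapply(keys, function(k) get(k, meta)))
  out$label_a <- NA_character_; out$label_b <- NA_character_
  out$frames_present <- unname(np)
  out$frames_total <- n_total
  out$occupancy <- unname(np) / n_total
  rownames(out) <- NULL
  out <- attach_labels(out, ensemble$topology$atoms, map_a, map_b)
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  out[order(-out$occupancy, out$chain_a, out$resnum_a, out$icode_a,
            out$chain_b, out$resnum_b, out$icode_b), , drop = FALSE]
}

#' Per-residue contact counts against a partner group
#'
#' For an ensemble: mean number of partner residues in contact per analyzed
#' frame. For a list of structures: contact count per structure, then the
#' mean. The residue with the maximum count is flagged.
#'
#' @param x a `gik_ensemble` or a list of `gik_structure`s.
#' @param labels generic labels of the residues to profile (on side a).
#' @param map numbering map resolving `labels`; for a structure list, either
#'   one map or a list of maps (one per structure).
#' @param partner_group atom indices of the partner side (for a structure
#'   list, a list of index vectors).
#' @param cutoff contact cutoff (A).
#' @param kind "heavy_atom" or "polar".
#' @param ... passed to [occupancy_map()] for ensembles (stride, discard).
#' @return data.frame label, mean_count, is_max.
#' @export
per_residue_contact_counts <- function(x, labels, map, partner_group,
                                       cutoff = 4.5, kind = "heavy_atom", ...) {
  labels <- normalize_label(labels)
  count_one <- function(struct, m, pg) {
    ga <- select_atoms(struct, label = labels, map = m)
    if (length(ga) == 0) stop("lookup error: no atoms for requested labels")
    cc <- heavy_atom_contacts(struct, ga, pg, cutoff = cutoff, kind = kind,
                              map_a = m)
    vapply(labels, function(l) sum(cc$label_a == l, na.rm = TRUE), numeric(1))
  }
  if (inherits(x, "gik_ensemble")) {
    frames <- analyzed_frames(x, ...)
    tot <- rep(0, length(labels))
    for (i in seq_len(nrow(frames))) {
      fr <- ensemble_frame(x, frames$replicate[i], frames$frame[i])
      tot <- tot + count_one(fr, map, partner_group)
    }
    mean_count <- tot / nrow(frames)
  } else {
    stopifnot(is.list(x))
    maps <- if (inherits(map, "gik_numbering_map"))
      rep(list(map), length(x)) else map
    pgs <- if (is.list(partner_group) && !is.numeric(partner_group[[1]]))
      partner_group else if (is.numeric(partner_group))
        rep(list(partner_group), length(x)) else partner_group
    per <- mapply(function(s, m, pg) count_one(s, m, pg),
                  x, maps, pgs, SIMPLIFY = TRUE)
    mean_count <- if (is.matrix(per)) rowMeans(per) else mean(per)
  }
  data.frame(label = labels, mean_count = unname(mean_count),
             is_max = seq_along(labels) == which.max(mean_count),
             stringsAsFactors = FALSE)
}
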