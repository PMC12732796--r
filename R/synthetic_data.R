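# Synthetic-data generators with planted ground truth: ideal helices, toy
# receptor-Galpha complexes with planted contacts, multi-replicate ensembles
# with planted conformational basins, H-bond geometry probes, Galpha
# subfamily alignments, and complex sets with planted contact conservation.
# Every generator is deterministic in (arguments, seed).

# --- small rigid-geometry helpers ---------------------------------------

rot_about_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  c3 <- cos(th); s3 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c3 + ux^2 * (1 - c3), ux * uy * (1 - c3) - uz * s3, ux * uz * (1 - c3) + uy * s3,
    uy * ux * (1 - c3) + uz * s3, c3 + uy^2 * (1 - c3), uy * uz * (1 - c3) - ux * s3,
    uz * ux * (1 - c3) - uy * s3, uz * uy * (1 - c3) + ux * s3, c3 + uz^2 * (1 - c3)),
    3, 3, byrow = TRUE)
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a
    return(rot_about_axis(axis, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

apply_rigid <- function(xyz, R = diag(3), t = c(0, 0, 0), center = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, "+")
}

# --- ideal helix ---------------------------------------------------------

#' Ideal alpha-helix backbone with one side-chain pseudo-atom per residue
#'
#' Rise 1.5 A/residue, twist 100 degrees/residue, C-alpha radius 2.3 A.
#' Atoms per residue: N, CA, C and a CB side-chain pseudo-atom. The helix is
#' built along +z starting at the origin, then rotated onto `direction` and
#' translated. Deterministic.
#'
#' @param n_res number of residues (>= 4).
#' @param origin 3-vector; position of the helix start (first-residue frame).
#' @param direction axis direction (N- to C-terminal).
#' @param chain chain id.
#' @param resnum_start first residue number.
#' @param resname residue name(s), recycled.
#' @param id structure id.
#' @param phase twist phase offset in degrees.
#' @return a `gik_structure`.
#' @export
make_helix <- function(n_res, origin = c(0, 0, 0), direction = c(0, 0, 1),
                       chain = "A", resnum_start = 1L, resname = "ALA",
                       id = "helix", phase = 0) {
  if (n_res < 4) stop("parameter error: n_res must be >= 4")
  k <- seq_len(n_res) - 1L
  ang <- (phase + 100 * k) * pi / 180
  z <- 1.5 * k
  build_ring <- function(r, dang, dz) {
    cbind(r * cos(ang + dang), r * sin(ang + dang), z + dz)
  }
  ca <- build_ring(2.3, 0, 0)
  nn <- build_ring(1.6, -0.6, -0.6)
  cc <- build_ring(1.6, 0.6, 0.6)
  cb <- build_ring(3.8, 0.25, 0.3)
  per <- 4L
  xyz <- matrix(0, n_res * per, 3)
  xyz[seq(1, by = per, length.out = n_res), ] <- nn
  xyz[seq(2, by = per, length.out = n_res), ] <- ca
  xyz[seq(3, by = per, length.out = n_res), ] <- cc
  xyz[seq(4, by = per, length.out = n_res), ] <- cb
  R <- rotation_between(c(0, 0, 1), direction)
  xyz <- sweep(xyz %*% t(R), 2, origin, "+")
  atoms <- data.frame(
    chain = chain,
    resnum = rep(resnum_start + k, each = per),
    icode = "",
    resname = rep(rep_len(resname, n_res), each = per),
    atom = rep(c("N", "CA", "C", "CB"), n_res),
    element = rep(c("N", "C", "C", "C"), n_res),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE)
  new_structure(id = id, atoms = atoms)
}

# --- toy receptor-Galpha complex -----------------------------------------

# receptor segment layout: labels, author numbering and geometry of the toy
# 7TM bundle (+ ICL2, H8). Odd TMs run extracellular->intracellular (label
# index increases downward), even TMs the reverse; intracellular side is low z.
receptor_layout <- function() {
  seg <- list(
    list(tm = "1", lo = 30, hi = 41, resnum = 117L, az = 0, down = TRUE),
    list(tm = "2", lo = 35, hi = 46, resnum = 155L, az = 1, down = FALSE),
    list(tm = "3", lo = 44, hi = 55, resnum = 208L, az = 2, down = TRUE),
    list(tm = "4", lo = 40, hi = 51, resnum = 230L, az = 3, down = FALSE),
    list(tm = "5", lo = 60, hi = 75, resnum = 296L, az = 4, down = TRUE),
    list(tm = "6", lo = 28, hi = 39, resnum = 336L, az = 5, down = FALSE),
    list(tm = "7", lo = 47, hi = 60, resnum = 395L, az = 6, down = TRUE))
  seg
}

galpha_center <- c(0, 0, -14)

build_receptor <- function(chain = "R") {
  radius <- 16
  parts <- list(); labels <- character(); resnums <- integer()
  for (s in receptor_layout()) {
    n <- s$hi - s$lo + 1L
    a <- 2 * pi * s$az / 7
    base <- c(radius * cos(a), radius * sin(a), 0)
    if (s$down) {
      org <- base + c(0, 0, (n - 1) * 1.5)
      dirn <- c(0, 0, -1)
    } else {
      org <- base
      dirn <- c(0, 0, 1)
    }
    h <- make_helix(n, origin = org, direction = dirn, chain = chain,
                    resnum_start = s$resnum, id = paste0("TM", s$tm))
    parts[[length(parts) + 1]] <- h$atoms
    labels <- c(labels, sprintf("%s.%d", s$tm, s$lo:s$hi))
    resnums <- c(resnums, s$resnum + seq_len(n) - 1L)
  }
  # ICL2 (34.50-34.57, 221-228): horizontal helix between TM3 and TM4 azimuths
  a34 <- 2 * pi * 2.5 / 7
  start34 <- c(19 * cos(a34 - 0.18), 19 * sin(a34 - 0.18), -3)
  dir34 <- c(-sin(a34), cos(a34), 0)
  icl2 <- make_helix(8, origin = start34, direction = dir34, chain = chain,
                     resnum_start = 221L, id = "ICL2")
  parts[[length(parts) + 1]] <- icl2$atoms
  labels <- c(labels, sprintf("34.%d", 50:57))
  resnums <- c(resnums, 221:228)
  # H8 (8.47-8.58, 412-423): horizontal, pointing outward from TM7 azimuth
  a8 <- 2 * pi * 6 / 7
  dir8 <- c(cos(a8 + 0.35), sin(a8 + 0.35), 0)
  h8 <- make_helix(12, origin = c(17 * cos(a8), 17 * sin(a8), -2),
                   direction = dir8, chain = chain, resnum_start = 412L,
                   id = "H8")
  parts[[length(parts) + 1]] <- h8$atoms
  labels <- c(labels, sprintf("8.%d", 47:58))
  resnums <- c(resnums, 412:423)
  atoms <- do.call(rbind, parts)
  st <- new_structure("toy_receptor", atoms)
  map <- numbering_map(chain, "BW", resnums, labels, source = "synthetic-layout")
  list(structure = st, map = map)
}

build_galpha <- function(chain = "G") {
  # alpha5-like helix H5.01-H5.26 (369-394) along +x under the bundle
  h5 <- make_helix(26, origin = galpha_center - c(18.75, 0, 0),
                   direction = c(1, 0, 0), chain = chain,
                   resnum_start = 369L, id = "H5")
  # Ras-domain stub carrying S1.01-S1.03 (40-42) and S3.01-S3.03 (217-219)
  stub <- make_helix(6, origin = galpha_center + c(-3.75, 6, -3),
                     direction = c(1, 0, 0), chain = chain,
                     resnum_start = 40L, id = "stub")
  stub$atoms$resnum <- rep(c(40L, 41L, 42L, 217L, 218L, 219L), each = 4)
  atoms <- rbind(h5$atoms, stub$atoms)
  st <- new_structure("toy_galpha", atoms)
  labels <- c(sprintf("H5.%02d", 1:26),
              sprintf("S1.%02d", 1:3), sprintf("S3.%02d", 1:3))
  resnums <- c(369:394, 40:42, 217:219)
  map <- numbering_map(chain, "CGN", resnums, labels, source = "synthetic-layout")
  list(structure = st, map = map)
}

plant_distance <- function(kind) switch(kind, heavy_atom = 3.0, polar = 2.8,
                                        hbond = 2.8)

#' Toy receptor-Galpha complex with planted interface contacts
#'
#' Builds a 7-helix receptor bundle (plus ICL2 and H8 segments) with a docked
#' Galpha alpha5-like helix and Ras-domain stub underneath, annotated with
#' synthetic BW/CGN numbering maps. Planted contacts are realized
#' geometrically by extending a side-chain pseudo-atom of the Galpha residue
#' to a fixed distance from the receptor residue: 3.0 A (heavy_atom, carbon),
#' 2.8 A (polar/hbond, side-chain oxygen on both sides; hbond adds an
#' in-line hydrogen). All non-planted inter-group residue pairs are kept
#' beyond the default cutoffs by construction, and the realized contact set
#' is verified against the planted one.
#'
#' @param planted_contacts data.frame with columns `receptor_label`,
#'   `galpha_label` and optional `kind` ("heavy_atom" default, "polar",
#'   "hbond"); NULL plants nothing.
#' @param id complex id.
#' @param family "Gs", "Gi", "Gq" or "other".
#' @param verify check that the realized heavy-atom/polar contact sets equal
#'   the planted sets (generation error if not).
#' @return a `gik_complex`; attribute "planted" stores the realization table
#'   (atom indices, on/off positions) used by [make_ensemble()].
#' @export
make_complex <- function(planted_contacts = NULL, id = "toy_complex",
                         family = "Gs", verify = TRUE) {
  rec <- build_receptor()
  gal <- build_galpha()
  atoms <- rbind(rec$structure$atoms, gal$structure$atoms)
  planted <- NULL
  if (!is.null(planted_contacts) && nrow(planted_contacts) > 0) {
    pc <- planted_contacts
    if (is.null(pc$kind)) pc$kind <- "heavy_atom"
    pc$receptor_label <- normalize_label(pc$receptor_label)
    pc$galpha_label <- normalize_label(pc$galpha_label)
    per_res_count <- integer(0)
    rows <- list()
    # pass 1: receptor side-chain oxygens for polar/hbond targets
    targets <- vector("list", nrow(pc))
    tgt_rows <- rep(NA_integer_, nrow(pc))
    for (i in seq_len(nrow(pc))) {
      rres <- to_residue(rec$map, pc$receptor_label[i])
      ridx <- which(atoms$chain == rres$chain & atoms$resnum == rres$resnum)
      cb_r <- unlist(atoms[ridx[atoms$atom[ridx] == "CB"][1], c("x", "y", "z")])
      ca_r <- unlist(atoms[ridx[atoms$atom[ridx] == "CA"][1], c("x", "y", "z")])
      if (pc$kind[i] %in% c("polar", "hbond")) {
        existing <- which(atoms$chain == rres$chain &
                            atoms$resnum == rres$resnum &
                            startsWith(atoms$atom, "OG"))
        if (length(existing) > 0) {
          targets[[i]] <- unlist(atoms[existing[1], c("x", "y", "z")])
          tgt_rows[i] <- existing[1]
        } else {
          og <- cb_r + 1.4 * (cb_r - ca_r) / sqrt(sum((cb_r - ca_r)^2))
          atoms <- rbind(atoms, data.frame(
            chain = rres$chain, resnum = rres$resnum, icode = "",
            resname = rres$resname, atom = "OG1", element = "O",
            x = og[1], y = og[2], z = og[3], occ = 1))
          targets[[i]] <- og
          tgt_rows[i] <- nrow(atoms)
        }
      } else {
        targets[[i]] <- cb_r
      }
    }
    # candidate directions for clearance-maximizing placement
    cand <- do.call(rbind, lapply(seq(0, 330, by = 30) * pi / 180, function(az)
      do.call(rbind, lapply(c(-60, -30, 0, 30) * pi / 180, function(el)
        c(cos(el) * cos(az), cos(el) * sin(az), sin(el))))))
    rec_chain <- rec$map$chain
    for (i in seq_len(nrow(pc))) {
      rres <- to_residue(rec$map, pc$receptor_label[i])
      gres <- to_residue(gal$map, pc$galpha_label[i])
      gidx <- which(atoms$chain == gres$chain & atoms$resnum == gres$resnum)
      ca_g <- unlist(atoms[gidx[atoms$atom[gidx] == "CA"][1], c("x", "y", "z")])
      target <- targets[[i]]
      key <- paste(gres$chain, gres$resnum)
      per_res_count[key] <- (if (is.na(per_res_count[key])) 0L
                             else per_res_count[key]) + 1L
      if (per_res_count[key] > 6L)
        stop("generation error: infeasible contact geometry for pair ",
             pc$receptor_label[i], "-", pc$galpha_label[i],
             " (too many planted partners on one residue)")
      # place the contact atom at the exact contact distance from the target
      # residue while keeping clear of every other receptor atom
      other <- which(atoms$chain == rec_chain &
                       !(atoms$resnum == rres$resnum & atoms$icode == rres$icode))
      oxyz <- cbind(atoms$x[other], atoms$y[other], atoms$z[other])
      d <- plant_distance(pc$kind[i])
      pos_cand <- sweep(d * cand, 2, target, "+")
      clearance <- apply(pos_cand, 1, function(p)
        min(sqrt(rowSums(sweep(oxyz, 2, p)^2))))
      best <- which.max(clearance)
      if (clearance[best] < 4.8)
        stop("generation error: infeasible contact geometry for pair ",
             pc$receptor_label[i], "-", pc$galpha_label[i],
             " (no placement clears neighbouring residues)")
      on_pos <- pos_cand[best, ]
      off_pos <- ca_g + c(0, 0, -2.5)
      aname <- paste0(if (pc$kind[i] == "heavy_atom") "XC" else "XO",
                      per_res_count[key])
      atoms <- rbind(atoms, data.frame(
        chain = gres$chain, resnum = gres$resnum, icode = "",
        resname = gres$resname, atom = aname,
        element = if (pc$kind[i] == "heavy_atom") "C" else "O",
        x = on_pos[1], y = on_pos[2], z = on_pos[3], occ = 1))
      arow <- nrow(atoms)
      hrow <- NA_integer_
      if (pc$kind[i] == "hbond") {
        hpos <- on_pos + 1.0 * (target - on_pos) / sqrt(sum((target - on_pos)^2))
        atoms <- rbind(atoms, data.frame(
          chain = gres$chain, resnum = gres$resnum, icode = "",
          resname = gres$resname, atom = paste0("HX", per_res_count[key]),
          element = "H", x = hpos[1], y = hpos[2], z = hpos[3], occ = 1))
        hrow <- nrow(atoms)
      }
      rows[[i]] <- data.frame(
        receptor_label = pc$receptor_label[i],
        galpha_label = pc$galpha_label[i], kind = pc$kind[i],
        prob = if (is.null(pc$prob)) 1 else pc$prob[i],
        atom_row = arow, h_row = hrow, tgt_row = tgt_rows[i],
        on_x = on_pos[1], on_y = on_pos[2], on_z = on_pos[3],
        off_x = off_pos[1], off_y = off_pos[2], off_z = off_pos[3],
        tgt_x = target[1], tgt_y = target[2], tgt_z = target[3],
        stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
  }
  st <- new_structure(id, atoms)
  cx <- complex_record(id, st, rec$map, gal$map, family = family)
  if (verify && !is.null(planted)) verify_planted(cx, planted)
  attr(cx, "planted") <- planted
  cx
}

verify_planted <- function(cx, planted) {
  got <- complex_interface_contacts(cx, cutoff = 4.5, kind = "heavy_atom")
  got_keys <- sort(paste(got$label_a, got$label_b))
  want_keys <- sort(paste(planted$receptor_label, planted$galpha_label))
  if (!identical(got_keys, unique(want_keys))) {
    extra <- setdiff(got_keys, want_keys); miss <- setdiff(want_keys, got_keys)
    stop("generation error: infeasible contact geometry for pair(s) ",
         paste(c(miss, extra), collapse = "; "))
  }
  pol <- complex_interface_contacts(cx, cutoff = 4.0, kind = "polar")
  want_pol <- sort(unique(paste(planted$receptor_label,
                                planted$galpha_label)[planted$kind != "heavy_atom"]))
  if (!identical(sort(paste(pol$label_a, pol$label_b)), want_pol))
    stop("generation error: polar contact realization mismatch")
  invisible(TRUE)
}

#' Two-residue hydrogen-bond geometry probe
#'
#' A minimal structure with a donor (O), its hydrogen, and an acceptor (O)
#' planted at an exact donor-acceptor distance and D-H...A deviation from
#' linearity; used to exercise the hydrogen-bond criterion.
#'
#' @param d_da donor-acceptor distance (A).
#' @param deviation_deg deviation of D-H...A from 180 degrees.
#' @return list: `structure` (a `gik_structure`), and atom indices `donor`,
#'   `hydrogen`, `acceptor`.
#' @export
make_hbond_probe <- function(d_da = 2.8, deviation_deg = 0) {
  d <- c(0, 0, 0)
  h <- c(1.0, 0, 0)
  # place A so that angle D-H-A = 180 - deviation at distance d_da from D
  th <- (180 - deviation_deg) * pi / 180
  # direction of H->A makes angle (180deg - th) with H->D direction (-x)
  dir_ha <- c(-cos(th), sin(th), 0)  # th=180: +x (linear)
  # solve |(h + t*dir_ha) - d| = d_da for t > 0
  b <- sum(2 * (h - d) * dir_ha); cc <- sum((h - d)^2) - d_da^2
  t <- (-b + sqrt(b^2 - 4 * cc)) / 2
  a <- h + t * dir_ha
  atoms <- data.frame(
    chain = "A", resnum = c(1L, 1L, 2L), icode = "",
    resname = c("SER", "SER", "SER"),
    atom = c("OG", "HG", "OG"), element = c("O", "H", "O"),
    x = c(d[1], h[1], a[1]), y = c(d[2], h[2], a[2]),
    z = c(d[3], h[3], a[3]), occ = 1, stringsAsFactors = FALSE)
  list(structure = new_structure("hbond_probe", atoms),
       donor = 1L, hydrogen = 2L, acceptor = 3L)
}

# --- scenario specification and ensemble generator -----------------------

#' Scenario specification for the synthetic ensemble generator
#'
#' Defaults emulate the study conditions: 12 replicates of 625 stored frames
#' at 1 ns/frame, three conformational basins holding 47%, 15.5% and 14.9%
#' of the frames (the remainder diffuse), and 0.5 A isotropic Gaussian
#' coordinate noise representing thermal fluctuation.
#'
#' @param seed RNG seed (single stream per scenario).
#' @param n_replicates number of independent replicates.
#' @param frames_per_replicate stored frames per replicate.
#' @param frame_interval_ns time between stored frames.
#' @param basins list of `list(fraction, displacement, rotation)`: fraction
#'   of frames, rigid displacement (3-vector, A) and rotation (degrees,
#'   about the mobile group's own axis) defining each basin; fractions must
#'   sum to <= 1, the remainder is diffuse.
#' @param noise_sigma isotropic Gaussian coordinate noise (A), >= 0.
#' @param planted_contacts as in [make_complex()], plus optional `prob`
#'   column: per-frame Bernoulli presence probability in [0, 1].
#' @param mobile "galpha" (the docked helix and stub move between basins) or
#'   a BW segment name such as "TM6" (that receptor segment moves).
#' @param diffuse_displacement half-width (A) of the uniform in-plane
#'   displacement of diffuse frames.
#' @param diffuse_rotation half-width (degrees) of their uniform rotation.
#' @param discard_fraction equilibration discard recorded on the ensemble
#'   (0 for generated scenarios: frames are stationary by construction).
#' @return list of class `gik_scenario`.
#' @export
scenario_spec <- function(seed = 1L, n_replicates = 12L,
                          frames_per_replicate = 625L,
                          frame_interval_ns = 1,
                          basins = list(
                            list(fraction = 0.470, displacement = c(0, 0, 0), rotation = 0),
                            list(fraction = 0.155, displacement = c(4, 2, 0), rotation = 25),
                            list(fraction = 0.149, displacement = c(-4, 2, 0), rotation = -25)),
                          noise_sigma = 0.5,
                          planted_contacts = NULL,
                          mobile = "galpha",
                          diffuse_displacement = 8,
                          diffuse_rotation = 60,
                          discard_fraction = 0) {
  fr <- vapply(basins, function(b) b$fraction, numeric(1))
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("spec error: basin fractions must be >= 0 and sum to <= 1")
  if (noise_sigma < 0) stop("spec error: noise_sigma must be >= 0")
  if (!is.null(planted_contacts) && !is.null(planted_contacts$prob) &&
      (any(planted_contacts$prob < 0) || any(planted_contacts$prob > 1)))
    stop("spec error: contact probabilities must be in [0, 1]")
  base::structure(list(seed = as.integer(seed),
                       n_replicates = as.integer(n_replicates),
                       frames_per_replicate = as.integer(frames_per_replicate),
                       frame_interval_ns = frame_interval_ns,
                       basins = basins, noise_sigma = noise_sigma,
                       planted_contacts = planted_contacts, mobile = mobile,
                       diffuse_displacement = diffuse_displacement,
                       diffuse_rotation = diffuse_rotation,
                       discard_fraction = discard_fraction),
                  class = "gik_scenario")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate a multi-replicate ensemble with planted basins and contacts
#'
#' Frames are drawn i.i.d. from the basin mixture; within a basin the mobile
#' group is rigidly transformed (rotation about its own axis, then
#' displacement) and isotropic Gaussian noise is added to every coordinate.
#' Diffuse remainder frames get a per-frame uniform random displacement and
#' rotation, so they do not form a coherent cluster. Planted contacts are
#' re-realized per frame by a Bernoulli draw of their presence probability;
#' contact-realization atoms are placed exactly (no noise) so the planted
#' occupancy is exactly the Bernoulli fraction.
#'
#' @param spec a `gik_scenario` from [scenario_spec()].
#' @param complex optionally a pre-built `gik_complex` from [make_complex()]
#'   (must carry the same planted contacts).
#' @return a `gik_ensemble`; attribute "truth" holds the per-frame basin
#'   assignment, per-basin planted fractions, empirical contact on-counts,
#'   and the generating spec. Attribute "complex" holds the topology complex.
#' @export
make_ensemble <- function(spec, complex = NULL) {
  stopifnot(inherits(spec, "gik_scenario"))
  if (is.null(complex)) complex <- make_complex(spec$planted_contacts)
  planted <- attr(complex, "planted")
  top <- complex$structure
  base <- coords(top)
  n_atoms <- nrow(base)
  # mobile atom set and its rotation axis
  if (identical(spec$mobile, "galpha")) {
    mob <- select_atoms(top, chain = complex$galpha_map$chain)
  } else {
    mob <- select_atoms(top, segment = spec$mobile, map = complex$receptor_map)
    if (length(mob) == 0) stop("spec error: unknown mobile segment ", spec$mobile)
  }
  mob_ca <- intersect(mob, select_atoms(top, atom = "CA"))
  ctr <- colMeans(base[mob_ca, , drop = FALSE])
  cm <- sweep(base[mob_ca, , drop = FALSE], 2, ctr)
  axis <- svd(cm, nu = 0, nv = 1)$v[, 1]
  n_basins <- length(spec$basins)
  basin_coords <- lapply(spec$basins, function(b) {
    R <- rot_about_axis(axis, b$rotation)
    apply_rigid(base[mob, , drop = FALSE], R, b$displacement, ctr)
  })
  fr <- vapply(spec$basins, function(b) b$fraction, numeric(1))
  total <- spec$n_replicates * spec$frames_per_replicate
  with_seed(spec$seed, {
    # categories 1..n_basins, plus n_basins+1 = diffuse remainder (coded 0)
    basin_of <- sample.int(n_basins + 1L, total, replace = TRUE,
                           prob = c(fr, max(0, 1 - sum(fr))))
    basin_of[basin_of == n_basins + 1L] <- 0L
    on_draws <- if (!is.null(planted))
      matrix(stats::runif(total * nrow(planted)) <
               rep(planted$prob, each = total), total, nrow(planted))
    else NULL
    reps <- vector("list", spec$n_replicates)
    f0 <- 0L
    for (r in seq_len(spec$n_replicates)) {
      nf <- spec$frames_per_replicate
      arr <- array(0, dim = c(n_atoms, 3L, nf))
      for (f in seq_len(nf)) {
        g <- f0 + f
        xyz <- base
        b <- basin_of[g]
        if (b >= 1L) {
          xyz[mob, ] <- basin_coords[[b]]
        } else {
          dd <- spec$diffuse_displacement
          disp <- c(stats::runif(2, -dd, dd), stats::runif(1, -dd / 8, dd / 8))
          R <- rot_about_axis(axis, stats::runif(1, -spec$diffuse_rotation,
                                                 spec$diffuse_rotation))
          xyz[mob, ] <- apply_rigid(base[mob, , drop = FALSE], R, disp, ctr)
        }
        if (spec$noise_sigma > 0)
          xyz <- xyz + matrix(stats::rnorm(n_atoms * 3, 0, spec$noise_sigma),
                              n_atoms, 3)
        if (!is.null(planted)) {
          for (p in seq_len(nrow(planted))) {
            row <- planted$atom_row[p]
            # synthetic polar/hbond acceptor atoms are placed exactly, like
            # the realization atoms, so planted occupancy is the Bernoulli
            # fraction and not eroded by noise at the strict criterion
            if (!is.na(planted$tgt_row[p]))
              xyz[planted$tgt_row[p], ] <- c(planted$tgt_x[p],
                                             planted$tgt_y[p],
                                             planted$tgt_z[p])
            if (on_draws[g, p]) {
              xyz[row, ] <- c(planted$on_x[p], planted$on_y[p], planted$on_z[p])
              if (!is.na(planted$h_row[p])) {
                # hydrogen in line from donor toward the acceptor target
                don <- xyz[row, ]
                tgt <- c(planted$tgt_x[p], planted$tgt_y[p], planted$tgt_z[p])
                xyz[planted$h_row[p], ] <- don +
                  (tgt - don) / sqrt(sum((tgt - don)^2))
              }
            } else {
              xyz[row, ] <- c(planted$off_x[p], planted$off_y[p], planted$off_z[p])
              if (!is.na(planted$h_row[p]))
                xyz[planted$h_row[p], ] <- xyz[row, ] + c(0, 0, -1)
            }
          }
        }
        arr[, , f] <- xyz
      }
      reps[[r]] <- arr
      f0 <- f0 + nf
    }
    ens <- read_ensemble(top, reps, spec$frame_interval_ns,
                         discard_fraction = spec$discard_fraction)
    attr(ens, "truth") <- list(
      basin_of_frame = basin_of,
      basin_fractions = fr,
      empirical_fractions = tabulate(basin_of, nbins = n_basins) / total,
      contact_on = if (!is.null(planted)) colSums(on_draws) else NULL,
      spec = spec)
    attr(ens, "complex") <- complex
    ens
  })
}

# --- Galpha subfamily alignment ------------------------------------------

#' Synthetic Galpha H5 alignment with planted conserved columns
#'
#' Builds an alignment over the 26 H5 positions (CGN H5.01-H5.26) for
#' `n_families` Galpha subfamily sequences in which exactly
#' `conserved_labels` are invariant columns.
#'
#' @param n_families number of subfamily sequences (>= 2).
#' @param conserved_labels CGN H5 labels to make invariant.
#' @param seed RNG seed.
#' @return character matrix, rownames = family names, colnames = CGN labels.
#' @export
make_alignment <- function(n_families = 6,
                           conserved_labels = c("H5.01", "H5.03", "H5.07",
                                                "H5.08", "H5.13", "H5.20",
                                                "H5.25"),
                           seed = 1L) {
  conserved_labels <- normalize_label(conserved_labels)
  cols <- sprintf("H5.%02d", 1:26)
  bad <- setdiff(conserved_labels, cols)
  if (length(bad) > 0)
    stop("labels outside the H5 grammar: ", paste(bad, collapse = ", "))
  fam <- c("Gs", "Gi1", "Gi2", "Go", "Gq", "G12", "Gz", "Gt")[seq_len(n_families)]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    m <- matrix("", n_families, length(cols), dimnames = list(fam, cols))
    for (j in seq_along(cols)) {
      if (cols[j] %in% conserved_labels) {
        m[, j] <- sample(aas, 1)
      } else {
        v <- sample(aas, n_families, replace = TRUE)
        if (length(unique(v)) == 1)
          v[n_families] <- sample(setdiff(aas, v[1]), 1)
        m[, j] <- v
      }
    }
    m
  })
}

#' Write a CGN-keyed Galpha alignment as TSV
#' @param alignment matrix from [make_alignment()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_galpha_alignment <- function(alignment, path) {
  df <- data.frame(family = rownames(alignment), alignment,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- demo complex sets emulating the Gs/Gi interface statistics ----------

#' Demo Gs-bound and Gi-bound complex sets with planted conservation
#'
#' Builds two sets of toy complexes whose planted interface statistics
#' emulate the class A receptor-Gs/Gi structural record: H5.20 and H5.25
#' contact the receptor consistently in both families (modal partners 3.54
#' and 6.33), H5.08 and H5.13 only sporadically, and six contact pairs are
#' conserved in at least 77% of the Gs set.
#'
#' @param n_per_family complexes per set.
#' @return list with elements `gs` and `gi` (lists of `gik_complex`).
#' @export
demo_complex_sets <- function(n_per_family = 6) {
  pair <- function(r, g) data.frame(receptor_label = r, galpha_label = g,
                                    stringsAsFactors = FALSE)
  gs <- lapply(seq_len(n_per_family), function(i) {
    pc <- rbind(
      pair("3.50", "H5.23"),
      if (i <= ceiling(5 / 6 * n_per_family)) pair("3.53", "H5.23"),
      pair("3.54", "H5.16"),
      pair("3.54", "H5.20"),
      if (i <= ceiling(5 / 6 * n_per_family)) pair("5.65", "H5.20"),
      if (i <= ceiling(5 / 6 * n_per_family)) pair("5.68", "H5.24"),
      if (i <= ceiling(4 / 6 * n_per_family)) pair("6.33", "H5.25")
      else pair("7.56", "H5.25"),
      if (i <= ceiling(1 / 6 * n_per_family)) pair("34.51", "H5.08"),
      if (i <= ceiling(2 / 6 * n_per_family)) pair("5.65", "H5.13"),
      if (i <= ceiling(2 / 6 * n_per_family)) pair("2.39", "H5.26"))
    make_complex(pc, id = sprintf("GS%02d", i), family = "Gs")
  })
  gi <- lapply(seq_len(n_per_family), function(i) {
    pc <- rbind(
      pair("3.54", "H5.20"),
      if (i <= ceiling(5 / 6 * n_per_family)) pair("6.33", "H5.25")
      else pair("7.56", "H5.25"),
      if (i <= ceiling(1 / 6 * n_per_family)) pair("34.51", "H5.08"),
      if (i <= ceiling(2 / 6 * n_per_family)) pair("5.65", "H5.13"),
      if (i <= ceiling(4 / 6 * n_per_family)) pair("3.50", "H5.22"))
    make_complex(pc, id = sprintf("GI%02d", i), family = "Gi")
  })
  list(gs = gs, gi = gi)
}

#' Demo model complex preserving five of the six conserved pairs
#'
#' The docked-model stand-in: plants the two restraint contacts and the five
#' conserved receptor-Gs pairs, omitting the sixth (5.68-H5.24).
#'
#' @return a `gik_complex`.
#' @export
demo_model_complex <- function() {
  pc <- data.frame(
    receptor_label = c("3.50", "3.53", "3.54", "3.54", "5.65", "6.33"),
    galpha_label = c("H5.23", "H5.23", "H5.16", "H5.20", "H5.20", "H5.25"),
    stringsAsFactors = FALSE)
  make_complex(pc, id = "MODEL", family = "Gs")
}

#' Demo hydrophobic-pocket complex around ICL2 position 34.51
#'
#' Plants five Galpha partner contacts for 34.51 (H5.08, H5.12, H5.15,
#' S1.02, S3.01) and one for 34.52, emulating an ICL2 anchoring pocket.
#'
#' @return a `gik_complex`.
#' @export
demo_pocket_complex <- function() {
  pc <- data.frame(
    receptor_label = c(rep("34.51", 5), "34.52"),
    galpha_label = c("H5.08", "H5.12", "H5.15", "S1.02", "S3.01", "H5.08"),
    stringsAsFactors = FALSE)
  make_complex(pc, id = "POCKET", family = "Gs")
}
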