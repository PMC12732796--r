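#' Construct a Structure object
#'
#' A Structure is an ordered, chain-aware atom table: one row per atom, grouped
#' into residues identified by (chain, resnum, icode). Residue order is source
#' order. Coordinates are in Angstrom.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   `atom` (atom name), `element`, `x`, `y`, `z`, `occ`.
#' @param model_index which model of a multi-model source these coordinates
#'   come from.
#' @param n_models number of models in the source.
#' @return object of class `gik_structure`.
#' @export
new_structure <- function(id, atoms, model_index = 1L, n_models = 1L) {
  req <- c("chain", "resnum", "icode", "resname", "atom", "element",
           "x", "y", "z", "occ")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty-input error: structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$atom))) stop("atom names must be non-empty")
  atoms$icode[is.na(atoms$icode)] <- ""
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms,
         model_index = as.integer(model_index),
         n_models = as.integer(n_models)),
    class = "gik_structure")
}

#' @export
print.gik_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<gik_structure '%s': %d atoms, %d residues, chains %s, model %d/%d>\n",
              x$id, nrow(x$atoms), nrow(rt),
              paste(unique(x$atoms$chain), collapse = ","),
              x$model_index, x$n_models))
  invisible(x)
}

# residue id strings in atom order (internal key: chain|resnum|icode)
res_uid <- function(atoms) paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")

#' Residue table of a Structure
#'
#' One row per residue in file order, with the atom-index span of each residue.
#'
#' @param x a `gik_structure`.
#' @return data.frame with chain, resnum, icode, resname, first, last.
#' @export
residue_table <- function(x) {
  uid <- res_uid(x$atoms)
  first <- which(!duplicated(uid))
  idx <- match(uid, uid[first])
  last <- vapply(seq_along(first), function(i) max(which(idx == i)), integer(1))
  data.frame(chain = x$atoms$chain[first],
             resnum = x$atoms$resnum[first],
             icode = x$atoms$icode[first],
             resname = x$atoms$resname[first],
             first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Coordinates of a Structure as an N x 3 matrix
#' @param x a `gik_structure`.
#' @return numeric matrix.
#' @export
coords <- function(x) {
  m <- cbind(x$atoms$x, x$atoms$y, x$atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of a Structure
#' @param x a `gik_structure`.
#' @param xyz N x 3 matrix congruent with the atom table.
#' @return the Structure with new coordinates.
#' @export
set_coords <- function(x, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(x$atoms) || ncol(xyz) != 3)
    stop("congruence error: coordinate matrix must be ",
         nrow(x$atoms), " x 3")
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

water_resnames <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")

#' Read a structure from PDB or mmCIF
#'
#' Returns the requested model (first by default). HETATM waters are stripped
#' unless `keep_water = TRUE`. For alternate locations the highest-occupancy
#' conformer is kept. The number of models in the source is recorded in the
#' `n_models` field.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif" (default guessed from extension).
#' @param model 1-based model index to extract.
#' @param keep_water keep crystallographic/solvent waters.
#' @return a `gik_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1L, keep_water = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty-input error: ", path, " is empty")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("format error parsing ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  n_models <- max(1L, nrow(as.matrix(pdb$xyz)))
  if (model > n_models)
    stop("model ", model, " requested but file has ", n_models, " models")
  at <- pdb$atom
  xyzm <- as.matrix(pdb$xyz)
  xyz <- matrix(xyzm[model, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resnum = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     guess_element(at$elety), at$elesy),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(atoms))
  if (!keep_water) keep <- keep & !(atoms$resname %in% water_resnames)
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(alt))) {
    # keep highest-occupancy alt-loc per (residue, atom name)
    key <- paste(res_uid(atoms), atoms$atom)
    ord <- order(-atoms$occ)
    best <- ord[!duplicated(key[ord])]
    keep_alt <- logical(nrow(atoms)); keep_alt[best] <- TRUE
    keep <- keep & keep_alt
  }
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty-input error: no atoms retained from ", path)
  new_structure(id = sub("\\.[^.]+$", "", basename(path)), atoms = atoms,
                model_index = model, n_models = n_models)
}

guess_element <- function(name) {
  n <- toupper(gsub("[0-9' ]", "", name))
  el <- substr(n, 1, 1)
  el[substr(n, 1, 2) %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")] <-
    substr(n, 1, 2)[substr(n, 1, 2) %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")]
  el
}

#' Write a Structure (or ensemble frames) as PDB
#'
#' @param x a `gik_structure`.
#' @param path output file.
#' @param frames optional list of N x 3 coordinate matrices; when given the
#'   file is written as a multi-model PDB (one MODEL per frame), which is the
#'   package's native text trajectory carrier.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, frames = NULL) {
  a <- x$atoms
  if (is.null(frames)) {
    xyz <- as.vector(t(coords(x)))
  } else {
    xyz <- do.call(rbind, lapply(frames, function(f) {
      f <- as.matrix(f)
      if (nrow(f) != nrow(a)) stop("congruence error: frame has ", nrow(f),
                                   " atoms, topology has ", nrow(a))
      as.vector(t(f))
    }))
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resnum, resid = a$resname,
                   chain = a$chain, insert = ifelse(nzchar(a$icode), a$icode, ""),
                   elety = a$atom, elesy = a$element, o = a$occ)
  invisible(path)
}

#' Build a trajectory ensemble
#'
#' Replicates are kept separate; concatenation is an explicit downstream
#' choice. Frame sources may be file paths (multi-model PDB) or in-memory
#' frames: an N x 3 x F array or a list of N x 3 matrices per replicate
#' (the adapter contract for binary trajectory readers).
#'
#' @param topology `gik_structure` giving the atom ordering.
#' @param frame_sources list, one element per replicate.
#' @param frame_interval_ns time between stored frames (ns), > 0.
#' @param discard_fraction leading fraction of each replicate that analysis
#'   operations drop as equilibration (default 0.5, matching the exclusion of
#'   the first half of each trajectory).
#' @return object of class `gik_ensemble` with fields topology, replicates
#'   (list of N x 3 x F arrays), frame_interval_ns, discard_fraction.
#' @export
read_ensemble <- function(topology, frame_sources, frame_interval_ns,
                          discard_fraction = 0.5) {
  stopifnot(inherits(topology, "gik_structure"))
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0)
    stop("frame_interval_ns must be > 0")
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  n <- nrow(topology$atoms)
  reps <- vector("list", length(frame_sources))
  for (i in seq_along(frame_sources)) {
    src <- frame_sources[[i]]
    if (is.character(src)) {
      pdb <- bio3d::read.pdb(src, multi = TRUE, verbose = FALSE)
      xyzm <- as.matrix(pdb$xyz)
      if (ncol(xyzm) != 3L * n)
        stop("congruence error: replicate ", i, " has ", ncol(xyzm) / 3,
             " atoms per frame, topology has ", n)
      arr <- array(0, dim = c(n, 3L, nrow(xyzm)))
      for (f in seq_len(nrow(xyzm)))
        arr[, , f] <- matrix(xyzm[f, ], ncol = 3, byrow = TRUE)
    } else if (is.list(src)) {
      bad <- which(vapply(src, nrow, integer(1)) != n)
      if (length(bad) > 0)
        stop("congruence error: replicate ", i, " frame ", bad[1],
             " atom count differs from topology (", n, ")")
      arr <- array(unlist(src), dim = c(n, 3L, length(src)))
      # unlist concatenates column-major per matrix, which matches (n, 3) slices
    } else if (is.array(src) && length(dim(src)) == 3) {
      if (dim(src)[1] != n)
        stop("congruence error: replicate ", i, " has ", dim(src)[1],
             " atoms, topology has ", n)
      arr <- src
    } else stop("unsupported frame source for replicate ", i)
    reps[[i]] <- arr
  }
  structure(list(topology = topology, replicates = reps,
                 frame_interval_ns = frame_interval_ns,
                 discard_fraction = discard_fraction),
            class = "gik_ensemble")
}

#' @export
print.gik_ensemble <- function(x, ...) {
  nf <- vapply(x$replicates, function(r) dim(r)[3], integer(1))
  cat(sprintf("<gik_ensemble: %d replicates x [%s] frames, %d atoms, %.3g ns/frame, discard %.2f>\n",
              length(nf), paste(unique(nf), collapse = ","),
              nrow(x$topology$atoms), x$frame_interval_ns, x$discard_fraction))
  invisible(x)
}

#' Indices of analyzed frames after equilibration discard and stride sampling
#'
#' @param ensemble a `gik_ensemble`.
#' @param stride keep every `stride`-th frame after the discard.
#' @param discard_fraction override the ensemble's own discard fraction.
#' @return data.frame with columns replicate, frame (index within replicate).
#' @export
analyzed_frames <- function(ensemble, stride = 1L, discard_fraction = NULL) {
  if (is.null(discard_fraction)) discard_fraction <- ensemble$discard_fraction
  out <- lapply(seq_along(ensemble$replicates), function(r) {
    nf <- dim(ensemble$replicates[[r]])[3]
    start <- floor(nf * discard_fraction) + 1L
    if (start > nf) return(NULL)
    idx <- seq.int(start, nf, by = stride)
    data.frame(replicate = r, frame = idx)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0)
    stop("empty-analysis error: no frames retained after discard")
  res
}

#' Extract one frame of an ensemble as a Structure
#' @param ensemble a `gik_ensemble`.
#' @param replicate replicate index.
#' @param frame frame index within the replicate.
#' @return a `gik_structure` with that frame's coordinates.
#' @export
ensemble_frame <- function(ensemble, replicate, frame) {
  arr <- ensemble$replicates[[replicate]]
  set_coords(ensemble$topology, arr[, , frame])
}

#' Select atoms of a structure
#'
#' Deterministic, order-stable atom selection over chains, residue numbers,
#' atom names, elements, and (given a numbering map) generic labels. All
#' criteria are combined with AND; `NULL` means "no constraint". Returns an
#' increasing integer index vector; an empty selection is an empty vector,
#' not an error.
#'
#' @param x a `gik_structure`.
#' @param chain chain id(s).
#' @param resnum residue numbers (vector; use e.g. `150:160` for ranges).
#' @param atom atom name(s), e.g. "CA".
#' @param element element symbol(s).
#' @param label generic label(s), e.g. "3.54" or "H5.20"; requires `map`.
#' @param map a `gik_numbering_map` used to resolve `label`.
#' @param segment generic segment(s), e.g. "TM6" or "H5"; requires `map`.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(x, chain = NULL, resnum = NULL, atom = NULL,
                         element = NULL, label = NULL, map = NULL,
                         segment = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resnum)) keep <- keep & a$resnum %in% resnum
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(label) || !is.null(segment)) {
    if (is.null(map)) stop("selection error: generic-label selection needs a numbering map")
    p <- map$pairs
    if (!is.null(label)) {
      lab <- normalize_label(label)
      unknown <- setdiff(lab, p$label)
      if (length(unknown) > 0)
        stop("selection error: unmapped label(s) ", paste(unknown, collapse = ", "))
      p <- p[p$label %in% lab, , drop = FALSE]
    }
    if (!is.null(segment)) p <- p[p$segment %in% segment, , drop = FALSE]
    uid <- res_uid(a)
    keep <- keep & uid %in% paste(p$chain, p$resnum, p$icode, sep = "|")
  }
  which(keep)
}
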