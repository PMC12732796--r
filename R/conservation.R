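# Contact-conservation tables over sets of receptor-Galpha complexes, H5
# sequence conservation across Galpha subfamilies, and the restraint-selection
# funnel used to derive docking restraints for a receptor-Gs complex.

#' Bundle a structure with its numbering maps into a complex record
#'
#' @param id unique identifier (e.g. a PDB id).
#' @param structure a `gik_structure` containing both chains.
#' @param receptor_map BW `gik_numbering_map` for the receptor chain.
#' @param galpha_map CGN `gik_numbering_map` for the Galpha chain.
#' @param family one of "Gs", "Gi", "Gq", "other".
#' @return object of class `gik_complex`.
#' @export
complex_record <- function(id, structure, receptor_map, galpha_map,
                           family = c("Gs", "Gi", "Gq", "other")) {
  family <- match.arg(family)
  for (m in list(receptor_map, galpha_map)) {
    sel <- select_atoms(structure, chain = m$chain)
    if (length(sel) == 0)
      stop("numbering map chain ", m$chain, " absent from structure ", id)
  }
  base::structure(list(id = id, structure = structure,
                       receptor_map = receptor_map, galpha_map = galpha_map,
                       family = family),
                  class = "gik_complex")
}

complex_interface_contacts <- function(cx, cutoff = 4.5, kind = "heavy_atom") {
  ga <- select_atoms(cx$structure, chain = cx$receptor_map$chain)
  gb <- select_atoms(cx$structure, chain = cx$galpha_map$chain)
  heavy_atom_contacts(cx$structure, ga, gb, cutoff = cutoff, kind = kind,
                      map_a = cx$receptor_map, map_b = cx$galpha_map)
}

#' Read a Galpha subfamily alignment keyed by CGN labels
#'
#' TSV with a `family` column and one column per CGN position (column names
#' are CGN labels, dots allowed). One row per Galpha subfamily sequence.
#'
#' @param path TSV path, or the packaged name "galpha_h5_alignment_synthetic".
#' @return character matrix, rownames = families, colnames = CGN labels.
#' @export
read_galpha_alignment <- function(path) {
  p <- if (file.exists(path)) path else
    system.file("extdata", paste0(path, ".tsv"), package = "gik")
  if (!nzchar(p) || !file.exists(p)) stop("alignment not found: ", path)
  tab <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!"family" %in% names(tab))
    stop("alignment-format error: missing 'family' column")
  m <- as.matrix(tab[, setdiff(names(tab), "family"), drop = FALSE])
  rownames(m) <- tab$family
  bad <- !label_valid(colnames(m), "CGN")
  if (any(bad))
    stop("alignment-format error: unkeyed/invalid column(s) ",
         paste(colnames(m)[bad], collapse = ", "))
  colnames(m) <- normalize_label(colnames(m))
  m
}

#' Fully conserved H5 positions across a Galpha subfamily alignment
#'
#' Returns the CGN labels, restricted to segment H5, whose alignment column
#' holds exactly one amino-acid type across all sequences.
#'
#' @param alignment character matrix from [read_galpha_alignment()] or
#'   [make_alignment()].
#' @return character vector of CGN labels, in column order.
#' @export
h5_conserved_positions <- function(alignment) {
  if (is.null(colnames(alignment)) || any(!label_valid(colnames(alignment), "CGN")))
    stop("alignment-format error: columns must be keyed by CGN labels")
  if (nrow(alignment) < 2) stop("alignment needs at least 2 sequences")
  h5 <- grepl("^H5\\.", colnames(alignment))
  conserved <- apply(alignment, 2, function(col) length(unique(col)) == 1)
  colnames(alignment)[h5 & conserved]
}

galpha_positions_with_receptor_contact <- function(cx, cutoff) {
  cc <- complex_interface_contacts(cx, cutoff = cutoff)
  unique(cc$label_b[!is.na(cc$label_b)])
}

#' Galpha positions contacting the receptor in both a Gi set and a Gs set
#'
#' A candidate CGN position is shared when it forms at least one receptor
#' contact in at least `membership` of the complexes of BOTH sets
#' ("any" = one complex suffices, "majority" = more than half).
#'
#' @param gi_set,gs_set lists of `gik_complex` records.
#' @param candidate candidate CGN labels (e.g. conserved H5 positions).
#' @param cutoff contact cutoff (A).
#' @param membership "any" or "majority".
#' @return character vector (subset of `candidate`, original order).
#' @export
shared_interface_positions <- function(gi_set, gs_set, candidate,
                                       cutoff = 4.5,
                                       membership = c("any", "majority")) {
  membership <- match.arg(membership)
  if (length(gi_set) == 0 || length(gs_set) == 0)
    stop("empty-set error: both complex sets must be non-empty")
  candidate <- normalize_label(candidate)
  if (length(candidate) == 0) return(character())
  hit_frac <- function(set, lab) {
    mean(vapply(set, function(cx)
      lab %in% galpha_positions_with_receptor_contact(cx, cutoff), logical(1)))
  }
  thr <- if (membership == "any") 0 else 0.5
  keep <- vapply(candidate, function(lab)
    hit_frac(gi_set, lab) > thr && hit_frac(gs_set, lab) > thr, logical(1))
  candidate[keep]
}

#' Contact-conservation table over a complex set
#'
#' Every generic (receptor label, Galpha label) pair occurring in at least
#' one complex of the set is tabulated with the exact count of complexes in
#' which it occurs.
#'
#' @param set list of annotated `gik_complex` records with unique ids.
#' @param cutoff contact cutoff (A).
#' @param kind contact kind ("heavy_atom" or "polar").
#' @return data.frame receptor_label, galpha_label, n_present, n_total,
#'   fraction; sorted by fraction desc then labels.
#' @export
build_conservation_table <- function(set, cutoff = 4.5, kind = "heavy_atom") {
  ids <- vapply(set, function(cx) cx$id, character(1))
  if (anyDuplicated(ids)) stop("input error: duplicate complex ids")
  n_total <- length(set)
  pairs <- lapply(set, function(cx) {
    cc <- complex_interface_contacts(cx, cutoff = cutoff, kind = kind)
    cc <- cc[!is.na(cc$label_a) & !is.na(cc$label_b), , drop = FALSE]
    unique(paste(cc$label_a, cc$label_b, sep = "~"))
  })
  tab <- table(unlist(pairs))
  if (length(tab) == 0)
    return(data.frame(receptor_label = character(), galpha_label = character(),
                      n_present = integer(), n_total = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(tab), "~", fixed = TRUE))
  out <- data.frame(receptor_label = parts[, 1], galpha_label = parts[, 2],
                    n_present = as.integer(tab), n_total = n_total,
                    fraction = as.integer(tab) / n_total,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$receptor_label, out$galpha_label), , drop = FALSE]
}

#' Pairs conserved in at least a given fraction of the complex set
#'
#' @param table output of [build_conservation_table()].
#' @param min_fraction threshold in (0, 1] (the conserved class A
#'   receptor-Gs analysis uses 0.77).
#' @return subset of `table`, sorted by fraction desc then labels.
#' @export
conserved_pairs <- function(table, min_fraction = 0.77) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("precondition error: min_fraction must be in (0, 1]")
  out <- table[table$fraction >= min_fraction, , drop = FALSE]
  out[order(-out$fraction, out$receptor_label, out$galpha_label), , drop = FALSE]
}

#' Check which reference contact pairs a model complex preserves
#'
#' Partitions the reference pairs into preserved / missing / unmappable
#' (labels absent from the model's numbering maps are reported, never
#' silently dropped). The partition is exhaustive and disjoint.
#'
#' @param model a `gik_complex`.
#' @param reference_pairs data.frame with columns receptor_label,
#'   galpha_label.
#' @param cutoff contact cutoff (A).
#' @return list(preserved, missing, unmappable) of data.frames.
#' @export
check_model_contacts <- function(model, reference_pairs, cutoff = 4.5) {
  rp <- data.frame(receptor_label = normalize_label(reference_pairs$receptor_label),
                   galpha_label = normalize_label(reference_pairs$galpha_label),
                   stringsAsFactors = FALSE)
  mappable <- rp$receptor_label %in% model$receptor_map$pairs$label &
    rp$galpha_label %in% model$galpha_map$pairs$label
  cc <- complex_interface_contacts(model, cutoff = cutoff)
  present_keys <- paste(cc$label_a, cc$label_b, sep = "~")
  keys <- paste(rp$receptor_label, rp$galpha_label, sep = "~")
  preserved <- mappable & keys %in% present_keys
  list(preserved = rp[preserved, , drop = FALSE],
       missing = rp[mappable & !preserved, , drop = FALSE],
       unmappable = rp[!mappable, , drop = FALSE])
}

#' Restraint-selection funnel for receptor-Galpha docking
#'
#' Composes three stages: (1) H5 positions fully conserved across Galpha
#' subfamilies; (2) of those, positions contacting the receptor in both the
#' Gi-bound and Gs-bound complex sets; (3) of those, positions whose receptor
#' contact is consistent - i.e. the position contacts some receptor position
#' in at least `conservation_min` of the complexes of each set. Surviving
#' positions are paired with their modal receptor partner (most frequent
#' partner label over both sets, ties by label order) and mapped onto the
#' target receptor/Galpha chains as residue-level restraints.
#'
#' @param alignment Galpha subfamily alignment (CGN-keyed matrix).
#' @param gi_set,gs_set lists of `gik_complex` records.
#' @param receptor_map,galpha_map numbering maps of the docking target pair.
#' @param cutoff contact cutoff (A).
#' @param conservation_min per-set consistency threshold (default 0.77).
#' @param max_distance restraint radius emitted with each pair (A).
#' @return object of class `gik_restraints`: list with `stages` (named
#'   survivor counts), `survivors` (per-stage label lists), and `restraints`
#'   (data.frame galpha_label, receptor_label, galpha_resnum,
#'   receptor_resnum, max_distance); if no position survives, `restraints`
#'   has zero rows and `status` is "no restraints derivable".
#' @export
select_restraints <- function(alignment, gi_set, gs_set,
                              receptor_map, galpha_map,
                              cutoff = 4.5, conservation_min = 0.77,
                              max_distance = 5.0) {
  stage1 <- h5_conserved_positions(alignment)
  stage2 <- if (length(stage1) > 0)
    shared_interface_positions(gi_set, gs_set, stage1, cutoff = cutoff)
  else character()
  consistency <- function(set, lab) {
    mean(vapply(set, function(cx)
      lab %in% galpha_positions_with_receptor_contact(cx, cutoff), logical(1)))
  }
  stage3 <- stage2[vapply(stage2, function(lab)
    consistency(gi_set, lab) >= conservation_min &&
      consistency(gs_set, lab) >= conservation_min, logical(1))]
  modal_partner <- function(lab) {
    partners <- unlist(lapply(c(gi_set, gs_set), function(cx) {
      cc <- complex_interface_contacts(cx, cutoff = cutoff)
      cc$label_a[!is.na(cc$label_b) & cc$label_b == lab & !is.na(cc$label_a)]
    }))
    if (length(partners) == 0) return(NA_character_)
    tt <- table(partners)
    names(tt)[which.max(tt)]  # ties: first in label sort order
  }
  restraints <- data.frame(galpha_label = character(),
                           receptor_label = character(),
                           galpha_resnum = integer(),
                           receptor_resnum = integer(),
                           max_distance = numeric(), stringsAsFactors = FALSE)
  for (lab in stage3) {
    partner <- modal_partner(lab)
    if (is.na(partner)) next
    gres <- tryCatch(to_residue(galpha_map, lab), error = function(e) NULL)
    rres <- tryCatch(to_residue(receptor_map, partner), error = function(e) NULL)
    if (is.null(gres) || is.null(rres)) next
    restraints <- rbind(restraints, data.frame(
      galpha_label = lab, receptor_label = partner,
      galpha_resnum = gres$resnum, receptor_resnum = rres$resnum,
      max_distance = max_distance, stringsAsFactors = FALSE))
  }
  base::structure(list(
    stages = c(conserved_h5 = length(stage1),
               shared_interface = length(stage2),
               consistent_contact = length(stage3)),
    survivors = list(conserved_h5 = stage1, shared_interface = stage2,
                     consistent_contact = stage3),
    restraints = restraints,
    status = if (nrow(restraints) == 0) "no restraints derivable" else "ok",
    params = list(cutoff = cutoff, conservation_min = conservation_min,
                  max_distance = max_distance)),
    class = "gik_restraints")
}

#' @export
print.gik_restraints <- function(x, ...) {
  cat(sprintf("<gik_restraints: funnel %s; %d restraint pair(s); cutoff %.1f A, conservation_min %.2f>\n",
              paste(x$stages, collapse = " -> "), nrow(x$restraints),
              x$params$cutoff, x$params$conservation_min))
  if (nrow(x$restraints) > 0) print(x$restraints)
  invisible(x)
}

#' Docking-score combination helper (documented metadata)
#'
#' Applies the published weighted-score combination
#' E = 0.40 E_rep - 0.40 E_att + 600 E_elect + 1.00 E_dars
#' to user-supplied component energies. Computing the component energies is
#' out of scope; this records the weighting convention under which the
#' docking model pool was scored.
#'
#' @param e_rep,e_att,e_elect,e_dars component energies.
#' @return weighted score.
#' @export
cluspro_weighted_score <- function(e_rep, e_att, e_elect, e_dars) {
  0.40 * e_rep + (-0.40) * e_att + 600 * e_elect + 1.00 * e_dars
}
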