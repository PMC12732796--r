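# End-to-end workflow drivers: restraint selection and ensemble report.
# Every numeric report carries the parameter values that produced it.

#' Run configuration for the workflow drivers
#'
#' @param contact_cutoff heavy-atom contact cutoff (A).
#' @param hbond_cutoff donor-acceptor cutoff (A).
#' @param hbond_angle D-H...A linearity tolerance (degrees).
#' @param polar_cutoff side-chain N/O contact cutoff (A).
#' @param cluster_cutoff GROMOS neighbor RMSD cutoff (A).
#' @param conservation_min conservation threshold for restraint selection.
#' @param min_occupancy occupancy report threshold.
#' @param discard_fraction equilibration discard for file-based ensembles.
#' @param block_size block length (frames) for block-averaged RMSD.
#' @param seed RNG seed for synthetic scenarios.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class `gik_config`.
#' @export
run_config <- function(contact_cutoff = 4.5, hbond_cutoff = 3.0,
                       hbond_angle = 20, polar_cutoff = 4.0,
                       cluster_cutoff = 1.5, conservation_min = 0.77,
                       min_occupancy = 0.05, discard_fraction = 0.5,
                       block_size = 50L, seed = 1L, out_dir = NULL) {
  cfg <- list(contact_cutoff = contact_cutoff, hbond_cutoff = hbond_cutoff,
              hbond_angle = hbond_angle, polar_cutoff = polar_cutoff,
              cluster_cutoff = cluster_cutoff,
              conservation_min = conservation_min,
              min_occupancy = min_occupancy,
              discard_fraction = discard_fraction,
              block_size = as.integer(block_size), seed = as.integer(seed),
              out_dir = out_dir)
  stopifnot(contact_cutoff > 0, hbond_cutoff > 0, polar_cutoff > 0,
            cluster_cutoff > 0, conservation_min > 0, conservation_min <= 1,
            min_occupancy >= 0, min_occupancy <= 1,
            discard_fraction >= 0, discard_fraction < 1)
  class(cfg) <- "gik_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restraint-selection workflow
#'
#' Composes the conservation operations over a Galpha subfamily alignment
#' and Gi/Gs complex sets, reporting per-stage survivor counts and the final
#' residue-level restraint pairs. With no inputs, the packaged synthetic
#' demo fixtures are used (alignment with seven conserved H5 positions; demo
#' Gs/Gi complex sets; demo model complex as the docking target).
#'
#' @param config a `gik_config`.
#' @param alignment CGN-keyed alignment matrix (default: packaged fixture).
#' @param gi_set,gs_set complex sets (default: [demo_complex_sets()]).
#' @param receptor_map,galpha_map target maps (default: demo model's).
#' @return list of class `gik_restraint_report`: the `gik_restraints`
#'   object, the stage counts, and the parameters used. Written as TSV +
#'   JSON when `config$out_dir` is set.
#' @export
run_restraint_workflow <- function(config = run_config(),
                                   alignment = NULL,
                                   gi_set = NULL, gs_set = NULL,
                                   receptor_map = NULL, galpha_map = NULL) {
  if (is.null(alignment))
    alignment <- read_galpha_alignment("galpha_h5_alignment_synthetic")
  if (is.null(gi_set) || is.null(gs_set)) {
    sets <- demo_complex_sets()
    if (is.null(gi_set)) gi_set <- sets$gi
    if (is.null(gs_set)) gs_set <- sets$gs
  }
  if (length(gi_set) == 0 || length(gs_set) == 0)
    stop("empty-set error: restraint workflow needs non-empty complex sets")
  if (is.null(receptor_map) || is.null(galpha_map)) {
    model <- demo_model_complex()
    if (is.null(receptor_map)) receptor_map <- model$receptor_map
    if (is.null(galpha_map)) galpha_map <- model$galpha_map
  }
  res <- select_restraints(alignment, gi_set, gs_set,
                           receptor_map, galpha_map,
                           cutoff = config$contact_cutoff,
                           conservation_min = config$conservation_min)
  report <- list(restraints = res, stages = res$stages,
                 params = config[c("contact_cutoff", "conservation_min")])
  class(report) <- "gik_restraint_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res$restraints, file.path(config$out_dir, "restraints.tsv"))
    jsonlite::write_json(
      list(stages = as.list(res$stages),
           survivors = res$survivors,
           restraints = res$restraints,
           params = report$params, status = res$status),
      file.path(config$out_dir, "restraints.json"), auto_unbox = TRUE,
      digits = NA)
  }
  report
}

#' @export
print.gik_restraint_report <- function(x, ...) {
  cat("Restraint-selection workflow\n")
  cat(sprintf("  funnel: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  contact cutoff %.1f A, conservation threshold %.2f\n",
              x$params$contact_cutoff, x$params$conservation_min))
  print(x$restraints$restraints)
  invisible(x)
}

#' Ensemble analysis report
#'
#' Composes clustering of the alpha5-helix position, interface contact
#' occupancies, per-residue contact counts, the TM2-TM6 opening series, and
#' block-averaged RMSD statistics over one trajectory ensemble, into a
#' single self-describing summary.
#'
#' @param ensemble a `gik_ensemble` whose topology is a complex from
#'   [make_complex()] (attribute "complex"), or pass `complex` explicitly.
#' @param config a `gik_config`.
#' @param complex the annotated `gik_complex` matching the topology.
#' @param cluster_segment CGN segment clustered for helix position ("H5").
#' @param tm_labels the TM-opening label pair.
#' @return list of class `gik_ensemble_report` with elements clusters,
#'   occupancy, contact_counts (NULL unless labels given), tm_distance
#'   (summary + series), block_rmsd, params. TSV/JSON written when
#'   `config$out_dir` is set.
#' @export
run_ensemble_report <- function(ensemble, config = run_config(),
                                complex = NULL,
                                cluster_segment = "H5",
                                tm_labels = c("6.33", "2.39")) {
  if (is.null(complex)) complex <- attr(ensemble, "complex")
  if (is.null(complex)) stop("input error: need the annotated complex")
  top <- ensemble$topology
  rmap <- complex$receptor_map; gmap <- complex$galpha_map
  sel_h5 <- intersect(select_atoms(top, segment = cluster_segment, map = gmap),
                      select_atoms(top, atom = "CA"))
  clusters <- cluster_frames(ensemble, sel_h5,
                             rmsd_cutoff = config$cluster_cutoff)
  ga <- select_atoms(top, chain = rmap$chain)
  gb <- select_atoms(top, chain = gmap$chain)
  occ <- occupancy_map(ensemble, ga, gb, kind = "polar",
                       cutoff = config$polar_cutoff,
                       min_occupancy = config$min_occupancy,
                       map_a = rmap, map_b = gmap)
  tm <- tm_distance_series(ensemble, rmap, tm_labels[1], tm_labels[2])
  series <- rmsd_series(ensemble, sel_h5, superpose = TRUE)
  nframes <- length(series[[1]]$values)
  bs <- min(config$block_size, max(1L, nframes))
  blocks <- block_stats(series, bs)
  params <- config[c("contact_cutoff", "polar_cutoff", "cluster_cutoff",
                     "min_occupancy", "block_size", "seed")]
  params$analyzed_frames <- length(clusters$assignments)
  report <- list(clusters = clusters, occupancy = occ,
                 tm_distance = list(labels = tm_labels,
                                    mean = mean(tm$distance),
                                    median = stats::median(tm$distance),
                                    series = tm),
                 block_rmsd = blocks, params = params)
  class(report) <- "gik_ensemble_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(clusters$populations, file.path(config$out_dir, "clusters.tsv"))
    write_tsv(occ, file.path(config$out_dir, "occupancy.tsv"))
    write_tsv(tm, file.path(config$out_dir, "tm_distance.tsv"))
    write_tsv(blocks$per_replicate, file.path(config$out_dir, "block_rmsd.tsv"))
    jsonlite::write_json(summary_list(report),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

summary_list <- function(x) {
  list(
    clusters = utils::head(x$clusters$populations, 10),
    cluster_cutoff = x$clusters$rmsd_cutoff,
    n_occupancy_pairs = nrow(x$occupancy),
    tm_labels = x$tm_distance$labels,
    tm_mean = x$tm_distance$mean,
    tm_median = x$tm_distance$median,
    block_rmsd = list(block_size = x$block_rmsd$block_size_frames,
                      ensemble_mean = x$block_rmsd$ensemble_mean,
                      ensemble_sem = x$block_rmsd$ensemble_sem),
    params = x$params)
}

#' @export
print.gik_ensemble_report <- function(x, ...) {
  cat("Ensemble analysis report\n")
  cat(sprintf("  %d analyzed frames; cluster cutoff %.2f A\n",
              x$params$analyzed_frames, x$params$cluster_cutoff))
  print(utils::head(x$clusters$populations, 3))
  cat(sprintf("  %d contact pairs above occupancy %.2f\n",
              nrow(x$occupancy), x$params$min_occupancy))
  cat(sprintf("  TM %s-%s distance mean %.1f A\n", x$tm_distance$labels[1],
              x$tm_distance$labels[2], x$tm_distance$mean))
  cat(sprintf("  block RMSD: %.2f +/- %.2f A (%d-frame blocks)\n",
              x$block_rmsd$ensemble_mean, x$block_rmsd$ensemble_sem,
              x$block_rmsd$block_size_frames))
  invisible(x)
}
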