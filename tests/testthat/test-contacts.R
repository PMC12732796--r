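two_residue_pair <- function(gap) {
  # residue 1 (chain R) and residue 2 (chain G) with closest heavy atoms at
  # exactly `gap` Angstrom
  tiny_structure(chain = c("R", "R", "G", "G"),
                 resnum = c(1, 1, 2, 2),
                 atom = c("CA", "CB", "CA", "CB"),
                 element = c("C", "C", "C", "C"),
                 xyz = rbind(c(0, 0, 0), c(1.5, 0, 0),
                             c(1.5 + gap + 1.5, 0, 0), c(1.5 + gap, 0, 0)))
}

test_that("contact decision is an exact threshold on the closest heavy-atom pair", {
  st <- two_residue_pair(4.0)
  ga <- select_atoms(st, chain = "R"); gb <- select_atoms(st, chain = "G")
  hit <- heavy_atom_contacts(st, ga, gb, cutoff = 4.5)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_distance, 4.0, tolerance = 1e-12)
  expect_equal(nrow(heavy_atom_contacts(st, ga, gb, cutoff = 3.5)), 0)
  expect_error(heavy_atom_contacts(st, integer(), gb), "empty-selection")
  expect_error(heavy_atom_contacts(st, ga, ga), "disjoint")
})

test_that("contact search equals the brute-force double loop on planted complexes", {
  cx <- demo_model_complex()
  st <- cx$structure
  ga <- select_atoms(st, chain = "R"); gb <- select_atoms(st, chain = "G")
  # cutoffs chosen away from the planted 3.0 A distance so the oracle
  # comparison never sits on a floating-point knife edge
  for (cutoff in c(2.5, 3.2, 4.5, 6.0, 9.0)) {
    fast <- heavy_atom_contacts(st, ga, gb, cutoff = cutoff)
    slow <- brute_contacts(st, ga, gb, cutoff = cutoff)
    if (is.null(slow)) {
      expect_equal(nrow(fast), 0)
    } else {
      fk <- sort(paste(fast$chain_a, fast$resnum_a, fast$chain_b, fast$resnum_b))
      sk <- do.call(rbind, strsplit(c(slow$key_a, slow$key_b), "|", fixed = TRUE))
      nslow <- nrow(slow)
      sk2 <- sort(paste(sk[1:nslow, 1], sk[1:nslow, 2],
                        sk[nslow + 1:nslow, 1], sk[nslow + 1:nslow, 2]))
      expect_equal(fk, sk2)
      expect_equal(sort(fast$min_distance), sort(slow$min_distance),
                   tolerance = 1e-9)
    }
  }
})

test_that("contact sets are symmetric in the group arguments", {
  cx <- demo_model_complex()
  st <- cx$structure
  ga <- select_atoms(st, chain = "R"); gb <- select_atoms(st, chain = "G")
  ab <- heavy_atom_contacts(st, ga, gb, map_a = cx$receptor_map,
                            map_b = cx$galpha_map)
  ba <- heavy_atom_contacts(st, gb, ga, map_a = cx$galpha_map,
                            map_b = cx$receptor_map)
  expect_setequal(paste(ab$label_a, ab$label_b), paste(ba$label_b, ba$label_a))
  expect_equal(sort(ab$min_distance), sort(ba$min_distance), tolerance = 1e-12)
})

test_that("contacts and occupancies are invariant under a common rigid motion", {
  pc <- data.frame(receptor_label = c("3.54", "5.65"),
                   galpha_label = c("H5.20", "H5.20"), stringsAsFactors = FALSE)
  cx <- make_complex(pc)
  st <- cx$structure
  ga <- select_atoms(st, chain = "R"); gb <- select_atoms(st, chain = "G")
  set.seed(1)
  st2 <- rigid_transform_structure(st, random_rotation(), c(11, -4, 7))
  c1 <- heavy_atom_contacts(st, ga, gb)
  c2 <- heavy_atom_contacts(st2, ga, gb)
  expect_equal(c1[, 1:6], c2[, 1:6])
  expect_equal(c1$min_distance, c2$min_distance, tolerance = 1e-6)
})

test_that("hydrogen-bond criterion gates on distance and linearity", {
  ok <- make_hbond_probe(2.8, 5)
  expect_true(as.logical(hbond_present(ok$structure, ok$donor, ok$hydrogen,
                                       ok$acceptor)))
  far <- make_hbond_probe(3.4, 5)
  expect_false(as.logical(hbond_present(far$structure, far$donor, far$hydrogen,
                                        far$acceptor)))
  bent <- make_hbond_probe(2.8, 35)
  expect_false(as.logical(hbond_present(bent$structure, bent$donor,
                                        bent$hydrogen, bent$acceptor)))
  # planted geometry is exact
  hb <- hbond_present(ok$structure, ok$donor, ok$hydrogen, ok$acceptor)
  expect_equal(attr(hb, "distance"), 2.8, tolerance = 1e-9)
  expect_equal(attr(hb, "deviation"), 5, tolerance = 1e-9)
  expect_error(hbond_present(ok$structure, ok$donor, NA, ok$acceptor),
               "heavy-atom-only fallback")
})

test_that("occupancy equals the planted per-frame presence exactly", {
  pc <- data.frame(receptor_label = c("3.54", "6.33"),
                   galpha_label = c("H5.20", "H5.25"),
                   prob = c(1.0, 0.3), stringsAsFactors = FALSE)
  ens <- make_ensemble(small_scenario(seed = 9, contacts = pc))
  cx <- attr(ens, "complex"); top <- ens$topology
  ga <- select_atoms(top, chain = "R"); gb <- select_atoms(top, chain = "G")
  occ <- occupancy_map(ens, ga, gb, min_occupancy = 0.05,
                       map_a = cx$receptor_map, map_b = cx$galpha_map)
  truth <- attr(ens, "truth")
  n <- 3 * 80
  expect_equal(occ$occupancy[occ$label_b == "H5.20"], 1.0)
  expect_equal(occ$occupancy[occ$label_b == "H5.25"],
               truth$contact_on[2] / n)
  # always-on contact survives any discard fraction
  occ2 <- occupancy_map(ens, ga, gb, min_occupancy = 0.05,
                        discard_fraction = 0.5,
                        map_a = cx$receptor_map, map_b = cx$galpha_map)
  expect_equal(occ2$occupancy[occ2$label_b == "H5.20"], 1.0)
  expect_equal(unique(occ2$frames_total), 120L)
  # occupancy bounds and the monotone sort contract
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  expect_true(all(diff(occ$occupancy) <= 0))
  expect_equal(occ$occupancy, occ$frames_present / occ$frames_total)
})

test_that("the occupancy threshold retains a pair sitting exactly at 0.05", {
  # planted in exactly 26 of 520 retained frames
  counts <- c(rep(1, 26), rep(0, 494))
  expect_equal(mean(counts), 0.05)
  pc <- data.frame(receptor_label = "3.54", galpha_label = "H5.20",
                   prob = 1, stringsAsFactors = FALSE)
  spec <- scenario_spec(seed = 2, n_replicates = 1L,
                        frames_per_replicate = 520L, planted_contacts = pc,
                        noise_sigma = 0)
  ens <- make_ensemble(spec)
  # overwrite the planted atom per frame so presence is exactly 26/520
  planted <- attr(attr(ens, "complex"), "planted")
  arr <- ens$replicates[[1]]
  off <- c(planted$off_x[1], planted$off_y[1], planted$off_z[1])
  on <- c(planted$on_x[1], planted$on_y[1], planted$on_z[1])
  for (f in 1:520) arr[planted$atom_row[1], , f] <- if (f <= 26) on else off
  ens$replicates[[1]] <- arr
  top <- ens$topology; cx <- attr(ens, "complex")
  occ <- occupancy_map(ens, select_atoms(top, chain = "R"),
                       select_atoms(top, chain = "G"), min_occupancy = 0.05,
                       map_a = cx$receptor_map, map_b = cx$galpha_map)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 0.05)
  expect_equal(occ$frames_present, 26L)
})

test_that("per-residue contact counts find the anchoring pocket and ordering", {
  pk <- demo_pocket_complex()
  st <- pk$structure
  gb <- select_atoms(st, chain = "G")
  counts <- per_residue_contact_counts(list(st), c("34.51", "34.52", "34.50"),
                                       pk$receptor_map, gb)
  expect_equal(counts$mean_count[counts$label == "34.51"], 5)
  expect_equal(counts$mean_count[counts$label == "34.52"], 1)
  expect_equal(counts$mean_count[counts$label == "34.50"], 0)
  expect_true(counts$is_max[counts$label == "34.51"])
  # dense ensemble interface vs sparse static interface ordering
  pc_dense <- data.frame(
    receptor_label = c("34.51", "34.51", "34.52"),
    galpha_label = c("H5.08", "H5.12", "H5.15"), stringsAsFactors = FALSE)
  ens <- make_ensemble(small_scenario(seed = 3, contacts = pc_dense))
  cxe <- attr(ens, "complex")
  dense <- per_residue_contact_counts(
    ens, c("34.51", "34.52"), cxe$receptor_map,
    select_atoms(ens$topology, chain = "G"))
  pc_sparse <- data.frame(receptor_label = "34.52", galpha_label = "H5.15",
                          stringsAsFactors = FALSE)
  cxs <- make_complex(pc_sparse, id = "sparse", family = "Gi")
  sparse <- per_residue_contact_counts(
    list(cxs$structure), c("34.51", "34.52"), cxs$receptor_map,
    select_atoms(cxs$structure, chain = "G"))
  expect_gt(sum(dense$mean_count), sum(sparse$mean_count))
})
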