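test_that("generators are deterministic in (arguments, seed)", {
  h1 <- make_helix(10, origin = c(1, 2, 3), direction = c(0, 1, 0))
  h2 <- make_helix(10, origin = c(1, 2, 3), direction = c(0, 1, 0))
  expect_identical(coords(h1), coords(h2))
  a1 <- make_alignment(5, c("H5.01", "H5.20"), seed = 3)
  a2 <- make_alignment(5, c("H5.01", "H5.20"), seed = 3)
  expect_identical(a1, a2)
  s <- small_scenario(seed = 17)
  e1 <- make_ensemble(s); e2 <- make_ensemble(s)
  expect_identical(e1$replicates, e2$replicates)
  # the scenario RNG stream does not leak into the session RNG
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_ensemble(small_scenario(seed = 99)))
  expect_identical(rnorm(1), before)
})

test_that("ideal helix closes the loop with the axis and distance operations", {
  h <- make_helix(26)
  ca <- coords(h)[select_atoms(h, atom = "CA"), ]
  expect_gte(sum(helix_axis(ca)$axis * c(0, 0, 1)), 0.999)
  expect_error(make_helix(3), "parameter error")
  # per-residue atom complement: minimal backbone + one side-chain pseudo-atom
  expect_equal(unique(table(h$atoms$resnum)), 4L)
  expect_setequal(unique(h$atoms$atom), c("N", "CA", "C", "CB"))
})

test_that("planted contacts are realized exactly and exclusively", {
  pc <- data.frame(receptor_label = c("3.50", "5.65"),
                   galpha_label = c("H5.23", "H5.20"),
                   stringsAsFactors = FALSE)
  cx <- make_complex(pc)
  st <- cx$structure
  cc <- heavy_atom_contacts(st, select_atoms(st, chain = "R"),
                            select_atoms(st, chain = "G"),
                            map_a = cx$receptor_map, map_b = cx$galpha_map)
  expect_setequal(paste(cc$label_a, cc$label_b),
                  c("3.50 H5.23", "5.65 H5.20"))
  # zero-contact complex has an empty interface
  cx0 <- make_complex(NULL)
  cc0 <- heavy_atom_contacts(cx0$structure,
                             select_atoms(cx0$structure, chain = "R"),
                             select_atoms(cx0$structure, chain = "G"))
  expect_equal(nrow(cc0), 0)
  # overloading one residue beyond its side-chain capacity is refused
  too_many <- data.frame(
    receptor_label = c("3.44", "3.46", "3.48", "3.50", "3.52", "3.54", "5.65"),
    galpha_label = rep("H5.23", 7), stringsAsFactors = FALSE)
  expect_error(make_complex(too_many), "generation error")
})

test_that("a set with a pair planted in five of six complexes shows 5/6 conservation", {
  mk <- function(i) {
    pc <- if (i <= 5)
      data.frame(receptor_label = "3.54", galpha_label = "H5.20")
    else NULL
    make_complex(pc, id = sprintf("C%02d", i))
  }
  set6 <- lapply(1:6, mk)
  tab <- build_conservation_table(set6)
  expect_equal(tab$fraction[tab$receptor_label == "3.54" &
                              tab$galpha_label == "H5.20"], 5 / 6)
})

test_that("ensemble shapes, frame policy and planted-contact limits hold", {
  pc <- data.frame(receptor_label = "3.54", galpha_label = "H5.20",
                   prob = 1, stringsAsFactors = FALSE)
  spec <- small_scenario(seed = 8, contacts = pc)
  ens <- make_ensemble(spec)
  expect_length(ens$replicates, 3)
  expect_equal(unique(vapply(ens$replicates, function(r) dim(r)[3], integer(1))),
               80L)
  # p = 1 contact stays at occupancy 1 under any discard fraction
  top <- ens$topology; cx <- attr(ens, "complex")
  for (df in c(0, 0.5)) {
    occ <- occupancy_map(ens, select_atoms(top, chain = "R"),
                         select_atoms(top, chain = "G"),
                         discard_fraction = df, min_occupancy = 0.05,
                         map_a = cx$receptor_map, map_b = cx$galpha_map)
    expect_equal(occ$occupancy[occ$label_a == "3.54" & occ$label_b == "H5.20"], 1)
  }
  expect_error(scenario_spec(basins = list(
    list(fraction = 0.8, displacement = c(0, 0, 0), rotation = 0),
    list(fraction = 0.4, displacement = c(1, 0, 0), rotation = 0))),
    "spec error")
  expect_error(scenario_spec(noise_sigma = -1), "spec error")
  bad_pc <- data.frame(receptor_label = "3.54", galpha_label = "H5.20",
                       prob = 1.2)
  expect_error(scenario_spec(planted_contacts = bad_pc), "spec error")
})

test_that("alignment generator plants exactly the requested invariant columns", {
  planted <- c("H5.02", "H5.11", "H5.26")
  for (seed in c(1, 2, 3)) {
    aln <- make_alignment(6, planted, seed = seed)
    expect_setequal(h5_conserved_positions(aln), planted)
  }
  expect_length(h5_conserved_positions(make_alignment(5, character(0), 2)), 0)
  # duplicated family sequences conserve every column
  dup <- make_alignment(2, sprintf("H5.%02d", 1:26), seed = 1)
  expect_length(h5_conserved_positions(dup), 26)
  expect_error(make_alignment(4, "S3.01"), "H5 grammar")
})

test_that("hbond probes and planted hbond contacts carry exact geometry", {
  pc <- data.frame(receptor_label = "3.54", galpha_label = "H5.20",
                   kind = "hbond", stringsAsFactors = FALSE)
  cx <- make_complex(pc)
  st <- cx$structure
  don <- which(st$atoms$chain == "G" & startsWith(st$atoms$atom, "XO"))
  hyd <- which(st$atoms$chain == "G" & startsWith(st$atoms$atom, "HX"))
  acc <- which(st$atoms$chain == "R" & startsWith(st$atoms$atom, "OG"))
  expect_length(don, 1); expect_length(hyd, 1); expect_length(acc, 1)
  hb <- hbond_present(st, don, hyd, acc)
  expect_true(as.logical(hb))
  expect_equal(attr(hb, "distance"), 2.8, tolerance = 1e-9)
  expect_lt(attr(hb, "deviation"), 1e-6)
  # ensemble-level hydrogen-bond occupancy recovers the Bernoulli planting
  pc2 <- data.frame(receptor_label = "3.54", galpha_label = "H5.20",
                    kind = "hbond", prob = 0.6, stringsAsFactors = FALSE)
  ens <- make_ensemble(small_scenario(seed = 23, contacts = pc2))
  cxe <- attr(ens, "complex"); top <- ens$topology
  occ <- occupancy_map(ens, select_atoms(top, chain = "R"),
                       select_atoms(top, chain = "G"), kind = "hbond",
                       min_occupancy = 0.05,
                       map_a = cxe$receptor_map, map_b = cxe$galpha_map)
  truth <- attr(ens, "truth")
  expect_equal(occ$occupancy[occ$label_a == "3.54"],
               truth$contact_on[1] / 240, tolerance = 0.02)
})
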