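test_that("H5 conservation finds exactly the invariant columns", {
  planted <- c("H5.01", "H5.03", "H5.07", "H5.08", "H5.13", "H5.20", "H5.25")
  aln <- read_galpha_alignment("galpha_h5_alignment_synthetic")
  expect_setequal(h5_conserved_positions(aln), planted)
  # generator agrees with the packaged fixture's planting
  aln2 <- make_alignment(6, planted, seed = 99)
  expect_setequal(h5_conserved_positions(aln2), planted)
  # degenerate alignments
  allsame <- matrix("L", 3, 26,
                    dimnames = list(NULL, sprintf("H5.%02d", 1:26)))
  expect_length(h5_conserved_positions(allsame), 26)
  set.seed(1)
  alldiff <- make_alignment(4, character(0), seed = 4)
  expect_length(h5_conserved_positions(alldiff), 0)
  bad <- matrix("A", 2, 2, dimnames = list(NULL, c("H5.01", "foo")))
  expect_error(h5_conserved_positions(bad), "alignment-format")
  expect_error(h5_conserved_positions(allsame[1, , drop = FALSE]),
               "2 sequences")
})

test_that("shared interface positions require contacts in both family sets", {
  sets <- demo_complex_sets()
  cand <- c("H5.01", "H5.03", "H5.07", "H5.08", "H5.13", "H5.20", "H5.25")
  shared <- shared_interface_positions(sets$gi, sets$gs, cand)
  expect_setequal(shared, c("H5.08", "H5.13", "H5.20", "H5.25"))
  # H5.16 contacts the receptor only in the Gs set
  expect_length(shared_interface_positions(sets$gi, sets$gs, "H5.16"), 0)
  expect_length(shared_interface_positions(sets$gi, sets$gs, character(0)), 0)
  expect_error(shared_interface_positions(list(), sets$gs, cand), "empty-set")
  # majority criterion drops the sporadic positions
  maj <- shared_interface_positions(sets$gi, sets$gs, cand,
                                    membership = "majority")
  expect_setequal(maj, c("H5.20", "H5.25"))
})

test_that("conservation table counts match planting and a brute-force recount", {
  sets <- demo_complex_sets()
  tab <- build_conservation_table(sets$gs)
  expect_true(all(tab$n_total == 6))
  expect_equal(tab$fraction, tab$n_present / tab$n_total)
  get_frac <- function(r, g) tab$fraction[tab$receptor_label == r &
                                            tab$galpha_label == g]
  expect_equal(get_frac("3.50", "H5.23"), 1.0)
  expect_equal(get_frac("3.53", "H5.23"), 5 / 6)
  expect_equal(get_frac("6.33", "H5.25"), 4 / 6)
  expect_equal(get_frac("34.51", "H5.08"), 1 / 6)
  # brute-force recount over every complex
  recount <- new.env(parent = emptyenv())
  for (cx in sets$gs) {
    st <- cx$structure
    cc <- brute_contacts(st, select_atoms(st, chain = "R"),
                         select_atoms(st, chain = "G"), 4.5)
    la <- cx$receptor_map$pairs; lb <- cx$galpha_map$pairs
    for (k in seq_len(nrow(cc))) {
      pa <- strsplit(cc$key_a[k], "|", fixed = TRUE)[[1]]
      pb <- strsplit(cc$key_b[k], "|", fixed = TRUE)[[1]]
      key <- paste(la$label[la$resnum == as.integer(pa[2])],
                   lb$label[lb$resnum == as.integer(pb[2])], sep = "~")
      assign(key, (if (exists(key, recount)) get(key, recount) else 0L) + 1L,
             recount)
    }
  }
  expect_equal(nrow(tab), length(ls(recount)))
  for (k in ls(recount)) {
    parts <- strsplit(k, "~")[[1]]
    expect_equal(tab$n_present[tab$receptor_label == parts[1] &
                                 tab$galpha_label == parts[2]],
                 get(k, recount))
  }
  expect_error(build_conservation_table(list(sets$gs[[1]], sets$gs[[1]])),
               "duplicate complex ids")
  # single-complex set: every fraction is 1
  single <- build_conservation_table(sets$gs[1])
  expect_true(all(single$fraction == 1))
})

test_that("conserved-pair filtering respects the threshold and its bounds", {
  sets <- demo_complex_sets()
  tab <- build_conservation_table(sets$gs)
  top <- conserved_pairs(tab, 0.77)
  expect_equal(nrow(top), 6)
  expect_true(all(top$fraction >= 0.77))
  expect_true(all(diff(top$fraction) <= 0))
  expect_equal(nrow(conserved_pairs(tab, 1e-9)), nrow(tab))
  expect_error(conserved_pairs(tab, 1.0 + 1e-9), "precondition")
  expect_error(conserved_pairs(tab, 0), "precondition")
})

test_that("model checking partitions reference pairs exhaustively and disjointly", {
  sets <- demo_complex_sets()
  ref6 <- conserved_pairs(build_conservation_table(sets$gs), 0.77)
  model <- demo_model_complex()
  chk <- check_model_contacts(model, ref6)
  expect_equal(nrow(chk$preserved), 5)
  expect_equal(nrow(chk$missing), 1)
  expect_equal(chk$missing$receptor_label, "5.68")
  expect_equal(nrow(chk$preserved) + nrow(chk$missing) + nrow(chk$unmappable),
               nrow(ref6))
  expect_setequal(
    paste(chk$preserved$receptor_label, chk$preserved$galpha_label),
    c("3.50 H5.23", "3.53 H5.23", "3.54 H5.16", "3.54 H5.20", "5.65 H5.20"))
  # limits: everything preserved at infinite cutoff, nothing at ~zero
  all_in <- check_model_contacts(model, ref6, cutoff = 1e6)
  expect_equal(nrow(all_in$preserved), 6)
  none <- check_model_contacts(model, ref6, cutoff = 1e-6)
  expect_equal(nrow(none$preserved), 0)
  # unmappable labels are reported, not dropped
  ref_x <- rbind(ref6[, c("receptor_label", "galpha_label")],
                 data.frame(receptor_label = "1.99", galpha_label = "H5.20"))
  chk_x <- check_model_contacts(model, ref_x)
  expect_equal(nrow(chk_x$unmappable), 1)
})

test_that("the restraint funnel reproduces the 7 -> 4 -> 2 selection", {
  sets <- demo_complex_sets()
  aln <- read_galpha_alignment("galpha_h5_alignment_synthetic")
  model <- demo_model_complex()
  res <- select_restraints(aln, sets$gi, sets$gs,
                           model$receptor_map, model$galpha_map)
  expect_equal(unname(res$stages),
               c(7L, 4L, 2L))
  expect_setequal(res$survivors$consistent_contact, c("H5.20", "H5.25"))
  expect_setequal(res$restraints$receptor_label, c("3.54", "6.33"))
  expect_equal(res$restraints$galpha_resnum[res$restraints$galpha_label == "H5.20"],
               388L)
  expect_equal(res$restraints$receptor_resnum[res$restraints$galpha_label == "H5.25"],
               341L)
  expect_equal(res$restraints$max_distance, c(5, 5))
  # funnel monotonicity: each stage is a subset of the previous one
  expect_true(all(res$survivors$shared_interface %in%
                    res$survivors$conserved_h5))
  expect_true(all(res$survivors$consistent_contact %in%
                    res$survivors$shared_interface))
  # degenerate alignment: explicit no-restraints outcome with stage counts
  empty_aln <- make_alignment(4, character(0), seed = 13)
  res0 <- select_restraints(empty_aln, sets$gi, sets$gs,
                            model$receptor_map, model$galpha_map)
  expect_equal(res0$status, "no restraints derivable")
  expect_equal(unname(res0$stages), c(0L, 0L, 0L))
})

test_that("docking-score helper applies the published weights", {
  expect_equal(cluspro_weighted_score(1, 1, 0, 0), 0)
  expect_equal(cluspro_weighted_score(10, 5, -1.2, 3),
               0.4 * 10 - 0.4 * 5 + 600 * -1.2 + 3)
})
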