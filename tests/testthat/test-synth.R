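test_that("zero insertion rates give an empty dataset; same seed gives identical data", {
  cfg <- toy_sim_config(seed = 61, rate = 0)
  ds <- simulate_retroposons(cfg)
  expect_equal(nrow(ds$insertions), 0)
  expect_equal(length(ds$matrix$markers), 0)
  expect_true(all(vapply(ds$annotations, nrow, 1L) == 0))

  a <- simulate_retroposons(toy_sim_config(seed = 62))
  b <- simulate_retroposons(toy_sim_config(seed = 62))
  expect_identical(a$insertions, b$insertions)
  expect_identical(a$matrix$states, b$matrix$states)
  expect_identical(lapply(a$annotations, as.data.frame),
                   lapply(b$annotations, as.data.frame))
  c2 <- simulate_retroposons(toy_sim_config(seed = 63))
  expect_false(identical(a$insertions, c2$insertions))
})

test_that("every true nested insertion has a guest younger than its host", {
  ds <- simulate_retroposons(toy_sim_config(seed = 64))
  expect_gt(nrow(ds$tint_truth), 0)
  expect_true(all(ds$tint_truth$guest_time > ds$tint_truth$host_time))
})

test_that("marker conflict rate rises with the lineage-sorting perturbation rate", {
  rates <- c(0, 0.08, 0.2, 0.35)
  grid <- expand.grid(rate = rates, rep = 1:12)
  frac <- mapply(function(r, i) {
    ds <- simulate_retroposons(toy_sim_config(seed = 700 + i * 7, rate = 25,
                                              ils_rate = r))
    nm <- length(ds$matrix$markers)
    if (nm < 2) return(0)
    nrow(marker_conflicts(ds$matrix)) / choose(nm, 2)
  }, grid$rate, grid$rep)
  expect_gt(cor(grid$rate, frac, method = "spearman"), 0)
  # and the clean control really is conflict-free
  expect_true(all(frac[grid$rate == 0] == 0))
})

test_that("deletion and masking perturbations are applied and logged", {
  ds <- simulate_retroposons(toy_sim_config(seed = 65, missing_rate = 0.1,
                                            deletion_rate = 0.05))
  expect_gt(sum(ds$matrix$states == "?"), 0)
  expect_gt(sum(ds$matrix$states == "d"), 0)
  logged_d <- ds$perturbations[ds$perturbations$type == "deletion", ]
  expect_equal(sum(ds$matrix$states == "d"), nrow(logged_d))
  for (i in head(seq_len(nrow(logged_d)), 20)) {
    expect_equal(unname(ds$matrix$states[logged_d$taxon[i],
                                         logged_d$marker[i]]), "d")
  }
})

test_that("clean simulations are recovered end to end: true tree at RF 0 and CI 1", {
  ds <- simulate_retroposons(recovery_sim_config(seed = 66))
  # precondition: several markers on every internal edge of the true tree
  tree <- ds$true_tree
  internal <- setdiff(unique(tree$edge[, 2]), seq_along(tree$tip.label))
  per_edge <- table(factor(ds$gain_edges$gain_node, levels = internal))
  expect_true(all(per_edge >= 3))
  hs <- heuristic_search(ds$matrix, n_random_additions = 30, seed = 8)
  expect_equal(hs$consistency_index, 1)
  expect_length(hs$trees, 1)
  ingroup <- ape::drop.tip(hs$trees[[1]], "Outgroup")
  rf <- ape::dist.topo(ape::unroot(ingroup), ape::unroot(tree))
  expect_equal(as.numeric(rf), 0)
})

test_that("emitted files all parse back to the dataset", {
  ds <- simulate_retroposons(toy_sim_config(seed = 67, rate = 40,
                                            missing_rate = 0.05))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  for (tip in names(ds$annotations)) {
    back <- read_repeatmasker(paths[[paste0("annotation_", tip)]], tip)
    expect_equal(nrow(back), nrow(ds$annotations[[tip]]))
    expect_equal(back$consensus_start, ds$annotations[[tip]]$consensus_start)
  }
  m <- read_marker_matrix(paths[["matrix"]], outgroup = "Outgroup")
  expect_identical(m$states, ds$matrix$states)
  expect_equal(canonical_topology(read_newick(paths[["tree"]])),
               canonical_topology(ds$true_tree))
  truth <- utils::read.delim(paths[["tint_truth"]])
  expect_equal(nrow(truth), nrow(ds$tint_truth))
  cfg <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg$seed, 67)

  # empty dataset still emits valid, parseable files
  empty <- simulate_retroposons(toy_sim_config(seed = 68, rate = 0))
  dir2 <- withr::local_tempdir()
  p2 <- write_dataset(empty, dir2)
  expect_equal(nrow(read_repeatmasker(p2[["annotation_A"]], "A")), 0)
})

test_that("the detector's event count matches the ledger on clean simulations", {
  ds <- simulate_retroposons(toy_sim_config(seed = 69))
  for (tip in names(ds$annotations)) {
    ev <- detect_nested_insertions(ds$annotations[[tip]])
    truth <- ds$tint_truth[ds$tint_truth$tip == tip & ds$tint_truth$clean, ]
    expect_equal(nrow(ev), nrow(truth))
  }
})

test_that("invalid simulation configurations are rejected", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  fam <- data.frame(name = "F", mu = 1, sigma = 0.5, rate = 10, length = 100)
  expect_error(sim_config(ape::rtree(3, br = NULL), fam), "durations")
  expect_error(sim_config(tr, fam[0, ]), "at least one row")
  expect_error(sim_config(tr, fam, missing_rate = 1.5), "probabilities")
})
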