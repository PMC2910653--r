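test_that("a single clean marker costs one gain on any tree", {
  st <- rbind(A = "+", B = "+", C = "+", O = "-")
  colnames(st) <- "m1"
  x <- marker_matrix(st, outgroup = "O")
  for (nwk in c("((A,B),C,O);", "((A,C),B,O);", "(((A,B),C),O);")) {
    expect_equal(irreversible_parsimony_score(read_newick(text = nwk), x), 1)
  }
})

test_that("the packaged matrix scores 53 on the published consensus topology", {
  x <- marsupial_markers()
  tree <- read_newick(text = fixture_consensus_newick())
  expect_equal(irreversible_parsimony_score(tree, x), 53)
  expect_equal(consistency_index(x, 53), 1)
})

test_that("the DP equals exhaustive ancestral-assignment enumeration", {
  for (seed in 1:12) {
    x <- random_marker_matrix(n_ingroup = 5, n_markers = 8,
                              p_missing = 0.2, seed = seed)
    tree <- random_outgroup_tree(paste0("t", 1:5), seed = seed)
    expect_equal(irreversible_parsimony_score(tree, x),
                 brute_force_irrev_score(tree, x),
                 label = paste("seed", seed))
  }
})

test_that("the DP agrees with an asymmetric-cost Sankoff fit (independent route)", {
  for (seed in 1:4) {
    x <- random_marker_matrix(n_ingroup = 6, n_markers = 12, seed = 40 + seed)
    tree <- random_outgroup_tree(paste0("t", 1:6), seed = seed)
    st <- x$states[tree$tip.label, , drop = FALSE]
    chr <- ifelse(st == "+", "1", ifelse(st == "-", "0", "?"))
    dat <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1"),
                            ambiguity = "?")
    cost <- matrix(c(0, 1e6, 1, 0), 2, 2, byrow = TRUE) # gain 1, loss barred
    ps <- phangorn::parsimony(tree, dat, method = "sankoff", cost = cost)
    expect_equal(irreversible_parsimony_score(tree, x), as.integer(ps))
  }
})

test_that("scores are invariant to child order and character relabeling; all-missing characters are free", {
  x <- random_marker_matrix(n_ingroup = 6, n_markers = 10, seed = 3)
  tree <- random_outgroup_tree(paste0("t", 1:6), seed = 3)
  s0 <- irreversible_parsimony_score(tree, x)
  rot <- ape::rotateConstr(tree, rev(tree$tip.label))
  expect_equal(irreversible_parsimony_score(rot, x), s0)
  set.seed(4)
  xp <- marker_matrix(x$states[, sample(ncol(x$states))], outgroup = "OUT")
  expect_equal(irreversible_parsimony_score(tree, xp), s0)
  xm <- marker_matrix(cbind(x$states,
                            mall = rep("?", nrow(x$states))),
                      outgroup = "OUT")
  expect_equal(irreversible_parsimony_score(tree, xm), s0)
})

test_that("consistency index arithmetic and guards", {
  st <- matrix(rep(c("+", "-"), 5), 2, 5, byrow = FALSE,
               dimnames = list(c("A", "B"), NULL))
  x <- marker_matrix(st)
  expect_equal(consistency_index(x, 6), 5 / 6)
  expect_error(consistency_index(x, 0), "tree length 0")
  expect_error(consistency_index(x, 3), "below the minimum")
  expect_error(irreversible_parsimony_score(
    read_newick(text = "((A,Z),B);"), x), "Z")
})

test_that("heuristic search equals exhaustive search over all topologies", {
  ingroup <- paste0("t", 1:5)
  all_trees <- all_outgroup_topologies(ingroup)
  expect_length(all_trees, 105)
  for (seed in 1:5) {
    x <- random_marker_matrix(n_ingroup = 5, n_markers = 9, seed = 60 + seed)
    exhaustive <- min(vapply(all_trees, irreversible_parsimony_score,
                             x = x, 1L))
    hs <- heuristic_search(x, n_random_additions = 30, seed = seed)
    expect_equal(hs$best_score, exhaustive, label = paste("seed", seed))
  }
})

test_that("a clean 4-taxon matrix yields exactly its one matching topology", {
  st <- rbind(A = c("+", "+"), B = c("+", "+"), C = c("-", "-"),
              O = c("-", "-"))
  colnames(st) <- c("m1", "m2")
  x <- marker_matrix(st, outgroup = "O")
  hs <- heuristic_search(x, n_random_additions = 10, seed = 2)
  expect_equal(hs$best_score, 2)
  expect_length(hs$trees, 1)
  expect_equal(canonical_topology(hs$trees[[1]]),
               canonical_topology(read_newick(text = "(((A,B),C),O);")))
})

test_that("search is reproducible for a fixed seed and conflict-free data give CI 1", {
  ds <- simulate_retroposons(toy_sim_config(seed = 51, rate = 40))
  x <- ds$matrix
  a <- heuristic_search(x, n_random_additions = 25, seed = 9)
  b <- heuristic_search(x, n_random_additions = 25, seed = 9)
  expect_equal(vapply(a$trees, canonical_topology, ""),
               vapply(b$trees, canonical_topology, ""))
  expect_equal(a$best_score, sum(colSums(x$states == "+") > 0))
  expect_equal(a$consistency_index, 1)
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- read_newick(text = "(((A,B),C),(D,E));")
  expect_equal(canonical_topology(strict_consensus(list(t1, t1))),
               canonical_topology(t1))
  t2 <- read_newick(text = "(((A,C),B),(D,E));")
  cons <- strict_consensus(list(t1, t2))
  expect_equal(canonical_topology(cons),
               canonical_topology(read_newick(text = "((A,B,C),(D,E));")))
  expect_error(strict_consensus(list(t1, read_newick(text = "((A,B),C);"))),
               "identical leaf set")
})

test_that("strict consensus matches the ape consensus oracle on random tree sets", {
  for (seed in 1:6) {
    set.seed(seed)
    trees <- lapply(1:4, function(i)
      random_outgroup_tree(paste0("t", 1:6), seed = seed * 10 + i))
    mine <- strict_consensus(trees)
    oracle <- ape::consensus(trees, p = 1, rooted = TRUE)
    expect_equal(canonical_topology(mine), canonical_topology(oracle))
  }
})

test_that("Newick io round-trips topologies including polytomies", {
  for (nwk in c("(A,B);", "((A,B),(C,D),E);", "((A,(B,C,D)),E);")) {
    tr <- read_newick(text = nwk)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    expect_equal(canonical_topology(read_newick(path)),
                 canonical_topology(tr))
  }
  set.seed(8)
  for (i in 1:5) {
    tr <- ape::rtree(8, br = NULL)
    expect_equal(canonical_topology(read_newick(text = ape::write.tree(tr))),
                 canonical_topology(tr))
  }
  expect_error(read_newick(text = "((A,B);"))
})
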