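# Independent oracles used to pin down expected values.

# Minimum gains under irreversible-up scoring by exhaustive enumeration of
# all 0/1 assignments to internal nodes (root forced to 0); missing leaves
# are free and never cost anything.
brute_force_irrev_score <- function(tree, x) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- x$states[tree$tip.label, , drop = FALSE]
  root_pos <- 1 # internal node ntip + 1
  total <- 0
  for (ch in seq_len(ncol(states))) {
    s <- states[, ch]
    best <- Inf
    for (mask in 0:(2^nnode - 1)) {
      asg <- as.integer(intToBits(mask))[seq_len(nnode)]
      if (asg[root_pos] != 0) next
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]
        c2 <- tree$edge[e, 2]
        sp <- asg[p - ntip]
        if (c2 <= ntip) {
          st <- s[c2]
          if (st == "+") sc <- 1
          else if (st == "-") sc <- 0
          else next # missing/deleted: free, copies the parent at no cost
        } else {
          sc <- asg[c2 - ntip]
        }
        if (sp == 0 && sc == 1) cost <- cost + 1
        if (sp == 1 && sc == 0) { cost <- Inf; break }
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# Exact trichotomy-null p-value by enumerating all 3^n equally likely
# assignments of n markers to the three resolutions.
enum_multinomial_p <- function(k, l, m) {
  n <- k + l + m
  if (n == 0) return(1)
  margin_obs <- k - max(l, m)
  grid <- expand.grid(rep(list(1:3), n))
  hits <- apply(grid, 1, function(a) {
    cnt <- tabulate(a, 3)
    cnt[1] - max(cnt[2], cnt[3]) >= margin_obs
  })
  sum(hits) / 3^n
}

# Random conflict-free-or-not marker matrix with an all-absent outgroup.
random_marker_matrix <- function(n_ingroup = 5, n_markers = 10,
                                 p_missing = 0.15, seed = 1) {
  set.seed(seed)
  taxa <- c(paste0("t", seq_len(n_ingroup)), "OUT")
  st <- matrix(sample(c("+", "-"), n_ingroup * n_markers, replace = TRUE),
               n_ingroup, n_markers)
  st[matrix(runif(length(st)) < p_missing, n_ingroup)] <- "?"
  st <- rbind(st, rep("-", n_markers))
  rownames(st) <- taxa
  colnames(st) <- paste0("m", seq_len(n_markers))
  marker_matrix(st, outgroup = "OUT")
}

# Random rooted binary tree with the outgroup attached at the root.
random_outgroup_tree <- function(ingroup, outgroup = "OUT", seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(length(ingroup), tip.label = sample(ingroup), br = NULL)
  nwk <- sub(";$", "", ape::write.tree(tr))
  read_newick(text = paste0("(", nwk, ",", outgroup, ");"))
}

# Every rooted-by-outgroup binary topology over the given taxa (the
# unrooted topologies on ingroup + outgroup, rooted on the outgroup edge).
all_outgroup_topologies <- function(ingroup, outgroup = "OUT") {
  trees <- phangorn::allTrees(length(ingroup) + 1,
                              tip.label = c(ingroup, outgroup))
  lapply(trees, function(t) {
    ape::root(t, outgroup = outgroup, resolve.root = TRUE)
  })
}

fixture_consensus_newick <- function() {
  paste0(
    "(((Monodelphis_domestica,(Didelphis_virginiana,Metachirus_nudicaudatus)),",
    "((Rhyncholestes_raphanurus,Caenolestes_fuliginosus),",
    "(Dromiciops_gliroides,((Notoryctes_typhlops,",
    "(Phascogale_tapoatafa,Dasyurus_geoffroii,Sminthopsis_crassicaudata,",
    "Myrmecobius_fasciatus),",
    "(Macrotis_lagotis,Perameles_gunnii,Isoodon_obesulus)),",
    "(Vombatus_ursinus,((Tarsipes_rostratus,Pseudocheirus_peregrinus),",
    "Trichosurus_vulpecula,(Macropus_robustus,Potorous_tridactylus))))))),",
    "Homo_sapiens);")
}
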