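# states coded for the C++ scorer: 0 absent, 1 present, 2 missing/deleted
states_to_int <- function(states) {
  m <- matrix(2L, nrow(states), ncol(states), dimnames = dimnames(states))
  m[states == "+"] <- 1L
  m[states == "-"] <- 0L
  m
}

#' Irreversible-up parsimony score of a rooted tree
#'
#' Scores a marker matrix on a rooted tree under irreversible (gains-only,
#' Camin--Sokal) character transformation: every character has root state 0,
#' a 0 to 1 gain on an edge costs one step, losses are forbidden, and
#' missing/deleted leaf states may take either state at no cost. The score
#' is the sum over characters of the minimum number of gains, computed by a
#' dynamic program over the rooted tree (polytomies allowed).
#'
#' @param tree A rooted `phylo` tree; every tip label must appear among the
#'   matrix taxa (the converse is not required).
#' @param x A [marker_matrix()].
#' @return Integer: the minimum total number of gains.
#' @export
irreversible_parsimony_score <- function(tree, x) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object")
  missing_taxa <- setdiff(tree$tip.label, x$taxa)
  if (length(missing_taxa) > 0) {
    abort(paste0("tree tips absent from matrix: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  # rooting convention: when the matrix outgroup is in the tree, the root
  # sits on the outgroup's edge (a basal trichotomy written in Newick is
  # resolved into outgroup versus ingroup before scoring)
  if (!is.null(x$outgroup) && x$outgroup %in% tree$tip.label) {
    og_edge <- which(tree$edge[, 2] == match(x$outgroup, tree$tip.label))
    if (tree$edge[og_edge, 1] != length(tree$tip.label) + 1 ||
        sum(tree$edge[, 1] == length(tree$tip.label) + 1) > 2) {
      tree <- ape::root(tree, outgroup = x$outgroup, resolve.root = TRUE)
    }
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- x$states[tree$tip.label, , drop = FALSE]
  cpp_irrev_score(tree$edge, length(tree$tip.label), tree$Nnode,
                  states_to_int(states))
}

#' Consistency index of a tree length
#'
#' The consistency index (CI) is the minimum conceivable number of steps of
#' the matrix divided by the realized tree length. Under irreversible binary
#' coding every character with at least one scored presence needs exactly
#' one gain, so the numerator is the number of such (variable) characters.
#' CI = 1 means the tree is free of homoplasy.
#'
#' @param x A [marker_matrix()].
#' @param tree_length Realized number of steps (e.g. from
#'   [irreversible_parsimony_score()]).
#' @return The consistency index.
#' @export
consistency_index <- function(x, tree_length) {
  min_steps <- sum(colSums(x$states == "+") > 0)
  if (tree_length == 0) {
    if (min_steps > 0) abort("tree length 0 with variable characters")
    return(NA_real_)
  }
  if (tree_length < min_steps) {
    abort("tree length is below the minimum conceivable number of steps")
  }
  min_steps / tree_length
}

#' Heuristic maximum parsimony search
#'
#' Searches tree space for the most parsimonious rooted trees under
#' irreversible-up scoring, the PAUP-style heuristic: each replicate builds
#' a starting tree by stepwise addition in a seeded random taxon order
#' (every insertion point scored, ties broken uniformly at random), then
#' hill-climbs with the configured branch-swapping neighbourhood (TBR by
#' default) under first-improvement acceptance until no rearrangement
#' shortens the tree. Swapping operates on the unrooted tree; scoring roots
#' at the outgroup with root state 0. All distinct binary topologies
#' attaining the best score across replicates are returned (topology
#' identity is the canonical rooted-at-outgroup form).
#'
#' @param x A [marker_matrix()] with at least 4 taxa.
#' @param n_random_additions Number of random-addition replicates
#'   (default 1000).
#' @param swap Branch-swapping neighbourhood: `"TBR"` (tree bisection and
#'   reconnection), `"SPR"` or `"NNI"`.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param outgroup Outgroup taxon label; defaults to the matrix outgroup.
#' @param keep_all_optimal Keep every distinct optimal topology (default);
#'   otherwise only the first is retained.
#'
#' @return An object of class `parsimony_search`: list with `trees` (a
#'   `multiPhylo` of distinct optimal rooted binary trees), `best_score`,
#'   `consistency_index`, `replicate_scores`, and the search configuration.
#' @export
heuristic_search <- function(x, n_random_additions = 1000,
                             swap = c("TBR", "SPR", "NNI"), seed = 1,
                             outgroup = x$outgroup,
                             keep_all_optimal = TRUE) {
  swap <- match.arg(swap)
  if (length(x$taxa) < 4) abort("heuristic search needs at least 4 taxa")
  if (n_random_additions < 1) abort("`n_random_additions` must be >= 1")
  if (is.null(outgroup)) {
    abort("an outgroup taxon is required (set it on the matrix or pass `outgroup`)")
  }
  if (!outgroup %in% x$taxa) abort("`outgroup` must be one of the matrix taxa")
  states <- states_to_int(x$states)
  og <- match(outgroup, x$taxa)
  swap_code <- c(NNI = 0L, SPR = 1L, TBR = 2L)[[swap]]
  res <- cpp_parsimony_search(states, og, as.integer(n_random_additions),
                              swap_code, as.integer(seed))
  scores <- res$scores
  best <- min(scores)
  is_best <- which(scores == best)
  canon <- res$canonical[is_best]
  keep <- is_best[!duplicated(canon)]
  if (!keep_all_optimal) keep <- keep[1]
  trees <- lapply(keep, function(i) {
    unrooted_edges_to_phylo(res$edges[[i]], x$taxa, og)
  })
  class(trees) <- "multiPhylo"
  structure(list(
    trees = trees, best_score = best,
    consistency_index = consistency_index(x, best),
    replicate_scores = as.integer(scores),
    n_random_additions = n_random_additions, swap = swap, seed = seed,
    outgroup = outgroup, taxa = x$taxa),
    class = "parsimony_search")
}

# convert a 1-based unrooted edge list (tips 1..n first) into a rooted
# binary phylo with the root splitting (outgroup, rest)
unrooted_edges_to_phylo <- function(edges, tip_labels, outgroup_index) {
  n <- length(tip_labels)
  maxn <- max(edges)
  adj <- vector("list", maxn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # rooted: root -> outgroup tip and root -> neighbour subtree
  n_internal <- n - 1 # root + (n - 2) unrooted internals
  root_id <- n + 1
  new_id <- setNames(seq_len(n), seq_len(n)) # tips keep ids
  next_internal <- n + 1 + 1
  parent <- integer(); child <- integer()
  # DFS from the outgroup's neighbour
  start <- adj[[outgroup_index]][1]
  stack <- list(c(start, outgroup_index, root_id))
  map <- integer(maxn)
  map[seq_len(n)] <- seq_len(n)
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- fr[1]; par <- fr[2]; par_new <- fr[3]
    if (v <= n) {
      vid <- v
    } else {
      vid <- next_internal
      next_internal <- next_internal + 1
    }
    map[v] <- vid
    parent <- c(parent, par_new)
    child <- c(child, vid)
    for (u in adj[[v]]) {
      if (u != par) stack[[length(stack) + 1]] <- c(u, v, vid)
    }
  }
  parent <- c(parent, root_id)
  child <- c(child, outgroup_index)
  tree <- list(edge = cbind(parent, child), tip.label = tip_labels,
               Nnode = n - 1)
  dimnames(tree$edge) <- NULL
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("<parsimony_search> best score ", x$best_score,
      " (CI ", format(x$consistency_index, digits = 4), "), ",
      length(x$trees), " distinct optimal trees from ",
      x$n_random_additions, " random-addition replicates (",
      x$swap, " swapping)\n", sep = "")
  invisible(x)
}

#' @export
glance.parsimony_search <- function(x, ...) {
  tibble(best_score = x$best_score,
         consistency_index = x$consistency_index,
         n_optimal_trees = length(x$trees),
         n_replicates = x$n_random_additions,
         swap = x$swap, seed = x$seed)
}

#' @export
tidy.parsimony_search <- function(x, ...) {
  tibble(replicate = seq_along(x$replicate_scores),
         score = x$replicate_scores)
}

#' Strict consensus of rooted trees
#'
#' The strict consensus contains exactly the clades present in every input
#' tree; all other resolutions collapse into polytomies. All trees must
#' share an identical leaf set.
#'
#' @param trees A `multiPhylo` or list of rooted `phylo` trees.
#' @return A rooted `phylo` tree (with polytomies where trees disagree).
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0) abort("no trees supplied")
  leafset <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), leafset)) {
      abort("all trees must share an identical leaf set")
    }
  }
  clade_keys <- function(tree) {
    ntip <- length(tree$tip.label)
    tips <- function(node) {
      if (node <= ntip) return(tree$tip.label[node])
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      unlist(lapply(kids, tips))
    }
    nodes <- unique(tree$edge[, 1])
    vapply(nodes, function(nd) paste(sort(tips(nd)), collapse = "\r"), "")
  }
  common <- Reduce(intersect, lapply(trees, clade_keys))
  clades <- lapply(strsplit(common, "\r", fixed = TRUE), sort)
  # add the root clade if absent, then build by nesting
  sizes <- vapply(clades, length, 1L)
  clades <- clades[order(-sizes)]
  if (length(clades) == 0 || length(clades[[1]]) < length(leafset)) {
    clades <- c(list(leafset), clades)
  }
  build <- function(members, sub) {
    # sub: clades strictly inside `members`, largest first
    taken <- character()
    parts <- list()
    for (cl in sub) {
      if (all(cl %in% members) && length(cl) < length(members) &&
          !any(cl %in% taken)) {
        inner <- Filter(function(z) all(z %in% cl) && length(z) < length(cl), sub)
        parts[[length(parts) + 1]] <- build(cl, inner)
        taken <- c(taken, cl)
      }
    }
    singles <- setdiff(members, taken)
    items <- c(parts, as.list(singles))
    paste0("(", paste(unlist(items), collapse = ","), ")")
  }
  nwk <- paste0(build(leafset, clades[-1]), ";")
  ape::read.tree(text = nwk)
}

#' Read and write Newick trees
#'
#' Thin wrappers over the ape Newick parser/serializer: round-trips
#' preserve topology, tip labels and polytomies.
#'
#' @param path File path (or, for `read_newick`, `text = ` a literal
#'   Newick string).
#' @param text Optional literal Newick string.
#' @param tree A `phylo` object (or `multiPhylo`).
#' @return `read_newick` returns a `phylo` (or `multiPhylo` when the file
#'   holds several trees); `write_newick` returns `path` invisibly.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  out <- ape::read.tree(file = path, text = text)
  if (is.null(out)) abort("malformed Newick input")
  out
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Canonical topology string of a rooted tree
#'
#' Label-sorted Newick form that is identical for topologically identical
#' rooted trees regardless of node rotation or edge order; used to
#' deduplicate trees.
#'
#' @param tree A rooted `phylo`.
#' @return A character scalar.
#' @export
canonical_topology <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  walk <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    parts <- sort(vapply(kids[[as.character(node)]], walk, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(walk(ntip + 1), ";")
}
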