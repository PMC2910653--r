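#' Configure a retroposon evolution simulation
#'
#' The simulator emulates the generative structure behind retroposon
#' presence/absence phylogenetics: repeat families whose insertion activity
#' is Normal(`mu`, `sigma`) on a relative time axis (larger = more recent,
#' the same axis as [estimate_activity()]) insert copies along a rooted
#' species tree whose branch durations live on that axis. Insertions land
#' uniformly at random in the growing genome; an insertion landing inside an
#' existing element splits it into two fragments with continuous consensus
#' coordinates (a ground-truth nested TinT event). Every insertion event on
#' a tree edge is inherited by all descendant tips and becomes a
#' presence/absence marker with that gain edge. Missing data, non-specific
#' deletions, and an incomplete-lineage-sorting-style perturbation (the
#' marker's gain edge is re-drawn from an adjacent edge) are applied last
#' and logged.
#'
#' @param species_tree Rooted `phylo` with positive edge lengths (relative
#'   time). The root sits at time 0 and time increases toward the tips.
#' @param families Data frame with columns `name`, `mu`, `sigma`,
#'   `rate` (expected insertions per lineage over the family's whole
#'   activity period), `length` (element length, bp); optional
#'   `repeat_class`.
#' @param genome_length Background genome size in bp (default 1e6).
#' @param missing_rate Probability that a matrix cell is masked to `?`.
#' @param deletion_rate Probability that a present cell suffers a
#'   non-specific deletion (becomes `d`).
#' @param ils_rate Probability that a marker's presence set is re-drawn
#'   discordantly around its gain edge (one daughter lineage of the gain
#'   node paired with a sibling lineage), emulating incomplete lineage
#'   sorting / hemiplasy; tip-edge markers are deepened onto the parent
#'   edge. A simple perturbation, not a coalescent model.
#' @param min_fragment Fragment length (bp) below which a true nested event
#'   is flagged unclean in the truth ledger (matching the detector default).
#' @param outgroup_label Label of an all-absent outgroup taxon appended to
#'   the marker matrix, or `NULL` for none.
#' @param seed Integer seed; the whole dataset is reproducible per seed.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_tree, families, genome_length = 1e6,
                       missing_rate = 0, deletion_rate = 0, ils_rate = 0,
                       min_fragment = 30, outgroup_label = "Outgroup",
                       seed = 1) {
  if (!inherits(species_tree, "phylo") || is.null(species_tree$edge.length)) {
    abort("`species_tree` must be a phylo with branch durations")
  }
  if (any(species_tree$edge.length <= 0)) {
    abort("branch durations must be positive")
  }
  families <- as_tibble(families)
  required <- c("name", "mu", "sigma", "rate", "length")
  if (!all(required %in% names(families)) || nrow(families) == 0) {
    abort("`families` needs at least one row with columns name, mu, sigma, rate, length")
  }
  if (!"repeat_class" %in% names(families)) families$repeat_class <- "SINE/sim"
  stopifnot(all(families$sigma > 0), all(families$length >= 10),
            all(families$rate >= 0))
  for (r in c(missing_rate, deletion_rate, ils_rate)) {
    if (r < 0 || r > 1) abort("rates must be probabilities in [0, 1]")
  }
  structure(list(species_tree = species_tree, families = families,
                 genome_length = genome_length, missing_rate = missing_rate,
                 deletion_rate = deletion_rate, ils_rate = ils_rate,
                 min_fragment = min_fragment, outgroup_label = outgroup_label,
                 seed = seed),
            class = "sim_config")
}

node_times <- function(tree) {
  ntip <- length(tree$tip.label)
  nt <- numeric(ntip + tree$Nnode)
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  for (i in seq_len(nrow(tree$edge))) {
    nt[tree$edge[i, 2]] <- nt[tree$edge[i, 1]] + tree$edge.length[i]
  }
  nt
}

clade_tip_labels <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tip_labels, tree = tree))
}

#' Simulate a retroposon dataset with ground-truth ledgers
#'
#' Runs the generative process described in [sim_config()] and returns the
#' complete dataset: per-tip repeat annotations (RepeatMasker-convention
#' coordinates), the global insertion ledger, the per-tip nested-insertion
#' (TinT) truth ledger with cleanliness flags, the presence/absence marker
#' matrix with perturbation log, per-marker true gain edges, and the true
#' tree.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset`.
#' @export
simulate_retroposons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- ape::reorder.phylo(config$species_tree, "cladewise")
  ntip <- length(tree$tip.label)
  times <- node_times(tree)
  fam <- config$families
  G <- config$genome_length

  ins <- list()          # global insertion ledger rows
  tip_elems <- list()    # tip label -> integer ids on its path
  n_ins <- 0L

  children_of <- split(tree$edge[, 2], tree$edge[, 1])

  new_insertions_on_edge <- function(t0, t1) {
    rows <- list()
    for (i in seq_len(nrow(fam))) {
      lam <- fam$rate[i] * (pnorm(t1, fam$mu[i], fam$sigma[i]) -
                              pnorm(t0, fam$mu[i], fam$sigma[i]))
      nf <- rpois(1, lam)
      if (nf == 0) next
      u <- runif(nf, pnorm(t0, fam$mu[i], fam$sigma[i]),
                 pnorm(t1, fam$mu[i], fam$sigma[i]))
      rows[[i]] <- tibble(family_idx = i, time = qnorm(u, fam$mu[i],
                                                       fam$sigma[i]))
    }
    out <- bind_rows(rows)
    if (nrow(out) > 0) out <- out[order(out$time), ]
    out
  }

  walk <- function(node, parent, elems, splits) {
    if (!is.null(parent)) {
      todo <- new_insertions_on_edge(times[parent], times[node])
      for (j in seq_len(nrow(todo))) {
        fi <- todo$family_idx[j]
        lens <- if (length(elems) > 0) {
          fam$length[vapply(elems, function(id) ins[[id]]$family_idx, 1L)]
        } else numeric()
        tot <- G + sum(lens)
        u <- runif(1, 0, tot)
        n_ins <<- n_ins + 1L
        id <- n_ins
        rec <- list(id = id, family_idx = fi,
                    family = fam$name[fi], time = todo$time[j],
                    strand = sample(c("+", "-"), 1),
                    edge_child = node, host_id = NA_integer_,
                    host_offset = NA_integer_, bg_pos = NA_integer_)
        if (u <= G || length(elems) == 0) {
          rec$bg_pos <- max(1L, as.integer(ceiling(u)))
        } else {
          idx <- findInterval(u - G, cumsum(lens), left.open = TRUE) + 1L
          host <- elems[idx]
          hl <- fam$length[ins[[host]]$family_idx]
          key <- as.character(host)
          used <- splits[[key]]
          # keep every resulting fragment at least 2 bp so the closed-interval
          # coordinate invariants hold for all annotated pieces
          repeat {
            o <- sample.int(hl - 3L, 1) + 1L
            if (length(used) == 0 || min(abs(o - used)) > 1L) break
          }
          splits[[key]] <- c(used, o)
          rec$host_id <- host
          rec$host_offset <- o
        }
        ins[[id]] <<- rec
        elems <- c(elems, id)
      }
    }
    if (node <= ntip) {
      tip_elems[[tree$tip.label[node]]] <<- elems
    } else {
      for (ch in children_of[[as.character(node)]]) {
        walk(ch, node, elems, splits)
      }
    }
  }
  walk(ntip + 1, NULL, integer(), list())

  insertions <- if (n_ins > 0) {
    bind_rows(lapply(ins, function(r) {
      tibble(id = r$id, marker = sprintf("m%04d", r$id), family = r$family,
             time = r$time, strand = r$strand, edge_child = r$edge_child,
             bg_pos = r$bg_pos, host_id = r$host_id,
             host_offset = r$host_offset)
    }))
  } else {
    tibble(id = integer(), marker = character(), family = character(),
           time = numeric(), strand = character(), edge_child = integer(),
           bg_pos = integer(), host_id = integer(), host_offset = integer())
  }

  # ---- marker matrix with perturbations -----------------------------------
  # Incomplete lineage sorting: with probability ils_rate a marker's
  # presence set is re-drawn around its gain edge -- one daughter lineage of
  # the gain node paired with a sibling lineage (a discordant, hemiplasy-like
  # grouping that conflicts with the species tree); a tip-edge marker is
  # deepened onto its parent edge instead.
  markers <- insertions$marker
  gain_node <- insertions$edge_child
  presence <- lapply(gain_node, clade_tip_labels, tree = tree)
  ils_log <- tibble(marker = character(), gain_node = integer(),
                    note = character())
  if (config$ils_rate > 0 && length(markers) > 0) {
    parent_of <- setNames(tree$edge[, 1], tree$edge[, 2])
    for (i in seq_along(markers)) {
      if (runif(1) >= config$ils_rate) next
      v <- gain_node[i]
      p <- parent_of[as.character(v)]
      sibs <- setdiff(children_of[[as.character(p)]], v)
      if (length(sibs) == 0) next
      sib <- sibs[sample.int(length(sibs), 1)]
      sib_leaves <- clade_tip_labels(tree, sib)
      if (v > ntip) {
        kid <- children_of[[as.character(v)]]
        ci <- kid[sample.int(length(kid), 1)]
        presence[[i]] <- c(clade_tip_labels(tree, ci), sib_leaves)
        note <- "discordant"
      } else {
        presence[[i]] <- c(tree$tip.label[v], sib_leaves)
        note <- "deepened"
      }
      ils_log <- bind_rows(ils_log, tibble(marker = markers[i],
                                           gain_node = v, note = note))
    }
  }
  taxa <- tree$tip.label
  states <- matrix("-", length(taxa), length(markers),
                   dimnames = list(taxa, markers))
  for (i in seq_along(markers)) {
    states[presence[[i]], i] <- "+"
  }
  perturbations <- list()
  if (config$deletion_rate > 0 && length(states) > 0) {
    del <- states == "+" & matrix(runif(length(states)) < config$deletion_rate,
                                  nrow(states))
    if (any(del)) {
      idx <- which(del, arr.ind = TRUE)
      perturbations[[length(perturbations) + 1]] <-
        tibble(taxon = taxa[idx[, 1]], marker = markers[idx[, 2]],
               type = "deletion", from = "+", to = "d")
      states[del] <- "d"
    }
  }
  if (config$missing_rate > 0 && length(states) > 0) {
    # deleted cells stay deleted: masking applies to scored states only,
    # keeping the perturbation ledgers one-to-one with the final matrix
    mis <- matrix(runif(length(states)) < config$missing_rate, nrow(states)) &
      states != "d"
    if (any(mis)) {
      idx <- which(mis, arr.ind = TRUE)
      perturbations[[length(perturbations) + 1]] <-
        tibble(taxon = taxa[idx[, 1]], marker = markers[idx[, 2]],
               type = "missing", from = states[mis], to = "?")
      states[mis] <- "?"
    }
  }
  perturbations <- if (length(perturbations) > 0) bind_rows(perturbations) else
    tibble(taxon = character(), marker = character(), type = character(),
           from = character(), to = character())
  outgroup <- NULL
  if (!is.null(config$outgroup_label)) {
    states <- rbind(states,
                    matrix("-", 1, ncol(states),
                           dimnames = list(config$outgroup_label, markers)))
    outgroup <- config$outgroup_label
  }
  matrix_out <- marker_matrix(states, outgroup = outgroup)

  gain_edges <- tibble(
    marker = markers, gain_node = gain_node,
    clade = vapply(gain_node, function(n)
      paste(sort(clade_tip_labels(tree, n)), collapse = ","), ""),
    ils = markers %in% ils_log$marker)

  # ---- per-tip annotations and TinT truth ---------------------------------
  annotations <- list()
  tint_rows <- list()
  for (tip in tree$tip.label) {
    elems <- tip_elems[[tip]]
    lay <- layout_tip(elems, ins, fam, config, times, tree, tip)
    annotations[[tip]] <- lay$annotation
    if (nrow(lay$tint) > 0) tint_rows[[tip]] <- lay$tint
  }
  tint_truth <- if (length(tint_rows) > 0) bind_rows(tint_rows) else
    tibble(tip = character(), guest_id = integer(), host_id = integer(),
           guest_marker = character(), guest_family = character(),
           host_family = character(), guest_time = numeric(),
           host_time = numeric(), left_flank = integer(),
           right_flank = integer(), guest_intact = logical(),
           clean = logical())

  structure(list(annotations = annotations, insertions = insertions,
                 tint_truth = tint_truth, matrix = matrix_out,
                 gain_edges = gain_edges, perturbations = perturbations,
                 ils_log = ils_log, true_tree = tree, config = config),
            class = "synthetic_dataset")
}

# lay out one tip's genome: standalone elements by background position,
# nested elements expanded recursively inside their hosts
layout_tip <- function(elems, ins, fam, config, times, tree, tip) {
  empty_ann <- repeat_annotation(tibble(
    sequence_id = character(), genome_start = integer(),
    genome_end = integer(), strand = character(), family = character(),
    repeat_class = character(), consensus_start = integer(),
    consensus_end = integer()), tip)
  empty_tint <- tibble(tip = character(), guest_id = integer(),
                       host_id = integer(), guest_marker = character(),
                       guest_family = character(), host_family = character(),
                       guest_time = numeric(), host_time = numeric(),
                       left_flank = integer(), right_flank = integer(),
                       guest_intact = logical(), clean = logical())
  if (length(elems) == 0) {
    return(list(annotation = empty_ann, tint = empty_tint))
  }
  recs <- ins[elems]
  ids <- vapply(recs, function(r) r$id, 1L)
  host_of <- vapply(recs, function(r) r$host_id %||% NA_integer_, 1L)
  kids_of <- split(ids[!is.na(host_of)], host_of[!is.na(host_of)])
  tip_time <- times[match(tip, tree$tip.label)]

  rows <- list()
  tint <- list()
  cursor <- 0L

  emit <- function(id) {
    r <- ins[[id]]
    L <- fam$length[r$family_idx]
    cls <- fam$repeat_class[r$family_idx]
    div <- round(pmin(45, 2 * (tip_time - r$time)), 1)
    kids <- kids_of[[as.character(id)]]
    offs <- if (is.null(kids)) integer() else
      vapply(ins[kids], function(k) k$host_offset, 1L)
    ord <- order(offs)
    kids <- kids[ord]; offs <- offs[ord]
    bounds <- c(0L, offs, L)
    nfrag <- length(bounds) - 1L
    frag <- function(i) { # consensus range of fragment i
      c(bounds[i] + 1L, bounds[i + 1L])
    }
    put_frag <- function(cr) {
      len <- cr[2] - cr[1] + 1L
      rows[[length(rows) + 1]] <<- tibble(
        sequence_id = "seq1", genome_start = cursor + 1L,
        genome_end = cursor + len, strand = r$strand, family = r$family,
        repeat_class = cls, consensus_start = cr[1], consensus_end = cr[2],
        divergence = div, score = 100, starred = FALSE,
        rm_id = as.character(id))
      cursor <<- cursor + len
    }
    order_idx <- if (r$strand == "+") seq_len(nfrag) else rev(seq_len(nfrag))
    for (fi in seq_len(nfrag)) {
      i <- order_idx[fi]
      put_frag(frag(i))
      # child after fragment i (plus strand) / before it (minus strand)
      ki <- if (r$strand == "+") i else i - 1L
      if (fi < nfrag && ki >= 1 && ki <= length(kids)) emit(kids[ki])
    }
    # truth ledger rows for this host's guests
    for (i in seq_along(kids)) {
      g <- ins[[kids[i]]]
      lf <- bounds[i + 1L] - bounds[i]
      rf <- bounds[i + 2L] - bounds[i + 1L]
      intact <- is.null(kids_of[[as.character(kids[i])]])
      tint[[length(tint) + 1]] <<- tibble(
        tip = tip, guest_id = g$id, host_id = id,
        guest_marker = sprintf("m%04d", g$id),
        guest_family = g$family, host_family = r$family,
        guest_time = g$time, host_time = r$time,
        left_flank = lf, right_flank = rf, guest_intact = intact,
        clean = intact && min(lf, rf) >= config$min_fragment)
    }
  }

  standalone <- ids[is.na(host_of)]
  bg <- vapply(ins[standalone], function(r) r$bg_pos, 1L)
  standalone <- standalone[order(bg, standalone)]
  prev_bg <- 0L
  for (i in seq_along(standalone)) {
    r <- ins[[standalone[i]]]
    cursor <- cursor + max(0L, r$bg_pos - prev_bg)
    prev_bg <- r$bg_pos
    emit(standalone[i])
  }
  ann <- repeat_annotation(bind_rows(rows), tip)
  tint <- if (length(tint) > 0) bind_rows(tint) else empty_tint
  list(annotation = ann, tint = tint)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$annotations), " tips, ",
      nrow(x$insertions), " insertions (", nrow(x$matrix$states), " x ",
      length(x$matrix$markers), " marker matrix, ",
      sum(x$tint_truth$clean), " clean nested events across tips)\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset to files
#'
#' Emits one RepeatMasker-style `.out` file per tip, the marker matrix as
#' delimited text, the true tree as Newick, the truth ledgers as
#' tab-separated tables and the scalar configuration as JSON -- every file
#' parseable by the package's own readers.
#'
#' @param dataset A [simulate_retroposons()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (tip in names(dataset$annotations)) {
    p <- file.path(dir, paste0(tip, ".rm.out"))
    write_repeatmasker(dataset$annotations[[tip]], p)
    paths[paste0("annotation_", tip)] <- p
  }
  paths["matrix"] <- file.path(dir, "markers.tsv")
  write_marker_matrix(dataset$matrix, paths["matrix"])
  paths["tree"] <- file.path(dir, "true_tree.nwk")
  write_newick(dataset$true_tree, paths["tree"])
  for (nm in c("insertions", "tint_truth", "gain_edges", "perturbations",
               "ils_log")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(dataset[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  cfg <- dataset$config
  cfg$species_tree <- ape::write.tree(cfg$species_tree)
  cfg$families <- as.data.frame(cfg$families)
  paths["config"] <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
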