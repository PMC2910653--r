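#' Conflict-free insertion significance
#'
#' Probability, under the trichotomy null in which each marker
#' independently supports one of the three possible resolutions of a node
#' with probability 1/3, that `k` independent markers all support the one
#' pre-specified resolution: `(1/3)^k`. This is the closed form behind all
#' conflict-free `[k 0 0]` support patterns; three or more conflict-free
#' markers give p < 0.05.
#'
#' @param k Non-negative integer count(s) of conflict-free supporting
#'   markers.
#' @return Numeric p-value(s).
#' @export
conflict_free_p <- function(k) {
  if (any(k < 0) || any(k != round(k))) {
    abort("`k` must be a non-negative integer")
  }
  (1 / 3)^k
}

#' Multinomial insertion significance test
#'
#' Exact tail probability of a `[k l m]` marker support pattern under the
#' trichotomy null: with `n = k + l + m` markers each independently
#' supporting one of the three resolutions with probability 1/3, the
#' p-value is the probability of an outcome `(a, b, c)` whose support
#' margin `a - max(b, c)` for the pre-specified resolution is at least the
#' observed margin `k - max(l, m)`, computed by full enumeration of the
#' trinomial distribution. For a conflict-free pattern (`l = m = 0`) this
#' reduces to `(1/3)^k`, the [conflict_free_p()] closed form.
#'
#' @param k Markers supporting the hypothesis edge (must be the
#'   best-supported resolution: `k >= max(l, m)`).
#' @param l,m Markers supporting the two alternative resolutions.
#' @return The exact p-value.
#' @export
multinomial_p <- function(k, l = 0, m = 0) {
  if (inherits(k, "support_pattern")) {
    l <- k$l; m <- k$m; k <- k$k
  }
  if (any(c(k, l, m) < 0)) abort("pattern counts must be non-negative")
  if (k < max(l, m)) {
    abort("the hypothesis must be the best-supported resolution (k >= max(l, m))")
  }
  n <- k + l + m
  if (n == 0) return(1)
  margin_obs <- k - max(l, m)
  p <- 0
  for (a in 0:n) {
    for (b in 0:(n - a)) {
      cc <- n - a - b
      if (a - max(b, cc) >= margin_obs) {
        p <- p + dmultinom(c(a, b, cc), prob = rep(1 / 3, 3))
      }
    }
  }
  p
}

#' Significance of a marker support pattern
#'
#' Wraps [multinomial_p()] with the conventional significance threshold:
#' a node is considered significantly supported when p < `alpha`, i.e.
#' with three or more conflict-free markers at `alpha = 0.05`.
#'
#' @param k A count or a [support_pattern()] object.
#' @param l,m Alternative-resolution counts (ignored when `k` is a
#'   support pattern).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble with `k`, `l`, `m`, `p_value`, `significant`.
#' @export
insertion_test <- function(k, l = 0, m = 0, alpha = 0.05) {
  if (inherits(k, "support_pattern")) {
    l <- k$l; m <- k$m; k <- k$k
  }
  p <- multinomial_p(k, l, m)
  tibble(k = as.integer(k), l = as.integer(l), m = as.integer(m),
         p_value = p, significant = p < alpha)
}

#' Per-edge support table of a tree
#'
#' For every internal clade of a rooted tree (excluding the root itself),
#' counts the `[k l m]` support pattern of the matrix around that edge --
#' the clade's daughters against the remaining taxa -- and attaches the
#' exact multinomial p-value. For a polytomous clade the daughter split
#' used for the conflict counts is the first child versus the rest.
#'
#' @param tree A rooted `phylo` tree whose tips appear in the matrix.
#' @param x A [marker_matrix()].
#' @param alpha Significance level.
#' @return A tibble with one row per internal edge: the clade's taxa, the
#'   pattern counts, p-value and significance flag.
#' @export
edge_support_table <- function(tree, x, alpha = 0.05) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object")
  missing_taxa <- setdiff(tree$tip.label, x$taxa)
  if (length(missing_taxa) > 0) {
    abort(paste0("tree tips absent from matrix: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  internal <- setdiff(unique(tree$edge[, 1]), root)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  clade_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], clade_tips))
  }
  rows <- lapply(internal, function(node) {
    kids <- children[[as.character(node)]]
    tips <- clade_tips(node)
    s1 <- clade_tips(kids[1])
    s2 <- setdiff(tips, s1)
    sp <- support_pattern(x, focal = tips, split = list(s1, s2))
    res <- if (sp$k >= max(sp$l, sp$m)) {
      insertion_test(sp, alpha = alpha)
    } else {
      # the edge is not the best-supported resolution; no test is defined
      tibble(k = sp$k, l = sp$l, m = sp$m, p_value = NA_real_,
             significant = FALSE)
    }
    tibble(node = node, clade = paste(sort(tips), collapse = ","),
           n_taxa = length(tips)) %>% dplyr::bind_cols(res)
  })
  bind_rows(rows) %>% arrange(dplyr::desc(.data$n_taxa))
}
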