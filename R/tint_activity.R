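#' TinT activity likelihood
#'
#' The chronology model treats each repeat family `f` as active over times
#' distributed Normal(`mu_f`, `sigma_f`) on a latent relative axis where
#' larger values are more recent. A guest inserting at time `t` can only land
#' in host copies already present, so the available target mass of host
#' family `j` at time `t` is `w_j * F_j(t)`, with `F_j` the host's activity
#' CDF and `w_j` its relative copy abundance. Conditional on the guest
#' family `i`, the probability that an observed nesting has host `j` is
#'
#'   `P(j | i) = E_t[w_j F_j(t)] / sum_k E_t[w_k F_k(t)]`,  `t ~ N(mu_i, sigma_i)`
#'
#' and the count matrix is multinomial per guest row. The expectation is
#' evaluated by fixed-node Gauss--Hermite quadrature.
#'
#' @param counts A `tint_matrix` (or square named count matrix).
#' @param mu,sigma Numeric vectors of per-family activity locations and
#'   spreads, in the order of `rownames(counts)`.
#' @param weights Relative copy abundances (any positive scale).
#' @param n_nodes Number of Gauss--Hermite quadrature nodes (>= 32 by
#'   default).
#' @return The log-likelihood of the count matrix.
#' @export
activity_log_likelihood <- function(counts, mu, sigma, weights = NULL,
                                    n_nodes = 32) {
  m <- unclass(counts)
  f <- nrow(m)
  stopifnot(length(mu) == f, length(sigma) == f, all(sigma > 0))
  if (is.null(weights)) weights <- default_copy_weights(m)
  gh <- pracma::gaussHermite(n_nodes)
  p <- host_probabilities(mu, sigma, weights, gh)
  sum(m * log(pmax(p, 1e-300)))
}

# P(host = j | guest = i): F x F row-stochastic matrix
host_probabilities <- function(mu, sigma, weights, gh) {
  f <- length(mu)
  q <- length(gh$x)
  # t values per guest family and node: F x Q
  tv <- outer(sigma * sqrt(2), gh$x) + mu
  # cdf array: (F*Q) x F, entry [iq, j] = Phi((t_iq - mu_j) / sigma_j)
  z <- (rep(as.vector(tv), times = f) -
          rep(mu, each = f * q)) / rep(sigma, each = f * q)
  cdf <- array(pnorm(z), dim = c(f, q, f))
  # expectation over nodes with GH weights (normalized by sqrt(pi))
  wq <- gh$w / sqrt(pi)
  ex <- apply(cdf * rep(wq, each = f), c(1, 3), sum)  # F x F
  ex <- sweep(ex, 2, weights, `*`)
  sweep(ex, 1, rowSums(ex), `/`)
}

default_copy_weights <- function(m) {
  w <- rowSums(m) + colSums(m)
  if (all(w == 0)) w <- rep(1, nrow(m))
  w / sum(w)
}

#' Estimate relative retroposon family activity periods
#'
#' Fits the TinT chronology model (see [activity_log_likelihood()]) to a
#' guest-into-host nesting count matrix by multi-start quasi-Newton
#' maximum likelihood. The relative time axis is identified by constraining
#' `mean(mu) = 0` and `mean(sigma) = 1`; spreads are optimized on the log
#' scale and floored at `sigma_floor`. Copy weights `w` are fixed, by
#' default to each family's share of total nesting participation; supply
#' genome-wide copy counts via `copy_weights` when available.
#'
#' Families with an all-zero row and column carry no information about
#' their activity and are excluded with a warning.
#'
#' @param counts A `tint_matrix` from [build_tint_matrix()], with at least
#'   two families and one event.
#' @param copy_weights Optional named positive vector of relative copy
#'   abundances per family.
#' @param n_restarts Number of optimizer starts (default 10).
#' @param n_nodes Gauss--Hermite nodes (default 32).
#' @param sigma_floor Lower bound for fitted spreads (default 1e-3).
#' @param seed Integer seed controlling the random restarts.
#' @param max_iter Maximum BFGS iterations per start.
#'
#' @return An object of class `activity_model`: a list with `families`,
#'   `mu`, `sigma`, `copy_weight`, `log_likelihood`, `n_events`,
#'   `convergence` and the call configuration. Larger `mu` means more
#'   recent activity.
#' @export
estimate_activity <- function(counts, copy_weights = NULL, n_restarts = 10,
                              n_nodes = 32, sigma_floor = 1e-3, seed = 1,
                              max_iter = 300) {
  m <- unclass(counts)
  if (is.null(rownames(m))) abort("`counts` must have family names")
  keep <- rowSums(m) + colSums(m) > 0
  if (any(!keep)) {
    warn(paste0("families with no nesting events excluded (activity unidentifiable): ",
                paste(rownames(m)[!keep], collapse = ", ")))
    m <- m[keep, keep, drop = FALSE]
  }
  fam <- rownames(m)
  f <- length(fam)
  if (f < 2) abort("activity estimation needs at least 2 families with events")
  if (sum(m) < 1) abort("activity estimation needs at least 1 nesting event")
  if (!is.null(copy_weights)) {
    if (is.null(names(copy_weights)) || !all(fam %in% names(copy_weights))) {
      abort("`copy_weights` must be named and cover every family")
    }
    w <- copy_weights[fam] / sum(copy_weights[fam])
  } else {
    w <- default_copy_weights(m)
  }
  gh <- pracma::gaussHermite(n_nodes)

  unpack <- function(par) {
    mu <- par[1:f] - mean(par[1:f])
    s <- exp(par[(f + 1):(2 * f)])
    sigma <- sigma_floor + (1 - sigma_floor) * f * s / sum(s)
    list(mu = mu, sigma = sigma)
  }
  negll <- function(par) {
    p <- unpack(par)
    pr <- host_probabilities(p$mu, p$sigma, w, gh)
    -sum(m * log(pmax(pr, 1e-300)))
  }

  # deterministic first start: order families by net guest excess
  asym <- (rowSums(m) - colSums(m)) / (rowSums(m) + colSums(m) + 1)
  asym <- if (stats::sd(asym) > 0) (asym - mean(asym)) / stats::sd(asym) else rep(0, f)
  starts <- list(c(asym, rep(0, f)))
  set.seed(seed)
  for (r in seq_len(max(0, n_restarts - 1))) {
    starts[[r + 1]] <- c(rnorm(f), rnorm(f, sd = 0.5))
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, negll, method = "BFGS",
            control = list(maxit = max_iter, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("activity optimization failed for every start")
  p <- unpack(best$par)
  structure(list(
    families = fam,
    mu = setNames(p$mu, fam),
    sigma = setNames(p$sigma, fam),
    copy_weight = setNames(as.numeric(w), fam),
    log_likelihood = -best$value,
    n_events = sum(m),
    convergence = best$convergence,
    n_restarts = n_restarts, n_nodes = n_nodes,
    sigma_floor = sigma_floor, seed = seed),
    class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model> ", length(x$families), " families, ",
      x$n_events, " nesting events, log-likelihood ",
      format(x$log_likelihood, digits = 6), "\n", sep = "")
  print(tidy(x), n = length(x$families))
  invisible(x)
}

#' @export
tidy.activity_model <- function(x, ...) {
  iv <- activity_intervals(x)
  wide <- iv %>%
    mutate(level = paste0("q", .data$level * 100)) %>%
    tidyr::pivot_wider(names_from = "level",
                       values_from = c("lower", "upper"))
  tibble(family = x$families, mu = as.numeric(x$mu),
         sigma = as.numeric(x$sigma),
         copy_weight = as.numeric(x$copy_weight)) %>%
    left_join(wide, by = "family") %>%
    arrange(.data$mu)
}

#' @export
glance.activity_model <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood,
         n_families = length(x$families), n_events = x$n_events,
         n_restarts = x$n_restarts, converged = x$convergence == 0)
}

#' Central activity intervals of fitted families
#'
#' Central intervals of each family's Normal activity density:
#' `mu_f +/- z(level) * sigma_f`, with `z(0.5) = 0.6745` and
#' `z(0.9) = 1.6449`. The 50% interval is always nested inside the 90%
#' interval.
#'
#' @param model An [estimate_activity()] fit.
#' @param levels Probability levels in (0, 1); default `c(0.5, 0.9)`.
#' @return A tibble with columns `family`, `level`, `lower`, `upper`.
#' @export
activity_intervals <- function(model, levels = c(0.5, 0.9)) {
  if (any(!is.finite(levels)) || any(levels <= 0) || any(levels >= 1)) {
    abort("`levels` must be probabilities strictly between 0 and 1")
  }
  purrr::map_dfr(levels, function(lv) {
    z <- qnorm((1 + lv) / 2)
    tibble(family = model$families, level = lv,
           lower = as.numeric(model$mu - z * model$sigma),
           upper = as.numeric(model$mu + z * model$sigma))
  })
}

#' Chronology plot of fitted activity periods
#'
#' Draws each family's activity period on the relative time axis: a thin
#' line spanning the 90% interval, a thick bar spanning the 50% interval,
#' and a point at the activity peak, families ordered by `mu`.
#'
#' @param object An `activity_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_model <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(family = factor(.data$family, levels = .data$family))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$family)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower_q90,
                                       xend = .data$upper_q90,
                                       yend = .data$family),
                          linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower_q50,
                                       xend = .data$upper_q50,
                                       yend = .data$family),
                          linewidth = 2.5, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mu), size = 2) +
    ggplot2::labs(x = "relative time (larger = more recent)", y = NULL)
}

#' Partition repeat families by lineage
#'
#' Given activity models fitted to two genomes, families present in only
#' one genome's annotation are lineage-specific; families in both are
#' shared. The partition is exhaustive and disjoint over the supplied
#' family universe.
#'
#' @param model_a,model_b `activity_model` fits (or plain character vectors
#'   of family names).
#' @param families Optional universe of families to classify; defaults to
#'   the union of the two models' families.
#' @return A list with elements `a_specific`, `b_specific`, `shared`.
#' @export
classify_lineages <- function(model_a, model_b, families = NULL) {
  fa <- if (inherits(model_a, "activity_model")) model_a$families else model_a
  fb <- if (inherits(model_b, "activity_model")) model_b$families else model_b
  if (is.null(families)) families <- union(fa, fb)
  list(a_specific = sort(intersect(setdiff(fa, fb), families)),
       b_specific = sort(intersect(setdiff(fb, fa), families)),
       shared = sort(intersect(intersect(fa, fb), families)))
}

#' Simulate a TinT count matrix from the chronology model
#'
#' Draws nesting events directly from the activity likelihood: each event
#' picks a guest family (proportional to `weights`), an insertion time from
#' the guest's activity density, and a host family with probability
#' proportional to `w_j * F_j(t)`. Used for parameter-recovery checks.
#'
#' @param mu,sigma Named numeric vectors of true activity locations/spreads.
#' @param n_events Number of nesting events to draw.
#' @param weights Relative copy abundances; default equal.
#' @param seed Integer seed.
#' @return A `tint_matrix`.
#' @export
simulate_tint_matrix <- function(mu, sigma, n_events, weights = NULL,
                                 seed = 1) {
  fam <- names(mu)
  if (is.null(fam)) abort("`mu` must be named by family")
  f <- length(fam)
  if (is.null(weights)) weights <- rep(1 / f, f)
  weights <- weights / sum(weights)
  set.seed(seed)
  guests <- sample.int(f, n_events, replace = TRUE, prob = weights)
  t <- rnorm(n_events, mu[guests], sigma[guests])
  # host probabilities per event: n x F
  ph <- outer(t, seq_len(f), function(tt, j) {
    weights[j] * pnorm((tt - mu[j]) / sigma[j])
  })
  ph <- ph / rowSums(ph)
  hosts <- vapply(seq_len(n_events),
                  function(i) sample.int(f, 1, prob = ph[i, ]), 1L)
  m <- matrix(0L, f, f, dimnames = list(guest = fam, host = fam))
  tab <- table(factor(guests, levels = seq_len(f)),
               factor(hosts, levels = seq_len(f)))
  m[] <- as.integer(tab)
  attr(m, "total_events") <- n_events
  class(m) <- c("tint_matrix", "matrix", "array")
  m
}
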