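#' Identify network hubs from betweenness centrality
#'
#' A node is a hub when its betweenness exceeds the network mean by more
#' than two standard deviations (sample SD over all N nodes, strict
#' inequality). The recommended basis is the per-node AUC of betweenness
#' over the density grid, which [hub_analysis()] computes for you.
#'
#' @param values A numeric vector of per-node betweenness values (typically
#'   AUC over densities), or a data frame with columns `roi` and `value`.
#' @param roi Node labels (ignored when `values` is a data frame).
#' @return A tibble of class `scn_hubs`: `roi`, `value`, `is_hub`, with
#'   attributes `mean`, `sd`, `threshold`. Zero variance across nodes gives
#'   an empty hub set with a warning.
#' @export
identify_hubs <- function(values, roi = NULL) {
  if (is.data.frame(values)) {
    roi <- values$roi
    values <- values$value %||% values$auc
  }
  if (length(values) < 3) abort("need at least 3 nodes", class = "scn_validation_error")
  if (is.null(roi)) roi <- paste0("node", seq_along(values))
  mu <- mean(values)
  s <- sd(values)
  if (s == 0) {
    warn("zero variance across nodes: no hubs identified")
    thr <- mu
    flags <- rep(FALSE, length(values))
  } else {
    thr <- mu + 2 * s
    flags <- values > thr
  }
  structure(tibble::tibble(roi = roi, value = values, is_hub = flags),
            mean = mu, sd = s, threshold = thr,
            class = c("scn_hubs", class(tibble::tibble())))
}

#' @method glance scn_hubs
#' @export
glance.scn_hubs <- function(x, ...) {
  tibble::tibble(mean = attr(x, "mean"), sd = attr(x, "sd"),
                 threshold = attr(x, "threshold"), n_hubs = sum(x$is_hub))
}

#' Per-group hub identification from betweenness AUC
#'
#' Computes each node's betweenness-centrality AUC over the density grid
#' within each group's covariance network and applies the
#' mean + 2 SD hub rule.
#'
#' @param residuals An `scn_residuals` table.
#' @param grid Densities from [density_grid()].
#' @return A tibble: `group`, `roi`, `value` (betweenness AUC), `is_hub`.
#' @export
hub_analysis <- function(residuals, grid = density_grid()) {
  nc <- nodal_curves(residuals, grid)
  aucs <- glance.scn_nodal_curves(nc)
  aucs <- aucs[aucs$metric == "betweenness", ]
  out <- dplyr::group_modify(
    dplyr::group_by(aucs, .data$group),
    function(d, key) {
      h <- identify_hubs(d$auc, d$roi)
      tibble::as_tibble(h)
    })
  dplyr::ungroup(out)
}

attack_curve <- function(net, order_fn) {
  N <- net$N
  g <- as_igraph(net)
  lcc <- numeric(N + 1)
  lcc[1] <- max(igraph::components(g)$csize) / N
  for (step in seq_len(N)) {
    victim <- order_fn(g)
    g <- igraph::delete_vertices(g, victim)
    lcc[step + 1] <- if (igraph::vcount(g) == 0) 0 else
      max(igraph::components(g)$csize) / N
  }
  tibble::tibble(n_removed = 0:N, frac_removed = (0:N) / N, lcc_frac = lcc)
}

#' Robustness under targeted (degree-ranked) attack
#'
#' Iteratively removes the node with the currently highest degree (degree
#' recomputed after every removal; ties broken by node order), recording the
#' largest connected component as a fraction of the original N after each
#' step.
#'
#' @param net An `scn_graph`.
#' @return A tibble of class `scn_robustness` with columns `n_removed`,
#'   `frac_removed`, `lcc_frac`, attribute `auc` (trapezoidal area of the
#'   curve), and `kind = "targeted"`.
#' @export
targeted_attack <- function(net) {
  stopifnot(inherits(net, "scn_graph"))
  if (!igraph::is_connected(as_igraph(net)))
    warn("input graph is not connected; robustness curve starts below full coverage")
  curve <- attack_curve(net, function(g) {
    deg <- igraph::degree(g)
    which.max(deg) # first max = lowest node order
  })
  structure(curve, kind = "targeted", auc = trapz(curve$frac_removed, curve$lcc_frac),
            class = c("scn_robustness", class(tibble::tibble())))
}

#' Robustness under random node-removal attack
#'
#' Averages the largest-component fraction over `reps` seeded uniformly
#' random removal orders at each removal count.
#'
#' @param net An `scn_graph`.
#' @param reps Number of random removal orders (default 100).
#' @param seed Integer seed.
#' @return A tibble of class `scn_robustness` (mean curve), attribute `auc`,
#'   `kind = "random"`, plus `reps` and `seed`.
#' @export
random_attack <- function(net, reps = 100, seed = 1L) {
  stopifnot(inherits(net, "scn_graph"), reps >= 1)
  N <- net$N
  curves <- local_seed(as.integer(seed), lapply(seq_len(reps), function(r) {
    ord <- sample.int(N)
    pos <- 0L
    attack_curve(net, function(g) {
      pos <<- pos + 1L
      which(igraph::V(g)$name == rownames(net$a)[ord[pos]])
    })$lcc_frac
  }))
  lcc <- Reduce(`+`, curves) / reps
  curve <- tibble::tibble(n_removed = 0:N, frac_removed = (0:N) / N, lcc_frac = lcc)
  structure(curve, kind = "random", reps = reps, seed = as.integer(seed),
            auc = trapz(curve$frac_removed, curve$lcc_frac),
            class = c("scn_robustness", class(tibble::tibble())))
}

#' @method glance scn_robustness
#' @export
glance.scn_robustness <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"), auc = attr(x, "auc"))
}
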