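core_metric_names <- c("cp", "lp", "eglob", "eloc", "transitivity", "assortativity")
global_metric_names <- c(core_metric_names, "modularity")

want_mask <- function(metrics) core_metric_names %in% metrics

#' Nodal graph metrics
#'
#' Degree (row sums of the adjacency), shortest-path betweenness centrality
#' normalized by `(N-1)(N-2)/2`, and the local clustering coefficient
#' `c_i = 2 t_i / (k_i (k_i - 1))` (zero when `k_i < 2`).
#'
#' @param net An `scn_graph`.
#' @return A tibble with columns `roi`, `degree`, `betweenness`, `clustering`.
#' @export
nodal_metrics <- function(net) {
  stopifnot(inherits(net, "scn_graph"))
  N <- net$N
  if (N < 3) abort("need at least 3 nodes", class = "scn_validation_error")
  res <- cpp_metrics_adjacency(net$a, rep(FALSE, 6))
  btw <- igraph::betweenness(as_igraph(net), directed = FALSE, normalized = FALSE)
  tibble::tibble(
    roi = rownames(net$a),
    degree = as.integer(res$degree),
    betweenness = unname(btw) / ((N - 1) * (N - 2) / 2),
    clustering = res$clustering)
}

#' Global graph metrics
#'
#' Computes the mean clustering coefficient `Cp`, the harmonic-mean
#' characteristic path length `Lp` (number of ordered node pairs divided by
#' the sum of reciprocal shortest-path distances, disconnected pairs
#' contributing zero), global efficiency (`Eglob = 1/Lp` exactly under this
#' convention), local efficiency, transitivity (3 x triangles / connected
#' triples), degree assortativity, and modularity `Q` of the best partition
#' found by greedy agglomerative optimization
#' ([igraph::cluster_fast_greedy()], which is deterministic).
#'
#' @param net An `scn_graph`.
#' @param modularity_seed Kept for interface stability; the modularity
#'   optimizer is deterministic, so this value does not change results.
#' @return A one-row tibble: `density`, `cp`, `lp`, `eglob`, `eloc`,
#'   `transitivity`, `assortativity`, `modularity`.
#' @export
global_metrics <- function(net, modularity_seed = 1L) {
  stopifnot(inherits(net, "scn_graph"))
  if (net$N < 3) abort("need at least 3 nodes", class = "scn_validation_error")
  if (net$E == 0) abort("empty graph: no global metrics", class = "scn_validation_error")
  res <- cpp_metrics_adjacency(net$a, rep(TRUE, 6))
  m <- res$metrics
  g <- as_igraph(net)
  q <- local_seed(as.integer(modularity_seed),
                  igraph::modularity(igraph::cluster_fast_greedy(g)))
  tibble::tibble(density = net$density,
                 cp = m[["cp"]], lp = m[["lp"]], eglob = m[["eglob"]],
                 eloc = m[["eloc"]], transitivity = m[["transitivity"]],
                 assortativity = m[["assortativity"]], modularity = q)
}

modularity_edges <- function(el, N) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < N) g <- igraph::add_vertices(g, N - igraph::vcount(g))
  igraph::modularity(igraph::cluster_fast_greedy(g))
}

#' Degree-preserving null ensemble
#'
#' Generates `m` rewired versions of a binary network by seeded double-edge
#' swaps (rejecting self-loops and multi-edges), preserving every node's
#' degree exactly, and records the ensemble-mean clustering coefficient
#' `C_rand` and harmonic path length `L_rand` used to normalize small-world
#' statistics. Graphs too rigid to swap (e.g. complete graphs) yield an
#' ensemble of identical copies with a warning.
#'
#' @param net An `scn_graph`.
#' @param m Number of null networks (default 20).
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed.
#' @return An object of class `scn_nulls`: list with `c_rand`, `l_rand`,
#'   per-member `cp` and `lp`, the member degree sequences, `m`, and `seed`.
#' @export
random_reference <- function(net, m = 20, swaps_per_edge = 10, seed = 1L) {
  stopifnot(inherits(net, "scn_graph"), m >= 1)
  if (net$E < 2) abort("need at least 2 edges to rewire", class = "scn_validation_error")
  g0 <- as_igraph(net)
  niter <- as.integer(swaps_per_edge * net$E)
  members <- local_seed(as.integer(seed), lapply(seq_len(m), function(i) {
    igraph::rewire(g0, igraph::keeping_degseq(loops = FALSE, niter = niter))
  }))
  stats <- lapply(members, function(g) {
    a <- as.integer(igraph::as_adjacency_matrix(g, sparse = FALSE))
    A <- matrix(a, net$N, net$N)
    r <- cpp_metrics_adjacency(A, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
    list(cp = r$metrics[["cp"]], lp = r$metrics[["lp"]],
         deg = as.integer(r$degree), A = A)
  })
  identical_all <- all(vapply(stats, function(s) identical(s$A, unname(net$a) + 0L) ||
                                all(s$A == net$a), logical(1)))
  if (identical_all) {
    warn("graph admits no degree-preserving swaps; null ensemble equals the input graph")
  }
  structure(list(
    c_rand = mean(vapply(stats, `[[`, numeric(1), "cp")),
    l_rand = mean(vapply(stats, `[[`, numeric(1), "lp")),
    cp = vapply(stats, `[[`, numeric(1), "cp"),
    lp = vapply(stats, `[[`, numeric(1), "lp"),
    degree_sequences = vapply(stats, `[[`, integer(net$N), "deg"),
    m = m, seed = as.integer(seed)), class = "scn_nulls")
}

#' Small-world parameters
#'
#' `gamma = Cp / C_rand`, `lambda = Lp / L_rand`, `sigma = gamma / lambda`,
#' normalizing against a degree-preserving null ensemble. `sigma > 1`
#' (clustering well above random at near-random path length) is the
#' small-world signature.
#'
#' @param net An `scn_graph`.
#' @param nulls An `scn_nulls` ensemble from [random_reference()].
#' @return A one-row tibble: `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(net, nulls) {
  stopifnot(inherits(net, "scn_graph"), inherits(nulls, "scn_nulls"))
  if (!is.finite(nulls$c_rand) || nulls$c_rand <= 0)
    abort("C_rand is zero: small-world parameters undefined", class = "scn_validation_error")
  if (!is.finite(nulls$l_rand) || nulls$l_rand <= 0)
    abort("L_rand is zero: small-world parameters undefined", class = "scn_validation_error")
  res <- cpp_metrics_adjacency(net$a, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  gamma <- res$metrics[["cp"]] / nulls$c_rand
  lambda <- res$metrics[["lp"]] / nulls$l_rand
  tibble::tibble(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Global metric curves across the density grid
#'
#' For each group and each grid density, builds the group covariance
#' network, thresholds it to that density, and computes the global metrics
#' (and optionally small-world parameters, each density point normalized by
#' its own null ensemble).
#'
#' @param residuals An `scn_residuals` table.
#' @param grid Densities from [density_grid()].
#' @param metrics Which metrics to compute (default all seven global
#'   metrics).
#' @param small_world Logical: also compute gamma/lambda/sigma per density.
#' @param m,swaps_per_edge Null-ensemble settings for small-world curves.
#' @param seed Integer seed for the null ensembles.
#' @return A tibble of class `scn_curves`: `group`, `metric`, `density`,
#'   `value`, one row per group x metric x density. [glance()] returns the
#'   trapezoidal AUC per group x metric.
#' @export
metric_curves <- function(residuals, grid = density_grid(),
                          metrics = global_metric_names,
                          small_world = FALSE, m = 20, swaps_per_edge = 10,
                          seed = 1L) {
  stopifnot(inherits(residuals, "scn_residuals"))
  groups <- unique(as.character(residuals[[group_col(residuals)]]))
  N <- length(roi_labels(residuals))
  Evec <- vapply(grid, edges_at_density, integer(1), N = N)
  want <- want_mask(metrics)
  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    X <- residual_matrix(residuals, grp)
    core <- cpp_group_curves(X, Evec, want)
    for (k in which(want)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = grp, metric = core_metric_names[k], density = grid,
        value = core[k, ])
    }
    need_graphs <- "modularity" %in% metrics || small_world
    if (need_graphs) {
      els <- cpp_density_edges(cor(X), Evec)
      if ("modularity" %in% metrics) {
        q <- vapply(els, modularity_edges, numeric(1), N = N)
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = grp, metric = "modularity", density = grid, value = q)
      }
      if (small_world) {
        sw <- purrr::imap(els, function(el, di) {
          a <- matrix(0L, N, N)
          a[el] <- 1L; a[el[, 2:1, drop = FALSE]] <- 1L
          gnet <- new_scn_graph(a, roi_labels(residuals), grp, "density grid")
          nulls <- random_reference(gnet, m = m, swaps_per_edge = swaps_per_edge,
                                    seed = stage_seed(seed, gi * 1000 + di))
          small_world(gnet, nulls)
        })
        swt <- dplyr::bind_rows(sw)
        for (nm in c("gamma", "lambda", "sigma")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            group = grp, metric = nm, density = grid, value = swt[[nm]])
        }
      }
    }
  }
  structure(dplyr::bind_rows(rows),
            groups = groups, grid = grid,
            class = c("scn_curves", class(tibble::tibble())))
}

#' @method glance scn_curves
#' @export
glance.scn_curves <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$group, .data$metric),
                   auc = trapz(.data$density, .data$value), .groups = "drop")
}

#' Nodal metric values across the density grid, with per-node AUC
#'
#' @param residuals An `scn_residuals` table.
#' @param grid Densities from [density_grid()].
#' @return A tibble of class `scn_nodal_curves`: `group`, `metric`, `roi`,
#'   `density`, `value`. [glance()] gives the per-node trapezoidal AUC.
#' @export
nodal_curves <- function(residuals, grid = density_grid()) {
  stopifnot(inherits(residuals, "scn_residuals"))
  groups <- unique(as.character(residuals[[group_col(residuals)]]))
  rois <- roi_labels(residuals)
  N <- length(rois)
  Evec <- vapply(grid, edges_at_density, integer(1), N = N)
  rows <- list()
  for (grp in groups) {
    X <- residual_matrix(residuals, grp)
    els <- cpp_density_edges(cor(X), Evec)
    for (di in seq_along(grid)) {
      nm <- nodal_from_edges(els[[di]], N, rois)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidyr::pivot_longer(nm, -"roi", names_to = "metric", values_to = "value"),
        group = grp, density = grid[di], .before = 1)
    }
  }
  structure(dplyr::bind_rows(rows),
            groups = groups, grid = grid,
            class = c("scn_nodal_curves", class(tibble::tibble())))
}

nodal_from_edges <- function(el, N, rois) {
  a <- matrix(0L, N, N)
  a[el] <- 1L; a[el[, 2:1, drop = FALSE]] <- 1L
  res <- cpp_metrics_adjacency(a, rep(FALSE, 6))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < N) g <- igraph::add_vertices(g, N - igraph::vcount(g))
  btw <- igraph::betweenness(g, directed = FALSE)
  tibble::tibble(roi = rois,
                 degree = as.numeric(res$degree),
                 betweenness = as.numeric(btw) / ((N - 1) * (N - 2) / 2),
                 clustering = res$clustering)
}

#' @method glance scn_nodal_curves
#' @export
glance.scn_nodal_curves <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$group, .data$metric, .data$roi),
    auc = trapz(.data$density, .data$value), .groups = "drop")
}
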