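#' Density grid for network thresholding
#'
#' Densities are generated by integer stepping (e.g. 33..50 / 100) so grid
#' values carry no floating-point drift. The defaults span 0.33-0.50 in
#' steps of 0.01: the lower bound is the minimum density at which group
#' covariance networks typically stay fully connected, the upper bound the
#' conventional limit beyond which binary brain graphs lose interpretability.
#'
#' @param d_min,d_max,step Grid bounds and increment, all in (0, 1].
#' @return A numeric vector of densities, increasing.
#' @export
density_grid <- function(d_min = 0.33, d_max = 0.50, step = 0.01) {
  stopifnot(d_min > 0, d_min <= d_max, d_max <= 1, step > 0)
  dec <- max(0, -floor(log10(step)))
  scale <- 10^dec
  lo <- round(d_min * scale)
  hi <- round(d_max * scale)
  by <- round(step * scale)
  seq(lo, hi, by = by) / scale
}

#' Group-level covariance network
#'
#' The structural covariance network of one group: entry `r_ij` is the
#' Pearson correlation between the covariate-adjusted volumes of regions
#' `i` and `j` across that group's subjects.
#'
#' @param residuals An `scn_residuals` table from [residualize()].
#' @param group Group label; `NULL` uses all subjects.
#' @return An object of class `scn_network`: list with elements `r` (the
#'   N x N correlation matrix), `roi_labels`, `group`, `n_subjects`.
#' @export
correlation_network <- function(residuals, group = NULL) {
  X <- residual_matrix(residuals, group)
  if (nrow(X) < 3) abort("need at least 3 subjects to correlate", class = "scn_validation_error")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance residuals for ROI: ",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
          class = "scn_validation_error")
  }
  r <- cor(X)
  structure(list(r = r, roi_labels = colnames(X),
                 group = group %||% "all", n_subjects = nrow(X)),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat("<scn_network> group:", x$group, "-", length(x$roi_labels), "ROIs,",
      x$n_subjects, "subjects\n")
  invisible(x)
}

new_scn_graph <- function(a, roi, group, provenance) {
  dimnames(a) <- list(roi, roi)
  N <- nrow(a)
  E <- sum(a) / 2
  structure(list(a = a, N = N, E = as.integer(E),
                 density = E / (N * (N - 1) / 2),
                 group = group, provenance = provenance),
            class = "scn_graph")
}

#' @export
print.scn_graph <- function(x, ...) {
  cat(sprintf("<scn_graph> %s: N=%d, E=%d, density=%.4f (%s)\n",
              x$group, x$N, x$E, x$density, x$provenance))
  invisible(x)
}

#' Binarize a covariance network at an absolute correlation threshold
#'
#' `a_ij = 1` iff `r_ij > t` and `i != j`; the diagonal is zero.
#'
#' @param net An `scn_network`.
#' @param t Threshold in (-1, 1); the field-standard default is 0.1.
#' @return An `scn_graph`: symmetric 0/1 adjacency with zero diagonal,
#'   achieved density, and provenance.
#' @export
threshold_absolute <- function(net, t = 0.1) {
  stopifnot(inherits(net, "scn_network"), t > -1, t < 1)
  a <- (net$r > t) * 1L
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  new_scn_graph(a, net$roi_labels, net$group, sprintf("absolute r > %g", t))
}

#' Binarize a covariance network at a target density
#'
#' Retains exactly `E = round(D * N(N-1)/2)` edges with the largest
#' correlations (rounding half away from zero). Only positive correlations
#' may form edges; ties at the boundary break lexicographically on the ROI
#' index pair, making the edge set deterministic and nested across
#' densities.
#'
#' @param net An `scn_network`.
#' @param D Target density in (0, 1].
#' @return An `scn_graph` at the achieved density `E / (N(N-1)/2)`.
#' @export
threshold_density <- function(net, D) {
  stopifnot(inherits(net, "scn_network"), D > 0, D <= 1)
  N <- nrow(net$r)
  E <- edges_at_density(D, N)
  if (E < 1) abort("density too small: zero edges requested", class = "scn_validation_error")
  el <- cpp_density_edges(net$r, E)[[1]]
  a <- matrix(0L, N, N)
  a[el] <- 1L
  a[el[, 2:1, drop = FALSE]] <- 1L
  new_scn_graph(a, net$roi_labels, net$group, sprintf("density D = %g", D))
}

#' Minimum grid density giving a fully connected network
#'
#' Scans the grid upward and returns the smallest density at which the
#' density-thresholded graph forms a single connected component spanning all
#' nodes, or `NA` if no grid density achieves this.
#'
#' @param net An `scn_network`.
#' @param grid Densities from [density_grid()].
#' @return A single density value, or `NA_real_`.
#' @export
min_connected_density <- function(net, grid = density_grid()) {
  for (D in grid) {
    g <- tryCatch(threshold_density(net, D), error = function(e) NULL)
    if (!is.null(g) && igraph::is_connected(as_igraph(g))) return(D)
  }
  NA_real_
}

#' Construct a binary network from an adjacency matrix
#'
#' @param a Symmetric 0/1 matrix (the diagonal is zeroed).
#' @param roi Node labels (defaults to the matrix dimnames or `n1..nN`).
#' @param group Group label for bookkeeping.
#' @return An `scn_graph`.
#' @export
as_scn_graph <- function(a, roi = NULL, group = "graph") {
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a), isTRUE(all.equal(a, t(a), check.attributes = FALSE)))
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  roi <- roi %||% rownames(a) %||% paste0("n", seq_len(nrow(a)))
  new_scn_graph(a, roi, group, "adjacency")
}

#' Convert an scn_graph to an igraph object
#' @param net An `scn_graph`.
#' @return An undirected `igraph` graph with ROI names as vertex names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "scn_graph"))
  igraph::graph_from_adjacency_matrix(net$a, mode = "undirected", diag = FALSE)
}

#' Export a network as a delimited matrix, edge list, or GraphML
#'
#' @param net An `scn_graph` or `scn_network`.
#' @param path Output path.
#' @param format `"matrix"` (square table with ROI headers), `"edgelist"`,
#'   or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edgelist", "graphml")) {
  format <- match.arg(format)
  m <- if (inherits(net, "scn_network")) net$r else net$a
  if (format == "matrix") {
    df <- tibble::as_tibble(as.data.frame(m))
    df <- dplyr::bind_cols(tibble::tibble(roi = rownames(m) %||% colnames(m)), df)
    readr::write_tsv(df, path)
  } else if (format == "edgelist") {
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    df <- tibble::tibble(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
                         weight = m[idx])
    readr::write_tsv(df, path)
  } else {
    g <- if (inherits(net, "scn_graph")) as_igraph(net) else
      igraph::graph_from_adjacency_matrix(abs(m) * upper.tri(m) > 0, mode = "undirected")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
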