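#' Seeded stream of group-label permutations
#'
#' Yields `n_perm` reassignments of subjects to two pseudo-groups that
#' preserve the original group sizes. The stream is canonical: it samples
#' the index set of the *smaller* group (ties resolved to the first-sorted
#' label), so swapping the two group labels leaves the stream — and hence
#' every two-tailed permutation p-value — unchanged.
#'
#' @param residuals An `scn_residuals` table (or `scn_cohort`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An integer matrix, `k x n_perm` (`k` = smaller group size), each
#'   column the row indices assigned to the sampled group; attributes
#'   `sampled_group`, `groups`, and `group_sizes`.
#' @export
permute_groups <- function(residuals, n_perm, seed = 1L) {
  stopifnot(n_perm >= 1)
  grp <- as.character(residuals[[group_col(residuals)]])
  sizes <- table(grp)
  groups <- names(sizes)
  sampled <- groups[order(as.integer(sizes), groups)][1]
  k <- as.integer(sizes[[sampled]])
  n <- length(grp)
  m <- local_seed(as.integer(seed),
                  vapply(seq_len(n_perm), function(i) sort(sample.int(n, k)),
                         integer(k)))
  m <- matrix(m, nrow = k)
  structure(m, sampled_group = sampled, groups = groups,
            group_sizes = as.integer(sizes[groups]))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q`: flags are `TRUE` for
#' every p-value at or below the largest `p_(i)` with `p_(i) <= i q / m`.
#'
#' @param p Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical vector in the input order (empty input gives empty output).
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  stopifnot(all(p > 0), all(p <= 1))
  p.adjust(p, method = "BH") <= q
}

perm_p <- function(observed, nulls) {
  (1 + sum(abs(nulls) >= abs(observed))) / (1 + length(nulls))
}

#' Permutation tests of group differences in network metrics
#'
#' For each label permutation the full pipeline — group correlation network,
#' density thresholding, metric computation — is recomputed on the permuted
#' pseudo-groups (covariate residuals stay fixed: they are estimated once on
#' the pooled cohort). Two-tailed p-values use the add-one rule
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`, so p is never zero.
#' Benjamini-Hochberg FDR is applied within families: per metric across grid
#' densities (`global_density`), per metric across nodes (`nodal_dmin`,
#' `nodal_auc`), and across metrics for the AUC scopes.
#'
#' @param residuals An `scn_residuals` table with exactly two groups.
#' @param grid Densities from [density_grid()].
#' @param scope One or more of `"global_density"`, `"global_auc"`,
#'   `"nodal_dmin"`, `"nodal_auc"`.
#' @param metrics Global metrics to test (any of `cp, lp, eglob, eloc,
#'   transitivity, assortativity, modularity`).
#' @param nodal_metrics Nodal metrics to test (any of `degree, betweenness,
#'   clustering`).
#' @param n_perm Number of permutations (default 1000).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble of class `scn_perm`: `scope`, `metric`, `density`,
#'   `roi`, `observed` (difference oriented first-sorted group label minus
#'   second, so relabeling the groups negates it), `p`, `fdr_significant`;
#'   the permutation null differences are kept in attribute `nulls`.
#' @export
permutation_test <- function(residuals, grid = density_grid(),
                             scope = c("global_density", "global_auc"),
                             metrics = c("cp", "lp", "eglob", "eloc",
                                         "transitivity", "assortativity", "modularity"),
                             nodal_metrics = c("degree", "betweenness", "clustering"),
                             n_perm = 1000, q = 0.05, seed = 1L) {
  stopifnot(inherits(residuals, "scn_residuals"))
  if (n_perm < 1) abort("n_perm must be at least 1", class = "scn_validation_error")
  scope <- match.arg(scope, c("global_density", "global_auc", "nodal_dmin", "nodal_auc"),
                     several.ok = TRUE)
  grp <- as.character(residuals[[group_col(residuals)]])
  groups <- sort(unique(grp)) # fixed orientation: observed = first - second
  if (length(groups) != 2) abort("need exactly two groups", class = "scn_validation_error")
  rois <- roi_labels(residuals)
  N <- length(rois)
  Evec <- vapply(grid, edges_at_density, integer(1), N = N)
  X <- as.matrix(residuals[rois])

  splits <- permute_groups(residuals, n_perm, seed)
  sampled <- attr(splits, "sampled_group")
  # engine computes sampled-group minus complement; flip if the sampled
  # group is the second level so `observed` is always group1 - group2
  flip <- if (sampled == groups[1]) 1 else -1
  obs_split <- matrix(sort(which(grp == sampled)), ncol = 1)

  need_core <- any(metrics %in% core_metric_names) &&
    any(c("global_density", "global_auc") %in% scope)
  need_mod <- "modularity" %in% metrics &&
    any(c("global_density", "global_auc") %in% scope)
  need_nodal <- any(c("nodal_dmin", "nodal_auc") %in% scope)

  rows <- list()
  nulls_out <- list()

  if (need_core || need_mod) {
    want <- want_mask(metrics)
    obs_core <- if (any(want))
      cpp_perm_curve_diffs(X, obs_split, Evec, want) * flip else NULL
    null_core <- if (any(want))
      cpp_perm_curve_diffs(X, splits, Evec, want) * flip else NULL
    obs_mod <- NULL; null_mod <- NULL
    if (need_mod) {
      mod_curve <- function(idxA) {
        XA <- X[idxA, , drop = FALSE]
        XB <- X[-idxA, , drop = FALSE]
        qa <- vapply(cpp_density_edges(cor(XA), Evec), modularity_edges, numeric(1), N = N)
        qb <- vapply(cpp_density_edges(cor(XB), Evec), modularity_edges, numeric(1), N = N)
        qa - qb
      }
      obs_mod <- mod_curve(obs_split[, 1]) * flip
      null_mod <- vapply(seq_len(n_perm), function(p) mod_curve(splits[, p]) * flip,
                         numeric(length(grid)))
      null_mod <- matrix(null_mod, nrow = length(grid))
    }
    get_obs <- function(met) {
      if (met == "modularity") obs_mod
      else obs_core[match(met, core_metric_names), , 1]
    }
    get_null <- function(met) {
      if (met == "modularity") null_mod # nD x n_perm
      else matrix(null_core[match(met, core_metric_names), , ], nrow = length(grid))
    }
    if ("global_density" %in% scope) {
      for (met in metrics) {
        ov <- get_obs(met); nv <- get_null(met)
        ps <- vapply(seq_along(grid), function(d) perm_p(ov[d], nv[d, ]), numeric(1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          scope = "global_density", metric = met, density = grid, roi = NA_character_,
          observed = ov, p = ps, fdr_significant = fdr_adjust(ps, q))
        nulls_out[[paste0("global_density.", met)]] <- nv
      }
    }
    if ("global_auc" %in% scope) {
      auc_rows <- purrr::map(metrics, function(met) {
        ov <- trapz(grid, get_obs(met))
        nv <- apply(get_null(met), 2, function(v) trapz(grid, v))
        nulls_out[[paste0("global_auc.", met)]] <<- nv
        tibble::tibble(scope = "global_auc", metric = met, density = NA_real_,
                       roi = NA_character_, observed = ov, p = perm_p(ov, nv))
      })
      auc_tbl <- dplyr::bind_rows(auc_rows)
      auc_tbl$fdr_significant <- fdr_adjust(auc_tbl$p, q)
      rows[[length(rows) + 1]] <- auc_tbl
    }
  }

  if (need_nodal) {
    dmin_only <- identical(scope[scope %in% c("nodal_dmin", "nodal_auc")], "nodal_dmin")
    Eu <- if (dmin_only) Evec[1] else Evec
    nodal_eval <- function(idxA) {
      XA <- X[idxA, , drop = FALSE]
      XB <- X[-idxA, , drop = FALSE]
      va <- nodal_stack(XA, Eu, N, rois)
      vb <- nodal_stack(XB, Eu, N, rois)
      list(dmin = va$dmin - vb$dmin,
           auc = if (!dmin_only) {
             ga <- vapply(va$stack, identity, va$stack[[1]])
             gb <- vapply(vb$stack, identity, vb$stack[[1]])
             auc_a <- apply(ga, c(1, 2), function(v) trapz(grid, v))
             auc_b <- apply(gb, c(1, 2), function(v) trapz(grid, v))
             auc_a - auc_b
           } else NULL)
    }
    obs_nodal <- nodal_eval(obs_split[, 1])
    null_nodal <- lapply(seq_len(n_perm), function(p) nodal_eval(splits[, p]))
    for (met in nodal_metrics) {
      if ("nodal_dmin" %in% scope) {
        ov <- obs_nodal$dmin[, met] * flip
        nv <- vapply(null_nodal, function(x) x$dmin[, met], numeric(N)) * flip
        ps <- vapply(seq_len(N), function(i) perm_p(ov[i], nv[i, ]), numeric(1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          scope = "nodal_dmin", metric = met, density = grid[1], roi = rois,
          observed = ov, p = ps, fdr_significant = fdr_adjust(ps, q))
        nulls_out[[paste0("nodal_dmin.", met)]] <- nv
      }
      if ("nodal_auc" %in% scope) {
        ov <- obs_nodal$auc[, met] * flip
        nv <- vapply(null_nodal, function(x) x$auc[, met], numeric(N)) * flip
        ps <- vapply(seq_len(N), function(i) perm_p(ov[i], nv[i, ]), numeric(1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          scope = "nodal_auc", metric = met, density = NA_real_, roi = rois,
          observed = ov, p = ps, fdr_significant = fdr_adjust(ps, q))
        nulls_out[[paste0("nodal_auc.", met)]] <- nv
      }
    }
  }

  structure(dplyr::bind_rows(rows),
            nulls = nulls_out, n_perm = n_perm, seed = as.integer(seed),
            groups = groups, grid = grid, q = q,
            class = c("scn_perm", class(tibble::tibble())))
}

# per-density nodal metric values for one pseudo-group
# returns dmin matrix (N x 3) and, via stack, one N x 3 matrix per density
nodal_stack <- function(Xg, Evec, N, rois) {
  els <- cpp_density_edges(cor(Xg), Evec)
  mats <- lapply(els, function(el) {
    nm <- nodal_from_edges(el, N, rois)
    as.matrix(nm[c("degree", "betweenness", "clustering")])
  })
  list(dmin = mats[[1]], stack = mats)
}

#' @method tidy scn_perm
#' @export
tidy.scn_perm <- function(x, ...) tibble::as_tibble(x)

#' @method glance scn_perm
#' @export
glance.scn_perm <- function(x, ...) {
  tibble::tibble(n_perm = attr(x, "n_perm"), seed = attr(x, "seed"),
                 q = attr(x, "q"),
                 n_tests = nrow(x), n_significant = sum(x$fdr_significant))
}
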