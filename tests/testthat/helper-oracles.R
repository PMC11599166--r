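# Brute-force oracles and fixture builders.  Everything here is written
# from definitions (path enumeration, O(n^3) loops) and deliberately does
# not share code with the package internals it checks.

rand_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

make_network <- function(r, group = "g") {
  diag(r) <- 1
  structure(list(r = r, roi_labels = rownames(r) %||% paste0("n", seq_len(nrow(r))),
                 group = group, n_subjects = 10L),
            class = "scn_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}

ring_lattice <- function(n, k) {
  # circular lattice, each node tied to k nearest neighbours (k even)
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

# Floyd-Warshall shortest paths
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# enumerate all simple paths s -> t, keep the shortest ones
bf_shortest_paths <- function(a, s, t) {
  n <- nrow(a)
  best <- Inf
  found <- list()
  walk <- function(v, seen, path) {
    if (v == t) {
      len <- length(path) - 1
      if (len < best) { best <<- len; found <<- list(path) }
      else if (len == best) found[[length(found) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= best) return(invisible())
    for (u in which(a[v, ] == 1)) if (!seen[u]) {
      seen[u] <- TRUE
      walk(u, seen, c(path, u))
      seen[u] <- FALSE
    }
  }
  seen <- rep(FALSE, n); seen[s] <- TRUE
  walk(s, seen, s)
  found
}

# betweenness by exhaustive shortest-path enumeration, normalized by
# (N-1)(N-2)/2 to match the package convention
bf_betweenness <- function(a) {
  n <- nrow(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- bf_shortest_paths(a, s, t)
    if (length(paths) == 0) next
    for (p in paths) for (v in setdiff(p, c(s, t)))
      b[v] <- b[v] + 1 / length(paths)
  }
  b / ((n - 1) * (n - 2) / 2)
}

bf_triangles <- function(a) {
  n <- nrow(a)
  tri <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (a[i, j] && a[j, k] && a[i, k]) tri <- tri + 1
  tri
}

bf_transitivity <- function(a) {
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  3 * bf_triangles(a) / triples
}

bf_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    2 * links / (k * (k - 1))
  })
}

bf_largest_component <- function(a) {
  n <- nrow(a)
  if (n == 0) return(0L)
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    q <- s; seen[s] <- TRUE; size <- 0L
    while (length(q)) {
      v <- q[1]; q <- q[-1]; size <- size + 1L
      for (u in which(a[v, ] == 1)) if (!seen[u]) { seen[u] <- TRUE; q <- c(q, u) }
    }
    best <- max(best, size)
  }
  best
}

# Benjamini-Hochberg step-up from the definition
bf_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  keep <- which(ps <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(keep)) flags[o[seq_len(max(keep))]] <- TRUE
  flags
}

# least squares via explicit normal equations
bf_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  y - X %*% beta
}

# tiny cohort fixture: deterministic values, valid schema
tiny_cohort_df <- function(n = 6, n_roi = 4, groups = c("A", "A", "A", "B", "B", "B")) {
  set.seed(99)
  df <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                   group = groups[seq_len(n)],
                   age = round(runif(n, 30, 60), 1),
                   sex = rep(c("F", "M"), length.out = n),
                   tiv = round(rnorm(n, 1.4e6, 1e5)))
  for (k in seq_len(n_roi))
    df[[paste0("vol_r", k)]] <- 5000 + 100 * k + rnorm(n, sd = 50)
  df
}

# residual table wrapper around an arbitrary numeric matrix
fake_residuals <- function(X, groups) {
  rois <- colnames(X) %||% paste0("r", seq_len(ncol(X)))
  colnames(X) <- rois
  df <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%03d", seq_len(nrow(X))), group = groups),
    tibble::as_tibble(X))
  structure(df, roi_labels = rois, model_terms = character(),
            group_col = "group", id_col = "subject_id",
            class = c("scn_residuals", class(tibble::tibble())))
}
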