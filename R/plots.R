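#' Plot metric curves across densities
#'
#' One panel per metric, one line per group.
#'
#' @param object An `scn_curves` tibble from [metric_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scn_curves
#' @export
autoplot.scn_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$density, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "network density", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot permutation-test results
#'
#' Per-density scopes are drawn as -log10(p) against density with the FDR
#' threshold marked; AUC and nodal scopes as ranked points.
#'
#' @param object An `scn_perm` tibble from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scn_perm
#' @export
autoplot.scn_perm <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$x <- ifelse(is.na(df$density),
                 as.numeric(factor(ifelse(is.na(df$roi), df$metric, df$roi))),
                 df$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                   colour = .data$fdr_significant)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ scope + metric, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)), colour = "FDR < q") +
    ggplot2::theme_minimal()
}

#' Plot an attack-robustness curve
#'
#' @param object An `scn_robustness` tibble.
#' @param ... Further `scn_robustness` objects to overlay (e.g. the other
#'   attack kind or group).
#' @return A ggplot object.
#' @method autoplot scn_robustness
#' @export
autoplot.scn_robustness <- function(object, ...) {
  extra <- list(...)
  dfs <- c(list(object), Filter(function(x) inherits(x, "scn_robustness"), extra))
  df <- dplyr::bind_rows(lapply(dfs, function(x)
    dplyr::mutate(tibble::as_tibble(x), kind = attr(x, "kind"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac_removed, y = .data$lcc_frac,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "largest component (fraction of N)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot hub identification
#'
#' Betweenness basis values per node with the mean + 2 SD threshold line;
#' hubs highlighted.
#'
#' @param object An `scn_hubs` tibble from [identify_hubs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scn_hubs
#' @export
autoplot.scn_hubs <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$value,
                                   colour = .data$is_hub)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "node index", y = "betweenness (AUC)", colour = "hub") +
    ggplot2::theme_minimal()
}
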