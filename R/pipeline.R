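#' Configuration for a full SCN analysis run
#'
#' One object drives the whole pipeline; a saved config plus the input
#' reproduces the analysis exactly. All stage seeds are fanned out
#' deterministically from `seed`.
#'
#' @param input Path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param scenario Reference scenario name (used when `input` is `NULL`).
#' @param roi ROI column rule passed to [load_cohort()].
#' @param covariates Covariate column names for [residualize()].
#' @param d_min,d_max,step Density grid (defaults 0.33-0.50 by 0.01).
#' @param n_perm Permutations for group inference (default 1000).
#' @param m_nulls Null networks per density for small-world normalization
#'   (default 20).
#' @param swaps_per_edge Rewiring effort for null networks (default 10).
#' @param attack_reps Random-attack repetitions (default 100).
#' @param seed Master seed.
#' @param stages Which stages to run (subset of `demographics`, `curves`,
#'   `small_world`, `inference`, `nodal`, `hubs`, `robustness`).
#' @return A list of class `scn_config`.
#' @export
scn_config <- function(input = NULL, scenario = "null", roi = "vol_",
                       covariates = c("age", "sex", "tiv"),
                       d_min = 0.33, d_max = 0.50, step = 0.01,
                       n_perm = 1000, m_nulls = 20, swaps_per_edge = 10,
                       attack_reps = 100, seed = 1L,
                       stages = c("demographics", "curves", "small_world",
                                  "inference", "nodal", "hubs", "robustness")) {
  structure(list(input = input, scenario = scenario, roi = roi,
                 covariates = covariates,
                 d_min = d_min, d_max = d_max, step = step,
                 n_perm = n_perm, m_nulls = m_nulls,
                 swaps_per_edge = swaps_per_edge, attack_reps = attack_reps,
                 seed = as.integer(seed), stages = stages),
            class = "scn_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match [scn_config()] arguments.
#' @return An `scn_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the yaml package is required to read config files")
  vals <- yaml::read_yaml(path)
  do.call(scn_config, vals)
}

#' Run the full structural covariance network analysis
#'
#' Orchestrates, in order: cohort input (or simulation), demographics,
#' pooled residualization, per-group metric curves with AUCs (optionally
#' small-world parameters), permutation inference with FDR (global
#' per-density, global AUC, and nodal scopes), hub identification from
#' betweenness AUC, and attack-robustness curves at the minimum grid
#' density. Identical config plus input reproduces the report exactly.
#'
#' @param config An `scn_config`.
#' @return A list of class `scn_report` with elements `provenance`,
#'   `demographics`, `min_connected_density`, `curves`, `auc`, `inference`,
#'   `hubs`, `robustness`, and `warnings`.
#' @export
scn_run <- function(config = scn_config()) {
  stopifnot(inherits(config, "scn_config"))
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  grid <- density_grid(config$d_min, config$d_max, config$step)
  seeds <- list(simulate = stage_seed(config$seed, 1),
                curves = stage_seed(config$seed, 2),
                inference = stage_seed(config$seed, 3),
                robustness = stage_seed(config$seed, 4))

  cohort <- if (!is.null(config$input)) {
    load_cohort(config$input, roi = config$roi)
  } else {
    simulate_cohort(scn_scenario(config$scenario), seed = seeds$simulate)
  }
  groups <- group_levels(cohort)

  report <- list(provenance = list(
    package = "scnet",
    version = as.character(utils::packageVersion("scnet")),
    config = unclass(config), stage_seeds = seeds,
    groups = groups, n_subjects = as.integer(table(cohort[[group_col(cohort)]])[groups])))

  withCallingHandlers({
    if ("demographics" %in% config$stages) {
      cont <- intersect(c("age", "tiv"), names(cohort))
      catg <- intersect("sex", names(cohort))
      report$demographics <- demographics(cohort, continuous = cont, categorical = catg)
    }

    res <- residualize(cohort, config$covariates)
    report$min_connected_density <- setNames(
      vapply(groups, function(g)
        min_connected_density(correlation_network(res, g), grid), numeric(1)),
      groups)

    if ("curves" %in% config$stages) {
      report$curves <- metric_curves(
        res, grid, small_world = "small_world" %in% config$stages,
        m = config$m_nulls, swaps_per_edge = config$swaps_per_edge,
        seed = seeds$curves)
      report$auc <- glance.scn_curves(report$curves)
    }

    if ("inference" %in% config$stages) {
      scopes <- c("global_density", "global_auc")
      if ("nodal" %in% config$stages) scopes <- c(scopes, "nodal_dmin", "nodal_auc")
      report$inference <- permutation_test(
        res, grid, scope = scopes, n_perm = config$n_perm, seed = seeds$inference)
    }

    if ("hubs" %in% config$stages) {
      report$hubs <- hub_analysis(res, grid)
    }

    if ("robustness" %in% config$stages) {
      nets <- lapply(groups, function(g)
        threshold_density(correlation_network(res, g), grid[1]))
      names(nets) <- groups
      report$robustness <- dplyr::bind_rows(lapply(groups, function(g) {
        tg <- targeted_attack(nets[[g]])
        rd <- random_attack(nets[[g]], reps = config$attack_reps,
                            seed = seeds$robustness)
        dplyr::bind_rows(
          dplyr::mutate(tibble::as_tibble(tg), group = g, kind = "targeted",
                        .before = 1),
          dplyr::mutate(tibble::as_tibble(rd), group = g, kind = "random",
                        .before = 1))
      }))
      report$robustness_auc <- dplyr::summarise(
        dplyr::group_by(report$robustness, .data$group, .data$kind),
        auc = trapz(.data$frac_removed, .data$lcc_frac), .groups = "drop")
    }
  }, warning = log_warning)

  report$warnings <- warnings_log
  structure(report, class = "scn_report")
}

#' @export
print.scn_report <- function(x, ...) {
  cat("<scn_report>", paste(x$provenance$groups, collapse = " vs "),
      sprintf("(n = %s)", paste(x$provenance$n_subjects, collapse = "/")), "\n")
  cat(" stages:", paste(intersect(
    c("demographics", "curves", "auc", "inference", "hubs", "robustness"),
    names(x)), collapse = ", "), "\n")
  if (!is.null(x$inference)) {
    sig <- x$inference[x$inference$fdr_significant, ]
    cat(" FDR-significant tests:", nrow(sig), "of", nrow(x$inference), "\n")
  }
  invisible(x)
}

#' Serialize a report to JSON (deterministically)
#'
#' @param report An `scn_report`.
#' @return A JSON string; identical reports serialize to identical bytes.
#' @export
report_json <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      tibble::as_tibble(x)
    } else if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::toJSON(strip(unclass(report)), digits = NA, auto_unbox = TRUE,
                   null = "null", na = "null")
}

#' Write a report to an output directory
#'
#' Writes `report.json` plus one TSV per tabular element (curves, AUCs,
#' inference table, hubs, robustness curves).
#'
#' @param report An `scn_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  for (el in c("demographics", "curves", "auc", "inference", "hubs",
               "robustness", "robustness_auc")) {
    if (!is.null(report[[el]]) && is.data.frame(report[[el]]))
      readr::write_tsv(tibble::as_tibble(report[[el]]),
                       file.path(dir, paste0(el, ".tsv")))
  }
  invisible(dir)
}
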