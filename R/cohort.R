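#' Read and validate a morphometry cohort table
#'
#' A cohort table has one row per subject: an identifier column, a group
#' label with exactly two levels, covariates (typically age, sex, and total
#' intracranial volume), and one column per region of interest (ROI) holding
#' that region's gray-matter volume in mm^3.
#'
#' @param path Path to a delimited text file (CSV or TSV, sniffed from the
#'   extension) with a header row.
#' @param roi Either a character vector naming the ROI columns explicitly, or
#'   a single string treated as a shared column-name prefix (e.g. `"vol_"`).
#' @param group_col,id_col Names of the group and subject-identifier columns.
#' @return A tibble of class `scn_cohort` with attributes `roi_labels`,
#'   `group_col`, and `id_col`. ROI column order is preserved as given.
#' @seealso [as_scn_cohort()] to validate an existing data frame,
#'   [simulate_cohort()] to generate a synthetic cohort.
#' @export
load_cohort <- function(path, roi = "vol_", group_col = "group", id_col = "subject_id") {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  as_scn_cohort(df, roi = roi, group_col = group_col, id_col = id_col)
}

#' Validate a data frame as a morphometry cohort
#'
#' @param df A data frame, one row per subject.
#' @inheritParams load_cohort
#' @return A validated `scn_cohort` tibble.
#' @export
as_scn_cohort <- function(df, roi = "vol_", group_col = "group", id_col = "subject_id") {
  df <- tibble::as_tibble(df)
  for (col in c(group_col, id_col)) {
    if (!col %in% names(df)) abort(paste0("required column missing: ", col), class = "scn_schema_error")
  }
  roi_labels <- if (length(roi) == 1 && !roi[1] %in% names(df)) {
    grep(paste0("^", roi), names(df), value = TRUE)
  } else roi
  missing_roi <- setdiff(roi_labels, names(df))
  if (length(roi_labels) == 0 || length(missing_roi) > 0) {
    abort(paste0("ROI columns not found: ",
                 paste(head(c(missing_roi, roi), 5), collapse = ", ")),
          class = "scn_schema_error")
  }
  if (length(roi_labels) < 3) abort("need at least 3 ROI columns", class = "scn_validation_error")

  grp <- as.character(df[[group_col]])
  levels <- unique(grp)
  if (length(levels) != 2) {
    abort(paste0("group column must have exactly two levels, found ",
                 length(levels), ": ", paste(head(levels, 5), collapse = ", ")),
          class = "scn_validation_error")
  }
  if (any(table(grp) < 2)) abort("each group needs at least 2 subjects", class = "scn_validation_error")

  vols <- as.matrix(df[roi_labels])
  if (!is.numeric(vols)) abort("ROI columns must be numeric", class = "scn_validation_error")
  if (anyNA(df)) abort("cohort table contains missing values; imputation is not supported",
                       class = "scn_validation_error")
  bad <- which(vols <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-positive volume for subject ", df[[id_col]][bad[1, 1]],
                 ", ROI ", roi_labels[bad[1, 2]]),
          class = "scn_validation_error")
  }
  if ("tiv" %in% names(df) && any(df$tiv <= 0)) {
    abort("total intracranial volume must be strictly positive", class = "scn_validation_error")
  }

  structure(df,
            roi_labels = roi_labels, group_col = group_col, id_col = id_col,
            class = c("scn_cohort", class(tibble::tibble())))
}

#' Write a cohort table to delimited text
#'
#' @param cohort An `scn_cohort`.
#' @param path Output path; `.tsv` extension writes tab-separated, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(unclass_cohort(cohort)), path, delim = delim)
  invisible(path)
}

unclass_cohort <- function(cohort) {
  attr(cohort, "roi_labels") <- NULL
  class(cohort) <- setdiff(class(cohort), "scn_cohort")
  cohort
}

roi_labels <- function(x) attr(x, "roi_labels")
group_col <- function(x) attr(x, "group_col") %||% "group"
group_levels <- function(cohort) unique(as.character(cohort[[group_col(cohort)]]))
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residualize ROI volumes on nuisance covariates
#'
#' Fits, for each ROI independently, an ordinary least-squares model of
#' volume on an intercept plus the named covariates over the *pooled* cohort
#' (both groups together), and returns the residuals. Sex, if requested, is
#' encoded as a single 0/1 indicator. Group-level covariance networks are
#' then built from these residuals, so inter-regional correlations are not
#' driven by shared dependence on age, sex, or head size.
#'
#' @param cohort An `scn_cohort`.
#' @param covariates Character vector of covariate column names
#'   (default `c("age", "sex", "tiv")`).
#' @return A tibble of class `scn_residuals` holding the identifier and group
#'   columns followed by one residual column per ROI, with attributes
#'   `roi_labels` and `model_terms`.
#' @export
residualize <- function(cohort, covariates = c("age", "sex", "tiv")) {
  stopifnot(inherits(cohort, "scn_cohort"))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0)
    abort(paste0("covariate columns not found: ", paste(missing_cov, collapse = ", ")),
          class = "scn_schema_error")
  rois <- roi_labels(cohort)
  n <- nrow(cohort)
  X <- cbind(`(Intercept)` = rep(1, n))
  kept <- character()
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (!is.numeric(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) > 2) abort(paste0("covariate ", cv, " has more than two levels"),
                                class = "scn_validation_error")
      v <- as.numeric(as.character(v) == lv[length(lv)])
    }
    if (sd(v) == 0) next # constant covariates are absorbed by the intercept
    X <- cbind(X, v)
    kept <- c(kept, cv)
  }
  colnames(X) <- c("(Intercept)", kept)
  if (n < ncol(X) + 2) abort("too few subjects to residualize on these covariates",
                             class = "scn_validation_error")
  if (qr(X)$rank < ncol(X)) abort("covariates are collinear (singular design)",
                                  class = "scn_singular_error")
  Y <- as.matrix(cohort[rois])
  fit <- lm.fit(X, Y)
  res <- tibble::as_tibble(as.data.frame(fit$residuals))
  names(res) <- rois
  out <- dplyr::bind_cols(
    cohort[c(attr(cohort, "id_col"), group_col(cohort))], res)
  structure(out,
            roi_labels = rois, model_terms = covariates,
            group_col = group_col(cohort), id_col = attr(cohort, "id_col"),
            class = c("scn_residuals", class(tibble::tibble())))
}

# subjects x ROI residual matrix for one group (or all subjects)
residual_matrix <- function(residuals, group = NULL) {
  stopifnot(inherits(residuals, "scn_residuals"))
  rows <- if (is.null(group)) rep(TRUE, nrow(residuals))
          else residuals[[group_col(residuals)]] == group
  as.matrix(residuals[rows, roi_labels(residuals)])
}

#' Group demographics with the tests used in clinical Table 1s
#'
#' Categorical variables are compared with Pearson's chi-square test
#' *without* continuity correction on the group-by-level contingency table.
#' Continuous variables use a two-sample t-test when Shapiro-Wilk normality
#' passes in both groups (at alpha = 0.05; pooled-variance t when an F-test
#' accepts equal variances, Welch otherwise), and a Wilcoxon rank-sum test
#' otherwise. The test actually used is reported per variable.
#'
#' @param cohort An `scn_cohort`.
#' @param continuous,categorical Character vectors of variable names.
#' @return A tibble of class `scn_demographics`: one row per variable with
#'   `variable`, `test`, `statistic`, `p`, and per-group summaries
#'   (mean (SD) or level counts).
#' @export
demographics <- function(cohort, continuous = character(), categorical = character()) {
  stopifnot(inherits(cohort, "scn_cohort"))
  vars <- c(continuous, categorical)
  missing_v <- setdiff(vars, names(cohort))
  if (length(missing_v) > 0)
    abort(paste0("variables not found: ", paste(missing_v, collapse = ", ")),
          class = "scn_schema_error")
  grp <- as.character(cohort[[group_col(cohort)]])
  lv <- group_levels(cohort)

  rows <- list()
  for (v in continuous) {
    x1 <- cohort[[v]][grp == lv[1]]
    x2 <- cohort[[v]][grp == lv[2]]
    normal <- shapiro.test(x1)$p.value > 0.05 && shapiro.test(x2)$p.value > 0.05
    if (normal) {
      eqvar <- var.test(x1, x2)$p.value > 0.05
      tt <- t.test(x1, x2, var.equal = eqvar)
      test <- if (eqvar) "t (pooled)" else "t (Welch)"
    } else {
      tt <- suppressWarnings(wilcox.test(x1, x2))
      test <- "wilcoxon"
    }
    rows[[v]] <- tibble::tibble(
      variable = v, test = test,
      statistic = unname(tt$statistic), p = tt$p.value,
      group1 = sprintf("%.2f (%.2f)", mean(x1), sd(x1)),
      group2 = sprintf("%.2f (%.2f)", mean(x2), sd(x2)))
  }
  for (v in categorical) {
    tab <- table(grp, as.character(cohort[[v]]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      abort(paste0("contingency table for ", v, " has an empty margin"),
            class = "scn_validation_error")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    summ <- apply(tab, 1, function(r) paste(r, colnames(tab), sep = "", collapse = "/"))
    rows[[v]] <- tibble::tibble(
      variable = v, test = "chi-square",
      statistic = unname(ct$statistic), p = ct$p.value,
      group1 = summ[lv[1]], group2 = summ[lv[2]])
  }
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "group1"] <- lv[1]
  names(out)[names(out) == "group2"] <- lv[2]
  structure(out, class = c("scn_demographics", class(tibble::tibble())))
}

#' The 90-region AAL parcellation lookup
#'
#' Index, conventional abbreviation (e.g. `TPOsup.L`), and full region name
#' for the 90 cortical and subcortical regions of the Automated Anatomical
#' Labeling atlas, in the standard interleaved left/right order.
#'
#' @return A 90-row tibble with columns `index`, `abbreviation`, `name`.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90.tsv", package = "scnet")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
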