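test_that("load_cohort round-trips a well-formed table and validates schema", {
  df <- tiny_cohort_df(5, 4, groups = c("A", "A", "A", "B", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  co <- load_cohort(path, roi = "vol_")
  expect_s3_class(co, "scn_cohort")
  expect_length(attr(co, "roi_labels"), 4)
  expect_equal(sort(as.integer(table(co$group))), c(2, 3))

  # write -> load round-trips to an identical cohort
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path2)
  co2 <- load_cohort(path2, roi = "vol_")
  expect_equal(tibble::as_tibble(co2), tibble::as_tibble(co))
})

test_that("cohort validation rejects bad volumes, groups, and missing columns", {
  df <- tiny_cohort_df()
  bad <- df; bad$vol_r2[3] <- 0
  expect_error(as_scn_cohort(bad), class = "scn_validation_error")
  expect_error(as_scn_cohort(bad), "s03.*vol_r2")

  three <- df; three$group <- rep(c("A", "B", "C"), 2)
  expect_error(as_scn_cohort(three), class = "scn_validation_error")

  expect_error(as_scn_cohort(df[, -2]), class = "scn_schema_error")
  expect_error(as_scn_cohort(df, roi = "nonexistent_"), class = "scn_schema_error")

  withna <- df; withna$vol_r1[1] <- NA
  expect_error(as_scn_cohort(withna), class = "scn_validation_error")
})

test_that("residualize removes exact linear covariate dependence", {
  df <- tiny_cohort_df()
  for (k in 1:4) df[[paste0("vol_r", k)]] <- 2 * df$age + 5
  # perturb off exact collinearity with tiv so the design is full rank
  co <- as_scn_cohort(df)
  res <- residualize(co, covariates = "age")
  expect_true(all(abs(as.matrix(res[attr(res, "roi_labels")])) < 1e-8))
})

test_that("constant covariates reduce residualization to centering", {
  df <- tiny_cohort_df()
  df$age <- 45
  co <- as_scn_cohort(df)
  res <- residualize(co, covariates = "age")
  vols <- as.matrix(df[paste0("vol_r", 1:4)])
  centred <- sweep(vols, 2, colMeans(vols))
  expect_equal(unname(as.matrix(res[attr(res, "roi_labels")])), unname(centred),
               tolerance = 1e-10)
})

test_that("residuals match a normal-equations oracle and are orthogonal to covariates", {
  set.seed(7)
  df <- tiny_cohort_df(10, 3, groups = rep(c("A", "B"), 5))
  co <- as_scn_cohort(df)
  res <- residualize(co, covariates = c("age", "sex", "tiv"))
  R <- as.matrix(res[attr(res, "roi_labels")])

  X <- cbind(1, df$age, as.numeric(df$sex == "M"), df$tiv)
  for (k in 1:3) {
    oracle <- bf_residuals(df[[paste0("vol_r", k)]], X)
    expect_equal(unname(R[, k]), drop(oracle), tolerance = 1e-8)
  }
  # orthogonality to every design column, and zero sum (intercept included)
  ip <- crossprod(X, R)
  expect_true(all(abs(ip) < 1e-6))

  # idempotence: residualizing the residuals changes nothing
  df2 <- df
  for (k in 1:3) df2[[paste0("vol_r", k)]] <- R[, k] + 1e4 # keep volumes positive
  res2 <- residualize(as_scn_cohort(df2), covariates = c("age", "sex", "tiv"))
  expect_equal(unname(as.matrix(res2[attr(res2, "roi_labels")])), unname(R),
               tolerance = 1e-8)
})

test_that("residualize flags singular designs and short cohorts", {
  df <- tiny_cohort_df()
  df$age2 <- df$age * 2
  co <- as_scn_cohort(df)
  expect_error(residualize(co, covariates = c("age", "age2")),
               class = "scn_singular_error")
  short <- as_scn_cohort(tiny_cohort_df(5, groups = c("A", "A", "A", "B", "B")))
  expect_error(residualize(short, covariates = c("age", "sex", "tiv")),
               class = "scn_validation_error")
})

test_that("demographics chi-square reproduces the published sex table statistic", {
  # 18F/20M vs 28F/22M
  df <- data.frame(
    subject_id = sprintf("s%03d", 1:88),
    group = rep(c("ESRD", "NC"), c(38, 50)),
    sex = c(rep(c("F", "M"), c(18, 20)), rep(c("F", "M"), c(28, 22))),
    age = seq(30, 60, length.out = 88), tiv = 1.4e6,
    vol_r1 = 5000, vol_r2 = 6000, vol_r3 = 7000)
  df$vol_r1 <- df$vol_r1 + seq_len(88) # avoid zero variance
  df$vol_r2 <- df$vol_r2 + seq_len(88) * 2
  df$vol_r3 <- df$vol_r3 + seq_len(88) * 3
  co <- as_scn_cohort(df)
  dem <- demographics(co, categorical = "sex")
  expect_equal(round(dem$statistic[dem$variable == "sex"], 3), 0.645)
})

test_that("demographics chi-square has its textbook properties", {
  base <- tiny_cohort_df(12, 3, groups = rep(c("A", "B"), c(4, 8)))

  # perfectly proportional table (A = 1F/3M, B = 2F/6M) -> statistic 0
  df <- base
  df$sex[df$group == "A"] <- c("F", "M", "M", "M")
  df$sex[df$group == "B"] <- c("F", "F", "M", "M", "M", "M", "M", "M")
  co <- as_scn_cohort(df)
  dem <- demographics(co, categorical = "sex")
  expect_equal(unname(dem$statistic), 0, tolerance = 1e-12)

  # [[5,15],[15,5]] matches brute-force sum((O-E)^2/E)
  df2 <- tiny_cohort_df(40, 3, groups = rep(c("A", "B"), each = 20))
  df2$sex <- c(rep(c("F", "M"), c(5, 15)), rep(c("F", "M"), c(15, 5)))
  co2 <- as_scn_cohort(df2)
  stat <- demographics(co2, categorical = "sex")$statistic
  O <- matrix(c(5, 15, 15, 5), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(unname(stat), sum((O - E)^2 / E), tolerance = 1e-10)

  # invariant to swapping group labels and category levels
  sw <- df2
  sw$group <- ifelse(sw$group == "A", "B", "A")
  sw$sex <- ifelse(sw$sex == "F", "M", "F")
  expect_equal(unname(demographics(as_scn_cohort(sw), categorical = "sex")$statistic),
               unname(stat), tolerance = 1e-12)
})

test_that("continuous demographics report which test was used", {
  set.seed(11)
  df <- tiny_cohort_df(30, 3, groups = rep(c("A", "B"), 15))
  df$age <- rnorm(30, 45, 5)
  co <- as_scn_cohort(df)
  dem <- demographics(co, continuous = "age")
  expect_true(dem$test %in% c("t (pooled)", "t (Welch)", "wilcoxon"))
  expect_true(dem$p >= 0 && dem$p <= 1)
})

test_that("the packaged AAL lookup has 90 indexed regions", {
  aal <- aal90_regions()
  expect_equal(nrow(aal), 90)
  expect_equal(aal$index, 1:90)
  expect_true("TPOsup.L" %in% aal$abbreviation)
  expect_false(any(duplicated(aal$abbreviation)))
})
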