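# nuisance design, voxelwise OLS fit, residualization

make_cov_df <- function(n, n_sites = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%02d", 1:n),
    group = rep(c("treated", "placebo"), length.out = n),
    icv = rnorm(n, 1400, 120),
    age = runif(n, 65, 80),
    site = paste0("site", sample.int(n_sites, n, replace = TRUE)),
    time_to_scan = runif(n, 1.4, 3),
    stringsAsFactors = FALSE
  )
}

test_that("design coding: site indicators, centring, rank checks", {
  df1 <- make_cov_df(10, n_sites = 1)
  d1 <- build_design(df1)
  expect_equal(d1$columns, c("intercept", "icv", "age", "time_to_scan"))
  df3 <- make_cov_df(20, n_sites = 3)
  d3 <- build_design(df3)
  expect_equal(sum(grepl("^site_", d3$columns)), 2)
  # centred continuous columns sum to zero
  expect_equal(unname(colSums(d3$values[, c("icv", "age", "time_to_scan")])),
               rep(0, 3), tolerance = 1e-9)
  # constant age makes the design rank-deficient
  dfbad <- make_cov_df(12)
  dfbad$age <- 70
  expect_error(build_design(dfbad), "rank-deficient")
  expect_error(build_design(make_cov_df(5, n_sites = 1)), "too few subjects")
})

test_that("OLS fit recovers constants and exact linear structure", {
  df <- make_cov_df(8, n_sites = 1, seed = 2)
  d <- build_design(df)
  # constant data: zero slopes, grand mean = the constant
  Y <- matrix(0.7, 8, 5)
  m <- fit_nuisance(Y, d)
  expect_equal(unname(m$grand_mean), rep(0.7, 5))
  expect_equal(max(abs(m$coefficients[-1, ])), 0, tolerance = 1e-12)
  # exactly linear in age: slope recovered to numerical precision
  Y2 <- 0.5 + 0.01 * outer(d$values[, "age"], rep(1, 4))
  m2 <- fit_nuisance(Y2, d)
  expect_equal(unname(m2$coefficients["age", ]), rep(0.01, 4),
               tolerance = 1e-10)
})

test_that("planted covariate slopes and site offsets are recovered within 3 SEs", {
  cfg <- synth_config(grid = tiny_grid(12), n_per_group = 30,
                      effect_size = 0, noise_sigma = 0.02, seed = 21)
  co <- generate_cohort(cfg)
  d <- build_design(co)
  mean_density <- matrix(rowMeans(cohort_matrix(co)), ncol = 1)
  m <- fit_nuisance(mean_density, d)
  truth <- c(icv = cfg$covariate_effects[["icv"]],
             age = cfg$covariate_effects[["age"]],
             time_to_scan = cfg$covariate_effects[["time_to_scan"]])
  # reference-coded sites: coefficient = offset difference to site1
  for (s in grep("^site_", d$columns, value = TRUE)) {
    k <- as.integer(sub("site_site", "", s))
    truth[s] <- cfg$site_offsets[k] - cfg$site_offsets[1]
  }
  z <- (m$coefficients[names(truth), 1] - truth) / m$se[names(truth), 1]
  # jointly standard-normal recovery errors: sum of squares ~ chi-square
  expect_lt(sum(z^2), qchisq(0.999, df = length(z)))
  expect_lt(max(abs(z)), 4)
})

test_that("residualization is an identity for zero slopes and idempotent under refit", {
  df <- make_cov_df(12, n_sites = 2, seed = 3)
  d <- build_design(df)
  Y <- matrix(0.4, 12, 6) + matrix(rnorm(72, sd = 0.05), 12, 6)
  m <- fit_nuisance(Y, d)
  m0 <- m
  m0$coefficients[m0$design$nuisance_columns, ] <- 0
  expect_equal(residualize(Y, m0), Y)
  adj <- residualize(Y, m)
  m2 <- fit_nuisance(adj, d)
  adj2 <- residualize(adj, m2)
  expect_equal(adj2, adj, tolerance = 1e-10)
})

test_that("residuals are orthogonal to every design column at every voxel", {
  co <- tiny_cohort(n_per_group = 10, shape = 8, seed = 5)
  d <- build_design(co)
  X <- cohort_matrix(co)
  m <- fit_nuisance(X, d)
  adj <- residualize(X, m)
  centred <- sweep(adj, 2, colMeans(adj))
  for (cn in d$nuisance_columns) {
    expect_lt(max(abs(crossprod(d$values[, cn], centred))) /
                nrow(X), 1e-10)
  }
})

test_that("randomization preserves the planted group effect through adjustment", {
  cfg <- synth_config(grid = tiny_grid(12), n_per_group = 40,
                      effect_size = 0.15, noise_sigma = 0.05, seed = 6)
  co <- generate_cohort(cfg)
  X <- cohort_matrix(co)
  treated <- cohort_labels(co)
  inmask_eff <- cfg$effect_mask[co$mask]
  gdiff <- function(M) mean(colMeans(M[!treated, inmask_eff, drop = FALSE]) -
                            colMeans(M[treated, inmask_eff, drop = FALSE]))
  adj <- residualize(X, fit_nuisance(X, build_design(co)))
  se <- 0.05 * sqrt(2 / 40)
  expect_lt(abs(gdiff(adj) - gdiff(X)), 2 * se)
})

test_that("covariate adjustment reduces between-site dispersion", {
  cfg <- synth_config(grid = tiny_grid(12), n_per_group = 20,
                      effect_size = 0, noise_sigma = 0.05,
                      site_offsets = c(0, 0.05, -0.05, 0.02), seed = 7)
  co <- generate_cohort(cfg)
  X <- cohort_matrix(co)
  adj <- residualize(X, fit_nuisance(X, build_design(co)))
  before <- site_dispersion(rowMeans(X), co$covariates$site)
  after <- site_dispersion(rowMeans(adj), co$covariates$site)
  for (mm in c("iqr", "mad", "range", "std")) {
    expect_lt(after[[mm]], before[[mm]])
  }
})
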