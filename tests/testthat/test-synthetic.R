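# synthetic cohort generator, atlas, demographics, detection scoring

test_that("degenerate generator without noise or effects yields identical subjects", {
  cfg <- synth_config(grid = tiny_grid(8), n_per_group = 3, effect_size = 0,
                      noise_sigma = 0,
                      covariate_effects = c(icv = 0, age = 0, time_to_scan = 0),
                      site_offsets = rep(0, 4), seed = 1)
  co <- generate_cohort(cfg)
  X <- cohort_matrix(co)
  expect_equal(max(apply(X, 2, function(v) diff(range(v)))), 0)
})

test_that("the cohort is a pure function of its config", {
  co1 <- tiny_cohort(seed = 11)
  co2 <- tiny_cohort(seed = 11)
  expect_identical(cohort_matrix(co1), cohort_matrix(co2))
  expect_identical(co1$covariates, co2$covariates)
  co3 <- tiny_cohort(seed = 12)
  expect_false(identical(cohort_matrix(co1), cohort_matrix(co3)))
})

test_that("generated densities are non-negative and masked", {
  co <- tiny_cohort(noise_sigma = 0.4, seed = 3)  # heavy noise forces clipping
  X <- cohort_matrix(co)
  expect_true(all(X >= 0))
  v1 <- co$subjects[[1]]$volume
  expect_true(all(v1$values[!co$mask] == 0))
})

test_that("planted group difference converges to effect_size (law of large numbers)", {
  cfg <- synth_config(grid = tiny_grid(12), n_per_group = 50,
                      effect_size = 0.2, noise_sigma = 0.05, seed = 4)
  co <- generate_cohort(cfg)
  X <- cohort_matrix(co)
  treated <- cohort_labels(co)
  inmask_eff <- cfg$effect_mask[co$mask]
  diff <- mean(colMeans(X[!treated, inmask_eff, drop = FALSE]) -
               colMeans(X[treated, inmask_eff, drop = FALSE]))
  expect_lt(abs(diff - 0.2), 3 * 0.05 / sqrt(50))
})

test_that("null cohorts give centred voxelwise t statistics", {
  grand <- 0
  nrep <- 200
  for (r in seq_len(nrep)) {
    co <- generate_cohort(synth_config(grid = tiny_grid(8), n_per_group = 20,
                                       effect_size = 0, seed = 5000 + r))
    X <- cohort_matrix(co)
    tmap <- voxel_t_stat("less")(X, matrix(as.integer(cohort_labels(co)), 1))
    grand <- grand + mean(tmap)
  }
  expect_lt(abs(grand / nrep), 0.1)
})

test_that("covariates follow the documented distributions", {
  co <- tiny_cohort(n_per_group = 200, shape = 8, seed = 6)
  cv <- co$covariates
  expect_true(all(cv$age >= 65 & cv$age <= 80))
  expect_true(all(cv$time_to_scan >= 1.4 & cv$time_to_scan <= 3.0))
  expect_true(all(cv$icv > 0))
  expect_equal(sort(unique(cv$group)), c("placebo", "treated"))
  expect_equal(table(cv$group)[["treated"]], 200)
})

test_that("atlas with one region labels every mask voxel 1", {
  g <- tiny_grid(8)
  mask <- ellipsoid_mask(g)
  at <- generate_atlas(mask, g, 1, seed = 1)
  expect_true(all(at$labels[mask] == 1L))
  expect_true(all(at$labels[!mask] == 0L))
})

test_that("atlas generation is deterministic and errors on too many regions", {
  g <- tiny_grid(8)
  mask <- ellipsoid_mask(g)
  a1 <- generate_atlas(mask, g, 5, seed = 9)
  a2 <- generate_atlas(mask, g, 5, seed = 9)
  expect_identical(a1$labels, a2$labels)
  expect_error(generate_atlas(mask, g, sum(mask) + 1, seed = 1),
               "exceeds")
})

test_that("atlas regions partition the mask into connected components", {
  g <- grid_geometry(c(16, 16, 16))
  mask <- ellipsoid_mask(g)
  at <- generate_atlas(mask, g, 8, seed = 2)
  expect_identical(at$labels > 0L, mask)        # union = mask, disjoint by construction
  for (r in 1:8) {
    reg <- at$labels == r
    expect_gt(sum(reg), 0)
    cl <- find_clusters(reg, connectivity = 6)
    expect_length(cl, 1)                        # region growing is 6-connected
  }
  expect_true(all(at$sides %in% c("L", "R")))
})

test_that("demographics tables are deterministic multinomials with valid margins", {
  probs <- list(smoking = c(never = 0.5, former = 0.3, current = 0.2))
  d1 <- generate_demographics(100, probs, seed = 3)
  d2 <- generate_demographics(100, probs, seed = 3)
  expect_identical(d1, d2)
  expect_equal(colSums(d1$smoking), c(treated = 100, placebo = 100))
  one <- generate_demographics(50, list(v = c(only = 1)), seed = 1)
  expect_equal(unname(one$v[1, ]), c(50, 50))
  expect_error(generate_demographics(10, list(v = c(-0.5, 1.5)), seed = 1),
               "negative")
})

test_that("large-sample demographic proportions satisfy the binomial bound", {
  n <- 1e5
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  d <- generate_demographics(n, list(v = p), seed = 4)
  for (arm in 1:2) {
    prop <- d$v[, arm] / n
    expect_true(all(abs(prop - p) < 3 * sqrt(p * (1 - p) / n)))
  }
})

test_that("detection scoring matches direct counting", {
  g <- tiny_grid(6)
  mask <- array(TRUE, c(6, 6, 6))
  truth <- array(FALSE, c(6, 6, 6))
  truth[1:10] <- TRUE                            # 10-voxel truth set
  s <- score_detection(truth, truth, mask)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$dice, 1)
  none <- array(FALSE, c(6, 6, 6))
  s0 <- score_detection(none, truth, mask)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$dice, 0)
  half <- array(FALSE, c(6, 6, 6))
  half[1:5] <- TRUE
  sh <- score_detection(half, truth, mask)
  expect_equal(sh$sensitivity, 0.5)
  expect_equal(sh$dice, 2 * 5 / (5 + 10))
  expect_equal(sh$specificity, 1)
  expect_error(score_detection(half, none, mask), "empty truth")
})
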