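# neighborhood decomposition, scatter, NDP solver, tallying, full map

test_that("neighborhood decomposition covers the mask with the expected geometry", {
  g <- grid_geometry(c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  nbs <- build_neighborhoods(mask, g, odvba_params(radius_mm = 1))
  expect_length(nbs$members, 125)                 # stride 1: one per voxel
  # the interior center has the 6-face ball: 7 members
  interior <- which(apply(nbs$coords[nbs$centers, ], 1,
                          function(v) all(v > 1 & v < 5)))
  expect_true(all(lengths(nbs$members[interior]) == 7))
  # every in-mask voxel is covered
  expect_setequal(unique(unlist(nbs$members)), seq_len(125))
})

test_that("degenerate radius and oversized stride raise coverage errors", {
  g <- grid_geometry(c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  expect_error(build_neighborhoods(mask, g, odvba_params(radius_mm = 0.5)),
               "coverage")
  expect_error(build_neighborhoods(mask, g,
                                   odvba_params(radius_mm = 1, stride = 3)),
               "coverage")
})

test_that("scatter matrices match hand computation and degenerate cases", {
  X <- rbind(c(1, 2), c(3, 4), c(0, 0), c(2, 2))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  sc <- scatter_matrices(X, labels)
  expect_equal(sc$S_b, rbind(c(1, 2), c(2, 4)))
  expect_equal(sc$S_w, rbind(c(2, 2), c(2, 2)))
  # identical class means: S_b = 0
  sc0 <- scatter_matrices(rbind(c(1, 0), c(3, 2), c(1, 2), c(3, 0)),
                          labels)
  expect_equal(sc0$S_b, matrix(0, 2, 2))
  # all subjects identical: both zero
  sc1 <- scatter_matrices(matrix(1, 4, 2), labels)
  expect_equal(sc1$S_b, matrix(0, 2, 2))
  expect_equal(sc1$S_w, matrix(0, 2, 2))
  expect_error(scatter_matrices(X, c(TRUE, FALSE, FALSE, FALSE)),
               "at least 2")
})

test_that("NDP solver handles axis-dominant and isotropic criteria", {
  fit <- solve_ndp(list(A = diag(c(2, 1))))
  expect_equal(fit$w, c(1, 0))
  expect_equal(fit$objective, 2)
  iso <- solve_ndp(list(A = diag(2)))
  expect_equal(iso$objective, 1)                  # any feasible w
  expect_error(solve_ndp(list(A = rbind(c(1, 2), c(0, 1)))), "symmetric")
})

test_that("solver solutions are feasible and match the brute-force grid oracle", {
  insts <- random_scatter_instances(100, seed = 42)
  for (z in insts) {
    fit <- solve_ndp(z$scatter)
    expect_true(all(fit$w >= 0))
    expect_lt(abs(sqrt(sum(fit$w^2)) - 1), 1e-9)
    orc <- ndp_grid_oracle(z$A)
    expect_lt(orc$objective - fit$objective, 1e-3)
  }
})

test_that("projected gradient ascent is monotone in the objective", {
  insts <- random_scatter_instances(25, seed = 8)
  for (z in insts) {
    tr <- ndp_ascend_r(z$A)$trajectory
    expect_true(all(diff(tr) >= 0))
  }
})

test_that("neighborhood statistic equals the textbook pooled t", {
  # projections yA = (1,2,3), yB = (3,4,5) via w = (1,0)
  X <- cbind(c(1, 2, 3, 3, 4, 5), c(9, 9, 9, 9, 9, 9))
  labels <- rep(c(TRUE, FALSE), each = 3)
  st <- neighborhood_statistic(X, labels, c(1, 0), "less")
  expect_equal(st$s, 2 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_false(st$degenerate)
  # direction flip negates the statistic
  expect_equal(neighborhood_statistic(X, labels, c(1, 0), "greater")$s,
               -st$s)
  # identical projections: s = 0
  same <- neighborhood_statistic(matrix(1, 6, 2), labels, c(1, 0), "less")
  expect_equal(same$s, 0)
  expect_true(same$degenerate)
  # zero pooled variance with separated means: degenerate contract
  X01 <- cbind(rep(c(0, 1), each = 3), 0)
  deg <- neighborhood_statistic(X01, labels, c(1, 0), "less")
  expect_equal(deg$s, 0)
  expect_true(deg$degenerate)
})

test_that("tallying sums weight-statistic products over overlapping neighborhoods", {
  g <- grid_geometry(c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  nbs <- build_neighborhoods(mask, g, odvba_params(radius_mm = 1))
  # three neighborhoods: {1,2}, {1,2,3}, {2,3}
  expect_equal(nbs$members, list(1:2, 1:3, 2:3))
  res <- list(list(w = c(0.6, 0.8), s = 2),
              list(w = c(0, 0, 0), s = 0),
              list(w = c(1, 0), s = 3))
  sm <- tally_map(nbs, res)
  expect_equal(sm$phi_vec, c(1.2, 1.6 + 3, 0))
  expect_error(tally_map(nbs, res[1:2]), "one result per neighborhood")
})

test_that("identical groups give an identically zero map", {
  g <- grid_geometry(c(5, 5, 5))
  mask <- array(FALSE, c(5, 5, 5)); mask[2:4, 2:4, 2:4] <- TRUE
  set.seed(1)
  X <- matrix(rep(runif(sum(mask)), each = 8), nrow = 8)  # subjects identical
  sm <- odvba_map(X, rep(c(TRUE, FALSE), 4), odvba_params(radius_mm = 1),
                  mask = mask, grid = g)
  expect_equal(sm$phi_vec, rep(0, sum(mask)))
})

test_that("the compiled and R engines agree and the map is deterministic", {
  co <- tiny_cohort(seed = 13)
  p <- odvba_params()
  m1 <- odvba_map(co, params = p, engine = "cpp")
  m2 <- odvba_map(co, params = p, engine = "cpp")
  expect_identical(m1$phi, m2$phi)
  mr <- odvba_map(co, params = p, engine = "r")
  expect_equal(m1$phi_vec, mr$phi_vec, tolerance = 1e-9)
})

test_that("the tallied statistic concentrates inside a planted effect", {
  cfg <- synth_config(grid = tiny_grid(14), n_per_group = 20,
                      effect_size = 0.1, noise_sigma = 0.1, seed = 14)
  co <- generate_cohort(cfg)
  sm <- odvba_map(co)
  ineff <- cfg$effect_mask[co$mask]
  expect_gt(mean(sm$phi_vec[ineff]), mean(sm$phi_vec[!ineff]))
})
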