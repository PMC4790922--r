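# permutation p-values, clusters, FWE correction, thresholding

test_that("permutation p-values respect the achievable floor and determinism", {
  co <- tiny_cohort(n_per_group = 8, effect_size = 0.3, noise_sigma = 0.05,
                    seed = 31)
  sch <- permutation_scheme(n_perm = 19, seed = 1)
  pm <- permutation_pvalues(co, scheme = sch)
  expect_true(all(pm$p_vec >= 1 / 20))
  expect_true(all(pm$p[!co$mask] == 1))
  # strong planted effect reaches the floor
  expect_equal(min(pm$p_vec), 1 / 20)
  pm2 <- permutation_pvalues(co, scheme = sch)
  expect_identical(pm$p, pm2$p)
  expect_error(permutation_scheme(n_perm = 0), "n_perm")
})

test_that("identical subjects give p = 1 everywhere", {
  g <- grid_geometry(c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  X <- matrix(rep(seq_len(64) / 64, each = 8), nrow = 8)
  pm <- permutation_pvalues(X, rep(c(TRUE, FALSE), 4),
                            odvba_params(radius_mm = 1),
                            permutation_scheme(n_perm = 1, seed = 2),
                            mask = mask, grid = g)
  expect_true(all(pm$p_vec == 1))
})

test_that("exhaustive 2v2 relabeling equals the enumeration oracle exactly", {
  cfg <- synth_config(grid = grid_geometry(c(6, 6, 6)), n_per_group = 2,
                      effect_size = 0.2, noise_sigma = 0.1, seed = 33)
  co <- generate_cohort(cfg)
  X <- cohort_matrix(co)
  labels <- cohort_labels(co)
  params <- odvba_params()
  pm <- permutation_pvalues(X, labels, params,
                            permutation_scheme(exhaustive = TRUE),
                            mask = co$mask, grid = co$grid)
  expect_equal(pm$n_perm, 5)
  # oracle: every distinct labeling evaluated independently via odvba_map
  combos <- combn(4, 2)
  phis <- sapply(seq_len(6), function(j) {
    la <- seq_len(4) %in% combos[, j]
    odvba_map(X, la, params, mask = co$mask, grid = co$grid)$phi_vec
  })
  phi_obs <- odvba_map(X, labels, params, mask = co$mask,
                       grid = co$grid)$phi_vec
  p_exh <- rowSums(phis >= phi_obs) / 6
  expect_equal(pm$p_vec, p_exh)
})

test_that("connected components distinguish 6- and 26-connectivity", {
  bin <- array(FALSE, c(4, 4, 4))
  bin[1:2, 1:2, 1] <- TRUE
  bin[3:4, 3:4, 1] <- TRUE                      # touches only diagonally
  expect_length(find_clusters(bin, 26), 1)
  expect_length(find_clusters(bin, 6), 2)
  expect_length(find_clusters(array(FALSE, c(4, 4, 4)), 26), 0)
  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2] <- TRUE
  cl1 <- find_clusters(single, 26)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$size, 1)
  # deterministic ids sorted by size descending
  bin2 <- bin; bin2[4, 1, 4] <- TRUE
  cl2 <- find_clusters(bin2, 6)
  expect_equal(vapply(cl2, `[[`, 0L, "id"), 1:3)
  expect_equal(vapply(cl2, function(x) as.integer(x$size), 0L), c(4L, 4L, 1L))
})

test_that("cluster-wise FWE correction counts the null tail and is monotone in size", {
  bin <- array(FALSE, c(5, 5, 5))
  bin[1:3, 1, 1] <- TRUE                        # one cluster, N = 3
  bin[5, 5, 5] <- TRUE                          # one cluster, N = 1
  cl <- cluster_fwe(find_clusters(bin, 26), null_max_sizes = 1:5)
  expect_equal(cl[[1]]$corrected_p, (1 + 3) / 6)
  expect_equal(cl[[2]]$corrected_p, (1 + 5) / 6)
  expect_true(cl[[1]]$corrected_p <= cl[[2]]$corrected_p)
  # observed larger than every null max: the floor
  clf <- cluster_fwe(find_clusters(bin, 26), null_max_sizes = rep(0L, 19))
  expect_equal(clf[[1]]$corrected_p, 1 / 20)
  expect_error(cluster_fwe(find_clusters(bin, 26), integer(0)), "empty null")
})

test_that("thresholding uses a strict inequality on in-mask p", {
  g <- grid_geometry(c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  pmap <- structure(list(p = array(c(0.01, 0.05, 0.2), c(3, 1, 1)),
                         p_vec = c(0.01, 0.05, 0.2), mask = mask, grid = g),
                    class = "p_value_map")
  expect_equal(sum(threshold_map(pmap, 0.05)), 1)
  expect_equal(sum(threshold_map(pmap, 0.9)), 3)
  expect_error(threshold_map(pmap, 1), "alpha")
})

test_that("frozen-weight fast mode runs and matches relearn on the observed map", {
  co <- tiny_cohort(n_per_group = 6, shape = 8, seed = 35)
  schF <- permutation_scheme(n_perm = 9, seed = 3, relearn = FALSE)
  pmF <- permutation_pvalues(co, scheme = schF)
  sm <- odvba_map(co)
  expect_equal(pmF$stat$phi_vec, sm$phi_vec, tolerance = 1e-9)
  expect_true(all(pmF$p_vec >= 1 / 10 & pmF$p_vec <= 1))
})
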