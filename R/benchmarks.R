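#' Dense-grid brute-force oracle for the NDP objective
#'
#' Evaluates `w' A w` over a dense angular grid of non-negative unit vectors
#' (the positive orthant of the unit sphere) and returns the grid maximum —
#' an independent check of the projected-gradient solver on small problems
#' (2 to 4 members).
#'
#' @param A symmetric matrix, 2 to 4 rows.
#' @param n_grid grid points per angular coordinate.
#' @return list with `objective` and `w` (the best grid vector).
#' @export
ndp_grid_oracle <- function(A, n_grid = NULL) {
  m <- nrow(A)
  stopifnot(m >= 2, m <= 4)
  if (is.null(n_grid)) n_grid <- c(2000, 400, 80)[m - 1]
  th <- seq(0, pi / 2, length.out = n_grid)
  W <- if (m == 2) {
    cbind(cos(th), sin(th))
  } else if (m == 3) {
    g <- expand.grid(a = th, b = th)
    cbind(sin(g$a) * cos(g$b), sin(g$a) * sin(g$b), cos(g$a))
  } else {
    g <- expand.grid(a = th, b = th, c = th)
    cbind(sin(g$a) * sin(g$b) * cos(g$c), sin(g$a) * sin(g$b) * sin(g$c),
          sin(g$a) * cos(g$b), cos(g$a))
  }
  f <- rowSums((W %*% A) * W)
  i <- which.max(f)
  list(objective = f[i], w = W[i, ])
}

#' Random small scatter instances for solver validation
#'
#' Draws a random two-class data block (2-4 members, 4+4 to 10+10 subjects,
#' random mean separation), builds its scatter pair and the criterion matrix
#' `A = S_b - lambda S_w` with the automatic lambda.
#'
#' @param n_instances number of instances.
#' @param seed RNG seed.
#' @return list of lists with `A`, `scatter`, `labels`, `X`.
#' @export
random_scatter_instances <- function(n_instances = 100, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_instances), function(i) {
    m <- sample(2:4, 1)
    npc <- sample(4:10, 1)
    labels <- rep(c(TRUE, FALSE), each = npc)
    delta <- stats::rnorm(m, sd = 1)
    X <- matrix(stats::rnorm(2 * npc * m), 2 * npc, m)
    X[labels, ] <- X[labels, ] + matrix(delta, npc, m, byrow = TRUE)
    sc <- scatter_matrices(X, labels)
    lam <- sum(diag(sc$S_b)) / max(sum(diag(sc$S_w)), 1e-12)
    list(A = sc$S_b - lam * sc$S_w, scatter = sc, labels = labels, X = X)
  })
}

#' Null calibration of the permutation inference
#'
#' Generates `n_rep` null cohorts (no planted effect), runs the full
#' permutation inference on each, and reports (i) the pooled in-mask
#' fraction of voxels with uncorrected p < `alpha` and (ii) the fraction of
#' replicates with at least one FWE-significant cluster — both of which
#' should be near or below `alpha` for a calibrated test.
#'
#' @param n_rep number of null replicates.
#' @param n_per_group subjects per arm.
#' @param grid_shape voxel grid of the null cohorts.
#' @param n_perm permutations per replicate.
#' @param alpha voxel and cluster significance level.
#' @param seed base seed; replicate r uses `seed + r` for the cohort and the
#'   permutations.
#' @param params an [odvba_params()].
#' @return list with `voxel_rate`, `family_error_rate`, `per_rep_rates`,
#'   `n_rep`, `n_voxels`.
#' @export
null_calibration <- function(n_rep = 100, n_per_group = 15,
                             grid_shape = c(16, 16, 16), n_perm = 99,
                             alpha = 0.05, seed = 100L,
                             params = odvba_params()) {
  grid <- grid_geometry(grid_shape)
  rates <- numeric(n_rep)
  any_sig <- logical(n_rep)
  nvox <- NA_integer_
  nbs <- NULL
  for (r in seq_len(n_rep)) {
    cfg <- synth_config(grid = grid, n_per_group = n_per_group,
                        effect_size = 0, seed = seed + r)
    cohort <- generate_cohort(cfg)
    if (is.null(nbs))
      nbs <- build_neighborhoods(cohort$mask, cohort$grid, params)
    pmap <- permutation_pvalues(
      cohort, params = params,
      # offset stream: the relabelings must be independent of the cohort draw
      scheme = permutation_scheme(n_perm = n_perm, seed = seed + 500000L + r),
      cluster_alpha = alpha, nbs = nbs)
    rates[r] <- mean(pmap$p_vec < alpha)
    cl <- cluster_fwe(find_clusters(threshold_map(pmap, alpha),
                                    pmap$connectivity),
                      pmap$null_max_sizes)
    any_sig[r] <- any(vapply(cl, `[[`, 0, "corrected_p") < alpha)
    nvox <- length(pmap$p_vec)
  }
  list(voxel_rate = mean(rates), family_error_rate = mean(any_sig),
       per_rep_rates = rates, n_rep = n_rep, n_voxels = nvox)
}

#' Planted-effect detection benchmark: ODVBA vs smoothed voxelwise t
#'
#' Generates one cohort with a sharp-edged planted density deficit
#' (effect/noise ratio about 1), then compares two detectors at matched
#' thresholds: the ODVBA tallied map and the conventional baseline
#' (per-subject Gaussian smoothing at FWHM = the neighborhood diameter,
#' then a voxelwise two-sample t). Both get permutation p-values from the
#' same relabelings and are thresholded at uncorrected p < `alpha`; Dice
#' overlap with the planted mask is reported for each.
#'
#' @param n_per_group subjects per arm.
#' @param grid_shape voxel grid.
#' @param effect_size,noise_sigma planted deficit and noise level.
#' @param n_perm permutations.
#' @param alpha detection threshold (uncorrected).
#' @param seed RNG seed (cohort and permutations).
#' @param params an [odvba_params()].
#' @return list with `dice_odvba`, `dice_gaussian`, `score_odvba`,
#'   `score_gaussian`, `n_effect_voxels`.
#' @export
detection_benchmark <- function(n_per_group = 20, grid_shape = c(24, 24, 24),
                                effect_size = 0.1, noise_sigma = 0.1,
                                n_perm = 199, alpha = 0.05, seed = 7L,
                                params = odvba_params()) {
  cfg <- synth_config(grid = grid_geometry(grid_shape),
                      n_per_group = n_per_group,
                      effect_size = effect_size, noise_sigma = noise_sigma,
                      seed = seed)
  cohort <- generate_cohort(cfg)
  labels <- cohort_labels(cohort)
  X <- cohort_matrix(cohort)
  scheme <- permutation_scheme(n_perm = n_perm, seed = seed + 500000L)

  pmap_o <- permutation_pvalues(X, labels, params, scheme,
                                cluster_alpha = alpha,
                                mask = cohort$mask, grid = cohort$grid)
  det_o <- threshold_map(pmap_o, alpha)

  Xs <- smooth_subjects(X, cohort$mask, cohort$grid, 2 * params$radius_mm)
  pmap_g <- permutation_pvalues(Xs, labels, params, scheme,
                                cluster_alpha = alpha,
                                mask = cohort$mask, grid = cohort$grid,
                                stat_fun = voxel_t_stat(params$direction))
  det_g <- threshold_map(pmap_g, alpha)

  so <- score_detection(det_o, cohort$truth, cohort$mask)
  sg <- score_detection(det_g, cohort$truth, cohort$mask)
  list(dice_odvba = so$dice, dice_gaussian = sg$dice,
       score_odvba = so, score_gaussian = sg,
       n_effect_voxels = sum(cfg$effect_mask))
}
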