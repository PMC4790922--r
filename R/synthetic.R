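#' Configuration of the synthetic RAVENS-like cohort generator
#'
#' Defines a two-arm randomized cohort of tissue-density volumes with known
#' ground truth: a smooth baseline field, additive nuisance-covariate effects,
#' per-site offsets, spatially correlated Gaussian noise, and a localized
#' density reduction in the treated arm inside `effect_mask`.
#'
#' Default covariate distributions: age uniform on 65-80 y, ICV normal with
#' mean 1400 mL and 10% coefficient of variation, clinic site uniform over
#' `n_sites`, time from randomization to scan uniform on 1.4-3.0 y.
#' Sensitivity flags: low baseline cognition and diabetes, each Bernoulli(0.07).
#'
#' @param grid a [grid_geometry()]; default 24^3 at 1 mm.
#' @param n_per_group subjects per arm (>= 2).
#' @param mask logical analysis mask; default [ellipsoid_mask()] of the grid.
#' @param effect_mask logical array; default a small anterior ellipsoid blob
#'   (see [default_effect_mask()]).
#' @param effect_size density reduction applied to treated subjects inside
#'   `effect_mask` (dimensionless density units).
#' @param noise_sigma marginal standard deviation of the voxel noise.
#' @param smoothness_fwhm mm FWHM of the spatial correlation of the noise.
#' @param covariate_effects named numeric: slopes (density per covariate
#'   unit) for `icv` (per mL), `age` (per year), `time_to_scan` (per year).
#' @param site_offsets numeric of length `n_sites`: additive density offset
#'   per clinic site.
#' @param n_sites number of clinic sites.
#' @param flag_probs named numeric: Bernoulli rates of the `low_3ms` and
#'   `diabetes` sensitivity flags.
#' @param baseline_mean constant part of the baseline density field.
#' @param seed integer RNG seed; the cohort is a pure function of the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid = grid_geometry(c(24, 24, 24)),
                         n_per_group = 20,
                         mask = NULL,
                         effect_mask = NULL,
                         effect_size = 0.1,
                         noise_sigma = 0.1,
                         smoothness_fwhm = 3,
                         covariate_effects = c(icv = 1e-4, age = -0.002,
                                               time_to_scan = -0.01),
                         site_offsets = NULL,
                         n_sites = 4,
                         flag_probs = c(low_3ms = 0.07, diabetes = 0.07),
                         baseline_mean = 0.5,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_geometry"), n_per_group >= 2,
            noise_sigma >= 0, n_sites >= 1)
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  if (!identical(dim(mask), as.integer(grid$shape)))
    stop("mask shape does not match grid")
  if (is.null(effect_mask)) effect_mask <- default_effect_mask(grid, mask)
  if (!identical(dim(effect_mask), as.integer(grid$shape)))
    stop("effect_mask shape does not match grid")
  if (any(effect_mask & !mask)) stop("effect_mask must lie inside the mask")
  if (is.null(site_offsets))
    site_offsets <- c(0, 0.02, -0.02, 0.01, -0.01)[
      ((seq_len(n_sites) - 1) %% 5) + 1]
  stopifnot(length(site_offsets) == n_sites)
  ce <- c(icv = 0, age = 0, time_to_scan = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(list(grid = grid, n_per_group = as.integer(n_per_group),
                 mask = mask, effect_mask = effect_mask,
                 effect_size = effect_size, noise_sigma = noise_sigma,
                 smoothness_fwhm = smoothness_fwhm, covariate_effects = ce,
                 site_offsets = site_offsets, n_sites = as.integer(n_sites),
                 flag_probs = flag_probs, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted-effect mask
#'
#' A small ellipsoidal blob in the anterior half of the mask (a synthetic
#' analogue of a focal medial-prefrontal gray-matter deficit), intersected
#' with the analysis mask.
#'
#' @param grid a [grid_geometry()].
#' @param mask logical analysis mask.
#' @param radius_frac blob semi-axes as a fraction of the grid shape.
#' @return logical 3D array.
#' @export
default_effect_mask <- function(grid, mask, radius_frac = 0.14) {
  sh <- grid$shape
  ctr <- c((sh[1] + 1) / 2, (sh[2] + 1) / 2 + 0.22 * sh[2], (sh[3] + 1) / 2)
  semi <- pmax(radius_frac * sh, 1)
  i <- (seq_len(sh[1]) - ctr[1]) / semi[1]
  j <- (seq_len(sh[2]) - ctr[2]) / semi[2]
  k <- (seq_len(sh[3]) - ctr[3]) / semi[3]
  blob <- outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
  out <- blob & mask
  if (!any(out)) stop("default effect mask is empty; enlarge radius_frac")
  out
}

# smooth low-frequency baseline: constant + cosine components
baseline_field <- function(grid, mean_level) {
  sh <- grid$shape
  i <- seq_len(sh[1]) / sh[1]
  j <- seq_len(sh[2]) / sh[2]
  k <- seq_len(sh[3]) / sh[3]
  f <- mean_level +
    0.06 * outer(outer(cos(pi * i), cos(pi * j), `*`), rep(1, sh[3]), `*`) +
    0.05 * outer(outer(rep(1, sh[1]), sin(pi * j), `*`), cos(pi * k), `*`) +
    0.04 * outer(outer(cos(2 * pi * i), rep(1, sh[2]), `*`), sin(pi * k), `*`)
  f
}

# one draw of spatially correlated noise with marginal sd sigma
correlated_noise <- function(grid, sigma, fwhm_mm) {
  sh <- grid$shape
  white <- array(stats::rnorm(prod(sh)), sh)
  if (fwhm_mm <= 0 || sigma <= 0) return(sigma * white)
  sm <- gaussian_smooth3d(white, fwhm_mm, grid$voxel_size)
  sm$values * (sigma / sqrt(sm$kernel_ss))
}

#' Generate a synthetic two-arm cohort with ground truth
#'
#' Each subject's volume is `baseline + sum(slope * covariate) + site offset
#' + correlated noise`, minus `effect_size` inside `effect_mask` for treated
#' subjects, clipped at zero. Covariates are drawn from the distributions
#' documented in [synth_config()]. The result is a pure function of the
#' config (including its seed).
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_cohort`: a list with `subjects` (list of
#'   subject records, each with `subject_id`, `covariates`, `volume`),
#'   `grid`, `mask`, `covariates` (one data frame row per subject) and
#'   `truth` (a `ground_truth` list: `effect_mask`, `effect_size`,
#'   `covariate_effects`, `site_offsets`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- 2L * config$n_per_group
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  group <- rep(c("treated", "placebo"), each = config$n_per_group)
  cov_df <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    icv = stats::rnorm(n, mean = 1400, sd = 140),
    age = stats::runif(n, 65, 80),
    site = paste0("site", sample.int(config$n_sites, n, replace = TRUE)),
    time_to_scan = stats::runif(n, 1.4, 3.0),
    low_3ms = stats::runif(n) < config$flag_probs[["low_3ms"]],
    diabetes = stats::runif(n) < config$flag_probs[["diabetes"]],
    stringsAsFactors = FALSE
  )
  cov_df$icv <- pmax(cov_df$icv, 800)

  base <- baseline_field(config$grid, config$baseline_mean)
  ce <- config$covariate_effects
  site_idx <- as.integer(sub("site", "", cov_df$site))

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    shift <- ce[["icv"]] * cov_df$icv[i] + ce[["age"]] * cov_df$age[i] +
      ce[["time_to_scan"]] * cov_df$time_to_scan[i] +
      config$site_offsets[site_idx[i]]
    vals <- base + shift +
      correlated_noise(config$grid, config$noise_sigma,
                       config$smoothness_fwhm)
    if (group[i] == "treated" && config$effect_size != 0)
      vals[config$effect_mask] <- vals[config$effect_mask] - config$effect_size
    vals[vals < 0] <- 0
    vals[!config$mask] <- 0
    subjects[[i]] <- list(
      subject_id = cov_df$subject_id[i],
      covariates = as.list(cov_df[i, -1]),
      volume = volume_map(vals, config$grid, config$mask)
    )
  }
  truth <- structure(list(effect_mask = config$effect_mask,
                          effect_size = config$effect_size,
                          covariate_effects = ce,
                          site_offsets = config$site_offsets),
                     class = "ground_truth")
  structure(list(subjects = subjects, grid = config$grid, mask = config$mask,
                 covariates = cov_df, truth = truth, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synth_cohort:", length(x$subjects), "subjects (",
      sum(x$covariates$group == "treated"), "treated /",
      sum(x$covariates$group == "placebo"), "placebo ),",
      sum(x$mask), "mask voxels\n")
  invisible(x)
}

# save/restore .Random.seed so generators don't disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Subject-by-voxel data matrix of a cohort
#'
#' Stacks the in-mask voxel values of every subject into a numeric matrix
#' (subjects x in-mask voxels, voxels in column-major mask order) — the
#' working representation of all voxelwise computations.
#'
#' @param cohort a `synth_cohort` or a list of [volume_map()]s.
#' @param mask logical mask (required when `cohort` is a plain list).
#' @return numeric matrix.
#' @export
cohort_matrix <- function(cohort, mask = NULL) {
  if (inherits(cohort, "synth_cohort")) {
    maps <- lapply(cohort$subjects, `[[`, "volume")
    mask <- cohort$mask
  } else {
    maps <- cohort
    if (is.null(mask)) mask <- maps[[1]]$mask
  }
  t(vapply(maps, function(v) v$values[mask], numeric(sum(mask))))
}

#' Group labels of a cohort as a logical "is treated" vector
#' @param cohort a `synth_cohort`.
#' @return logical vector, TRUE for the treated arm.
#' @export
cohort_labels <- function(cohort) cohort$covariates$group == "treated"

#' Generate a synthetic region atlas by seeded region growing
#'
#' Partitions the in-mask voxels into `n_regions` connected regions: seeds
#' are drawn uniformly from the mask, then grown breadth-first under
#' 6-connectivity (ties go to the lower region id); any voxels unreachable
#' from every seed are assigned to the nearest seed. Left/right side of each
#' region is the sign of the world x coordinate of its centre of mass.
#'
#' @param mask logical 3D array.
#' @param grid a [grid_geometry()].
#' @param n_regions number of regions (>= 1, <= number of mask voxels).
#' @param seed RNG seed.
#' @return An object of class `label_atlas`: list with `labels` (integer 3D
#'   array, 0 = background), `names` (label -> region name), `sides`
#'   (label -> "L"/"R"), `grid`.
#' @export
generate_atlas <- function(mask, grid, n_regions, seed = 1L) {
  stopifnot(inherits(grid, "grid_geometry"), n_regions >= 1)
  nvox <- sum(mask)
  if (n_regions > nvox)
    stop("n_regions exceeds the number of mask voxels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  idx <- which(mask)
  seeds <- sort(sample(idx, n_regions))
  labels <- array(0L, dim(mask))
  labels[seeds] <- seq_len(n_regions)

  sh <- dim(mask)
  # iterative frontier growth, 6-connectivity; ties -> lower label
  repeat {
    unl <- mask & labels == 0L
    if (!any(unl)) break
    cand <- array(0L, sh)
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      shifted <- shift_int(labels, ax, dir)
      take <- unl & shifted > 0L & (cand == 0L | (shifted < cand))
      cand[take] <- shifted[take]
    }
    if (!any(cand > 0L)) {  # disconnected remainder: nearest seed
      rem <- which(unl)
      rc <- arrayInd(rem, sh)
      sc <- arrayInd(seeds, sh)
      mm_r <- voxel_to_world(grid, rc)
      mm_s <- voxel_to_world(grid, sc)
      d2 <- outer(rowSums(mm_r^2), rep(1, nrow(mm_s))) +
        outer(rep(1, nrow(mm_r)), rowSums(mm_s^2)) - 2 * mm_r %*% t(mm_s)
      labels[rem] <- max.col(-d2, ties.method = "first")
      break
    }
    labels[cand > 0L] <- cand[cand > 0L]
  }

  nm <- sprintf("region_%02d", seq_len(n_regions))
  sides <- character(n_regions)
  for (r in seq_len(n_regions)) {
    com <- colMeans(voxel_to_world(grid, arrayInd(which(labels == r), sh)))
    sides[r] <- if (com[1] < 0) "L" else "R"
  }
  structure(list(labels = labels, names = stats::setNames(nm, seq_len(n_regions)),
                 sides = stats::setNames(sides, seq_len(n_regions)),
                 grid = grid),
            class = "label_atlas")
}

# shift an integer array by one voxel along an axis, zero fill
shift_int <- function(arr, axis, dir) {
  out <- array(0L, dim(arr))
  n <- dim(arr)[axis]
  src <- if (dir > 0) 1:(n - 1) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1)
  if (axis == 1L) out[dst, , ] <- arr[src, , ]
  else if (axis == 2L) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

#' Generate synthetic categorical demographics as two-arm contingency tables
#'
#' Draws multinomial category counts per arm for each variable — fixtures in
#' the style of a baseline-characteristics table.
#'
#' @param n_per_group subjects per arm.
#' @param category_probs named list: variable -> probability vector (each
#'   sums to 1; names of the vector are the category labels).
#' @param seed RNG seed.
#' @return named list of count matrices (categories x 2 arms).
#' @export
generate_demographics <- function(n_per_group, category_probs, seed = 1L) {
  stopifnot(n_per_group >= 1, length(category_probs) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (v in names(category_probs)) {
    p <- category_probs[[v]]
    if (any(p < 0)) stop("negative probabilities for variable ", v)
    if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1 for ", v)
    counts <- cbind(
      treated = stats::rmultinom(1, n_per_group, p)[, 1],
      placebo = stats::rmultinom(1, n_per_group, p)[, 1]
    )
    rownames(counts) <- if (!is.null(names(p))) names(p)
      else paste0("cat", seq_along(p))
    out[[v]] <- counts
  }
  out
}

#' Score a detected mask against the planted ground truth
#'
#' @param detected logical 3D array (or in-mask logical vector).
#' @param truth a `ground_truth` (from [generate_cohort()]) or a logical
#'   array of the true effect voxels.
#' @param mask logical analysis mask over which specificity is computed.
#' @return list with `sensitivity`, `specificity` and `dice`, all in [0, 1].
#' @export
score_detection <- function(detected, truth, mask) {
  tmask <- if (inherits(truth, "ground_truth")) truth$effect_mask else truth
  if (is.null(dim(detected))) {
    d <- array(FALSE, dim(mask)); d[mask] <- detected; detected <- d
  }
  stopifnot(identical(dim(detected), dim(tmask)))
  if (!any(tmask)) stop("empty truth mask")
  detected <- detected & mask
  tp <- sum(detected & tmask)
  fp <- sum(detected & !tmask & mask)
  tn <- sum(!detected & !tmask & mask)
  list(
    sensitivity = tp / sum(tmask),
    specificity = tn / (tn + fp),
    dice = if (sum(detected) + sum(tmask) == 0) 0
           else 2 * tp / (sum(detected) + sum(tmask))
  )
}
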