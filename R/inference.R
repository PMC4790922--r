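#' Permutation scheme for nonparametric significance
#'
#' @param n_perm number of random relabelings (default 2000).
#' @param seed RNG seed for the relabelings.
#' @param relearn re-solve the discriminative weights under every permuted
#'   labeling (default TRUE — required for exchangeability; `FALSE` freezes
#'   the observed weights and only recomputes the projected statistics, an
#'   approximate fast mode for smoke runs).
#' @param exhaustive enumerate every distinct labeling that preserves group
#'   sizes instead of sampling (feasible for very small cohorts); `n_perm`
#'   and `seed` are then ignored.
#' @return list of class `permutation_scheme`.
#' @export
permutation_scheme <- function(n_perm = 2000, seed = 1L, relearn = TRUE,
                               exhaustive = FALSE) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 relearn = relearn, exhaustive = exhaustive),
            class = "permutation_scheme")
}

# matrix of 0/1 labelings: observed first row, then permutations
build_labelings <- function(labels, scheme) {
  n <- length(labels)
  nA <- sum(labels)
  if (scheme$exhaustive) {
    combos <- utils::combn(n, nA)
    labmat <- matrix(0L, ncol(combos), n)
    for (j in seq_len(ncol(combos))) labmat[j, combos[, j]] <- 1L
    obs <- as.integer(labels)
    is_obs <- apply(labmat, 1, function(r) all(r == obs))
    labmat <- rbind(obs, labmat[!is_obs, , drop = FALSE])
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(scheme$seed)
    labmat <- matrix(0L, scheme$n_perm + 1L, n)
    labmat[1, ] <- as.integer(labels)
    for (j in seq_len(scheme$n_perm))
      labmat[j + 1L, sample.int(n, nA)] <- 1L
  }
  unname(labmat)
}

#' Voxelwise permutation p-values and the null max-cluster-size distribution
#'
#' Recomputes the whole-brain statistic map under permuted group labels
#' (preserving group sizes) and assigns each voxel the add-one Monte-Carlo
#' p-value `(1 + #{permutations with phi* >= phi}) / (n_perm + 1)`; ties
#' count toward the null (conservative). For the cluster-wise FWE
#' correction it also records, for every permutation, the maximum cluster
#' size after thresholding that permutation's own map at the
#' cluster-forming level (`cluster_alpha`, uncorrected).
#'
#' @param maps,labels,params,mask,grid,nbs as in [odvba_map()].
#' @param scheme a [permutation_scheme()].
#' @param cluster_alpha primary (cluster-forming) uncorrected threshold.
#' @param connectivity 6, 18 or 26 (voxel neighborhood for clusters).
#' @param stat_fun optional replacement statistic: `function(X, labmat)`
#'   returning a labelings x voxels matrix (used e.g. for the
#'   Gaussian-smoothed voxelwise-t baseline). Default: the ODVBA map.
#' @return list of class `p_value_map`: `p` (3D array, 1 outside mask),
#'   `p_vec`, `stat` (observed `stat_map`), `null_max_sizes`, `n_perm`,
#'   `grid`, `mask`, `cluster_alpha`, `connectivity`.
#' @export
permutation_pvalues <- function(maps, labels = NULL,
                                params = odvba_params(),
                                scheme = permutation_scheme(),
                                cluster_alpha = 0.05, connectivity = 26,
                                mask = NULL, grid = NULL, nbs = NULL,
                                stat_fun = NULL) {
  if (inherits(maps, "synth_cohort")) {
    if (is.null(labels)) labels <- cohort_labels(maps)
    mask <- maps$mask; grid <- maps$grid
    X <- cohort_matrix(maps)
  } else if (is.matrix(maps)) {
    X <- maps
    stopifnot(!is.null(mask), !is.null(grid))
  } else {
    mask <- maps[[1]]$mask; grid <- maps[[1]]$grid
    X <- cohort_matrix(maps, mask)
  }
  labels <- as.logical(labels)
  labmat <- build_labelings(labels, scheme)
  L <- nrow(labmat) - 1L                      # permutations
  if (L < 1) stop("need at least 1 permutation")

  if (is.null(stat_fun)) {
    if (is.null(nbs)) nbs <- build_neighborhoods(mask, grid, params)
    lam <- if (identical(params$lambda, "auto")) -1 else params$lambda
    sgn <- if (params$direction == "less") 1L else -1L
    phis <- if (scheme$relearn) {
      odvba_phi_cpp(X, labmat, nbs$members, lam, params$max_iter,
                    params$tol, sgn)
    } else {
      frozen_weight_phis(X, labmat, nbs, params, lam, sgn)
    }
  } else {
    phis <- stat_fun(X, labmat)
  }

  phi_obs <- phis[1, ]
  perm <- phis[-1, , drop = FALSE]
  # observed p: add-one estimator over the permutation distribution
  cnt <- colSums(perm >= matrix(phi_obs, L, length(phi_obs), byrow = TRUE))
  p_vec <- (1 + cnt) / (L + 1)
  # per-permutation p maps (self counted, symmetric treatment), then the
  # max cluster size at the primary threshold
  rk <- matrix(apply(perm, 2, rank, ties.method = "min"), nrow = L)  # L x V
  p_perm <- (L - rk + 1) / (L + 1)
  null_max <- integer(L)
  for (j in seq_len(L)) {
    bin <- array(FALSE, dim(mask))
    bin[mask] <- p_perm[j, ] < cluster_alpha
    lab <- label_components_cpp(as.logical(bin), dim(bin), connectivity)
    null_max[j] <- if (any(lab > 0)) max(tabulate(lab)) else 0L
  }

  p_arr <- array(1, dim(mask))
  p_arr[mask] <- p_vec
  structure(list(p = p_arr, p_vec = p_vec,
                 stat = vec_to_stat_map(phi_obs, grid, mask),
                 null_max_sizes = null_max, n_perm = L,
                 grid = grid, mask = mask, cluster_alpha = cluster_alpha,
                 connectivity = connectivity),
            class = "p_value_map")
}

# fast approximate mode: weights solved once on the observed labeling, only
# the projected t statistics are recomputed per permutation
frozen_weight_phis <- function(X, labmat, nbs, params, lam, sgn) {
  obs <- as.logical(labmat[1, ])
  K <- length(nbs$members)
  V <- ncol(X)
  W <- vector("list", K)
  Yproj <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    mb <- nbs$members[[k]]
    Xs <- X[, mb, drop = FALSE]
    sc <- scatter_matrices(Xs, obs)
    w <- if (sum(diag(sc$S_b)) <= 0) rep(1 / sqrt(length(mb)), length(mb))
         else solve_ndp(sc, params)$w
    W[[k]] <- w
    Yproj[, k] <- Xs %*% w
  }
  phis <- matrix(0, nrow(labmat), V)
  for (l in seq_len(nrow(labmat))) {
    la <- as.logical(labmat[l, ])
    nA <- sum(la); nB <- sum(!la)
    mA <- colMeans(Yproj[la, , drop = FALSE])
    mB <- colMeans(Yproj[!la, , drop = FALSE])
    vA <- apply(Yproj[la, , drop = FALSE], 2, stats::var)
    vB <- apply(Yproj[!la, , drop = FALSE], 2, stats::var)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    s <- ifelse(sp2 > 0,
                sgn * (mB - mA) / sqrt(sp2 * (1 / nA + 1 / nB)), 0)
    phi <- numeric(V)
    for (k in seq_len(K)) {
      mb <- nbs$members[[k]]
      phi[mb] <- phi[mb] + W[[k]] * s[k]
    }
    phis[l, ] <- phi
  }
  phis
}

#' Connected clusters of a binary map
#'
#' Connected-component labeling under 6-, 18- or 26-connectivity, sorted by
#' size descending (ties: smaller first linear index first), with
#' deterministic ids 1..k.
#'
#' @param binary logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param grid optional [grid_geometry()] stored with the clusters.
#' @return list of clusters, each a list with `id`, `voxels` (ijk matrix),
#'   `size`; the labeled integer array is attached as attribute `labels`.
#' @export
find_clusters <- function(binary, connectivity = 26, grid = NULL) {
  stopifnot(connectivity %in% c(6, 18, 26))
  lab <- label_components_cpp(as.logical(binary), dim(binary),
                              as.integer(connectivity))
  lab <- array(lab, dim(binary))
  if (!any(lab > 0)) {
    out <- list()
    attr(out, "labels") <- lab
    return(out)
  }
  sizes <- tabulate(lab)
  first <- vapply(seq_along(sizes), function(r) min(which(lab == r)), 0)
  ord <- order(-sizes, first)
  out <- lapply(seq_along(ord), function(i) {
    r <- ord[i]
    list(id = i, voxels = arrayInd(which(lab == r), dim(binary)),
         size = sizes[r])
  })
  attr(out, "labels") <- lab
  out
}

#' Cluster-wise family-wise-error corrected p-values
#'
#' Each observed cluster's corrected p is the add-one tail probability of
#' its size under the permutation distribution of the maximum cluster size:
#' `(1 + #{null max sizes >= N}) / (n_perm + 1)`. Monotone in N.
#'
#' @param clusters a [find_clusters()] result.
#' @param null_max_sizes integer vector from [permutation_pvalues()]
#'   (recorded at the same primary threshold).
#' @return the clusters, each gaining a `corrected_p` element.
#' @export
cluster_fwe <- function(clusters, null_max_sizes) {
  if (length(null_max_sizes) == 0) stop("empty null max-cluster-size distribution")
  L <- length(null_max_sizes)
  out <- lapply(clusters, function(cl) {
    cl$corrected_p <- (1 + sum(null_max_sizes >= cl$size)) / (L + 1)
    cl
  })
  attributes(out) <- attributes(clusters)
  out
}

#' Threshold a p-value map
#'
#' @param pmap a `p_value_map`.
#' @param alpha significance level in (0, 1); voxels with in-mask `p < alpha`
#'   (strict) are returned TRUE.
#' @return logical 3D array.
#' @export
threshold_map <- function(pmap, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  out <- array(FALSE, dim(pmap$mask))
  out[pmap$mask] <- pmap$p_vec < alpha
  out
}

#' Plain voxelwise two-sample t statistic function
#'
#' Returns a `stat_fun` for [permutation_pvalues()] computing, per labeling,
#' the pooled-variance two-sample t at every voxel (group-of-interest
#' deficit positive under `direction = "less"`). Combined with per-subject
#' Gaussian pre-smoothing this is the conventional smoothed-VBM baseline.
#'
#' @param direction `"less"` or `"greater"`.
#' @return function(X, labmat) -> labelings x voxels matrix.
#' @export
voxel_t_stat <- function(direction = c("less", "greater")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "less") 1 else -1
  function(X, labmat) {
    out <- matrix(0, nrow(labmat), ncol(X))
    for (l in seq_len(nrow(labmat))) {
      la <- labmat[l, ] == 1L
      nA <- sum(la); nB <- sum(!la)
      XA <- X[la, , drop = FALSE]; XB <- X[!la, , drop = FALSE]
      mA <- colMeans(XA); mB <- colMeans(XB)
      vA <- colSums(sweep(XA, 2, mA)^2)
      vB <- colSums(sweep(XB, 2, mB)^2)
      sp2 <- (vA + vB) / (nA + nB - 2)
      t <- sgn * (mB - mA) / sqrt(sp2 * (1 / nA + 1 / nB))
      t[sp2 <= 0] <- 0
      out[l, ] <- t
    }
    out
  }
}

#' Smooth every subject volume with a Gaussian kernel
#'
#' Per-subject pre-smoothing used by the conventional-VBM baseline.
#'
#' @param X subjects x voxels matrix ([cohort_matrix()] order).
#' @param mask,grid the cohort geometry.
#' @param fwhm_mm kernel FWHM in mm.
#' @return smoothed subjects x voxels matrix.
#' @export
smooth_subjects <- function(X, mask, grid, fwhm_mm) {
  out <- X
  for (i in seq_len(nrow(X))) {
    arr <- array(0, dim(mask))
    arr[mask] <- X[i, ]
    sm <- gaussian_smooth3d(arr, fwhm_mm, grid$voxel_size)$values
    out[i, ] <- sm[mask]
  }
  out
}
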