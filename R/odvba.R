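#' Parameters of the ODVBA neighborhood analysis
#'
#' @param radius_mm neighborhood radius in mm (Euclidean ball around each
#'   center). Default 2 mm — two voxels at the default 1 mm desk-scale grid.
#' @param stride voxel spacing of the neighborhood-center lattice. Must be
#'   small enough that every in-mask voxel is covered (stride 1 puts a
#'   neighborhood on every in-mask voxel).
#' @param lambda trade-off weight of the within-class scatter in the
#'   discriminative criterion `f(w) = w'(S_b - lambda S_w)w`; `"auto"`
#'   (default) uses the scale-free per-neighborhood heuristic
#'   `trace(S_b) / trace(S_w)`.
#' @param max_iter,tol projected-gradient solver iteration cap and objective
#'   convergence tolerance.
#' @param direction which one-sided hypothesis is scored: `"less"` (the
#'   group of interest has lower density; its deficits get positive
#'   statistics) or `"greater"`.
#' @return list of class `odvba_params`.
#' @export
odvba_params <- function(radius_mm = 2, stride = 1, lambda = "auto",
                         max_iter = 200, tol = 1e-9,
                         direction = c("less", "greater")) {
  direction <- match.arg(direction)
  stopifnot(radius_mm > 0, stride >= 1, max_iter >= 1, tol > 0)
  if (!identical(lambda, "auto")) stopifnot(is.numeric(lambda), lambda >= 0)
  structure(list(radius_mm = radius_mm, stride = as.integer(stride),
                 lambda = lambda, max_iter = as.integer(max_iter),
                 tol = tol, direction = direction),
            class = "odvba_params")
}

#' Decompose the mask into overlapping neighborhoods
#'
#' Places a neighborhood on every in-mask voxel of a stride-subsampled
#' lattice; its members are the in-mask voxels within `radius_mm` (Euclidean,
#' in mm) of the center. Neighborhoods with fewer than 2 members are dropped;
#' an error is raised if any in-mask voxel then belongs to no neighborhood
#' (insufficient coverage — reduce `stride` or increase `radius_mm`).
#'
#' @param mask logical 3D array (non-empty).
#' @param grid a [grid_geometry()].
#' @param params an [odvba_params()].
#' @return list of class `neighborhoods`: `members` (list of integer vectors
#'   indexing in-mask voxels in [cohort_matrix()] column order), `centers`
#'   (integer vector, same indexing), `coords` (in-mask voxel ijk matrix),
#'   `grid`, `mask`.
#' @export
build_neighborhoods <- function(mask, grid, params = odvba_params()) {
  if (!any(mask)) stop("mask is empty")
  coords <- mask_coords(mask)                 # V x 3, column-major order
  V <- nrow(coords)
  idmap <- array(0L, dim(mask))
  idmap[mask] <- seq_len(V)

  on_lattice <- (coords[, 1] - 1L) %% params$stride == 0L &
                (coords[, 2] - 1L) %% params$stride == 0L &
                (coords[, 3] - 1L) %% params$stride == 0L
  centers <- which(on_lattice)
  if (length(centers) == 0) stop("stride leaves no neighborhood centers")

  # integer offsets within the mm radius
  rad_vox <- floor(params$radius_mm / grid$voxel_size)
  og <- as.matrix(expand.grid(dx = -rad_vox[1]:rad_vox[1],
                              dy = -rad_vox[2]:rad_vox[2],
                              dz = -rad_vox[3]:rad_vox[3]))
  mm2 <- (og[, 1] * grid$voxel_size[1])^2 +
         (og[, 2] * grid$voxel_size[2])^2 +
         (og[, 3] * grid$voxel_size[3])^2
  og <- og[mm2 <= params$radius_mm^2, , drop = FALSE]

  sh <- dim(mask)
  cc <- coords[centers, , drop = FALSE]
  memb <- matrix(0L, nrow = length(centers), ncol = nrow(og))
  for (o in seq_len(nrow(og))) {
    p <- cbind(cc[, 1] + og[o, 1], cc[, 2] + og[o, 2], cc[, 3] + og[o, 3])
    ok <- p[, 1] >= 1 & p[, 1] <= sh[1] & p[, 2] >= 1 & p[, 2] <= sh[2] &
          p[, 3] >= 1 & p[, 3] <= sh[3]
    val <- integer(nrow(p))
    lin <- p[ok, 1] + sh[1] * (p[ok, 2] - 1L) + sh[1] * sh[2] * (p[ok, 3] - 1L)
    val[ok] <- idmap[lin]
    memb[, o] <- val
  }
  members <- lapply(seq_len(nrow(memb)), function(i) {
    m <- memb[i, ]
    sort(m[m > 0L])
  })
  keep <- lengths(members) >= 2
  members <- members[keep]
  centers <- centers[keep]
  if (length(members) == 0)
    stop("coverage error: no neighborhood has 2 or more members ",
         "(radius too small for the voxel size)")
  covered <- logical(V)
  covered[unlist(members, use.names = FALSE)] <- TRUE
  if (!all(covered))
    stop("coverage error: ", sum(!covered),
         " in-mask voxels belong to no neighborhood; reduce stride or ",
         "increase radius_mm")
  structure(list(members = members, centers = centers, coords = coords,
                 grid = grid, mask = mask),
            class = "neighborhoods")
}

#' Between- and within-class scatter of a neighborhood data block
#'
#' `S_b = (m1 - m0)(m1 - m0)'` from the two class mean vectors;
#' `S_w` is the pooled within-class cross-product divided by `n - 2`.
#'
#' @param X subjects x members data matrix.
#' @param labels logical (TRUE = group A) with >= 2 subjects per class.
#' @return list with `S_b`, `S_w`.
#' @export
scatter_matrices <- function(X, labels) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("each class needs at least 2 subjects")
  XA <- X[labels, , drop = FALSE]
  XB <- X[!labels, , drop = FALSE]
  mA <- colMeans(XA); mB <- colMeans(XB)
  d <- mA - mB
  CA <- sweep(XA, 2, mA); CB <- sweep(XB, 2, mB)
  list(S_b = outer(d, d),
       S_w = (crossprod(CA) + crossprod(CB)) / (nrow(X) - 2))
}

#' Non-negative discriminative projection
#'
#' Maximizes `f(w) = w' (S_b - lambda S_w) w` over the non-negative unit
#' sphere by projected gradient ascent (negative components clipped to zero,
#' then renormalized) with backtracking line search, run from a small set of
#' deterministic feasible starts (uniform, the clipped +/- class-mean
#' difference, the dominant diagonal axis), keeping the best stationary
#' point; the single-coordinate solution `argmax_i A_ii` is always a
#' candidate, which also covers collapse of the iterate to zero. The
#' objective sequence of accepted iterations is non-decreasing.
#'
#' @param scatter a [scatter_matrices()] result, or a list with a single
#'   symmetric matrix `A` (then `lambda` is ignored).
#' @param params an [odvba_params()].
#' @return list of class `ndp_result`: `w` (non-negative, unit L2 norm),
#'   `objective`, `iterations`, `converged`, `lambda`.
#' @export
solve_ndp <- function(scatter, params = odvba_params()) {
  if (!is.null(scatter$A)) {
    A <- scatter$A
    lam <- 0
    d <- diag(A) * 0
  } else {
    S_b <- scatter$S_b; S_w <- scatter$S_w
    if (max(abs(S_b - t(S_b))) > 1e-8 || max(abs(S_w - t(S_w))) > 1e-8)
      stop("scatter matrices must be symmetric")
    lam <- if (identical(params$lambda, "auto"))
      sum(diag(S_b)) / max(sum(diag(S_w)), 1e-12) else params$lambda
    A <- S_b - lam * S_w
    # a rank-1 S_b = dd' has d recoverable up to sign from its largest column
    jmax <- which.max(diag(S_b))
    d <- if (diag(S_b)[jmax] > 0) S_b[, jmax] / sqrt(diag(S_b)[jmax])
         else diag(A) * 0
  }
  if (max(abs(A - t(A))) > 1e-8) stop("criterion matrix must be symmetric")
  m <- nrow(A)
  if (m < 2) stop("need at least 2 members")
  starts <- cbind(rep(1 / sqrt(m), m), pmax(d, 0), pmax(-d, 0),
                  as.numeric(seq_len(m) == which.max(diag(A))))
  fit <- ndp_solve_cpp(A, starts, params$max_iter, params$tol)
  structure(list(w = as.numeric(fit$w), objective = fit$objective,
                 iterations = fit$iterations, converged = fit$converged,
                 lambda = lam),
            class = "ndp_result")
}

#' Pure-R reference of the projected-gradient NDP ascent
#'
#' Single-start projected gradient ascent with backtracking, returning the
#' whole accepted-objective trajectory; used to verify the solver contract
#' (feasibility, monotone ascent) independently of the compiled path.
#'
#' @param A symmetric criterion matrix.
#' @param w0 feasible start (default uniform).
#' @param max_iter,tol as in [odvba_params()].
#' @return list with `w`, `objective`, `trajectory`, `converged`.
#' @export
ndp_ascend_r <- function(A, w0 = NULL, max_iter = 200, tol = 1e-9) {
  m <- nrow(A)
  proj <- function(v) {
    v[v < 0] <- 0
    nv <- sqrt(sum(v^2))
    if (nv <= 0) return(NULL)
    v / nv
  }
  w <- if (is.null(w0)) rep(1 / sqrt(m), m) else proj(w0)
  f <- drop(t(w) %*% A %*% w)
  eta <- 1 / (norm(A, "F") + 1e-12)
  traj <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- 2 * drop(A %*% w)
    step <- eta
    accepted <- FALSE
    for (b in 1:40) {
      v <- proj(w + step * g)
      if (is.null(v)) { step <- step / 2; next }
      fv <- drop(t(v) %*% A %*% v)
      if (fv >= f) {
        impr <- fv - f
        w <- v; f <- fv; eta <- step * 1.5
        traj <- c(traj, f)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted || (accepted && (f - traj[length(traj) - 1]) <= tol)) {
      converged <- TRUE
      break
    }
  }
  list(w = w, objective = f, trajectory = traj, converged = converged)
}

#' Group-difference statistic of a neighborhood projection
#'
#' Projects the neighborhood data on `w` and returns the pooled-variance
#' two-sample t statistic of the projections, signed so that positive values
#' support the configured one-sided hypothesis (`direction = "less"`: the
#' group-of-interest mean is lower). A zero pooled variance (degenerate
#' projection) returns `s = 0` with `degenerate = TRUE`.
#'
#' @param X subjects x members data matrix.
#' @param labels logical, TRUE = group of interest (A).
#' @param w feasible weight vector.
#' @param direction `"less"` or `"greater"`.
#' @return list with `s` and `degenerate`.
#' @export
neighborhood_statistic <- function(X, labels, w,
                                   direction = c("less", "greater")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("each class needs at least 2 subjects")
  y <- drop(X %*% w)
  yA <- y[labels]; yB <- y[!labels]
  nA <- length(yA); nB <- length(yB)
  sp2 <- ((nA - 1) * stats::var(yA) + (nB - 1) * stats::var(yB)) / (nA + nB - 2)
  if (sp2 <= 0) return(list(s = 0, degenerate = TRUE))
  diff <- mean(yB) - mean(yA)            # positive when A is lower
  if (direction == "greater") diff <- -diff
  list(s = diff / sqrt(sp2 * (1 / nA + 1 / nB)), degenerate = FALSE)
}

#' Tally neighborhood statistics into a whole-brain map
#'
#' Each voxel accumulates, over every neighborhood containing it, the
#' product of its learned weight and the neighborhood's statistic:
#' `phi_i = sum_k w_{k,i} s_k`.
#'
#' @param nbs a [build_neighborhoods()] result.
#' @param results list (one per neighborhood) with elements `w` and `s`.
#' @return list of class `stat_map`: `phi` (3D array, 0 outside the mask),
#'   `phi_vec` (in-mask vector), `grid`, `mask`.
#' @export
tally_map <- function(nbs, results) {
  if (length(results) != length(nbs$members))
    stop("one result per neighborhood required")
  phi <- numeric(nrow(nbs$coords))
  for (k in seq_along(results)) {
    mb <- nbs$members[[k]]
    phi[mb] <- phi[mb] + results[[k]]$w * results[[k]]$s
  }
  vec_to_stat_map(phi, nbs$grid, nbs$mask)
}

vec_to_stat_map <- function(phi_vec, grid, mask) {
  arr <- array(0, dim(mask))
  arr[mask] <- phi_vec
  structure(list(phi = arr, phi_vec = phi_vec, grid = grid, mask = mask),
            class = "stat_map")
}

#' Whole-brain ODVBA statistic map
#'
#' Full composition: neighborhood decomposition, per-neighborhood scatter,
#' non-negative discriminative projection, projected two-sample t, and
#' voxelwise tallying. `engine = "cpp"` runs the compiled hot path;
#' `engine = "r"` composes the exported R operations (identical algorithm,
#' used as an internal cross-check).
#'
#' @param maps a `synth_cohort`, list of [volume_map()]s, or subjects x
#'   voxels matrix.
#' @param labels logical, TRUE = group of interest; defaults to the treated
#'   arm of a `synth_cohort`.
#' @param params an [odvba_params()].
#' @param mask,grid required for plain matrix input.
#' @param nbs optional precomputed [build_neighborhoods()].
#' @param engine `"cpp"` or `"r"`.
#' @return a `stat_map`.
#' @export
odvba_map <- function(maps, labels = NULL, params = odvba_params(),
                      mask = NULL, grid = NULL, nbs = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
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
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("each class needs at least 2 subjects")
  if (is.null(nbs)) nbs <- build_neighborhoods(mask, grid, params)
  lam <- if (identical(params$lambda, "auto")) -1 else params$lambda
  sgn <- if (params$direction == "less") 1L else -1L
  if (engine == "cpp") {
    labmat <- matrix(as.integer(labels), nrow = 1)
    phi <- odvba_phi_cpp(X, labmat, nbs$members, lam, params$max_iter,
                         params$tol, sgn)
    return(vec_to_stat_map(drop(phi), grid, mask))
  }
  results <- lapply(nbs$members, function(mb) {
    Xs <- X[, mb, drop = FALSE]
    sc <- scatter_matrices(Xs, labels)
    if (sum(diag(sc$S_b)) <= 0)
      return(list(w = rep(1 / sqrt(length(mb)), length(mb)), s = 0))
    fit <- solve_ndp(sc, params)
    st <- neighborhood_statistic(Xs, labels, fit$w, params$direction)
    list(w = fit$w, s = st$s)
  })
  tally_map(nbs, results)
}
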