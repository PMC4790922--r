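#' Nuisance design matrix
#'
#' Builds the subjects x columns design for voxelwise nuisance removal:
#' intercept, mean-centred intracranial volume, age and time-to-scan, and
#' reference-coded clinic-site indicators (the alphabetically first site is
#' the reference). Optionally a protected group indicator can be appended so
#' the nuisance fit cannot absorb the group difference.
#'
#' @param covariates data frame with columns `icv`, `age`, `site`,
#'   `time_to_scan` (and `group` if `protect_group`); or a `synth_cohort`.
#' @param protect_group add a treated-arm indicator column (not removed at
#'   residualization).
#' @return list of class `design_matrix`: `values` (numeric matrix),
#'   `columns`, `site_levels`, `centers` (the means subtracted from the
#'   continuous columns), `nuisance_columns` (columns removed by
#'   [residualize()]).
#' @export
build_design <- function(covariates, protect_group = FALSE) {
  if (inherits(covariates, "synth_cohort")) covariates <- covariates$covariates
  stopifnot(is.data.frame(covariates),
            all(c("icv", "age", "site", "time_to_scan") %in% names(covariates)))
  n <- nrow(covariates)
  site <- factor(as.character(covariates$site))
  cont <- cbind(icv = covariates$icv, age = covariates$age,
                time_to_scan = covariates$time_to_scan)
  centers <- colMeans(cont)
  cont <- sweep(cont, 2, centers)
  X <- cbind(intercept = rep(1, n), cont)
  if (nlevels(site) > 1) {
    ind <- stats::model.matrix(~site)[, -1, drop = FALSE]
    colnames(ind) <- paste0("site_", levels(site)[-1])
    X <- cbind(X, ind)
  }
  nuisance <- setdiff(colnames(X), "intercept")
  if (protect_group) {
    if (!"group" %in% names(covariates)) stop("protect_group needs a group column")
    g <- as.integer(covariates$group == sort(unique(covariates$group))[2])
    X <- cbind(X, group = g - mean(g))
  }
  if (n < ncol(X) + 2)
    stop("too few subjects for the design (need >= columns + 2)")
  if (qr(X)$rank < ncol(X)) stop("degenerate design: rank-deficient")
  structure(list(values = X, columns = colnames(X),
                 site_levels = levels(site), centers = centers,
                 nuisance_columns = nuisance),
            class = "design_matrix")
}

#' Voxelwise ordinary-least-squares nuisance fit
#'
#' Fits, at every in-mask voxel independently, the linear model
#' `density ~ design` over all subjects pooled. With a centred design the
#' intercept is the prediction at the covariate means (the per-voxel grand
#' mean).
#'
#' @param maps a `synth_cohort`, list of [volume_map()]s, or a subjects x
#'   voxels matrix from [cohort_matrix()].
#' @param design a [build_design()] result aligned with the subject order.
#' @param mask logical mask (required for a plain list/matrix input).
#' @return list of class `nuisance_model`: `coefficients` (columns x voxels),
#'   `design`, `grand_mean` (the intercept row), `sigma2` (per-voxel residual
#'   variance), `se` (columns x voxels coefficient standard errors).
#' @export
fit_nuisance <- function(maps, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- if (is.matrix(maps)) maps else cohort_matrix(maps, mask)
  X <- design$values
  if (nrow(Y) != nrow(X)) stop("subjects do not align with design rows")
  if (nrow(X) < ncol(X)) stop("underdetermined fit: fewer subjects than columns")
  qx <- qr(X)
  coef <- qr.coef(qx, Y)                      # columns x voxels
  res <- Y - X %*% coef
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(xtxinv), sigma2))
  rownames(se) <- design$columns
  rownames(coef) <- design$columns
  structure(list(coefficients = coef, design = design,
                 grand_mean = coef["intercept", ], sigma2 = sigma2, se = se),
            class = "nuisance_model")
}

#' Remove fitted nuisance effects from tissue-density maps
#'
#' Subtracts the fitted contribution of every nuisance column (all columns
#' except the intercept and a protected `group` column) and keeps the
#' per-voxel grand mean, so adjusted maps stay on the density scale. No
#' clipping by default, preserving exact orthogonality of the residuals to
#' the design; `clip = TRUE` restores hard non-negativity.
#'
#' @param maps same forms as in [fit_nuisance()].
#' @param model a [fit_nuisance()] result.
#' @param mask logical mask for plain inputs.
#' @param clip clip adjusted values at 0.
#' @return adjusted subjects x voxels matrix (same voxel order as
#'   [cohort_matrix()]).
#' @export
residualize <- function(maps, model, mask = NULL, clip = FALSE) {
  stopifnot(inherits(model, "nuisance_model"))
  Y <- if (is.matrix(maps)) maps else cohort_matrix(maps, mask)
  X <- model$design$values
  if (nrow(Y) != nrow(X)) stop("subjects do not align with model design rows")
  nuis <- model$design$nuisance_columns
  adj <- Y - X[, nuis, drop = FALSE] %*% model$coefficients[nuis, , drop = FALSE]
  dimnames(adj) <- dimnames(Y)
  if (clip) adj[adj < 0] <- 0
  adj
}

#' Rebuild volume_map objects from an adjusted data matrix
#'
#' @param X subjects x voxels matrix (voxels in [cohort_matrix()] order).
#' @param grid a [grid_geometry()].
#' @param mask logical mask whose TRUE count equals `ncol(X)`.
#' @return list of [volume_map()]s (values clipped at 0 to satisfy the
#'   density invariant).
#' @export
matrix_to_volumes <- function(X, grid, mask) {
  stopifnot(ncol(X) == sum(mask))
  lapply(seq_len(nrow(X)), function(i) {
    vals <- array(0, dim(mask))
    vals[mask] <- pmax(X[i, ], 0)
    volume_map(vals, grid, mask)
  })
}
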