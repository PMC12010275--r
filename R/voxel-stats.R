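#' TFCE parameters
#'
#' Container for threshold-free cluster enhancement settings. Defaults are
#' the standard TFCE literature values: extent exponent E = 0.5, height
#' exponent H = 2, 26-connectivity; 5000 permutations for family-wise
#' error correction. With `dh = NULL` (default) the threshold integral is
#' evaluated exactly (see [tfce_enhance()]); a finite `dh` requests the
#' conventional step approximation.
#'
#' @param E cluster-extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh threshold step in statistic units, or `NULL` for exact
#'   evaluation of the threshold integral.
#' @param connectivity 6, 18 or 26.
#' @param n_perm permutation count for [permutation_fwe()].
#' @param seed integer RNG seed for the permutations.
#' @return a `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26L,
                        n_perm = 5000L, seed = 1L) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0,
            connectivity %in% c(6L, 18L, 26L))
  if (n_perm < 1L) stop("invalid argument: n_perm must be >= 1")
  structure(list(E = E, H = H, dh = dh,
                 connectivity = as.integer(connectivity),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "tfce_params")
}

stat_map <- function(values, kind, mask) {
  structure(list(values = values, kind = kind, mask = mask),
            class = "stat_map")
}

#' Gaussian smoothing with mask renormalization
#'
#' Separable Gaussian smoothing with sigma = fwhm / (2 sqrt(2 ln 2)) /
#' voxel_size. To avoid rim artifacts, the masked volume is divided by the
#' identically smoothed mask, so out-of-mask zeros never dilute in-mask
#' values; output outside the mask is 0.
#'
#' @param volume 3D numeric array.
#' @param mask logical array of the same shape.
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0; 0 = identity).
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @return smoothed 3D array.
#' @export
smooth_gaussian <- function(volume, mask, fwhm_mm, voxel_size_mm = 1) {
  if (fwhm_mm < 0) stop("invalid argument: fwhm must be >= 0")
  stopifnot(identical(dim(volume), dim(mask)))
  if (fwhm_mm == 0) return(volume * mask)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  num <- conv3d_separable(volume * mask, k)
  den <- conv3d_separable(mask * 1, k)
  out <- array(0, dim = dim(volume))
  out[mask] <- num[mask] / den[mask]
  out
}

# zero-padded separable 3D convolution with the same 1D kernel on each axis
conv3d_separable <- function(a, k) {
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      src <- seq_len(dp[1]) + (j - r - 1L)
      ok <- src >= 1L & src <= dp[1]
      if (!any(ok)) next
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    }
    a <- aperm(array(out, dp), order(perm))
  }
  a
}

# design matrix (intercept, group, covariates) with a rank check
cohort_design <- function(cohort) {
  X <- cbind(intercept = 1, group = cohort$group,
             as.matrix(cohort$covariates))
  if (qr(X)$rank < ncol(X))
    stop("design error: design matrix (intercept, group, covariates) ",
         "is rank deficient")
  X
}

# vectorized OLS group-contrast t over the columns of Y (n x V)
ols_group_t <- function(X, Y) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)           # p x V
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / (n - p)
  cvar <- XtXinv[2, 2]                      # group column
  tval <- B[2, ] / sqrt(pmax(sigma2 * cvar, .Machine$double.xmin))
  tval[sigma2 == 0 & B[2, ] == 0] <- 0
  tval
}

#' Voxel-wise GLM group t-map
#'
#' Fits, at every in-mask voxel, the OLS model
#' `value ~ intercept + group + covariates` and returns the t statistic of
#' the group coefficient (patients minus controls, i.e. the
#' patient > control contrast).
#'
#' @param cohort a `voxel_cohort` (see [gen_cohort()]); `data` is subjects
#'   x voxels, `group` coded 0/1 with patients = 1.
#' @return a `stat_map` of kind `"t"` (0 outside the mask).
#' @export
fit_glm_tmap <- function(cohort) {
  stopifnot(inherits(cohort, "voxel_cohort"))
  if (length(unique(cohort$group)) < 2L)
    stop("design error: both group levels are required")
  X <- cohort_design(cohort)
  mask_idx <- which(cohort$mask)
  tval <- ols_group_t(X, cohort$data[, mask_idx, drop = FALSE])
  vol <- array(0, dim = cohort$shape)
  vol[mask_idx] <- tval
  stat_map(vol, "t", cohort$mask)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Applies the TFCE transform `TFCE(v) = integral_h e_h(v)^E h^H dh`,
#' where `e_h(v)` is the size of the connected suprathreshold component
#' containing v at height h. Because `e_h(v)` is piecewise constant in h
#' (it changes only where h crosses a voxel height), the integral has a
#' closed form on each interval and is evaluated exactly by default; a
#' finite `dh` in `params` requests the conventional discrete summation
#' over midpoint thresholds instead. The two signs are enhanced in
#' separate one-sided passes (the negative part is negated, enhanced, and
#' its sign restored), so the output is an odd function of the input.
#'
#' @param stat a `stat_map` (typically kind `"t"`).
#' @param params a [tfce_params()] object.
#' @return a `stat_map` of kind `"tfce"`.
#' @export
tfce_enhance <- function(stat, params = tfce_params()) {
  stopifnot(inherits(stat, "stat_map"))
  v <- stat$values * stat$mask
  dh <- if (is.null(params$dh)) -1 else params$dh
  dims <- as.integer(dim(v))
  pos <- .tfce_cpp(as.numeric(pmax(v, 0)), dims, params$E, params$H, dh,
                   params$connectivity)
  neg <- .tfce_cpp(as.numeric(pmax(-v, 0)), dims, params$E, params$H, dh,
                   params$connectivity)
  stat_map(array(pos - neg, dim = dims), "tfce", stat$mask)
}

#' Permutation family-wise error correction of the TFCE map
#'
#' Freedman-Lane permutation inference for the group effect in the presence
#' of covariates: the phenotype is residualized on the reduced model
#' (intercept + covariates), residual rows are permuted, reduced-model
#' fitted values are added back, and the full-model group t-map and its
#' TFCE transform are recomputed. The null distribution of the maximum
#' |TFCE| over the mask gives `p_fwe(v) = (1 + #(max_null >= |TFCE(v)|)) /
#' (n_perm + 1)`. The exact TFCE evaluation (default `dh = NULL`) puts
#' observed and null enhancements on a common scale with no step
#' parameter; a finite `dh` is applied unchanged to both.
#'
#' @param cohort a `voxel_cohort`.
#' @param params a [tfce_params()] (permutation count, seed, TFCE
#'   settings).
#' @return a `stat_map` of kind `"p_fwe"` (1 outside the mask), with
#'   attributes `tfce` (the observed TFCE `stat_map`), `tmap`, and
#'   `max_null` (the permutation distribution of the maximum |TFCE|).
#' @export
permutation_fwe <- function(cohort, params = tfce_params()) {
  stopifnot(inherits(cohort, "voxel_cohort"),
            inherits(params, "tfce_params"))
  tmap <- fit_glm_tmap(cohort)
  tfce_obs <- tfce_enhance(tmap, params)
  mask_idx <- which(cohort$mask)
  obs <- abs(tfce_obs$values[mask_idx])

  X <- cohort_design(cohort)
  Y <- cohort$data[, mask_idx, drop = FALSE]
  Z <- X[, -2, drop = FALSE]                 # reduced model
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  fitted_red <- Hz %*% Y
  resid_red <- Y - fitted_red
  n <- nrow(Y)
  dims <- as.integer(cohort$shape)
  vol <- array(0, dim = dims)
  dh <- if (is.null(params$dh)) -1 else params$dh
  max_null <- with_seed(params$seed, vapply(seq_len(params$n_perm),
    function(i) {
      Ystar <- fitted_red + resid_red[sample.int(n), , drop = FALSE]
      tstar <- ols_group_t(X, Ystar)
      vol[mask_idx] <- tstar
      pos <- .tfce_cpp(as.numeric(pmax(vol, 0)), dims, params$E, params$H,
                       dh, params$connectivity)
      neg <- .tfce_cpp(as.numeric(pmax(-vol, 0)), dims, params$E, params$H,
                       dh, params$connectivity)
      max(abs(pos - neg))
    }, numeric(1)))
  p <- (1 + vapply(obs, function(o) sum(max_null >= o), numeric(1))) /
       (params$n_perm + 1)
  pvol <- array(1, dim = dims)
  pvol[mask_idx] <- p
  out <- stat_map(pvol, "p_fwe", cohort$mask)
  attr(out, "tfce") <- tfce_obs
  attr(out, "tmap") <- tmap
  attr(out, "max_null") <- max_null
  out
}

#' Parcellate a statistic map into regional means
#'
#' Averages the map over the in-mask voxels of each atlas region
#' (background label 0 ignored). Regions with no in-mask voxels are
#' flagged with a warning and set to `NA`.
#'
#' @param stat a `stat_map`.
#' @param atlas a `parcellation_atlas` of matching shape.
#' @return a `regional_phenotype`: list with `region_ids` and `values`.
#' @export
parcellate <- function(stat, atlas) {
  stopifnot(inherits(stat, "stat_map"), inherits(atlas, "parcellation_atlas"),
            identical(dim(stat$values), dim(atlas$label_volume)))
  lab <- as.vector(atlas$label_volume)
  vals <- as.vector(stat$values)
  inm <- as.vector(stat$mask) & lab > 0
  means <- vapply(atlas$region_ids, function(r) {
    sel <- inm & lab == r
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  if (anyNA(means))
    warning(sum(is.na(means)), " region(s) with no in-mask voxels set to NA")
  regional_phenotype(atlas$region_ids, means)
}

#' Construct a regional phenotype
#' @param region_ids ordered region identifiers.
#' @param values one numeric value per region.
#' @return a `regional_phenotype`.
#' @export
regional_phenotype <- function(region_ids, values) {
  stopifnot(length(region_ids) == length(values))
  structure(list(region_ids = region_ids, values = as.numeric(values)),
            class = "regional_phenotype")
}
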