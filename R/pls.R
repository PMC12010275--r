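#' Z-score the columns of a matrix, dropping degenerate columns
#'
#' Centers and scales every column to mean 0, SD 1. Columns with zero
#' variance cannot be scaled; they are dropped with a warning reporting
#' the count.
#'
#' @param m numeric matrix (e.g. regions x genes expression).
#' @return matrix with scaled columns (possibly fewer than input).
#' @export
zscore_columns <- function(m) {
  stopifnot(is.matrix(m))
  sds <- apply(m, 2, sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance column(s) dropped")
    m <- m[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Z-score a vector
#' @param x numeric vector with nonzero variance.
#' @return scaled vector (mean 0, SD 1).
#' @export
zscore_vector <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) stop("invalid argument: zero-variance vector")
  (x - mean(x)) / s
}

#' Partial least squares regression with a univariate response
#'
#' NIPALS PLS1: per component, the weight vector is `w = X'y / ||X'y||`
#' (for component 1 this makes the weights proportional to the
#' gene-phenotype covariances), scores are `t = X w`, and both `X` and `y`
#' are deflated on `t` before the next component. Inputs are expected
#' z-scored (see [zscore_columns()]); the fit itself does no centering.
#'
#' @param X R x G predictor matrix (z-scored expression).
#' @param y length-R response (z-scored regional phenotype).
#' @param K number of components, `K <= min(R - 1, G)`.
#' @return a `pls_model`: `weights` (G x K), `scores` (R x K),
#'   `y_loadings`, `explained_variance_y` (incremental R^2 of y per
#'   component), `explained_variance_x`, `score_phenotype_corr`
#'   (Pearson r between each score and y).
#' @export
plsr_fit <- function(X, y, K = 10L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  R <- nrow(X); G <- ncol(X)
  if (K < 1L || K > min(R - 1L, G))
    stop("invalid argument: K must be in [1, min(R-1, G)]")
  Xd <- X; yd <- as.numeric(y)
  W <- matrix(0, G, K); Tm <- matrix(0, R, K)
  q <- numeric(K); evx <- numeric(K)
  ssx <- sum(X^2); ssy <- sum((y - mean(y))^2)
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5)
      stop("deflated covariance vanished before component ", k)
    w <- w / nw
    tt <- as.numeric(Xd %*% w)
    tt2 <- sum(tt^2)
    p <- crossprod(Xd, tt) / tt2
    q[k] <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - tt * q[k]
    W[, k] <- w
    Tm[, k] <- tt
    evx[k] <- tt2 * sum(p^2) / ssx
  }
  # scores are orthogonal across components, so incremental R^2 of the
  # original y decomposes over components
  yc <- y - mean(y)
  evy <- vapply(seq_len(K), function(k) {
    tt <- Tm[, k]
    sum(yc * tt)^2 / (sum(tt^2) * ssy)
  }, numeric(1))
  rownames(W) <- colnames(X)
  structure(list(n_components = K, weights = W, scores = Tm,
                 y_loadings = q,
                 explained_variance_y = evy,
                 explained_variance_x = evx,
                 score_phenotype_corr = as.numeric(cor(Tm, y))),
            class = "pls_model")
}

#' Direction-aligned component weights
#'
#' PLS weights carry an arbitrary joint sign (negating a weight vector and
#' its scores leaves the fit unchanged). This enforces the convention that
#' genes with large positive aligned weight have expression positively
#' correlated with the phenotype: if the component scores correlate
#' negatively with `y`, the weights are negated; if positively, they are
#' kept. A zero correlation keeps the sign and warns.
#'
#' @param model a `pls_model`.
#' @param y the phenotype the model was fit to.
#' @param k component index.
#' @return named numeric vector of aligned weights.
#' @export
align_weights <- function(model, y, k = 1L) {
  stopifnot(inherits(model, "pls_model"))
  if (k < 1L || k > model$n_components)
    stop("invalid argument: component index out of range")
  r <- suppressWarnings(cor(model$scores[, k], y))
  w <- model$weights[, k]
  if (is.na(r) || r == 0) {
    warning("component ", k, " scores uncorrelated with phenotype; ",
            "weight sign kept")
    return(w)
  }
  sign(r) * w
}

#' Null-calibrated gene ranking from PLS weights
#'
#' Fits PLS of the z-scored phenotype on the z-scored expression matrix,
#' aligns the component-`k` weights ([align_weights()]), then refits the
#' same model on every surrogate map of a spatial-autocorrelation-
#' preserving ensemble to obtain a per-gene null SD of the aligned weight.
#' The gene statistic is `Z_g = w_g(observed) / SD_null(w_g)`; genes are
#' ranked by descending Z (ties broken by gene symbol). Genes with a null
#' SD of zero are excluded with a warning. Optionally the denominator can
#' instead be a region-resampling bootstrap SD (`null = "bootstrap"`).
#'
#' @param X regions x genes expression matrix (raw; z-scored internally,
#'   zero-variance genes dropped).
#' @param y regional phenotype values (raw; z-scored internally).
#' @param surrogates a `surrogate_ensemble` on the same regions.
#' @param k PLS component used for ranking (default 1).
#' @param null `"spatial"` (surrogate-map SD, default) or `"bootstrap"`
#'   (region resampling; `n_boot` draws, seeded by `boot_seed`).
#' @param n_boot,boot_seed bootstrap settings (only for
#'   `null = "bootstrap"`).
#' @return a `gene_ranking` data frame: `gene`, `aligned_weight`, `z`,
#'   `rank`, sorted by descending `z`, with the fitted `pls_model` in
#'   attribute `model`.
#' @export
gene_z_scores <- function(X, y, surrogates, k = 1L,
                          null = c("spatial", "bootstrap"),
                          n_boot = 1000L, boot_seed = 1L) {
  null <- match.arg(null)
  Xz <- suppressWarnings(zscore_columns(X))
  n_dropped <- ncol(X) - ncol(Xz)
  if (n_dropped > 0)
    message(n_dropped, " zero-variance gene(s) excluded from ranking")
  yz <- zscore_vector(y)
  model <- plsr_fit(Xz, yz, K = k)
  w_obs <- align_weights(model, yz, k)
  refit_w <- function(ystar) {
    yzs <- zscore_vector(ystar)
    m <- plsr_fit(Xz, yzs, K = k)
    align_weights(m, yzs, k)
  }
  Wnull <- if (null == "spatial") {
    stopifnot(inherits(surrogates, "surrogate_ensemble"),
              ncol(surrogates$maps) == nrow(Xz))
    vapply(seq_len(nrow(surrogates$maps)),
           function(i) refit_w(surrogates$maps[i, ]), numeric(ncol(Xz)))
  } else {
    R <- nrow(Xz)
    with_seed(boot_seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(R, replace = TRUE)
      yzs <- zscore_vector(yz[idx])
      m <- plsr_fit(Xz[idx, , drop = FALSE], yzs, K = k)
      align_weights(m, yzs, k)
    }, numeric(ncol(Xz))))
  }
  sd_null <- apply(Wnull, 1, sd)
  keep <- sd_null > 0
  if (!all(keep))
    warning(sum(!keep), " gene(s) with zero null SD excluded")
  z <- w_obs[keep] / sd_null[keep]
  genes <- colnames(Xz)[keep]
  ord <- order(-z, genes)
  out <- data.frame(gene = genes[ord], aligned_weight = w_obs[keep][ord],
                    z = z[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  attr(out, "model") <- model
  attr(out, "component") <- k
  out
}

#' Validate a gene ranking by direct univariate regression
#'
#' For the top and bottom `k_top` genes of a ranking, regresses each
#' gene's (raw) expression on the phenotype and reports the slope and
#' Pearson r. On a sound ranking, top genes have positive slopes and
#' bottom genes negative slopes.
#'
#' @param X_raw regions x genes expression (raw scale).
#' @param y regional phenotype values.
#' @param ranking a `gene_ranking`.
#' @param k_top genes taken from each end (`2 * k_top <=` ranked genes).
#' @return data frame: `gene`, `end` ("top"/"bottom"), `slope`, `r`.
#' @export
validate_ranking <- function(X_raw, y, ranking, k_top = 5L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  G <- nrow(ranking)
  if (2L * k_top > G)
    stop("invalid argument: k_top exceeds half the ranked genes")
  sel <- rbind(data.frame(gene = head(ranking$gene, k_top), end = "top"),
               data.frame(gene = tail(ranking$gene, k_top), end = "bottom"))
  res <- lapply(seq_len(nrow(sel)), function(i) {
    x <- X_raw[, sel$gene[i]]
    f <- lm.fit(cbind(1, y), x)
    data.frame(gene = sel$gene[i], end = sel$end[i],
               slope = unname(f$coefficients[2]),
               r = suppressWarnings(cor(x, y)))
  })
  do.call(rbind, res)
}
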