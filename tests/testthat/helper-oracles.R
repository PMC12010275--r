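# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: connected components by iterative
# min-label propagation, TFCE by literal threshold summation, GSEA by a
# literal running-sum walk, variograms/parcellation/SI by plain loops.

neighbor_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  off[keep, , drop = FALSE]
}

shift_inf <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(Inf, d)
  sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
  sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
  sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
  out[sx, sy, sz] <- a[sx + dx, sy + dy, sz + dz]
  out
}

label_components_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- seq_len(sum(mask))
  off <- neighbor_offsets(connectivity)
  repeat {
    new_lab <- lab
    for (i in seq_len(nrow(off))) {
      sh <- shift_inf(lab, off$dx[i], off$dy[i], off$dz[i])
      new_lab <- pmin(new_lab, sh)
    }
    new_lab[!mask] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  out <- array(0L, d)
  out[mask] <- match(lab[mask], sort(unique(lab[mask])))
  out
}

# exact reference: sum closed-form interval contributions over the sorted
# distinct voxel heights (the dh -> 0 limit of the threshold summation)
tfce_exact_oracle <- function(vol, E, H, connectivity = 26) {
  out <- array(0, dim(vol))
  for (sgn in c(1, -1)) {
    v <- pmax(sgn * vol, 0)
    hs <- sort(unique(v[v > 0]), decreasing = TRUE)
    if (!length(hs)) next
    h_lo <- c(hs[-1], 0)
    for (j in seq_along(hs)) {
      supra <- v >= hs[j]
      lab <- label_components_oracle(supra, connectivity)
      sizes <- tabulate(lab[supra])
      idx <- which(supra)
      term <- (hs[j]^(H + 1) - h_lo[j]^(H + 1)) / (H + 1)
      out[idx] <- out[idx] + sgn * sizes[lab[idx]]^E * term
    }
  }
  out
}

tfce_oracle <- function(vol, E, H, dh, connectivity = 26) {
  out <- array(0, dim(vol))
  for (sgn in c(1, -1)) {
    v <- pmax(sgn * vol, 0)
    m <- max(v)
    if (m <= 0) next
    K <- floor(m / dh + 0.5)
    for (k in seq_len(K)) {
      h <- (k - 0.5) * dh      # midpoint rule, as in the enhancer
      supra <- v >= h
      if (!any(supra)) next
      lab <- label_components_oracle(supra, connectivity)
      sizes <- tabulate(lab[supra])
      idx <- which(supra)
      out[idx] <- out[idx] + sgn * sizes[lab[idx]]^E * h^H * dh
    }
  }
  out
}

# fine-step TFCE summation over midpoint thresholds h_k = (k - 1/2) dh.
# Identical by construction to tfce_oracle, but the component labelling is
# computed once per interval between consecutive voxel heights (where the
# suprathreshold set cannot change) instead of once per step.
tfce_finestep_oracle <- function(vol, E, H, dh, connectivity = 26) {
  out <- array(0, dim(vol))
  for (sgn in c(1, -1)) {
    v <- pmax(sgn * vol, 0)
    m <- max(v)
    if (m <= 0) next
    K <- floor(m / dh + 0.5)
    hk <- (seq_len(K) - 0.5) * dh
    hs <- sort(unique(v[v > 0]), decreasing = TRUE)
    h_lo <- c(hs[-1], 0)
    for (j in seq_along(hs)) {
      in_int <- hk > h_lo[j] & hk <= hs[j]
      if (!any(in_int)) next
      supra <- v >= hs[j]
      lab <- label_components_oracle(supra, connectivity)
      sizes <- tabulate(lab[supra])
      idx <- which(supra)
      out[idx] <- out[idx] +
        sgn * sizes[lab[idx]]^E * sum(hk[in_int]^H) * dh
    }
  }
  out
}

# literal GSEA running sum: walk the ranking, step up at hits, down at misses
gsea_es_oracle <- function(stats, genes, set, p_weight) {
  N <- length(stats)
  hit <- genes %in% set
  m <- sum(hit)
  nr <- sum(abs(stats[hit])^p_weight)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (nr > 0) abs(stats[i])^p_weight / nr else 1 / m)
    } else cur - 1 / (N - m)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

variogram_oracle <- function(values, centroids) {
  R <- length(values)
  d <- sv <- numeric(0)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    d <- c(d, sqrt(sum((centroids[i, ] - centroids[j, ])^2)))
    sv <- c(sv, 0.5 * (values[i] - values[j])^2)
  }
  list(dist = d, semivar = sv)
}

si_oracle <- function(mean_fpkm, eps = 1) {
  G <- nrow(mean_fpkm)
  n_types <- ncol(mean_fpkm)
  si <- matrix(0, G, n_types)
  for (a in seq_len(n_types)) {
    rs <- matrix(0, G, 0)
    for (b in seq_len(n_types)) {
      if (b == a) next
      fc <- (mean_fpkm[, a] + eps) / (mean_fpkm[, b] + eps)
      rs <- cbind(rs, rank(-fc, ties.method = "average"))
    }
    si[, a] <- rowMeans(rs)
  }
  si
}

# small smoothed random t-map for TFCE tests
random_tmap <- function(shape, seed, fwhm = 2.5) {
  set.seed(seed)
  v <- array(rnorm(prod(shape)), shape)
  mask <- array(TRUE, shape)
  smooth_gaussian(v, mask, fwhm) * 3
}
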