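#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format (set name, description, member
#' genes). Duplicate genes within a set are removed; sets left empty are
#' skipped with a warning.
#'
#' @param path file path.
#' @return a `gene_set_collection`: named list of gene symbol vectors with
#'   `description` and `namespace` attributes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("parse error at line ", i, ": fewer than 3 tab-separated fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("empty set '", f[1], "' skipped (line ", i, ")")
      next
    }
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  structure(sets, description = descs, namespace = "file",
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection named list of gene symbol vectors.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running-sum statistic on a ranked gene list: walking
#' down the ranking, membership hits increment the sum by
#' `|stat|^p_weight / sum(|stat|^p_weight over hits)` and misses decrement
#' by `1 / (N - m)`. The enrichment score is the signed maximum deviation
#' from zero; the leading edge is the hit genes up to (positive ES) or
#' from (negative ES) the extremum.
#'
#' @param ranking a `gene_ranking` or a named numeric vector of statistics
#'   sorted in descending order.
#' @param set character vector of member gene symbols.
#' @param p_weight weighting exponent (0 = unweighted KS, 1 = classic
#'   GSEA).
#' @return list with `es`, `running` (length-N running sum) and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranking, set, p_weight = 1) {
  rs <- ranking_stats(ranking)
  stats <- rs$stats; genes <- rs$genes
  N <- length(stats)
  hit <- genes %in% set
  m <- sum(hit)
  if (m == 0L) stop("invalid argument: set does not intersect the universe")
  if (m == N) stop("invalid argument: set equals the universe")
  w <- abs(stats)^p_weight
  wh <- w * hit
  sw <- sum(wh)
  inc <- if (sw > 0) wh / sw else hit / m   # all-zero stats: unweighted
  running <- cumsum(inc - (!hit) / (N - m))
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) genes[seq_len(i_ext)][hit[seq_len(i_ext)]]
             else genes[i_ext:N][hit[i_ext:N]]
  list(es = es, running = running, leading_edge = leading)
}

# accept either a gene_ranking or a named, descending-sorted stat vector
ranking_stats <- function(ranking) {
  if (inherits(ranking, "gene_ranking"))
    list(stats = ranking$z, genes = ranking$gene)
  else {
    stopifnot(is.numeric(ranking), !is.null(names(ranking)))
    list(stats = as.numeric(ranking), genes = names(ranking))
  }
}

# ES from sorted hit positions only (O(m)); used in the permutation loop.
# absw: |stat|^p for all N positions; cumabs: cumsum(absw).
es_from_positions <- function(pos, absw, N) {
  pos <- sort.int(pos)
  m <- length(pos)
  w <- absw[pos]
  sw <- sum(w)
  fh <- if (sw > 0) cumsum(w) / sw else seq_len(m) / m
  miss <- (pos - seq_len(m)) / (N - m)
  after <- fh - miss                   # running sum just after each hit
  before <- c(0, fh[-m]) - miss        # just before each hit
  hi <- max(after); lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' For each gene set, computes the weighted-KS enrichment score against
#' the ranking, a gene-label permutation null (random sets of the same
#' size drawn from the universe), a same-sign permutation p-value, the
#' normalized enrichment score `NES = ES / mean(|null ES| of same sign)`,
#' and the standard GSEA NES-based FDR q. Sets outside
#' `[min_size, max_size]` (after intersection with the universe) are
#' excluded.
#'
#' @param ranking a `gene_ranking` or named descending stat vector.
#' @param collection a `gene_set_collection`.
#' @param n_perm permutations per set.
#' @param seed integer RNG seed.
#' @param min_size,max_size inclusive set-size filter.
#' @param p_weight running-sum weight exponent.
#' @return an `enrichment_result` data frame: `set`, `size`, `es`, `nes`,
#'   `pval`, `padj`, `leading_edge` (list column), sorted by `pval`.
#' @export
gsea_preranked <- function(ranking, collection, n_perm = 1000L, seed = 1L,
                           min_size = 10L, max_size = 500L, p_weight = 1) {
  if (n_perm < 1L) stop("invalid argument: n_perm must be >= 1")
  rs <- ranking_stats(ranking)
  N <- length(rs$stats)
  sets <- lapply(collection, function(s) which(rs$genes %in% s))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    warning("no gene set within the size filter; empty result")
    return(empty_enrichment_result())
  }
  sets <- sets[keep]; sizes <- sizes[keep]
  absw <- abs(rs$stats)^p_weight
  res <- lapply(seq_along(sets), function(i) {
    esr <- enrichment_score(ranking, collection[[names(sets)[i]]], p_weight)
    esr
  })
  es_obs <- vapply(res, `[[`, numeric(1), "es")
  # permutation null: resample hit positions uniformly, one null matrix
  # per set (sizes differ); RNG consumed in set order under one seed
  null_es <- with_seed(seed, lapply(seq_along(sets), function(i) {
    vapply(seq_len(n_perm),
           function(j) es_from_positions(sample.int(N, sizes[i]), absw, N),
           numeric(1))
  }))
  pval <- numeric(length(sets)); nes <- numeric(length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nn <- null_es[[i]]
    same <- if (es_obs[i] >= 0) nn[nn >= 0] else nn[nn < 0]
    pval[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    pos_mean <- mean(nn[nn >= 0]); neg_mean <- mean(abs(nn[nn < 0]))
    nes[i] <- if (es_obs[i] >= 0) {
      if (is.nan(pos_mean) || pos_mean == 0) NA_real_
      else es_obs[i] / pos_mean
    } else {
      if (is.nan(neg_mean) || neg_mean == 0) NA_real_
      else es_obs[i] / neg_mean
    }
    null_nes[[i]] <- c(nn[nn >= 0] / pos_mean, -abs(nn[nn < 0]) / neg_mean)
  }
  padj <- gsea_fdr(nes, unlist(null_nes))
  out <- data.frame(set = names(sets), size = as.integer(sizes),
                    es = es_obs, nes = nes, pval = pval, padj = padj,
                    stringsAsFactors = FALSE)
  out$leading_edge <- lapply(res, `[[`, "leading_edge")
  out <- out[order(out$pval, -abs(out$nes)), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

empty_enrichment_result <- function() {
  out <- data.frame(set = character(0), size = integer(0),
                    es = numeric(0), nes = numeric(0),
                    pval = numeric(0), padj = numeric(0))
  out$leading_edge <- list()
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# standard GSEA FDR: for each observed NES*, the fraction of pooled null
# NES at least as extreme (same sign) divided by the fraction of observed
# NES at least as extreme, clipped to [0, 1]
gsea_fdr <- function(nes, pooled_null) {
  vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num_pool <- pooled_null[pooled_null >= 0]
      num <- if (length(num_pool)) mean(num_pool >= x) else 0
      obs <- nes[!is.na(nes) & nes >= 0]
      den <- mean(obs >= x)
    } else {
      num_pool <- pooled_null[pooled_null < 0]
      num <- if (length(num_pool)) mean(num_pool <= x) else 0
      obs <- nes[!is.na(nes) & nes < 0]
      den <- mean(obs <= x)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
}

#' Prune redundant gene sets from an enrichment result
#'
#' Greedy redundancy filter: sets are visited from most to least
#' significant; a set is dropped if its Jaccard gene overlap with any
#' already-kept set exceeds `jaccard_threshold`. This plays the role of a
#' term "simplify" step using gene overlap rather than ontology semantic
#' similarity.
#'
#' @param results an `enrichment_result`.
#' @param collection the `gene_set_collection` the results came from.
#' @param jaccard_threshold overlap above which the later set is dropped
#'   (1 = never prune).
#' @return the pruned `enrichment_result`.
#' @export
prune_redundant <- function(results, collection, jaccard_threshold = 0.7) {
  if (jaccard_threshold < 0 || jaccard_threshold > 1)
    stop("invalid argument: jaccard_threshold must be in [0, 1]")
  if (nrow(results) == 0L) return(results)
  ord <- order(results$pval, -abs(results$nes))
  kept <- integer(0)
  for (i in ord) {
    gi <- collection[[results$set[i]]]
    redundant <- any(vapply(kept, function(j) {
      gj <- collection[[results$set[j]]]
      length(intersect(gi, gj)) / length(union(gi, gj)) > jaccard_threshold
    }, logical(1)))
    if (!redundant) kept <- c(kept, i)
  }
  out <- results[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}
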