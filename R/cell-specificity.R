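#' Per-type mean FPKM
#'
#' Averages FPKM across the samples of each of the six cell types
#' (endothelial, neuron, oligodendrocyte, astrocyte, microglia, OPC),
#' returning the columns in that fixed order.
#'
#' @param table a `celltype_table` (see [gen_celltype_fpkm()]) or a list
#'   with `fpkm` (genes x samples) and `sample_type`.
#' @return G x 6 matrix of mean FPKM, columns in the fixed type order.
#' @export
average_fpkm <- function(table) {
  fpkm <- table$fpkm; st <- table$sample_type
  stopifnot(is.matrix(fpkm), length(st) == ncol(fpkm))
  missing_types <- setdiff(CELL_TYPES, unique(st))
  if (length(missing_types))
    stop("invalid argument: no samples for cell type(s) ",
         paste(missing_types, collapse = ", "))
  out <- vapply(CELL_TYPES, function(ct)
    rowMeans(fpkm[, st == ct, drop = FALSE]), numeric(nrow(fpkm)))
  rownames(out) <- rownames(fpkm)
  out
}

#' Specificity index
#'
#' For each target cell type A and each of the five other types B, genes
#' are ranked by descending fold change `(FPKM_A + eps) / (FPKM_B + eps)`
#' (rank 1 = most A-enriched; ties get average ranks). The specificity
#' index `SI_A(g)` is the mean of the five ranks, so a gene expressed only
#' in A has SI_A = 1 and exchangeable genes average (G + 1) / 2.
#'
#' @param mean_fpkm G x 6 matrix from [average_fpkm()].
#' @param eps pseudo-count guarding zero FPKM (default 1).
#' @return G x 6 SI matrix (same dimnames).
#' @export
specificity_index <- function(mean_fpkm, eps = 1) {
  stopifnot(is.matrix(mean_fpkm), ncol(mean_fpkm) == length(CELL_TYPES),
            nrow(mean_fpkm) >= 2L)
  G <- nrow(mean_fpkm)
  si <- matrix(0, G, ncol(mean_fpkm), dimnames = dimnames(mean_fpkm))
  for (a in seq_len(ncol(mean_fpkm))) {
    ranks <- matrix(0, G, ncol(mean_fpkm) - 1L)
    j <- 0L
    for (b in seq_len(ncol(mean_fpkm))) {
      if (b == a) next
      j <- j + 1L
      fc <- (mean_fpkm[, a] + eps) / (mean_fpkm[, b] + eps)
      ranks[, j] <- rank(-fc, ties.method = "average")
    }
    si[, a] <- rowMeans(ranks)
  }
  si
}

#' Permutation p-values for the specificity index
#'
#' Null model: the sample-to-cell-type assignment is permuted, type means
#' and the SI matrix are recomputed, and all null SI values are pooled
#' across genes and types. Sample-label permutation is the exchangeability
#' unit that matches how the tables arise (grouped RNA-seq samples): under
#' the null of no cell-type structure it reproduces the observed SI
#' distribution exactly, so pooled p-values are uniform, while genuine
#' specificity is destroyed by scattering a gene's high samples across
#' pseudo-types. Pooling across genes gives p-value resolution of
#' `1 / (G * 6 * n_perm)`, far finer than `1 / n_perm`:
#' `pSI(g, A) = (1 + #(null SI <= SI_A(g))) / (pooled count + 1)`. Small
#' SI means specific, so small pSI flags specific genes.
#'
#' @param table a `celltype_table` (genes x samples FPKM with the
#'   sample-to-type mapping).
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param eps pseudo-count passed to [specificity_index()].
#' @return a `specificity_result`: list with `SI`, `pSI` (both G x 6) and
#'   `n_perm`.
#' @export
psi_permutation <- function(table, n_perm = 100L, seed = 1L, eps = 1) {
  if (n_perm < 1L) stop("invalid argument: n_perm must be >= 1")
  mean_fpkm <- average_fpkm(table)
  si <- specificity_index(mean_fpkm, eps)
  G <- nrow(mean_fpkm)
  null_si <- with_seed(seed, {
    vals <- vector("list", n_perm)
    for (i in seq_len(n_perm)) {
      st <- sample(table$sample_type)
      mfn <- vapply(CELL_TYPES, function(ct)
        rowMeans(table$fpkm[, st == ct, drop = FALSE]), numeric(G))
      vals[[i]] <- as.vector(specificity_index(mfn, eps))
    }
    unlist(vals)
  })
  sorted_null <- sort.int(null_si)
  n_pool <- length(sorted_null)
  psi <- matrix((1 + findInterval(si, sorted_null)) / (n_pool + 1),
                nrow = G, dimnames = dimnames(si))
  structure(list(SI = si, pSI = psi, n_perm = n_perm),
            class = "specificity_result")
}

#' Cell-type-specific gene sets from a specificity result
#'
#' Per cell type, the genes with `pSI < threshold`. The conventional
#' threshold 0.001 defines the cell-type-specific gene lists. Empty sets
#' are retained with a warning so downstream size filters can act on them.
#'
#' @param spec a `specificity_result`.
#' @param threshold pSI cutoff in (0, 1), default 0.001.
#' @param series optional series label prefixed to set names.
#' @return a `gene_set_collection` (namespace "celltype").
#' @export
celltype_gene_sets <- function(spec, threshold = 0.001, series = NULL) {
  stopifnot(inherits(spec, "specificity_result"))
  if (threshold <= 0 || threshold >= 1)
    stop("invalid argument: threshold must be in (0, 1)")
  genes <- rownames(spec$pSI)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(spec$pSI)))
  sets <- lapply(seq_len(ncol(spec$pSI)), function(a)
    genes[spec$pSI[, a] < threshold])
  names(sets) <- if (is.null(series)) CELL_TYPES
                 else paste(series, CELL_TYPES, sep = "_")
  n_empty <- sum(lengths(sets) == 0)
  if (n_empty > 0)
    warning(n_empty, " cell type(s) with no gene below pSI < ", threshold)
  structure(sets, namespace = "celltype", class = "gene_set_collection")
}
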