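#' Generate a Voronoi parcellation atlas
#'
#' Builds a synthetic volumetric parcellation: `n_regions` seed voxels are
#' drawn at random and every in-mask voxel is labelled by its nearest seed
#' (Euclidean distance in grid units, ties to the lowest region id), giving
#' contiguous Voronoi-style regions. The default of 83 regions matches the
#' Desikan-Killiany parcellation commonly used for regional expression
#' matrices.
#'
#' @param shape integer length-3 grid size.
#' @param n_regions number of regions (>= 1, <= number of voxels).
#' @param seed integer RNG seed.
#' @return A `parcellation_atlas`: list with `label_volume` (3D integer
#'   array, 0 = background), `region_ids`, `centroids` (regions x 3, grid
#'   units) and `shape`.
#' @export
gen_atlas <- function(shape, n_regions = 83L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  n_vox <- prod(shape)
  if (n_regions < 1L) stop("invalid argument: n_regions must be >= 1")
  if (n_regions > n_vox)
    stop("invalid argument: n_regions exceeds the voxel count")
  coords <- as.matrix(expand.grid(x = seq_len(shape[1]),
                                  y = seq_len(shape[2]),
                                  z = seq_len(shape[3])))
  seeds <- with_seed(seed, sample.int(n_vox, n_regions))
  seed_xyz <- coords[seeds, , drop = FALSE]
  # nearest-seed labels; ties resolved toward the lowest region id
  lab <- integer(n_vox)
  best <- rep(Inf, n_vox)
  for (r in seq_len(n_regions)) {
    d2 <- (coords[, 1] - seed_xyz[r, 1])^2 +
          (coords[, 2] - seed_xyz[r, 2])^2 +
          (coords[, 3] - seed_xyz[r, 3])^2
    upd <- d2 < best
    lab[upd] <- r
    best[upd] <- d2[upd]
  }
  label_volume <- array(lab, dim = shape)
  centroids <- t(vapply(seq_len(n_regions), function(r)
    colMeans(coords[lab == r, , drop = FALSE]), numeric(3)))
  colnames(centroids) <- c("x", "y", "z")
  structure(list(label_volume = label_volume,
                 region_ids = seq_len(n_regions),
                 centroids = centroids,
                 shape = shape),
            class = "parcellation_atlas")
}

#' Simulate a two-group voxel cohort with a planted focal effect
#'
#' Subject volumes are unit-variance Gaussian noise plus a group mean shift
#' of `effect_size` (a Cohen's d, since the noise SD is 1) inside the voxels
#' of `effect_regions`, plus linear age and sex contributions applied over
#' the whole mask. Age is drawn uniform on 45-75 years and sex is Bernoulli
#' with probability one half, emulating a late-life case-control cohort.
#'
#' @param atlas a `parcellation_atlas`.
#' @param n_per_group subjects per group (>= 3).
#' @param effect_size standardized group mean difference inside the effect
#'   regions (unitless; patients minus controls).
#' @param effect_regions region ids carrying the effect (may be empty).
#' @param covariate_slopes named numeric, per-unit slopes of `age` (per
#'   year, on mean-centred age) and `sex` applied to every in-mask voxel.
#' @param seed integer RNG seed.
#' @return list with `cohort` (a `voxel_cohort`: subjects x voxels matrix
#'   `data`, `group` 0/1, `covariates` data frame, logical `mask`, `shape`)
#'   and `truth` (a `synthetic_truth` recording `effect_mask` voxel indices,
#'   `effect_size` and the seed).
#' @export
gen_cohort <- function(atlas, n_per_group, effect_size = 0,
                       effect_regions = integer(0),
                       covariate_slopes = c(age = 0.02, sex = 0.2),
                       seed = 1L) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  if (n_per_group < 3L) stop("invalid argument: n_per_group must be >= 3")
  if (length(effect_regions) &&
      !all(effect_regions %in% atlas$region_ids))
    stop("invalid argument: unknown effect region id")
  shape <- atlas$shape
  n_vox <- prod(shape)
  mask <- array(TRUE, dim = shape)
  n <- 2L * n_per_group
  eff_idx <- which(as.vector(atlas$label_volume) %in% effect_regions)
  with_seed(seed, {
    group <- rep(c(0L, 1L), each = n_per_group)
    age <- runif(n, 45, 75)
    sex <- rbinom(n, 1L, 0.5)
    data <- matrix(rnorm(n * n_vox), nrow = n, ncol = n_vox)
  })
  if (length(eff_idx))
    data[group == 1L, eff_idx] <- data[group == 1L, eff_idx] + effect_size
  slope_age <- if ("age" %in% names(covariate_slopes))
    covariate_slopes[["age"]] else 0
  slope_sex <- if ("sex" %in% names(covariate_slopes))
    covariate_slopes[["sex"]] else 0
  data <- data + (age - mean(age)) * slope_age + sex * slope_sex
  cohort <- structure(list(data = data, group = group,
                           covariates = data.frame(age = age, sex = sex),
                           mask = mask, shape = shape),
                      class = "voxel_cohort")
  truth <- structure(list(effect_mask = eff_idx, effect_size = effect_size,
                          coupled_gene_ids = NULL, specific_gene_ids = NULL,
                          seed = seed),
                     class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' Simulate a regions-by-genes expression matrix coupled to a phenotype
#'
#' Each coupled gene g with coupling coefficient rho is built as
#' `rho * z(phenotype) + sqrt(1 - rho^2) * eta`, where `eta` is
#' spatially autocorrelated Gaussian noise with exponential covariance
#' `exp(-d / spatial_range)` over region centroid distances; uncoupled
#' genes are pure spatially autocorrelated noise. Expected sample
#' correlation of a coupled gene with the phenotype is rho.
#'
#' @param atlas a `parcellation_atlas` supplying centroids.
#' @param phenotype a `regional_phenotype` on the atlas regions.
#' @param n_genes total number of genes (>= number of coupled genes).
#' @param coupling named numeric vector, gene symbol -> rho in [-1, 1].
#' @param spatial_range exponential correlation range of the noise, in
#'   centroid grid units.
#' @param seed integer RNG seed.
#' @return list with `expression` (R x G numeric matrix, rownames = region
#'   ids, colnames = gene symbols) and `truth` (a `synthetic_truth` with
#'   `coupled_gene_ids` and the full `gene_symbols` universe).
#' @export
gen_expression <- function(atlas, phenotype, n_genes,
                           coupling = numeric(0), spatial_range = 5,
                           seed = 1L) {
  stopifnot(inherits(atlas, "parcellation_atlas"),
            inherits(phenotype, "regional_phenotype"))
  if (!identical(as.integer(phenotype$region_ids),
                 as.integer(atlas$region_ids)))
    stop("phenotype must be defined on the atlas regions")
  if (length(coupling) && any(abs(coupling) > 1))
    stop("invalid argument: |rho| must be <= 1")
  if (n_genes < length(coupling))
    stop("invalid argument: n_genes smaller than the coupled set")
  R <- length(phenotype$values)
  zphen <- zscore_vector(phenotype$values)
  D <- as.matrix(stats::dist(atlas$centroids))
  Sigma <- exp(-D / spatial_range)
  L <- t(chol(Sigma + diag(1e-10, R)))
  coupled <- names(coupling)
  if (length(coupling) && is.null(coupled))
    stop("coupling must be a named vector (gene symbol -> rho)")
  n_fill <- n_genes - length(coupling)
  fill <- setdiff(sprintf("G%05d", seq_len(n_genes + length(coupling))),
                  coupled)[seq_len(n_fill)]
  genes <- c(coupled, fill)
  expr <- with_seed(seed, {
    noise <- L %*% matrix(rnorm(R * n_genes), R, n_genes)
    m <- noise
    if (length(coupling))
      m[, seq_along(coupling)] <-
        zphen %o% coupling + sweep(noise[, seq_along(coupling), drop = FALSE],
                                   2, sqrt(1 - coupling^2), `*`)
    m
  })
  dimnames(expr) <- list(as.character(phenotype$region_ids), genes)
  truth <- structure(list(effect_mask = NULL, effect_size = NULL,
                          coupled_gene_ids = coupling,
                          specific_gene_ids = NULL,
                          gene_symbols = genes, seed = seed),
                     class = "synthetic_truth")
  list(expression = expr, truth = truth)
}

#' The six brain cell types used throughout the package
#' @export
CELL_TYPES <- c("endothelial", "neuron", "oligodendrocyte", "astrocyte",
                "microglia", "OPC")

#' Simulate cell-type FPKM tables with planted specific genes
#'
#' Produces three independently seeded RNA-seq-like series (emulating
#' independent published datasets), each a genes x samples FPKM table over
#' the six brain cell types (endothelial cells, neurons, oligodendrocytes,
#' astrocytes, microglia, OPCs). FPKM values are log-normal; a planted gene
#' is multiplied by `fold` in the samples of its target type.
#'
#' @param n_genes gene universe size.
#' @param specific named list, cell type -> character vector of planted
#'   gene symbols; sets must be disjoint across types.
#' @param fold expression multiplier in the target type (> 1).
#' @param n_samples_per_type samples per cell type per series.
#' @param seed integer RNG seed (split across the three series).
#' @param gene_symbols optional gene universe (default `G00001`...).
#' @return list with `tables` (list of three `celltype_table`s: `fpkm`
#'   G x S matrix, `sample_type`, `series`) and `truth` (a
#'   `synthetic_truth` with `specific_gene_ids`).
#' @export
gen_celltype_fpkm <- function(n_genes, specific = list(), fold = 10,
                              n_samples_per_type = 5L, seed = 1L,
                              gene_symbols = NULL) {
  if (fold <= 1) stop("invalid argument: fold must be > 1")
  if (length(specific)) {
    if (!all(names(specific) %in% CELL_TYPES))
      stop("invalid argument: unknown cell type in `specific`")
    all_planted <- unlist(specific, use.names = FALSE)
    if (anyDuplicated(all_planted))
      stop("invalid argument: planted gene sets overlap across cell types")
  }
  if (is.null(gene_symbols)) gene_symbols <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(gene_symbols) == n_genes)
  if (length(specific) && !all(unlist(specific) %in% gene_symbols))
    stop("invalid argument: planted gene not in the gene universe")
  series_seeds <- split_seed(seed, 3L)
  n_types <- length(CELL_TYPES)
  tables <- lapply(seq_len(3L), function(s) {
    sample_type <- rep(CELL_TYPES, each = n_samples_per_type)
    fpkm <- with_seed(series_seeds[s], {
      mu <- rnorm(n_genes, mean = 2, sd = 1)  # per-gene baseline (log scale)
      matrix(rlnorm(n_genes * n_types * n_samples_per_type,
                    meanlog = mu, sdlog = 0.5),
             nrow = n_genes)
    })
    dimnames(fpkm) <- list(gene_symbols,
                           paste0(sample_type, "_", seq_along(sample_type)))
    for (ct in names(specific)) {
      gi <- match(specific[[ct]], gene_symbols)
      fpkm[gi, sample_type == ct] <- fpkm[gi, sample_type == ct] * fold
    }
    structure(list(fpkm = fpkm, sample_type = sample_type,
                   series = paste0("synthetic_series_", s)),
              class = "celltype_table")
  })
  truth <- structure(list(effect_mask = NULL, effect_size = NULL,
                          coupled_gene_ids = NULL,
                          specific_gene_ids = specific,
                          gene_symbols = gene_symbols, seed = seed),
                     class = "synthetic_truth")
  list(tables = tables, truth = truth)
}

#' Build a gene-set collection containing the planted sets plus decoys
#'
#' Returns one set of the positively coupled genes ("planted_positive"),
#' one of the negatively coupled genes ("planted_negative"), and
#' `n_decoys` sets drawn uniformly without replacement from the gene
#' universe with sizes uniform in `size_range`.
#'
#' @param truth a `synthetic_truth` with `coupled_gene_ids` and
#'   `gene_symbols` (as returned by [gen_expression()]).
#' @param n_decoys number of random decoy sets.
#' @param size_range integer pair, inclusive decoy size range.
#' @param seed integer RNG seed.
#' @return a `gene_set_collection` (named list of gene symbol vectors with
#'   a `namespace` attribute of "synthetic").
#' @export
gen_genesets <- function(truth, n_decoys = 100L, size_range = c(10L, 50L),
                         seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            !is.null(truth$coupled_gene_ids), !is.null(truth$gene_symbols))
  universe <- truth$gene_symbols
  if (size_range[1] < 1L || size_range[2] > length(universe))
    stop("invalid argument: size_range outside the gene universe")
  rho <- truth$coupled_gene_ids
  sets <- list(planted_positive = names(rho)[rho > 0],
               planted_negative = names(rho)[rho < 0])
  decoys <- with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_decoys,
                    replace = TRUE)
    lapply(sizes, function(m) sample(universe, m))
  })
  names(decoys) <- sprintf("DECOY%03d", seq_len(n_decoys))
  collection <- c(sets, decoys)
  collection <- collection[lengths(collection) > 0]
  structure(collection, namespace = "synthetic",
            class = "gene_set_collection")
}
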