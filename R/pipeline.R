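#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with one top-level seed
#' that is deterministically split into per-stage seeds (see
#' [split_seed()]). Stage defaults follow the conventions documented on
#' each stage function (TFCE E = 0.5 / H = 2 / 26-connectivity, spatial
#' nulls n = 1000, PLS component 1 of K, GSEA n_perm = 1000 with sizes
#' 10-500, pSI threshold 0.001). The default problem size here is the
#' synthetic quick-start scale (16^3 grid, 20 subjects per group, 2000
#' genes, 200 nulls) so that a full run completes on a laptop; every value
#' can be raised.
#'
#' @param seed top-level integer seed.
#' @param shape voxel grid size.
#' @param n_regions atlas regions.
#' @param n_per_group subjects per group.
#' @param effect_size planted group effect (Cohen's d).
#' @param n_effect_regions number of atlas regions carrying the effect.
#' @param covariate_slopes named slopes for age / sex.
#' @param fwhm_mm smoothing kernel FWHM, mm.
#' @param voxel_size_mm voxel edge, mm.
#' @param n_perm_fwe TFCE FWE permutations.
#' @param n_genes expression genes.
#' @param n_coupled_pos,n_coupled_neg planted coupled genes per sign.
#' @param rho coupling magnitude of planted genes.
#' @param spatial_range expression noise correlation range (grid units).
#' @param n_null surrogate maps.
#' @param pls_component PLS component used for ranking.
#' @param n_perm_gsea,gsea_min_size,gsea_max_size GSEA settings.
#' @param n_decoys decoy gene sets.
#' @param n_specific planted specific genes per cell type.
#' @param fold planted cell-type fold change.
#' @param n_samples_per_type FPKM samples per type.
#' @param n_perm_psi pSI permutations.
#' @param psi_threshold pSI cutoff.
#' @param contrast `"gt"` (patient > control phenotype) or `"lt"`
#'   (negated map).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            shape = c(16L, 16L, 16L),
                            n_regions = 83L,
                            n_per_group = 20L,
                            effect_size = 1.5,
                            n_effect_regions = 2L,
                            covariate_slopes = c(age = 0.02, sex = 0.2),
                            fwhm_mm = 3, voxel_size_mm = 1,
                            n_perm_fwe = 100L,
                            n_genes = 2000L,
                            n_coupled_pos = 50L, n_coupled_neg = 50L,
                            rho = 0.8,
                            spatial_range = 5,
                            n_null = 200L,
                            pls_component = 1L,
                            n_perm_gsea = 500L,
                            gsea_min_size = 10L, gsea_max_size = 500L,
                            n_decoys = 100L,
                            n_specific = 10L, fold = 10,
                            n_samples_per_type = 5L,
                            n_perm_psi = 100L, psi_threshold = 0.001,
                            contrast = c("gt", "lt")) {
  contrast <- match.arg(contrast)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic imaging-transcriptomics pipeline
#'
#' Executes, with a single top-level seed: atlas and cohort simulation,
#' smoothing, voxel-wise GLM, TFCE with permutation FWE, parcellation,
#' spatially autocorrelated expression simulation coupled to the regional
#' phenotype, surrogate-map generation, null-calibrated PLS gene ranking,
#' preranked GSEA over planted + decoy gene sets, and cell-type SI/pSI
#' gene sets (three synthetic FPKM series) with their own GSEA. If
#' `out_dir` is given, all tables (TSV/GMT), volumes (NIfTI) and a
#' provenance record (JSON) are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return invisibly, a result bundle: `phenotype`, `ranking`,
#'   `enrichment`, `enrichment_celltype`, `celltype_sets`, `pfwe`,
#'   `truth`, `validation`, `provenance`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 9L)
  names(seeds) <- c("atlas", "cohort", "fwe", "expression", "nulls",
                    "genesets", "gsea", "celltype", "psi")

  atlas <- stage("atlas", gen_atlas(config$shape, config$n_regions,
                                    seed = seeds["atlas"]))
  effect_regions <- atlas$region_ids[seq_len(config$n_effect_regions)]
  sim <- stage("cohort",
    gen_cohort(atlas, config$n_per_group, config$effect_size,
               effect_regions, config$covariate_slopes,
               seed = seeds["cohort"]))
  cohort <- sim$cohort
  cohort$data <- stage("smooth", {
    t(apply(cohort$data, 1, function(v)
      as.vector(smooth_gaussian(array(v, cohort$shape), cohort$mask,
                                config$fwhm_mm, config$voxel_size_mm))))
  })
  params <- tfce_params(n_perm = config$n_perm_fwe, seed = seeds["fwe"])
  pfwe <- stage("vba", permutation_fwe(cohort, params))
  tfce_map <- attr(pfwe, "tfce")
  if (config$contrast == "lt")
    tfce_map$values <- -tfce_map$values
  phenotype <- stage("parcellate", parcellate(tfce_map, atlas))

  coupling <- c(stats::setNames(rep(config$rho, config$n_coupled_pos),
                                sprintf("POS%03d",
                                        seq_len(config$n_coupled_pos))),
                stats::setNames(rep(-config$rho, config$n_coupled_neg),
                                sprintf("NEG%03d",
                                        seq_len(config$n_coupled_neg))))
  expr_sim <- stage("expression",
    gen_expression(atlas, phenotype, config$n_genes, coupling,
                   config$spatial_range, seed = seeds["expression"]))
  surrogates <- stage("nulls",
    generate_surrogates(phenotype, atlas$centroids, config$n_null,
                        seed = seeds["nulls"]))
  ranking <- stage("rank",
    gene_z_scores(expr_sim$expression, phenotype$values, surrogates,
                  k = config$pls_component))
  validation <- stage("validate",
    validate_ranking(expr_sim$expression, phenotype$values, ranking))

  genesets <- stage("genesets",
    gen_genesets(expr_sim$truth, config$n_decoys,
                 seed = seeds["genesets"]))
  enrichment <- stage("gsea",
    gsea_preranked(ranking, genesets, config$n_perm_gsea,
                   seed = seeds["gsea"], min_size = config$gsea_min_size,
                   max_size = config$gsea_max_size))
  enrichment <- prune_redundant(enrichment, genesets)

  specific <- lapply(stats::setNames(seq_along(CELL_TYPES), CELL_TYPES),
    function(i) {
      pool <- setdiff(expr_sim$truth$gene_symbols, names(coupling))
      pool[seq((i - 1) * config$n_specific + 1, i * config$n_specific)]
    })
  ct_sim <- stage("celltype",
    gen_celltype_fpkm(config$n_genes, specific, config$fold,
                      config$n_samples_per_type, seed = seeds["celltype"],
                      gene_symbols = expr_sim$truth$gene_symbols))
  psi_seeds <- split_seed(seeds["psi"], 3L)
  celltype_sets <- lapply(seq_along(ct_sim$tables), function(s) {
    spec <- psi_permutation(ct_sim$tables[[s]], config$n_perm_psi,
                            seed = psi_seeds[s])
    celltype_gene_sets(spec, config$psi_threshold,
                       series = ct_sim$tables[[s]]$series)
  })
  enrichment_ct <- lapply(celltype_sets, function(sets)
    gsea_preranked(ranking, sets, config$n_perm_gsea,
                   seed = seeds["gsea"], min_size = 2L,
                   max_size = config$gsea_max_size))

  truth <- list(cohort = sim$truth, expression = expr_sim$truth,
                celltype = ct_sim$truth)
  provenance <- list(package = "regiontx",
                     version = as.character(utils::packageVersion("regiontx")),
                     seed = config$seed,
                     stage_seeds = as.list(seeds),
                     config = unclass(config)[setdiff(names(config),
                                                      "contrast")],
                     contrast = config$contrast)

  result <- list(phenotype = phenotype, ranking = ranking,
                 enrichment = enrichment,
                 enrichment_celltype = enrichment_ct,
                 celltype_sets = celltype_sets,
                 pfwe = pfwe, atlas = atlas, truth = truth,
                 validation = validation, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(out_dir, ...)
    write_nifti_volume(atlas$label_volume * 1, fp("atlas.nii.gz"),
                       config$voxel_size_mm)
    write_nifti_volume(attr(pfwe, "tmap")$values, fp("tmap.nii.gz"),
                       config$voxel_size_mm)
    write_nifti_volume(tfce_map$values, fp("tfce.nii.gz"),
                       config$voxel_size_mm)
    write_nifti_volume(pfwe$values, fp("p_fwe.nii.gz"),
                       config$voxel_size_mm)
    write_phenotype_tsv(phenotype, fp("regional_phenotype.tsv"))
    write_matrix_tsv(expr_sim$expression, fp("expression.tsv"), "region_id")
    write_ranking_tsv(ranking, fp("gene_ranking.tsv"))
    write_enrichment_tsv(enrichment, fp("enrichment.tsv"))
    write_gmt(genesets, fp("genesets.gmt"))
    for (s in seq_along(celltype_sets)) {
      write_gmt(celltype_sets[[s]],
                fp(sprintf("celltype_sets_series%d.gmt", s)))
      write_enrichment_tsv(enrichment_ct[[s]],
                           fp(sprintf("enrichment_celltype_series%d.tsv", s)))
    }
    jsonlite::write_json(provenance, fp("provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
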