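Package: regiontx
Title: Imaging Transcriptomics of Regional Brain Phenotype Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for imaging-transcriptomics analysis of
    volumetric brain phenotype maps. Implements voxel-wise group inference
    with threshold-free cluster enhancement (TFCE) and permutation
    family-wise error control, atlas parcellation, partial least squares
    (PLS) regression of regional phenotypes on gene expression with gene
    ranking calibrated against spatial-autocorrelation-preserving surrogate
    maps, preranked gene set enrichment analysis (GSEA), and cell-type
    specificity index (SI/pSI) gene sets derived from FPKM tables. A
    synthetic-data module generates every pipeline input with known ground
    truth so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
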