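#' Write / read a 3D volume as NIfTI
#'
#' Thin wrappers over RNifti keeping a fixed isotropic voxel size.
#'
#' @param volume 3D numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @return `write_nifti_volume` returns the path invisibly;
#'   `read_nifti_volume` returns a plain 3D array.
#' @export
write_nifti_volume <- function(volume, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(volume, pixdim = rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("validation error: expected a 3D volume in ", path)
  arr
}

#' Write / read a numeric matrix as TSV
#'
#' Rows and columns carry their identifiers (region ids, gene symbols,
#' sample names) so joins are always by key. Round-trips preserve
#' dimnames and values to full double precision.
#'
#' @param m matrix with dimnames.
#' @param path TSV path.
#' @param id_col name of the first (row-identifier) column.
#' @return the path (write) / the matrix (read).
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write / read a regional phenotype as TSV
#' @param phenotype a `regional_phenotype`.
#' @param path TSV path.
#' @return the path (write) / a `regional_phenotype` (read).
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  df <- data.frame(region_id = phenotype$region_ids,
                   value = format(phenotype$values, digits = 17,
                                  trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "value") %in% colnames(df)))
    stop("validation error: expected columns region_id, value in ", path)
  regional_phenotype(df$region_id, as.numeric(df$value))
}

#' Write an enrichment result as TSV
#'
#' The leading-edge list column is collapsed to a comma-separated string.
#'
#' @param results an `enrichment_result`.
#' @param path TSV path.
#' @export
write_enrichment_tsv <- function(results, path) {
  df <- as.data.frame(results[, setdiff(colnames(results), "leading_edge")])
  df$leading_edge <- vapply(results$leading_edge, paste,
                            character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene ranking as TSV
#' @param ranking a `gene_ranking`.
#' @param path TSV path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
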