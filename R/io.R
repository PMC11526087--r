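# Plain-text readers/writers for the pipeline's inputs. TSV dialect:
# tab-separated with a header row; the quant matrix carries the gene
# symbol in a `protein` first column. Single-cell data travel as an MTX
# triplet (matrix.mtx, genes.tsv, barcodes.tsv, celltypes.tsv).

#' Write a synthetic cohort bundle to disk
#'
#' Emits `quant.tsv`, `design.tsv`, `samples.tsv` and `matrisome.tsv`
#' into `dir`.
#'
#' @param cohort An `ecm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$quant, file.path(dir, "quant.tsv"))
  readr::write_tsv(cohort$design, file.path(dir, "design.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$annotation, file.path(dir, "matrisome.tsv"))
  invisible(dir)
}

#' Read a protein quantification matrix and its design
#'
#' @param quant_path TSV with a `protein` column plus channel columns.
#' @param design_path TSV with columns channel, plex, role, sample_id.
#' @return List with `quant` and `design` tibbles.
#' @export
read_quant <- function(quant_path, design_path) {
  quant <- readr::read_tsv(quant_path, show_col_types = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE)
  need <- c("channel", "plex", "role")
  if (!all(need %in% names(design))) {
    abort("design table needs channel, plex and role columns")
  }
  list(quant = quant, design = design)
}

#' Write single-cell data as an MTX triplet
#'
#' @param cells A `cell_data` object.
#' @param dir Output directory; receives `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and `celltypes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_sc_data <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(
    Matrix::Matrix(cells$counts, sparse = TRUE),
    file.path(dir, "matrix.mtx")
  )
  readr::write_tsv(
    tibble(gene = rownames(cells$counts)),
    file.path(dir, "genes.tsv"), col_names = FALSE
  )
  readr::write_tsv(
    tibble(barcode = colnames(cells$counts)),
    file.path(dir, "barcodes.tsv"), col_names = FALSE
  )
  readr::write_tsv(cells$cells, file.path(dir, "celltypes.tsv"))
  invisible(dir)
}

#' Read single-cell data from an MTX triplet
#'
#' @param dir Directory written by [write_sc_data()].
#' @return A `cell_data` object.
#' @export
read_sc_data <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(
    file.path(dir, "genes.tsv"), col_names = "gene", show_col_types = FALSE
  )
  barcodes <- readr::read_tsv(
    file.path(dir, "barcodes.tsv"), col_names = "barcode", show_col_types = FALSE
  )
  cells <- readr::read_tsv(file.path(dir, "celltypes.tsv"), show_col_types = FALSE)
  dimnames(m) <- list(genes$gene, barcodes$barcode)
  structure(list(counts = m, cells = cells), class = "cell_data")
}
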