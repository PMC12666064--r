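# Readers/writers for the 10x-style MTX triplet and annotation tables.
# All writers round-trip with the package's readers.

#' Write annotated counts as an MTX triplet plus annotations
#'
#' Writes `matrix.mtx` (MatrixMarket, via [Matrix::writeMM()]),
#' `features.tsv` (gene ids), `barcodes.tsv` (cell ids) and
#' `annotations.tsv` (cell metadata) into `dir`. With `gzip = TRUE` the
#' four files are gzip-compressed (`.gz` suffixes).
#'
#' @param data An `annotated_counts` object.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the outputs.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(data, dir, gzip = FALSE) {
  stopifnot(inherits(data, "annotated_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(data$counts, mtx_plain)
  if (gzip) {
    con_in <- readLines(mtx_plain)
    gz <- gzfile(paste0(mtx_plain, ".gz"), "w")
    writeLines(con_in, gz); close(gz)
    unlink(mtx_plain)
  }
  write_maybe_gz <- function(lines, path) {
    con <- if (gzip) gzfile(paste0(path, ext), "w") else file(path, "w")
    writeLines(lines, con); close(con)
  }
  write_maybe_gz(data$gene_ids, file.path(dir, "features.tsv"))
  write_maybe_gz(data$cell_ids, file.path(dir, "barcodes.tsv"))
  ann_path <- file.path(dir, paste0("annotations.tsv", ext))
  con <- if (gzip) gzfile(ann_path, "w") else file(ann_path, "w")
  utils::write.table(data$cell_meta, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(dir)
}

#' Read annotated counts written by [write_counts_mtx()]
#'
#' @param dir Directory holding the MTX triplet and `annotations.tsv`
#'   (plain or gzipped).
#' @return An `annotated_counts` object.
#' @export
read_counts_mtx <- function(dir) {
  pick <- function(base) {
    for (p in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(p)) return(p)
    }
    stop("missing file: ", file.path(dir, base))
  }
  counts <- methods::as(Matrix::readMM(pick("matrix.mtx")), "CsparseMatrix")
  gene_ids <- readLines(pick("features.tsv"))
  cell_ids <- readLines(pick("barcodes.tsv"))
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  meta <- utils::read.delim(pick("annotations.tsv"), sep = "\t",
                            stringsAsFactors = FALSE)
  annotated_counts(counts, meta)
}

#' Write a cell-type test table as TSV
#'
#' Columns mirror the standard report layout: t-statistic, log fold
#' change, fold change, CI bounds, raw and corrected p.
#'
#' @param x A `celltype_test` table.
#' @param path Output path.
#' @export
write_celltype_test <- function(x, path) {
  stopifnot(inherits(x, "celltype_test"))
  write_tsv_file(as.data.frame(x), path)
}
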