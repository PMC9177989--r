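#' Read a count matrix from MatrixMarket or CSV files
#'
#' For `format = "mtx"` the MatrixMarket coordinate file is read together
#' with companion feature and barcode TSVs (first column of each holds the
#' identifier, as in 10x `features.tsv`/`barcodes.tsv`). `path` may be a
#' directory containing `matrix.mtx`, `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`, or the `.mtx` file itself with `features`/`barcodes`
#' given explicitly. The on-disk orientation is declared by `orientation`;
#' the default follows the 10x convention (rows of the matrix are the rows
#' of the features file, i.e. genes x samples). The returned matrix is
#' always genes x samples.
#'
#' For `format = "csv"` the file holds genes as rows and samples as
#' columns, with a header row of sample ids and gene ids in the first
#' column.
#'
#' @param path directory or main matrix file.
#' @param format `"mtx"` or `"csv"`.
#' @param features,barcodes optional explicit paths to the id TSVs (mtx
#'   only).
#' @param orientation `"genes_by_samples"` (default, 10x convention) or
#'   `"samples_by_genes"` if the coordinate file is transposed on disk.
#' @return A [count_matrix()] with `layer = "raw"`.
#' @export
read_count_matrix <- function(path, format = c("mtx", "csv"),
                              features = NULL, barcodes = NULL,
                              orientation = c("genes_by_samples",
                                              "samples_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    if (length(vals) && anyNA(vals)) {
      stop("CSV count matrix contains non-numeric or missing entries",
           call. = FALSE)
    }
    if (length(vals) && min(vals) < 0) {
      stop("count matrix contains negative entries", call. = FALSE)
    }
    return(count_matrix(vals, gene_ids, colnames(df)[-1]))
  }

  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feats <- file.path(path, "features.tsv")
    if (!file.exists(feats)) feats <- file.path(path, "genes.tsv")
    bcs <- file.path(path, "barcodes.tsv")
  } else {
    mtx <- path
    feats <- features
    bcs <- barcodes
  }
  for (f in c(mtx, feats, bcs)) {
    if (is.null(f) || !file.exists(f)) {
      stop("missing input file: ", f %||% "features/barcodes not given",
           call. = FALSE)
    }
  }
  m <- Matrix::readMM(mtx)
  gene_ids <- utils::read.table(feats, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  sample_ids <- utils::read.table(bcs, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
  if (orientation == "samples_by_genes") m <- Matrix::t(m)
  if (nrow(m) != length(gene_ids)) {
    stop(sprintf(paste0("format error: matrix declares %d genes but the ",
                        "features file lists %d"), nrow(m), length(gene_ids)),
         call. = FALSE)
  }
  if (ncol(m) != length(sample_ids)) {
    stop(sprintf(paste0("format error: matrix declares %d samples but the ",
                        "barcodes file lists %d"), ncol(m), length(sample_ids)),
         call. = FALSE)
  }
  if (length(m@x) && min(m@x) < 0) {
    stop("count matrix contains negative entries", call. = FALSE)
  }
  count_matrix(as.matrix(m), gene_ids, sample_ids)
}

#' Write a count matrix as MatrixMarket + TSV files
#'
#' Inverse of [read_count_matrix()] for the mtx dialect: writes
#' `matrix.mtx`, `features.tsv` and `barcodes.tsv` (genes x samples
#' orientation) into `dir`.
#'
#' @param m a [count_matrix()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(m$gene_ids), file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(m$sample_ids), file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' Read a two-column annotation TSV
#'
#' @param path TSV with columns `sample_id` and `label` (header optional;
#'   headerless files are taken in that column order).
#' @return A tibble, see [as_annotation()].
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("sample_id", "label")
  as_annotation(df[, c("sample_id", "label")])
}

#' Write predicted cell fractions to CSV
#'
#' The first column holds the spot id, followed by one column per cell
#' type, at full double precision so that a read-back reproduces the values
#' to within 1e-12.
#'
#' @param fractions a [fraction_map()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fraction_map <- function(fractions, path) {
  stopifnot(inherits(fractions, "fraction_map"))
  vals <- fractions$fractions
  df <- data.frame(spot_id = fractions$spot_ids, stringsAsFactors = FALSE)
  for (j in seq_along(fractions$cell_types)) {
    df[[fractions$cell_types[j]]] <-
      sprintf("%.17g", vals[, j, drop = TRUE])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fraction CSV written by [write_fraction_map()]
#'
#' @param path CSV path.
#' @return A [fraction_map()].
#' @export
read_fraction_map <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  fraction_map(vals, spot_ids = as.character(df[[1]]),
               cell_types = colnames(df)[-1], validate_rows = FALSE)
}
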