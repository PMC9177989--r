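#' Construct a count matrix container
#'
#' `count_matrix` is the package's basic expression container: a dense
#' genes-by-samples matrix of non-negative values together with gene and
#' sample identifiers, optional per-sample metadata, and a `layer` tag that
#' records which preprocessing stage the values are in. The tag enforces the
#' fixed pipeline order raw -> normalized -> lognorm -> scaled01: each
#' preprocessing function checks the tag of its input and refuses
#' out-of-order calls.
#'
#' @param values numeric matrix, genes in rows and samples (cells or spots)
#'   in columns. Sparse `Matrix` input is densified.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param sample_meta optional data frame keyed by a `sample_id` column
#'   (cell-type label, coordinates, region label, ...).
#' @param layer one of `"raw"`, `"normalized"`, `"lognorm"`, `"scaled01"`.
#' @return An object of class `count_matrix`.
#' @examples
#' m <- count_matrix(matrix(rpois(6, 4), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("c1", "c2"))))
#' dim(m)
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values),
                         sample_meta = NULL, layer = "raw") {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(nrow(values)))
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample_%d", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  dimnames(values) <- list(gene_ids, sample_ids)
  out <- structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         sample_meta = sample_meta, layer = layer),
    class = "count_matrix"
  )
  validate_count_matrix(out)
}

validate_count_matrix <- function(x) {
  layers <- c("raw", "normalized", "lognorm", "scaled01")
  if (!x$layer %in% layers) {
    stop("unknown layer tag: ", x$layer, call. = FALSE)
  }
  if (length(x$gene_ids) != nrow(x$values)) {
    stop("length of gene_ids (", length(x$gene_ids),
         ") does not match number of matrix rows (", nrow(x$values), ")",
         call. = FALSE)
  }
  if (length(x$sample_ids) != ncol(x$values)) {
    stop("length of sample_ids (", length(x$sample_ids),
         ") does not match number of matrix columns (", ncol(x$values), ")",
         call. = FALSE)
  }
  dup <- unique(x$gene_ids[duplicated(x$gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(utils::head(dup, 10), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(x$sample_ids[duplicated(x$sample_ids)])
  if (length(dup)) {
    stop("duplicate sample ids: ", paste(utils::head(dup, 10), collapse = ", "),
         call. = FALSE)
  }
  if (x$layer == "raw" && length(x$values) && min(x$values) < 0) {
    stop("raw count matrix contains negative entries", call. = FALSE)
  }
  if (x$layer == "scaled01" && length(x$values) &&
      (min(x$values) < -1e-12 || max(x$values) > 1 + 1e-12)) {
    stop("scaled01 matrix has values outside [0, 1]", call. = FALSE)
  }
  x
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Subset and reorder a count matrix to a gene panel
#'
#' @param m a [count_matrix()].
#' @param genes character vector of gene ids; all must be present in `m`.
#' @return A `count_matrix` restricted to `genes`, in that order.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "count_matrix"))
  missing <- setdiff(genes, m$gene_ids)
  if (length(missing)) {
    stop("genes not present in matrix: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  count_matrix(m$values[genes, , drop = FALSE], genes, m$sample_ids,
               m$sample_meta, m$layer)
}

#' Normalise a cell/spot annotation to a two-column tibble
#'
#' Accepts a data frame with `sample_id` and `label` columns or a named
#' character vector (names are sample ids). Labels form a finite set; an
#' explicit `"unknown"` label is permitted and treated specially by the
#' evaluation functions.
#'
#' @param x annotation input.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
as_annotation <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "label") %in% names(x))) {
      stop("annotation data frame needs `sample_id` and `label` columns",
           call. = FALSE)
    }
    out <- tibble::tibble(sample_id = as.character(x$sample_id),
                          label = as.character(x$label))
  } else if (!is.null(names(x))) {
    out <- tibble::tibble(sample_id = names(x), label = as.character(x))
  } else {
    stop("annotation must be a data frame or a named character vector",
         call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("annotation has duplicated sample ids", call. = FALSE)
  }
  out
}

# Labels aligned to `sample_ids`; errors if any sample is unannotated.
annotation_labels <- function(annot, sample_ids) {
  annot <- as_annotation(annot)
  idx <- match(sample_ids, annot$sample_id)
  if (anyNA(idx)) {
    stop("samples without annotation: ",
         paste(utils::head(sample_ids[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  }
  annot$label[idx]
}
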