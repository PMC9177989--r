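#' Generate pseudospots from a single-cell reference
#'
#' A pseudospot is a virtual spatial spot: `k` cells drawn uniformly
#' without replacement from the reference, combined with random weights
#' into one composite expression profile. The weights are i.i.d.
#' Uniform(0,1) draws normalised to sum to 1 (optionally a Dirichlet law),
#' so the true cell-type composition of every pseudospot is known exactly:
#' the label row is the weight mass summed per cell type. Composites are
#' computed on log-normalised expression; the batch is subsequently passed
#' through [minmax_scale()] together with the real spots.
#'
#' @param sc a [count_matrix()] with `layer = "lognorm"`, already subset to
#'   the shared marker panel.
#' @param annot cell-type annotation, see [as_annotation()].
#' @param k cells per pseudospot.
#' @param n number of pseudospots.
#' @param seed integer seed; the batch is fully reproducible from it.
#' @param weight_law `"uniform"` (normalised i.i.d. Uniform(0,1), default)
#'   or `"dirichlet"` with concentration `alpha0`.
#' @param alpha0 Dirichlet concentration when `weight_law = "dirichlet"`.
#' @return An object of class `pseudospot_batch`: `X` (n x genes composite
#'   expression), `Y` (n x K true fractions, rows sum to 1), `k_cells`,
#'   `cell_type_order`, `gene_ids`, `layer`, and a `provenance` list with
#'   the sampled cell indices and weights of every pseudospot.
#' @export
generate_pseudospots <- function(sc, annot, k, n, seed = 0L,
                                 weight_law = c("uniform", "dirichlet"),
                                 alpha0 = 1) {
  stopifnot(inherits(sc, "count_matrix"))
  weight_law <- match.arg(weight_law)
  if (sc$layer != "lognorm") {
    stop("generate_pseudospots expects log-normalised input", call. = FALSE)
  }
  assert_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
  assert_scalar_number(n, "n", positive = TRUE, integerish = TRUE)
  n_cells <- ncol(sc$values)
  if (k > n_cells) {
    stop("k (", k, ") exceeds the number of reference cells (", n_cells, ")",
         call. = FALSE)
  }
  labels <- annotation_labels(annot, sc$sample_ids)
  types <- sort(unique(labels))

  out <- with_seed(seed, {
    cells <- matrix(0L, n, k)
    for (s in seq_len(n)) cells[s, ] <- sample.int(n_cells, k)
    u <- matrix(stats::runif(n * k), n, k)
    if (weight_law == "dirichlet") {
      u <- matrix(stats::rgamma(n * k, shape = alpha0, rate = 1), n, k)
    }
    w <- u / rowSums(u)
    list(cells = cells, w = w)
  })
  cells <- out$cells
  w <- out$w

  # sparse n x n_cells weight matrix: composite = W %*% t(expr)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(cells), x = as.vector(w),
    dims = c(n, n_cells)
  )
  X <- as.matrix(W %*% t(sc$values))
  colnames(X) <- sc$gene_ids
  type_ind <- Matrix::sparseMatrix(
    i = seq_len(n_cells), j = match(labels, types), x = 1,
    dims = c(n_cells, length(types))
  )
  Y <- as.matrix(W %*% type_ind)
  colnames(Y) <- types

  structure(
    list(X = X, Y = Y, k_cells = as.integer(k),
         cell_type_order = types, gene_ids = sc$gene_ids,
         layer = "lognorm",
         provenance = list(cells = cells, weights = w, seed = seed,
                           weight_law = weight_law, alpha0 = alpha0)),
    class = "pseudospot_batch"
  )
}

#' @export
print.pseudospot_batch <- function(x, ...) {
  cat(sprintf(
    "<pseudospot_batch> %d pseudospots x %d genes, k = %d, %d cell types (%s)\n",
    nrow(x$X), ncol(x$X), x$k_cells, length(x$cell_type_order), x$layer))
  invisible(x)
}

#' Write a pseudospot batch to CSV files for audit
#'
#' Writes `X.csv` (composite expression), `Y.csv` (true fractions) and
#' `provenance.csv` (pseudospot, slot, cell index, cell id, weight) into
#' `dir`.
#'
#' @param batch a `pseudospot_batch`.
#' @param dir output directory, created if absent.
#' @param cell_ids optional cell identifiers for the provenance table.
#' @return `dir`, invisibly.
#' @export
write_pseudospots <- function(batch, dir, cell_ids = NULL) {
  stopifnot(inherits(batch, "pseudospot_batch"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(batch$X, file.path(dir, "X.csv"), row.names = FALSE)
  utils::write.csv(batch$Y, file.path(dir, "Y.csv"), row.names = FALSE)
  k <- batch$k_cells
  n <- nrow(batch$X)
  prov <- data.frame(
    pseudospot = rep(seq_len(n), each = k),
    slot = rep(seq_len(k), times = n),
    cell = as.vector(t(batch$provenance$cells)),
    weight = as.vector(t(batch$provenance$weights))
  )
  if (!is.null(cell_ids)) prov$cell_id <- cell_ids[prov$cell]
  utils::write.csv(prov, file.path(dir, "provenance.csv"), row.names = FALSE)
  invisible(dir)
}
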