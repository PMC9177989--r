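#' Simulate a clustered single-cell reference
#'
#' Generates a gene x cell count matrix with `n_types` cell clusters, each
#' over-expressing its own disjoint block of `n_markers_per_type` marker
#' genes by a factor `fold_change`. Counts are negative-binomial
#' (dispersion `theta`) around gene base means drawn log-normally, with a
#' per-cell library-size factor that is log-normal with sdlog `lib_sigma` -
#' the classic droplet-data structure of over-dispersed counts and variable
#' depth.
#'
#' @param n_types number of cell clusters.
#' @param n_cells_per_type cells per cluster.
#' @param n_genes total genes; must be at least
#'   `n_types * n_markers_per_type`.
#' @param n_markers_per_type planted marker genes per cluster.
#' @param fold_change mean multiplier of a cluster's markers in that
#'   cluster (> 1).
#' @param theta negative-binomial dispersion (size) parameter.
#' @param lib_sigma sdlog of the per-cell library-size factor.
#' @param base_meanlog,base_sdlog log-normal parameters of the gene base
#'   means.
#' @param seed integer seed; output is reproducible from it.
#' @return A list with `counts` (a raw [count_matrix()]), `annotation`
#'   (tibble, see [as_annotation()]) and `markers` (named list of the
#'   planted marker genes per type).
#' @export
make_reference <- function(n_types = 5L, n_cells_per_type = 250L,
                           n_genes = 200L, n_markers_per_type = 10L,
                           fold_change = 8, theta = 2, lib_sigma = 0.3,
                           base_meanlog = 0.5, base_sdlog = 0.8,
                           seed = 0L) {
  assert_scalar_number(n_types, "n_types", positive = TRUE, integerish = TRUE)
  assert_scalar_number(n_genes, "n_genes", positive = TRUE, integerish = TRUE)
  if (fold_change < 1) stop("fold_change must be >= 1", call. = FALSE)
  if (n_markers_per_type * n_types > n_genes) {
    stop("n_markers_per_type * n_types exceeds n_genes", call. = FALSE)
  }
  n_cells <- n_types * n_cells_per_type
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  cells <- sprintf("cell_%05d", seq_len(n_cells))
  types <- sprintf("type_%d", seq_len(n_types))
  labels <- rep(types, each = n_cells_per_type)

  res <- with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    lib <- stats::rlnorm(n_cells, 0, lib_sigma)
    # genes x types mean multiplier with disjoint marker blocks
    mult <- matrix(1, n_genes, n_types)
    markers <- vector("list", n_types)
    for (t in seq_len(n_types)) {
      block <- (t - 1L) * n_markers_per_type + seq_len(n_markers_per_type)
      mult[block, t] <- fold_change
      markers[[t]] <- genes[block]
    }
    mu <- (base_mu * mult[, match(labels, types)]) *
      rep(lib, each = n_genes)
    counts <- matrix(stats::rnbinom(length(mu), size = theta, mu = mu),
                     n_genes, n_cells)
    list(counts = counts, markers = markers)
  })
  names(res$markers) <- types
  list(
    counts = count_matrix(res$counts, genes, cells),
    annotation = tibble::tibble(sample_id = cells, label = labels),
    markers = res$markers
  )
}

validate_shift <- function(shift) {
  shift <- utils::modifyList(
    list(libsize_factor = 1, noise_sd = 0, dropout_rate = 0), shift
  )
  if (shift$libsize_factor <= 0) {
    stop("libsize_factor must be positive", call. = FALSE)
  }
  if (shift$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (shift$dropout_rate < 0 || shift$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  shift
}

#' Simulate domain-shifted spatial spots with known composition
#'
#' Builds `n_spots` spots the same way pseudospots are built - `k` cells
#' with normalised-uniform random weights - and then applies a domain
#' shift that pseudospots never see: a global library-size factor,
#' entrywise multiplicative log-normal noise, and independent dropout
#' zeroing. When `region_priors` is given, spots are assigned to named
#' regions (equal shares) and the `k` cell types of each spot are drawn
#' from the region's prior over types, so a type with prior 0 outside its
#' region is truly region-restricted.
#'
#' @param reference raw [count_matrix()] from [make_reference()].
#' @param annot cell-type annotation of the reference.
#' @param n_spots number of spots.
#' @param k cells per spot.
#' @param shift list with `libsize_factor` (> 0), `noise_sd` (>= 0) and
#'   `dropout_rate` (in `[0, 1)`).
#' @param region_priors optional named list: region -> prior weight vector
#'   over cell types (named by type, unnamed entries matched by order).
#' @param seed integer seed.
#' @return A list with `spots` (raw `count_matrix`) and `truth` (a
#'   [fraction_map()] with region labels when regions were used).
#' @export
make_spatial <- function(reference, annot, n_spots = 500L, k = 8L,
                         shift = list(libsize_factor = 1, noise_sd = 0,
                                      dropout_rate = 0),
                         region_priors = NULL, seed = 0L) {
  stopifnot(inherits(reference, "count_matrix"))
  if (reference$layer != "raw") {
    stop("make_spatial expects the raw reference counts", call. = FALSE)
  }
  assert_scalar_number(n_spots, "n_spots", positive = TRUE, integerish = TRUE)
  assert_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
  shift <- validate_shift(shift)
  labels <- annotation_labels(annot, reference$sample_ids)
  types <- sort(unique(labels))
  n_cells <- ncol(reference$values)
  if (k > n_cells) stop("k exceeds the number of reference cells",
                        call. = FALSE)
  cells_of_type <- split(seq_len(n_cells), labels)

  res <- with_seed(seed, {
    if (is.null(region_priors)) {
      region <- NULL
      cells <- matrix(0L, n_spots, k)
      for (s in seq_len(n_spots)) cells[s, ] <- sample.int(n_cells, k)
    } else {
      regions <- names(region_priors)
      if (is.null(regions)) stop("region_priors must be named", call. = FALSE)
      region <- rep(regions, length.out = n_spots)
      cells <- matrix(0L, n_spots, k)
      for (s in seq_len(n_spots)) {
        prior <- region_priors[[region[s]]]
        if (is.null(names(prior))) names(prior) <- types
        prior <- prior[types]
        prior[is.na(prior)] <- 0
        slot_types <- sample(types, k, replace = TRUE, prob = prior)
        for (t in unique(slot_types)) {
          pool <- cells_of_type[[t]]
          cnt <- sum(slot_types == t)
          cells[s, slot_types == t] <-
            sample(pool, cnt, replace = cnt > length(pool))
        }
      }
    }
    u <- matrix(stats::runif(n_spots * k), n_spots, k)
    w <- u / rowSums(u)

    W <- Matrix::sparseMatrix(i = rep(seq_len(n_spots), k),
                              j = as.vector(cells), x = as.vector(w),
                              dims = c(n_spots, n_cells))
    mix <- as.matrix(W %*% t(reference$values))  # spots x genes
    type_ind <- Matrix::sparseMatrix(i = seq_len(n_cells),
                                     j = match(labels, types), x = 1,
                                     dims = c(n_cells, length(types)))
    Y <- as.matrix(W %*% type_ind)
    colnames(Y) <- types

    vals <- mix * shift$libsize_factor
    if (shift$noise_sd > 0) {
      vals <- vals * exp(matrix(stats::rnorm(length(vals), 0,
                                             shift$noise_sd),
                                nrow(vals)))
    }
    if (shift$dropout_rate > 0) {
      vals <- vals * (matrix(stats::runif(length(vals)), nrow(vals)) >=
                        shift$dropout_rate)
    }
    list(vals = vals, Y = Y, region = region)
  })

  spot_ids <- sprintf("spot_%05d", seq_len(n_spots))
  spots <- count_matrix(t(res$vals), reference$gene_ids, spot_ids)
  truth <- fraction_map(res$Y, spot_ids = spot_ids, cell_types = types,
                        region_label = res$region)
  list(spots = spots, truth = truth)
}
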