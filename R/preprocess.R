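#' Total-count normalisation per sample
#'
#' Scales every column (cell or spot) so that its total equals
#' `target_sum`, making expression comparable between samples of different
#' sequencing depth. All-zero samples are left untouched with a warning;
#' they carry no information and would otherwise divide by zero.
#'
#' @param m a [count_matrix()] with `layer = "raw"`.
#' @param target_sum desired column total; the counts-per-10k convention
#'   (1e4) is the default.
#' @return A `count_matrix` with `layer = "normalized"`.
#' @export
normalize_total <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  assert_scalar_number(target_sum, "target_sum", positive = TRUE)
  if (m$layer != "raw") {
    stop("normalize_total expects a raw count matrix (layer = 'raw'), got '",
         m$layer, "'", call. = FALSE)
  }
  totals <- colSums(m$values)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left unnormalised: ",
            paste(utils::head(m$sample_ids[zero], 5), collapse = ", "),
            call. = FALSE)
    totals[zero] <- 1
  }
  vals <- m$values * rep(target_sum / totals, each = nrow(m$values))
  count_matrix(vals, m$gene_ids, m$sample_ids, m$sample_meta,
               layer = "normalized")
}

#' Natural-log transform of normalised counts
#'
#' Elementwise `log(1 + x)`.
#'
#' @param m a [count_matrix()] with `layer = "normalized"`.
#' @return A `count_matrix` with `layer = "lognorm"`.
#' @export
log1p_transform <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "normalized") {
    stop("log1p_transform expects a normalized matrix, got '", m$layer, "'",
         call. = FALSE)
  }
  if (length(m$values) && min(m$values) < 0) {
    stop("log1p_transform: negative input values", call. = FALSE)
  }
  count_matrix(log1p(m$values), m$gene_ids, m$sample_ids, m$sample_meta,
               layer = "lognorm")
}

#' Intersect a gene panel with both modalities
#'
#' Restricts the pooled marker panel to genes measured in both the spatial
#' and the single-cell data, preserving the panel's order and dropping
#' duplicates. Downstream, both matrices are subset to exactly this list.
#'
#' @param panel ordered character vector of candidate genes (typically
#'   `marker_set$pooled_panel`).
#' @param spatial,sc [count_matrix()] objects (any layer).
#' @return Character vector of shared genes, in panel order.
#' @export
intersect_genes <- function(panel, spatial, sc) {
  stopifnot(inherits(spatial, "count_matrix"), inherits(sc, "count_matrix"))
  panel <- as.character(panel)
  panel <- panel[!duplicated(panel)]
  shared <- panel[panel %in% spatial$gene_ids & panel %in% sc$gene_ids]
  if (!length(shared)) {
    stop(paste0("no overlap between the marker panel and the measured ",
                "genes; consider increasing the number of markers per ",
                "cluster"), call. = FALSE)
  }
  shared
}

# Row-wise min-max scaling of a plain matrix (samples in rows).
# Constant rows map to all zeros: they carry no signal and this avoids a
# divide-by-zero.
minmax_rows <- function(x) {
  if (!nrow(x)) return(x)
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  out <- (x - lo) / rng
  if (any(const)) out[const, ] <- 0
  out
}

#' Min-max scale each sample to [0, 1]
#'
#' For every cell, spot, or pseudospot independently, maps its expression
#' vector over the (already subset) gene panel to `[0, 1]` by
#' `(x - min) / (max - min)`. This is the final preprocessing stage before
#' the values enter the network; it is applied identically to single-cell,
#' pseudospot and real-spot data. Constant samples are mapped to all zeros.
#'
#' @param m a [count_matrix()] with `layer = "lognorm"`, or a
#'   [generate_pseudospots()] batch on log-normalised values.
#' @return Object of the same class, tagged `scaled01`.
#' @export
minmax_scale <- function(m) UseMethod("minmax_scale")

#' @export
minmax_scale.count_matrix <- function(m) {
  if (!m$layer %in% c("lognorm", "scaled01")) {
    stop("minmax_scale expects a lognorm matrix, got '", m$layer, "'",
         call. = FALSE)
  }
  vals <- t(minmax_rows(t(m$values)))
  count_matrix(vals, m$gene_ids, m$sample_ids, m$sample_meta,
               layer = "scaled01")
}

#' @export
minmax_scale.pseudospot_batch <- function(m) {
  if (!m$layer %in% c("lognorm", "scaled01")) {
    stop("minmax_scale expects a lognorm pseudospot batch, got '", m$layer,
         "'", call. = FALSE)
  }
  m$X <- minmax_rows(m$X)
  m$layer <- "scaled01"
  m
}
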