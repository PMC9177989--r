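#' Benjamini-Hochberg adjustment of p-values
#'
#' Standard step-up false-discovery-rate adjustment, returned in the input
#' order: `adj_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1. Wraps
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorised one-vs-rest Wilcoxon rank-sum across all genes for one group.
# `ranks` is the genes x cells matrix of within-gene ranks (average ranks
# for ties), `tie_term` the per-gene sum of (t^3 - t) over tie groups.
# Returns the rank-sum U statistic and the one-sided (or two-sided) normal
# approximation p-value with tie correction and continuity correction.
rank_sum_group <- function(ranks, tie_term, in_group,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  stopifnot(n1 >= 1, n2 >= 1)
  n <- n1 + n2
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  z <- u - mu
  if (alternative == "greater") {
    # continuity correction as in the standard normal approximation
    p <- ifelse(sigma == 0, 1,
                stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE))
  } else {
    zc <- z - sign(z) * 0.5
    lo <- stats::pnorm(zc / ifelse(sigma == 0, 1, sigma))
    p <- ifelse(sigma == 0, 1, pmin(1, 2 * pmin(lo, 1 - lo)))
  }
  p <- pmin(pmax(p, 0), 1)
  list(statistic = u, p_value = p)
}

#' Select per-cluster marker genes by Wilcoxon rank-sum test
#'
#' For every annotated cell cluster, compares each gene's log-normalised
#' expression in the cluster against all remaining cells with a one-sided
#' (enrichment) Wilcoxon rank-sum test, using the tie-corrected normal
#' approximation with continuity correction. P-values are
#' Benjamini-Hochberg adjusted within each cluster comparison, genes sorted
#' by ascending adjusted p (ties broken by descending rank-sum statistic,
#' then gene id) and the top `l` retained per cluster. The per-cluster
#' lists are pooled, in cluster order, into a deduplicated signature panel.
#'
#' @param sc a [count_matrix()] with `layer = "lognorm"`.
#' @param annot cell-type annotation, see [as_annotation()]; every cell
#'   must be annotated and every cluster needs at least 2 cells.
#' @param l markers to keep per cluster.
#' @param alternative `"greater"` (default; highly expressed markers) or
#'   `"two.sided"`.
#' @return An object of class `marker_set`: a list with `per_cluster`
#'   (tibble: cluster, rank, gene, statistic, p_value, p_adj),
#'   `pooled_panel` (ordered unique gene ids) and `l`.
#' @export
rank_sum_markers <- function(sc, annot, l, alternative = "greater") {
  stopifnot(inherits(sc, "count_matrix"))
  if (sc$layer != "lognorm") {
    stop("rank_sum_markers expects log-normalised input (layer = 'lognorm')",
         call. = FALSE)
  }
  assert_scalar_number(l, "l", positive = TRUE, integerish = TRUE)
  labels <- annotation_labels(annot, sc$sample_ids)
  clusters <- unique(labels)
  if (length(clusters) < 2) {
    stop("need at least 2 cell clusters for marker selection", call. = FALSE)
  }
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop("cluster(s) with fewer than 2 cells: ",
         paste(small, collapse = ", "), call. = FALSE)
  }

  # canonicalise cell order so results are invariant to input permutation
  ord <- order(sc$sample_ids)
  vals <- sc$values[, ord, drop = FALSE]
  labels <- labels[ord]
  clusters <- sort(unique(labels))
  ranks <- t(apply(vals, 1L, rank))  # average ranks for ties
  tie_term <- apply(vals, 1L, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })

  per <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    res <- rank_sum_group(ranks, tie_term, labels == cl,
                          alternative = alternative)
    p_adj <- bh_adjust(res$p_value)
    ord <- order(p_adj, -res$statistic, sc$gene_ids)
    keep <- utils::head(ord, l)
    per[[i]] <- tibble::tibble(
      cluster = cl,
      rank = seq_along(keep),
      gene = sc$gene_ids[keep],
      statistic = unname(res$statistic[keep]),
      p_value = unname(res$p_value[keep]),
      p_adj = p_adj[keep]
    )
  }
  per_cluster <- dplyr::bind_rows(per)
  pooled <- per_cluster$gene[!duplicated(per_cluster$gene)]
  structure(list(per_cluster = per_cluster, pooled_panel = pooled,
                 l = as.integer(l)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d clusters, l = %d, pooled panel of %d genes\n",
              length(unique(x$per_cluster$cluster)), x$l,
              length(x$pooled_panel)))
  invisible(x)
}

#' Tidy a marker set
#'
#' @param x a `marker_set` from [rank_sum_markers()].
#' @param ... unused.
#' @return The per-cluster marker tibble.
#' @method tidy marker_set
#' @export
tidy.marker_set <- function(x, ...) x$per_cluster

#' Export a marker set to TSV
#'
#' @param x a `marker_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(x, path) {
  stopifnot(inherits(x, "marker_set"))
  utils::write.table(x$per_cluster, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
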