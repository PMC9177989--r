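#' ROC area under the curve for a region-restricted cell type
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`,
#' i.e. the Mann-Whitney statistic: the probability that a spot inside the
#' target region scores higher than one outside. Computed from average
#' ranks, which handles ties exactly.
#'
#' @param scores numeric vector, e.g. a cell type's predicted fraction per
#'   spot.
#' @param positives logical vector: spot belongs to the target region.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives) || anyNA(scores) ||
      anyNA(positives)) {
    stop("scores and positives must be complete vectors of equal length",
         call. = FALSE)
  }
  n1 <- sum(positives)
  n2 <- sum(!positives)
  if (n1 == 0 || n2 == 0) {
    stop("need at least one positive and one negative spot", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' One-sided significance of an AUC above 0.5
#'
#' Wilcoxon rank-sum test of the null hypothesis that the AUC is at or
#' below 0.5, i.e. that in-region scores are not stochastically larger than
#' out-of-region scores. Exact enumeration is used for small tie-free
#' groups (both sizes <= 25), the tie-corrected normal approximation with
#' continuity correction otherwise. The caller applies Bonferroni
#' correction across (cell type x slide) comparisons, e.g. with
#' [stats::p.adjust()]; corrected p < 0.05 declares significance.
#'
#' @inheritParams roc_auc
#' @return One-sided p-value.
#' @export
auc_significance <- function(scores, positives) {
  positives <- as.logical(positives)
  n1 <- sum(positives)
  n2 <- sum(!positives)
  if (n1 == 0 || n2 == 0) {
    stop("need at least one positive and one negative spot", call. = FALSE)
  }
  use_exact <- n1 <= 25 && n2 <= 25 && !anyDuplicated(scores)
  suppressWarnings(
    stats::wilcox.test(scores[positives], scores[!positives],
                       alternative = "greater", exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Region-specificity report for all cell types
#'
#' For every (cell type, region) pair, tests whether the predicted fraction
#' localises the region: AUC, one-sided rank-sum p-value and
#' Bonferroni-corrected p across all pairs tested. Spots labelled
#' `"unknown"` (or `NA`) are excluded from both positives and negatives.
#'
#' @param fm a [fraction_map()] with `region_label` (or supply `regions`).
#' @param regions optional per-spot region labels overriding
#'   `fm$region_label`.
#' @param pairs optional two-column data frame (`cell_type`, `region`)
#'   restricting which pairs are tested; defaults to all combinations.
#' @return A tibble: `cell_type`, `region`, `auc`, `p_value`, `p_bonf`,
#'   `significant` (corrected p < 0.05).
#' @export
auc_report <- function(fm, regions = NULL, pairs = NULL) {
  stopifnot(inherits(fm, "fraction_map"))
  regions <- regions %||% fm$region_label
  if (is.null(regions)) stop("no region labels available", call. = FALSE)
  keep <- !is.na(regions) & regions != "unknown"
  fr <- fm$fractions[keep, , drop = FALSE]
  reg <- regions[keep]
  if (length(unique(reg)) < 2) {
    stop("need spots annotated with at least 2 regions (excluding 'unknown')",
         call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(cell_type = fm$cell_types, region = unique(reg),
                         stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- pairs$cell_type[i]
    rg <- pairs$region[i]
    pos <- reg == rg
    sc <- fr[, ct]
    tibble::tibble(cell_type = ct, region = rg,
                   auc = roc_auc(sc, pos),
                   p_value = auc_significance(sc, pos))
  })
  out <- dplyr::bind_rows(res)
  out$p_bonf <- pmin(out$p_value * nrow(out), 1)
  out$significant <- out$p_bonf < 0.05
  out
}

#' Rank cell types by tissue-domain predominance
#'
#' Reproduces the tissue-compartment ranking procedure: each cell type's
#' fraction is min-max scaled to `[0, 1]` across all spots; within every
#' annotated domain the mean scaled fraction is compared to the mean over
#' all other domains, and cell types are ranked by that ratio (an infinite
#' ratio - zero outside the domain - sorts above all finite ones, ties
#' broken by adjusted p). Types with an in-domain mean scaled fraction
#' below `min_scaled_fraction` are excluded. A one-sided Wilcoxon rank-sum
#' test (in-domain vs rest) with Benjamini-Hochberg adjustment across the
#' cell types of each domain flags significant enrichment at adjusted
#' p < 0.05. The top `top_n` types per domain are reported.
#'
#' @param fm a [fraction_map()] with `region_label`.
#' @param top_n cell types reported per domain.
#' @param min_scaled_fraction exclusion threshold on the in-domain mean
#'   scaled fraction.
#' @return A tibble: `region`, `rank`, `cell_type`, `mean_in`, `mean_out`,
#'   `ratio`, `p_value`, `p_adj`, `significant`.
#' @export
domain_fraction_ranking <- function(fm, top_n = 7L,
                                    min_scaled_fraction = 0.2) {
  stopifnot(inherits(fm, "fraction_map"))
  regions <- fm$region_label
  if (is.null(regions)) stop("fraction_map has no region labels", call. = FALSE)
  keep <- !is.na(regions) & regions != "unknown"
  reg <- regions[keep]
  doms <- sort(unique(reg))
  if (length(doms) < 2) {
    stop("need at least 2 annotated domains", call. = FALSE)
  }
  # per-type min-max scaling across all (annotated) spots
  scaled <- apply(fm$fractions[keep, , drop = FALSE], 2L, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  })

  out <- list()
  for (d in doms) {
    inside <- reg == d
    if (!any(inside)) {
      warning("domain with no spots skipped: ", d, call. = FALSE)
      next
    }
    mean_in <- colMeans(scaled[inside, , drop = FALSE])
    mean_out <- colMeans(scaled[!inside, , drop = FALSE])
    p <- vapply(seq_along(fm$cell_types), function(j) {
      suppressWarnings(
        stats::wilcox.test(scaled[inside, j], scaled[!inside, j],
                           alternative = "greater", exact = FALSE,
                           correct = TRUE)$p.value
      )
    }, numeric(1))
    p_adj <- bh_adjust(p)
    ratio <- mean_in / mean_out  # Inf when the type is absent outside
    tab <- tibble::tibble(region = d, cell_type = fm$cell_types,
                          mean_in = unname(mean_in),
                          mean_out = unname(mean_out),
                          ratio = unname(ratio), p_value = p, p_adj = p_adj,
                          significant = p_adj < 0.05)
    tab <- tab[tab$mean_in >= min_scaled_fraction, , drop = FALSE]
    ord <- order(-is.infinite(tab$ratio), -tab$ratio, tab$p_adj)
    tab <- tab[utils::head(ord, top_n), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    out[[d]] <- tab
  }
  dplyr::bind_rows(out)[, c("region", "rank", "cell_type", "mean_in",
                            "mean_out", "ratio", "p_value", "p_adj",
                            "significant")]
}

#' Per-type recovery correlation between true and predicted fractions
#'
#' Pearson correlation across spots, per cell type, between a ground-truth
#' fraction map (e.g. from [make_spatial()]) and a predicted one.
#'
#' @param truth,predicted [fraction_map()] objects over the same spots;
#'   cell types are matched by name.
#' @return A tibble: `cell_type`, `pearson`.
#' @export
fraction_recovery <- function(truth, predicted) {
  stopifnot(inherits(truth, "fraction_map"),
            inherits(predicted, "fraction_map"))
  if (!identical(truth$spot_ids, predicted$spot_ids)) {
    stop("truth and prediction must cover the same spots in the same order",
         call. = FALSE)
  }
  types <- intersect(truth$cell_types, predicted$cell_types)
  if (!length(types)) stop("no shared cell types", call. = FALSE)
  r <- vapply(types, function(ct) {
    stats::cor(truth$fractions[, ct], predicted$fractions[, ct])
  }, numeric(1))
  tibble::tibble(cell_type = types, pearson = unname(r))
}
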