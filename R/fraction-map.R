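#' Construct a per-spot cell-fraction map
#'
#' Holds a spots-by-cell-types matrix of proportions (each row a probability
#' vector), with optional per-spot region labels and coordinates so that
#' predictions can be joined to tissue annotation for evaluation.
#'
#' @param fractions numeric matrix, spots in rows, cell types in columns.
#' @param spot_ids,cell_types identifiers; default to dimnames.
#' @param region_label optional character vector of per-spot tissue
#'   region/layer labels (`"unknown"` or `NA` marks unannotated spots).
#' @param coords optional two-column matrix/data frame of x,y positions.
#' @param validate_rows check that rows sum to 1 (within 1e-6). Disable for
#'   tables that are not probability vectors (e.g. scaled fractions).
#' @return An object of class `fraction_map`.
#' @export
fraction_map <- function(fractions, spot_ids = rownames(fractions),
                         cell_types = colnames(fractions),
                         region_label = NULL, coords = NULL,
                         validate_rows = TRUE) {
  fractions <- as.matrix(fractions)
  storage.mode(fractions) <- "double"
  if (is.null(spot_ids)) {
    spot_ids <- sprintf("spot_%d", seq_len(nrow(fractions)))
  }
  if (is.null(cell_types)) {
    cell_types <- sprintf("type_%d", seq_len(ncol(fractions)))
  }
  spot_ids <- as.character(spot_ids)
  cell_types <- as.character(cell_types)
  if (length(spot_ids) != nrow(fractions) ||
      length(cell_types) != ncol(fractions)) {
    stop("id lengths do not match fraction matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(spot_ids) || anyDuplicated(cell_types)) {
    stop("spot ids and cell types must be unique", call. = FALSE)
  }
  dimnames(fractions) <- list(spot_ids, cell_types)
  if (validate_rows && nrow(fractions)) {
    rs <- rowSums(fractions)
    if (min(fractions) < -1e-9 || max(abs(rs - 1)) > 1e-6) {
      stop("fraction rows must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (!is.null(region_label) && length(region_label) != nrow(fractions)) {
    stop("region_label length does not match number of spots", call. = FALSE)
  }
  structure(
    list(fractions = fractions, spot_ids = spot_ids, cell_types = cell_types,
         region_label = if (is.null(region_label)) NULL
                        else as.character(region_label),
         coords = coords),
    class = "fraction_map"
  )
}

#' @export
dim.fraction_map <- function(x) dim(x$fractions)

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf("<fraction_map> %d spots x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  if (!is.null(x$region_label)) {
    cat("  regions:", paste(unique(x$region_label), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.fraction_map <- function(x, ...) {
  df <- data.frame(spot_id = x$spot_ids, x$fractions, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(x$region_label)) df$region <- x$region_label
  if (!is.null(x$coords)) {
    df$x <- x$coords[, 1]
    df$y <- x$coords[, 2]
  }
  df
}

#' Tidy a fraction map into long format
#'
#' One row per (spot, cell type) with the predicted proportion, plus region
#' label and coordinates when present.
#'
#' @param x a [fraction_map()].
#' @param ... unused.
#' @return A tibble with columns `spot_id`, `cell_type`, `fraction` (and
#'   optionally `region`, `x`, `y`).
#' @method tidy fraction_map
#' @export
tidy.fraction_map <- function(x, ...) {
  n <- nrow(x$fractions)
  k <- ncol(x$fractions)
  out <- tibble::tibble(
    spot_id = rep(x$spot_ids, times = k),
    cell_type = rep(x$cell_types, each = n),
    fraction = as.vector(x$fractions)
  )
  if (!is.null(x$region_label)) out$region <- rep(x$region_label, times = k)
  if (!is.null(x$coords)) {
    out$x <- rep(x$coords[, 1], times = k)
    out$y <- rep(x$coords[, 2], times = k)
  }
  out
}

#' Plot a fraction map in tissue coordinates
#'
#' Scatter of spots coloured by the predicted fraction of each cell type,
#' faceted by cell type. Requires coordinates.
#'
#' @param object a [fraction_map()] with `coords`.
#' @param cell_types subset of cell types to plot (default all).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fraction_map
#' @export
autoplot.fraction_map <- function(object, cell_types = NULL, ...) {
  if (is.null(object$coords)) {
    stop("fraction_map has no coordinates to plot", call. = FALSE)
  }
  df <- tidy.fraction_map(object)
  if (!is.null(cell_types)) {
    df <- df[df$cell_type %in% cell_types, , drop = FALSE]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$fraction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "fraction") +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Stacked composition plot per region
#'
#' Mean predicted composition within each annotated region, as a stacked
#' bar chart; a quick check of whether region-restricted cell types land in
#' their region.
#'
#' @param fm a [fraction_map()] with `region_label`.
#' @return A ggplot object.
#' @export
plot_region_composition <- function(fm) {
  if (is.null(fm$region_label)) {
    stop("fraction_map has no region labels", call. = FALSE)
  }
  df <- tidy.fraction_map(fm)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$cell_type),
    fraction = mean(.data$fraction), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$region, y = .data$fraction,
                                    fill = .data$cell_type)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "mean predicted fraction") +
    ggplot2::theme_minimal()
}
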