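stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Deconvolve spatial spots against a single-cell reference
#'
#' End-to-end in-memory pipeline: total-count normalisation and log
#' transform of both modalities, Wilcoxon marker selection on the
#' single-cell data (`l` markers per cluster), intersection of the pooled
#' panel with the spatial genes, pseudospot generation (`k` cells,
#' `n_pseudospots` mixtures), per-sample min-max scaling, source
#' pretraining, adversarial domain adaptation (skipped when
#' `baseline = TRUE`), and prediction of per-spot cell fractions. Every
#' random stage is seeded deterministically from `cfg$seed`.
#'
#' @param sc raw single-cell [count_matrix()].
#' @param sc_annot cell-type annotation, see [as_annotation()].
#' @param spatial raw spatial [count_matrix()].
#' @param l markers per cluster for [rank_sum_markers()].
#' @param k cells per pseudospot.
#' @param n_pseudospots number of pseudospots.
#' @param target_sum total-count normalisation target.
#' @param cfg a [training_config()].
#' @param baseline train without the adversarial phases (the
#'   no-domain-adaptation ablation).
#' @param check_freeze assert freeze contracts every adversarial iteration.
#' @return An object of class `spotdecon_fit`: list with `fractions` (a
#'   [fraction_map()]), `model`, `markers`, `panel`, `config` and
#'   `manifest`.
#' @export
deconvolve <- function(sc, sc_annot, spatial, l = 20L, k = 8L,
                       n_pseudospots = 20000L, target_sum = 1e4,
                       cfg = training_config(), baseline = FALSE,
                       check_freeze = FALSE) {
  stopifnot(inherits(sc, "count_matrix"), inherits(spatial, "count_matrix"))
  seeds <- derive_seeds(cfg$seed, c("pseudospots", "init", "pretrain",
                                    "adversarial"))

  sc_ln <- stage("preprocess_sc",
                 log1p_transform(normalize_total(sc, target_sum)))
  sp_ln <- stage("preprocess_spatial",
                 log1p_transform(normalize_total(spatial, target_sum)))
  markers <- stage("markers", rank_sum_markers(sc_ln, sc_annot, l))
  panel <- stage("intersect",
                 intersect_genes(markers$pooled_panel, spatial, sc))
  sc_panel <- subset_genes(sc_ln, panel)
  sp_panel <- subset_genes(sp_ln, panel)

  pseudo <- stage("pseudospots",
                  generate_pseudospots(sc_panel, sc_annot, k = k,
                                       n = n_pseudospots,
                                       seed = seeds[["pseudospots"]]))
  pseudo <- minmax_scale(pseudo)
  spots_scaled <- minmax_scale(sp_panel)

  model <- stage("init",
                 init_model(length(panel), length(pseudo$cell_type_order),
                            alpha = cfg$alpha, seed = seeds[["init"]]))
  model$panel <- panel
  model$cell_types <- pseudo$cell_type_order

  cfg_pre <- cfg
  cfg_pre$seed <- seeds[["pretrain"]]
  model <- stage("pretrain", pretrain_source(model, pseudo, cfg_pre))
  if (!baseline) {
    cfg_adv <- cfg
    cfg_adv$seed <- seeds[["adversarial"]]
    model <- stage("adversarial",
                   adversarial_train(model, pseudo, spots_scaled, cfg_adv,
                                     check_freeze = check_freeze))
  }
  fractions <- stage("predict", predict_fractions(model, spots_scaled))

  manifest <- list(
    package = "spotdecon", version = "0.1.0",
    parameters = list(
      l = as.integer(l), k = as.integer(k),
      n_pseudospots = as.integer(n_pseudospots), target_sum = target_sum,
      iterations = cfg$iterations, batch_size = cfg$batch_size,
      lr_main = cfg$lr_main, lr_domain = cfg$lr_domain, alpha = cfg$alpha,
      pretrain_epochs = cfg$pretrain_epochs, baseline = baseline
    ),
    master_seed = cfg$seed, stage_seeds = as.list(seeds),
    panel_size = length(panel),
    n_cells = ncol(sc$values), n_spots = ncol(spatial$values),
    input_hash = list(sc = rlang::hash(sc$values),
                      spatial = rlang::hash(spatial$values))
  )

  structure(list(fractions = fractions, model = model, markers = markers,
                 panel = panel, config = cfg, manifest = manifest),
            class = "spotdecon_fit")
}

#' @export
print.spotdecon_fit <- function(x, ...) {
  cat(sprintf(
    "<spotdecon_fit> %d spots x %d cell types (panel of %d genes)%s\n",
    nrow(x$fractions$fractions), ncol(x$fractions$fractions),
    length(x$panel),
    if (isTRUE(x$manifest$parameters$baseline)) " [baseline, no adaptation]"
    else ""))
  invisible(x)
}

#' @method tidy spotdecon_fit
#' @export
tidy.spotdecon_fit <- function(x, ...) tidy.fraction_map(x$fractions)

#' @method glance spotdecon_fit
#' @export
glance.spotdecon_fit <- function(x, ...) {
  g <- glance.adda_model(x$model)
  g$panel_size <- length(x$panel)
  g$n_spots <- nrow(x$fractions$fractions)
  g$baseline <- isTRUE(x$manifest$parameters$baseline)
  g
}

#' Run the full pipeline on files and write the outputs
#'
#' File-level wrapper around [deconvolve()]: reads the single-cell matrix,
#' its annotation and the spatial matrix, runs the pipeline, and writes
#' `fractions.csv`, `markers.tsv` and a machine-readable `manifest.json`
#' (all parameters, stage seeds, input hashes) into `out_dir`. On failure
#' the partial outputs are removed and the error names the failing stage.
#'
#' @param sc_path,spatial_path matrix locations, see [read_count_matrix()].
#' @param sc_annotation_path annotation TSV, see [read_annotation()].
#' @param out_dir output directory, created if absent.
#' @param format `"mtx"` or `"csv"`, applied to both matrices.
#' @param orientation on-disk MTX orientation, see [read_count_matrix()].
#' @param ... passed to [deconvolve()] (`l`, `k`, `n_pseudospots`, `cfg`,
#'   `baseline`, ...).
#' @return The `spotdecon_fit`, invisibly.
#' @export
run_pipeline <- function(sc_path, sc_annotation_path, spatial_path, out_dir,
                         format = "mtx",
                         orientation = "genes_by_samples", ...) {
  sc <- stage("read_sc", read_count_matrix(sc_path, format = format,
                                           orientation = orientation))
  annot <- stage("read_annotation", read_annotation(sc_annotation_path))
  spatial <- stage("read_spatial",
                   read_count_matrix(spatial_path, format = format,
                                     orientation = orientation))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- file.path(out_dir, c("fractions.csv", "markers.tsv",
                                  "manifest.json"))
  tryCatch({
    fit <- deconvolve(sc, annot, spatial, ...)
    write_fraction_map(fit$fractions, outputs[1])
    write_marker_set(fit$markers, outputs[2])
    jsonlite::write_json(fit$manifest, outputs[3], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(fit)
  }, error = function(e) {
    unlink(outputs[file.exists(outputs)])
    stop(conditionMessage(e), call. = FALSE)
  })
}
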