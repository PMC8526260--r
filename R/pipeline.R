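#' Default pipeline configuration
#'
#' Every tunable of the pipeline stages with its default; round-trips
#' losslessly through JSON via [write_config()] / [read_config()].
#'
#' @param ... Overrides (name = value).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    denoise_basis = "db6", denoise_levels = NULL,
    qrs_freqs = c(5, 7.5, 10, 15), qrs_threshold_frac = 0.4,
    qrs_refractory = 0.2, slope_frac = 0.10,
    compress_method = "dwt", compress_k = 32L,
    lpp_neighbors = 7L, lpp_t = NULL,
    feature_set = "fused",
    nrounds = 60L, max_depth = 6L, learning_rate = 0.1,
    lambda = 1, gamma = 0, colsample = 0.8,
    cv_k = 10L, seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_keys <- c("compress_k", "lpp_neighbors", "nrounds", "max_depth",
                "cv_k", "seed")
  num_keys <- c("qrs_freqs", "qrs_threshold_frac", "qrs_refractory",
                "slope_frac", "lpp_t", "nrounds_frac", "learning_rate",
                "lambda", "gamma", "colsample")
  for (k in intersect(int_keys, names(cfg))) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in intersect(num_keys, names(cfg))) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  }
  do.call(pipeline_config, cfg)
}

#' Run the full classification pipeline on a record
#'
#' Denoise, delineate, extract the per-lead rule and QT features, compress,
#' fuse, and evaluate by stratified k-fold cross-validation. The single
#' entry point realizing the whole flow; each stage is also exported on its
#' own.
#'
#' @param record An `ecg_record` with per-beat labels (for simulated
#'   records the ground-truth labels are used automatically).
#' @param config A [pipeline_config()].
#' @param labels Optional per-beat labels (overrides record truth).
#' @return List: `denoised` record, `fiducials`, tidy `features`, and the
#'   `cv` result (`mi_cv`).
#' @export
run_mi_pipeline <- function(record, config = pipeline_config(),
                            labels = NULL) {
  den <- ecg_denoise(record, basis = config$denoise_basis,
                     levels = config$denoise_levels)
  fid <- delineate_record(den)
  feats <- extract_features(den, fiducials = fid, labels = labels)
  if (!"label" %in% names(feats)) {
    stop("no beat labels available; pass labels=", call. = FALSE)
  }
  cv <- kfold_cv(feats, k = config$cv_k, method = config$compress_method,
                 feature_set = config$feature_set, seed = config$seed,
                 nrounds = config$nrounds, max_depth = config$max_depth,
                 learning_rate = config$learning_rate,
                 lambda = config$lambda, gamma = config$gamma,
                 colsample = config$colsample)
  list(denoised = den, fiducials = fid, features = feats, cv = cv)
}
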