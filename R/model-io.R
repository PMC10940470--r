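# Save/load for the boosted CNN ensemble: a directory holding one JSON
# parameter file per estimator plus a manifest (rounds, architecture,
# seeds). Plain-text on purpose so models diff and version cleanly.

#' Save a boosted CNN ensemble to a directory
#'
#' @param model a [train_boosted_cnn()] fit.
#' @param dir output directory (created if needed).
#' @export
save_boosted_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    Q = model$Q, learning_rate = model$learning_rate,
    epochs = model$epochs, seed = model$seed,
    cfg = unclass(model$cfg), D = model$D
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (q in seq_len(model$Q)) {
    params <- lapply(model$estimators[[q]]$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
      else list(dim = length(w), data = as.vector(w))
    })
    jsonlite::write_json(params,
                         file.path(dir, sprintf("estimator_%03d.json", q)),
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(dir)
}

#' Load a boosted CNN ensemble saved by [save_boosted_cnn()]
#'
#' @param dir directory written by [save_boosted_cnn()].
#' @return A `boosted_cnn` model (round-trip preserves scores bitwise).
#' @export
load_boosted_cnn <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- structure(manifest$cfg, class = "cnn_config")
  estimators <- lapply(seq_len(manifest$Q), function(q) {
    raw <- jsonlite::read_json(
      file.path(dir, sprintf("estimator_%03d.json", q)),
      simplifyVector = TRUE)
    params <- lapply(raw, function(p) {
      v <- as.numeric(p$data)
      if (length(p$dim) == 2L) matrix(v, p$dim[1L], p$dim[2L]) else v
    })
    structure(list(params = params, cfg = cfg, epochs = manifest$epochs,
                   seed = manifest$seed),
              class = "cnn_estimator")
  })
  structure(list(estimators = estimators, Q = as.integer(manifest$Q),
                 D = as.numeric(manifest$D),
                 learning_rate = manifest$learning_rate,
                 epochs = as.integer(manifest$epochs), cfg = cfg,
                 seed = as.integer(manifest$seed), round_log = NULL),
            class = "boosted_cnn")
}
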