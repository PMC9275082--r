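#' Save a fitted model checkpoint
#'
#' A checkpoint is a single archive (RDS) holding every weight matrix, the
#' model configuration and the bookkeeping needed to restore scoring
#' (`predict()` on the restored object reproduces the original scores
#' exactly).
#'
#' @param fit A `gcn_link` object.
#' @param path Output path (conventionally `.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gcn_link"))
  saveRDS(list(format = "gcnlink-checkpoint-1", fit = unclass(fit)), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return The restored `gcn_link` object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gcnlink-checkpoint-1"))
    stop("not a gcnlink checkpoint: ", path)
  structure(obj$fit, class = "gcn_link")
}
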