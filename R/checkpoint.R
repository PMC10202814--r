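vocab_fingerprint <- function(vocab) {
  # order-sensitive 64-bit-ish rolling hash of the token list
  s <- paste(vocab$tokens, collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d:%d", length(vocab$tokens), h)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the model configuration, the
#' vocabulary (with a fingerprint), and all parameter matrices. Loading
#' against a dataset whose vocabulary fingerprint differs is refused, since
#' embedding rows would silently mean different diagnosis codes.
#'
#' @param model a `trajrisk_model` (or a `trajrisk_run`, whose best model is
#'   saved).
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   `trajrisk_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "trajrisk_run")) model <- model$model
  stopifnot(inherits(model, "trajrisk_model"))
  obj <- list(config = unclass(model$config),
              vocab_tokens = model$vocab$tokens,
              vocab_fingerprint = vocab_fingerprint(model$vocab),
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @param vocab optional `trajrisk_vocab` (or `trajrisk_data`) to validate
#'   against.
#' @export
load_model <- function(path, vocab = NULL) {
  obj <- readRDS(path)
  vc <- structure(list(tokens = obj$vocab_tokens,
                       index = stats::setNames(seq_along(obj$vocab_tokens),
                                               obj$vocab_tokens),
                       pad_index = length(obj$vocab_tokens) + 1L),
                  class = "trajrisk_vocab")
  if (vocab_fingerprint(vc) != obj$vocab_fingerprint) {
    stop("load_model: checkpoint vocabulary fingerprint mismatch (corrupt file?)")
  }
  if (!is.null(vocab)) {
    if (inherits(vocab, "trajrisk_data")) vocab <- vocab$vocab
    if (vocab_fingerprint(vocab) != obj$vocab_fingerprint) {
      stop("load_model: vocabulary mismatch between checkpoint and data")
    }
  }
  structure(list(config = structure(obj$config, class = "trajrisk_config"),
                 vocab = vc, params = obj$params),
            class = "trajrisk_model")
}
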