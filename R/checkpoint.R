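# Checkpoints: a self-describing JSON archive of named numeric arrays plus
# metadata.  Weight arrays are serialized as "%.17g" strings, which
# round-trip IEEE-754 doubles exactly, so a reloaded model reproduces the
# saving model's scores bitwise.

CHECKPOINT_FORMAT <- "oncosgan-checkpoint/1"

pack_array <- function(x) {
  list(dim = as.integer(dim(x) %||% length(x)), data = format_exact(c(x)))
}

unpack_array <- function(a) {
  v <- as.numeric(a$data)
  d <- as.integer(a$dim)
  if (length(d) > 1L) array(v, d) else v
}

pack_tree <- function(p) {
  if (is.list(p)) lapply(p, pack_tree) else pack_array(p)
}

unpack_tree <- function(p) {
  if (!is.null(p$dim) && !is.null(p$data)) unpack_array(p) else
    lapply(p, unpack_tree)
}

#' Save a trained model (and preprocessing states) to a checkpoint
#'
#' The checkpoint is a single JSON file: format version, network specs,
#' training config, column manifest, all network weights and batch-norm
#' statistics, and (when `prep` is given) the encoder and scaler states plus
#' a summary of the imputer (its `k` and reference dimensions; the reference
#' matrix itself is not embedded).
#'
#' @param fit An `sgan_fit`.
#' @param path Output file path.
#' @param prep Optional `sgan_preprocessor` to embed.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path, prep = NULL) {
  stopifnot(inherits(fit, "sgan_fit"))
  ck <- list(
    format = CHECKPOINT_FORMAT,
    mode = fit$mode,
    classes = fit$classes,
    config = unclass(fit$config),
    manifest = if (!is.null(fit$manifest)) as.list(fit$manifest),
    epochs_trained = if (is.null(fit$history)) 0L else nrow(fit$history),
    discriminator = list(spec = unclass(fit$discriminator$spec),
                         params = pack_tree(fit$discriminator$params)))
  if (!is.null(fit$generator)) {
    ck$generator <- list(spec = unclass(fit$generator$spec),
                         params = pack_tree(fit$generator$params),
                         bn_state = pack_tree(fit$generator$bn_state))
  }
  if (!is.null(prep)) {
    ck$preprocessor <- list(
      encoder = unclass(prep$encoder),
      scaler = list(min = format_exact(prep$scaler$min),
                    max = format_exact(prep$scaler$max),
                    constant = prep$scaler$constant,
                    columns = prep$scaler$columns),
      imputer_summary = list(k = prep$imputer$k,
                             reference_rows = nrow(prep$imputer$reference),
                             reference_cols = ncol(prep$imputer$reference)))
  }
  writeLines(jsonlite::toJSON(ck, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path to a file written by [save_checkpoint()].
#' @return A list with `fit` (an `sgan_fit` that reproduces the saved
#'   model's interpretation scores bitwise) and, when embedded, `encoder`
#'   and `scaler` states and the `imputer_summary`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_oncosgan("no such checkpoint: ", path)
  ck <- tryCatch(jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                          collapse = "\n"),
                                    simplifyDataFrame = FALSE,
                                    simplifyVector = TRUE),
                 error = function(e) {
                   stop_oncosgan("unreadable checkpoint (", conditionMessage(e), ")")
                 })
  if (!identical(ck$format, CHECKPOINT_FORMAT)) {
    stop_oncosgan("checkpoint format '", ck$format %||% "<missing>",
                  "' does not match supported '", CHECKPOINT_FORMAT, "'")
  }
  dspec <- do.call(discriminator_spec, ck$discriminator$spec)
  disc <- init_discriminator_from(dspec, unpack_tree(ck$discriminator$params))
  gen <- NULL
  if (!is.null(ck$generator)) {
    gspec <- do.call(generator_spec, ck$generator$spec)
    gen <- list(spec = gspec, params = unpack_tree(ck$generator$params),
                bn_state = unpack_tree(ck$generator$bn_state))
  }
  cfg <- do.call(training_config, ck$config[names(ck$config) %in%
                                              names(formals(training_config))])
  manifest <- if (!is.null(ck$manifest)) {
    as.data.frame(lapply(ck$manifest, function(col) {
      unlist(lapply(col, function(v) if (is.null(v)) NA else v))
    }), stringsAsFactors = FALSE)
  }
  fit <- as_sgan_fit(list(generator = gen, discriminator = disc),
                     manifest, cfg, mode = ck$mode)
  out <- list(fit = fit)
  if (!is.null(ck$preprocessor)) {
    pp <- ck$preprocessor
    out$encoder <- evidence_encoder(pp$encoder$noise_sd, pp$encoder$seed)
    out$scaler <- structure(list(min = as.numeric(pp$scaler$min),
                                 max = as.numeric(pp$scaler$max),
                                 constant = as.logical(pp$scaler$constant),
                                 columns = pp$scaler$columns),
                            class = "minmax_scaler")
    out$imputer_summary <- pp$imputer_summary
  }
  out
}

init_discriminator_from <- function(spec, params) {
  d <- init_discriminator(spec)
  d$params <- params
  d
}
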