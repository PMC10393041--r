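# Artifact round-tripping: aligned tensors, model checkpoints. Everything is
# plain text (JSON) so artifacts survive text-only environments and diffs.

flat_array <- function(a) list(dim = dim(a), data = as.numeric(a))
unflat_array <- function(fl) array(fl$data, dim = fl$dim)

#' Write / read an aligned dataset as JSON
#'
#' Stores the input/target tensors (flattened with dims), per-sample
#' normalization parameters and sample order in one JSON artifact.
#'
#' @param data An `aligned_dataset`.
#' @param norm_params Named list of per-sample `list(min, max)`.
#' @param path JSON file path.
#' @return `write_aligned`: path, invisibly. `read_aligned`: list with the
#'   `aligned_dataset` and `norm_params`.
#' @export
write_aligned <- function(data, norm_params, path) {
  obj <- list(X = flat_array(data$X), Y = flat_array(data$Y),
              sample_order = data$sample_order, role = data$role,
              method = data$method, norm_params = norm_params,
              tool = as.character(utils::packageVersion("hetercgm")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aligned
#' @export
read_aligned <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- new_aligned_dataset(unflat_array(obj$X), unflat_array(obj$Y),
                              obj$norm_params, obj$sample_order,
                              obj$role, obj$method)
  list(data = data, norm_params = obj$norm_params)
}

#' Save / load a HETER checkpoint
#'
#' A single JSON file embedding the configuration and every learnable tensor
#' (flattened with dims, full double precision).
#'
#' @param params `heter_params`.
#' @param config `heter_config`.
#' @param path Checkpoint path.
#' @param extra Optional named list of metadata (seed, loss history, ...).
#' @return `save_checkpoint`: path, invisibly. `load_checkpoint`: list with
#'   `params`, `config`, `extra`.
#' @export
save_checkpoint <- function(params, config, path, extra = list()) {
  ser <- lapply(params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = NULL, data = as.numeric(p))
  })
  obj <- list(config = unclass(config), params = ser, extra = extra,
              tool = as.character(utils::packageVersion("hetercgm")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$candidate_activation <- as.character(cfg$candidate_activation)
  for (nm in setdiff(names(cfg), "candidate_activation"))
    if (nm %in% c("dropout_g", "dropout_co", "dropout_o")) cfg[[nm]] <- as.numeric(cfg[[nm]])
    else cfg[[nm]] <- as.integer(cfg[[nm]])
  class(cfg) <- "heter_config"
  validate_heter_config(cfg)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) array(p$data, dim = p$dim)
    else as.numeric(p$data)
  })
  # wr/wu/wc keep 1 x d orientation
  class(params) <- "heter_params"
  list(params = params, config = cfg, extra = obj$extra)
}

# md5 of an in-memory object via its canonical JSON rendering (base tools
# only; no digest dependency).
content_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

file_hash <- function(path) unname(tools::md5sum(path))
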