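#' Save / load a model checkpoint
#'
#' Writes the full weight set, trainable mask and configuration to `path`
#' (R serialisation) with a human-readable JSON metadata sidecar
#' (`<path>.json`) describing the architecture, the trainable mask and any
#' LoRA configuration.
#'
#' @param model a `vit_model`.
#' @param path checkpoint file path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(config = unclass(model$config),
               trainable = as.list(model$trainable),
               lora = if (is.null(model$lora)) NULL else unclass(model$lora),
               n_parameters = count_parameters(model),
               n_trainable = count_parameters(model, trainable_only = TRUE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vit_model"))
    stop("not a model checkpoint: ", path, call. = FALSE)
  model
}

#' Save / load an adapter state file
#'
#' Serialises the transmitted adapter weight set (keys
#' `block{i}.attn.{query|value}.{A|B}`, plus the head when configured
#' trainable) with a JSON header recording rank, alpha and scaling
#' convention.
#'
#' @param model an adapted `vit_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_adapter_state <- function(model, path) {
  state <- extract_adapter_state(model)
  saveRDS(state, path)
  cfg <- model$lora
  jsonlite::write_json(list(rank = cfg$rank, alpha = cfg$alpha,
                            scaling_convention = cfg$scaling_convention,
                            n_elements = tensor_elements(state)),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_adapter_state
#' @export
load_adapter_state_file <- function(model, path) {
  load_adapter_state(model, readRDS(path))
}
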