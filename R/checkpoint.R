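# Checkpoint I/O: weights and normalization statistics as a flat named list,
# serialized with saveRDS. Keys are dotted module paths (see README);
# buffer entries carry a "buf:" prefix.

flatten_buffers <- function(m, prefix = "") {
  out <- list()
  rec_env <- function(e, pre) {
    for (nm in ls(e)) {
      v <- get(nm, envir = e)
      if (is.environment(v)) rec_env(v, paste0(pre, nm, "."))
      else out[[paste0(pre, nm)]] <<- v
    }
  }
  rec_env(m$buffers, paste0("buf:", prefix))
  for (nm in names(m$sub))
    out <- c(out, flatten_buffers(m$sub[[nm]], paste0(prefix, nm, ".")))
  out
}

restore_buffers <- function(m, flat, prefix = "") {
  rec_env <- function(e, pre) {
    for (nm in ls(e)) {
      v <- get(nm, envir = e)
      if (is.environment(v)) rec_env(v, paste0(pre, nm, "."))
      else {
        key <- paste0(pre, nm)
        if (key %in% names(flat)) assign(nm, flat[[key]], envir = e)
      }
    }
  }
  rec_env(m$buffers, paste0("buf:", prefix))
  for (nm in names(m$sub))
    restore_buffers(m$sub[[nm]], flat, paste0(prefix, nm, "."))
  invisible(m)
}

#' Save model weights and normalization statistics
#' @param model a `bd_module`.
#' @param path output file (RDS).
#' @export
save_weights <- function(model, path) {
  saveRDS(c(bd_flat_params(model), flatten_buffers(model)), path)
  invisible(path)
}

#' Load weights saved with [save_weights()]
#' @param model a compatible `bd_module` (same architecture).
#' @param path weights file.
#' @return the model with parameters and statistics restored.
#' @export
load_weights <- function(model, path) {
  flat <- readRDS(path)
  model <- bd_set_flat(model, flat[!startsWith(names(flat), "buf:")])
  restore_buffers(model, flat)
  model
}

#' Convert a trained multi-branch checkpoint to its fused single-branch form
#'
#' Loads weights into `model`, fuses every RepConv into its equivalent
#' single 3x3 convolution, and saves the fused weights. The fused state
#' loads into the model produced by `fuse_model(model)`.
#'
#' @param model the (unfused) architecture the checkpoint belongs to.
#' @param path_in multi-branch weights file.
#' @param path_out output file for the fused weights.
#' @return the fused model, invisibly.
#' @export
convert_checkpoint <- function(model, path_in, path_out) {
  model <- load_weights(model, path_in)
  fused <- fuse_model(model)
  save_weights(fused, path_out)
  invisible(fused)
}
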