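# Module framework.
#
# A module is a plain list:
#   kind     character, also its S3 class
#   params   named list of trainable arrays (or ag_param nodes when bound)
#   buffers  named list of non-trainable state (BN running stats, templates)
#   sub      named list of child modules
#   cfg      construction hyper-parameters
#
# bd_forward() dispatches on kind; counting walks the tree so every parameter
# is counted exactly once.

new_module <- function(kind, params = list(), buffers = list(),
                       sub = list(), cfg = list()) {
  # buffers live in an environment so running statistics update in place
  structure(list(kind = kind, params = params,
                 buffers = list2env(buffers, parent = emptyenv()),
                 sub = sub, cfg = cfg),
            class = c(kind, "bd_module"))
}

#' Switch a model between training and inference normalization
#'
#' In training mode batch normalization uses per-channel spatial statistics
#' of the current input and updates the stored running statistics; in
#' inference mode (default) the stored statistics are used.
#'
#' @param on logical.
#' @export
bd_train_mode <- function(on = TRUE) {
  .bd_mode$train <- isTRUE(on)
  invisible(on)
}

.bd_mode <- new.env(parent = emptyenv())
.bd_mode$train <- FALSE

#' Forward pass through a module
#' @param m a `bd_module`.
#' @param x input (feature map array, matrix, or list of maps per kind).
#' @param ... passed on to methods.
#' @return module output.
#' @export
bd_forward <- function(m, x, ...) UseMethod("bd_forward")

#' Number of trainable parameters of a module tree
#'
#' Counts every scalar in `params` of the module and its children; buffers
#' (running statistics, coordinate templates) are excluded.
#'
#' @param m a `bd_module`.
#' @return integer scalar count.
#' @export
bd_n_params <- function(m) {
  n <- sum(vapply(m$params, function(p) length(ag_value(p)), numeric(1)))
  if (length(m$sub)) n <- n + sum(vapply(m$sub, bd_n_params, numeric(1)))
  n
}

#' Flatten the parameter arrays of a module tree
#' @param m a `bd_module`.
#' @param prefix internal path prefix.
#' @return named list of arrays, names are `sub1.sub2.param` paths.
#' @export
bd_flat_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- ag_value(m$params[[nm]])
  for (nm in names(m$sub))
    out <- c(out, bd_flat_params(m$sub[[nm]], paste0(prefix, nm, ".")))
  out
}

#' Load a flat parameter list produced by [bd_flat_params()]
#' @param m a `bd_module`.
#' @param flat named list of arrays.
#' @param prefix internal path prefix.
#' @return the module with parameters replaced.
#' @export
bd_set_flat <- function(m, flat, prefix = "") {
  for (nm in names(m$params)) {
    key <- paste0(prefix, nm)
    if (!key %in% names(flat)) stop("missing parameter: ", key)
    p <- flat[[key]]
    old <- ag_value(m$params[[nm]])
    if (length(p) != length(old)) stop("size mismatch for ", key)
    dim(p) <- dim(old)
    m$params[[nm]] <- p
  }
  for (nm in names(m$sub))
    m$sub[[nm]] <- bd_set_flat(m$sub[[nm]], flat, paste0(prefix, nm, "."))
  m
}

# Replace every parameter array with an ag_param node; returns the bound
# module and the flat list of nodes (for an optimizer).
bd_bind <- function(m) {
  nodes <- list()
  rec <- function(mm, prefix) {
    for (nm in names(mm$params)) {
      node <- ag_param(ag_value(mm$params[[nm]]))
      mm$params[[nm]] <- node
      nodes[[paste0(prefix, nm)]] <<- node
    }
    for (nm in names(mm$sub))
      mm$sub[[nm]] <- rec(mm$sub[[nm]], paste0(prefix, nm, "."))
    mm
  }
  m2 <- rec(m, "")
  list(module = m2, nodes = nodes)
}

# Kaiming-style initialization for a (Cout, Cin_g, kh, kw) kernel.
init_kernel <- function(cout, cin_g, kh, kw, gain = 2) {
  array(stats::rnorm(cout * cin_g * kh * kw, sd = sqrt(gain / (cin_g * kh * kw))),
        c(cout, cin_g, kh, kw))
}

init_mat <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)), din, dout)
}

act_apply <- function(x, act) {
  switch(act,
         silu = ag_silu(x), relu = ag_relu(x), gelu = ag_gelu(x),
         sigmoid = ag_sigmoid(x), none = x,
         stop("unknown activation: ", act))
}

# ---- convolution unit (conv [+ BN] [+ activation]) -------------------------

#' Convolution unit: convolution, optional batch norm, optional activation
#'
#' The standard building block: a 2-D convolution followed by inference-mode
#' batch normalization (running statistics stored as buffers) and an
#' activation. Bias is omitted when a norm follows, as usual.
#'
#' @param cin,cout channel counts.
#' @param k kernel size (scalar or length-2).
#' @param stride,pad stride and padding (pad defaults to "same" for odd k).
#' @param groups convolution groups.
#' @param norm include batch normalization.
#' @param act one of "silu", "relu", "gelu", "sigmoid", "none".
#' @param bias force a bias term (default: only when `norm = FALSE`).
#' @return a `bd_module` of kind `conv_unit`.
#' @export
mk_conv <- function(cin, cout, k, stride = 1, pad = NULL, groups = 1,
                    norm = TRUE, act = "silu", bias = !norm) {
  k <- rep(as.integer(k), length.out = 2)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  params <- list(w = init_kernel(cout, cin %/% groups, k[1], k[2]))
  if (bias) params$b <- numeric(cout)
  buffers <- list()
  if (norm) {
    params$gamma <- rep(1, cout)
    params$beta <- numeric(cout)
    buffers <- list(mean = numeric(cout), var = rep(1, cout), eps = 1e-5)
  }
  new_module("conv_unit", params, buffers,
             cfg = list(cin = cin, cout = cout, k = k, stride = stride,
                        pad = rep(as.integer(pad), length.out = 2),
                        groups = groups, norm = norm, act = act, bias = bias))
}

#' @export
bd_forward.conv_unit <- function(m, x, ...) {
  cfg <- m$cfg
  y <- ag_conv2d(x, m$params$w, m$params$b, stride = cfg$stride,
                 pad = cfg$pad, groups = cfg$groups)
  if (cfg$norm)
    y <- ag_bn(y, m$params$gamma, m$params$beta, m$buffers)
  act_apply(y, cfg$act)
}

# ---- dense unit ------------------------------------------------------------

#' Dense (fully connected) unit
#' @param din,dout feature dimensions.
#' @param act activation name.
#' @param bias include bias.
#' @export
mk_dense <- function(din, dout, act = "none", bias = TRUE) {
  params <- list(w = init_mat(din, dout))
  if (bias) params$b <- numeric(dout)
  new_module("dense_unit", params,
             cfg = list(din = din, dout = dout, act = act, bias = bias))
}

#' @export
bd_forward.dense_unit <- function(m, x, ...) {
  act_apply(ag_linear(x, m$params$w, m$params$b), m$cfg$act)
}

# ---- layer norm unit -------------------------------------------------------

mk_ln <- function(d) {
  new_module("ln_unit", params = list(gamma = rep(1, d), beta = numeric(d)),
             cfg = list(d = d))
}

#' @export
bd_forward.ln_unit <- function(m, x, ...) {
  ag_layernorm(x, m$params$gamma, m$params$beta)
}

# Sequential container.
mk_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "bd_module"))
    mods <- mods[[1]]
  names(mods) <- sprintf("m%02d", seq_along(mods))
  new_module("seq_unit", sub = mods)
}

#' @export
bd_forward.seq_unit <- function(m, x, ...) {
  for (child in m$sub) x <- bd_forward(child, x)
  x
}
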