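# Parameterized layer constructors.  A layer is a plain list of ag_param
# tensors plus metadata; forwards are free functions so the same parameters
# can be run with or without the gradient tape.

new_conv <- function(in_ch, out_ch, k = 3L, dil = 1L, init_sd = NULL) {
  fan_in <- k * k * in_ch
  sd <- init_sd %||% sqrt(2 / fan_in)     # He initialization for ReLU stacks
  list(
    kind = "conv",
    w = ag_param(array(stats::rnorm(k * k * in_ch * out_ch, 0, sd),
                       c(k, k, in_ch, out_ch))),
    b = ag_param(rep(0, out_ch)),
    dil = as.integer(dil)
  )
}

conv_fw <- function(l, x) ag_conv2d(x, l$w, l$b, l$dil)

new_bn <- function(ch) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, ch)
  st$var <- rep(1, ch)
  list(kind = "bn", gamma = ag_param(rep(1, ch)), beta = ag_param(rep(0, ch)),
       state = st)
}

bn_fw <- function(l, x, training = FALSE) {
  ag_bn(x, l$gamma, l$beta, l$state, training = training)
}

new_dense <- function(in_ch, out_ch, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / in_ch)
  list(kind = "dense",
       w = ag_param(matrix(stats::rnorm(in_ch * out_ch, 0, sd), in_ch, out_ch)),
       b = ag_param(rep(0, out_ch)))
}

dense_fw <- function(l, s) ag_dense(s, l$w, l$b)

# Convolution + batch norm + ReLU, the workhorse unit of both U-Nets.
new_cbr <- function(in_ch, out_ch, k = 3L, dil = 1L) {
  list(kind = "cbr", conv = new_conv(in_ch, out_ch, k, dil), bn = new_bn(out_ch))
}

cbr_fw <- function(l, x, training = FALSE) {
  ag_relu(bn_fw(l$bn, conv_fw(l$conv, x), training))
}

# Recursively collect every trainable ag_param in a module tree.
collect_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ag(x)) {
      if (x$req) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

# Recursively collect batch-norm running-statistic environments.
collect_bn_states <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.list(x) && !is_ag(x)) {
      if (identical(x$kind, "bn")) out[[length(out) + 1L]] <<- x$state
      for (el in x) if (is.list(el) || is.environment(el)) walk(el)
    }
  }
  walk(module)
  out
}

#' Count the trainable parameters of a model or block
#'
#' @param module A [gaad_model()] or any parameter list built by the
#'   block constructors.
#' @return Total number of trainable scalar parameters.
#' @export
n_parameters <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params,
       m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * p$g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * p$g^2
    mhat <- opt$m[[i]] / (1 - b1^opt$t)
    vhat <- opt$v[[i]] / (1 - b2^opt$t)
    p$v <- p$v - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}
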