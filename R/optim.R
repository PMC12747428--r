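#' AdamW optimizer state
#'
#' Minimal decoupled-weight-decay Adam over a named list of numeric arrays.
#' Used by all three training loops (species embeddings, DNA encoder,
#' co-occurrence layer); weight decay defaults to 0 so it reduces to Adam
#' unless asked otherwise.
#'
#' @param params named list of numeric vectors/matrices/arrays.
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates for the moment estimates.
#' @param eps numerical stabilizer added to the denominator.
#' @param weight_decay decoupled weight decay coefficient.
#' @return an object of class `adamw` holding parameters and moments.
#' @keywords internal
adamw_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  stopifnot(is.list(params), length(params) > 0)
  structure(
    list(
      params = params,
      m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
      v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
      t = 0L,
      lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
      weight_decay = weight_decay
    ),
    class = "adamw"
  )
}

#' One AdamW update
#'
#' @param opt an `adamw` object.
#' @param grads named list of gradients, same shapes as `opt$params`; entries
#'   may be missing (parameter left untouched this step).
#' @return the updated `adamw` object.
#' @keywords internal
adamw_step <- function(opt, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    p <- opt$params[[nm]]
    p <- p - opt$lr * (mhat / (sqrt(vhat) + opt$eps) + opt$weight_decay * p)
    opt$params[[nm]] <- p
  }
  opt
}

`%||%` <- function(x, y) if (is.null(x)) y else x
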