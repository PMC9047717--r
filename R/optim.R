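# Plain base-R implementations of the standard first-order optimizers used
# for SNN parameter updates (SGD, Adam, AdamW with decoupled weight decay).
# State is kept per layer and per tensor (w_in, w_rec, bias, tau).

opt_init <- function(network, method = c("adamw", "adam", "sgd"),
                     lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0, l1_decay = 0) {
  method <- match.arg(method)
  zeros_like <- function(p) list(w_in = p$w_in * 0, w_rec = p$w_rec * 0,
                                 bias = p$bias * 0, tau = p$tau * 0)
  state <- list(method = method, lr = lr, beta1 = beta1, beta2 = beta2,
                eps = eps, weight_decay = weight_decay, l1_decay = l1_decay,
                t = 0L)
  if (method != "sgd") {
    state$m <- lapply(network, zeros_like)
    state$v <- lapply(network, zeros_like)
  }
  state
}

# One update of every tensor of every layer; grads is a list of gradient
# bundles parallel to the network holding the *data* gradients. The l1
# synaptic-sparsity term is applied decoupled from the adaptive moment
# statistics, as lr * l1_decay * sign(w) (for SGD this coincides with
# folding it into the gradient; for Adam/AdamW decoupling keeps the decay
# at its stated magnitude instead of being renormalized to the full
# learning rate). Returns list(network, opt).
opt_step <- function(opt, network, grads) {
  opt$t <- opt$t + 1L
  tensors <- c(w_in = "d_w_in", w_rec = "d_w_rec", bias = "d_bias",
               tau = "d_tau")
  for (l in seq_along(network)) {
    for (nm in names(tensors)) {
      g <- grads[[l]][[tensors[[nm]]]]
      p <- network[[l]][[nm]]
      if (opt$method == "sgd") {
        step <- opt$lr * g
        if (opt$weight_decay > 0 && nm %in% c("w_in", "w_rec"))
          step <- step + opt$lr * opt$weight_decay * p
      } else {
        m <- opt$beta1 * opt$m[[l]][[nm]] + (1 - opt$beta1) * g
        v <- opt$beta2 * opt$v[[l]][[nm]] + (1 - opt$beta2) * g^2
        opt$m[[l]][[nm]] <- m
        opt$v[[l]][[nm]] <- v
        m_hat <- m / (1 - opt$beta1^opt$t)
        v_hat <- v / (1 - opt$beta2^opt$t)
        step <- opt$lr * m_hat / (sqrt(v_hat) + opt$eps)
        if (opt$method == "adamw" && opt$weight_decay > 0 &&
            nm %in% c("w_in", "w_rec"))
          step <- step + opt$lr * opt$weight_decay * p
      }
      if (opt$l1_decay > 0 && nm %in% c("w_in", "w_rec"))
        step <- step + opt$lr * opt$l1_decay * sign(p)
      network[[l]][[nm]] <- p - step
    }
    network[[l]] <- clamp_layer(network[[l]])
  }
  list(network = network, opt = opt)
}
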