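#' Fit a sparse spiking neural network classifier
#'
#' Trains a network of heterogeneous leaky integrate-and-fire neurons on
#' encoded spike trains with surrogate-gradient backpropagation through
#' time, optional spiking (l2) and synaptic (l1) sparsity regularization,
#' and optional weight/gradient-driven synaptic rewiring. The readout is
#' the spike-count softmax of the last layer.
#'
#' Initialization draws weights from N(0, 1) (clamped to the threshold
#' range), biases from U(0, 1), leak coefficients start at 0.5, and neuron
#' coordinates are uniform in the unit cube. Training is mini-batch, with
#' cross-entropy and the spiking penalty averaged per batch, parameters
#' clamped after every update, and divergence detected (non-finite loss
#' aborts; a firing rate above 0.99 sustained for three epochs flags the
#' fit as diverged).
#'
#' @param x spike array `channels x T x samples` of 0/1, or a
#'   [make_synthetic_task()] object (then `y` and `validation` default to
#'   the task's training labels and test split).
#' @param y class labels (factor or integer), one per sample.
#' @param arch architecture string such as `"r20-fc10-fc2"` (see
#'   [parse_arch()]); the last layer width must equal the number of
#'   classes.
#' @param epochs training epochs (default 50).
#' @param batch_size mini-batch size (default 32).
#' @param lr learning rate (default 1e-2).
#' @param optimizer `"adamw"` (default), `"adam"` or `"sgd"`.
#' @param lambda_s spiking regularization coefficient (default 1e-7).
#' @param lambda_w synaptic l1 coefficient; defaults to 1e-2 when rewiring
#'   is enabled, otherwise 0.
#' @param rewire enable synaptic pruning and distance-gated growth.
#' @param rewire_opts options forwarded to [rewire_state()].
#' @param u_th spiking threshold (default 1).
#' @param alpha surrogate-gradient shape constant (default 0.7).
#' @param tau_init initial leak coefficient (default 0.5).
#' @param tau_shared share one leak value per layer.
#' @param self_synapse allow recurrent self-connections.
#' @param validation optional list `list(x = , y = )` scored each epoch.
#' @param seed integer seed; the whole fit is reproducible given
#'   (arguments, seed).
#' @param verbose print one line per epoch.
#' @param keep_data store the training data in the fit (needed by
#'   [residuals.bpsr()] without new data; default `TRUE`).
#' @return an object of class `"bpsr"`; see [predict.bpsr()],
#'   [summary.bpsr()], [plot.bpsr()], [coef.bpsr()], [simulate.bpsr()].
#' @examples
#' task <- make_synthetic_task("rate_clusters", n_train = 60, n_test = 30,
#'                             seed = 7)
#' fit <- bpsr(task, arch = "r10-fc5-fc2", epochs = 3, seed = 7)
#' predict(fit, task$x_test[, , 1:5])
#' @export
bpsr <- function(x, y = NULL, arch, epochs = 50, batch_size = 32,
                 lr = 1e-2, optimizer = c("adamw", "adam", "sgd"),
                 lambda_s = 1e-7, lambda_w = if (rewire) 1e-2 else 0,
                 rewire = FALSE, rewire_opts = list(), u_th = 1,
                 alpha = 0.7, tau_init = 0.5, tau_shared = FALSE,
                 self_synapse = FALSE, validation = NULL, seed = NULL,
                 verbose = FALSE, keep_data = TRUE) {
  cl <- match.call()
  optimizer <- match.arg(optimizer)
  if (inherits(x, "bpsr_task")) {
    if (is.null(validation) && length(x$y_test))
      validation <- list(x = x$x_test, y = x$y_test)
    y <- x$y_train
    x <- x$x_train
  }
  if (is.null(y)) stop("labels y are required")
  y <- as.factor(y)
  n <- dim(x)[3]
  T_ <- dim(x)[2]
  if (length(y) != n) stop("length(y) must match the number of samples")
  arch_df <- parse_arch(arch)
  n_class <- nlevels(y)
  if (utils::tail(arch_df$size, 1) != n_class)
    stop("last layer width (", utils::tail(arch_df$size, 1),
         ") must equal the number of classes (", n_class, ")")

  if (!is.null(seed)) set.seed(seed)
  network <- init_network(arch_df, n_in = dim(x)[1], u_th = u_th,
                          tau_init = tau_init, tau_shared = tau_shared,
                          self_synapse = self_synapse)
  state <- training_state(network, lr = lr, optimizer = optimizer,
                          lambda_s = lambda_s, lambda_w = lambda_w,
                          alpha = alpha, rewire = rewire,
                          rewire_opts = rewire_opts)
  y_int <- as.integer(y)
  history <- vector("list", epochs)
  high_fr_epochs <- 0L
  diverged <- FALSE
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_stats <- c(ce = 0, spike_pen = 0, weight_pen = 0, total = 0,
                  fr = 0, fr_hidden = 0, acc = 0)
    n_batches <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      res <- train_step(state, x[, , idx, drop = FALSE],
                        y_int[idx])
      state <- res$state
      ep_stats <- ep_stats + c(res$loss$cross_entropy, res$loss$spike_penalty,
                               res$loss$weight_penalty, res$loss$total,
                               res$loss$fr, res$loss$fr_hidden,
                               res$loss$accuracy)
      n_batches <- n_batches + 1L
    }
    ep_stats <- ep_stats / n_batches
    val_acc <- NA_real_
    if (!is.null(validation))
      val_acc <- evaluate_network(state$network, validation$x,
                                  validation$y)$accuracy
    history[[ep]] <- data.frame(
      epoch = ep, ce = ep_stats[["ce"]], spike_pen = ep_stats[["spike_pen"]],
      weight_pen = ep_stats[["weight_pen"]], total = ep_stats[["total"]],
      fr = ep_stats[["fr"]], fr_hidden = ep_stats[["fr_hidden"]],
      train_accuracy = ep_stats[["acc"]], val_accuracy = val_acc,
      synapse_count = synapse_count(state$network))
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.3f  val %.3f  FR %.3f  synapses %d",
        ep, ep_stats[["total"]], ep_stats[["acc"]], val_acc,
        ep_stats[["fr"]], synapse_count(state$network)))
    high_fr_epochs <- if (ep_stats[["fr"]] >= 0.99) high_fr_epochs + 1L else 0L
    if (high_fr_epochs >= 3L) {
      diverged <- TRUE
      warning("sustained near-saturation firing rate: ",
              "network flagged as diverged (threshold likely too high)")
      break
    }
  }

  structure(list(
    layers = state$network, arch = arch, levels = levels(y), T = T_,
    history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
    rewire_log = state$rewire_log,
    hyper = list(epochs = epochs, batch_size = batch_size, lr = lr,
                 optimizer = optimizer, lambda_s = lambda_s,
                 lambda_w = lambda_w, rewire = rewire,
                 rewire_opts = rewire_opts, u_th = u_th, alpha = alpha,
                 tau_init = tau_init, seed = seed),
    initial_synapses = synapse_count(network),
    diverged = diverged, quantized = NULL,
    data = if (keep_data) list(x = x, y = y) else NULL,
    validation = validation, call = cl),
    class = "bpsr")
}
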