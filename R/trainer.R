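#' Create a training state for step-wise optimization
#'
#' Bundles a network with its optimizer and (optionally) per-layer rewiring
#' state so that [train_step()] can be applied batch by batch. [bpsr()] is
#' the high-level driver built on these two functions.
#'
#' @param network list of layers from [init_network()].
#' @param lr learning rate (default 1e-2).
#' @param optimizer `"adamw"` (default), `"adam"` or `"sgd"`.
#' @param lambda_s spiking (l2) regularization coefficient.
#' @param lambda_w synaptic (l1) regularization coefficient.
#' @param alpha surrogate-gradient shape constant.
#' @param rewire enable the pruning/growth mechanism.
#' @param rewire_opts named arguments forwarded to [rewire_state()]
#'   (thresholds, momentum coefficient, interval, ...).
#' @param weight_decay decoupled weight decay for AdamW (default 0).
#' @return object of class `"bpsr_training_state"`.
#' @export
training_state <- function(network, lr = 1e-2,
                           optimizer = c("adamw", "adam", "sgd"),
                           lambda_s = 0, lambda_w = 0, alpha = 0.7,
                           rewire = FALSE, rewire_opts = list(),
                           weight_decay = 0) {
  optimizer <- match.arg(optimizer)
  if (lambda_s < 0 || lambda_w < 0)
    stop("regularization coefficients must be non-negative")
  rew <- if (rewire)
    lapply(network, function(p) do.call(rewire_state, c(list(p), rewire_opts)))
  else NULL
  structure(list(
    network = network,
    opt = opt_init(network, optimizer, lr = lr, weight_decay = weight_decay,
                   l1_decay = lambda_w),
    rewire = rew, lambda_s = lambda_s, lambda_w = lambda_w, alpha = alpha,
    step = 0L,
    rewire_log = data.frame(step = integer(), layer = integer(),
                            pruned = integer(), grown = integer(),
                            synapses = integer())),
    class = "bpsr_training_state")
}

#' One training step on a mini-batch
#'
#' Runs the full update pipeline of sparsity-regularized spiking
#' backpropagation: batched forward pass through all layers, spike-count
#' softmax readout, cross-entropy + regularization loss, backward potential
#' recursion and parameter gradients layer by layer (the input-spike
#' gradient of each layer, plus the spiking-penalty term, becomes the spike
#' gradient of the layer below), gradient-momentum update and rewiring at
#' its interval, optimizer step, and parameter clamping (weights and bias
#' to \[-u_th, u_th\], tau to \[0, 1\]; masked synapses stay exactly zero).
#'
#' Cross-entropy and the spiking penalty are averaged over the batch; the
#' synaptic l1 term enters once per batch (it does not depend on the data).
#' A non-finite loss aborts with a divergence diagnostic.
#'
#' @param state a [training_state()].
#' @param x_batch spike array `channels x T x B` (a single `channels x T`
#'   matrix is treated as B = 1).
#' @param y_batch one-hot matrix `C x B`, or integer/factor class labels.
#' @return list with the updated `state` and `loss` (a `"bpsr_loss"`
#'   report augmented with the batch firing rates).
#' @export
train_step <- function(state, x_batch, y_batch) {
  network <- state$network
  if (is.matrix(x_batch)) x_batch <- array(x_batch, c(dim(x_batch), 1L))
  B <- dim(x_batch)[3]
  n_class <- nrow(network[[length(network)]]$w_in)
  if (!is.matrix(y_batch)) {
    y_idx <- as.integer(y_batch)
    y_batch <- matrix(0, n_class, B)
    y_batch[cbind(y_idx, seq_len(B))] <- 1
  }
  T_ <- dim(x_batch)[2]
  L <- length(network)
  k <- 10 / T_

  acts <- forward_network_batch(network, x_batch)

  counts <- apply(acts[[L]]$S, 3, rowSums)          # C x B spike counts
  logits <- k * matrix(counts, n_class, B)
  zmax <- apply(logits, 2, max)
  ez <- exp(sweep(logits, 2, zmax))
  probs <- sweep(ez, 2, colSums(ez), "/")
  ce <- -mean(log(pmax(colSums(probs * y_batch), .Machine$double.xmin)))
  hidden_spikes <- if (L > 1)
    sum(vapply(acts[-L], function(a) sum(a$S), 0)) else 0
  spike_pen <- state$lambda_s / 2 * hidden_spikes / B
  weight_pen <- state$lambda_w * sum(vapply(network, function(p)
    sum(abs(p$w_in)) + sum(abs(p$w_rec)), 0))
  total <- ce + spike_pen + weight_pen
  if (!is.finite(total))
    stop("training diverged: non-finite loss at step ", state$step + 1L,
         call. = FALSE)

  # output-layer spike gradient (p - y)/B, identical at every timestep
  d_s <- array(0, dim(acts[[L]]$S))
  err <- (probs - y_batch) / B
  for (t in seq_len(T_)) d_s[, t, ] <- err

  state$step <- state$step + 1L
  # data gradients only; the l1 term is added for the rewiring momentum
  # (full synaptic gradient) and applied decoupled inside the optimizer
  grads <- vector("list", L)
  for (l in L:1) {
    p <- network[[l]]
    d_u <- potential_grad_batch(d_s, acts[[l]]$U, acts[[l]]$S, p,
                                alpha = state$alpha)
    x_in <- if (l == 1) x_batch else acts[[l - 1]]$S
    grads[[l]] <- parameter_grads_batch(d_u, acts[[l]]$U, acts[[l]]$S, x_in,
                                        p, lambda_w = 0)
    if (l > 1)
      d_s <- grads[[l]]$d_x + (state$lambda_s / B) * acts[[l - 1]]$S
  }

  for (l in seq_len(L)) {
    if (!is.null(state$rewire)) {
      full <- grads[[l]]
      full$d_w_in <- full$d_w_in + state$lambda_w * sign(network[[l]]$w_in)
      full$d_w_rec <- full$d_w_rec + state$lambda_w * sign(network[[l]]$w_rec)
      state$rewire[[l]] <- update_momentum(state$rewire[[l]], full)
      if (state$step %% state$rewire[[l]]$interval == 0L) {
        res <- apply_rewire(network[[l]], grads[[l]], state$rewire[[l]])
        network[[l]] <- res$params
        grads[[l]] <- res$grads
        state$rewire_log <- rbind(state$rewire_log, data.frame(
          step = state$step, layer = l, pruned = res$pruned,
          grown = res$grown,
          synapses = sum(network[[l]]$mask_in) + sum(network[[l]]$mask_rec)))
        next
      }
    }
    grads[[l]] <- mask_gradients(grads[[l]], network[[l]])
  }

  upd <- opt_step(state$opt, network, grads)
  state$opt <- upd$opt
  # re-superimpose the masks: optimizer momentum must not revive pruned
  # synapses
  state$network <- lapply(upd$network, function(p) {
    p$w_in <- p$w_in * p$mask_in
    p$w_rec <- p$w_rec * p$mask_rec
    p
  })

  loss <- structure(list(
    cross_entropy = ce, spike_penalty = spike_pen,
    weight_penalty = weight_pen, total = total, probs = probs,
    accuracy = mean(apply(probs, 2, which.max) ==
                      apply(y_batch, 2, which.max)),
    fr = sum(vapply(acts, function(a) sum(a$S), 0)) /
      sum(vapply(acts, function(a) length(a$S), 0)),
    fr_hidden = if (L > 1) hidden_spikes /
      sum(vapply(acts[-L], function(a) length(a$S), 0)) else NA_real_),
    class = "bpsr_loss")
  list(state = state, loss = loss)
}

#' Evaluate a network on a labelled spike dataset
#'
#' Deterministic inference metrics: classification accuracy (argmax of the
#' spike-count softmax readout), firing rate over all non-input layers and
#' over hidden layers only, existing-synapse count, mean spikes per sample,
#' and the normalized event-driven energy per sample (see [count_energy()]).
#'
#' @param network list of layers or fitted `bpsr` object.
#' @param x spike array `channels x T x n`.
#' @param y labels (factor or integer).
#' @param batch_size forward-pass batch size.
#' @return list of metrics.
#' @export
evaluate_network <- function(network, x, y, batch_size = 128) {
  if (inherits(network, "bpsr")) network <- network$layers
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  n <- dim(x)[3]
  if (n == 0L) stop("empty evaluation set")
  y <- as.integer(y)
  L <- length(network)
  correct <- 0; spk <- 0; spk_hidden <- 0; acc_ops <- 0; bias_ops <- 0
  size <- sum(vapply(network, function(p) nrow(p$w_in), 0)) * dim(x)[2]
  size_hidden <- if (L > 1)
    sum(vapply(network[-L], function(p) nrow(p$w_in), 0)) * dim(x)[2] else 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    acts <- forward_network_batch(network, x[, , idx, drop = FALSE])
    counts <- apply(acts[[L]]$S, 3, rowSums)
    pred <- apply(matrix(counts, ncol = length(idx)), 2, which.max)
    correct <- correct + sum(pred == y[idx])
    spk <- spk + sum(vapply(acts, function(a) sum(a$S), 0))
    if (L > 1)
      spk_hidden <- spk_hidden + sum(vapply(acts[-L], function(a) sum(a$S), 0))
    # event-driven op counts (aggregate over the batch)
    input <- x[, , idx, drop = FALSE]
    for (l in seq_len(L)) {
      p <- network[[l]]
      T_ <- dim(acts[[l]]$S)[2]
      src_spikes <- rowSums(input)
      acc_ops <- acc_ops + sum(colSums(p$mask_in) * src_spikes)
      if (T_ > 1L && any(p$mask_rec))
        acc_ops <- acc_ops + sum(colSums(p$mask_rec) *
                                   rowSums(acts[[l]]$S[, -T_, , drop = FALSE]))
      bias_ops <- bias_ops + length(acts[[l]]$S)
      input <- acts[[l]]$S
    }
  }
  quantized <- !is.null(network[[1]]$quant)
  energy <- if (quantized) (acc_ops + bias_ops) * 0.2
            else (acc_ops + bias_ops) * 1 + bias_ops * 4
  list(accuracy = correct / n,
       fr = spk / (size * n),
       fr_hidden = if (L > 1) spk_hidden / (size_hidden * n) else NA_real_,
       synapse_count = synapse_count(network),
       spikes_per_sample = spk / n,
       energy = energy / n)
}
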