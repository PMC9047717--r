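#' @export
print.bpsr <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("Sparse spiking network classifier (LIF, surrogate-gradient BPTT)\n")
  cat(sprintf("  architecture: %s   T = %d   classes: %s\n",
              x$arch, x$T, paste(x$levels, collapse = ", ")))
  cat(sprintf("  epochs: %d   final loss %.4f   train accuracy %.3f\n",
              nrow(x$history), last$total, last$train_accuracy))
  if (!is.na(last$val_accuracy))
    cat(sprintf("  validation accuracy %.3f\n", last$val_accuracy))
  cat(sprintf("  firing rate %.3f   synapses %d/%d%s\n",
              last$fr, last$synapse_count, x$initial_synapses,
              if (isTRUE(x$diverged)) "   [DIVERGED]" else ""))
  if (!is.null(x$quantized))
    cat(sprintf("  quantized to %d-bit fixed point\n", x$quantized))
  invisible(x)
}

#' Summary of a fitted spiking network
#'
#' @param object fitted `bpsr` object.
#' @param ... unused.
#' @return a `"summary.bpsr"` list: the final training metrics, per-layer
#'   synapse counts and leak statistics, and the loss decomposition.
#' @export
summary.bpsr <- function(object, ...) {
  last <- object$history[nrow(object$history), ]
  per_layer <- data.frame(
    layer = seq_along(object$layers),
    type = vapply(object$layers, `[[`, "", "type"),
    neurons = vapply(object$layers, function(l) nrow(l$w_in), 0L),
    synapses = synapse_count(object$layers, per_layer = TRUE),
    density = synapse_count(object$layers, per_layer = TRUE) /
      vapply(object$layers, function(l)
        length(l$w_in) + if (l$type == "recurrent") length(l$w_rec) else 0L,
        0L),
    tau_mean = vapply(object$layers, function(l) mean(l$tau), 0))
  structure(list(arch = object$arch, final = last, per_layer = per_layer,
                 hyper = object$hyper, diverged = object$diverged,
                 rewire_events = nrow(object$rewire_log)),
            class = "summary.bpsr")
}

#' @export
print.summary.bpsr <- function(x, ...) {
  cat("Sparse spiking network:", x$arch, "\n\n")
  cat(sprintf(
    "Final epoch: loss %.4f (CE %.4f, spikes %.3g, weights %.3g)\n",
    x$final$total, x$final$ce, x$final$spike_pen, x$final$weight_pen))
  cat(sprintf("Train accuracy %.3f   firing rate %.3f (hidden %.3f)\n\n",
              x$final$train_accuracy, x$final$fr, x$final$fr_hidden))
  print(x$per_layer, row.names = FALSE)
  cat(sprintf("\nlambda_s = %g, lambda_w = %g, lr = %g, optimizer = %s\n",
              x$hyper$lambda_s, x$hyper$lambda_w, x$hyper$lr,
              x$hyper$optimizer))
  if (x$rewire_events > 0)
    cat(sprintf("%d rewiring events logged\n", x$rewire_events))
  invisible(x)
}

#' Extract network parameters
#'
#' @param object fitted `bpsr` object.
#' @param ... unused.
#' @return list with one element per layer holding `w_in`, `w_rec`, `bias`
#'   and `tau`.
#' @export
coef.bpsr <- function(object, ...) {
  lapply(object$layers, function(l)
    list(w_in = l$w_in, w_rec = l$w_rec, bias = l$bias, tau = l$tau))
}

#' Predict from a fitted spiking network
#'
#' Runs the deterministic forward pass and the spike-count softmax readout.
#'
#' @param object fitted `bpsr` object.
#' @param newdata spike array `channels x T x n` (or one `channels x T`
#'   matrix).
#' @param type `"class"` (default), `"prob"` for the n x C probability
#'   matrix, or `"count"` for raw output spike counts.
#' @param ... unused.
#' @return factor of predicted classes, or a numeric matrix.
#' @export
predict.bpsr <- function(object, newdata,
                         type = c("class", "prob", "count"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- array(newdata, c(dim(newdata), 1L))
  n <- dim(newdata)[3]
  L <- length(object$layers)
  acts <- forward_network_batch(object$layers, newdata)
  counts <- matrix(apply(acts[[L]]$S, 3, rowSums),
                   nrow = length(object$levels))
  if (type == "count") return(t(counts))
  k <- 10 / dim(newdata)[2]
  logits <- k * counts
  ez <- exp(sweep(logits, 2, apply(logits, 2, max)))
  probs <- t(sweep(ez, 2, colSums(ez), "/"))
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' Response residuals of a fitted spiking network
#'
#' One-hot labels minus predicted class probabilities (the negative of the
#' error signal driving the output-layer spike gradient).
#'
#' @param object fitted `bpsr` object.
#' @param newdata,y optional evaluation data; defaults to the stored
#'   training set.
#' @param ... unused.
#' @return n x C matrix of residuals.
#' @export
residuals.bpsr <- function(object, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data))
      stop("fit stores no data; supply newdata and y")
    newdata <- object$data$x
    y <- object$data$y
  }
  probs <- predict(object, newdata, type = "prob")
  y_idx <- as.integer(factor(y, levels = object$levels))
  onehot <- matrix(0, nrow(probs), ncol(probs))
  onehot[cbind(seq_len(nrow(probs)), y_idx)] <- 1
  onehot - probs
}

#' Simulate spike responses of a fitted network
#'
#' Runs the network forward and returns the full layer traces (membrane
#' potentials and spikes). If `values` (channel intensities in \[0, 1\])
#' are given instead of spike trains, each of the `nsim` repetitions draws
#' a fresh Bernoulli rate encoding, simulating stochastic presentations of
#' the same stimulus; with spike-train `newdata` the dynamics are
#' deterministic and `nsim` repetitions are identical.
#'
#' @param object fitted `bpsr` object.
#' @param nsim number of simulated presentations.
#' @param seed optional seed for the stochastic encoding.
#' @param newdata one spike train `channels x T`.
#' @param values channel intensity vector to rate-encode per repetition.
#' @param ... unused.
#' @return list of length `nsim`; each element is the list of per-layer
#'   `"bpsr_trace"` objects.
#' @export
simulate.bpsr <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                          values = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata) && is.null(values))
    stop("supply a spike train (newdata) or intensities (values)")
  lapply(seq_len(nsim), function(i) {
    x <- if (!is.null(values)) rate_encode(values, object$T) else newdata
    traces <- vector("list", length(object$layers))
    for (l in seq_along(object$layers)) {
      traces[[l]] <- lif_forward(object$layers[[l]], x)
      x <- traces[[l]]$spikes
    }
    traces
  })
}

#' Training-history plots of a fitted spiking network
#'
#' Four panels: total loss, train/validation accuracy, firing rate, and
#' existing-synapse count, against the training epoch.
#'
#' @param x fitted `bpsr` object.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.bpsr <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Total loss", ...)
  graphics::plot(h$epoch, h$train_accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (any(!is.na(h$val_accuracy)))
    graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  graphics::plot(h$epoch, h$fr, type = "l", xlab = "epoch",
                 ylab = "firing rate", main = "Firing rate", ...)
  if (any(!is.na(h$fr_hidden)))
    graphics::lines(h$epoch, h$fr_hidden, lty = 2)
  graphics::plot(h$epoch, h$synapse_count, type = "l", xlab = "epoch",
                 ylab = "synapses", main = "Synapse count", ...)
  invisible(x)
}
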