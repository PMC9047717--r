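#' Spike-count softmax readout
#'
#' The class logits are the output-layer spike counts scaled by
#' `k = 10 / T`, so that a neuron spiking at every timestep contributes
#' logit 10 regardless of the window length, and doubling T at fixed spike
#' *rates* leaves the logits unchanged. Probabilities come from a
#' numerically stabilized (max-subtracted) softmax.
#'
#' @param output_spikes C x T spike train of the readout layer (0/1), or a
#'   `"bpsr_trace"`.
#' @param k logit scaling factor; default `10 / T`.
#' @return probability vector of length C.
#' @export
readout_probs <- function(output_spikes, k = NULL) {
  if (inherits(output_spikes, "bpsr_trace")) output_spikes <- output_spikes$spikes
  output_spikes <- as.matrix(output_spikes)
  if (nrow(output_spikes) < 2L)
    stop("readout requires at least 2 classes")
  if (is.null(k)) k <- 10 / ncol(output_spikes)
  logits <- k * rowSums(output_spikes)
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Sparsity-regularized classification loss
#'
#' Total loss of one sample:
#' \deqn{L = -\sum_c y_c \log p_c
#'   + \frac{\lambda_s}{2} \sum_{hidden} \|s\|_2^2
#'   + \lambda_w \sum_{layers} \|w\|_1}
#' The spiking penalty covers every layer except the output layer (to
#' protect classification accuracy); since spikes are boolean its value is
#' `lambda_s / 2` times the hidden spike count. The synaptic penalty covers
#' the inter- and intra-layer weights of all layers.
#'
#' @param traces list of layer traces ordered input to output.
#' @param params list of layers (same order).
#' @param labels one-hot label vector, or a class index.
#' @param lambda_s spiking (l2) regularization coefficient, >= 0.
#' @param lambda_w synaptic (l1) regularization coefficient, >= 0.
#' @param k readout scaling, see [readout_probs()].
#' @return object of class `"bpsr_loss"`: list with `cross_entropy`,
#'   `spike_penalty`, `weight_penalty`, `total` and the probability vector
#'   `probs`.
#' @export
total_loss <- function(traces, params, labels, lambda_s = 0, lambda_w = 0,
                       k = NULL) {
  if (lambda_s < 0 || lambda_w < 0)
    stop("regularization coefficients must be non-negative")
  probs <- readout_probs(traces[[length(traces)]], k = k)
  if (length(labels) == 1L)
    labels <- as.numeric(seq_along(probs) == labels)
  ce <- -sum(labels * log(pmax(probs, .Machine$double.xmin)))
  hidden <- traces[-length(traces)]
  spike_pen <- lambda_s / 2 * sum(vapply(hidden, function(tr) sum(tr$spikes), 0))
  weight_pen <- lambda_w * sum(vapply(params, function(p)
    sum(abs(p$w_in)) + sum(abs(p$w_rec)), 0))
  structure(list(cross_entropy = ce, spike_penalty = spike_pen,
                 weight_penalty = weight_pen,
                 total = ce + spike_pen + weight_pen, probs = probs),
            class = "bpsr_loss")
}

#' @export
print.bpsr_loss <- function(x, ...) {
  cat(sprintf("loss %.5f = CE %.5f + spikes %.3g + weights %.3g\n",
              x$total, x$cross_entropy, x$spike_penalty, x$weight_penalty))
  invisible(x)
}
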