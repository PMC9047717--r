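#' Post-training fixed-point quantization of layer parameters
#'
#' Rounds weights and biases to n-bit fixed point with 1 sign bit and
#' `n_bits - 1` fraction bits: nearest multiple of `2^-(n_bits-1)`
#' (round-half-to-even), saturating at `+/-(1 - 2^-(n_bits-1))`. This
#' matches the clamp contract |w| <= u_th = 1, and lets synaptic
#' accumulation run in fixed-point addition. Leak coefficients are rounded
#' to powers of two, `tau ~ 2^-m` with `m = round(-log2(tau))`, so the leak
#' multiplication becomes an m-bit right shift (`tau = 0` maps to an
#' immediate full reset, `tau = 1` to m = 0). Exact zeros stay exactly zero
#' and masks are untouched, so sparsity is preserved.
#'
#' @param params a [layer_params()] object (trained, clamped).
#' @param n_bits total word width including the sign bit, >= 2.
#' @return the quantized layer; the chosen spec (bit widths and per-neuron
#'   shifts `tau_shift`, `Inf` marking full reset) is stored in
#'   `$quant`.
#' @export
quantize_params <- function(params, n_bits = 8) {
  if (n_bits < 2) stop("n_bits must be at least 2")
  frac_bits <- n_bits - 1L
  step <- 2^-frac_bits
  lim <- 1 - step
  fx <- function(w) pmin(pmax(round(w / step) * step, -lim), lim)
  params$w_in <- fx(params$w_in) * params$mask_in
  params$w_rec <- fx(params$w_rec) * params$mask_rec
  params$bias <- fx(params$bias)
  m <- ifelse(params$tau > 0, pmax(round(-log2(params$tau)), 0), Inf)
  params$tau <- ifelse(is.finite(m), 2^-m, 0)
  params$quant <- list(n_bits = as.integer(n_bits), frac_bits = frac_bits,
                       tau_shift = m)
  params
}

#' Quantize every layer of a network
#'
#' @param network list of layers or fitted `bpsr` object.
#' @param n_bits word width passed to [quantize_params()].
#' @return object of the same kind with quantized layers.
#' @export
quantize_network <- function(network, n_bits = 8) {
  if (inherits(network, "bpsr")) {
    network$layers <- lapply(network$layers, quantize_params, n_bits = n_bits)
    network$quantized <- as.integer(n_bits)
    return(network)
  }
  lapply(network, quantize_params, n_bits = n_bits)
}

#' Parameter deviation introduced by quantization
#'
#' Maximum and mean absolute deviation over weights and biases of congruent
#' layers (or lists of layers). For non-saturated entries the maximum is
#' bounded by half a quantization step, `2^-(frac_bits+1)`; entries at the
#' clamp boundary `|w| = u_th = 1` saturate to `1 - 2^-frac_bits` and carry
#' a full-step deviation, reported separately as `max_nonsaturated` vs
#' `max`.
#'
#' @param params original layer or network.
#' @param params_q quantized counterpart (its `$quant` spec, when present,
#'   defines the saturation boundary).
#' @return list with `max`, `mean` and `max_nonsaturated` absolute
#'   deviation.
#' @export
quantization_error <- function(params, params_q) {
  if (inherits(params, "bpsr_layer")) { params <- list(params); params_q <- list(params_q) }
  lim <- if (!is.null(params_q[[1]]$quant))
    1 - 2^-params_q[[1]]$quant$frac_bits else Inf
  devs <- unlist(lapply(seq_along(params), function(i) {
    a <- params[[i]]; b <- params_q[[i]]
    abs(c(a$w_in - b$w_in, a$w_rec - b$w_rec, a$bias - b$bias))
  }))
  orig <- unlist(lapply(params, function(a) abs(c(a$w_in, a$w_rec, a$bias))))
  nonsat <- devs[orig <= lim]
  list(max = max(devs), mean = mean(devs),
       max_nonsaturated = if (length(nonsat)) max(nonsat) else 0)
}

#' Event-driven operation and energy accounting of an inference
#'
#' Counts the arithmetic work of one forward pass the way neuromorphic
#' accounting does: one accumulate per spike per existing outgoing synapse
#' (event-driven, so silent channels cost nothing), one bias add and one
#' leak multiplication per neuron-timestep. Recurrent spikes at the final
#' timestep are never consumed and are not counted. The counts convert to a
#' normalized energy with the cost model (relative to a floating-point
#' add): FL-ADD 1, FL-MUL 4, FI-ADD 0.2, BIT-OP 0. In a quantized network
#' the accumulates become fixed-point adds and the power-of-two leak becomes
#' a bit shift.
#'
#' @param traces list of layer traces from the forward pass.
#' @param params list of layers (same order).
#' @param x the encoded input spike train that entered layer 1.
#' @param quantized count with fixed-point costs (default: taken from the
#'   layers' `$quant` field).
#' @param cost_model named costs `fl_add`, `fl_mul`, `fi_add`, `bit_op`.
#' @return normalized energy (scalar) with attribute `"counts"`, the
#'   breakdown `c(acc, bias_add, leak_mul)`.
#' @export
count_energy <- function(traces, params, x,
                         quantized = NULL,
                         cost_model = c(fl_add = 1, fl_mul = 4,
                                        fi_add = 0.2, bit_op = 0)) {
  if (is.null(quantized))
    quantized <- !is.null(params[[1]]$quant)
  stopifnot(all(c("fl_add", "fl_mul", "fi_add", "bit_op") %in% names(cost_model)))
  acc <- 0; bias_add <- 0; leak_mul <- 0
  input <- as.matrix(x)
  for (l in seq_along(params)) {
    p <- params[[l]]
    tr <- traces[[l]]
    T_ <- ncol(tr$spikes)
    # inter-layer events: spikes of the presynaptic train times the number
    # of existing synapses leaving each source channel
    acc <- acc + sum(colSums(p$mask_in) * rowSums(input))
    if (T_ > 1L && any(p$mask_rec))
      acc <- acc + sum(colSums(p$mask_rec) *
                         rowSums(tr$spikes[, -T_, drop = FALSE]))
    bias_add <- bias_add + length(tr$spikes)
    leak_mul <- leak_mul + length(tr$spikes)
    input <- tr$spikes
  }
  energy <- if (quantized) {
    (acc + bias_add) * cost_model[["fi_add"]] + leak_mul * cost_model[["bit_op"]]
  } else {
    (acc + bias_add) * cost_model[["fl_add"]] + leak_mul * cost_model[["fl_mul"]]
  }
  structure(energy, counts = c(acc = acc, bias_add = bias_add,
                               leak_mul = leak_mul))
}
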