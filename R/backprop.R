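#' Gaussian surrogate derivative of the spike threshold
#'
#' The Heaviside spike function has a Dirac derivative, so backpropagation
#' substitutes a unit-mass Gaussian:
#' \deqn{g'(x) = \frac{\alpha}{\sqrt{\pi}} e^{-\alpha^2 x^2}}
#' which integrates to 1 for every shape constant `alpha` and is maximal at
#' the threshold (x = 0). The normalization constant can be overridden via
#' `norm_const` for alternative conventions.
#'
#' @param x numeric vector/matrix of potential margins (u - u_th).
#' @param alpha positive shape constant (default 0.7).
#' @param norm_const normalization constant; default `alpha / sqrt(pi)`
#'   (unit mass).
#' @return surrogate derivative values, strictly positive, same shape as `x`.
#' @export
surrogate_deriv <- function(x, alpha = 0.7, norm_const = alpha / sqrt(pi)) {
  if (alpha <= 0) stop("alpha must be positive")
  norm_const * exp(-(alpha * x)^2)
}

#' Loss gradient w.r.t. output-layer spikes
#'
#' With the spike-count softmax readout, the derivative of the cross-entropy
#' loss w.r.t. every output spike is simply `p_i - y_i`, identical at every
#' timestep (the readout sums spikes over the window).
#'
#' @param probs predicted class probabilities (length C, sums to 1).
#' @param labels one-hot label vector (length C).
#' @param T time window length.
#' @return C x T matrix of spike gradients.
#' @export
output_layer_spike_grad <- function(probs, labels, T) {
  if (abs(sum(probs) - 1) > 1e-6)
    stop("probs must be a probability vector")
  matrix(probs - labels, length(probs), T)
}

#' Loss gradient w.r.t. hidden-layer spikes
#'
#' The spike gradient of a hidden layer is the input-spike gradient passed
#' down from the following layer plus the derivative of the l2
#' spiking-sparsity penalty, `lambda_s * s`, which is zero wherever the
#' neuron did not spike.
#'
#' @param d_x_next N x T input-spike gradient backpropagated by the layer
#'   above.
#' @param spikes this layer's own N x T spike train (0/1).
#' @param lambda_s spiking-regularization coefficient.
#' @return N x T spike gradient.
#' @export
hidden_layer_spike_grad <- function(d_x_next, spikes, lambda_s = 0) {
  if (!identical(dim(as.matrix(d_x_next)), dim(as.matrix(spikes))))
    stop("hidden_layer_spike_grad: shape mismatch")
  d_x_next + lambda_s * spikes
}

#' Backward-in-time potential gradient, flat layer
#'
#' One O(T) backward pass per neuron:
#' at t = T, `d_u = d_s * g'(u - u_th)`; at t < T,
#' `d_u^t = d_s^t * g'(u^t - u_th) + d_u^{t+1} * tau * (1 - s^t)`.
#' The gating dependency of u^t on s^{t-1} carries no information and is
#' deliberately excluded from the backward graph.
#'
#' @param d_s N x T gradient of the loss w.r.t. this layer's spikes.
#' @param trace `"bpsr_trace"` from [lif_forward()].
#' @param params the layer.
#' @param alpha,norm_const surrogate shape, see [surrogate_deriv()].
#' @return N x T matrix of potential gradients.
#' @export
potential_grad_flat <- function(d_s, trace, params, alpha = 0.7,
                                norm_const = alpha / sqrt(pi)) {
  if (any(!is.finite(d_s))) stop("non-finite spike gradient")
  g <- surrogate_deriv(trace$potentials - params$u_th, alpha, norm_const)
  T_ <- ncol(g)
  d_u <- matrix(0, nrow(g), T_)
  d_u[, T_] <- d_s[, T_] * g[, T_]
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    d_u[, t] <- d_s[, t] * g[, t] +
      d_u[, t + 1L] * params$tau * (1 - trace$spikes[, t])
  }
  d_u
}

#' Backward-in-time potential gradient, recurrent layer
#'
#' As [potential_grad_flat()] with the intra-layer term: for t < T the
#' direct error is augmented by the next-timestep potential gradients routed
#' back through the transposed recurrent weights,
#' `[d_s^t + W_rec' d_u^{t+1}] * g'(u^t - u_th) + d_u^{t+1} * tau * (1 - s^t)`.
#' With `w_rec = 0` this reduces exactly to the flat recursion.
#'
#' @inheritParams potential_grad_flat
#' @return N x T matrix of potential gradients.
#' @export
potential_grad_recurrent <- function(d_s, trace, params, alpha = 0.7,
                                     norm_const = alpha / sqrt(pi)) {
  if (any(!is.finite(d_s))) stop("non-finite spike gradient")
  g <- surrogate_deriv(trace$potentials - params$u_th, alpha, norm_const)
  T_ <- ncol(g)
  d_u <- matrix(0, nrow(g), T_)
  d_u[, T_] <- d_s[, T_] * g[, T_]
  w_rec_t <- t(params$w_rec)
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    d_u[, t] <- (d_s[, t] + as.vector(w_rec_t %*% d_u[, t + 1L])) * g[, t] +
      d_u[, t + 1L] * params$tau * (1 - trace$spikes[, t])
  }
  d_u
}

#' Gradients of the loss w.r.t. layer parameters and input spikes
#'
#' Given the potential gradients from the appropriate backward recursion,
#' accumulates over the time window (initial state u^0 = s^0 = 0):
#' \itemize{
#'   \item `d_x[j, t] = sum_i d_u[i, t] w_in[i, j]`
#'   \item `d_w_in[i, j] = sum_t d_u[i, t] x[j, t] + lambda_w sign(w)`
#'   \item `d_bias[i] = sum_t d_u[i, t]`
#'   \item `d_tau[i] = sum_t d_u[i, t] u[i, t-1] (1 - s[i, t-1])`
#'   \item `d_w_rec[i, k] = sum_t d_u[i, t] s[k, t-1] + lambda_w sign(w)`
#' }
#' `sign(0) = 0`, so pruned (exactly zero) weights receive no l1 push. The
#' returned gradients are *not* masked; masking is a separate step of the
#' rewiring pass (see [apply_rewire()] and [mask_gradients()]).
#' For `tau_shared` layers the tau gradient is summed across the layer and
#' broadcast back.
#'
#' @param d_u N x T potential gradients.
#' @param trace forward trace of this layer.
#' @param x N_in x T input spike train seen by this layer.
#' @param params the layer.
#' @param lambda_w synaptic l1 regularization coefficient.
#' @return list (gradient bundle) with `d_x`, `d_w_in`, `d_w_rec`, `d_bias`,
#'   `d_tau`.
#' @export
parameter_grads <- function(d_u, trace, x, params, lambda_w = 0) {
  x <- as.matrix(x)
  T_ <- ncol(d_u)
  if (ncol(x) != T_ || nrow(d_u) != nrow(params$w_in) ||
      nrow(x) != ncol(params$w_in))
    stop("parameter_grads: shape mismatch")
  d_x <- t(params$w_in) %*% d_u
  d_w_in <- d_u %*% t(x) + lambda_w * sign(params$w_in)
  d_bias <- rowSums(d_u)
  if (T_ > 1L) {
    idx <- 2:T_
    prev <- idx - 1L
    d_tau <- rowSums(d_u[, idx, drop = FALSE] *
                       trace$potentials[, prev, drop = FALSE] *
                       (1 - trace$spikes[, prev, drop = FALSE]))
    d_w_rec <- d_u[, idx, drop = FALSE] %*%
      t(trace$spikes[, prev, drop = FALSE]) + lambda_w * sign(params$w_rec)
  } else {
    d_tau <- numeric(nrow(d_u))
    d_w_rec <- lambda_w * sign(params$w_rec)
  }
  if (params$tau_shared) d_tau <- rep(sum(d_tau), length(d_tau))
  list(d_x = d_x, d_w_in = d_w_in, d_w_rec = d_w_rec,
       d_bias = d_bias, d_tau = d_tau)
}

#' Zero the gradients of masked (non-existing) synapses
#'
#' @param grads gradient bundle from [parameter_grads()].
#' @param params the layer whose masks apply.
#' @return the bundle with `d_w_in`/`d_w_rec` masked.
#' @export
mask_gradients <- function(grads, params) {
  grads$d_w_in <- grads$d_w_in * params$mask_in
  grads$d_w_rec <- grads$d_w_rec * params$mask_rec
  grads
}

# ---- batched backward (internal) ------------------------------------------
# d_s, U, S: [N, T, B] arrays. Mirrors the exported single-sample recursions.
potential_grad_batch <- function(d_s, U, S, params, alpha = 0.7,
                                 norm_const = alpha / sqrt(pi)) {
  d <- dim(U); n <- d[1]; T_ <- d[2]; B <- d[3]
  g <- surrogate_deriv(U - params$u_th, alpha, norm_const)
  d_u <- array(0, d)
  d_u[, T_, ] <- matrix(d_s[, T_, ], n, B) * matrix(g[, T_, ], n, B)
  recurrent <- params$type == "recurrent"
  if (recurrent) w_rec_t <- t(params$w_rec)
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    nxt <- matrix(d_u[, t + 1L, ], n, B)
    direct <- matrix(d_s[, t, ], n, B)
    if (recurrent) direct <- direct + w_rec_t %*% nxt
    d_u[, t, ] <- direct * matrix(g[, t, ], n, B) +
      nxt * params$tau * (1 - matrix(S[, t, ], n, B))
  }
  d_u
}

# Sum parameter gradients over time and batch. Weight/bias/tau gradients are
# divided by B (batch-mean data loss); the l1 term is added once, unscaled.
parameter_grads_batch <- function(d_u, U, S, x_arr, params, lambda_w = 0) {
  d <- dim(d_u); n <- d[1]; T_ <- d[2]; B <- d[3]
  n_in <- dim(x_arr)[1]
  du_flat <- matrix(d_u, n, T_ * B)
  d_x <- array(t(params$w_in) %*% du_flat, c(n_in, T_, B))
  d_w_in <- (matrix(d_u, n, T_ * B) %*% t(matrix(x_arr, n_in, T_ * B))) / B +
    lambda_w * sign(params$w_in)
  d_bias <- rowSums(du_flat) / B
  if (T_ > 1L) {
    du_tail <- matrix(d_u[, -1L, , drop = FALSE], n, (T_ - 1L) * B)
    u_prev <- matrix(U[, -T_, , drop = FALSE], n, (T_ - 1L) * B)
    s_prev <- matrix(S[, -T_, , drop = FALSE], n, (T_ - 1L) * B)
    d_tau <- rowSums(du_tail * u_prev * (1 - s_prev)) / B
    d_w_rec <- (du_tail %*% t(s_prev)) / B + lambda_w * sign(params$w_rec)
  } else {
    d_tau <- numeric(n)
    d_w_rec <- lambda_w * sign(params$w_rec)
  }
  if (params$tau_shared) d_tau <- rep(sum(d_tau), n)
  list(d_x = d_x, d_w_in = d_w_in, d_w_rec = d_w_rec,
       d_bias = d_bias, d_tau = d_tau)
}
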