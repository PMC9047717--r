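#' One discrete-time step of a heterogeneous LIF layer
#'
#' Advances the membrane potential of every neuron in a layer by one
#' timestep:
#' \deqn{u_i^t = u_i^{t-1} \tau_i (1 - s_i^{t-1}) + \sum_j w_{ij} x_j^t +
#'       \sum_k w_{ik} s_k^{t-1} + b_i, \qquad s_i^t = [u_i^t \ge U_{th}]}
#' A spike at t-1 gates the leak term to zero (reset to the rest potential
#' 0); the threshold comparison is `>=`. All neurons update synchronously
#' from the t-1 state; recurrent input uses the previous step's spikes.
#'
#' @param params a [layer_params()] object.
#' @param u_prev membrane potentials at t-1 (length N).
#' @param s_prev spikes at t-1, 0/1 (length N).
#' @param x_t input spikes at t, 0/1 (length N_in).
#' @return list with numeric vectors `u` (potentials) and `s` (spikes, 0/1).
#' @export
lif_step <- function(params, u_prev, s_prev, x_t) {
  n <- nrow(params$w_in)
  if (length(u_prev) != n || length(s_prev) != n ||
      length(x_t) != ncol(params$w_in))
    stop("lif_step: shape mismatch between state/input and layer parameters")
  # event-driven accumulation: only spiking channels contribute, columns
  # added in channel order. This keeps the result bit-reproducible across
  # vector lengths (no BLAS reassociation) and mirrors how spike-driven
  # hardware accumulates potentials.
  u <- u_prev * params$tau * (1 - s_prev)
  for (j in which(x_t != 0)) u <- u + params$w_in[, j]
  for (k in which(s_prev != 0)) u <- u + params$w_rec[, k]
  u <- u + params$bias
  if (any(!is.finite(u)))
    stop("lif_step: non-finite membrane potential (neuron ",
         which(!is.finite(u))[1], ")")
  list(u = u, s = as.numeric(u >= params$u_th))
}

#' Simulate a LIF layer over a full time window
#'
#' Iterates [lif_step()] from the initial state u^0 = s^0 = 0 over the T
#' columns of the input spike train. The spike output of one layer is the
#' spike input of the next, so stacking calls simulates a whole network.
#'
#' @param params a [layer_params()] object.
#' @param x input spike train, N_in x T matrix of 0/1.
#' @return an object of class `"bpsr_trace"`: list with `potentials` and
#'   `spikes`, both N x T matrices, and the threshold `u_th`.
#' @export
lif_forward <- function(params, x) {
  x <- as.matrix(x)
  T_ <- ncol(x)
  if (T_ < 1L) stop("lif_forward: time window must be at least 1")
  n <- nrow(params$w_in)
  potentials <- matrix(0, n, T_)
  spikes <- matrix(0, n, T_)
  u <- numeric(n)
  s <- numeric(n)
  for (t in seq_len(T_)) {
    st <- lif_step(params, u, s, x[, t])
    u <- st$u
    s <- st$s
    potentials[, t] <- u
    spikes[, t] <- s
  }
  structure(list(potentials = potentials, spikes = spikes, u_th = params$u_th),
            class = "bpsr_trace")
}

#' @export
print.bpsr_trace <- function(x, ...) {
  cat(sprintf("<bpsr_trace> %d neurons x %d timesteps, %d spikes (FR %.3f)\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes),
              mean(x$spikes)))
  invisible(x)
}

#' Mean firing rate of a set of layer traces
#'
#' Average spikes per neuron per timestep, pooled over the listed layers
#' (layers are weighted by their neuron count). Input encoding spikes are
#' never part of the traces and so are never counted; set `exclude_output`
#' to drop the last (readout) layer as well, mirroring the scope of the
#' spiking-sparsity penalty.
#'
#' @param traces list of `"bpsr_trace"` objects ordered input to output
#'   (a single trace is accepted).
#' @param exclude_output drop the final trace from the count.
#' @return scalar firing rate in \[0, 1\].
#' @export
firing_rate <- function(traces, exclude_output = FALSE) {
  if (inherits(traces, "bpsr_trace")) traces <- list(traces)
  if (exclude_output) traces <- traces[-length(traces)]
  if (length(traces) == 0L) stop("firing_rate: no traces to count")
  tot <- sum(vapply(traces, function(tr) sum(tr$spikes), 0))
  size <- sum(vapply(traces, function(tr) length(tr$spikes), 0))
  tot / size
}

# ---- batched forward (internal) -------------------------------------------
# x_arr: [N_in, T, B] array of 0/1. Returns U and S as [N, T, B] arrays.
# Same arithmetic as lif_step, vectorized across the batch.
forward_layer_batch <- function(params, x_arr) {
  d <- dim(x_arr)
  T_ <- d[2]; B <- d[3]
  n <- nrow(params$w_in)
  U <- array(0, c(n, T_, B))
  S <- array(0, c(n, T_, B))
  u <- matrix(0, n, B)
  s <- matrix(0, n, B)
  for (t in seq_len(T_)) {
    u <- u * params$tau * (1 - s) +
      params$w_in %*% matrix(x_arr[, t, ], ncol = B) +
      params$w_rec %*% s +
      params$bias
    s <- (u >= params$u_th) * 1
    U[, t, ] <- u
    S[, t, ] <- s
  }
  if (any(!is.finite(U)))
    stop("forward_layer_batch: non-finite membrane potential")
  list(U = U, S = S)
}

# Forward a whole network on a batch; returns per-layer U/S arrays.
forward_network_batch <- function(network, x_arr) {
  acts <- vector("list", length(network))
  a <- x_arr
  for (l in seq_along(network)) {
    acts[[l]] <- forward_layer_batch(network[[l]], a)
    a <- acts[[l]]$S
  }
  acts
}
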