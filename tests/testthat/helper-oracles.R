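# Independent reference implementations used as oracles. These are written
# as plain scalar loops over the unrolled dynamics / computational graph,
# deliberately separate from the package's vectorized O(T) paths.

# Scalar step-by-step LIF simulator: per neuron, start from the gated leak
# term and accumulate every synaptic contribution and the bias with ordered
# scalar additions (zero input terms contribute an exact 0).
scalar_lif_forward <- function(params, x) {
  n <- nrow(params$w_in)
  T_ <- ncol(x)
  U <- matrix(0, n, T_)
  S <- matrix(0, n, T_)
  u_prev <- rep(0, n)
  s_prev <- rep(0, n)
  for (t in seq_len(T_)) {
    for (i in seq_len(n)) {
      acc <- u_prev[i] * params$tau[i] * (1 - s_prev[i])
      for (j in seq_len(nrow(x)))
        if (x[j, t] != 0) acc <- acc + params$w_in[i, j] * x[j, t]
      for (k in seq_len(n))
        if (s_prev[k] != 0) acc <- acc + params$w_rec[i, k] * s_prev[k]
      acc <- acc + params$bias[i]
      U[i, t] <- acc
      S[i, t] <- as.numeric(acc >= params$u_th)
    }
    u_prev <- U[, t]
    s_prev <- S[, t]
  }
  list(potentials = U, spikes = S)
}

# Full-unroll adjoint oracle: pushes adjoints edge by edge through the
# explicit unrolled computational graph (u and s nodes at every timestep),
# with the Gaussian surrogate substituted for the threshold derivative and
# the gating edge s^{t-1} -> u^t excluded. Returns every gradient the
# backward pass produces. lambda terms are zero here; the regularizers are
# tested separately.
unroll_backward <- function(params, x, trace, d_s, alpha = 0.7) {
  n <- nrow(params$w_in)
  n_in <- nrow(x)
  T_ <- ncol(x)
  gd <- function(u) (alpha / sqrt(pi)) * exp(-(alpha * (u - params$u_th))^2)
  a_u <- matrix(0, n, T_)       # adjoints of potential nodes
  a_s <- matrix(0, n, T_)       # adjoints of spike nodes
  g_w_in <- matrix(0, n, n_in)
  g_w_rec <- matrix(0, n, n)
  g_bias <- rep(0, n)
  g_tau <- rep(0, n)
  g_x <- matrix(0, n_in, T_)
  for (t in T_:1) {
    for (i in seq_len(n)) {
      # spike node: external error plus edges into next-step potentials
      # through the intra-layer synapses
      acc <- d_s[i, t]
      if (t < T_) for (k in seq_len(n)) acc <- acc + a_u[k, t + 1] * params$w_rec[k, i]
      a_s[i, t] <- acc
      # potential node: surrogate edge from its spike plus the leak edge
      # from the next-step potential
      au <- a_s[i, t] * gd(trace$potentials[i, t])
      if (t < T_) au <- au + a_u[i, t + 1] * params$tau[i] * (1 - trace$spikes[i, t])
      a_u[i, t] <- au
      # distribute to parameter and input nodes
      u_prev <- if (t > 1) trace$potentials[i, t - 1] else 0
      s_prev_i <- if (t > 1) trace$spikes[i, t - 1] else 0
      g_tau[i] <- g_tau[i] + au * u_prev * (1 - s_prev_i)
      g_bias[i] <- g_bias[i] + au
      for (j in seq_len(n_in)) {
        g_w_in[i, j] <- g_w_in[i, j] + au * x[j, t]
        g_x[j, t] <- g_x[j, t] + au * params$w_in[i, j]
      }
      for (k in seq_len(n)) {
        s_prev_k <- if (t > 1) trace$spikes[k, t - 1] else 0
        g_w_rec[i, k] <- g_w_rec[i, k] + au * s_prev_k
      }
    }
  }
  list(d_u = a_u, d_x = g_x, d_w_in = g_w_in, d_w_rec = g_w_rec,
       d_bias = g_bias, d_tau = g_tau)
}

# Random layer + input generator for property tests.
random_layer <- function(n_out, n_in, type = c("flat", "recurrent"),
                         u_th = 1, weight_scale = 1) {
  type <- match.arg(type)
  w_rec <- if (type == "recurrent")
    matrix(stats::rnorm(n_out^2, sd = weight_scale), n_out, n_out)
  else matrix(0, n_out, n_out)
  diag(w_rec) <- 0
  layer_params(
    w_in = matrix(stats::rnorm(n_out * n_in, sd = weight_scale), n_out, n_in),
    w_rec = w_rec, bias = stats::runif(n_out, -0.5, 0.5),
    tau = stats::runif(n_out), u_th = u_th, type = type)
}

random_spikes <- function(n, T_, p = 0.4) {
  matrix(as.numeric(stats::runif(n * T_) < p), n, T_)
}

# 16-class directed triad census via igraph, restricted to the 13
# connected classes, as the independent cross-check for the package census.
igraph_census13 <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix((adj != 0) * 1, mode = "directed")
  as.integer(igraph::triad_census(g)[4:16])
}

# norm-wise relative error between congruent numeric arrays
rel_err <- function(a, b) {
  max(abs(a - b)) / max(abs(a), abs(b), 1e-300)
}
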