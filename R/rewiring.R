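#' Create the state of the rewiring mechanism for one layer
#'
#' Holds the gradient momentum (exponential moving average of the synaptic
#' weight gradient) and the pruning/growth thresholds. Defaults: pruning
#' threshold `theta_w = 1e-2`, growth threshold `theta_m = 1e-4`, distance
#' ratio `mu_m = 5`, moving-average coefficient `beta_m = 0.99`, rewiring
#' every update step.
#'
#' @param params the layer being rewired (shapes of the momentum matrices).
#' @param theta_w positive pruning threshold on |w|.
#' @param theta_m positive growth threshold on |m|.
#' @param mu_m non-negative distance ratio: growing a synapse of length d
#'   requires `|m| > theta_m * (1 + mu_m * d^dist_pow)`.
#' @param beta_m moving-average coefficient in (0, 1).
#' @param interval rewiring period in update steps.
#' @param dist_pow exponent on the Euclidean distance (default 1; 0.5
#'   selectable).
#' @param ema if `TRUE` (default) the momentum is the standard exponential
#'   moving average `m <- beta_m * m + (1 - beta_m) * grad`; if `FALSE` the
#'   literal accumulation rule `m <- m + (1 - beta_m) * grad` is used.
#' @param grow_candidates `"all_absent"` (default: any currently missing
#'   synapse position may grow, including never-wired ones) or
#'   `"pruned_only"` (only positions that once existed).
#' @return object of class `"bpsr_rewire_state"`.
#' @export
rewire_state <- function(params, theta_w = 1e-2, theta_m = 1e-4, mu_m = 5,
                         beta_m = 0.99, interval = 1L, dist_pow = 1,
                         ema = TRUE,
                         grow_candidates = c("all_absent", "pruned_only")) {
  stopifnot(theta_w > 0, theta_m > 0, mu_m >= 0, beta_m > 0, beta_m < 1)
  structure(list(
    momentum_in = matrix(0, nrow(params$w_in), ncol(params$w_in)),
    momentum_rec = matrix(0, nrow(params$w_rec), ncol(params$w_rec)),
    theta_w = theta_w, theta_m = theta_m, mu_m = mu_m, beta_m = beta_m,
    interval = as.integer(interval), dist_pow = dist_pow, ema = ema,
    grow_candidates = match.arg(grow_candidates),
    initial_mask_in = params$mask_in, initial_mask_rec = params$mask_rec),
    class = "bpsr_rewire_state")
}

#' Update the gradient momentum
#'
#' `m <- beta_m * m + (1 - beta_m) * grad`, elementwise, on the *unmasked*
#' weight gradients (momentum keeps tracking gradients of pruned synapses so
#' they can regrow). With `ema = FALSE` in the state, the accumulation
#' variant `m <- m + (1 - beta_m) * grad` is applied instead.
#'
#' @param state a [rewire_state()].
#' @param grads unmasked gradient bundle from [parameter_grads()].
#' @return the updated state.
#' @export
update_momentum <- function(state, grads) {
  if (!identical(dim(state$momentum_in), dim(grads$d_w_in)))
    stop("update_momentum: shape mismatch")
  decay <- if (state$ema) state$beta_m else 1
  state$momentum_in <- decay * state$momentum_in +
    (1 - state$beta_m) * grads$d_w_in
  state$momentum_rec <- decay * state$momentum_rec +
    (1 - state$beta_m) * grads$d_w_rec
  state
}

#' Synapses eligible for pruning
#'
#' TRUE exactly where a currently existing synapse has weight magnitude
#' strictly below the pruning threshold, `|w| < theta_w`. Absent synapses
#' are never re-pruned.
#'
#' @param params the layer.
#' @param state a [rewire_state()].
#' @return list of logical matrices `inn` (inter-layer) and `rec`
#'   (intra-layer).
#' @export
prune_mask <- function(params, state) {
  list(inn = params$mask_in & (abs(params$w_in) < state$theta_w),
       rec = params$mask_rec & (abs(params$w_rec) < state$theta_w))
}

#' Synapses eligible for growth
#'
#' TRUE exactly where a currently absent synapse has gradient momentum
#' strong enough to overcome the distance-gated growth condition
#' `|m| > theta_m * (1 + mu_m * d^dist_pow)` with d the Euclidean distance
#' between the two neurons' coordinates: establishing a longer-range synapse
#' requires a stronger growth trend. Grown synapses enter with weight
#' exactly 0 and are moved by subsequent updates.
#'
#' @param params the layer (must carry `coords`/`coords_in`).
#' @param state a [rewire_state()].
#' @return list of logical matrices `inn` and `rec`.
#' @export
grow_mask <- function(params, state) {
  if (is.null(params$coords) || is.null(params$coords_in))
    stop("grow_mask: neuron coordinates missing")
  thr_in <- state$theta_m *
    (1 + state$mu_m * pair_dist(params$coords, params$coords_in)^state$dist_pow)
  thr_rec <- state$theta_m *
    (1 + state$mu_m * pair_dist(params$coords, params$coords)^state$dist_pow)
  absent_in <- !params$mask_in
  absent_rec <- !params$mask_rec
  if (state$grow_candidates == "pruned_only") {
    absent_in <- absent_in & state$initial_mask_in
    absent_rec <- absent_rec & state$initial_mask_rec
  }
  # flat layers never grow intra-layer synapses; neither does the diagonal
  # when self-synapses are disabled
  if (params$type != "recurrent") absent_rec[] <- FALSE
  if (!params$self_synapse) diag(absent_rec) <- FALSE
  list(inn = absent_in & (abs(state$momentum_in) > thr_in),
       rec = absent_rec & (abs(state$momentum_rec) > thr_rec))
}

# Euclidean distance matrix between row-coordinate sets (n_out x n_in).
pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Apply one rewiring event to a layer
#'
#' Computes the prune and grow sets, updates the synapse mask as
#' `(existing AND NOT pruned) OR grown`, and superimposes the mask on both
#' the weights and the gradient bundle so masked entries are exactly zero
#' thereafter. Pruning and growth act on disjoint domains (existing vs
#' absent synapses), so no synapse can be both in one call.
#'
#' @param params the layer.
#' @param grads gradient bundle (will be masked).
#' @param state a [rewire_state()] with up-to-date momentum.
#' @return list with updated `params`, masked `grads`, and the integer
#'   counts `pruned` and `grown`.
#' @export
apply_rewire <- function(params, grads, state) {
  pr <- prune_mask(params, state)
  gr <- grow_mask(params, state)
  new_in <- (params$mask_in & !pr$inn) | gr$inn
  new_rec <- (params$mask_rec & !pr$rec) | gr$rec
  params$mask_in <- new_in
  params$mask_rec <- new_rec
  params$w_in <- params$w_in * new_in
  params$w_rec <- params$w_rec * new_rec
  if (!is.null(grads)) grads <- mask_gradients(grads, params)
  list(params = params, grads = grads,
       pruned = sum(pr$inn) + sum(pr$rec),
       grown = sum(gr$inn) + sum(gr$rec))
}
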