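#' Construct the parameter set of one spiking layer
#'
#' A layer bundles every learnable and structural quantity of a group of
#' leaky integrate-and-fire (LIF) neurons: inter-layer weights `w_in`
#' (N_out x N_in), intra-layer weights `w_rec` (N_out x N_out, all zero for a
#' flat layer), bias, per-neuron leak coefficients `tau`, the spiking
#' threshold `u_th`, boolean synapse masks congruent to the weight matrices,
#' and 3-d neuron coordinates in the unit cube used by distance-gated
#' synaptic growth.
#'
#' Invariants enforced on construction: `tau` lies in \[0, 1\]; weights and
#' bias are clamped to \[-u_th, u_th\]; masked synapse entries are exactly
#' zero; the diagonal of `w_rec` is zero unless `self_synapse = TRUE`.
#'
#' @param w_in numeric matrix of inter-layer weights, N_out x N_in.
#' @param w_rec numeric matrix of intra-layer weights, N_out x N_out.
#'   Defaults to all-zero (flat layer).
#' @param bias numeric vector of neuron biases, length N_out.
#' @param tau numeric vector of leak coefficients in \[0, 1\], length N_out,
#'   or a single value recycled to all neurons.
#' @param u_th positive spiking threshold (default 1).
#' @param type `"flat"` or `"recurrent"`.
#' @param mask_in,mask_rec logical matrices marking existing synapses;
#'   default: all inter-layer synapses exist, intra-layer synapses exist for
#'   recurrent layers (minus the diagonal when `self_synapse = FALSE`).
#' @param coords N_out x 3 matrix of neuron positions in the unit cube.
#' @param coords_in N_in x 3 matrix of presynaptic (previous layer) neuron
#'   positions, used when growing inter-layer synapses.
#' @param tau_shared logical; if `TRUE` the layer uses one shared leak value
#'   and the tau gradient is summed across the layer.
#' @param self_synapse logical; allow diagonal entries of `w_rec`.
#' @return an object of class `"bpsr_layer"`.
#' @export
layer_params <- function(w_in, w_rec = NULL, bias = NULL, tau = 0.5,
                         u_th = 1, type = c("flat", "recurrent"),
                         mask_in = NULL, mask_rec = NULL,
                         coords = NULL, coords_in = NULL,
                         tau_shared = FALSE, self_synapse = FALSE) {
  type <- match.arg(type)
  w_in <- as.matrix(w_in)
  n_out <- nrow(w_in)
  n_in <- ncol(w_in)
  if (is.null(w_rec)) w_rec <- matrix(0, n_out, n_out)
  w_rec <- as.matrix(w_rec)
  if (is.null(bias)) bias <- rep(0, n_out)
  if (length(bias) == 1L) bias <- rep(bias, n_out)
  if (length(tau) == 1L) tau <- rep(tau, n_out)
  if (is.null(mask_in)) mask_in <- matrix(TRUE, n_out, n_in)
  if (is.null(mask_rec)) {
    mask_rec <- matrix(type == "recurrent", n_out, n_out)
    if (!self_synapse) diag(mask_rec) <- FALSE
  }
  if (is.null(coords)) coords <- matrix(stats::runif(n_out * 3), n_out, 3)
  if (is.null(coords_in)) coords_in <- matrix(stats::runif(n_in * 3), n_in, 3)

  layer <- structure(
    list(w_in = w_in, w_rec = w_rec, bias = bias, tau = tau, u_th = u_th,
         mask_in = mask_in, mask_rec = mask_rec,
         coords = coords, coords_in = coords_in,
         type = type, tau_shared = tau_shared, self_synapse = self_synapse),
    class = "bpsr_layer")
  validate_layer(clamp_layer(layer))
}

#' @export
print.bpsr_layer <- function(x, ...) {
  cat(sprintf("<bpsr_layer> %s, %d neurons, %d inputs, %d/%d synapses, u_th = %g\n",
              x$type, nrow(x$w_in), ncol(x$w_in),
              sum(x$mask_in) + sum(x$mask_rec),
              length(x$mask_in) + if (x$type == "recurrent") length(x$mask_rec) else 0L,
              x$u_th))
  invisible(x)
}

validate_layer <- function(layer) {
  n_out <- nrow(layer$w_in)
  stopifnot(
    is.matrix(layer$w_rec), nrow(layer$w_rec) == n_out, ncol(layer$w_rec) == n_out,
    length(layer$bias) == n_out, length(layer$tau) == n_out,
    identical(dim(layer$mask_in), dim(layer$w_in)),
    identical(dim(layer$mask_rec), dim(layer$w_rec)),
    nrow(layer$coords) == n_out, ncol(layer$coords) == 3L,
    nrow(layer$coords_in) == ncol(layer$w_in), ncol(layer$coords_in) == 3L,
    layer$u_th > 0)
  if (any(layer$tau < 0 | layer$tau > 1))
    stop("tau must lie in [0, 1]")
  if (any(layer$w_in[!layer$mask_in] != 0) || any(layer$w_rec[!layer$mask_rec] != 0))
    stop("masked synapse entries must be exactly zero")
  layer
}

# Enforce the parameter range contract: |w|, |b| <= u_th, tau in [0, 1],
# masked entries exactly zero.
clamp_layer <- function(layer) {
  u <- layer$u_th
  layer$w_in <- pmin(pmax(layer$w_in, -u), u) * layer$mask_in
  layer$w_rec <- pmin(pmax(layer$w_rec, -u), u) * layer$mask_rec
  layer$bias <- pmin(pmax(layer$bias, -u), u)
  layer$tau <- pmin(pmax(layer$tau, 0), 1)
  layer
}

#' Parse a compact architecture string
#'
#' Network structures are written in the compact field notation
#' `"r20-fc10-fc2"`: `r` is a recurrent layer (intra-layer synapses), `fc` a
#' flat fully connected layer, the number is the layer width, layers are
#' listed input-side first and the last layer is the classifier readout.
#'
#' @param arch architecture string.
#' @return data frame with columns `type` ("recurrent"/"flat") and `size`.
#' @examples
#' parse_arch("r18-fc8-fc5")
#' @export
parse_arch <- function(arch) {
  parts <- strsplit(gsub("\\s", "", arch), "-", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(r|fc)([0-9]+)$", parts))
  if (any(lengths(m) != 3L))
    stop("cannot parse architecture string: ", arch)
  data.frame(
    type = ifelse(vapply(m, `[`, "", 2L) == "r", "recurrent", "flat"),
    size = as.integer(vapply(m, `[`, "", 3L)))
}

#' Initialize a spiking network
#'
#' Draws the parameters of every layer: weights from N(0, 1) then clamped to
#' \[-u_th, u_th\], biases from U(0, 1), leak coefficients set to the
#' empirical initial value 0.5, neuron coordinates uniform in the unit cube.
#' All synapse masks start full (every potential synapse exists, no
#' self-synapses unless requested).
#'
#' @param arch architecture string (see [parse_arch()]) or the data frame it
#'   returns.
#' @param n_in number of input channels (spike channels entering layer 1).
#' @param u_th spiking threshold shared by all layers (default 1).
#' @param tau_init initial leak coefficient (default 0.5).
#' @param self_synapse allow recurrent self-connections (default `FALSE`).
#' @param tau_shared use a shared leak per layer (default `FALSE`,
#'   heterogeneous neurons).
#' @param seed optional integer seed; same seed, bit-identical network.
#' @return list of [layer_params()] objects, input side first.
#' @export
init_network <- function(arch, n_in, u_th = 1, tau_init = 0.5,
                         self_synapse = FALSE, tau_shared = FALSE,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(arch)) arch <- parse_arch(arch)
  sizes <- c(n_in, arch$size)
  coords_prev <- matrix(stats::runif(n_in * 3), n_in, 3)
  layers <- vector("list", nrow(arch))
  for (l in seq_len(nrow(arch))) {
    n_out <- sizes[l + 1L]
    n_prev <- sizes[l]
    recurrent <- arch$type[l] == "recurrent"
    w_in <- matrix(stats::rnorm(n_out * n_prev), n_out, n_prev)
    w_rec <- if (recurrent) matrix(stats::rnorm(n_out * n_out), n_out, n_out)
             else matrix(0, n_out, n_out)
    coords <- matrix(stats::runif(n_out * 3), n_out, 3)
    layers[[l]] <- layer_params(
      w_in = w_in, w_rec = w_rec,
      bias = stats::runif(n_out), tau = tau_init, u_th = u_th,
      type = arch$type[l], coords = coords, coords_in = coords_prev,
      tau_shared = tau_shared, self_synapse = self_synapse)
    coords_prev <- coords
  }
  layers
}

#' Count existing synapses of a network
#'
#' @param network list of layers (or a fitted `bpsr` object).
#' @param per_layer return a per-layer vector instead of the total.
#' @return integer count of unmasked synapses.
#' @export
synapse_count <- function(network, per_layer = FALSE) {
  if (inherits(network, "bpsr")) network <- network$layers
  counts <- vapply(network, function(l) sum(l$mask_in) + sum(l$mask_rec), 0)
  if (per_layer) counts else sum(counts)
}

#' Write and read a network checkpoint
#'
#' Serializes every layer (w_in, w_rec, bias, tau, mask_in, mask_rec,
#' coords) plus a metadata block (u_th, layer type, seed, optional
#' hyper-parameters and quantization spec) to a JSON container.
#'
#' @param network list of layers or fitted `bpsr` object.
#' @param path file path.
#' @param meta optional named list stored alongside the layers.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the list of layers with a `"meta"` attribute.
#' @export
write_checkpoint <- function(network, path, meta = list()) {
  if (inherits(network, "bpsr")) {
    meta <- utils::modifyList(list(arch = network$arch), meta)
    network <- network$layers
  }
  payload <- list(
    meta = meta,
    layers = lapply(network, function(l) list(
      w_in = l$w_in, w_rec = l$w_rec, bias = l$bias, tau = l$tau,
      u_th = l$u_th, mask_in = l$mask_in * 1L, mask_rec = l$mask_rec * 1L,
      coords = l$coords, coords_in = l$coords_in, type = l$type,
      tau_shared = l$tau_shared, self_synapse = l$self_synapse)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow_or_len(payload$layers)), function(i) {
    l <- index_layerlist(payload$layers, i)
    layer_params(
      w_in = as.matrix(l$w_in), w_rec = as.matrix(l$w_rec),
      bias = as.numeric(l$bias), tau = as.numeric(l$tau), u_th = l$u_th,
      type = l$type, mask_in = as.matrix(l$mask_in) != 0,
      mask_rec = as.matrix(l$mask_rec) != 0, coords = as.matrix(l$coords),
      coords_in = as.matrix(l$coords_in),
      tau_shared = isTRUE(l$tau_shared), self_synapse = isTRUE(l$self_synapse))
  })
  attr(layers, "meta") <- payload$meta
  layers
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
index_layerlist <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col) {
    if (is.list(col)) col[[i]] else col[i]
  }) else x[[i]]
}
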