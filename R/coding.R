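#' Rate (Bernoulli) spike encoding
#'
#' Treats each channel intensity in \[0, 1\] as a per-timestep spike
#' probability and samples independently across the window: intensity 0
#' never spikes, intensity 1 spikes at every timestep. The same seed yields
#' a bit-identical train; the caller's RNG state is restored.
#'
#' @param values numeric vector of intensities in \[0, 1\].
#' @param T time window length.
#' @param seed optional integer seed.
#' @return N x T spike matrix of 0/1.
#' @export
rate_encode <- function(values, T, seed = NULL) {
  if (any(values < 0 | values > 1)) stop("intensities must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- length(values)
  matrix(as.numeric(stats::runif(n * T) < values), n, T)
}

#' Rank-order (intensity-to-latency) spike encoding
#'
#' Temporal sparse coding: each channel emits at most one spike, and larger
#' values spike earlier. The default latency map is linear,
#' `t(v) = round((1 - v / v_max) * (T - 1)) + 1` for v > 0, so the largest
#' value fires at t = 1 and values collapse onto the T grid (ties share a
#' timestep). Channels with value <= 0 stay silent. With
#' `strict = TRUE` channels instead fire at their rank position (ties broken
#' by channel index, capped at T), giving unique spike times when N <= T.
#'
#' @param values numeric vector of channel intensities.
#' @param T time window length.
#' @param v_max intensity mapped to the earliest timestep; defaults to
#'   `max(values)`. Fix it across samples for an absolute latency scale.
#' @param strict use the strict-rank variant.
#' @return N x T spike matrix of 0/1 with at most one spike per row.
#' @export
rank_order_encode <- function(values, T, v_max = NULL, strict = FALSE) {
  n <- length(values)
  spikes <- matrix(0, n, T)
  pos <- which(values > 0)
  if (length(pos) == 0L) return(spikes)
  if (strict) {
    ord <- pos[order(-values[pos], pos)]
    times <- pmin(seq_along(ord), T)
    spikes[cbind(ord, times)] <- 1
    return(spikes)
  }
  if (is.null(v_max)) v_max <- max(values)
  v <- pmin(values[pos], v_max)
  times <- round((1 - v / v_max) * (T - 1)) + 1
  spikes[cbind(pos, times)] <- 1
  spikes
}

#' Level-crossing (LC) spike encoding
#'
#' Converts each real-valued signal channel into a bipolar spike pair: a
#' spike on the UP channel whenever the signal rises through an absolute
#' amplitude boundary `k * delta`, and on the DOWN channel when it falls
#' through one, so the spikes reflect the changing trend of the signal
#' (e.g. a 2-channel ECG becomes a 4-channel spike train). Levels are an
#' absolute grid, so the encoding does not drift. Samples are mapped onto
#' the T-step window by uniform binning with OR-reduction inside a bin.
#'
#' Output rows are ordered (ch1 UP, ch1 DOWN, ch2 UP, ch2 DOWN, ...). The
#' returned train carries attributes `delta` and `init_level` (the starting
#' level index per channel) so that the signal can be reconstructed to
#' within `delta` as `(init_level + cumsum(UP) - cumsum(DOWN)) * delta`
#' when the sampling is fine enough that bins hold at most one crossing.
#'
#' @param signal numeric matrix, channels x samples (a vector is one
#'   channel).
#' @param delta positive level-crossing step.
#' @param T output time window; defaults to the number of samples.
#' @return 2*channels x T spike matrix of 0/1.
#' @export
lc_encode <- function(signal, delta, T = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  if (delta <= 0) stop("delta must be positive")
  if (any(!is.finite(signal))) stop("signal must be finite")
  n_ch <- nrow(signal)
  n_s <- ncol(signal)
  if (is.null(T)) T <- n_s
  # level index per sample on the absolute k*delta grid; small epsilon keeps
  # exact boundary values on their level under floating-point division
  lev <- floor(signal / delta + 1e-9)
  bins <- floor((seq_len(n_s) - 1) * T / n_s) + 1L
  spikes <- matrix(0, 2L * n_ch, T)
  for (ch in seq_len(n_ch)) {
    d <- diff(lev[ch, ])
    up_at <- which(d > 0) + 1L
    dn_at <- which(d < 0) + 1L
    spikes[2L * ch - 1L, unique(bins[up_at])] <- 1
    spikes[2L * ch, unique(bins[dn_at])] <- 1
  }
  attr(spikes, "delta") <- delta
  attr(spikes, "init_level") <- lev[, 1]
  spikes
}

#' Read an MNIST-style IDX file
#'
#' Minimal reader for the big-endian IDX format (magic 0x00000801 for label
#' vectors, 0x00000803 for image stacks), for optional runs on real digit
#' data. Images are returned as a pixels x n matrix scaled to \[0, 1\],
#' ready for [rate_encode()] or [rank_order_encode()]; labels as an integer
#' vector.
#'
#' @param path path to an uncompressed IDX file.
#' @return matrix (images) or integer vector (labels).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2049L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else if (magic == 2051L) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    raw <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
    matrix(raw / 255, nrow = dims[2] * dims[3], ncol = dims[1])
  } else {
    stop("not an IDX label/image file: magic ", magic)
  }
}
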