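#' Generate a synthetic spiking classification task
#'
#' Seeded generators for three task families that exercise the three spike
#' encoders and the different credit-assignment demands of spiking network
#' training:
#'
#' \describe{
#'   \item{`rate_clusters`}{Each class has a fixed channel-intensity
#'     template drawn uniformly in \[0, 1\]; samples add Gaussian noise
#'     (sd `noise_sd`), clip to \[0, 1\] and are Bernoulli rate-encoded.
#'     Information lives in spike *counts* (an intensity-cluster task in the
#'     spirit of rate-coded digit classification).}
#'   \item{`temporal_order`}{Each class is a characteristic ordering of the
#'     channels: a class-specific permutation of an evenly spaced intensity
#'     ladder, jittered multiplicatively, then rank-order encoded against a
#'     fixed scale. Every channel emits exactly one spike, so total spike
#'     counts are identical across classes and only spike *timing* carries
#'     label information -- solving it requires temporal credit assignment.}
#'   \item{`lc_waveforms`}{Each class is a quasi-periodic multichannel
#'     waveform (class-specific frequency and harmonic mix, random phase
#'     and amplitude jitter per sample, additive noise) converted to
#'     bipolar spikes by level-crossing encoding, emulating multichannel
#'     biosignals such as ECG; `n_channels` signal channels give
#'     `2 * n_channels` spike channels.}
#' }
#'
#' @param kind one of `"rate_clusters"`, `"temporal_order"`,
#'   `"lc_waveforms"`.
#' @param n_classes number of classes (default 2).
#' @param n_channels input channels (signal channels for `lc_waveforms`;
#'   default 20, or 2 for `lc_waveforms`).
#' @param T time window length (default 20).
#' @param n_train,n_test sample counts (defaults 400 / 200).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param noise_sd additive noise sd for `rate_clusters` (default 0.1).
#' @param jitter multiplicative intensity jitter sd for `temporal_order`
#'   (default 0.05).
#' @param lc_delta level-crossing step for `lc_waveforms` (default 0.1).
#' @return object of class `"bpsr_task"`: list with spike arrays `x_train`,
#'   `x_test` (`channels x T x samples`), factor labels `y_train`,
#'   `y_test`, the class templates, and the generator settings.
#' @export
make_synthetic_task <- function(kind = c("rate_clusters", "temporal_order",
                                         "lc_waveforms"),
                                n_classes = 2, n_channels = NULL, T = 20,
                                n_train = 400, n_test = 200, seed = 1,
                                noise_sd = 0.1, jitter = 0.05,
                                lc_delta = 0.1) {
  kind <- match.arg(kind)
  if (is.null(n_channels)) n_channels <- if (kind == "lc_waveforms") 2L else 20L
  stopifnot(n_classes >= 2, n_channels >= 1, T >= 1, n_train >= n_classes,
            n_test >= 0)
  set.seed(seed)

  templates <- switch(kind,
    rate_clusters = matrix(stats::runif(n_classes * n_channels),
                           n_channels, n_classes),
    temporal_order = {
      ladder <- seq(1 / n_channels, 1, length.out = n_channels)
      # class 1 ascending, class 2 descending, further classes random orders
      tmpl <- sapply(seq_len(n_classes), function(c.)
        if (c. == 1L) ladder
        else if (c. == 2L) rev(ladder)
        else ladder[sample.int(n_channels)])
      matrix(tmpl, n_channels, n_classes)
    },
    lc_waveforms = NULL)
  freqs <- if (kind == "lc_waveforms") seq_len(n_classes) + 1 else NULL
  harmonics <- if (kind == "lc_waveforms") stats::runif(n_classes, 0.2, 0.6) else NULL

  gen_split <- function(n) {
    y <- rep_len(seq_len(n_classes), n)
    n_rows <- if (kind == "lc_waveforms") 2L * n_channels else n_channels
    x <- array(0, c(n_rows, T, n))
    for (i in seq_len(n)) {
      c. <- y[i]
      x[, , i] <- switch(kind,
        rate_clusters = {
          v <- pmin(pmax(templates[, c.] + stats::rnorm(n_channels, 0, noise_sd),
                         0), 1)
          rate_encode(v, T)
        },
        temporal_order = {
          v <- templates[, c.] * (1 + stats::rnorm(n_channels, 0, jitter))
          rank_order_encode(pmin(pmax(v, 1e-6), 1), T, v_max = 1)
        },
        lc_waveforms = {
          n_s <- 4L * T
          tgrid <- seq(0, 1, length.out = n_s)
          phase <- stats::runif(1, 0, 2 * pi)
          amp <- 1 + stats::rnorm(1, 0, 0.1)
          sig <- t(sapply(seq_len(n_channels), function(ch)
            amp * (sin(2 * pi * freqs[c.] * tgrid + phase + (ch - 1) * pi / 2) +
                     harmonics[c.] * sin(2 * pi * 2 * freqs[c.] * tgrid + phase)) +
              stats::rnorm(n_s, 0, 0.02)))
          lc_encode(matrix(sig, n_channels, n_s), delta = lc_delta, T = T)
        })
    }
    list(x = x, y = factor(y, levels = seq_len(n_classes)))
  }

  train <- gen_split(n_train)
  test <- gen_split(n_test)
  structure(list(
    x_train = train$x, y_train = train$y,
    x_test = test$x, y_test = test$y,
    templates = templates, kind = kind, T = T,
    n_channels = dim(train$x)[1], n_classes = n_classes, seed = seed,
    settings = list(noise_sd = noise_sd, jitter = jitter,
                    lc_delta = lc_delta)),
    class = "bpsr_task")
}

#' @export
print.bpsr_task <- function(x, ...) {
  cat(sprintf(
    "<bpsr_task> %s: %d classes, %d spike channels, T = %d, %d train / %d test\n",
    x$kind, x$n_classes, x$n_channels, x$T,
    dim(x$x_train)[3], dim(x$x_test)[3]))
  invisible(x)
}

#' Collapse a spike train over time
#'
#' Reduces every sample to a single timestep carrying only the per-channel
#' spike indicator (any spike in the window -> 1). Training on the collapsed
#' data is the time-ablated control: any accuracy above chance must come
#' from spike counts, not timing.
#'
#' @param x spike array `channels x T x samples` (or a single matrix).
#' @return array `channels x 1 x samples` (or `channels x 1` matrix).
#' @export
collapse_time <- function(x) {
  if (is.matrix(x)) return(matrix(as.numeric(rowSums(x) > 0), ncol = 1))
  collapsed <- apply(x, c(1, 3), function(r) as.numeric(any(r > 0)))
  array(collapsed, c(dim(x)[1], 1, dim(x)[3]))
}
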