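test_that("momentum follows the exponential moving average", {
  set.seed(81)
  p <- random_layer(3, 4, "recurrent")
  st <- rewire_state(p, beta_m = 0.9)
  g <- list(d_w_in = matrix(0.5, 3, 4), d_w_rec = matrix(-0.2, 3, 3),
            d_bias = rep(0, 3), d_tau = rep(0, 3))
  # constant gradient: EMA converges to the gradient
  for (i in 1:300) st <- update_momentum(st, g)
  expect_equal(st$momentum_in, g$d_w_in, tolerance = 1e-10)
  expect_equal(st$momentum_rec, g$d_w_rec, tolerance = 1e-10)
  # zero gradient: geometric decay by beta_m per step
  g0 <- list(d_w_in = matrix(0, 3, 4), d_w_rec = matrix(0, 3, 3))
  m0 <- st$momentum_in
  st <- update_momentum(st, g0)
  expect_equal(st$momentum_in, 0.9 * m0, tolerance = 1e-12)
  expect_error(update_momentum(st, list(d_w_in = matrix(0, 2, 2),
                                        d_w_rec = matrix(0, 3, 3))), "shape")
})

test_that("momentum trajectory matches a scalar reference EMA", {
  set.seed(82)
  p <- random_layer(1, 1, "flat")
  st <- rewire_state(p, beta_m = 0.97)
  gs <- rnorm(200) * rep(c(1, -1), 100)   # alternating-sign gradients
  m_ref <- 0
  for (g in gs) {
    st <- update_momentum(st, list(d_w_in = matrix(g), d_w_rec = matrix(0)))
    m_ref <- 0.97 * m_ref + 0.03 * g
    expect_equal(st$momentum_in[1, 1], m_ref, tolerance = 1e-12)
  }
})

test_that("the literal accumulation variant is available behind the switch", {
  p <- layer_params(w_in = matrix(0.5))
  st <- rewire_state(p, beta_m = 0.99, ema = FALSE)
  g <- list(d_w_in = matrix(1), d_w_rec = matrix(0))
  st <- update_momentum(update_momentum(st, g), g)
  expect_equal(st$momentum_in[1, 1], 0.02)   # m = m + (1 - beta) * grad
})

test_that("pruning selects existing weak synapses with a strict threshold", {
  p <- layer_params(w_in = matrix(c(0.005, 0.01, 0.5, 0), 2, 2),
                    mask_in = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  st <- rewire_state(p, theta_w = 0.01)
  pr <- prune_mask(p, st)
  expect_true(pr$inn[1, 1])        # |w| = 0.005 < 0.01
  expect_false(pr$inn[2, 1])       # boundary: strict <
  expect_false(pr$inn[1, 2])       # strong synapse stays
  expect_false(pr$inn[2, 2])       # already absent: not re-pruned
})

test_that("growth requires stronger momentum for longer synapses", {
  p <- layer_params(w_in = matrix(0, 2, 2),
                    mask_in = matrix(FALSE, 2, 2),
                    coords = rbind(c(0, 0, 0), c(1, 0, 0)),
                    coords_in = rbind(c(0, 0, 0), c(0, 0, 0)))
  st <- rewire_state(p, theta_m = 1e-4, mu_m = 5)
  # coincident neurons grow just above theta_m; boundary |m| = theta_m not
  st$momentum_in <- matrix(1e-4, 2, 2)
  gr <- grow_mask(p, st)
  expect_false(any(gr$inn))
  st$momentum_in <- matrix(1.01e-4, 2, 2)
  gr <- grow_mask(p, st)
  expect_true(gr$inn[1, 1] && gr$inn[1, 2])   # dist 0 -> threshold theta_m
  expect_false(gr$inn[2, 1] || gr$inn[2, 2])  # dist 1 -> threshold 6e-4
  st$momentum_in <- matrix(7e-4, 2, 2)
  expect_true(all(grow_mask(p, st)$inn))
})

test_that("the growable set shrinks monotonically with distance", {
  dists <- seq(0, 1.5, by = 0.1)
  p <- layer_params(w_in = matrix(0, 1, length(dists)),
                    mask_in = matrix(FALSE, 1, length(dists)),
                    coords = matrix(0, 1, 3),
                    coords_in = cbind(dists, 0, 0))
  st <- rewire_state(p)
  n_grow <- vapply(c(1e-4, 2e-4, 5e-4, 1e-3), function(m) {
    st$momentum_in <- matrix(m, 1, length(dists))
    g <- grow_mask(p, st)$inn
    # growable set is a prefix of the distance-ordered channels
    if (any(g)) expect_true(all(g[1:max(which(g))]))
    sum(g)
  }, 0)
  expect_true(all(diff(n_grow) >= 0))
})

test_that("rewiring keeps masks and weight zero patterns coincident", {
  set.seed(83)
  for (i in 1:20) {
    p <- random_layer(5, 6, "recurrent")
    st <- rewire_state(p, theta_w = 0.5)   # aggressive pruning
    st$momentum_in <- matrix(rnorm(30, sd = 3e-4), 5, 6)
    st$momentum_rec <- matrix(rnorm(25, sd = 3e-4), 5, 5)
    before_in <- p$mask_in; before_rec <- p$mask_rec
    pr <- prune_mask(p, st); gr <- grow_mask(p, st)
    res <- apply_rewire(p, NULL, st)
    q <- res$params
    # masked entries are exactly zero; every nonzero weight is masked-in
    expect_true(all(q$w_in[!q$mask_in] == 0))
    expect_true(all(q$mask_in[q$w_in != 0]))
    expect_true(all(q$w_rec[!q$mask_rec] == 0))
    # conservation: after = existing - pruned + grown
    expect_equal(sum(q$mask_in) + sum(q$mask_rec),
                 sum(before_in) + sum(before_rec) - res$pruned + res$grown)
    # prune and grow act on disjoint domains
    expect_false(any(pr$inn & gr$inn))
    expect_false(any(pr$rec & gr$rec))
    # grown synapses enter at exactly zero
    grown_now <- gr$inn & q$mask_in
    expect_true(all(q$w_in[grown_now] == 0))
  }
})

test_that("rewiring matches a brute-force elementwise evaluation", {
  set.seed(84)
  p <- random_layer(4, 4, "recurrent")
  p$mask_in[1, 2] <- FALSE; p$w_in[1, 2] <- 0
  st <- rewire_state(p, theta_w = 0.3, theta_m = 1e-4, mu_m = 5)
  st$momentum_in <- matrix(rnorm(16, sd = 5e-4), 4, 4)
  res <- apply_rewire(p, NULL, st)
  for (i in 1:4) for (j in 1:4) {
    d <- sqrt(sum((p$coords[i, ] - p$coords_in[j, ])^2))
    expected <- if (p$mask_in[i, j]) {
      !(abs(p$w_in[i, j]) < 0.3)                    # survives unless pruned
    } else {
      abs(st$momentum_in[i, j]) > 1e-4 * (1 + 5 * d) # grows if trend strong
    }
    expect_identical(res$params$mask_in[i, j], expected)
  }
})

test_that("an identity rewiring leaves the layer untouched", {
  set.seed(85)
  p <- random_layer(3, 3, "flat", weight_scale = 0.5)
  p$w_in <- p$w_in + sign(p$w_in) * 0.05  # keep everything above theta_w
  st <- rewire_state(p, theta_w = 1e-3)
  res <- apply_rewire(p, NULL, st)
  expect_equal(res$params$w_in, p$w_in)
  expect_identical(res$params$mask_in, p$mask_in)
  expect_equal(res$pruned + res$grown, 0)
})

test_that("full disconnection is legal and reported", {
  p <- layer_params(w_in = matrix(c(0.001, -0.002), 1, 2))
  st <- rewire_state(p, theta_w = 0.01)
  res <- apply_rewire(p, NULL, st)
  expect_equal(sum(res$params$mask_in), 0)
  expect_equal(res$pruned, 2)
})

test_that("pure l1 decay shrinks weights monotonically until pruned", {
  # SGD, zero data gradient: |w| decreases by lr * lambda_w each step,
  # reaches the pruning threshold, and the synapse dies exactly then
  p <- layer_params(w_in = matrix(c(0.06, -0.04, 0.05, 0.03), 2, 2),
                    bias = c(0, 0), type = "flat")
  st <- training_state(list(p), lr = 1e-2, optimizer = "sgd",
                       lambda_w = 1, rewire = TRUE,
                       rewire_opts = list(theta_m = 10))  # growth disabled
  x <- array(0, c(2, 3, 1))    # silent input: no data gradient anywhere
  w_hist <- abs(p$w_in[1, 1])
  for (i in 1:10) {
    res <- train_step(st, x, factor(1, levels = c(1, 2)))
    st <- res$state
    w_hist <- c(w_hist, abs(st$network[[1]]$w_in[1, 1]))
  }
  expect_true(all(diff(w_hist) <= 1e-12))
  expect_equal(sum(st$network[[1]]$mask_in), 0)  # every synapse pruned
})
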