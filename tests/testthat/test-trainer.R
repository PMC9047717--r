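test_that("architecture strings parse into layer tables", {
  a <- parse_arch("r18-fc8-fc5")
  expect_equal(a$type, c("recurrent", "flat", "flat"))
  expect_equal(a$size, c(18L, 8L, 5L))
  expect_error(parse_arch("conv8-fc2"), "parse")
})

test_that("network initialization follows the stated distributions", {
  net <- init_network("r30-fc10-fc4", n_in = 12, seed = 1)
  expect_length(net, 3)
  for (l in net) {
    expect_true(all(l$tau == 0.5))
    expect_true(all(abs(l$w_in) <= l$u_th))
    expect_true(all(l$bias >= 0 & l$bias <= 1))
    expect_true(all(l$coords >= 0 & l$coords <= 1))
    expect_true(all(diag(l$w_rec) == 0))
  }
  expect_equal(net[[1]]$type, "recurrent")
  expect_true(all(net[[2]]$w_rec == 0))
  # weights follow a clamped standard normal: sizeable mass near the clamp
  w <- net[[1]]$w_in
  expect_gt(mean(abs(w) == 1), 0.2)      # P(|N(0,1)| > 1) ~ 0.32
  expect_lt(abs(mean(w)), 0.1)
  # determinism
  net2 <- init_network("r30-fc10-fc4", n_in = 12, seed = 1)
  expect_identical(net, net2)
})

test_that("a zero learning rate leaves parameters untouched", {
  set.seed(111)
  net <- init_network("fc6-fc2", n_in = 4)
  st <- training_state(net, lr = 0, optimizer = "sgd")
  x <- array(random_spikes(4, 8 * 5), c(4, 8, 5))
  y <- factor(c(1, 2, 1, 2, 1))
  res <- train_step(st, x, y)
  expect_equal(res$state$network[[1]]$w_in, net[[1]]$w_in)
  expect_equal(res$state$network[[2]]$bias, net[[2]]$bias)
  expect_equal(res$state$network[[1]]$tau, net[[1]]$tau)
})

test_that("SGD steps on a fixed batch drive the loss down", {
  # the spike-count loss is piecewise constant in the parameters (a step
  # that flips no spike leaves it exactly unchanged), so descent shows up
  # over a short run of surrogate-gradient steps rather than a single one
  set.seed(112)
  net <- init_network("r8-fc2", n_in = 6)
  x <- array(random_spikes(6, 10 * 4), c(6, 10, 4))
  y <- factor(c(1, 2, 1, 2))
  st <- training_state(net, lr = 1e-2, optimizer = "sgd", lambda_s = 0)
  losses <- numeric(30)
  for (i in 1:30) {
    r <- train_step(st, x, y)
    st <- r$state
    losses[i] <- r$loss$total
  }
  expect_lt(losses[30], losses[1])
  expect_lt(min(losses), 0.6 * losses[1])
})

test_that("updates clamp weights to the threshold range and tau to [0, 1]", {
  p <- layer_params(w_in = matrix(c(0.99, -0.99), 2, 1), bias = c(0.9, -0.9),
                    tau = c(0.99, 0.01), u_th = 1, type = "flat")
  st <- training_state(list(p), lr = 10, optimizer = "sgd")
  x <- array(1, c(1, 4, 2))
  y <- factor(c(1, 2))
  for (i in 1:5) st <- train_step(st, x, y)$state
  q <- st$network[[1]]
  expect_true(all(abs(q$w_in) <= 1))
  expect_true(all(abs(q$bias) <= 1))
  expect_true(all(q$tau >= 0 & q$tau <= 1))
})

test_that("training is reproducible given the seed", {
  task <- make_synthetic_task("rate_clusters", n_train = 40, n_test = 10,
                              seed = 4)
  f1 <- bpsr(task, arch = "fc6-fc2", epochs = 2, seed = 9)
  f2 <- bpsr(task, arch = "fc6-fc2", epochs = 2, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})

test_that("synthetic tasks are seeded, shaped and balanced", {
  for (kind in c("rate_clusters", "temporal_order", "lc_waveforms")) {
    t1 <- make_synthetic_task(kind, n_train = 24, n_test = 12, seed = 5)
    t2 <- make_synthetic_task(kind, n_train = 24, n_test = 12, seed = 5)
    expect_identical(t1$x_train, t2$x_train)
    expect_identical(t1$y_train, t2$y_train)
    expect_equal(dim(t1$x_train)[3], 24)
    expect_equal(dim(t1$x_train)[2], 20)
    expect_equal(as.vector(table(t1$y_train)), c(12, 12))
    expect_true(all(t1$x_train %in% c(0, 1)))
  }
  # lc task: 2 signal channels -> 4 bipolar spike channels
  tl <- make_synthetic_task("lc_waveforms", n_train = 8, n_test = 4, seed = 1)
  expect_equal(dim(tl$x_train)[1], 4)
})

test_that("temporal task balances spike counts across classes exactly", {
  tk <- make_synthetic_task("temporal_order", n_train = 50, n_test = 0,
                            seed = 8)
  counts <- apply(tk$x_train, 3, sum)
  expect_true(all(counts == counts[1]))   # every sample: one spike/channel
  # collapsing time destroys all class information
  xc <- collapse_time(tk$x_train)
  expect_equal(dim(xc)[2], 1)
  expect_true(all(xc == 1))
})

test_that("evaluation metrics are deterministic and sane on a fixed network", {
  set.seed(113)
  task <- make_synthetic_task("rate_clusters", n_train = 30, n_test = 20,
                              seed = 2)
  net <- init_network("r8-fc4-fc2", n_in = 20)
  m1 <- evaluate_network(net, task$x_test, task$y_test)
  m2 <- evaluate_network(net, task$x_test, task$y_test)
  expect_identical(m1, m2)
  expect_true(m1$accuracy >= 0 && m1$accuracy <= 1)
  expect_true(m1$fr >= 0 && m1$fr <= 1)
  expect_equal(m1$synapse_count, synapse_count(net))
  expect_error(evaluate_network(net, task$x_test[, , 0], integer()), "empty")
})

test_that("a fully disconnected network is silent and scores at chance", {
  set.seed(114)
  task <- make_synthetic_task("rate_clusters", n_train = 10, n_test = 40,
                              seed = 3)
  net <- init_network("fc6-fc2", n_in = 20)
  for (l in seq_along(net)) {
    net[[l]]$mask_in[] <- FALSE; net[[l]]$w_in[] <- 0
    net[[l]]$bias[] <- 0
  }
  m <- evaluate_network(net, task$x_test, task$y_test)
  expect_equal(m$fr, 0)
  expect_equal(m$synapse_count, 0)
  expect_equal(m$accuracy, 0.5)   # constant prediction on balanced classes
})

test_that("fit object methods expose the expected interfaces", {
  task <- make_synthetic_task("rate_clusters", n_train = 60, n_test = 20,
                              seed = 6)
  fit <- bpsr(task, arch = "r8-fc4-fc2", epochs = 4, seed = 6)
  expect_s3_class(fit, "bpsr")
  expect_output(print(fit), "architecture: r8-fc4-fc2")
  s <- summary(fit)
  expect_s3_class(s, "summary.bpsr")
  expect_equal(nrow(s$per_layer), 3)
  expect_output(print(s), "lambda_s")
  cf <- coef(fit)
  expect_length(cf, 3)
  expect_equal(dim(cf[[1]]$w_in), c(8, 20))
  pr <- predict(fit, task$x_test, type = "prob")
  expect_equal(dim(pr), c(20, 2))
  expect_equal(rowSums(pr), rep(1, 20), tolerance = 1e-9)
  cls <- predict(fit, task$x_test)
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), fit$levels)
  cnt <- predict(fit, task$x_test, type = "count")
  expect_true(all(cnt >= 0 & cnt <= fit$T))
  r <- residuals(fit)
  expect_equal(dim(r), c(60, 2))
  expect_true(all(abs(r) <= 1))
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = task$x_test[, , 1])
  expect_length(sims, 2)
  expect_length(sims[[1]], 3)
  expect_identical(sims[[1]][[3]]$spikes, sims[[2]][[3]]$spikes)
  # stochastic presentations from intensities differ between repetitions
  sims2 <- simulate(fit, nsim = 2, seed = 1,
                    values = runif(20))
  expect_false(identical(sims2[[1]][[1]]$spikes, sims2[[2]][[1]]$spikes))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("history records the loss decomposition and synapse trajectory", {
  task <- make_synthetic_task("rate_clusters", n_train = 40, n_test = 10,
                              seed = 10)
  fit <- bpsr(task, arch = "fc6-fc2", epochs = 3, seed = 10,
              lambda_s = 1e-6, lambda_w = 1e-3)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_true(all(h$total >= h$ce))
  expect_true(all(h$spike_pen >= 0 & h$weight_pen >= 0))
  expect_true(all(h$synapse_count == fit$initial_synapses))  # no rewiring
})

test_that("tau_shared layers keep a single shared leak value", {
  task <- make_synthetic_task("rate_clusters", n_train = 40, n_test = 10,
                              seed = 11)
  fit <- bpsr(task, arch = "r6-fc2", epochs = 3, seed = 11, tau_shared = TRUE)
  for (l in fit$layers)
    expect_equal(length(unique(l$tau)), 1L)
})

test_that("mismatched label/architecture combinations are rejected", {
  task <- make_synthetic_task("rate_clusters", n_train = 20, n_test = 5,
                              seed = 12)
  expect_error(bpsr(task, arch = "fc6-fc3", epochs = 1), "classes")
  expect_error(bpsr(task$x_train, y = NULL, arch = "fc6-fc2"), "required")
})
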