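test_that("training is deterministic and beats chance on a separable task", {
  set.seed(1)
  task <- make_blob_task(n_classes = 4, n_train = 600, n_test = 200)
  cfg <- rnn_config(epochs = 2, seed = 3)
  n1 <- train_rnn(task$x_train, task$y_train, cfg, n_classes = 4)
  n2 <- train_rnn(task$x_train, task$y_train, cfg, n_classes = 4)
  expect_identical(n1$params, n2$params)
  u <- untrained_rnn(task$x_train, cfg, 4)
  acc0 <- rnn_accuracy(u, task$x_test, task$y_test)
  expect_lt(acc0, 0.55)   # near chance for 4 classes
  expect_gt(rnn_accuracy(n1, task$x_test, task$y_test), acc0)
})

test_that("the four-class task is learned to high accuracy", {
  set.seed(2)
  task <- make_blob_task(n_classes = 4)
  net <- train_rnn(task$x_train, task$y_train, rnn_config(seed = 2),
                   n_classes = 4)
  expect_gt(rnn_accuracy(net, task$x_test, task$y_test), 0.9)
})

test_that("connection classification applies the weight threshold", {
  W <- rbind(c(0.02, 0.005), c(0.011, 0.0))
  cls <- classify_connections(W, 0.01)
  expect_equal(cls$mask, rbind(c(FALSE, FALSE), c(TRUE, FALSE)))
  # diagonal never counts even above threshold
  expect_false(cls$mask[1, 1])
  all_conn <- classify_connections(W, -Inf)
  expect_true(all(all_conn$mask[row(W) != col(W)]))
  expect_equal(all_conn$frac_connected, 1)
})

test_that("hidden signal correlations equal direct Pearson recomputation", {
  set.seed(5)
  task <- make_blob_task(n_classes = 4, n_train = 300, n_test = 120)
  cfg <- rnn_config(epochs = 1, seed = 5)
  net <- train_rnn(task$x_train, task$y_train, cfg, n_classes = 4)
  # duplicate a unit: identical incoming weights and bias
  net$params$W_in[, 2] <- net$params$W_in[, 1]
  net$params$W_rec[, 2] <- net$params$W_rec[, 1]
  net$params$b[2] <- net$params$b[1]
  sc <- hidden_signal_correlations(net, task$x_test)
  expect_equal(sc[1, 2], 1)
  h <- likewire:::rnn_forward(net$params, task$x_test,
                              cfg$timesteps)$h
  expect_equal(sc[3, 4], stats::cor(h[, 3], h[, 4]))
})

test_that("connection probability curve matches direct per-bin counting", {
  set.seed(6)
  h <- 30
  sig <- stats::cor(matrix(stats::rnorm(200 * h), 200, h))
  mask <- matrix(stats::runif(h * h) < 0.3, h, h); diag(mask) <- FALSE
  breaks <- seq(-1, 1, length.out = 6)
  got <- connection_probability_curve(mask, sig, breaks)
  off <- row(mask) != col(mask)
  bin <- cut(sig[off], breaks, labels = FALSE)
  codes <- sort(unique(bin))
  expect_equal(nrow(got), length(codes))
  for (k in seq_along(codes)) {
    expect_equal(got$p_connected[k], mean(mask[off][bin == codes[k]]))
    expect_equal(got$n_pairs[k], sum(bin == codes[k]))
  }
})

test_that("ablation is cumulative, capped, and strength-matched", {
  set.seed(8)
  task <- make_blob_task(n_classes = 4, n_train = 600, n_test = 200)
  cfg <- rnn_config(epochs = 3, seed = 8)
  net <- train_rnn(task$x_train, task$y_train, cfg, n_classes = 4)
  sc <- hidden_signal_correlations(net, task$x_test)
  base <- rnn_accuracy(net, task$x_test, task$y_test)
  set.seed(1)
  ab <- ablate_and_evaluate(net, task$x_test, task$y_test, sc,
                            "like_to_like", n_list = c(0, 20))
  expect_equal(ab$accuracy[1], base)     # n = 0 leaves the net untouched
  expect_warning(
    ablate_and_evaluate(net, task$x_test, task$y_test, sc,
                        "like_to_like", n_list = c(0, 1e6)),
    "capping")
  # strength matching: ablated-weight magnitude distributions agree
  set.seed(2)
  ab_l <- ablate_and_evaluate(net, task$x_test, task$y_test, sc,
                              "like_to_like", n_list = c(0, 150))
  set.seed(2)
  ab_r <- ablate_and_evaluate(net, task$x_test, task$y_test, sc,
                              "random", n_list = c(0, 150))
  ks <- stats::ks.test(abs(attr(ab_l, "ablated_weights")),
                       abs(attr(ab_r, "ablated_weights")))
  expect_gt(ks$p.value, 0.05)
  # removing every recurrent weight reaches the no-recurrence baseline
  gutted <- net; gutted$params$W_rec[] <- 0
  norec <- rnn_accuracy(gutted, task$x_test, task$y_test)
  all_pos <- net
  all_pos$params$W_rec[] <- 0
  expect_equal(rnn_accuracy(all_pos, task$x_test, task$y_test), norec)
})

test_that("post-post analysis delegates to the common-input machinery", {
  set.seed(9)
  task <- make_blob_task(n_classes = 4, n_train = 600, n_test = 200)
  cfg <- rnn_config(epochs = 3, seed = 9)
  net <- train_rnn(task$x_train, task$y_train, cfg, n_classes = 4)
  pp <- post_post_analysis(net, task$x_test)
  expect_true(all(c("rho_obs", "rho_exp") %in% names(pp$rho)))
  # recompute one unit's observed rho directly from the exported graph
  i <- pp$rho$pre_id[1]
  partners <- setdiff(seq_len(nrow(pp$sigcorr)), i)
  sims <- pp$sigcorr[partners, partners, drop = FALSE]
  diag(sims) <- NA_real_
  manual <- rho_observed(as.numeric(pp$mask[i, partners]), sims)
  expect_equal(pp$rho$rho_obs[1], manual)
})
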