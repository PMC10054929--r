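#' Configuration of the recurrent-network experiment
#'
#' A vanilla recurrent network: images pass through a trainable linear
#' input map, the static input drives a tanh recurrent layer for a fixed
#' number of timesteps, and a linear readout of the final hidden state
#' produces class scores. Trained with categorical cross-entropy and
#' Adam. The full-scale configuration is 1000 hidden units, 20
#' timesteps, 10 epochs, batch 512; the package defaults are the
#' desk-scale task (64 units, 12 timesteps, 12 epochs) on synthetic
#' Gaussian-blob images with a weak input drive (see [make_blob_task()]).
#'
#' @param hidden_units Hidden layer size.
#' @param timesteps Recurrent simulation steps.
#' @param epochs,batch_size,learning_rate Training schedule (Adam).
#' @param weight_threshold Recurrent weight above which a directed unit
#'   pair counts as connected (default 0.01).
#' @param sigcorr_threshold Signal-correlation threshold for
#'   like-to-like ablation candidates (default 0.2).
#' @param connection_percentile Percentile interpretation of the weight
#'   threshold (reported, not enforced; default 0.65 = top 35%).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return Object of class `rnn_config`.
#' @export
rnn_config <- function(hidden_units = 64L, timesteps = 12L, epochs = 12L,
                       batch_size = 128L, learning_rate = 1e-3,
                       weight_threshold = 0.01, sigcorr_threshold = 0.2,
                       connection_percentile = 0.65, seed = 1L) {
  stopifnot(hidden_units >= 2L, timesteps >= 1L)
  structure(list(hidden_units = as.integer(hidden_units),
                 timesteps = as.integer(timesteps),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_threshold = weight_threshold,
                 sigcorr_threshold = sigcorr_threshold,
                 connection_percentile = connection_percentile,
                 seed = as.integer(seed)),
            class = "rnn_config")
}

#' Synthetic Gaussian-blob image classification task
#'
#' Each class is a 2D Gaussian blob at a class-specific location on the
#' image, plus pixel noise -- a linearly separable stand-in for a digit
#' task that needs no external download.
#'
#' @param n_classes Number of classes (blob locations on a ring).
#' @param n_train,n_test Sample counts.
#' @param img Image side length (default 28).
#' @param blob_sd Blob width in pixels.
#' @param noise_sd Pixel noise sd.
#' @param jitter_px Random blob-center jitter per sample.
#' @param gain Overall image gain (default 0.03). The weak drive keeps
#'   the tanh hidden units in their sensitive range, so the recurrent
#'   amplification -- not the input map alone -- must carry the
#'   classification; with a strong static drive a small network solves
#'   the task feedforward and ablation of recurrent weights shows
#'   nothing.
#' @return List `x_train, y_train, x_test, y_test` with images flattened
#'   to rows and integer labels in `1..n_classes`.
#' @export
make_blob_task <- function(n_classes = 8L, n_train = 2000L, n_test = 500L,
                           img = 28L, blob_sd = 2.5, noise_sd = 0.2,
                           jitter_px = 1, gain = 0.03) {
  centers <- cbind(img / 2 + img / 4 * cos(2 * pi * seq_len(n_classes) /
                                             n_classes),
                   img / 2 + img / 4 * sin(2 * pi * seq_len(n_classes) /
                                             n_classes))
  gen <- function(n) {
    y <- sample.int(n_classes, n, replace = TRUE)
    px <- expand.grid(r = seq_len(img), c = seq_len(img))
    x <- matrix(0, n, img * img)
    for (i in seq_len(n)) {
      ctr <- centers[y[i], ] + stats::rnorm(2, sd = jitter_px)
      x[i, ] <- exp(-((px$r - ctr[1])^2 + (px$c - ctr[2])^2) /
                      (2 * blob_sd^2))
    }
    x <- gain * (x + matrix(stats::rnorm(n * img * img, sd = noise_sd), n))
    list(x = x, y = y)
  }
  tr <- gen(n_train); te <- gen(n_test)
  list(x_train = tr$x, y_train = tr$y, x_test = te$x, y_test = te$y,
       n_classes = n_classes)
}

rnn_init <- function(input_dim, n_classes, config) {
  h <- config$hidden_units
  list(
    W_in = matrix(stats::rnorm(input_dim * h, sd = 1 / sqrt(input_dim)),
                  input_dim, h),
    W_rec = matrix(stats::rnorm(h * h, sd = 1 / sqrt(h)), h, h),
    b = numeric(h),
    W_out = matrix(stats::rnorm(h * n_classes, sd = 1 / sqrt(h)),
                   h, n_classes),
    b_out = numeric(n_classes))
}

rnn_forward <- function(params, x, timesteps, keep_states = FALSE) {
  u <- x %*% params$W_in
  h <- matrix(0, nrow(x), ncol(u))
  states <- if (keep_states) vector("list", timesteps) else NULL
  for (t in seq_len(timesteps)) {
    h <- tanh(u + h %*% params$W_rec +
                matrix(params$b, nrow(x), length(params$b), byrow = TRUE))
    if (keep_states) states[[t]] <- h
  }
  logits <- h %*% params$W_out +
    matrix(params$b_out, nrow(x), length(params$b_out), byrow = TRUE)
  list(h = h, logits = logits, states = states, u = u)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the vanilla recurrent classifier
#'
#' Full backpropagation through time with the Adam optimizer; all three
#' layers (input map, recurrent weights, readout) are trained. Training
#' is serial and deterministic under the config seed.
#'
#' @param x Training images, samples x pixels.
#' @param y Integer class labels in `1..n_classes`.
#' @param config An [rnn_config()].
#' @param n_classes Number of classes (default `max(y)`).
#' @param verbose Print per-epoch loss.
#' @return Object of class `rnn_net`: the parameters, config, and the
#'   per-epoch training-loss trace.
#' @export
train_rnn <- function(x, y, config, n_classes = max(y), verbose = FALSE) {
  stopifnot(inherits(config, "rnn_config"), n_classes >= 2L)
  set.seed(config$seed)
  params <- rnn_init(ncol(x), n_classes, config)
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  Tn <- config$timesteps
  loss_trace <- numeric(config$epochs)
  Y <- diag(n_classes)[y, , drop = FALSE]
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(x))
    losses <- c()
    for (start in seq(1L, nrow(x), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, nrow(x))]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fw <- rnn_forward(params, xb, Tn, keep_states = TRUE)
      p_hat <- softmax_rows(fw$logits)
      losses <- c(losses, -mean(log(pmax(
        p_hat[cbind(seq_len(nrow(xb)), y[idx])], 1e-12))))
      nb <- nrow(xb)
      dlogits <- (p_hat - yb) / nb
      grads <- list(
        W_in = matrix(0, nrow(params$W_in), ncol(params$W_in)),
        W_rec = matrix(0, nrow(params$W_rec), ncol(params$W_rec)),
        b = numeric(length(params$b)),
        W_out = t(fw$h) %*% dlogits,
        b_out = colSums(dlogits))
      dh <- dlogits %*% t(params$W_out)
      dU <- matrix(0, nb, length(params$b))
      for (t in rev(seq_len(Tn))) {
        ht <- fw$states[[t]]
        da <- dh * (1 - ht^2)
        h_prev <- if (t > 1L) fw$states[[t - 1L]] else matrix(0, nb,
                                                              ncol(ht))
        grads$W_rec <- grads$W_rec + t(h_prev) %*% da
        grads$b <- grads$b + colSums(da)
        dU <- dU + da
        dh <- da %*% t(params$W_rec)
      }
      grads$W_in <- t(xb) %*% dU
      step <- step + 1L
      for (nm in names(params)) {
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * grads[[nm]]
        v_state[[nm]] <- beta2 * v_state[[nm]] +
          (1 - beta2) * grads[[nm]]^2
        m_hat <- m_state[[nm]] / (1 - beta1^step)
        v_hat <- v_state[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
      }
    }
    loss_trace[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, loss_trace[ep]))
  }
  structure(list(params = params, config = config, n_classes = n_classes,
                 loss_trace = loss_trace),
            class = "rnn_net")
}

#' Untrained network with the same initialization
#' @inheritParams train_rnn
#' @return An `rnn_net` with freshly initialized, untrained parameters.
#' @export
untrained_rnn <- function(x, config, n_classes) {
  set.seed(config$seed)
  structure(list(params = rnn_init(ncol(x), n_classes, config),
                 config = config, n_classes = n_classes,
                 loss_trace = numeric(0)),
            class = "rnn_net")
}

#' Classification accuracy of a network
#' @param net An `rnn_net`.
#' @param x,y Evaluation stimuli and labels.
#' @return Fraction correct.
#' @export
rnn_accuracy <- function(net, x, y) {
  fw <- rnn_forward(net$params, x, net$config$timesteps)
  mean(max.col(fw$logits) == y)
}

#' Pairwise signal correlations of hidden units
#'
#' Each unit's response to a stimulus is its final-timestep activation
#' (what the readout sees); the dynamics are deterministic, so response
#' correlation across the stimulus set is the network analog of signal
#' correlation. Constant-response units get `NA` rows/columns.
#'
#' @param net An `rnn_net`.
#' @param stimuli Held-out stimulus matrix, samples x pixels.
#' @return `hidden_units` x `hidden_units` correlation matrix.
#' @export
hidden_signal_correlations <- function(net, stimuli) {
  fw <- rnn_forward(net$params, stimuli, net$config$timesteps)
  resp <- fw$h
  sds <- apply(resp, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(resp))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  cc
}

#' Classify directed unit pairs as connected
#'
#' A pre/post pair is connected when the recurrent weight exceeds the
#' threshold; the threshold's percentile in the weight distribution is
#' reported alongside.
#'
#' @param W_rec Recurrent weight matrix (`W_rec[i, j]` = weight from
#'   unit i to unit j).
#' @param weight_threshold Threshold (default 0.01).
#' @return List with `mask` (logical matrix, diagonal `FALSE`),
#'   `threshold`, `threshold_percentile`, `frac_connected`.
#' @export
classify_connections <- function(W_rec, weight_threshold = 0.01) {
  mask <- W_rec > weight_threshold
  diag(mask) <- FALSE
  w <- W_rec[row(W_rec) != col(W_rec)]
  list(mask = mask, threshold = weight_threshold,
       threshold_percentile = mean(w <= weight_threshold),
       frac_connected = mean(mask[row(mask) != col(mask)]))
}

#' Connection probability as a function of signal correlation
#'
#' Empirical probability of connection per signal-correlation bin over
#' all ordered unit pairs, with exact binomial confidence intervals.
#'
#' @param mask Connected mask from [classify_connections()].
#' @param sigcorr Matrix from [hidden_signal_correlations()].
#' @param breaks Bin breaks over signal correlation (default 8 bins over
#'   the observed range).
#' @return Data frame `bin_mid, p_connected, lo, hi, n_pairs` (empty
#'   bins omitted).
#' @export
connection_probability_curve <- function(mask, sigcorr, breaks = 8) {
  off <- row(mask) != col(mask) & is.finite(sigcorr)
  s <- sigcorr[off]; m <- mask[off]
  if (length(breaks) == 1L) {
    breaks <- seq(min(s), max(s), length.out = breaks + 1L)
    breaks[1] <- breaks[1] - 1e-9
  }
  bin <- cut(s, breaks, labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(k) {
    sel <- bin == k
    n <- sum(sel); x <- sum(m[sel])
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(bin_mid = (breaks[k] + breaks[k + 1L]) / 2,
               p_connected = x / n, lo = ci[1], hi = ci[2], n_pairs = n)
  })
  do.call(rbind, rows)
}

#' Ablate connections and track test accuracy
#'
#' Like-to-like mode draws ablation targets from directed pairs passing
#' both thresholds (weight above `weight_threshold` and signal
#' correlation above `sigcorr_threshold`); random mode draws
#' strength-matched controls from the remaining connected pairs,
#' stratified into deciles of |weight| matched to the like-to-like
#' sample. Ablated weights are set to zero permanently (cumulative along
#' `n_list`).
#'
#' @param net A trained `rnn_net`.
#' @param x,y Test stimuli and labels.
#' @param sigcorr Signal-correlation matrix of the hidden units.
#' @param mode `"like_to_like"` or `"random"`.
#' @param n_list Increasing numbers of ablated connections.
#' @return Data frame `n_ablated, accuracy, mode`; an attribute
#'   `ablated_weights` carries the ablated weight values for
#'   strength-matching checks.
#' @export
ablate_and_evaluate <- function(net, x, y, sigcorr,
                                mode = c("like_to_like", "random"),
                                n_list = c(0, 50, 100, 200, 400)) {
  mode <- match.arg(mode)
  cfg <- net$config
  W <- net$params$W_rec
  offdiag <- row(W) != col(W)
  like_pool <- which(offdiag & W > cfg$weight_threshold &
                       is.finite(sigcorr) &
                       sigcorr > cfg$sigcorr_threshold)
  n_list <- sort(unique(n_list))
  if (max(n_list) > length(like_pool)) {
    warning("requested ablation exceeds candidate pool; capping at ",
            length(like_pool))
    n_list <- unique(pmin(n_list, length(like_pool)))
  }
  # order of removal fixed up-front so ablation is cumulative
  like_order <- sample(like_pool, min(max(n_list), length(like_pool)))
  if (mode == "like_to_like") {
    removal <- like_order
  } else {
    # strength-match the random removals to the like-to-like removals;
    # the random pool is any connected weight not in the like-to-like
    # removal set (matching the full-scale protocol of drawing random
    # weights with the same connection strengths)
    conn_pool <- setdiff(which(offdiag & W > cfg$weight_threshold),
                         like_order)
    edges <- stats::quantile(abs(W[like_pool]), probs = seq(0, 1, 0.1))
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    target_bins <- cut(abs(W[like_order]), edges, labels = FALSE)
    pool_bins <- cut(abs(W[conn_pool]), edges, labels = FALSE)
    removal <- integer(0)
    remaining <- conn_pool
    rem_bins <- pool_bins
    for (k in seq_along(like_order)) {
      if (length(remaining) == 0L) {
        warning("random pool exhausted; capping at ", length(removal))
        n_list <- unique(pmin(n_list, length(removal)))
        break
      }
      cand <- remaining[rem_bins == target_bins[k]]
      pick <- if (length(cand) > 0L) {
        if (length(cand) == 1L) cand else sample(cand, 1L)
      } else {
        if (length(remaining) == 1L) remaining else sample(remaining, 1L)
      }
      removal <- c(removal, pick)
      drop <- match(pick, remaining)
      remaining <- remaining[-drop]
      rem_bins <- rem_bins[-drop]
    }
  }
  rows <- list()
  params <- net$params
  done <- 0L
  for (n in n_list) {
    if (n > done) {
      params$W_rec[removal[(done + 1L):n]] <- 0
      done <- n
    }
    net2 <- net
    net2$params <- params
    rows[[length(rows) + 1L]] <- data.frame(
      n_ablated = n, accuracy = rnn_accuracy(net2, x, y), mode = mode)
  }
  out <- do.call(rbind, rows)
  attr(out, "ablated_weights") <- W[removal]
  out
}

#' Observed vs pairwise-expected post-post similarity in the network
#'
#' Treats the thresholded weight matrix as a connectivity graph with one
#' synapse per connected pair and reuses the common-input machinery: for
#' each unit with at least two outgoing connections, the observed rho
#' (mean signal correlation among its target units, connection-weighted)
#' is compared with the rho-prime expected from a pairwise Poisson model
#' of connectivity on signal correlation.
#'
#' @param net An `rnn_net`.
#' @param stimuli Held-out stimuli for signal correlations.
#' @return List with `rho` (data frame per presynaptic unit) and `test`
#'   (the paired comparison from [compare_rho()]).
#' @export
post_post_analysis <- function(net, stimuli) {
  sigcorr <- hidden_signal_correlations(net, stimuli)
  cls <- classify_connections(net$params$W_rec,
                              net$config$weight_threshold)
  h <- nrow(sigcorr)
  units <- seq_len(h)
  pre <- rep(units, times = h - 1L)
  post <- unlist(lapply(units, function(i) units[-i]))
  pairs <- data.frame(
    pre_id = pre, post_id = post,
    nsyn = as.integer(cls$mask[cbind(pre, post)]),
    sim_signal_corr = sigcorr[cbind(pre, post)],
    projection = factor("recurrent"))
  pairs <- pairs[is.finite(pairs$sim_signal_corr), ]
  fit <- fit_joint_pairwise_model(pairs, metrics = "sim_signal_corr",
                                  method = "glm")
  lookup <- function(ids) {
    m <- sigcorr[ids, ids, drop = FALSE]
    diag(m) <- NA_real_
    m
  }
  rho <- rho_analysis(pairs, lookup, fit = fit)
  list(rho = rho, test = compare_rho(rho), sigcorr = sigcorr,
       mask = cls$mask)
}
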