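#' Observed common-input similarity (rho)
#'
#' For presynaptic neuron i, the synapse-count-weighted mean pairwise
#' similarity over its partners:
#' `rho(i) = sum_{j != k} Sim_jk * Nsyn_ij * Nsyn_ik /
#'           sum_{j != k} Sim-weights`, with j, k ranging over the
#' candidate partners of i (excluding i itself). Weights are symmetric,
#' so ordered and unordered summation give the same value. Defined only
#' when at least two partners have `Nsyn > 0`.
#'
#' @param nsyn Named or plain numeric vector of synapse counts from the
#'   presynaptic neuron to each candidate partner.
#' @param sims Symmetric similarity matrix among the same partners
#'   (diagonal ignored), dimensions `length(nsyn)` square.
#' @return The weighted mean similarity.
#' @export
rho_observed <- function(nsyn, sims) {
  n <- length(nsyn)
  if (!is.matrix(sims) || nrow(sims) != n || ncol(sims) != n) {
    stop("`sims` must be a square matrix matching `nsyn`", call. = FALSE)
  }
  if (sum(nsyn > 0) < 2L) {
    stop("rho undefined: fewer than 2 partners with synapses",
         call. = FALSE)
  }
  W <- outer(nsyn, nsyn)
  diag(W) <- 0
  keep <- is.finite(sims)
  diag(keep) <- FALSE
  sum(W[keep] * sims[keep]) / sum(W[keep])
}

#' Joint pairwise like-to-like model for Nsyn
#'
#' A single Poisson model for the synapse count including all three
#' functional similarities (signal correlation, feature similarity, RF
#' center distance), projection type, and all similarity-by-projection
#' interactions, with a grouping intercept per (presyn x projection).
#' This is the "as much pairwise rule as possible" model whose
#' predictions define the pairwise expectation rho-prime.
#'
#' @param pairs Pair table with `nsyn`, the three similarity columns, and
#'   `projection`.
#' @param metrics Similarity columns to include.
#' @param method `"glm"` (fixed-effects fallback) or `"glmm"`.
#' @return Object of class `joint_pairwise_fit` with the fitted model
#'   and a `predict` helper used by [rho_expected()].
#' @export
fit_joint_pairwise_model <- function(pairs,
                                     metrics = c("sim_signal_corr",
                                                 "sim_feature",
                                                 "rf_distance_deg"),
                                     method = c("glm", "glmm")) {
  method <- match.arg(method)
  stopifnot(all(c(metrics, "nsyn", "projection", "pre_id") %in% names(pairs)))
  d <- pairs
  d$projection <- droplevels(factor(d$projection))
  d$pre_id <- factor(d$pre_id)
  d$group <- interaction(d$pre_id, d$projection, drop = TRUE)
  multi_proj <- nlevels(d$projection) >= 2L
  sim_terms <- if (multi_proj)
    paste(sprintf("%s * projection", metrics), collapse = " + ") else
      paste(metrics, collapse = " + ")
  fit <- NULL
  degraded <- FALSE
  if (method == "glmm") {
    form <- stats::as.formula(paste("nsyn ~", sim_terms, "+ (1 | group)"))
    fit <- glmmTMB::glmmTMB(form, data = d, family = stats::poisson())
    if (any(!is.finite(as.matrix(stats::vcov(fit)$cond)))) {
      degraded <- TRUE
    }
  }
  if (method == "glm" || degraded) {
    form <- stats::as.formula(paste("nsyn ~", sim_terms, "+ group"))
    fit <- stats::glm(form, data = d, family = stats::poisson())
    if (any(is.na(stats::coef(fit)))) {
      # rank deficiency: degrade to main effects
      degraded <- TRUE
      form <- stats::as.formula(paste(
        "nsyn ~", paste(metrics, collapse = " + "),
        if (multi_proj) "+ projection" else "", "+ group"))
      fit <- stats::glm(form, data = d, family = stats::poisson())
    }
    method <- "glm"
  }
  structure(list(model = fit, method = method, metrics = metrics,
                 degraded = degraded, data = d),
            class = "joint_pairwise_fit")
}

#' Predicted synapse counts from the joint pairwise model
#' @param object A `joint_pairwise_fit`.
#' @param ... Unused.
#' @return Numeric vector of predicted Nsyn, aligned with the pair table
#'   the model was fitted on.
#' @export
predict.joint_pairwise_fit <- function(object, ...) {
  as.numeric(stats::fitted(object$model))
}

#' Expected common-input similarity under the pairwise rule (rho-prime)
#'
#' The rho formula evaluated with the model-predicted synapse counts
#' over all candidate partners of the presynaptic neuron (not only the
#' observed postsynaptic targets).
#'
#' @param nsyn_pred Predicted synapse counts to each candidate partner.
#' @param sims Symmetric similarity matrix among the partners.
#' @return The pairwise-expected weighted mean similarity.
#' @export
rho_expected <- function(nsyn_pred, sims) {
  n <- length(nsyn_pred)
  if (!is.matrix(sims) || nrow(sims) != n || ncol(sims) != n) {
    stop("`sims` must be a square matrix matching `nsyn_pred`",
         call. = FALSE)
  }
  if (all(nsyn_pred <= 0)) stop("all predicted counts are zero",
                                call. = FALSE)
  W <- outer(nsyn_pred, nsyn_pred)
  diag(W) <- 0
  keep <- is.finite(sims)
  diag(keep) <- FALSE
  sum(W[keep] * sims[keep]) / sum(W[keep])
}

#' Compute rho and rho-prime for every presynaptic neuron
#'
#' Fits the joint pairwise model (unless one is supplied), then for each
#' presynaptic neuron with at least two synaptic partners computes the
#' observed rho over its candidate set and the pairwise-expected
#' rho-prime from the model predictions over the same candidates.
#' Partner-pair similarity is the chosen metric evaluated between
#' candidate partners (by default the feature cosine of the generating
#' population is used when a population is supplied; otherwise a
#' similarity matrix per presyn must be provided via `sim_lookup`).
#'
#' @param pairs Pair table.
#' @param sim_lookup Function `(post_ids) -> similarity matrix` among the
#'   given partner neurons, e.g. built from a population's feature
#'   matrix or response signal correlations.
#' @param fit Optional pre-fitted [fit_joint_pairwise_model()] result.
#' @param method Backend for the joint model when `fit` is missing.
#' @return Data frame `pre_id, rho_obs, rho_exp, n_post` (class
#'   `rho_result`), one row per presynaptic neuron with defined rho.
#' @export
rho_analysis <- function(pairs, sim_lookup, fit = NULL,
                         method = c("glm", "glmm")) {
  if (is.null(fit)) fit <- fit_joint_pairwise_model(pairs, method = method)
  pred <- predict(fit)
  rows <- list()
  for (i in unique(pairs$pre_id)) {
    sel <- which(pairs$pre_id == i)
    nsyn <- pairs$nsyn[sel]
    if (sum(nsyn > 0) < 2L) next
    sims <- sim_lookup(pairs$post_id[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      pre_id = i,
      rho_obs = rho_observed(nsyn, sims),
      rho_exp = rho_expected(pred[sel], sims),
      n_post = sum(nsyn > 0))
  }
  if (length(rows) == 0L) {
    stop("no presynaptic neuron has 2+ synaptic partners", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rho_result", class(out))
  out
}

#' Build a partner-similarity lookup from a feature matrix
#'
#' @param features Neuron-by-dimension feature matrix with rows indexed
#'   by neuron id.
#' @return Function mapping a vector of neuron ids to their pairwise
#'   cosine-similarity matrix.
#' @export
feature_sim_lookup <- function(features) {
  norm <- features / sqrt(rowSums(features^2))
  function(ids) {
    m <- norm[ids, , drop = FALSE] %*% t(norm[ids, , drop = FALSE])
    diag(m) <- NA_real_
    m
  }
}

#' Paired comparison of observed vs pairwise-expected rho
#'
#' Paired t-test of rho against rho-prime across presynaptic neurons. A
#' positive mean difference indicates common-input structure beyond the
#' pairwise like-to-like rule: the postsynaptic cohorts are more similar
#' to each other than the pairwise model predicts.
#'
#' @param rho A `rho_result` from [rho_analysis()].
#' @return List with `mean_diff`, `t`, `p`, `n_presyn`, `conf_int`.
#' @export
compare_rho <- function(rho) {
  if (nrow(rho) < 2L) {
    stop("need at least 2 presynaptic neurons with defined rho",
         call. = FALSE)
  }
  d <- rho$rho_obs - rho$rho_exp
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), t = 0, p = 1, n_presyn = nrow(rho),
                conf_int = c(mean(d), mean(d))))
  }
  tt <- stats::t.test(rho$rho_obs, rho$rho_exp, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, n_presyn = nrow(rho),
       conf_int = as.numeric(tt$conf.int))
}
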