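#' @title Like-to-like regression models
#' @description
#' The axonal-scale model regresses the co-travel distance Ld on a
#' functional-similarity metric, projection type, and their interaction,
#' with a grouping intercept per (presynaptic neuron x projection type),
#' under a log-link Tweedie law (continuous, nonnegative, exact zeros).
#' The synaptic-scale models do the same for the synapse count Nsyn
#' (Poisson), optionally with `log Ld` (in mm) as an offset so the
#' coefficients describe the synapse conversion rate Nsyn/Ld -- the
#' like-to-like selectivity left after conditioning on axonal
#' opportunity.
#' @name ltl-models
NULL

ltl_prepare <- function(pairs, metric, response) {
  need <- c("pre_id", "projection", metric, response)
  if (!all(need %in% names(pairs))) {
    stop("pair table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    y = pairs[[response]],
    sim = pairs[[metric]],
    projection = droplevels(factor(pairs$projection)),
    pre_id = factor(pairs$pre_id))
  if (any(!is.finite(d$sim))) stop("non-finite similarity values",
                                   call. = FALSE)
  # projection levels with all-zero response carry no information for a
  # log-link model with its own intercept: drop with a warning
  zero_lev <- tapply(d$y, d$projection, function(v) all(v == 0))
  if (any(zero_lev)) {
    warning("dropping projection level(s) with all-zero response: ",
            paste(names(zero_lev)[zero_lev], collapse = ", "))
    d <- droplevels(d[!(d$projection %in% names(zero_lev)[zero_lev]), ])
  }
  d$group <- interaction(d$pre_id, d$projection, drop = TRUE)
  d
}

ltl_fit_backend <- function(d, family, method, xi = 1.5, offset_log = NULL) {
  d$off <- if (is.null(offset_log)) 0 else offset_log
  single_proj <- nlevels(d$projection) < 2L
  if (method == "glmm") {
    form <- if (single_proj) y ~ sim + (1 | group) + offset(off) else
      y ~ sim * projection + (1 | group) + offset(off)
    fam <- switch(family,
                  tweedie = glmmTMB::tweedie(link = "log"),
                  poisson = stats::poisson(link = "log"))
    fit <- glmmTMB::glmmTMB(form, data = d, family = fam)
    beta <- glmmTMB::fixef(fit)$cond
    V <- as.matrix(stats::vcov(fit)$cond)
    re_var <- glmmTMB::VarCorr(fit)$cond$group[1, 1]
    phi <- stats::sigma(fit)
    xi_hat <- if (family == "tweedie")
      unname(glmmTMB::family_params(fit)) else NA_real_
    ll <- as.numeric(stats::logLik(fit))
    mu <- stats::fitted(fit)
    singular <- any(!is.finite(V))
  } else {
    # exact fixed-effects fallback: one intercept per (presyn x projection).
    # Groups whose responses are all zero are profiled out exactly: their
    # intercept tends to -Inf, the group's likelihood contribution tends
    # to one, and such rows carry no information on the slopes -- keeping
    # them only destabilizes the IRLS.
    all_zero <- tapply(d$y, d$group, function(v) all(v == 0))
    if (any(all_zero)) {
      d <- droplevels(d[!(d$group %in% names(all_zero)[all_zero]), ,
                        drop = FALSE])
      single_proj <- nlevels(d$projection) < 2L
    }
    form <- if (single_proj) y ~ sim + group + offset(off) else
      y ~ sim * projection + group + offset(off)
    fam <- switch(family,
                  tweedie = mgcv::Tweedie(p = xi, link = "log"),
                  poisson = stats::poisson(link = "log"))
    fit <- tryCatch(
      stats::glm(form, data = d, family = fam),
      error = function(e) NULL)
    if (is.null(fit)) {
      # IRLS can diverge with extreme offsets in sparse groups; restart
      # from the marginal rate
      mustart <- rep(max(mean(d$y), 1e-3), nrow(d)) * exp(d$off)
      fit <- stats::glm(form, data = d, family = fam,
                        mustart = pmax(mustart, 1e-8),
                        control = stats::glm.control(maxit = 100))
    }
    cf <- stats::coef(fit)
    keep <- !startsWith(names(cf), "group") & !is.na(cf)
    beta <- cf[keep]
    V <- stats::vcov(fit)[names(beta), names(beta), drop = FALSE]
    gr <- cf[startsWith(names(cf), "group")]
    re_var <- if (length(gr) > 1L) stats::var(gr, na.rm = TRUE) else 0
    phi <- if (family == "tweedie")
      summary(fit)$dispersion else 1
    xi_hat <- if (family == "tweedie") xi else NA_real_
    ll <- if (family == "poisson") as.numeric(stats::logLik(fit)) else
      sum(dtweedie_series(d$y, stats::fitted(fit),
                          tweedie_params(xi, phi), log = TRUE))
    mu <- stats::fitted(fit)
    singular <- any(is.na(cf[keep]))
  }
  list(fit = fit, beta = beta, vcov = V, re_var = re_var, phi = phi,
       xi = xi_hat, logLik = ll, mu = mu, singular = singular, data = d)
}

## Nakagawa-style pseudo-R2 on the latent (log) scale, lognormal
## approximation for the observation-level variance.
nakagawa_r2 <- function(d, beta, re_var, family, phi, xi, offset_log = NULL) {
  X <- if (nlevels(d$projection) < 2L) stats::model.matrix(~sim, d) else
    stats::model.matrix(~ sim * projection, d)
  b <- beta[colnames(X)]
  if (anyNA(b)) return(c(marginal = NA_real_, conditional = NA_real_))
  eta_f <- as.numeric(X %*% b)
  var_f <- stats::var(eta_f)
  mu_bar <- mean(exp(eta_f + if (is.null(offset_log)) 0 else offset_log))
  var_e <- switch(family,
                  poisson = log1p(1 / mu_bar),
                  tweedie = log1p(phi * mu_bar^(xi - 2)))
  tot <- var_f + re_var + var_e
  c(marginal = var_f / tot, conditional = (var_f + re_var) / tot)
}

ltl_fit <- function(pairs, metric, response, family, method, xi,
                    profile_xi, offset_log = NULL, scale) {
  method <- match.arg(method, c("glm", "glmm"))
  d <- ltl_prepare(pairs, metric, response)
  if (!is.null(offset_log)) offset_log <- offset_log[as.numeric(rownames(d))]
  if (family == "tweedie" && profile_xi && method == "glm") {
    d$off <- if (is.null(offset_log)) 0 else offset_log
    prof <- profile_tweedie_xi(
      if (nlevels(d$projection) < 2L) y ~ sim + group + offset(off) else
        y ~ sim * projection + group + offset(off), d)
    xi <- prof$xi
  }
  bk <- ltl_fit_backend(d, family, method, xi, offset_log)
  r2 <- nakagawa_r2(bk$data, bk$beta, bk$re_var, family, bk$phi, bk$xi,
                    bk$data$off)
  structure(list(
    family = family, method = method, metric = metric, scale = scale,
    coefficients = bk$beta, vcov = bk$vcov, re_var = bk$re_var,
    phi = bk$phi, xi = bk$xi, logLik = bk$logLik,
    r_squared = r2, singular = bk$singular,
    projection_levels = levels(bk$data$projection),
    n = nrow(bk$data), data = bk$data, model = bk$fit),
    class = "ltl_fit")
}

#' Fit the axonal-scale (Tweedie) like-to-like model for Ld
#'
#' `log E[Ld] = b0 + b1*Sim + b2*Proj + b3*Sim:Proj + u(presyn x Proj)`
#' with a Tweedie error law (index in (1,2)). Zero-Ld pairs must be
#' included -- they carry the zero-inflation information.
#'
#' @param pairs Pair table (see [generate_anatomy()]): needs `pre_id`,
#'   `projection`, `ld_um` and the similarity column.
#' @param metric Similarity column name (e.g. `"sim_feature"`,
#'   `"sim_signal_corr"`, `"rf_distance_deg"`).
#' @param method `"glmm"` for the Laplace random-intercept fit
#'   (glmmTMB), `"glm"` for the exact fixed-effects fallback with one
#'   intercept per (presyn x projection) group.
#' @param xi Tweedie index: used directly by the `"glm"` backend
#'   (default 1.5); the `"glmm"` backend estimates it.
#' @param profile_xi If `TRUE` (glm backend), choose `xi` by profile
#'   likelihood over a grid in (1, 2).
#' @return An `ltl_fit` object; see [conditional_slopes()].
#' @export
fit_ld_model <- function(pairs, metric = "sim_feature",
                         method = c("glm", "glmm"), xi = 1.5,
                         profile_xi = FALSE) {
  ltl_fit(pairs, metric, "ld_um", "tweedie", match.arg(method), xi,
          profile_xi, scale = "axonal")
}

#' Fit the joint-scale (Poisson) like-to-like model for Nsyn
#'
#' Same fixed/random structure as [fit_ld_model()] with a Poisson law for
#' the synapse count; its slopes mix axonal- and synaptic-scale
#' selectivity.
#' @inheritParams fit_ld_model
#' @return An `ltl_fit` object.
#' @export
fit_nsyn_model <- function(pairs, metric = "sim_feature",
                           method = c("glm", "glmm")) {
  ltl_fit(pairs, metric, "nsyn", "poisson", match.arg(method), NA,
          FALSE, scale = "joint")
}

#' Fit the synaptic-scale (synapse conversion rate) model
#'
#' Poisson model for Nsyn with `log Ld` (in mm) as a fixed offset,
#' restricted to pairs with positive co-travel: the slopes measure
#' synapses per millimetre of co-travel, i.e. selectivity at the
#' synaptic scale after conditioning on axonal opportunity.
#'
#' @inheritParams fit_ld_model
#' @param pairs Pair table restricted to `ld_um > 0`; rows violating this
#'   are rejected with an error.
#' @return An `ltl_fit` object.
#' @export
fit_density_model <- function(pairs, metric = "sim_feature",
                              method = c("glm", "glmm")) {
  if (any(pairs$ld_um <= 0)) {
    stop("fit_density_model requires pairs with ld_um > 0; subset first",
         call. = FALSE)
  }
  off <- log(pairs$ld_um / 1000)   # co-travel in mm
  rownames(pairs) <- seq_len(nrow(pairs))
  ltl_fit(pairs, metric, "nsyn", "poisson", match.arg(method), NA,
          FALSE, offset_log = off, scale = "synaptic")
}

#' @export
print.ltl_fit <- function(x, ...) {
  cat(sprintf(
    "<ltl_fit> %s-scale %s model (%s backend), metric %s, n = %d\n",
    x$scale, x$family, x$method, x$metric, x$n))
  if (x$family == "tweedie") {
    cat(sprintf("  xi = %.3f, phi = %.3f\n", x$xi, x$phi))
  }
  cat(sprintf("  R2 (Nakagawa): marginal %.3f, conditional %.3f\n",
              x$r_squared["marginal"], x$r_squared["conditional"]))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Per-projection conditional like-to-like slopes
#'
#' The slope of the linear predictor in the similarity metric,
#' conditioned on each projection type: `b1` for the reference level and
#' `b1 + b3[proj]` otherwise, with delta-method standard errors from the
#' fixed-effect covariance, Wald p-values, and Benjamini-Hochberg
#' adjustment across the reported family of projections.
#'
#' @param fit An `ltl_fit`.
#' @return Data frame `metric, scale, projection, slope, se, z, p, p_adj`.
#' @export
conditional_slopes <- function(fit) {
  stopifnot(inherits(fit, "ltl_fit"))
  if (is.null(fit$vcov) || any(!is.finite(fit$vcov))) {
    stop("fit has no finite fixed-effect covariance", call. = FALSE)
  }
  cn <- names(fit$coefficients)
  levs <- fit$projection_levels
  out <- lapply(levs, function(lv) {
    L <- stats::setNames(numeric(length(cn)), cn)
    L["sim"] <- 1
    inter <- paste0("sim:projection", lv)
    if (inter %in% cn) L[inter] <- 1
    slope <- sum(L * fit$coefficients)
    se <- sqrt(as.numeric(t(L) %*% fit$vcov %*% L))
    z <- slope / se
    data.frame(metric = fit$metric, scale = fit$scale, projection = lv,
               slope = slope, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Admissible projection levels for synaptic-scale reporting
#'
#' Keeps projection types with more than 30 synapses observed, more than
#' 5 presynaptic neurons, and no single presynaptic neuron contributing
#' more than half of the level's synapses.
#'
#' @param pairs Pair table with `pre_id, projection, nsyn`.
#' @param min_synapses,min_presyn Strict lower bounds (defaults 30, 5).
#' @param max_presyn_share Maximum share of one presyn (default 0.5).
#' @return Character vector of admissible projection levels.
#' @export
filter_projections <- function(pairs, min_synapses = 30, min_presyn = 5,
                               max_presyn_share = 0.5) {
  levs <- unique(as.character(pairs$projection))
  keep <- vapply(levs, function(lv) {
    p <- pairs[pairs$projection == lv, ]
    tot <- sum(p$nsyn)
    if (tot <= min_synapses) return(FALSE)
    if (length(unique(p$pre_id)) <= min_presyn) return(FALSE)
    by_pre <- tapply(p$nsyn, p$pre_id, sum)
    max(by_pre) / tot <= max_presyn_share
  }, logical(1))
  levs[keep]
}

#' Paired cohort comparison of mean functional similarity
#'
#' For each presynaptic neuron (within a projection type, and pooled),
#' the mean similarity to its connected, ADP-control, and
#' same-region-control partners is computed; presynaptic neurons with
#' more than `min_targets` connected targets qualify. Paired t-tests
#' compare the cohort means across presynaptic neurons, with BH
#' adjustment over the reported comparisons.
#'
#' @param pairs Pair table carrying a `cohort` column (see
#'   [build_cohorts()]) and the similarity metric.
#' @param metric Similarity column name.
#' @param min_targets Strict lower bound on connected targets per
#'   presynaptic neuron (default 10).
#' @param by_projection Also report per-projection tests.
#' @return Data frame `projection, comparison, n_presyn, mean_diff, t, p,
#'   p_adj`; comparisons with fewer than 2 qualifying presyns are
#'   reported with `NA` statistics and a `note`.
#' @export
paired_cohort_test <- function(pairs, metric = "sim_signal_corr",
                               min_targets = 10, by_projection = TRUE) {
  stopifnot("cohort" %in% names(pairs), metric %in% names(pairs))
  scopes <- list(all = pairs)
  if (by_projection) {
    for (lv in unique(as.character(pairs$projection))) {
      scopes[[lv]] <- pairs[pairs$projection == lv, ]
    }
  }
  comps <- list(c("connected", "adp_control"),
                c("connected", "same_region_control"),
                c("adp_control", "same_region_control"))
  rows <- list()
  for (sc in names(scopes)) {
    p <- scopes[[sc]]
    n_conn <- tapply(p$cohort == "connected", p$pre_id, sum)
    qualified <- names(n_conn)[n_conn > min_targets]
    means <- lapply(c("connected", "adp_control", "same_region_control"),
                    function(ch) {
                      sel <- p$cohort == ch & p$pre_id %in% qualified
                      tapply(p[[metric]][sel], factor(p$pre_id[sel],
                                                      levels = qualified),
                             mean, na.rm = TRUE)
                    })
    names(means) <- c("connected", "adp_control", "same_region_control")
    for (cmp in comps) {
      a <- means[[cmp[1]]]; b <- means[[cmp[2]]]
      ok <- is.finite(a) & is.finite(b)
      lab <- paste(cmp, collapse = " vs ")
      if (sum(ok) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          projection = sc, comparison = lab, n_presyn = sum(ok),
          mean_diff = NA_real_, t = NA_real_, p = NA_real_,
          note = "fewer than 2 qualifying presynaptic neurons",
          stringsAsFactors = FALSE)
      } else if (stats::sd(a[ok] - b[ok]) == 0) {
        # constant differences: degenerate paired t
        m <- mean(a[ok] - b[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          projection = sc, comparison = lab, n_presyn = sum(ok),
          mean_diff = m, t = if (m == 0) 0 else sign(m) * Inf,
          p = if (m == 0) 1 else 0, note = "constant differences",
          stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          projection = sc, comparison = lab, n_presyn = sum(ok),
          mean_diff = unname(tt$estimate), t = unname(tt$statistic),
          p = tt$p.value, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  has_p <- !is.na(out$p)
  out$p_adj[has_p] <- bh_adjust(out$p[has_p])
  out
}

#' Two-step residual regression of similarity on synaptic anatomy
#'
#' Step 1 regresses functional similarity on Ld by ordinary least
#' squares and keeps the residuals (the similarity variation not
#' explained by physical proximity). Step 2 regresses those residuals on
#' the synapse count and the mean log10 cleft volume of the connection.
#' Restricted to connected pairs (`nsyn >= 1`) with cleft measurements.
#'
#' @param pairs Pair table with `ld_um, nsyn, mean_log10_cleft` and the
#'   metric column.
#' @param metric Similarity column name.
#' @return List with `step1` (lm), `step2` (lm) and `coefficients` (tidy
#'   data frame for step 2).
#' @export
residual_anatomy_regression <- function(pairs, metric = "sim_signal_corr") {
  d <- pairs[pairs$nsyn >= 1 & is.finite(pairs$mean_log10_cleft), ]
  if (nrow(d) < 4L) stop("fewer connected records than parameters",
                         call. = FALSE)
  d$sim <- d[[metric]]
  step1 <- stats::lm(sim ~ ld_um, data = d)
  d$resid_sim <- stats::resid(step1)
  step2 <- stats::lm(resid_sim ~ nsyn + mean_log10_cleft, data = d)
  sm <- summary(step2)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      se = sm[, 2], t = sm[, 3], p = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(step1 = step1, step2 = step2, coefficients = coefs)
}

#' Presyn-centered binning with bootstrap errors
#'
#' Visualization summary of how an anatomical quantity varies with a
#' functional similarity: per presynaptic neuron the mean similarity and
#' mean outcome over its eligible pairs are subtracted (removing
#' presyn-level offsets), the centered pairs are binned by delta
#' similarity, and the per-bin mean delta outcome is computed, with a
#' bootstrap SD over pair resampling (presyn means recomputed per
#' resample). For `y = "ld"` the eligible pairs are those with no
#' synapses; for `y = "density"` those with `ld_um > 0`, with the
#' outcome Nsyn per millimetre of co-travel.
#'
#' @param pairs Pair table.
#' @param y `"ld"` or `"density"`.
#' @param metric Similarity column name.
#' @param n_bins Number of equal-width bins over the delta-similarity
#'   range.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param min_pairs,min_presyn Strict lower bounds for a bin to be
#'   reported (defaults 10 and 10).
#' @return Data frame `bin_mid, mean_dy, boot_sd, n_pairs, n_presyn`
#'   (possibly zero rows).
#' @export
center_and_bin <- function(pairs, y = c("ld", "density"),
                           metric = "sim_signal_corr", n_bins = 8,
                           n_boot = 1000, min_pairs = 10, min_presyn = 10) {
  y <- match.arg(y)
  if (y == "ld") {
    d <- pairs[pairs$nsyn == 0, ]
    d$yval <- d$ld_um
  } else {
    d <- pairs[pairs$ld_um > 0, ]
    d$yval <- d$nsyn / (d$ld_um / 1000)
  }
  empty <- data.frame(bin_mid = numeric(0), mean_dy = numeric(0),
                      boot_sd = numeric(0), n_pairs = integer(0),
                      n_presyn = integer(0))
  if (nrow(d) == 0L) return(empty)
  d$sim <- d[[metric]]
  center <- function(dd) {
    mx <- tapply(dd$sim, dd$pre_id, mean)
    my <- tapply(dd$yval, dd$pre_id, mean)
    key <- as.character(dd$pre_id)
    dd$dx <- dd$sim - mx[key]
    dd$dy <- dd$yval - my[key]
    dd
  }
  d <- center(d)
  if (max(d$dx) - min(d$dx) < 1e-12) {
    breaks <- c(min(d$dx) - 0.5, min(d$dx) + 0.5)   # degenerate spread
  } else {
    breaks <- seq(min(d$dx), max(d$dx), length.out = n_bins + 1L)
    breaks[1] <- breaks[1] - 1e-9
  }
  bin_of <- function(x) cut(x, breaks, labels = FALSE)
  d$bin <- bin_of(d$dx)
  stat <- tapply(d$dy, d$bin, mean)
  n_pairs <- tapply(d$dy, d$bin, length)
  n_pre <- tapply(as.character(d$pre_id), d$bin,
                  function(v) length(unique(v)))
  boot <- matrix(NA_real_, n_boot, n_bins)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(d), replace = TRUE)
    db <- center(d[idx, ])
    db$bin <- bin_of(db$dx)
    m <- tapply(db$dy, db$bin, mean)
    boot[b, as.integer(names(m))] <- m
  }
  bins <- as.integer(names(stat))
  out <- data.frame(
    bin_mid = (breaks[bins] + breaks[bins + 1L]) / 2,
    mean_dy = as.numeric(stat),
    boot_sd = vapply(bins, function(k) stats::sd(boot[, k], na.rm = TRUE),
                     numeric(1)),
    n_pairs = as.integer(n_pairs),
    n_presyn = as.integer(n_pre))
  out <- out[out$n_pairs > min_pairs & out$n_presyn > min_presyn, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values, each at least its raw value.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
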