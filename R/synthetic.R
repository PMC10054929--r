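#' Configuration for the synthetic like-to-like generator
#'
#' Collects every knob of the synthetic population: sizes, retinotopy,
#' feature-tuning mixture, the planted axonal-scale (Tweedie) and
#' synaptic-scale (Poisson) like-to-like slopes, higher-order
#' (common-input) structure, and response variance components. The
#' defaults are the package's study conditions: 40 presynaptic neurons,
#' 2000 candidate neurons with 50 sampled candidates per presynaptic
#' neuron (2000 pairs), feature dimension 64, and a feature-similarity
#' rule planted at both scales.
#'
#' @param n_presyn Number of presynaptic neurons.
#' @param n_neurons Total neurons (candidates), must exceed `n_presyn`.
#' @param n_candidates_per_presyn Candidates sampled per presynaptic
#'   neuron for the pair table.
#' @param feature_dim Feature-weight dimensionality (>= 2).
#' @param n_feature_clusters Mixture components of the feature-tuning
#'   clusters; these double as the latent community labels for
#'   higher-order structure.
#' @param feature_cluster_sd Within-cluster spread of feature vectors
#'   (unit-norm cluster centers; smaller = tighter clusters).
#' @param area_layout Named list mapping area to its x-extent in um.
#' @param rf_gradient Retinotopy slope, degrees of visual angle per um of
#'   cortex within an area.
#' @param beta_axonal Named numeric: planted slopes on `log E[Ld]` per
#'   similarity column (`sim_feature`, `sim_signal_corr`,
#'   `rf_distance_deg`).
#' @param beta_synaptic Named numeric: planted slopes on the log synapse
#'   rate (per mm of co-travel), same names.
#' @param b0_axonal Intercept of `log E[Ld]` (um scale).
#' @param b0_synaptic Intercept of the log synapse rate per mm.
#' @param presyn_sd_axonal,presyn_sd_synaptic SDs of the per-presyn
#'   random intercepts at each scale.
#' @param tweedie A [tweedie_params()] object for the Ld law.
#' @param higher_order_strength Log-rate boost added when the postsyn
#'   belongs to the presyn's (independently drawn) target community;
#'   plants common-input clustering beyond any pairwise rule. 0 = pure
#'   pairwise rule; negative values plant ensemble avoidance. The
#'   planted-structure study condition used throughout the package is 2.
#' @param signal_var,noise_var Response variance components.
#' @param signal_corr_noise_sd Estimation noise added to the pair-table
#'   signal-correlation column (emulates finite-movie estimation and
#'   response nonlinearity; decouples it from the feature cosine).
#' @param cleft_log10_mean,cleft_log10_slope,cleft_log10_sd Log10 cleft
#'   volume model: mean, slope on feature similarity, residual sd.
#' @param unreliable_frac Fraction of neurons planted below the
#'   functional inclusion thresholds.
#' @param n_trials,n_timepoints,sampling_rate_hz Response structure.
#' @param n_tuning_blocks Direction-tuning blocks of 16 directions.
#' @param tuning_noise_sd Noise sd on direction-block responses.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_presyn = 40L,
    n_neurons = 2000L,
    n_candidates_per_presyn = 50L,
    feature_dim = 64L,
    n_feature_clusters = 5L,
    feature_cluster_sd = 0.45,
    area_layout = list(V1 = c(0, 400), RL = c(400, 700), AL = c(700, 1000)),
    rf_gradient = 0.07,
    beta_axonal = c(sim_feature = 0.8, sim_signal_corr = 0,
                    rf_distance_deg = 0),
    beta_synaptic = c(sim_feature = 0.6, sim_signal_corr = 0,
                      rf_distance_deg = 0),
    b0_axonal = log(5),
    b0_synaptic = log(40),
    presyn_sd_axonal = 0.3,
    presyn_sd_synaptic = 0.3,
    tweedie = tweedie_params(xi = 1.5, phi = 4),
    higher_order_strength = 0,
    signal_var = 1,
    noise_var = 1,
    signal_corr_noise_sd = 0.1,
    cleft_log10_mean = 3.7,
    cleft_log10_slope = 0.3,
    cleft_log10_sd = 0.25,
    unreliable_frac = 0.1,
    n_trials = 10L,
    n_timepoints = 300L,
    sampling_rate_hz = 10,
    n_tuning_blocks = 20L,
    tuning_noise_sd = 0.05,
    seed = 1L) {
  cfg <- list(
    n_presyn = as.integer(n_presyn), n_neurons = as.integer(n_neurons),
    n_candidates_per_presyn = as.integer(n_candidates_per_presyn),
    feature_dim = as.integer(feature_dim),
    n_feature_clusters = as.integer(n_feature_clusters),
    feature_cluster_sd = feature_cluster_sd,
    area_layout = area_layout, rf_gradient = rf_gradient,
    beta_axonal = beta_axonal, beta_synaptic = beta_synaptic,
    b0_axonal = b0_axonal, b0_synaptic = b0_synaptic,
    presyn_sd_axonal = presyn_sd_axonal,
    presyn_sd_synaptic = presyn_sd_synaptic,
    tweedie = tweedie, higher_order_strength = higher_order_strength,
    signal_var = signal_var, noise_var = noise_var,
    signal_corr_noise_sd = signal_corr_noise_sd,
    cleft_log10_mean = cleft_log10_mean,
    cleft_log10_slope = cleft_log10_slope,
    cleft_log10_sd = cleft_log10_sd,
    unreliable_frac = unreliable_frac,
    n_trials = as.integer(n_trials),
    n_timepoints = as.integer(n_timepoints),
    sampling_rate_hz = sampling_rate_hz,
    n_tuning_blocks = as.integer(n_tuning_blocks),
    tuning_noise_sd = tuning_noise_sd,
    seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  ok(cfg$feature_dim >= 2L, "feature_dim must be >= 2")
  ok(cfg$n_neurons > cfg$n_presyn && cfg$n_presyn >= 1L,
     "need n_neurons > n_presyn >= 1")
  ok(cfg$n_candidates_per_presyn < cfg$n_neurons,
     "n_candidates_per_presyn must be below n_neurons")
  ok(cfg$signal_var >= 0 && cfg$noise_var >= 0,
     "variance components must be nonnegative")
  ok(is.finite(cfg$higher_order_strength),
     "higher_order_strength must be finite")
  ok(inherits(cfg$tweedie, "tweedie_params"), "tweedie must be tweedie_params")
  ok(cfg$n_trials >= 2L, "n_trials must be >= 2")
  sim_cols <- c("sim_feature", "sim_signal_corr", "rf_distance_deg")
  ok(all(names(cfg$beta_axonal) %in% sim_cols) &&
       all(names(cfg$beta_synaptic) %in% sim_cols),
     "planted slopes must be named over sim_feature, sim_signal_corr, rf_distance_deg")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_config> %d presyn / %d neurons, %d pairs, feature_dim %d\n",
    "  axonal slopes: %s\n  synaptic slopes: %s\n",
    "  higher-order strength %g, seed %d\n"),
    x$n_presyn, x$n_neurons, x$n_presyn * x$n_candidates_per_presyn,
    x$feature_dim,
    paste(names(x$beta_axonal), signif(x$beta_axonal, 3), sep = "=",
          collapse = ", "),
    paste(names(x$beta_synaptic), signif(x$beta_synaptic, 3), sep = "=",
          collapse = ", "),
    x$higher_order_strength, x$seed))
  invisible(x)
}

#' Generate a synthetic neuron population with planted tuning structure
#'
#' Neurons receive a soma position (areas laid out along the x axis),
#' a cortical layer, a retinotopic receptive-field center (deterministic
#' in the soma position via `rf_gradient`), a unit-norm feature-weight
#' vector drawn from a mixture of `n_feature_clusters` directions (the
#' mixture component is the neuron's latent community label), bimodal von
#' Mises direction-tuning parameters, and planted reliability metrics
#' (CCmax/CCabs) with a configurable unreliable fraction.
#'
#' @param config A [synthetic_config()].
#' @return List with `neurons` (data frame) and `features`
#'   (n_neurons x feature_dim matrix); class `synthetic_population`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  areas <- names(config$area_layout)
  x_min <- min(vapply(config$area_layout, min, numeric(1)))
  x_max <- max(vapply(config$area_layout, max, numeric(1)))
  soma_x <- stats::runif(n, x_min, x_max)
  soma_y <- stats::runif(n, 0, 400)
  soma_z <- stats::runif(n, 0, 200)
  area <- rep(NA_character_, n)
  for (a in areas) {
    ext <- config$area_layout[[a]]
    in_a <- soma_x >= ext[1] & soma_x <= ext[2] & is.na(area)
    area[in_a] <- a
  }
  layer <- sample(c("L2/3", "L4", "L5"), n, replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
  # deterministic retinotopy within area: rf_gradient deg per um
  rf_az <- rf_el <- numeric(n)
  for (a in areas) {
    ext <- config$area_layout[[a]]
    sel <- area == a
    rf_az[sel] <- config$rf_gradient *
      (soma_x[sel] - mean(ext))
    rf_el[sel] <- config$rf_gradient * (soma_y[sel] - 200)
  }
  # feature mixture: unit-norm cluster centers + within-cluster spread
  k <- config$n_feature_clusters
  d <- config$feature_dim
  centers <- matrix(stats::rnorm(k * d), k, d)
  centers <- centers / sqrt(rowSums(centers^2))
  community <- sample.int(k, n, replace = TRUE)
  feats <- centers[community, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = config$feature_cluster_sd / sqrt(d)),
           n, d)
  feats <- feats / sqrt(rowSums(feats^2))
  # reliability: analytic ceiling +- jitter; a fraction planted unreliable
  cc_true <- sqrt(config$signal_var /
                    (config$signal_var + config$noise_var / config$n_trials))
  unreliable <- stats::runif(n) < config$unreliable_frac
  cc_max <- pmin(1, pmax(0, cc_true + stats::rnorm(n, sd = 0.05)))
  cc_abs <- pmin(1, pmax(0, 0.6 + stats::rnorm(n, sd = 0.1)))
  cc_max[unreliable] <- stats::runif(sum(unreliable), 0, 0.35)
  presyn_ids <- sort(sample.int(n, config$n_presyn))
  neurons <- data.frame(
    neuron_id = seq_len(n),
    is_presyn = seq_len(n) %in% presyn_ids,
    area = area, layer = layer,
    soma_x = soma_x, soma_y = soma_y, soma_z = soma_z,
    rf_azimuth_deg = rf_az, rf_elevation_deg = rf_el,
    community = community,
    cc_max = cc_max, cc_abs = cc_abs,
    tune_mu = stats::runif(n, 0, 360),
    tune_kappa = stats::runif(n, 1, 4),
    tune_p = stats::runif(n, 0.3, 0.7),
    tune_b = stats::runif(n, 0.05, 0.2),
    tune_amp = stats::runif(n, 0.5, 2),
    stringsAsFactors = FALSE)
  structure(list(neurons = neurons, features = feats, config = config),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d neurons (%d presyn), %d-dim features\n",
              nrow(x$neurons), sum(x$neurons$is_presyn),
              ncol(x$features)))
  invisible(x)
}

#' Generate trial-structured responses and direction-tuning blocks
#'
#' Responses follow a low-rank factor model: a shared white stimulus
#' drive in feature space is projected through each neuron's feature
#' weights (so signal correlation equals feature cosine similarity by
#' construction), scaled to `signal_var`, and independent Gaussian noise
#' with `noise_var` is added per trial. Direction-tuning blocks present 16
#' equally spaced directions per block, generated from each neuron's
#' planted bimodal von Mises curve plus noise.
#'
#' @param population A [generate_population()] result.
#' @param neuron_ids Optional subset of neurons to simulate (default all;
#'   the response array is the memory-heavy part of the generator).
#' @return List with `responses` (array neurons x trials x timepoints),
#'   `tuning` (array neurons x blocks x 16), `directions_deg`,
#'   `neuron_ids`, `sampling_rate_hz`.
#' @export
generate_responses <- function(population, neuron_ids = NULL) {
  stopifnot(inherits(population, "synthetic_population"))
  cfg <- population$config
  set.seed(cfg$seed + 1L)
  if (is.null(neuron_ids)) neuron_ids <- population$neurons$neuron_id
  w <- population$features[neuron_ids, , drop = FALSE]
  n <- length(neuron_ids)
  tt <- cfg$n_timepoints
  drive <- matrix(stats::rnorm(cfg$feature_dim * tt), cfg$feature_dim, tt)
  sig <- w %*% drive                        # unit variance per row (approx)
  sig <- sig / sqrt(rowMeans(sig^2))
  resp <- array(0, dim = c(n, cfg$n_trials, tt))
  for (tr in seq_len(cfg$n_trials)) {
    resp[, tr, ] <- sqrt(cfg$signal_var) * sig +
      matrix(stats::rnorm(n * tt, sd = sqrt(cfg$noise_var)), n, tt)
  }
  dirs <- seq(0, 360 - 22.5, by = 22.5)
  nb <- cfg$n_tuning_blocks
  tun <- array(0, dim = c(n, nb, length(dirs)))
  nr <- population$neurons[neuron_ids, , drop = FALSE]
  for (i in seq_len(n)) {
    mean_curve <- von_mises_curve(dirs, nr$tune_mu[i], nr$tune_kappa[i],
                                  nr$tune_p[i], nr$tune_b[i],
                                  amplitude = nr$tune_amp[i])
    tun[i, , ] <- matrix(rep(mean_curve, each = nb), nb) +
      matrix(stats::rnorm(nb * length(dirs), sd = cfg$tuning_noise_sd), nb)
  }
  list(responses = resp, tuning = tun, directions_deg = dirs,
       neuron_ids = neuron_ids, sampling_rate_hz = cfg$sampling_rate_hz)
}

#' Generate the synthetic pair table with planted connectivity rules
#'
#' For each presynaptic neuron, a fixed-size candidate subset is drawn
#' and each (presyn, candidate) pair receives: functional similarities
#' (feature cosine, a noisy signal-correlation proxy, RF center
#' distance), a projection type, an axon-dendrite co-travel distance Ld
#' sampled from the compound Poisson-Gamma law with
#' `log E[Ld] = b0_axonal + beta_axonal . sims + u_i`, a synapse count
#' `Nsyn | Ld > 0 ~ Poisson(Ld_mm * exp(b0_synaptic + beta_synaptic .
#' sims + v_i + higher-order boost))`, and a mean log10 cleft volume with
#' a similarity-dependent mean. The higher-order boost adds
#' `higher_order_strength` to the log rate when the postsynaptic neuron
#' belongs to the presyn's independently drawn target community (see
#' the parameter's documentation). `Nsyn = 0` whenever `Ld = 0`.
#'
#' @param population A [generate_population()] result.
#' @return List of class `synthetic_anatomy` with `pairs` (data frame)
#'   and `truth` (the planted slopes, random intercepts and community
#'   labels, recorded exactly as used).
#' @export
generate_anatomy <- function(population) {
  stopifnot(inherits(population, "synthetic_population"))
  cfg <- population$config
  set.seed(cfg$seed + 2L)
  nr <- population$neurons
  feats <- population$features
  presyn <- nr$neuron_id[nr$is_presyn]
  u_ax <- stats::rnorm(length(presyn), sd = cfg$presyn_sd_axonal)
  u_sy <- stats::rnorm(length(presyn), sd = cfg$presyn_sd_synaptic)
  names(u_ax) <- names(u_sy) <- presyn
  # Higher-order (common-input) mechanism: each presynaptic neuron is
  # assigned a target community drawn independently of its own tuning;
  # synapse rates onto members of that community gain the boost. The
  # boost is therefore uncorrelated with presyn-target similarity (the
  # marginal pairwise rule is preserved) while the targets of one presyn
  # become mutually similar -- structure no pairwise model can produce.
  target_comm <- sample.int(cfg$n_feature_clusters, length(presyn),
                            replace = TRUE)
  names(target_comm) <- presyn
  sim_cols <- c("sim_feature", "sim_signal_corr", "rf_distance_deg")
  beta_of <- function(beta) {
    out <- stats::setNames(numeric(3), sim_cols)
    out[names(beta)] <- beta
    out
  }
  b_ax <- beta_of(cfg$beta_axonal)
  b_sy <- beta_of(cfg$beta_synaptic)
  rows <- vector("list", length(presyn))
  for (ip in seq_along(presyn)) {
    i <- presyn[ip]
    cand <- sample(setdiff(nr$neuron_id, i), cfg$n_candidates_per_presyn)
    sim_feature <- as.numeric(feats[cand, , drop = FALSE] %*% feats[i, ])
    sim_signal <- pmin(1, pmax(-1, sim_feature +
      stats::rnorm(length(cand), sd = cfg$signal_corr_noise_sd)))
    rf_dist <- sqrt((nr$rf_azimuth_deg[cand] - nr$rf_azimuth_deg[i])^2 +
                      (nr$rf_elevation_deg[cand] - nr$rf_elevation_deg[i])^2)
    X <- cbind(sim_feature = sim_feature, sim_signal_corr = sim_signal,
               rf_distance_deg = rf_dist)
    mu_ld <- exp(cfg$b0_axonal + X %*% b_ax + u_ax[[as.character(i)]])
    ld <- rtweedie(length(cand), as.numeric(mu_ld), cfg$tweedie)
    ho <- cfg$higher_order_strength *
      (nr$community[cand] == target_comm[[as.character(i)]])
    log_rate <- cfg$b0_synaptic + X %*% b_sy + u_sy[[as.character(i)]] + ho
    nsyn <- integer(length(cand))
    pos <- ld > 0
    nsyn[pos] <- stats::rpois(sum(pos),
                              (ld[pos] / 1000) * exp(log_rate[pos]))
    cleft <- rep(NA_real_, length(cand))
    if (any(nsyn > 0)) {
      idx <- which(nsyn > 0)
      cleft[idx] <- vapply(idx, function(q) {
        mean(stats::rnorm(nsyn[q],
                          mean = cfg$cleft_log10_mean +
                            cfg$cleft_log10_slope * sim_feature[q],
                          sd = cfg$cleft_log10_sd))
      }, numeric(1))
    }
    rows[[ip]] <- data.frame(
      pre_id = i, post_id = cand,
      projection = projection_type(rep(nr$area[nr$neuron_id == i],
                                       length(cand)), nr$area[cand]),
      ld_um = ld, nsyn = nsyn, mean_log10_cleft = cleft,
      sim_feature = sim_feature, sim_signal_corr = sim_signal,
      rf_distance_deg = rf_dist,
      in_target_community = nr$community[cand] ==
        target_comm[[as.character(i)]],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  truth <- list(beta_axonal = b_ax, beta_synaptic = b_sy,
                b0_axonal = cfg$b0_axonal, b0_synaptic = cfg$b0_synaptic,
                u_axonal = u_ax, u_synaptic = u_sy,
                tweedie = cfg$tweedie,
                higher_order_strength = cfg$higher_order_strength,
                community = stats::setNames(nr$community, nr$neuron_id),
                target_community = target_comm,
                signal_var = cfg$signal_var, noise_var = cfg$noise_var)
  structure(list(pairs = pairs, truth = truth, config = cfg),
            class = "synthetic_anatomy")
}

#' @export
print.synthetic_anatomy <- function(x, ...) {
  cat(sprintf(
    "<synthetic_anatomy> %d pairs, %d presyn; %.1f%% Ld > 0, %.1f%% connected\n",
    nrow(x$pairs), length(unique(x$pairs$pre_id)),
    100 * mean(x$pairs$ld_um > 0), 100 * mean(x$pairs$nsyn > 0)))
  invisible(x)
}

#' Generate skeleton fixtures with analytically known Ld
#'
#' Emits small axon/dendrite skeleton pairs built from geometric
#' primitives whose true co-travel distance is known in closed form:
#' parallel runs (full dendrite inside or outside the 5 um radius),
#' crossing runs with integer geometry (the proximal window is exact),
#' and disjoint runs (Ld = 0). Synapses are placed at known distances
#' from proximity vertices so the 3 um assignment rule is also testable.
#'
#' @param n_scenes Number of scenes; scene kinds cycle through parallel /
#'   crossing / disjoint.
#' @return List of scenes, each with `axon`, `dend` ([skeleton()]s),
#'   `synapses` (data frame), `expected_ld`, `expected_assigned`
#'   (logical per synapse), and `kind`.
#' @export
generate_skeleton_scene <- function(n_scenes = 3L) {
  kinds <- rep(c("parallel_near", "crossing", "disjoint"),
               length.out = n_scenes)
  # Unit-spaced straight runs built from exact coordinates (the crossing
  # scene sits exactly on the closed-ball boundary, so no interpolation
  # rounding is tolerable).
  line_skel <- function(axis_vals, fixed, axis, compartment, id) {
    n <- length(axis_vals)
    v <- matrix(rep(fixed, each = n), n, 3L)
    v[, axis] <- axis_vals
    skeleton(v, cbind(seq_len(n - 1L), 2:n), compartment, id)
  }
  scenes <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    kind <- kinds[s]
    if (kind == "parallel_near") {
      # 10 um parallel runs, 3 um apart: every dendritic vertex proximal
      axon <- line_skel(0:10, c(0, 0, 0), 1L, "axon", "pre")
      dend <- line_skel(0:10, c(0, 3, 0), 1L, "dendrite", "post")
      expected_ld <- 10
      syn <- data.frame(synapse_id = 1:2, pre_id = "pre", post_id = "post",
                        x_um = c(5, 5), y_um = c(3, 3), z_um = c(0, 10),
                        cleft_volume_voxels = c(4000, 4000))
      expected_assigned <- c(TRUE, FALSE)
    } else if (kind == "crossing") {
      # axon along x at z = 0; dendrite along y at z = 3, length 20.
      # Dendrite vertex at (0, y, 3) is within 5 um of the axon iff
      # sqrt(y^2 + 9) <= 5, i.e. |y| <= 4 (closed ball, exact at 4).
      # Proximal vertices y in {-4..4}; touched edges span y in [-5, 5]:
      # Ld = 10.
      axon <- line_skel(-10:10, c(0, 0, 0), 1L, "axon", "pre")
      dend <- line_skel(-10:10, c(0, 0, 3), 2L, "dendrite", "post")
      expected_ld <- 10
      syn <- data.frame(synapse_id = 1:2, pre_id = "pre", post_id = "post",
                        x_um = c(0, 0), y_um = c(0, 9), z_um = c(3, 3),
                        cleft_volume_voxels = c(5000, 5000))
      expected_assigned <- c(TRUE, FALSE)
    } else {
      # parallel runs 6 um apart: nothing within the 5 um radius
      axon <- line_skel(0:10, c(0, 0, 0), 1L, "axon", "pre")
      dend <- line_skel(0:10, c(0, 6, 0), 1L, "dendrite", "post")
      expected_ld <- 0
      syn <- data.frame(synapse_id = 1L, pre_id = "pre", post_id = "post",
                        x_um = 5, y_um = 6, z_um = 0,
                        cleft_volume_voxels = 3000)
      expected_assigned <- FALSE
    }
    scenes[[s]] <- list(axon = axon, dend = dend, synapses = syn,
                        expected_ld = expected_ld,
                        expected_assigned = expected_assigned, kind = kind)
  }
  scenes
}

#' Random skeletons for oracle-equivalence checks
#'
#' Random-walk skeletons inside a bounding box, used to compare the
#' spatial-index proximity search against the brute-force oracle.
#'
#' @param n_vertices Number of vertices.
#' @param compartment,neuron_id Passed to [skeleton()].
#' @param box Bounding box half-width (um).
#' @param step Mean step length (um).
#' @return A [skeleton()] (a single path).
#' @export
random_skeleton <- function(n_vertices, compartment = "axon",
                            neuron_id = NA, box = 20, step = 1.5) {
  v <- matrix(0, n_vertices, 3L)
  v[1L, ] <- stats::runif(3, -box, box)
  for (i in 2:n_vertices) {
    d <- stats::rnorm(3)
    v[i, ] <- v[i - 1L, ] + step * d / sqrt(sum(d^2))
  }
  skeleton(v, cbind(seq_len(n_vertices - 1L), 2:n_vertices),
           compartment, neuron_id)
}
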