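test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(feature_dim = 1), "feature_dim")
  expect_error(synthetic_config(n_presyn = 50, n_neurons = 40),
               "n_neurons > n_presyn")
  expect_error(synthetic_config(signal_var = -1), "nonnegative")
  expect_error(synthetic_config(beta_axonal = c(bogus = 1)), "named over")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_neurons = 150, n_presyn = 8,
                          n_candidates_per_presyn = 25, seed = 99)
  p1 <- generate_population(cfg); p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  a1 <- generate_anatomy(p1); a2 <- generate_anatomy(p2)
  expect_identical(a1$pairs, a2$pairs)
  r1 <- generate_responses(p1, neuron_ids = 1:10)
  r2 <- generate_responses(p2, neuron_ids = 1:10)
  expect_identical(r1, r2)
})

test_that("zero retinotopy gradient collapses all RF centers", {
  cfg <- synthetic_config(n_neurons = 80, n_presyn = 4,
                          n_candidates_per_presyn = 20,
                          rf_gradient = 0, seed = 5)
  pop <- generate_population(cfg)
  expect_equal(stats::sd(pop$neurons$rf_azimuth_deg), 0)
  expect_equal(stats::sd(pop$neurons$rf_elevation_deg), 0)
  anat <- generate_anatomy(pop)
  expect_true(all(anat$pairs$rf_distance_deg == 0))
})

test_that("feature mixture separates within- from between-cluster similarity", {
  cfg <- synthetic_config(n_neurons = 300, n_presyn = 10,
                          n_candidates_per_presyn = 20,
                          n_feature_clusters = 2, seed = 13)
  pop <- generate_population(cfg)
  f <- pop$features
  cs <- f %*% t(f)
  same <- outer(pop$neurons$community, pop$neurons$community, "==")
  off <- upper.tri(cs)
  expect_gt(mean(cs[off & same]), mean(cs[off & !same]) + 0.3)
})

test_that("responses carry the planted signal and noise structure", {
  cfg <- synthetic_config(n_neurons = 60, n_presyn = 4,
                          n_candidates_per_presyn = 20,
                          noise_var = 0, seed = 3)
  pop <- generate_population(cfg)
  # two neurons with identical feature vectors
  pop$features[2, ] <- pop$features[1, ]
  rs <- generate_responses(pop, neuron_ids = 1:5)
  # zero noise: repeated trials identical
  expect_equal(rs$responses[1, 1, ], rs$responses[1, 2, ])
  r12 <- signal_correlation(rs$responses[1, , ], rs$responses[2, , ],
                            rs$sampling_rate_hz)
  expect_equal(r12, 1, tolerance = 1e-10)
})

test_that("empirical CCmax matches the variance-component prediction", {
  cfg <- synthetic_config(n_neurons = 120, n_presyn = 4,
                          n_candidates_per_presyn = 20,
                          signal_var = 1, noise_var = 2, seed = 31)
  pop <- generate_population(cfg)
  rs <- generate_responses(pop, neuron_ids = 1:60)
  est <- vapply(1:60, function(i) cc_max(rs$responses[i, , ]), numeric(1))
  N <- cfg$n_trials
  pred <- sqrt(min(1, (N / (N - 1)) / (1 + 2 / N)))
  expect_equal(mean(est), pred, tolerance = 0.03)
})

test_that("anatomy obeys the no-proximity-no-synapse constraint", {
  anat <- quick_anatomy(seed = 17)
  expect_true(all(anat$pairs$nsyn[anat$pairs$ld_um == 0] == 0))
  expect_true(all(anat$pairs$ld_um >= 0))
  # cleft volumes present exactly for connected pairs
  expect_true(all(is.finite(anat$pairs$mean_log10_cleft) ==
                    (anat$pairs$nsyn > 0)))
  # ground truth recorded as used
  expect_equal(unname(anat$truth$beta_axonal["sim_feature"]), 0.8)
  expect_equal(length(anat$truth$u_axonal), 40L)
})

test_that("conditional synapse counts follow the planted Poisson law", {
  # with known truth, nsyn | ld, sims is Poisson(ld_mm * exp(eta));
  # compare binned observed/expected counts
  anat <- quick_anatomy(seed = 23)
  p <- anat$pairs[anat$pairs$ld_um > 0, ]
  tr <- anat$truth
  eta <- tr$b0_synaptic +
    as.matrix(p[, names(tr$beta_synaptic)]) %*% tr$beta_synaptic +
    tr$u_synaptic[as.character(p$pre_id)]
  lam <- (p$ld_um / 1000) * exp(as.numeric(eta))
  expect_equal(sum(p$nsyn), sum(lam), tolerance = 0.15)
  # Poisson dispersion: (obs - lam)^2 / lam should average ~ 1
  disp <- mean((p$nsyn - lam)^2 / lam)
  expect_gt(disp, 0.8); expect_lt(disp, 1.25)
})
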