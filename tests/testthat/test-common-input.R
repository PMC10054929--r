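test_that("rho is the synapse-weighted mean partner similarity", {
  # two partners, one synapse each, similarity 0.5
  s2 <- matrix(c(NA, 0.5, 0.5, NA), 2)
  expect_equal(rho_observed(c(1, 1), s2), 0.5)
  # hand evaluation: partners (j,k,l), nsyn (2,1,1),
  # sims jk=0.2, jl=0.4, kl=0.6 -> (2*1*0.2 + 2*1*0.4 + 1*1*0.6)/5 = 0.36
  s3 <- matrix(NA_real_, 3, 3)
  s3[1, 2] <- s3[2, 1] <- 0.2
  s3[1, 3] <- s3[3, 1] <- 0.4
  s3[2, 3] <- s3[3, 2] <- 0.6
  expect_equal(rho_observed(c(2, 1, 1), s3), 0.36)
  # constant similarity: rho = c regardless of weights
  sc <- matrix(0.7, 3, 3); diag(sc) <- NA
  expect_equal(rho_observed(c(5, 1, 2), sc), 0.7)
  # invariant to global rescaling of Nsyn
  expect_equal(rho_observed(c(2, 1, 1), s3),
               rho_observed(10 * c(2, 1, 1), s3))
  expect_error(rho_observed(c(3, 0, 0), s3), "fewer than 2")
})

test_that("rho-prime reduces to the unweighted mean under uniform predictions", {
  s3 <- matrix(NA_real_, 3, 3)
  s3[upper.tri(s3)] <- c(0.2, 0.4, 0.6)
  s3[lower.tri(s3)] <- t(s3)[lower.tri(s3)]
  expect_equal(rho_expected(rep(0.3, 3), s3), mean(c(0.2, 0.4, 0.6)))
  # hand-built prediction: weights (0.5, 1, 2)
  w <- c(0.5, 1, 2)
  num <- 2 * (0.5 * 1 * 0.2 + 0.5 * 2 * 0.4 + 1 * 2 * 0.6)
  den <- 2 * (0.5 * 1 + 0.5 * 2 + 1 * 2)
  expect_equal(rho_expected(w, s3), num / den)
})

test_that("equal observed and expected rho give t = 0, p = 1", {
  rho <- data.frame(pre_id = 1:5, rho_obs = seq(0.1, 0.5, 0.1),
                    rho_exp = seq(0.1, 0.5, 0.1), n_post = 3)
  got <- compare_rho(rho)
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
})

test_that("joint pairwise model recovers which similarity carries the rule", {
  anat <- quick_anatomy(seed = 41,
                        beta_axonal = c(sim_feature = 0.8),
                        beta_synaptic = c(sim_feature = 1),
                        signal_corr_noise_sd = 0.35)
  fit <- fit_joint_pairwise_model(anat$pairs)
  cf <- stats::coef(fit$model)
  se <- sqrt(diag(stats::vcov(fit$model)))
  z <- cf / se
  expect_gt(z["sim_feature"], 2)
  # RF distance carries no rule here
  expect_lt(abs(z["rf_distance_deg"]), 3)
})

test_that("pairwise-only generator is calibrated; planted structure is found", {
  anat0 <- quick_anatomy(seed = 55)
  rho0 <- rho_analysis(anat0$pairs, feature_sim_lookup(
    generate_population(synthetic_config(seed = 55))$features))
  expect_lt(abs(compare_rho(rho0)$mean_diff), 0.05)
  # planted common input: positive excess similarity
  cfgp <- synthetic_config(seed = 56, higher_order_strength = 2)
  popp <- generate_population(cfgp)
  rhop <- rho_analysis(generate_anatomy(popp)$pairs,
                       feature_sim_lookup(popp$features))
  tp <- compare_rho(rhop)
  expect_gt(tp$mean_diff, 0)
  expect_lt(tp$p, 0.05)
  # ensemble avoidance is higher-order structure too: excluding a random
  # community concentrates the realized targets relative to the smooth
  # pairwise prediction, so the excess similarity is again positive --
  # rho detects concentration, not the sign of the ensemble preference
  cfgn <- synthetic_config(seed = 56, higher_order_strength = -2)
  popn <- generate_population(cfgn)
  rhon <- rho_analysis(generate_anatomy(popn)$pairs,
                       feature_sim_lookup(popn$features))
  tn <- compare_rho(rhon)
  expect_gt(tn$mean_diff, 0)
})
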