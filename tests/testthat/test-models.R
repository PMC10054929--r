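test_that("planted slopes are recovered by the axonal and synaptic models", {
  anat <- quick_anatomy(seed = 7)
  s_ax <- conditional_slopes(fit_ld_model(anat$pairs, "sim_feature"))
  # every projection's conditional slope estimates the common planted 0.8
  expect_true(all(abs(s_ax$slope - 0.8) <= 3 * s_ax$se))
  s_sy <- conditional_slopes(
    fit_density_model(anat$pairs[anat$pairs$ld_um > 0, ], "sim_feature"))
  expect_true(all(abs(s_sy$slope - 0.6) <= 3 * s_sy$se))
  s_jt <- conditional_slopes(fit_nsyn_model(anat$pairs, "sim_feature"))
  # joint-scale slope mixes both rules: clearly positive
  expect_true(all(s_jt$slope > 0))
})

test_that("null planting gives slopes centered on zero", {
  anat <- quick_anatomy(seed = 8, beta_axonal = c(sim_feature = 0),
                        beta_synaptic = c(sim_feature = 0))
  s <- conditional_slopes(fit_ld_model(anat$pairs, "sim_feature"))
  expect_true(all(abs(s$z) < 3.5))
})

test_that("random-intercept and fixed-effects backends agree", {
  anat <- quick_anatomy(seed = 5)
  f_glm <- fit_nsyn_model(anat$pairs, "sim_feature", method = "glm")
  f_glmm <- fit_nsyn_model(anat$pairs, "sim_feature", method = "glmm")
  s1 <- conditional_slopes(f_glm); s2 <- conditional_slopes(f_glmm)
  expect_equal(sign(s1$slope), sign(s2$slope))
  expect_true(all(abs(s1$slope - s2$slope) < pmax(s1$se, s2$se)))
})

test_that("conditional slopes equal the emmeans trend computation", {
  anat <- quick_anatomy(seed = 5)
  fit <- fit_ld_model(anat$pairs, "sim_feature")
  s <- conditional_slopes(fit)
  emt <- as.data.frame(emmeans::emtrends(fit$model, ~projection,
                                         var = "sim"))
  m <- merge(s, emt, by = "projection")
  expect_equal(m$slope, m$sim.trend, tolerance = 1e-10)
  expect_equal(m$se, m$SE, tolerance = 1e-10)
  # reference level slope is the bare similarity coefficient
  ref <- s$slope[s$projection == fit$projection_levels[1]]
  expect_equal(ref, unname(fit$coefficients["sim"]))
})

test_that("density-model offset algebra: rescaling Ld only shifts the intercept", {
  anat <- quick_anatomy(seed = 9)
  pos <- anat$pairs[anat$pairs$ld_um > 0, ]
  f1 <- fit_density_model(pos, "sim_feature")
  pos2 <- pos; pos2$ld_um <- 2 * pos2$ld_um
  f2 <- fit_density_model(pos2, "sim_feature")
  expect_equal(unname(f2$coefficients["(Intercept)"]),
               unname(f1$coefficients["(Intercept)"]) - log(2),
               tolerance = 1e-6)
  keep <- setdiff(names(f1$coefficients),
                  grep("Intercept|^group", names(f1$coefficients),
                       value = TRUE))
  expect_equal(f1$coefficients[keep], f2$coefficients[keep],
               tolerance = 1e-6)
  expect_error(fit_density_model(anat$pairs, "sim_feature"), "ld_um > 0")
})

test_that("projection admissibility filter applies the strict count rules", {
  mk <- function(proj, pre, nsyn) data.frame(projection = proj,
                                             pre_id = pre, nsyn = nsyn)
  # exactly 30 synapses: excluded (strict >)
  t1 <- mk("A", rep(1:6, each = 6), rep(c(1, 0), 18)[1:36])
  stopifnot(sum(t1$nsyn) == 18)
  t1$nsyn[t1$nsyn == 1][1:12] <- 2   # now 30 synapses over 6 presyns
  expect_equal(sum(t1$nsyn), 30)
  expect_length(filter_projections(t1), 0)
  # 31 synapses, 6 presyns, balanced: kept
  t2 <- t1; t2$nsyn[which(t2$nsyn == 0)[1]] <- 1
  expect_equal(filter_projections(t2), "A")
  # one presyn holding > half: excluded
  t3 <- t2; t3$nsyn[t3$pre_id == 1] <- 0
  t3$nsyn[which(t3$pre_id == 1)[1]] <- 40
  expect_length(filter_projections(t3), 0)
  # 5 presyns only: excluded
  t4 <- mk("B", rep(1:5, each = 8), rep(1, 40))
  expect_length(filter_projections(t4), 0)
})

test_that("paired cohort test matches the textbook paired t formula", {
  set.seed(33)
  pre <- rep(1:12, each = 40)
  cohort <- rep(c(rep("connected", 14), rep("adp_control", 13),
                  rep("same_region_control", 13)), 12)
  sim <- stats::rnorm(480) + 0.3 * (cohort == "connected")
  pairs <- data.frame(pre_id = pre, projection = "V1->V1",
                      cohort = cohort, sim_signal_corr = sim)
  got <- paired_cohort_test(pairs, min_targets = 10, by_projection = FALSE)
  a <- tapply(sim[cohort == "connected"], pre[cohort == "connected"], mean)
  b <- tapply(sim[cohort == "adp_control"], pre[cohort == "adp_control"],
              mean)
  want <- stats::t.test(a, b, paired = TRUE)
  row <- got[got$comparison == "connected vs adp_control", ]
  expect_equal(row$t, unname(want$statistic))
  expect_equal(row$p, want$p.value)
  expect_equal(row$mean_diff, unname(want$estimate))
  # identical cohort values per presyn: t = 0, p = 1
  flat <- pairs; flat$sim_signal_corr <- rep(stats::rnorm(12), each = 40)
  g2 <- paired_cohort_test(flat, min_targets = 10, by_projection = FALSE)
  expect_equal(g2$t[1], 0)
  expect_equal(g2$p[1], 1)
  # too few qualifying presyns: reported with a notice
  small <- pairs[pairs$pre_id == 1, ]
  g3 <- paired_cohort_test(small, min_targets = 10, by_projection = FALSE)
  expect_true(all(is.na(g3$p)))
  expect_match(g3$note[1], "fewer than 2")
})

test_that("residual anatomy regression isolates synaptic-scale structure", {
  set.seed(44)
  n <- 400
  ld <- stats::runif(n, 1, 50)
  nsyn <- stats::rpois(n, 1) + 1
  cleft <- stats::rnorm(n, 3.7, 0.3)
  # similarity exactly linear in Ld, anatomy independent
  pairs <- data.frame(ld_um = ld, nsyn = nsyn, mean_log10_cleft = cleft,
                      sim_signal_corr = 0.2 + 0.01 * ld)
  res <- residual_anatomy_regression(pairs)
  expect_true(all(abs(res$coefficients$estimate[-1]) < 1e-10))
  # planted cleft-volume effect is recovered with its sign
  pairs2 <- pairs
  pairs2$sim_signal_corr <- 0.2 + 0.01 * ld + 0.25 * (cleft - 3.7) +
    stats::rnorm(n, sd = 0.05)
  res2 <- residual_anatomy_regression(pairs2)
  cl <- res2$coefficients[res2$coefficients$term == "mean_log10_cleft", ]
  expect_gt(cl$estimate, 0.15)
  expect_lt(cl$p, 0.01)
  # synapse-multiplicity effect
  pairs3 <- pairs
  pairs3$sim_signal_corr <- 0.2 + 0.01 * ld + 0.1 * nsyn +
    stats::rnorm(n, sd = 0.05)
  res3 <- residual_anatomy_regression(pairs3)
  ns <- res3$coefficients[res3$coefficients$term == "nsyn", ]
  expect_gt(ns$estimate, 0.05)
})

test_that("centered binning reproduces hand-computed summaries", {
  # 2 presyns x 12 unconnected pairs each, all identical within presyn:
  # all deltas zero, a single populated bin at zero with mean zero
  pairs0 <- data.frame(pre_id = rep(1:11, each = 12),
                       ld_um = rep(seq(2, 42, by = 4), each = 12),
                       nsyn = 0,
                       sim_signal_corr = rep(seq(0.1, 0.9, length.out = 11),
                                             each = 12))
  out0 <- center_and_bin(pairs0, "ld", n_boot = 25)
  expect_true(all(abs(out0$mean_dy) < 1e-12))
  expect_true(all(abs(out0$bin_mid) < 1e-9))
  # tiny input fails the bin filters
  tiny <- pairs0[1:10, ]
  expect_equal(nrow(center_and_bin(tiny, "ld", n_boot = 10)), 0L)
  # hand-built check of the centering arithmetic
  pairs1 <- data.frame(
    pre_id = rep(c(1, 2), each = 12),
    ld_um = c(seq(10, 32, by = 2), seq(5, 27, by = 2)),
    nsyn = 0,
    sim_signal_corr = c(seq(-0.5, 0.6, by = 0.1), seq(-0.6, 0.5, by = 0.1)))
  out1 <- center_and_bin(pairs1, "ld", n_bins = 1, n_boot = 25,
                         min_pairs = 10, min_presyn = 1)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$mean_dy, 0, tolerance = 1e-12)  # centering removes means
  expect_equal(out1$n_pairs, 24L)
  expect_gt(out1$boot_sd, 0)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.001, 0.02, 0.3, 0.9)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
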