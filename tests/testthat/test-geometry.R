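test_that("discretization subdivides uniformly and preserves cable length", {
  one_edge <- skeleton(rbind(c(0, 0, 0), c(10, 0, 0)), rbind(c(1, 2)),
                       "dendrite")
  d <- discretize_skeleton(one_edge, 1)
  expect_equal(nrow(d$edges), 10L)
  expect_equal(cable_length(d), 10)
  expect_true(all(edge_lengths(d) <= 1 + 1e-12))
  # idempotence when the bound already holds
  expect_identical(discretize_skeleton(d, 1), d)
  # random skeleton: total length conserved to 1e-9 relative
  set.seed(3)
  sk <- random_skeleton(80, "axon")
  expect_equal(cable_length(discretize_skeleton(sk, 1)), cable_length(sk),
               tolerance = 1e-9)
})

test_that("zero-length edges are dropped with a warning", {
  sk <- skeleton(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                 rbind(c(1, 2), c(2, 3)), "axon")
  expect_warning(d <- discretize_skeleton(sk, 1), "zero-length")
  expect_equal(nrow(d$edges), 1L)
})

test_that("skeleton constructor rejects malformed input", {
  expect_error(skeleton(rbind(c(0, 0, 0)), rbind(c(1, 1)), "axon"),
               "self-loop")
  expect_error(skeleton(rbind(c(0, 0, 0)), rbind(c(1, 2)), "axon"),
               "out of range")
})

test_that("grid proximity search equals brute force on random scenes", {
  set.seed(10)
  for (rep in 1:20) {
    a <- random_skeleton(sample(20:200, 1), "axon", box = 12)
    b <- random_skeleton(sample(20:200, 1), "dendrite", box = 12)
    r <- stats::runif(1, 2, 8)
    expect_identical(find_proximities(a, b, r),
                     find_proximities_brute(a, b, r))
  }
})

test_that("proximal pair set is symmetric under swapping the skeletons", {
  set.seed(4)
  a <- random_skeleton(120, "axon", box = 10)
  b <- random_skeleton(120, "dendrite", box = 10)
  p_ab <- find_proximities(a, b, 5)
  p_ba <- find_proximities(b, a, 5)
  swapped <- p_ba[, c(2L, 1L)]
  colnames(swapped) <- c("a_vertex", "b_vertex")
  swapped <- swapped[order(swapped[, 1L], swapped[, 2L]), , drop = FALSE]
  expect_identical(p_ab, swapped)
})

test_that("empty and coincident cases behave as specified", {
  a <- skeleton(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2)), "axon")
  far <- skeleton(rbind(c(100, 0, 0), c(101, 0, 0)), rbind(c(1, 2)),
                  "dendrite")
  expect_equal(nrow(find_proximities(a, far, 5)), 0L)
  co <- skeleton(rbind(c(0, 0, 0), c(0, 0, 1)), rbind(c(1, 2)), "dendrite")
  expect_true(any(find_proximities(a, co, 5)[, 1L] == 1L))
})

test_that("Ld matches the analytic fixtures and the brute-force oracle", {
  for (sc in generate_skeleton_scene(3)) {
    prox <- compute_ld(sc$axon, sc$dend)
    expect_equal(prox$ld_um, sc$expected_ld, tolerance = 1e-9)
    expect_equal(prox$ld_um, oracle_ld(sc$axon, sc$dend), tolerance = 1e-12)
  }
  set.seed(20)
  for (rep in 1:5) {
    a <- random_skeleton(100, "axon", box = 8)
    d <- random_skeleton(100, "dendrite", box = 8)
    expect_equal(compute_ld(a, d)$ld_um, oracle_ld(a, d),
                 tolerance = 1e-12)
  }
})

test_that("Ld is non-decreasing in the proximity radius", {
  set.seed(6)
  a <- random_skeleton(100, "axon", box = 8)
  d <- random_skeleton(100, "dendrite", box = 8)
  lds <- vapply(c(1, 2.5, 5, 8, 12),
                function(r) compute_ld(a, d, radius = r)$ld_um, numeric(1))
  expect_true(all(diff(lds) >= 0))
  expect_lte(max(lds), cable_length(discretize_skeleton(d, 1)) + 1e-9)
})

test_that("synapse assignment uses the 3 um rule and validates ids", {
  sc <- generate_skeleton_scene(3)[[1]]   # parallel run fixture
  prox <- compute_ld(sc$axon, sc$dend)
  prox <- assign_synapses(sc$synapses, prox)
  expect_equal(prox$synapses$assigned, sc$expected_assigned)
  bad <- sc$synapses
  bad$pre_id <- "someone_else"
  expect_error(assign_synapses(bad, prox), "do not match")
  # random placements vs direct distance check
  set.seed(9)
  pos <- cbind(stats::runif(30, -2, 12), stats::runif(30, -2, 6),
               stats::runif(30, -4, 4))
  syn <- data.frame(synapse_id = 1:30, pre_id = "pre", post_id = "post",
                    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                    cleft_volume_voxels = 1000)
  got <- assign_synapses(syn, prox)$synapses$assigned
  pv <- rbind(prox$axon$vertices[unique(prox$pairs[, 1]), , drop = FALSE],
              prox$dend$vertices[unique(prox$pairs[, 2]), , drop = FALSE])
  want <- vapply(1:30, function(i)
    min(sqrt(colSums((t(pv) - pos[i, ])^2))) <= 3, logical(1))
  expect_equal(got, want)
})

test_that("projection types map areas (AL/RL pooled as HVA) correctly", {
  expect_equal(as.character(projection_type("V1", "V1")), "V1->V1")
  expect_equal(as.character(projection_type("AL", "V1")), "HVA->V1")
  expect_equal(as.character(projection_type("V1", "RL")), "V1->HVA")
  expect_equal(as.character(projection_type("RL", "AL")), "HVA->HVA")
  expect_error(projection_type("V2", "V1"), "unknown area")
  expect_equal(projection_type("V1", "AL", "L4", "L2/3"), "V1-L4->HVA-L2/3")
})

test_that("cohort assignment enforces thresholds and ADP precedence", {
  neurons <- data.frame(
    neuron_id = 1:6,
    area = c("V1", "V1", "V1", "V1", "V1", "V1"),
    cc_max = c(0.9, 0.9, 0.9, 0.9, 0.3, 0.9),
    cc_abs = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.1))
  pairs <- data.frame(
    pre_id = 1L, post_id = 2:6,
    ld_um = c(4, 7, 0, 6, 9),
    nsyn  = c(2, 0, 0, 0, 0))
  got <- build_cohorts(1L, neurons, pairs, target_region = "V1")
  expect_equal(got$cohort,
               c("connected",
                 "adp_control",          # Ld > 0, same region: ADP wins
                 "same_region_control",
                 "excluded",             # CCmax 0.3: out regardless of ADP
                 "excluded"))            # CCabs 0.1 fails inclusion
  low <- neurons; low$cc_max[2] <- 0.3
  got2 <- build_cohorts(1L, low, pairs, target_region = "V1")
  expect_equal(got2$cohort[1], "excluded")  # connected but unreliable
  expect_error(build_cohorts(99L, neurons, pairs), "absent")
})
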