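test_that("simulated experiments have the canonical replicate geometry", {
  cfg <- simulation_config(seed = 11)  # default 37-lectin panel, 3+3 slides
  sim <- simulate_experiment(cfg)
  expect_length(sim$spots, 6)
  blocks <- unlist(lapply(sim$spots, function(s) unique(s$block)))
  expect_equal(sort(unique(blocks)), 1:3)
  # 9 blocks and 27 spots per lectin per group
  model_slides <- sim$manifest$slide[sim$manifest$group_id == "MODEL"]
  all_model <- do.call(rbind, lapply(sim$spots[model_slides], as.data.frame))
  expect_equal(nrow(unique(all_model[, c("slide_id", "block")])), 9)
  expect_equal(sum(all_model$lectin == "PSA"), 27)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(planted_fold = c(PSA = 2), seed = 42)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$spots, s2$spots)
  # different seed: different noise, identical ground truth
  s3 <- simulate_experiment(simulation_config(planted_fold = c(PSA = 2),
                                              seed = 43))
  expect_false(identical(s1$spots, s3$spots))
  expect_identical(s1$truth, s3$truth)
})

test_that("expected_nfi_ratio matches the hand-derived compositional form", {
  panel <- tiny_panel(3)
  # equal baselines, fold 2 on one of three lectins: 2/(1+(2-1)/3) = 1.5
  cfg <- exact_config(panel, c(L1 = 2))
  expect_equal(unname(expected_nfi_ratio(cfg, "L1")), 1.5)
  # fold 1 anywhere is identity
  expect_equal(unname(expected_nfi_ratio(exact_config(panel, c(L1 = 1)), "L2")), 1)
  # weight -> 0 limit approaches the raw fold
  w <- c(L1 = 1e-9, L2 = 1, L3 = 1)
  cfg2 <- exact_config(panel, c(L1 = 2), baseline = w * 1000)
  expect_equal(unname(expected_nfi_ratio(cfg2, "L1")), 2, tolerance = 1e-6)
  expect_error(expected_nfi_ratio(cfg, "nope"), "unknown lectin")
})

test_that("zero-noise pipeline reproduces ground truth to machine precision", {
  panel <- tiny_panel(5)
  cfg <- exact_config(panel, c(L2 = 2, L4 = 0.5), seed = 9)
  sim <- simulate_experiment(cfg)
  profs <- quantify_groups(sim$spots, sim$manifest, panel)
  calls <- call_table(profs, "MODEL/CTRL", panel, p_gate = "off")
  expect_equal(stats::setNames(calls$ratio, calls$lectin),
               expected_nfi_ratio(cfg), tolerance = 1e-12)
  # no-effect, no-noise: all ratios exactly 1
  sim0 <- simulate_experiment(exact_config(panel, numeric(0)))
  p0 <- quantify_groups(sim0$spots, sim0$manifest, panel)
  c0 <- call_table(p0, "MODEL/CTRL", panel, p_gate = "off")
  expect_equal(c0$ratio, rep(1, 5))
  expect_true(all(c0$direction == "unchanged"))
})

test_that("mean measured ratio converges to the compositional expectation", {
  panel <- tiny_panel(6)
  folds <- c(L1 = 2, L5 = 0.4)
  ratios <- sapply(1:30, function(s) {
    cfg <- simulation_config(panel = panel, planted_fold = folds,
                             spot_cv = 0.1, block_sd = 0.05, slide_sd = 0.05,
                             bg_sd = 10, dropout_rate = 0, seed = 1000 + s)
    sim <- simulate_experiment(cfg)
    profs <- quantify_groups(sim$spots, sim$manifest, panel)
    calls <- call_table(profs, "MODEL/CTRL", panel, p_gate = "off")
    stats::setNames(calls$ratio, calls$lectin)
  })
  cfg <- simulation_config(panel = panel, planted_fold = folds, seed = 1)
  expect_equal(rowMeans(ratios), expected_nfi_ratio(cfg), tolerance = 0.05)
})

test_that("increasing a planted fold never decreases that lectin's ratio", {
  panel <- tiny_panel(4)
  folds <- seq(0.5, 4, by = 0.25)
  r <- vapply(folds, function(f) {
    unname(expected_nfi_ratio(exact_config(panel, c(L1 = f, L3 = 0.8)), "L1"))
  }, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("simulator flags dropouts and respects saturation", {
  cfg <- simulation_config(panel = tiny_panel(10), dropout_rate = 0.3,
                           baseline = 1e6, saturation = 5000, seed = 2)
  sim <- simulate_experiment(cfg)
  all_spots <- do.call(rbind, lapply(sim$spots, as.data.frame))
  expect_true(any(all_spots$flag < 0))
  expect_true(all(all_spots$fg_median <= 5000))
  expect_error(simulation_config(dropout_rate = 1), "dropout")
  expect_error(simulation_config(planted_fold = c(PSA = -1)), "> 0")
  expect_error(simulation_config(planted_fold = c(NOPE = 2)), "panel")
})
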