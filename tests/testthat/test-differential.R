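test_that("pooled t statistic matches the independent oracle", {
  tt <- nfi_t_test(c(1, 2, 3), c(2, 3, 4))
  o <- oracle_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, o$t, tolerance = 1e-12)
  expect_equal(tt$p_value, o$p_value, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:1000) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    got <- nfi_t_test(x, y)
    want <- oracle_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("t-test symmetry, antisymmetry and degenerate cases", {
  x <- c(0.1, 0.2, 0.15, 0.12)
  expect_equal(nfi_t_test(x, x), list(t = 0, df = 6, p_value = 1))
  y <- c(0.3, 0.25, 0.28)
  a <- nfi_t_test(x, y); b <- nfi_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  expect_warning(z <- nfi_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(z$p_value, 0)
  expect_error(nfi_t_test(1, c(1, 2)), ">= 2")
  # Welch form agrees with stats::t.test default
  w <- nfi_t_test(x, y, welch = TRUE)
  ow <- stats::t.test(x, y)
  expect_equal(w$t, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(w$p_value, ow$p.value, tolerance = 1e-12)
})

test_that("direction thresholds are inclusive and published-ratio cases hold", {
  expect_equal(direction_from_ratio(2.35), "up")
  expect_equal(direction_from_ratio(0.61), "down")
  expect_equal(direction_from_ratio(c(1.39, 1.58)), c("unchanged", "up"))
  expect_equal(direction_from_ratio(1.5), "up")     # inclusive boundary
  expect_equal(direction_from_ratio(0.67), "down")  # inclusive boundary
  expect_equal(direction_from_ratio(1.4999), "unchanged")
  expect_true(is.na(direction_from_ratio(NA)))
})

test_that("calls are invariant under joint scaling and monotone in ratio", {
  panel <- tiny_panel(4)
  cfg <- simulation_config(panel = panel, planted_fold = c(L2 = 3),
                           spot_cv = 0.05, seed = 21)
  sim <- simulate_experiment(cfg)
  profs <- quantify_groups(sim$spots, sim$manifest, panel)
  calls <- call_table(profs, "MODEL/CTRL", panel)
  # NFIs are already scale-free: rescaling all intensities of every slide
  # leaves calls identical
  spots2 <- lapply(sim$spots, function(s) {
    s$fg_median <- s$fg_median * 7.3; s$bg_median <- s$bg_median * 7.3; s
  })
  calls2 <- call_table(quantify_groups(spots2, sim$manifest, panel),
                       "MODEL/CTRL", panel)
  expect_equal(calls2$ratio, calls$ratio, tolerance = 1e-12)
  expect_equal(calls2$direction, calls$direction)
})

test_that("p-gate modes behave as documented", {
  panel <- tiny_panel(3)
  cfg <- simulation_config(panel = panel, planted_fold = c(L1 = 3),
                           spot_cv = 0.05, block_sd = 0.02, slide_sd = 0.02,
                           seed = 8, dropout_rate = 0)
  sim <- simulate_experiment(cfg)
  profs <- quantify_groups(sim$spots, sim$manifest, panel)
  lt <- call_table(profs, "MODEL/CTRL", panel, p_gate = "lt")
  off <- call_table(profs, "MODEL/CTRL", panel, p_gate = "off")
  gt <- call_table(profs, "MODEL/CTRL", panel, p_gate = "gt")
  expect_equal(lt$direction[lt$lectin == "L1"], "up")
  expect_equal(off$direction[off$lectin == "L1"], "up")
  # a strong, well-replicated effect has p << 0.05, so the "gt" reading
  # suppresses it
  expect_equal(gt$direction[gt$lectin == "L1"], "unchanged")
  # BH adjustment is available but does not destroy a lone strong effect
  bh <- call_table(profs, "MODEL/CTRL", panel, p_gate = "lt", fdr = "bh")
  expect_equal(bh$direction[bh$lectin == "L1"], "up")
})

test_that("call_lectin errors on zero control mean and unknown lectins", {
  panel <- tiny_panel(2)
  mk <- function(v) {
    bs <- lapply(v, function(a) block_profile(
      make_block(rbind(c(a, a, a), c(1, 1, 1)) * 1000, bg = 0,
                 panel = panel), panel))
    group_profile(bs, "G")
  }
  g1 <- mk(c(0.5, 0.6, 0.7)); g0 <- mk(c(0.5, 0.6, 0.7))
  g0$lectins$mean_nfi[1] <- 0
  expect_error(call_lectin(g1, g0, "L1"), "control mean NFI is 0")
  expect_error(call_lectin(g1, g0, "L9"), "not present")
})

test_that("cross-model comparison identifies shared and opposite lectins", {
  rc <- reference_calls()
  cr <- compare_models(rc$sad, rc$mcao)
  expect_setequal(cr$opposite_lectins,
                  c("WFA", "PTL-I", "PTL-II", "PHA-E + L", "SNA"))
  expect_true(all(cr$opposite_lectins %in% cr$shared_lectins))
  # identity: comparing a call set to itself yields no opposite lectins
  self <- compare_models(rc$sad, rc$sad)
  expect_length(self$opposite_lectins, 0)
  expect_setequal(self$shared_lectins, significant_lectins(rc$sad))
  # membership symmetry, direction antisymmetry
  rev <- compare_models(rc$mcao, rc$sad)
  expect_setequal(rev$shared_lectins, cr$shared_lectins)
  expect_setequal(rev$opposite_lectins, cr$opposite_lectins)
  # significant only in one model -> excluded from shared
  expect_false("PSA" %in% cr$shared_lectins)
  expect_false("ECA" %in% cr$shared_lectins)
  expect_error(compare_models(rc$sad[0, ], rc$mcao), "no lectins")
})

test_that("timepoint semantics: significant at any timepoint counts", {
  rc <- reference_calls()
  # DBA: 1.39 at 16 h (unchanged), 1.58 at 48 h (up) -> significant overall
  dba <- rc$mcao[rc$mcao$lectin == "DBA", ]
  expect_equal(dba$direction, c("unchanged", "up"))
  expect_true("DBA" %in% significant_lectins(rc$mcao))
})

test_that("motif summary tokenizes with longest match", {
  m1 <- motif_summary("Sia2-6Gal/GalNAc")
  expect_setequal(m1$token, c("Sia", "Gal", "GalNAc"))
  expect_true(all(m1$n_lectins == 1))
  # GalNAc never double-counts as Gal
  expect_equal(motif_summary("GalNAc")$token, "GalNAc")
  # Glc(NAc) with parenthesis is Glc, not GlcNAc
  m2 <- motif_summary("Fucα1-2Galβ1-4Glc(NAc)")
  expect_setequal(m2$token, c("Fuc", "Gal", "Glc"))
  expect_equal(nrow(motif_summary(c("", ""))), 0)
  # the five opposite-pattern lectins are dominated by Gal/GalNAc motifs
  rc <- reference_calls()
  cr <- compare_models(rc$sad, rc$mcao)
  ms <- cr$motif_summary
  gal <- ms$n_lectins[ms$token == "Gal"]
  galnac <- ms$n_lectins[ms$token == "GalNAc"]
  expect_gte(gal, 3)
  expect_gte(galnac, 3)
  # Gal leads the ranking: the shared structural theme of the opposite set
  expect_equal(ms$token[1], "Gal")
})
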