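test_that("background subtraction floors at zero", {
  expect_equal(subtract_background(1000, 200), 800)
  expect_equal(subtract_background(100, 150), 0)
  expect_equal(subtract_background(1000, 0), 1000)
  expect_error(subtract_background(NaN, 0), "finite")
})

test_that("block_profile computes hand-checked NFIs", {
  panel <- tiny_panel(3)
  # net medians {2, 3, 5} -> NFIs {0.2, 0.3, 0.5}
  fg <- matrix(c(2, 2, 2, 3, 3, 3, 5, 5, 5), 3, 3, byrow = TRUE) + 10
  bp <- block_profile(make_block(fg, bg = 10, panel = panel), panel)
  expect_equal(bp$lectins$nfi, c(0.2, 0.3, 0.5))
  expect_equal(sum(bp$lectins$nfi), 1)
  # 37 equal lectins -> each 1/37
  p37 <- tiny_panel(37)
  bp37 <- block_profile(make_block(matrix(500, 37, 3), panel = p37), p37)
  expect_equal(bp37$lectins$nfi, rep(1 / 37, 37))
  # median robust to one outlier: {100, 900, 110} -> 110
  fg2 <- rbind(c(100, 900, 110), c(50, 50, 50))
  p2 <- tiny_panel(2)
  bp2 <- block_profile(make_block(fg2, bg = 0, panel = p2), p2)
  expect_equal(bp2$lectins$net_median, c(110, 50))
})

test_that("block_profile matches the naive oracle on random small instances", {
  set.seed(101)
  for (rep in 1:500) {
    nl <- sample(2:5, 1); ns <- sample(2:4, 1)
    panel <- tiny_panel(nl, spots = ns)
    fg <- matrix(runif(nl * ns, 0, 2000), nl, ns)
    bg <- matrix(runif(nl * ns, 0, 300), nl, ns)
    tab <- spot_table("s", 1L, rep(seq_len(nl), each = ns),
                      rep(seq_len(ns), nl),
                      rep(panel$name, each = ns),
                      as.vector(t(fg)), as.vector(t(bg)))
    got <- block_profile(tab, panel)$lectins$nfi
    expect_equal(got, naive_block_profile(fg, bg), tolerance = 1e-12)
  }
})

test_that("NFIs are invariant under global block scaling and spot order", {
  panel <- tiny_panel(4)
  set.seed(7)
  fg <- matrix(runif(12, 500, 3000), 4, 3)
  tab <- make_block(fg, bg = 100, panel = panel)
  ref <- block_profile(tab, panel)$lectins$nfi
  for (c_ in c(0.01, 3, 250)) {
    scaled <- tab
    scaled$fg_median <- tab$fg_median * c_
    scaled$bg_median <- tab$bg_median * c_
    expect_equal(block_profile(scaled, panel)$lectins$nfi, ref,
                 tolerance = 1e-12)
  }
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(block_profile(perm, panel)$lectins$nfi, ref)
})

test_that("flagged spots are excluded; missing and degenerate blocks handled", {
  panel <- tiny_panel(2)
  fg <- rbind(c(100, 5000, 120), c(200, 200, 200))
  # flag the outlier spot away
  tab <- make_block(fg, bg = 0, panel = panel,
                    flag = c(0L, -100L, 0L, 0L, 0L, 0L))
  bp <- block_profile(tab, panel)
  expect_equal(bp$lectins$net_median[1], 110)  # midpoint of the 2 survivors
  # all spots of one lectin flagged -> marked missing, excluded from sum
  tab2 <- make_block(fg, bg = 0, panel = panel,
                     flag = c(-100L, -100L, -100L, 0L, 0L, 0L))
  expect_warning(bp2 <- block_profile(tab2, panel), "no unflagged spot")
  expect_true(bp2$lectins$missing[1])
  expect_true(is.na(bp2$lectins$nfi[1]))
  expect_equal(bp2$lectins$nfi[2], 1)
  # every spot flagged -> empty block; all-zero net -> degenerate
  expect_error(block_profile(make_block(fg, panel = panel, flag = -50L), panel),
               "empty block")
  expect_error(block_profile(make_block(matrix(5, 2, 3), bg = 10,
                                        panel = panel), panel),
               "degenerate")
})

test_that("bg_mode block-mean subtracts the block-wide mean background", {
  panel <- tiny_panel(2)
  tab <- make_block(rbind(c(1000, 1000, 1000), c(500, 500, 500)),
                    bg = 0, panel = panel)
  tab$bg_median <- c(100, 200, 300, 0, 0, 0)  # mean 100
  bp <- block_profile(tab, panel, bg_mode = "block-mean")
  expect_equal(bp$lectins$net_median, c(900, 400))
  bp2 <- block_profile(tab, panel, bg_mode = "per-spot")
  expect_equal(bp2$lectins$net_median, c(800, 500))
})

test_that("group_profile averages block NFIs with sample SD", {
  panel <- tiny_panel(2)
  mk <- function(a) block_profile(
    make_block(rbind(c(a, a, a), c(1 - a, 1 - a, 1 - a)) * 1000,
               bg = 0, panel = panel), panel)
  # lectin 1 NFIs {0.1, 0.2, 0.3}: mean 0.2, sample SD 0.1
  gp <- group_profile(list(mk(0.1), mk(0.2), mk(0.3)), "G")
  expect_equal(gp$lectins$mean_nfi[1], 0.2)
  expect_equal(gp$lectins$sd_nfi[1], 0.1)
  expect_equal(gp$n_blocks, 3)
  expect_equal(rowMeans(gp$nfi_matrix), c(L1 = 0.2, L2 = 0.8))
  # identical blocks -> zero SD
  gp0 <- group_profile(replicate(9, mk(0.25), simplify = FALSE), "G0")
  expect_equal(gp0$lectins$sd_nfi, c(0, 0))
  expect_equal(gp0$n_blocks, 9)
  expect_error(group_profile(list(), "G"), "at least one")
})

test_that("paper-geometry simulation yields 9 blocks per group", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_experiment(cfg)
  profs <- quantify_groups(sim$spots, sim$manifest, cfg$panel)
  expect_equal(vapply(profs, function(p) p$n_blocks, integer(1)),
               c(MODEL = 9L, CTRL = 9L))
})
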