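# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's code paths: naive_block_profile recomputes median-sum
# normalization from first principles, the t oracle delegates to
# stats::t.test, the clustering oracle to stats::hclust.

tiny_panel <- function(n = 3, spots = 3L, blocks = 3L) {
  lectin_panel(data.frame(name = paste0("L", seq_len(n)),
                          specificity = "", stringsAsFactors = FALSE),
               spots_per_lectin = spots, blocks_per_slide = blocks)
}

# build a one-block spot_table from a lectins x spots matrix of fg values
make_block <- function(fg, bg = 0, slide = "s1", block = 1L, flag = 0L,
                       panel = tiny_panel(nrow(fg))) {
  nl <- nrow(fg); ns <- ncol(fg)
  spot_table(slide_id = slide, block = block,
             row = rep(seq_len(nl), each = ns),
             column = rep(seq_len(ns), nl),
             lectin = rep(panel$name[seq_len(nl)], each = ns),
             fg_median = as.vector(t(fg)),
             bg_median = rep_len(bg, nl * ns),
             flag = rep_len(flag, nl * ns))
}

# first-principles NFI computation for one block (per-spot background)
naive_block_profile <- function(fg, bg, flag = NULL) {
  nl <- nrow(fg)
  if (is.null(flag)) flag <- matrix(0L, nl, ncol(fg))
  med <- numeric(nl)
  for (i in seq_len(nl)) {
    net <- c()
    for (j in seq_len(ncol(fg))) {
      if (flag[i, j] >= 0) net <- c(net, max(0, fg[i, j] - bg[i, j]))
    }
    med[i] <- stats::median(net)
  }
  med / sum(med)
}

oracle_t <- function(x, y) {
  o <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(o$statistic), p_value = o$p.value)
}

# noise-free simulation config over a small panel
exact_config <- function(panel, planted_fold, seed = 1L, baseline = 1000,
                         groups = NULL) {
  args <- list(panel = panel, baseline = baseline,
               planted_fold = planted_fold, spot_cv = 0, block_sd = 0,
               slide_sd = 0, bg_level = 100, bg_sd = 0, dropout_rate = 0,
               seed = seed)
  if (!is.null(groups)) args$groups <- groups
  do.call(simulation_config, args)
}
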