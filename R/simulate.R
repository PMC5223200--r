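# Synthetic slide simulator. One pooled biological sample per group is
# assumed (the replication is purely technical: spots within block, blocks
# within slide, slides within group), matching the pooled-sample design the
# pipeline targets. Planted fold changes act on the raw net intensity of a
# lectin in model-role groups; the compositional closure of the median-sum
# normalization then determines the NFI ratio actually observable
# downstream, for which expected_nfi_ratio() gives the closed form.

#' Simulation configuration
#'
#' @param panel a \code{\link{lectin_panel}}.
#' @param groups data.frame with columns \code{group_id}, \code{role}
#'   ("model" or "control") and \code{n_slides}. Default: one model and one
#'   control group with 3 slides each, giving 9 blocks per group under the
#'   default 3-blocks-per-slide layout.
#' @param baseline per-lectin mean net intensity (a.u.), a single number or
#'   a vector named by lectin. Default 1000 for every lectin.
#' @param planted_fold multiplicative effect on net intensity in model
#'   groups: a named numeric vector (applied to every model group) or a
#'   named list \code{group_id -> named vector} for per-group effects.
#'   Lectins not named get fold 1. All folds must be > 0.
#' @param spot_cv per-spot multiplicative log-normal coefficient of
#'   variation (default 0.1).
#' @param block_sd,slide_sd log-scale SDs of shared batch-effect
#'   multipliers per block and per slide (default 0.05 each).
#' @param bg_level,bg_sd additive background mean and SD (a.u.); the
#'   background draw is truncated at 0.
#' @param saturation scanner ceiling (a.u., default 65535).
#' @param dropout_rate probability a spot is flagged bad (default 0.01).
#' @param seed integer RNG seed.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(panel = default_panel(),
                              groups = data.frame(
                                group_id = c("MODEL", "CTRL"),
                                role = c("model", "control"),
                                n_slides = c(3L, 3L),
                                stringsAsFactors = FALSE),
                              baseline = 1000,
                              planted_fold = numeric(0),
                              spot_cv = 0.1,
                              block_sd = 0.05,
                              slide_sd = 0.05,
                              bg_level = 100,
                              bg_sd = 20,
                              saturation = 65535,
                              dropout_rate = 0.01,
                              seed = 1L) {
  stopifnot(inherits(panel, "lectin_panel"),
            is.data.frame(groups),
            all(c("group_id", "role", "n_slides") %in% names(groups)),
            nrow(groups) >= 1, all(groups$n_slides >= 1),
            all(groups$role %in% c("model", "control")))
  if (anyDuplicated(groups$group_id)) stop("duplicate group_id in groups")
  if (length(baseline) == 1) {
    baseline <- stats::setNames(rep(baseline, nrow(panel)), panel$name)
  }
  if (is.null(names(baseline)) || !all(panel$name %in% names(baseline))) {
    stop("baseline must be a single number or a vector named by panel lectin")
  }
  baseline <- baseline[panel$name]
  if (any(baseline < 0)) stop("baseline intensities must be >= 0")
  if (!is.list(planted_fold)) {
    planted_fold <- stats::setNames(
      rep(list(planted_fold), sum(groups$role == "model")),
      groups$group_id[groups$role == "model"])
  }
  for (g in names(planted_fold)) {
    pf <- planted_fold[[g]]
    if (length(pf)) {
      if (is.null(names(pf)) || !all(names(pf) %in% panel$name)) {
        stop("planted_fold names must be panel lectins")
      }
      if (any(pf <= 0)) stop("planted folds must be > 0")
    }
    if (!g %in% groups$group_id[groups$role == "model"]) {
      stop("planted_fold group '", g, "' is not a model group")
    }
  }
  stopifnot(spot_cv >= 0, block_sd >= 0, slide_sd >= 0, bg_sd >= 0,
            bg_level >= 0, dropout_rate >= 0, dropout_rate < 1,
            saturation > bg_level)
  structure(list(panel = panel, groups = groups, baseline = baseline,
                 planted_fold = planted_fold, spot_cv = spot_cv,
                 block_sd = block_sd, slide_sd = slide_sd,
                 bg_level = bg_level, bg_sd = bg_sd,
                 saturation = saturation, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# per-group fold vector over the full panel (1 where not planted)
.group_folds <- function(config, group_id) {
  f <- stats::setNames(rep(1, nrow(config$panel)), config$panel$name)
  role <- config$groups$role[config$groups$group_id == group_id]
  if (length(role) && role == "model") {
    pf <- config$planted_fold[[group_id]]
    if (length(pf)) f[names(pf)] <- pf
  }
  f
}

#' Closed-form expected NFI ratio under a planted fold
#'
#' The median-sum normalization is compositional: planting a fold
#' \eqn{f_l} on lectin \eqn{l}'s net intensity changes every lectin's NFI.
#' With baselines \eqn{\mu_k} and per-group folds \eqn{f_k}, the
#' noise-free model-vs-control NFI ratio for lectin \eqn{l} is
#' \deqn{ (f_l \mu_l / \sum_k f_k \mu_k) / (\mu_l / \sum_k \mu_k)
#'        = f_l \sum_k \mu_k / \sum_k f_k \mu_k. }
#' For a single planted fold \eqn{f} on a lectin of baseline NFI weight
#' \eqn{w} this reduces to \eqn{f / (1 + (f - 1) w)}, approaching \eqn{f}
#' as \eqn{w \to 0}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param lectin lectin name(s); default: all panel lectins.
#' @param group model group id; default: the first model group.
#' @return named numeric vector of expected NFI ratios.
#' @export
expected_nfi_ratio <- function(config, lectin = NULL, group = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(group)) {
    group <- config$groups$group_id[config$groups$role == "model"][1]
  }
  if (is.null(lectin)) lectin <- config$panel$name
  if (!all(lectin %in% config$panel$name)) {
    stop("unknown lectin(s): ",
         paste(setdiff(lectin, config$panel$name), collapse = ", "))
  }
  f <- .group_folds(config, group)
  mu <- config$baseline
  ratio <- f * sum(mu) / sum(f * mu)
  ratio[lectin]
}

#' Ground truth of a simulated experiment
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{net} (lectins x groups matrix of true mean net
#'   intensities), \code{expected_ratio} (lectins x model-groups matrix of
#'   closed-form NFI ratios vs control) and \code{planted_fold}.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gids <- config$groups$group_id
  net <- sapply(gids, function(g) .group_folds(config, g) * config$baseline)
  net <- matrix(net, nrow = nrow(config$panel),
                dimnames = list(config$panel$name, gids))
  models <- gids[config$groups$role == "model"]
  er <- sapply(models, function(g) expected_nfi_ratio(config, group = g))
  er <- matrix(er, nrow = nrow(config$panel),
               dimnames = list(config$panel$name, models))
  list(net = net, expected_ratio = er, planted_fold = config$planted_fold)
}

# mean-1 log-normal multiplier: sdlog from a CV (spot noise) or given
# directly (batch effects)
.lnorm_mult <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a lectin-microarray experiment
#'
#' Generates one spot table per slide with the configured replicate
#' structure. Each spot's foreground is
#' \code{min(saturation, net * spot_noise * block_eff * slide_eff + bg)}
#' with a truncated-normal additive background \code{bg} that is also
#' reported as the spot's local background estimate; bad spots get
#' \code{flag = -100}. Identical seeds give identical output.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{spots} (named list of \code{spot_table}, one per
#'   slide), \code{manifest} (data.frame group_id/role/slide) and
#'   \code{truth} (see \code{\link{ground_truth}}).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$panel
  nspot <- attr(panel, "spots_per_lectin")
  nblk <- attr(panel, "blocks_per_slide")
  sdlog_spot <- sqrt(log(1 + config$spot_cv^2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  truth <- ground_truth(config)
  spots <- list()
  manifest <- NULL
  for (gi in seq_len(nrow(config$groups))) {
    gid <- config$groups$group_id[gi]
    net_true <- truth$net[, gid]
    for (si in seq_len(config$groups$n_slides[gi])) {
      slide_id <- sprintf("%s_slide%d", gid, si)
      slide_eff <- .lnorm_mult(1, config$slide_sd)
      recs <- vector("list", nblk)
      for (b in seq_len(nblk)) {
        block_eff <- .lnorm_mult(1, config$block_sd)
        n <- nrow(panel) * nspot
        lectin <- rep(panel$name, each = nspot)
        net <- rep(net_true, each = nspot) *
          .lnorm_mult(n, sdlog_spot) * block_eff * slide_eff
        bg <- pmax(0, stats::rnorm(n, config$bg_level, config$bg_sd))
        fg <- pmin(config$saturation, net + bg)
        flag <- ifelse(stats::runif(n) < config$dropout_rate, -100L, 0L)
        recs[[b]] <- data.frame(
          slide_id = slide_id, block = b,
          row = rep(seq_len(nrow(panel)), each = nspot),
          column = rep(seq_len(nspot), nrow(panel)),
          lectin = lectin, fg_median = fg, bg_median = bg, flag = flag,
          stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, recs)
      spots[[slide_id]] <- spot_table(df$slide_id, df$block, df$row,
                                      df$column, df$lectin, df$fg_median,
                                      df$bg_median, df$flag, panel = panel)
      manifest <- rbind(manifest, data.frame(group_id = gid,
                                             role = config$groups$role[gi],
                                             slide = slide_id,
                                             stringsAsFactors = FALSE))
    }
  }
  list(spots = spots, manifest = manifest, truth = truth)
}
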