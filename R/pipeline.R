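# End-to-end pipeline: simulate (or read) -> quantify -> differential ->
# cross-model compare -> report, driven by a single JSON config, plus a
# thin argv-style CLI (`glycolect {simulate,quantify,diff,compare,report,
# run}`) intended for Rscript wrappers.

.log <- function(...) message("[glycolect] ", sprintf(...))

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  config
}

.config_panel <- function(config) {
  if (!is.null(config$panel)) read_panel(config$panel) else default_panel()
}

.config_sim <- function(config, panel, seed) {
  sim <- config$simulate
  groups <- do.call(rbind, lapply(sim$groups, function(g) {
    data.frame(group_id = g$group_id, role = g$role,
               n_slides = as.integer(g$n_slides %||% 3L),
               stringsAsFactors = FALSE)
  }))
  pf <- sim$planted_fold %||% numeric(0)
  if (is.list(pf) && length(pf) && is.list(pf[[1]])) {
    pf <- lapply(pf, unlist)
  } else if (is.list(pf)) {
    pf <- unlist(pf)
    if (is.null(pf)) pf <- numeric(0)
  }
  simulation_config(
    panel = panel, groups = groups,
    baseline = sim$baseline %||% 1000,
    planted_fold = pf,
    spot_cv = sim$spot_cv %||% 0.1,
    block_sd = sim$block_sd %||% 0.05,
    slide_sd = sim$slide_sd %||% 0.05,
    bg_level = sim$bg_level %||% 100,
    bg_sd = sim$bg_sd %||% 20,
    saturation = sim$saturation %||% 65535,
    dropout_rate = sim$dropout_rate %||% 0.01,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages: obtain spot tables (from the built-in simulator or from a
#' manifest of existing files), quantify block and group NFI profiles,
#' call differential lectins for the configured contrasts, optionally
#' compare two models' call sets, and write reports (profile and call
#' TSVs, heat map + numeric sidecar, run manifest JSON). The run is
#' validated before any computation: every contrast group must exist.
#'
#' @param config path to a JSON config or an equivalent list. Keys:
#'   \code{seed}; either \code{simulate} (with \code{groups},
#'   \code{planted_fold}, noise parameters) or \code{manifest} (path);
#'   optional \code{panel} (TSV path); \code{bg_mode}; \code{contrasts}
#'   (vector of \code{"MODEL/CONTROL"}); optional \code{compare} with
#'   \code{a}/\code{b} contrast subsets; \code{up}, \code{down},
#'   \code{p_gate}, \code{alpha}, \code{fdr}; \code{heatmap} (logical).
#' @param out_dir output directory (overrides the config's
#'   \code{out_dir}).
#' @return invisibly, list with \code{profiles}, \code{calls},
#'   \code{cross}, \code{truth} (simulation mode only) and
#'   \code{files}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- .read_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "glycolect_out"
  seed <- as.integer(config$seed %||% 1L)
  panel <- .config_panel(config)
  contrasts <- config$contrasts %||% character(0)
  if (!length(contrasts)) stop("config must declare at least one contrast")
  cparts <- strsplit(unlist(contrasts), "/", fixed = TRUE)
  # fail fast: group names referenced by contrasts must exist
  declared <- if (!is.null(config$simulate)) {
    vapply(config$simulate$groups, function(g) g$group_id, character(1))
  } else if (!is.null(config$manifest)) {
    unique(read_manifest(config$manifest)$group_id)
  } else stop("config needs either 'simulate' or 'manifest'")
  for (ct in cparts) {
    if (length(ct) != 2 || !all(ct %in% declared)) {
      stop("contrast references undeclared group(s): ",
           paste(ct, collapse = "/"))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth <- NULL
  if (!is.null(config$simulate)) {
    .log("simulating experiment (seed %d)", seed)
    sim <- simulate_experiment(.config_sim(config, panel, seed))
    spots <- sim$spots; manifest <- sim$manifest; truth <- sim$truth
    for (sl in names(spots)) {
      f <- file.path(out_dir, paste0(sl, ".tsv"))
      write_spot_table(spots[[sl]], f)
      files <- c(files, f)
    }
    tf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(net = as.data.frame(truth$net),
                              expected_ratio = as.data.frame(truth$expected_ratio)),
                         tf, digits = NA)
    files <- c(files, tf)
  } else {
    .log("reading manifest %s", config$manifest)
    manifest <- read_manifest(config$manifest)
    spots <- lapply(stats::setNames(manifest$slide, manifest$slide),
                    function(f) read_spot_table(f, panel))
    # slide files are keyed by their slide_id column
    names(spots) <- vapply(spots, function(s) s$slide_id[1], character(1))
    manifest$slide <- names(spots)
  }
  bg_mode <- config$bg_mode %||% "per-spot"
  .log("quantifying %d slides (bg_mode=%s)", length(spots), bg_mode)
  profiles <- quantify_groups(spots, manifest, panel, bg_mode)
  prof_df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(group = p$group_id, p$lectins, stringsAsFactors = FALSE)
  }))
  pf <- file.path(out_dir, "profiles.tsv")
  utils::write.table(prof_df, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, pf)
  up <- config$up %||% 1.5; down <- config$down %||% 0.67
  p_gate <- config$p_gate %||% "lt"
  .log("calling differential lectins (up>=%.2f, down<=%.2f, p_gate=%s)",
       up, down, p_gate)
  calls <- call_table(profiles, unlist(contrasts), panel, up = up,
                      down = down, p_gate = p_gate,
                      alpha = config$alpha %||% 0.05,
                      welch = isTRUE(config$welch),
                      fdr = config$fdr %||% "none")
  cf <- file.path(out_dir, "calls.tsv")
  utils::write.table(calls, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, cf, export_tables(calls, NULL, out_dir))
  cross <- NULL
  if (!is.null(config$compare)) {
    a <- calls[calls$contrast %in% unlist(config$compare$a), , drop = FALSE]
    b <- calls[calls$contrast %in% unlist(config$compare$b), , drop = FALSE]
    if (!nrow(a) || !nrow(b)) stop("compare: contrasts not found in calls")
    cross <- compare_models(a, b)
    xf <- file.path(out_dir, "cross_model.json")
    jsonlite::write_json(list(shared = cross$shared_lectins,
                              opposite = cross$opposite_lectins,
                              motif_summary = cross$motif_summary),
                         xf, digits = NA)
    files <- c(files, xf, export_tables(calls, cross, out_dir))
    .log("cross-model: %d shared, %d opposite",
         length(cross$shared_lectins), length(cross$opposite_lectins))
  }
  if (isTRUE(config$heatmap %||% TRUE)) {
    sig <- significant_lectins(calls)
    if (length(sig) >= 2) {
      m <- do.call(rbind, lapply(profiles, function(p) {
        stats::setNames(p$lectins$mean_nfi, p$lectins$lectin)[sig]
      }))
      rownames(m) <- names(profiles)
      cl <- cluster_lectins(m)
      hf <- file.path(out_dir, "heatmap.png")
      hm <- render_heatmap(m, cl, hf)
      files <- c(files, hf, hm$sidecar)
    } else .log("heat map skipped: < 2 significant lectins")
  }
  rm <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(list(seed = seed, bg_mode = bg_mode, up = up,
                            down = down, p_gate = p_gate,
                            contrasts = unlist(contrasts),
                            n_slides = length(spots),
                            files = basename(files)),
                       rm, auto_unbox = TRUE)
  files <- c(files, rm)
  .log("done: %d files in %s", length(files), out_dir)
  invisible(list(profiles = profiles, calls = calls, cross = cross,
                 truth = truth, files = files))
}

# --- minimal argv parsing: --key value pairs -------------------------------

.parse_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      val <- if (i < length(args) && !startsWith(args[i + 1], "--")) {
        i <- i + 1; args[i]
      } else TRUE
      if (!is.null(out[[key]])) out[[key]] <- c(out[[key]], val)
      else out[[key]] <- val
    } else out$positional <- c(out$positional, a)
    i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Dispatches \code{glycolect <subcommand> [--options]}; intended to be
#' called from an Rscript wrapper (see \code{inst/cli/glycolect.R}).
#' Subcommands: \code{simulate} (--config --out-dir --seed),
#' \code{quantify} (--manifest --panel --bg-mode --out),
#' \code{diff} (--profiles-dir --manifest --panel --contrast ... --up
#' --down --p-gate --out), \code{compare} (--calls-a --calls-b --out),
#' \code{run} (--config --out-dir).
#'
#' @param args character vector, default \code{commandArgs(TRUE)}.
#' @return integer exit status (0 on success), invisibly.
#' @export
glycolect_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: glycolect {simulate,quantify,diff,compare,run} ...")
    cmd <- args[1]
    opt <- .parse_args(args[-1])
    switch(cmd,
      simulate = {
        config <- .read_config(opt$config)
        seed <- as.integer(opt$seed %||% config$seed %||% 1L)
        panel <- .config_panel(config)
        sim <- simulate_experiment(.config_sim(config, panel, seed))
        out_dir <- opt[["out-dir"]] %||% "sim_out"
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (sl in names(sim$spots)) {
          write_spot_table(sim$spots[[sl]], file.path(out_dir, paste0(sl, ".tsv")))
        }
        utils::write.table(
          data.frame(Group = sim$manifest$group_id, Role = sim$manifest$role,
                     Slide = file.path(out_dir, paste0(sim$manifest$slide, ".tsv"))),
          file.path(out_dir, "manifest.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        jsonlite::write_json(
          list(net = as.data.frame(sim$truth$net),
               expected_ratio = as.data.frame(sim$truth$expected_ratio)),
          file.path(out_dir, "ground_truth.json"), digits = NA)
        .log("wrote %d slides to %s", length(sim$spots), out_dir)
      },
      quantify = {
        panel <- if (!is.null(opt$panel)) read_panel(opt$panel) else default_panel()
        manifest <- read_manifest(opt$manifest)
        spots <- lapply(manifest$slide, function(f) read_spot_table(f, panel))
        names(spots) <- vapply(spots, function(s) s$slide_id[1], character(1))
        manifest$slide <- names(spots)
        profs <- quantify_groups(spots, manifest, panel,
                                 opt[["bg-mode"]] %||% "per-spot")
        df <- do.call(rbind, lapply(profs, function(p) {
          data.frame(group = p$group_id, p$lectins, stringsAsFactors = FALSE)
        }))
        utils::write.table(df, opt$out %||% "profiles.tsv", sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      diff = {
        # profile-level differential: mean-NFI ratios only, so the
        # fold-change gate alone applies (block vectors are not in the TSV)
        prof <- utils::read.delim(opt$profiles, stringsAsFactors = FALSE)
        up <- as.numeric(opt$up %||% 1.5)
        down <- as.numeric(opt$down %||% 0.67)
        calls <- do.call(rbind, lapply(opt$contrast, function(ct) {
          gg <- strsplit(ct, "[/:]")[[1]]
          if (length(gg) != 2) stop("bad --contrast, want MODEL:CONTROL")
          a <- prof[prof$group == gg[1], ]; b <- prof[prof$group == gg[2], ]
          if (!nrow(a) || !nrow(b)) stop("contrast group missing: ", ct)
          calls_from_ratios(
            data.frame(lectin = a$lectin,
                       ratio = a$mean_nfi / b$mean_nfi[match(a$lectin, b$lectin)],
                       stringsAsFactors = FALSE),
            paste0(gg[1], "/", gg[2]), up, down)
        }))
        utils::write.table(calls, opt$out %||% "calls.tsv", sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      compare = {
        a <- utils::read.delim(opt[["calls-a"]], stringsAsFactors = FALSE)
        b <- utils::read.delim(opt[["calls-b"]], stringsAsFactors = FALSE)
        cr <- compare_models(a, b)
        jsonlite::write_json(list(shared = cr$shared_lectins,
                                  opposite = cr$opposite_lectins,
                                  motif_summary = cr$motif_summary),
                             opt$out %||% "cross_model.json", digits = NA)
      },
      run = {
        run_pipeline(opt$config, out_dir = opt[["out-dir"]])
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("glycolect error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
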