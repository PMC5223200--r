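# Differential glycan calling. A lectin is called up-regulated in a
# model-vs-control contrast when its mean-NFI ratio is >= 1.5 (inclusive)
# and down-regulated when <= 0.67, optionally gated by a two-sample
# Student's t-test on the block-level NFIs. Cross-model comparison finds
# lectins significant in two disease models, in particular those with
# strictly opposite directions, and summarizes the monosaccharide motifs
# their glycan specificities share.

#' Two-sample pooled-variance Student's t-test
#'
#' Classical Student's t with pooled variance and a two-sided p-value from
#' the t distribution on \code{n1 + n2 - 2} degrees of freedom, implemented
#' directly (not delegated) so that it is independently checkable.
#' Optionally Welch's unequal-variance form.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite form instead of pooled
#'   variance.
#' @return list with \code{t}, \code{df}, \code{p_value}. Degenerate case:
#'   zero variance in both groups gives \code{t = 0, p = 1} for equal
#'   means, and \code{p = 0} with a warning for unequal means.
#' @export
nfi_t_test <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("t-test needs >= 2 observations per group")
  d <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
    warning("zero variance with unequal means; p-value is 0")
    return(list(t = sign(d) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- d / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}

#' Direction label from a fold-change ratio
#'
#' @param ratio mean-NFI ratio(s), model / control.
#' @param up inclusive up-regulation threshold (default 1.5).
#' @param down inclusive down-regulation threshold (default 0.67).
#' @return character vector: "up", "down" or "unchanged" (NA ratio gives
#'   NA).
#' @export
direction_from_ratio <- function(ratio, up = 1.5, down = 0.67) {
  stopifnot(up > down)
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio >= up, "up", ifelse(ratio <= down, "down", "unchanged")))
}

#' Differential call for one lectin
#'
#' @param model_profile,control_profile \code{\link{group_profile}}s.
#' @param lectin lectin name, present in both profiles.
#' @param up,down fold-change thresholds, inclusive as
#'   \code{\link{direction_from_ratio}}.
#' @param p_gate \code{"lt"} (default: require p < alpha in addition to the
#'   fold change), \code{"gt"} (require p > alpha; provided to reproduce an
#'   alternative reading of ambiguous conventions) or \code{"off"}
#'   (fold change only).
#' @param alpha significance level for the gate (default 0.05).
#' @param welch use Welch's t instead of Student's pooled t.
#' @return one-row data.frame: \code{lectin}, \code{contrast},
#'   \code{ratio}, \code{t}, \code{p_value}, \code{direction}.
#' @export
call_lectin <- function(model_profile, control_profile, lectin,
                        up = 1.5, down = 0.67,
                        p_gate = c("lt", "gt", "off"), alpha = 0.05,
                        welch = FALSE) {
  p_gate <- match.arg(p_gate)
  stopifnot(inherits(model_profile, "group_profile"),
            inherits(control_profile, "group_profile"))
  lm_ <- model_profile$lectins; lc_ <- control_profile$lectins
  if (!(lectin %in% lm_$lectin) || !(lectin %in% lc_$lectin)) {
    stop("lectin not present in both profiles: ", lectin)
  }
  m <- lm_$mean_nfi[lm_$lectin == lectin]
  cc <- lc_$mean_nfi[lc_$lectin == lectin]
  contrast <- paste0(model_profile$group_id, "/", control_profile$group_id)
  if (is.na(m) || is.na(cc)) {
    return(data.frame(lectin = lectin, contrast = contrast, ratio = NA_real_,
                      t = NA_real_, p_value = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE))
  }
  if (cc == 0) stop("undefined ratio: control mean NFI is 0 for ", lectin)
  ratio <- m / cc
  xm <- model_profile$nfi_matrix[lectin, ]
  xc <- control_profile$nfi_matrix[lectin, ]
  tt <- if (sum(!is.na(xm)) >= 2 && sum(!is.na(xc)) >= 2) {
    nfi_t_test(xm, xc, welch = welch)
  } else list(t = NA_real_, p_value = NA_real_)
  pass <- switch(p_gate,
                 off = TRUE,
                 lt = !is.na(tt$p_value) && tt$p_value < alpha,
                 gt = !is.na(tt$p_value) && tt$p_value > alpha)
  dir <- direction_from_ratio(ratio, up, down)
  if (!pass && dir != "unchanged") dir <- "unchanged"
  data.frame(lectin = lectin, contrast = contrast, ratio = ratio, t = tt$t,
             p_value = tt$p_value, direction = dir, stringsAsFactors = FALSE)
}

#' Differential call table over contrasts
#'
#' One call per panel lectin per contrast, in stable panel order.
#'
#' @param profiles named list of \code{\link{group_profile}} (e.g. from
#'   \code{\link{quantify_groups}}).
#' @param contrasts list of \code{c(model, control)} group-id pairs, or a
#'   character vector of \code{"MODEL/CONTROL"} strings.
#' @param panel optional \code{\link{lectin_panel}} supplying order and
#'   specificity annotation; defaults to the first profile's lectin order.
#' @param fdr \code{"none"} (default, matching the fold-change-centred
#'   design) or \code{"bh"} for Benjamini-Hochberg adjustment of the
#'   p-gate within each contrast.
#' @inheritParams call_lectin
#' @return data.frame of class \code{differential_calls}: \code{lectin},
#'   \code{specificity}, \code{contrast}, \code{ratio}, \code{t},
#'   \code{p_value}, \code{direction}. Per-lectin failures (undefined
#'   ratios) propagate as NA rows rather than aborting the table.
#' @export
call_table <- function(profiles, contrasts, panel = NULL,
                       up = 1.5, down = 0.67,
                       p_gate = c("lt", "gt", "off"), alpha = 0.05,
                       welch = FALSE, fdr = c("none", "bh")) {
  p_gate <- match.arg(p_gate); fdr <- match.arg(fdr)
  if (is.character(contrasts)) {
    contrasts <- strsplit(contrasts, "/", fixed = TRUE)
  }
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% names(profiles))) {
      stop("contrast groups missing from profiles: ", paste(ct, collapse = "/"))
    }
  }
  lectins <- if (!is.null(panel)) panel$name else profiles[[1]]$lectins$lectin
  spec <- if (!is.null(panel)) {
    stats::setNames(panel$specificity, panel$name)
  } else stats::setNames(rep("", length(lectins)), lectins)
  out <- list()
  for (ct in contrasts) {
    rows <- lapply(lectins, function(l) {
      tryCatch(
        call_lectin(profiles[[ct[1]]], profiles[[ct[2]]], l, up, down,
                    p_gate = "off", alpha = alpha, welch = welch),
        error = function(e) data.frame(
          lectin = l, contrast = paste0(ct[1], "/", ct[2]), ratio = NA_real_,
          t = NA_real_, p_value = NA_real_, direction = NA_character_,
          stringsAsFactors = FALSE))
    })
    tab <- do.call(rbind, rows)
    p <- tab$p_value
    if (fdr == "bh") p <- stats::p.adjust(p, "BH")
    pass <- switch(p_gate, off = rep(TRUE, nrow(tab)),
                   lt = !is.na(p) & p < alpha,
                   gt = !is.na(p) & p > alpha)
    tab$direction <- ifelse(!is.na(tab$direction) &
                              tab$direction != "unchanged" & !pass,
                            "unchanged", tab$direction)
    out[[length(out) + 1]] <- tab
  }
  res <- do.call(rbind, out)
  res$specificity <- unname(spec[res$lectin])
  res <- res[, c("lectin", "specificity", "contrast", "ratio", "t",
                 "p_value", "direction")]
  class(res) <- c("differential_calls", "data.frame")
  res
}

#' Build calls directly from a table of printed ratios
#'
#' Applies the fold-change classifier to already-computed mean-NFI ratios
#' (e.g. a published ratio table where block-level data are unavailable).
#' No p-gate is applied: only the ratio thresholds.
#'
#' @param ratios data.frame with columns \code{lectin} and \code{ratio},
#'   plus optionally \code{specificity}.
#' @param contrast contrast label, e.g. \code{"SAD/SAD-C"}.
#' @param up,down thresholds as in \code{\link{direction_from_ratio}}.
#' @return a \code{differential_calls} data.frame (with NA t and p).
#' @export
calls_from_ratios <- function(ratios, contrast, up = 1.5, down = 0.67) {
  stopifnot(is.data.frame(ratios), all(c("lectin", "ratio") %in% names(ratios)))
  res <- data.frame(
    lectin = as.character(ratios$lectin),
    specificity = if ("specificity" %in% names(ratios))
      as.character(ratios$specificity) else "",
    contrast = contrast,
    ratio = as.numeric(ratios$ratio),
    t = NA_real_, p_value = NA_real_,
    direction = direction_from_ratio(ratios$ratio, up, down),
    stringsAsFactors = FALSE)
  class(res) <- c("differential_calls", "data.frame")
  res
}

#' Lectins called significant in a set of calls
#'
#' @param calls a \code{differential_calls} data.frame, possibly spanning
#'   several contrasts (timepoints). A lectin is significant if called up
#'   or down in \emph{any} contrast.
#' @return character vector of lectin names, in call-table order.
#' @export
significant_lectins <- function(calls) {
  sig <- !is.na(calls$direction) & calls$direction != "unchanged"
  unique(calls$lectin[sig])
}

# collapse a multi-contrast call set to one direction per lectin:
# up / down / mixed / unchanged
.collapse_direction <- function(calls) {
  vapply(unique(calls$lectin), function(l) {
    d <- calls$direction[calls$lectin == l]
    d <- d[!is.na(d)]
    has_up <- any(d == "up"); has_down <- any(d == "down")
    if (has_up && has_down) "mixed"
    else if (has_up) "up"
    else if (has_down) "down"
    else "unchanged"
  }, character(1))
}

#' Compare differential calls between two disease models
#'
#' A lectin is \emph{shared} if significant (up or down in any contrast) in
#' both call sets and \emph{opposite} if additionally its collapsed
#' directions disagree strictly (up in one model, down in the other;
#' lectins with mixed within-model directions are never opposite). The
#' motif summary tokenizes the opposite lectins' glycan specificities.
#'
#' @param calls_a,calls_b \code{differential_calls} for the two models;
#'   either may span several timepoint contrasts.
#' @return list of class \code{cross_model_result}: \code{table}
#'   (per-lectin collapsed directions), \code{shared_lectins},
#'   \code{opposite_lectins}, \code{motif_summary}. Ordering follows
#'   \code{calls_a}'s lectin order.
#' @export
compare_models <- function(calls_a, calls_b) {
  common <- intersect(unique(calls_a$lectin), unique(calls_b$lectin))
  if (!length(common)) stop("call sets share no lectins")
  da <- .collapse_direction(calls_a)
  db <- .collapse_direction(calls_b)
  ord <- unique(calls_a$lectin)
  ord <- ord[ord %in% common]
  tab <- data.frame(lectin = ord, dir_a = unname(da[ord]),
                    dir_b = unname(db[ord]), stringsAsFactors = FALSE)
  sig_a <- tab$dir_a != "unchanged"
  sig_b <- tab$dir_b != "unchanged"
  shared <- tab$lectin[sig_a & sig_b]
  opp <- tab$lectin[(tab$dir_a == "up" & tab$dir_b == "down") |
                      (tab$dir_a == "down" & tab$dir_b == "up")]
  spec <- stats::setNames(calls_a$specificity[!duplicated(calls_a$lectin)],
                          unique(calls_a$lectin))
  motifs <- if (length(opp)) motif_summary(spec[opp]) else
    data.frame(token = character(0), n_lectins = integer(0))
  structure(list(table = tab, shared_lectins = shared,
                 opposite_lectins = opp, motif_summary = motifs),
            class = "cross_model_result")
}

#' @export
print.cross_model_result <- function(x, ...) {
  cat("Cross-model comparison\n")
  cat("  shared:  ", paste(x$shared_lectins, collapse = ", "), "\n")
  cat("  opposite:", paste(x$opposite_lectins, collapse = ", "), "\n")
  if (nrow(x$motif_summary)) {
    cat("  motifs:  ",
        paste(sprintf("%s (%d)", x$motif_summary$token,
                      x$motif_summary$n_lectins), collapse = ", "), "\n")
  }
  invisible(x)
}

# monosaccharide tokens, longest first so GalNAc never double-counts as Gal
.motif_tokens <- c("GalNAc", "GlcNAc", "Gal", "Glc", "Man", "Fuc", "Sia")

#' Monosaccharide motif summary of lectin specificities
#'
#' Tokenizes free-text glycan specificity strings into monosaccharide
#' symbols (GalNAc, GlcNAc, Gal, Glc, Man, Fuc, Sia; longest-match, case
#' insensitive so "High-Mannose" counts as Man) and counts, per token, how
#' many lectins mention it at least once.
#'
#' @param specificities character vector of specificity strings (named by
#'   lectin or not) or a \code{lectin_panel}.
#' @return data.frame with columns \code{token}, \code{n_lectins}, sorted
#'   by descending count (ties in fixed token order).
#' @export
motif_summary <- function(specificities) {
  if (inherits(specificities, "lectin_panel")) {
    specificities <- specificities$specificity
  }
  if (!length(specificities)) stop("motif_summary needs >= 1 specificity string")
  hits <- sapply(.motif_tokens, function(tok) {
    vapply(specificities, function(s) {
      if (is.na(s) || !nzchar(s)) return(FALSE)
      # mask longer tokens before testing shorter ones
      longer <- .motif_tokens[nchar(.motif_tokens) > nchar(tok)]
      for (lt in longer) s <- gsub(lt, "\x01", s, ignore.case = TRUE)
      grepl(tok, s, ignore.case = TRUE)
    }, logical(1), USE.NAMES = FALSE)
  })
  hits <- matrix(hits, ncol = length(.motif_tokens),
                 dimnames = list(NULL, .motif_tokens))
  counts <- colSums(hits)
  counts <- counts[counts > 0]
  ord <- order(-counts, match(names(counts), .motif_tokens))
  data.frame(token = names(counts)[ord],
             n_lectins = as.integer(counts[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
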