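# NFI quantification. Per block: drop flagged spots, subtract background,
# floor negatives at 0, take the per-lectin replicate median, then divide
# by the sum of medians over the block's lectins (median-sum, or
# "compositional", normalization: the NFIs of a block sum to 1). Per
# group: mean and sample SD of the block NFIs, canonically 9 blocks from
# 3 slides.

#' Background subtraction
#'
#' @param fg_median foreground median(s), a.u.
#' @param bg_estimate background estimate(s), a.u.
#' @return \code{max(0, fg_median - bg_estimate)}, vectorized. Negative net
#'   intensities are floored at 0 because NFIs are fractions of signal.
#' @export
subtract_background <- function(fg_median, bg_estimate) {
  stopifnot(all(is.finite(fg_median)), all(is.finite(bg_estimate)))
  pmax(0, fg_median - bg_estimate)
}

#' Per-block NFI profile
#'
#' Computes, for one block, each lectin's background-subtracted replicate
#' median and its normalized fluorescence intensity (NFI): the median
#' divided by the sum of all lectins' medians in the block.
#'
#' @param records \code{spot_table} rows, all from one (slide, block).
#' @param panel a \code{\link{lectin_panel}}.
#' @param bg_mode \code{"per-spot"} (default; each spot's own local
#'   background estimate) or \code{"block-mean"} (the block-wide mean
#'   background applied to every spot). The two agree when background is
#'   spatially flat.
#' @return list of class \code{block_profile}: \code{slide_id},
#'   \code{block}, and a data.frame \code{lectins} with columns
#'   \code{lectin}, \code{n_spots}, \code{net_median}, \code{nfi},
#'   \code{missing}. Lectins with no surviving spot are marked missing
#'   (NFI \code{NA}) and excluded from the normalization sum.
#' @export
block_profile <- function(records, panel, bg_mode = c("per-spot", "block-mean")) {
  bg_mode <- match.arg(bg_mode)
  stopifnot(is.data.frame(records), nrow(records) > 0,
            inherits(panel, "lectin_panel"))
  if (length(unique(records$slide_id)) != 1 || length(unique(records$block)) != 1) {
    stop("block_profile expects records from a single (slide, block)")
  }
  ok <- records$flag >= 0
  if (!any(ok)) {
    stop("empty block: all spots flagged in slide ", records$slide_id[1],
         " block ", records$block[1])
  }
  good <- records[ok, , drop = FALSE]
  bg <- switch(bg_mode,
               "per-spot" = good$bg_median,
               "block-mean" = rep(mean(good$bg_median), nrow(good)))
  net <- subtract_background(good$fg_median, bg)
  med <- vapply(panel$name, function(l) {
    v <- net[good$lectin == l]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  nspots <- vapply(panel$name, function(l) sum(good$lectin == l), integer(1))
  missing <- is.na(med)
  if (any(missing)) {
    warning("lectin(s) with no unflagged spot in slide ", good$slide_id[1],
            " block ", good$block[1], ": ",
            paste(panel$name[missing], collapse = ", "))
  }
  denom <- sum(med[!missing])
  if (denom <= 0) {
    stop("degenerate block: all net medians zero in slide ", good$slide_id[1],
         " block ", good$block[1])
  }
  structure(list(
    slide_id = good$slide_id[1], block = good$block[1], bg_mode = bg_mode,
    lectins = data.frame(lectin = panel$name, n_spots = nspots,
                         net_median = med, nfi = med / denom,
                         missing = missing, row.names = NULL,
                         stringsAsFactors = FALSE)),
    class = "block_profile")
}

#' All block profiles of one or more spot tables
#'
#' @param records a \code{spot_table} (possibly covering several slides).
#' @param panel a \code{\link{lectin_panel}}.
#' @param bg_mode see \code{\link{block_profile}}.
#' @return list of \code{block_profile}, ordered by slide then block.
#' @export
block_profiles <- function(records, panel, bg_mode = c("per-spot", "block-mean")) {
  bg_mode <- match.arg(bg_mode)
  parts <- split(records, list(records$slide_id, records$block), drop = TRUE)
  parts <- parts[order(vapply(parts, function(p) p$slide_id[1], character(1)),
                       vapply(parts, function(p) p$block[1], integer(1)))]
  lapply(parts, block_profile, panel = panel, bg_mode = bg_mode)
}

#' Per-group aggregate NFI profile
#'
#' Averages block NFIs into a group profile: per lectin, the mean and
#' sample SD (n - 1 denominator) over the contributing blocks. Lectins
#' missing in some blocks are averaged over the blocks where they are
#' present, with the count recorded.
#'
#' @param blocks list of \code{\link{block_profile}} (>= 1; >= 2 for a
#'   nonzero SD; canonically 9).
#' @param group_id group label.
#' @return list of class \code{group_profile}: \code{group_id},
#'   \code{n_blocks}, a data.frame \code{lectins} (columns \code{lectin},
#'   \code{mean_nfi}, \code{sd_nfi}, \code{n_blocks}), and the retained
#'   lectins x blocks NFI matrix \code{nfi_matrix}.
#' @export
group_profile <- function(blocks, group_id) {
  if (!length(blocks)) stop("group_profile needs at least one block")
  stopifnot(all(vapply(blocks, inherits, logical(1), "block_profile")))
  lectins <- blocks[[1]]$lectins$lectin
  for (b in blocks) {
    if (!identical(b$lectins$lectin, lectins)) {
      stop("all blocks must share the same panel")
    }
  }
  m <- vapply(blocks, function(b) b$lectins$nfi, numeric(length(lectins)))
  m <- matrix(m, nrow = length(lectins),
              dimnames = list(lectins,
                              vapply(blocks, function(b)
                                sprintf("%s.b%d", b$slide_id, b$block),
                                character(1))))
  n_ok <- rowSums(!is.na(m))
  mean_nfi <- ifelse(n_ok > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  sd_nfi <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  structure(list(
    group_id = group_id, n_blocks = length(blocks),
    lectins = data.frame(lectin = lectins, mean_nfi = mean_nfi,
                         sd_nfi = sd_nfi, n_blocks = as.integer(n_ok),
                         row.names = NULL, stringsAsFactors = FALSE),
    nfi_matrix = m), class = "group_profile")
}

#' Quantify an experiment into group profiles
#'
#' Convenience wrapper: splits spot tables by manifest group, computes
#' block profiles and aggregates each group.
#'
#' @param spots named list of \code{spot_table} (names = slide ids) or a
#'   single combined \code{spot_table}.
#' @param manifest data.frame with columns \code{group_id}, \code{role},
#'   \code{slide} (slide ids matching \code{spots} names or the tables'
#'   \code{slide_id} column).
#' @param panel a \code{\link{lectin_panel}}.
#' @param bg_mode see \code{\link{block_profile}}.
#' @return named list of \code{\link{group_profile}}, with a \code{roles}
#'   attribute mapping group_id to role.
#' @export
quantify_groups <- function(spots, manifest, panel,
                            bg_mode = c("per-spot", "block-mean")) {
  bg_mode <- match.arg(bg_mode)
  if (is.data.frame(spots)) {
    spots <- split(spots, spots$slide_id)
  }
  profs <- lapply(split(manifest, manifest$group_id)[unique(manifest$group_id)],
                  function(mg) {
    blocks <- list()
    for (sl in mg$slide) {
      if (!sl %in% names(spots)) stop("manifest slide not found: ", sl)
      blocks <- c(blocks, block_profiles(spots[[sl]], panel, bg_mode))
    }
    group_profile(blocks, mg$group_id[1])
  })
  roles <- manifest$role[!duplicated(manifest$group_id)]
  names(roles) <- manifest$group_id[!duplicated(manifest$group_id)]
  attr(profs, "roles") <- roles
  profs
}
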