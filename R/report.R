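# Reporting: hierarchical clustering of lectins over group profiles, a
# green-black-red heat map with a numeric sidecar (the sidecar, not the
# image, is the testable artifact), and publication-style table export.

#' Pairwise lectin distances
#'
#' Default metric is 1 - Pearson correlation across groups; pairs
#' involving a constant column fall back to Euclidean distance (with a
#' warning) because their correlation is undefined.
#'
#' @param mat numeric matrix, groups (rows) x lectins (columns).
#' @param metric \code{"pearson"} or \code{"euclidean"}.
#' @return a \code{dist} object over columns.
#' @export
lectin_dist <- function(mat, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") return(stats::dist(t(mat)))
  const <- apply(mat, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  if (any(const)) {
    warning("constant column(s) under correlation metric; using Euclidean ",
            "distance for pairs involving: ",
            paste(colnames(mat)[const], collapse = ", "))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- if (const[i] || const[j]) {
        sqrt(sum((mat[, i] - mat[, j])^2))
      } else {
        1 - stats::cor(mat[, i], mat[, j])
      }
    }
  }
  stats::as.dist(d)
}

#' Agglomerative clustering of lectins
#'
#' Deterministic agglomerative (average-linkage/UPGMA by default)
#' clustering with an explicit tie-break: among minimum-distance cluster
#' pairs, the pair whose smallest original (panel-order) member indices
#' are lexicographically first is merged. Cluster distances are the
#' arithmetic mean of all original cross-pair distances.
#'
#' @param mat groups x lectins matrix (e.g. stacked \code{mean_nfi} rows),
#'   or a \code{dist} over lectins.
#' @param metric see \code{\link{lectin_dist}} (ignored when \code{mat} is
#'   a \code{dist}).
#' @param method \code{"average"}, \code{"single"} or \code{"complete"}.
#' @return list of class \code{clustering_result}: \code{labels} (input
#'   order), \code{order} (leaf order), \code{merge}, \code{height}
#'   (non-decreasing for these monotone linkages), \code{metric},
#'   \code{method}, and \code{hc}, an \code{stats::hclust}-compatible
#'   object usable with \code{cophenetic}, \code{cutree} and \code{plot}.
#' @export
cluster_lectins <- function(mat, metric = c("pearson", "euclidean"),
                            method = c("average", "single", "complete")) {
  metric <- match.arg(metric); method <- match.arg(method)
  if (inherits(mat, "dist")) {
    d0 <- as.matrix(mat)
    labels <- attr(mat, "Labels")
    if (is.null(labels)) labels <- as.character(seq_len(nrow(d0)))
  } else {
    stopifnot(is.matrix(mat) || is.data.frame(mat))
    mat <- as.matrix(mat)
    if (ncol(mat) < 2) stop("clustering needs >= 2 lectins")
    if (anyNA(mat)) {
      warning("missing cells imputed as column means")
      for (j in seq_len(ncol(mat))) {
        mat[is.na(mat[, j]), j] <- mean(mat[, j], na.rm = TRUE)
      }
    }
    d0 <- as.matrix(lectin_dist(mat, metric))
    labels <- colnames(mat)
    if (is.null(labels)) labels <- as.character(seq_len(ncol(mat)))
  }
  n <- nrow(d0)
  # active clusters as lists of original indices; merge ids as in hclust
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  linkfun <- switch(method, average = mean, single = min, complete = max)
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- linkfun(d0[members[[i]], members[[j]]])
        key <- c(dij, min(members[[i]], members[[j]]),
                 max(min(members[[i]]), min(members[[j]])))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(d = dij, i = i, j = j, key = key)
        }
      }
    }
    a <- ids[best$i]; b <- ids[best$j]
    merge[step, ] <- sort(c(a, b))
    height[step] <- best$d
    members[[best$i]] <- sort(c(members[[best$i]], members[[best$j]]))
    ids[best$i] <- step
    members[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  # leaf order by traversal, putting the subtree with the smaller minimum
  # original index on the left
  min_leaf <- function(id) if (id < 0) -id else min_cache[[id]]
  min_cache <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    min_cache[s] <- min(min_leaf(merge[s, 1]), min_leaf(merge[s, 2]))
  }
  leaves <- function(id) {
    if (id < 0) return(-id)
    ch <- merge[id, ]
    ch <- ch[order(c(min_leaf(ch[1]), min_leaf(ch[2])))]
    c(leaves(ch[1]), leaves(ch[2]))
  }
  ord <- if (n > 1) leaves(n - 1) else 1L
  hc <- structure(list(merge = merge, height = height, order = ord,
                       labels = labels, method = method,
                       call = match.call(), dist.method = metric),
                  class = "hclust")
  structure(list(labels = labels, order = ord, leaf_names = labels[ord],
                 merge = merge, height = height, metric = metric,
                 method = method, hc = hc),
            class = "clustering_result")
}

#' Column-standardized heat-map matrix
#'
#' Z-scores each column (lectin) across rows (samples/groups), the usual
#' "expression relative to the rest of the column" scaling. Constant
#' columns become all-zero (the colormap midpoint).
#'
#' @param mat groups x lectins numeric matrix.
#' @return matrix of class \code{heatmap_matrix}: every column has mean 0,
#'   and unit variance where the input column was non-constant.
#' @export
heatmap_matrix <- function(mat) {
  mat <- as.matrix(mat)
  z <- apply(mat, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  z <- matrix(z, nrow = nrow(mat), dimnames = dimnames(mat))
  class(z) <- c("heatmap_matrix", class(z))
  z
}

#' Render a clustered heat map
#'
#' Draws the standardized matrix with a green-black-red diverging
#' colormap (low-medium-high), columns ordered by the clustering leaves,
#' and always writes a tab-delimited sidecar of the plotted values so the
#' figure is numerically testable.
#'
#' @param mat groups x lectins matrix of mean NFIs (standardized
#'   internally via \code{\link{heatmap_matrix}}; a \code{heatmap_matrix}
#'   is used as-is).
#' @param clustering optional \code{\link{cluster_lectins}} result giving
#'   the column order.
#' @param path output image path (PNG).
#' @param sidecar path of the numeric sidecar TSV (default
#'   \code{paste0(path, ".tsv")}).
#' @return invisibly, list with \code{image} and \code{sidecar} paths.
#' @export
render_heatmap <- function(mat, clustering = NULL, path,
                           sidecar = paste0(path, ".tsv")) {
  z <- if (inherits(mat, "heatmap_matrix")) mat else heatmap_matrix(mat)
  if (!is.null(clustering)) {
    stopifnot(inherits(clustering, "clustering_result"))
    z <- z[, clustering$order, drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(data.frame(sample = rownames(z), z,
                                  check.names = FALSE),
                       sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write heatmap sidecar to ", sidecar)
  pal <- grDevices::colorRampPalette(c("green", "black", "red"))(255)
  lim <- max(abs(z), 1e-9)
  grDevices::png(path, width = 120 + 28 * ncol(z), height = 160 + 40 * nrow(z))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(7, 6, 2, 1))
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(z)), colnames(z), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(z)), rev(rownames(z)), las = 1, cex.axis = 0.9)
  invisible(list(image = path, sidecar = sidecar))
}

#' Export publication-style call tables
#'
#' Writes, per contrast, a TSV of the significantly changed lectins
#' (columns \code{Lectins}, \code{Specificity Glycans}, \code{Ratio}, the
#' ratio rendered with 2 decimals), and when a cross-model result is
#' given, a wide table of the opposite-pattern lectins with one ratio
#' column per contrast.
#'
#' @param calls \code{differential_calls} spanning all contrasts
#'   (nonempty).
#' @param cross optional \code{\link{compare_models}} result.
#' @param out_dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
export_tables <- function(calls, cross = NULL, out_dir = ".") {
  stopifnot(is.data.frame(calls), nrow(calls) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ct in unique(calls$contrast)) {
    sub <- calls[calls$contrast == ct & !is.na(calls$direction) &
                   calls$direction != "unchanged", , drop = FALSE]
    out <- data.frame(
      "Lectins" = sub$lectin,
      "Specificity Glycans" = sub$specificity,
      "Ratio" = sprintf("%.2f", sub$ratio),
      check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(out_dir, paste0("calls_", gsub("[^A-Za-z0-9._-]", "_", ct),
                                   ".tsv"))
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(cross)) {
    stopifnot(inherits(cross, "cross_model_result"))
    wide <- data.frame(Lectins = cross$opposite_lectins,
                       stringsAsFactors = FALSE)
    for (ct in unique(calls$contrast)) {
      sub <- calls[calls$contrast == ct, , drop = FALSE]
      r <- sub$ratio[match(cross$opposite_lectins, sub$lectin)]
      wide[[ct]] <- sprintf("%.2f", r)
    }
    f <- file.path(out_dir, "cross_model.tsv")
    utils::write.table(wide, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
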