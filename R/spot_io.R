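# Spot-table I/O: a minimal tab-delimited dialect of the GenePix Results
# (GPR) format. Required columns: Slide, Block, Row, Column, Name,
# "F532 Median", "B532 Median", Flags. Metadata/header lines that full GPR
# exports prepend (quoted key=value pairs, the ATF magic, etc.) are skipped.

.spot_cols <- c("Slide", "Block", "Row", "Column", "Name",
                "F532 Median", "B532 Median", "Flags")

#' Read a spot quantification table
#'
#' Parses a tab-delimited GenePix-Results-style table into a validated spot
#' data.frame. Lines before the header row that look like GPR preamble
#' (quoted strings, `key=value` pairs, the `ATF` magic) are skipped
#' tolerantly. Lectin names are validated against the panel; geometry and
#' intensity fields are range-checked; duplicate
#' (slide, block, row, column) spot keys are a hard error.
#'
#' @param path path to a UTF-8 TSV file (LF or CRLF).
#' @param panel a \code{\link{lectin_panel}} the \code{Name} column must
#'   match.
#' @return data.frame of class \code{spot_table} with columns
#'   \code{slide_id}, \code{block}, \code{row}, \code{column},
#'   \code{lectin}, \code{fg_median}, \code{bg_median}, \code{flag}.
#' @export
read_spot_table <- function(path, panel) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_preamble <- function(x) grepl("^\"", x) || grepl("^ATF", x) ||
    grepl("^[A-Za-z0-9_ ]+=", x) || !nzchar(x)
  start <- 1L
  while (start <= length(lines) && is_preamble(lines[start])) start <- start + 1L
  if (start > length(lines)) stop("no header row found in ", path)
  df <- utils::read.delim(text = paste(lines[start:length(lines)], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(.spot_cols, names(df))
  if (length(miss)) {
    stop("spot table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  spot_table(
    slide_id = as.character(df$Slide),
    block = as.integer(df$Block),
    row = as.integer(df$Row),
    column = as.integer(df$Column),
    lectin = as.character(df$Name),
    fg_median = as.numeric(df[["F532 Median"]]),
    bg_median = as.numeric(df[["B532 Median"]]),
    flag = as.integer(df$Flags),
    panel = panel
  )
}

#' Assemble and validate a spot table
#'
#' @param slide_id,block,row,column,lectin,fg_median,bg_median,flag
#'   parallel vectors, one element per spot. Indices are 1-based (GPR
#'   convention); \code{flag < 0} marks a bad spot.
#' @param panel optional \code{lectin_panel} for name/geometry validation.
#' @return data.frame of class \code{spot_table}.
#' @export
spot_table <- function(slide_id, block, row, column, lectin,
                       fg_median, bg_median, flag = 0L, panel = NULL) {
  n <- max(length(slide_id), length(lectin), length(fg_median))
  df <- data.frame(slide_id = as.character(slide_id),
                   block = as.integer(block),
                   row = as.integer(row),
                   column = as.integer(column),
                   lectin = as.character(lectin),
                   fg_median = as.numeric(fg_median),
                   bg_median = as.numeric(bg_median),
                   flag = as.integer(rep_len(flag, n)),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$fg_median)) || any(!is.finite(df$bg_median))) {
    stop("fg_median/bg_median must be finite")
  }
  if (any(df$fg_median < 0) || any(df$bg_median < 0)) {
    stop("fg_median/bg_median must be non-negative")
  }
  if (any(df$block < 1) || any(df$row < 1) || any(df$column < 1)) {
    stop("block/row/column indices are 1-based and must be >= 1")
  }
  key <- paste(df$slide_id, df$block, df$row, df$column, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("duplicate spot key(s), e.g. slide=", dup$slide_id[1],
         " block=", dup$block[1], " row=", dup$row[1],
         " column=", dup$column[1])
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$lectin), panel$name)
    if (length(unknown)) {
      stop("lectin(s) not in panel: ", paste(unknown, collapse = ", "))
    }
    bps <- attr(panel, "blocks_per_slide")
    if (any(df$block > bps)) {
      stop("block index exceeds blocks_per_slide (", bps, ")")
    }
  }
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write a spot table
#'
#' Writes the tab-delimited dialect read by \code{\link{read_spot_table}};
#' the round trip \code{read(write(x))} is lossless on all fields.
#'
#' @param records a \code{spot_table} (nonempty).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spot_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("cannot write an empty spot table")
  out <- data.frame(records$slide_id, records$block, records$row,
                    records$column, records$lectin, records$fg_median,
                    records$bg_median, records$flag,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- .spot_cols
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write spot table to ", path)
  invisible(path)
}

#' Read a group/slide manifest
#'
#' A manifest maps experimental groups to their slide spot-table files and
#' roles. Two formats are accepted: JSON
#' (\code{{"groups": [{"group_id": ..., "role": "model"|"control",
#' "slides": [...]}]}}) or TSV with columns \code{Group}, \code{Role},
#' \code{Slide}.
#'
#' @param path manifest file.
#' @return data.frame with columns \code{group_id}, \code{role},
#'   \code{slide}, one row per slide.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (is.null(m$groups)) stop("manifest JSON must contain a 'groups' array")
    df <- do.call(rbind, lapply(m$groups, function(g) {
      if (is.null(g$group_id) || is.null(g$role) || !length(g$slides)) {
        stop("each manifest group needs group_id, role and >= 1 slide")
      }
      data.frame(group_id = g$group_id, role = g$role,
                 slide = unlist(g$slides), stringsAsFactors = FALSE)
    }))
  } else {
    t <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(c("Group", "Role", "Slide"), names(t))
    if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
    df <- data.frame(group_id = t$Group, role = t$Role, slide = t$Slide,
                     stringsAsFactors = FALSE)
  }
  if (!all(df$role %in% c("model", "control"))) {
    stop("manifest roles must be 'model' or 'control'")
  }
  df
}
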