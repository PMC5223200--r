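# Bundled reference ratio tables from a published two-model rat brain
# glycopattern study: mean-NFI fold changes of the significantly altered
# lectins in a sporadic Alzheimer's disease model (SAD vs its untreated
# control SAD-C) and a cerebral ischemia model (MCAO at 16 h and 48 h of
# occlusion, M16 and M48, vs untreated control MC). The raw fluorescence
# data behind these ratios were never deposited, so these printed ratios
# are the recoverable ground truth for validating the fold-change
# classifier and the cross-model comparison.

#' Reference differential ratio table, SAD model
#'
#' Published mean-NFI ratios (SAD / SAD-C) of the lectins reported as
#' significantly changed in the sporadic Alzheimer's disease rat model.
#'
#' @return data.frame with columns \code{lectin}, \code{specificity},
#'   \code{ratio}.
#' @export
sad_ratio_table <- function() {
  f <- system.file("extdata", "sad_ratios.tsv", package = "glycolect",
                   mustWork = TRUE)
  df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  data.frame(lectin = df$Lectin, specificity = df$Specificity,
             ratio = df$Ratio, stringsAsFactors = FALSE)
}

#' Reference differential ratio table, MCAO model
#'
#' Published mean-NFI ratios (M16 / MC and M48 / MC) of the lectins
#' reported as significantly changed in the middle-cerebral-artery
#' occlusion rat model at 16 h and 48 h.
#'
#' @return data.frame with columns \code{lectin}, \code{specificity},
#'   \code{ratio_m16}, \code{ratio_m48}.
#' @export
mcao_ratio_table <- function() {
  f <- system.file("extdata", "mcao_ratios.tsv", package = "glycolect",
                   mustWork = TRUE)
  df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  data.frame(lectin = df$Lectin, specificity = df$Specificity,
             ratio_m16 = df$Ratio_M16_MC, ratio_m48 = df$Ratio_M48_MC,
             stringsAsFactors = FALSE)
}

#' Differential calls from the bundled reference tables
#'
#' Runs the fold-change classifier (no p-gate; the reference tables carry
#' no replicate-level data) over the bundled SAD and MCAO ratio tables.
#'
#' @param up,down thresholds, see \code{\link{direction_from_ratio}}.
#' @return list with \code{sad} (one contrast) and \code{mcao} (two
#'   timepoint contrasts, stacked) \code{differential_calls}.
#' @export
reference_calls <- function(up = 1.5, down = 0.67) {
  sad <- sad_ratio_table()
  mcao <- mcao_ratio_table()
  list(
    sad = calls_from_ratios(sad, "SAD/SAD-C", up, down),
    mcao = rbind(
      calls_from_ratios(data.frame(lectin = mcao$lectin,
                                   specificity = mcao$specificity,
                                   ratio = mcao$ratio_m16,
                                   stringsAsFactors = FALSE),
                        "M16/MC", up, down),
      calls_from_ratios(data.frame(lectin = mcao$lectin,
                                   specificity = mcao$specificity,
                                   ratio = mcao$ratio_m48,
                                   stringsAsFactors = FALSE),
                        "M48/MC", up, down))
  )
}
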