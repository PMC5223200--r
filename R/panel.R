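#' Construct a lectin panel
#'
#' A panel is the ordered set of lectins printed on a slide, together with
#' the slide layout: how many replicate spots each lectin gets per block and
#' how many blocks each slide carries. The default layout (3 spots per
#' lectin per block, 3 blocks per slide) is the common design for
#' glycopattern profiling arrays.
#'
#' @param lectins data.frame with columns \code{name} and \code{specificity}
#'   (free-text glycan specificity), optionally \code{source}.
#' @param spots_per_lectin replicate spots per lectin within one block.
#' @param blocks_per_slide number of blocks (sub-grids) per slide.
#' @return An object of class \code{lectin_panel}: a data.frame with columns
#'   \code{name}, \code{specificity}, \code{source} and layout attributes.
#' @export
lectin_panel <- function(lectins, spots_per_lectin = 3L, blocks_per_slide = 3L) {
  stopifnot(is.data.frame(lectins), nrow(lectins) > 0,
            all(c("name", "specificity") %in% names(lectins)))
  name <- as.character(lectins$name)
  if (any(!nzchar(name))) stop("lectin names must be nonempty")
  if (anyDuplicated(name)) {
    stop("duplicate lectin names in panel: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  out <- data.frame(
    name = name,
    specificity = as.character(lectins$specificity),
    source = if ("source" %in% names(lectins)) as.character(lectins$source) else "",
    stringsAsFactors = FALSE
  )
  stopifnot(spots_per_lectin >= 1, blocks_per_slide >= 1)
  attr(out, "spots_per_lectin") <- as.integer(spots_per_lectin)
  attr(out, "blocks_per_slide") <- as.integer(blocks_per_slide)
  class(out) <- c("lectin_panel", "data.frame")
  out
}

#' @export
print.lectin_panel <- function(x, ...) {
  cat(sprintf("Lectin panel: %d lectins, %d spots/lectin/block, %d blocks/slide\n",
              nrow(x), attr(x, "spots_per_lectin"), attr(x, "blocks_per_slide")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more lectins\n", nrow(x) - 10))
  invisible(x)
}

# Panel entries whose specificity strings come from the study's published
# differential tables. "study" entries are authoritative; "registry" entries
# (including WGA, which the study names without printing a specificity) carry
# commonly documented specificities and are placeholders for the unpublished
# remainder of the 37-lectin layout.
.study_lectins <- function() {
  data.frame(stringsAsFactors = FALSE, name = c(
    "PSA", "WFA", "PTL-I", "AAL", "PTL-II", "SBA", "UEA-I", "PHA-E + L",
    "SNA", "ECA", "LCA", "VVA", "GNA", "DBA", "NPA", "SJA", "GLS-I", "STL",
    "ConA", "BPL", "PHA-E", "LEL"
  ), specificity = c(
    "Fucα-1,6GlcNAc, α-D-Man, α-D-Glc",
    "terminating in GalNAcα/β1-3/6 Gal",
    "GalNAc, GalNAcα-1,3 Gal, GalNAcα-1,3Galβ-1,3/4Glc",
    "Fucα1-6 GlcNAc(core fucose), Fucα1-3(Galβ1-4)GlcNAc",
    "Gal, blood group H, T-antigen",
    "α- or β-linked terminal GalNAc, (GalNAc)n, GalNAcα1-3 Gal",
    "Fucα1-2Galβ1-4Glc(NAc)",
    "Bisecting GlcNAc, bi-antennary N-glycans, tri- and tetra-antennary complex-type N-glycan",
    "Sia2-6Gal/GalNAc",
    "Galβ-1,4GlcNAc (type II), Galβ1-3GlcNAc (type I)",
    "α-D-Man, Fucα-1,6GlcNAc, α-D-Glc",
    "terminal GalNAc, GalNAcα-Ser/Thr(Tn), GalNAcα1-3 Gal",
    "High-Mannose, Manα1-3Man",
    "αGalNAc, Tn antigen, GalNAcα1-3((Fucα1-2))Gal (blood group A antigen)",
    "High-Mannose, Manα1-6Man",
    "Terminal in GalNAc and Gal",
    "αGalNAc, αGal, anti-A and B",
    "trimers and tetramers of GlcNAc, core (GlcNAc) of N-glycan, oligosaccharide containing GlcNAc and MurNAc",
    "High-Mannose, Manα1-6(Manα1-3)Man, αMannose, αGlc",
    "Galβ1-3GalNAc, Terminal GalNAc",
    "Bisecting GlcNAc, biantennary complex-type N-glycan with outer Gal",
    "(GlcNAc)n, high mannose-type N-glycans"
  ), source = "study")
}

.registry_lectins <- function() {
  data.frame(stringsAsFactors = FALSE, name = c(
    "WGA", "PNA", "RCA120", "Jacalin", "MAL-I", "MAL-II", "LTL", "GSL-II",
    "DSA", "EEL", "ACA", "MPL", "HHL", "SSA", "TJA-I"
  ), specificity = c(
    "(GlcNAc)n, GlcNAcβ1-4GlcNAc, multivalent Sia",
    "Galβ1-3GalNAcα-Ser/Thr (T-antigen)",
    "Galβ1-4GlcNAc (type II)",
    "Galβ1-3GalNAcα-Ser/Thr(T), GalNAcα-Ser/Thr(Tn)",
    "Galβ1-4GlcNAc, Sia2-3Gal",
    "Sia2-3Galβ1-3GalNAc",
    "Fucα1-3(Galβ1-4)GlcNAc, Fucα1-2Gal",
    "terminal GlcNAc, agalactosylated tri/tetra-antennary N-glycans",
    "Galβ1-4GlcNAc, (GlcNAc)n",
    "Galα1-3(Fucα1-2)Gal (blood group B)",
    "Galβ1-3GalNAcα-Ser/Thr (T-antigen), sialyl-T",
    "Galβ1-3GalNAcα-Ser/Thr(T), GalNAcα-Ser/Thr(Tn)",
    "High-Mannose, Manα1-3Man, Manα1-6Man",
    "Sia2-6Gal/GalNAc",
    "Sia2-6Galβ1-4GlcNAc, Fucα1-2Gal"
  ), source = "registry")
}

#' Default 37-lectin panel
#'
#' The built-in panel carries the 22 lectins whose glycan specificities are
#' printed in the study's differential tables plus WGA (named in the study
#' without a printed specificity), and fills the remaining 14 positions with
#' commonly used lectins from a documented registry. The registry entries
#' are placeholders for an unpublished array layout and are marked
#' \code{source == "registry"}; replace them via \code{\link{read_panel}}
#' when the true layout is known. Deterministic and order-stable.
#'
#' @return A \code{\link{lectin_panel}} of 37 lectins, 3 spots per lectin
#'   per block, 3 blocks per slide.
#' @export
#' @examples
#' p <- default_panel()
#' nrow(p)                      # 37
#' p$specificity[p$name == "SNA"]
default_panel <- function() {
  lectin_panel(rbind(.study_lectins(), .registry_lectins()),
               spots_per_lectin = 3L, blocks_per_slide = 3L)
}

#' Read a panel from a TSV file
#'
#' Expects a tab-delimited file with columns \code{Name} and
#' \code{Specificity} (optional \code{Source}).
#'
#' @param path file path.
#' @param spots_per_lectin,blocks_per_slide layout, as in
#'   \code{\link{lectin_panel}}.
#' @return A \code{lectin_panel}.
#' @export
read_panel <- function(path, spots_per_lectin = 3L, blocks_per_slide = 3L) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("Name", "Specificity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  lectin_panel(
    data.frame(name = df$Name, specificity = df$Specificity,
               source = if ("Source" %in% names(df)) df$Source else "user",
               stringsAsFactors = FALSE),
    spots_per_lectin, blocks_per_slide
  )
}
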