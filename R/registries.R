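#' Tract registry
#'
#' The roster of white-matter bundles shared by the two tractography pipelines.
#' The default registry ships with the package and holds the 49 bundles common
#' to a whole-brain-tractogram atlas segmentation and TractSeg bundle-specific
#' tractography: the anterior commissure, the seven corpus callosum
#' subdivisions, the middle cerebellar peduncle, and 20 bilateral association,
#' projection and cerebellar pathways.
#'
#' @param path Optional path to a custom registry: a tab-separated file with
#'   columns `abbreviation` and `full_name`. Defaults to the registry shipped
#'   in `inst/extdata`.
#' @return A tibble with columns `abbreviation` and `full_name`, one row per
#'   tract, abbreviations unique.
#' @examples
#' nrow(tract_registry())  # 49
#' @export
tract_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tract_registry.tsv",
                                package = "tractconcord", mustWork = TRUE)
  reg <- readr::read_tsv(path, col_types = readr::cols(
    abbreviation = readr::col_character(),
    full_name = readr::col_character()
  ))
  if (anyDuplicated(reg$abbreviation)) {
    abort("tract registry abbreviations must be unique")
  }
  reg
}

#' Feature registry
#'
#' The scalar features extracted per subject and tract, each labelled as
#' microstructural or volumetric. The default registry holds the nine features
#' common to both pipelines: four DTI-derived maps (AD, FA, MD, RD), three
#' NODDI-derived maps (NDI, ODI, ISOWF), and two volumetric measures (tract
#' volume and volume normalized by total brain volume).
#'
#' @param path Optional path to a custom registry: a tab-separated file with
#'   columns `feature` and `feature_class`
#'   (`"microstructural"` or `"volumetric"`).
#' @return A tibble with columns `feature` and `feature_class`.
#' @examples
#' table(feature_registry()$feature_class)  # 7 microstructural, 2 volumetric
#' @export
feature_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_registry.tsv",
                                package = "tractconcord", mustWork = TRUE)
  reg <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(),
    feature_class = readr::col_character()
  ))
  if (anyDuplicated(reg$feature)) {
    abort("feature registry names must be unique")
  }
  bad <- setdiff(unique(reg$feature_class), c("microstructural", "volumetric"))
  if (length(bad)) {
    abort(paste0("unknown feature_class: ", paste(bad, collapse = ", ")))
  }
  reg
}
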