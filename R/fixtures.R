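# Packaged reference tables for the 23-marker pak-choi core panel.

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "ssrfp")
  if (p == "") p <- file.path("inst", "extdata", f)  # pre-install use
  p
}

#' The 23-marker core panel
#'
#' Chromosome positions, primer sequences and allelic size ranges of the
#' 23 core SSR markers selected for non-heading Chinese cabbage variety
#' identification (10 chromosomes, fragment sizes 99-355 bp).
#'
#' @return A `marker_panel` with 23 rows.
#' @export
ssr_core_panel <- function() read_marker_panel(.extdata("ssr_core_panel.csv"))

#' Published per-locus diversity reference table
#'
#' The published per-locus genetic parameters of the 23 core markers on
#' the 423-variety collection: MAF (major allele frequency), Na, Ho, He,
#' PIC and Fst. Used for fixture arithmetic and as a realism yardstick for
#' the simulator; the underlying genotypes are not public.
#'
#' @return A data.frame with columns Marker, MAF, Na, Ho, He, PIC, Fst.
#' @export
ssr_reference_diversity <- function() {
  read.csv(.extdata("ssr_diversity_reference.csv"), stringsAsFactors = FALSE)
}

#' Published multiplex grouping of the core panel
#'
#' The five-group, four-dye multiplex assignment of the 23 core primers
#' (group x dye grid with the fragment-size window observed per marker).
#' Demonstrates feasibility of a 5-group panel under a 4-dye instrument.
#'
#' @return A data.frame with columns group, dye, marker, size_min, size_max.
#' @export
ssr_panel_groups <- function() {
  read.csv(.extdata("ssr_panel_groups.csv"), stringsAsFactors = FALSE)
}

#' Morphological characteristic schema
#'
#' The 30 coded morphological characteristics used in non-heading Chinese
#' cabbage DUS testing: 4 qualitative (QL), 11 pseudo-qualitative (PQ) and
#' 15 quantitative (QN) characteristics, each with its coded expression
#' states, plus the published Shannon-Wiener index per characteristic.
#'
#' @return A data.frame with columns no, characteristic, type, states
#'   (semicolon-separated `label:code` pairs) and H_reference.
#' @export
morpho_schema <- function() {
  df <- read.csv(.extdata("morpho_characteristics.csv"),
                 stringsAsFactors = FALSE)
  df$codes <- lapply(strsplit(df$states, ";", fixed = TRUE), function(ss) {
    as.integer(sub("^.*:", "", ss))
  })
  df
}
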