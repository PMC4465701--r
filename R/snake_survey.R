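#' Published survey summary of 12 Neotropical snake communities
#'
#' Per-community summary values transcribed from a compiled survey of
#' Brazilian snake communities: six forest sites (Amazon and Atlantic
#' forest) and six non-forest sites (Cerrado savanna and Campos grassland),
#' with site coordinates (southern latitude, degree-minute strings), local
#' species richness, and the published net relatedness (NRI) and nearest
#' taxon (NTI) indices computed against 500-km regional pools with 9,999
#' tip-label randomizations. These printed indices are the inputs for the
#' habitat/latitude regression and variation-partitioning stages; the
#' underlying composition matrix, trait measurements and pool phylogenies
#' are not redistributed here.
#'
#' @return Data frame with columns `site`, `vegetation`, `habitat`,
#'   `latitude` (absolute decimal degrees south), `richness`, `NRI`, `NTI`,
#'   and the 0/1 dummy `habitat_forest`.
#' @examples
#' sv <- snake_survey()
#' ols_fit(sv$NRI, sv[, c("habitat_forest", "latitude")])
#' @export
snake_survey <- function() {
  path <- system.file("extdata", "snake_communities.csv", package = "commphy",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df$latitude <- parse_latitude(df$latitude)
  df$habitat_forest <- as.numeric(df$habitat == "forest")
  df
}
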