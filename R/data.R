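#' Packaged default-mode-network node set
#'
#' Nine regions of interest with their Talairach center-of-mass
#' coordinates, as used by the packaged connectivity models.
#'
#' @return Data frame with columns `name`, `label`, `x`, `y`, `z`.
#' @export
dmn_nodes <- function() {
  j <- jsonlite::fromJSON(system.file("extdata", "dmn_nodes.json",
                                      package = "usemnet"))
  j$nodes
}

#' Packaged 13-edge exploratory connectivity model with decade coefficients
#'
#' The directed edge list of the exploratory default-mode-network model
#' together with the lagged-to-lagged path coefficient of each edge in each
#' of six decade cohorts (20s through 70s) and the published Pearson
#' correlation of each coefficient vector with decade.
#'
#' @return List with `nodes` (as [dmn_nodes()]), `edges` (data frame with
#'   `source`, `target`, `published_r`), `coefficients` (13 x 6 matrix,
#'   rows aligned with `edges`) and `cohorts` (decade labels).
#' @export
dmn_reference_model <- function() {
  j <- jsonlite::fromJSON(system.file("extdata", "dmn_exploratory_model.json",
                                      package = "usemnet"))
  co <- do.call(rbind, j$edges$coefficients)
  colnames(co) <- j$cohorts
  rownames(co) <- paste(j$edges$source, "->", j$edges$target)
  list(nodes = dmn_nodes(),
       edges = data.frame(source = j$edges$source,
                          target = j$edges$target,
                          published_r = j$edges$published_r,
                          stringsAsFactors = FALSE),
       coefficients = co,
       cohorts = j$cohorts)
}
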