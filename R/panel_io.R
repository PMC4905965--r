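#' Write a time-series panel as TSV files plus a JSON manifest
#'
#' The interchange format of the pipeline: one tab-separated file per
#' subject (rows = time points, columns = named ROIs) and a
#' `manifest.json` recording subject id, cohort, sex, file name, the
#' censoring mask (if any point is censored) and the generating seed when
#' known.  The same reader accepts user-supplied ROI-extracted data laid
#' out this way.
#'
#' @param panel a `usem_panel`.
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the manifest.
#' @param note optional free-text note recorded in the manifest (for
#'   example, the innovation-variance convention of a simulation).
#' @return The manifest path, invisibly.
#' @export
write_panel <- function(panel, dir, seed = NULL, note = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(panel$subjects))
  for (i in seq_along(panel$subjects)) {
    files[i] <- paste0(panel$meta$id[i], ".tsv")
    utils::write.table(panel$subjects[[i]],
                       file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    node_names = panel$node_names,
    subjects = lapply(seq_along(files), function(i) {
      entry <- list(id = panel$meta$id[i],
                    cohort = panel$meta$cohort[i],
                    sex = panel$meta$sex[i],
                    file = files[i])
      if (!all(panel$mask[[i]]))
        entry$censored <- which(!panel$mask[[i]])
      entry
    }))
  if (!is.null(seed)) manifest$seed <- seed
  if (!is.null(note)) manifest$note <- note
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a time-series panel from a manifest
#'
#' @param manifest path to a `manifest.json` written by [write_panel()].
#' @return A `usem_panel`.
#' @export
read_panel <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  j <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  node_names <- unlist(j$node_names)
  subjects <- vector("list", length(j$subjects))
  mask <- vector("list", length(j$subjects))
  meta <- data.frame(id = character(0), cohort = integer(0),
                     sex = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(j$subjects)) {
    e <- j$subjects[[i]]
    y <- as.matrix(utils::read.table(file.path(dir, e$file),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
    if (!identical(colnames(y), node_names))
      stop("subject ", e$id, ": ROI columns do not match manifest node_names")
    subjects[[i]] <- y
    m <- rep(TRUE, nrow(y))
    if (!is.null(e$censored)) m[unlist(e$censored)] <- FALSE
    mask[[i]] <- m
    meta <- rbind(meta, data.frame(id = e$id, cohort = e$cohort,
                                   sex = e$sex, stringsAsFactors = FALSE))
  }
  new_panel(subjects, meta, node_names, mask)
}
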