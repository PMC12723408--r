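#' Write and read ground-truth edge lists as JSON
#'
#' Lossless plain-text round trip for the planted-coupling ground truth (and
#' any edge-list data frame with numeric/character columns).
#'
#' @param gt Data frame, e.g. `study$ground_truth`.
#' @param path Output file path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns the data frame.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, digits = NA, auto_unbox = FALSE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a parcel book as plain text
#'
#' The parcel table (id, coarse parcel, system, visual subdivision, fidelity,
#' position) goes to `<stem>_parcels.tsv`, the mixing matrix to
#' `<stem>_mixing.tsv`.
#'
#' @param book A `parcel_book`.
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_parcel_book <- function(book, stem) {
  tab <- data.frame(parcel_id = book$parcel_ids, coarse = book$coarse_map,
                    system = as.character(book$system),
                    visual_subdivision = as.character(book$visual_subdivision),
                    fidelity = book$fidelity, position = book$position)
  f1 <- paste0(stem, "_parcels.tsv")
  f2 <- paste0(stem, "_mixing.tsv")
  utils::write.table(tab, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format(book$mixing, digits = 17), f2, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}

#' Write a hyperedge set as JSON
#'
#' @param hs A `hyperedge_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hyperedges <- function(hs, path) {
  jsonlite::write_json(list(edges = hs$edges, bundles = hs$bundles,
                            cutoff = hs$cutoff, min_size = hs$min_size),
                       path, digits = NA, dataframe = "columns")
  invisible(path)
}
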