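#' Read a GFF3 file
#'
#' Thin wrapper around \code{rtracklayer::import} returning a \code{GRanges}
#' (1-based inclusive coordinates, the native GFF3 and Bioconductor
#' convention).  \code{ID}/\code{Parent} attributes are preserved; features
#' whose \code{Parent} points at an absent \code{ID} are kept and reported
#' with a warning.
#'
#' @param path path to a GFF3 file.
#' @return a \code{GRanges} with at least \code{type}, \code{ID} and
#'   \code{Parent} metadata columns.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  m <- mcols(gr)
  if (!is.null(m$Parent) && length(gr)) {
    parents <- unique(unlist(m$Parent))
    ids <- unique(m$ID[!is.na(m$ID)])
    orphans <- setdiff(parents, ids)
    if (length(orphans))
      warning("Parent attribute(s) with no matching ID kept as orphans: ",
              paste(orphans, collapse = ", "))
  }
  gr
}

#' Write features to a GFF3 file
#'
#' @param gr a \code{GRanges}; metadata columns become GFF3 attributes.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Child features of a GFF3 feature set
#'
#' Resolves ID/Parent links: returns the rows of \code{gr} whose
#' \code{Parent} contains \code{id}.
#'
#' @param gr a \code{GRanges} read by \code{\link{readGff3}}.
#' @param id a feature ID.
#' @export
gffChildren <- function(gr, id) {
  if (is.null(mcols(gr)$Parent)) return(gr[FALSE])
  hit <- vapply(mcols(gr)$Parent, function(p) id %in% p, logical(1))
  gr[hit]
}
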