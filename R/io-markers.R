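.MARKER_TSV_COLS <- c("marker_id", "primer_type", "junction_pos", "te_type",
                      "te_source", "strand", "primer_role", "primer_seq",
                      "primer_start", "primer_end", "tm_c", "gc_pct",
                      "unique_flag", "product_size")

#' Flatten a MarkerSet to the marker-table schema
#'
#' One row per primer; marker-level fields (type, junction position(s),
#' TE type/source, uniqueness flag, primary product size) are repeated on
#' each of its primer rows.  \code{junction_pos} joins multiple junctions
#' with a comma.
#'
#' @param markers a \code{\link{MarkerSet}}.
#' @return a \code{data.frame} with the fixed column set
#'   \code{marker_id, primer_type, junction_pos, te_type, te_source, strand,
#'   primer_role, primer_seq, primer_start, primer_end, tm_c, gc_pct,
#'   unique_flag, product_size}.
#' @export
flattenMarkers <- function(markers) {
  if (nrow(markerTable(markers)) == 0L) {
    out <- data.frame(matrix(character(0), nrow = 0,
                             ncol = length(.MARKER_TSV_COLS)))
    colnames(out) <- .MARKER_TSV_COLS
    return(out)
  }
  mk <- as.data.frame(markerTable(markers)[, c("marker_id", "type", "te_type",
                                               "te_source", "unique_flag")])
  if (nrow(mk)) {
    mk$junction_pos <- vapply(markerTable(markers)$junctions,
                              function(j) paste(j, collapse = ","), character(1))
    prod <- productTable(markers)
    first_size <- vapply(mk$marker_id, function(id) {
      s <- prod$size[prod$marker_id == id]
      if (length(s)) as.integer(s[[1]]) else NA_integer_
    }, integer(1))
    mk$product_size <- first_size
  } else {
    mk$junction_pos <- character(0)
    mk$product_size <- integer(0)
  }
  pr <- as.data.frame(primerTable(markers))
  if (!nrow(pr)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(.MARKER_TSV_COLS)),
                                  .MARKER_TSV_COLS))
    return(out)
  }
  i <- match(pr$marker_id, mk$marker_id)
  data.frame(marker_id = pr$marker_id,
             primer_type = mk$type[i],
             junction_pos = mk$junction_pos[i],
             te_type = mk$te_type[i],
             te_source = mk$te_source[i],
             strand = pr$strand,
             primer_role = pr$role,
             primer_seq = pr$seq,
             primer_start = pr$start,
             primer_end = pr$end,
             tm_c = round(pr$tm_c, 2),
             gc_pct = round(pr$gc_pct, 2),
             unique_flag = mk$unique_flag[i],
             product_size = mk$product_size[i],
             stringsAsFactors = FALSE)
}

#' Write a marker table as TSV
#'
#' One row per primer (so a two-primer RJM contributes 2 rows and a
#' three-primer RBIP contributes 3).  An empty marker set yields a
#' header-only file.
#'
#' @param markers a \code{\link{MarkerSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerTable <- function(markers, path) {
  write.table(flattenMarkers(markers), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a marker table written by writeMarkerTable
#'
#' Reconstructs a \code{\link{MarkerSet}} from the flat TSV.  Information not
#' present in the schema (product coordinates beyond the primary size,
#' per-product configurations) is not recoverable; the round trip is exact
#' on the flattened representation.
#'
#' @param path path to a marker TSV.
#' @return a \code{\link{MarkerSet}}.
#' @export
readMarkerTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(marker_id = "character",
                                  junction_pos = "character",
                                  primer_seq = "character"))
  if (!identical(colnames(df), .MARKER_TSV_COLS))
    stop("unexpected marker-table columns in ", path)
  if (!nrow(df)) return(MarkerSet())
  first <- !duplicated(df$marker_id)
  mk <- DataFrame(marker_id = df$marker_id[first],
                  type = df$primer_type[first],
                  te_type = df$te_type[first],
                  te_source = df$te_source[first],
                  unique_flag = as.logical(df$unique_flag[first]))
  mk$junctions <- IRanges::IntegerList(lapply(
    strsplit(df$junction_pos[first], ",", fixed = TRUE), as.integer))
  pr <- DataFrame(marker_id = df$marker_id, role = df$primer_role,
                  seq = df$primer_seq, chrom = NA_character_,
                  start = df$primer_start, end = df$primer_end,
                  strand = df$strand, tm_c = df$tm_c, gc_pct = df$gc_pct)
  prod <- DataFrame(marker_id = mk$marker_id, configuration = "primary",
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, size = df$product_size[first])
  MarkerSet(markers = mk, primers = pr, products = prod)
}
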