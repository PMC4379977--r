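# lexicographically minimal rotation of a repeat motif
.minRotation <- function(motif) {
  n <- nchar(motif)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1, i - 1)), character(1))
  sort(rots)[[1]]
}

# smallest period of a string (e.g. "ATAT" -> 2)
.minPeriod <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
        motif == strrep(substr(motif, 1, p), n / p)) return(p)
  }
  n
}

#' Find perfect microsatellites (SSRs)
#'
#' Maximal perfect tandem repeats with motif length 1-6 bp.  A locus is
#' reported when its total length is at least \code{min_total_len} and its
#' copy number reaches the per-motif-length minimum.  Overlapping
#' candidates are resolved longest-first, ties to the smaller motif.
#'
#' @param seq a DNA sequence (character) or \code{DNAString}.
#' @param min_total_len minimum tract length (bp).
#' @param min_copies named minimum copy numbers per motif length (names
#'   "1".."6").
#' @return a data.frame with \code{start}, \code{end}, \code{motif}
#'   (lexicographically minimal rotation), \code{motif_len}, \code{copies}.
#' @export
findSsrs <- function(seq, min_total_len = 12,
                     min_copies = c(`1` = 10, `2` = 6, `3` = 5, `4` = 5,
                                    `5` = 5, `6` = 4)) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  cand <- list()
  for (m in 1:6) {
    if (n < 2 * m) next
    eq <- b[seq_len(n - m)] == b[seq_len(n - m) + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      tract_start <- starts[h]
      tract_len <- r$lengths[h] + m
      copies <- tract_len / m
      if (tract_len < min_total_len) next
      if (copies < min_copies[[as.character(m)]]) next
      motif <- substr(s, tract_start, tract_start + m - 1L)
      if (.minPeriod(motif) != m) next  # covered at the true period
      cand[[length(cand) + 1L]] <- data.frame(
        start = tract_start, end = tract_start + tract_len - 1L,
        motif = .minRotation(motif), motif_len = m, copies = copies)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_len = integer(),
                      copies = numeric()))
  df <- do.call(rbind, cand)
  df <- df[order(-(df$end - df$start + 1L), df$motif_len, df$start), ,
           drop = FALSE]
  keep <- logical(nrow(df))
  taken <- IRanges()
  for (i in seq_len(nrow(df))) {
    r <- IRanges(df$start[i], df$end[i])
    if (!length(findOverlaps(r, taken))) { keep[i] <- TRUE; taken <- c(taken, r) }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
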