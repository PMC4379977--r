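## In-silico PCR: primer binding-site search plus convergent-pair
## enumeration.  Supports the marker closure property and the genome-wide
## uniqueness screen.

# binding sites of one primer on one chromosome; the 3'-terminal base must
# match exactly even when internal mismatches are allowed
.primerSites <- function(primer, chrom_seq, max_mismatch) {
  subject <- Biostrings::DNAString(chrom_seq)
  out <- list()
  fwd <- Biostrings::matchPattern(primer, subject,
                                  max.mismatch = max_mismatch)
  if (length(fwd)) {
    en <- Biostrings::end(fwd)
    last <- substring(chrom_seq, en, en)
    keep <- last == substr(primer, nchar(primer), nchar(primer))
    if (any(keep))
      out$plus <- data.frame(start = Biostrings::start(fwd)[keep],
                             end = en[keep], strand = "+")
  }
  rcp <- revComp(primer)
  rev <- Biostrings::matchPattern(rcp, subject, max.mismatch = max_mismatch)
  if (length(rev)) {
    st <- Biostrings::start(rev)
    first <- substring(chrom_seq, st, st)
    keep <- first == substr(rcp, 1, 1)  # primer 3' end on the minus strand
    if (any(keep))
      out$minus <- data.frame(start = st[keep],
                              end = Biostrings::end(rev)[keep], strand = "-")
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' In-silico PCR
#'
#' Finds all binding sites of the given primers (up to \code{max_mismatch}
#' internal mismatches; the 3'-terminal base must always match) and reports
#' every convergent pair within \code{max_product}.
#'
#' @param primers character vector of primer sequences (5' to 3').
#' @param genome sequences (see \code{\link{findLtrPairs}}).
#' @param max_mismatch mismatches tolerated per binding site.
#' @param max_product maximum product size (bp).
#' @return a data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{size}, \code{fwd_primer}, \code{rev_primer} (indices into
#'   \code{primers}).
#' @export
inSilicoPcr <- function(primers, genome, max_mismatch = 0, max_product = 2000) {
  seqs <- .asGenome(genome)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), size = integer(),
                      fwd_primer = integer(), rev_primer = integer())
  out <- list()
  for (chrom in names(seqs)) {
    s <- as.character(seqs[[chrom]])
    sites <- lapply(primers, .primerSites, chrom_seq = s,
                    max_mismatch = max_mismatch)
    for (pi in seq_along(primers)) for (qi in seq_along(primers)) {
      sp <- sites[[pi]]; sq <- sites[[qi]]
      if (is.null(sp) || is.null(sq)) next
      fw <- sp[sp$strand == "+", , drop = FALSE]
      rv <- sq[sq$strand == "-", , drop = FALSE]
      if (!nrow(fw) || !nrow(rv)) next
      for (a in seq_len(nrow(fw))) {
        size <- rv$end - fw$start[a] + 1L
        ok <- rv$start >= fw$start[a] & size <= max_product & size >= 1L
        if (any(ok))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = fw$start[a], end = rv$end[ok],
            size = size[ok], fwd_primer = pi, rev_primer = qi)
      }
    }
  }
  if (!length(out)) return(empty)
  df <- unique(do.call(rbind, out))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Genome-wide uniqueness screen for markers
#'
#' Re-runs in-silico PCR for each marker's primer set with relaxed binding
#' (\code{max_mismatch = 2}) and flags the marker unique when all products
#' fall in exactly one genomic locus (overlapping products count as one
#' configuration).
#'
#' @param markers a \code{\link{MarkerSet}}.
#' @param genome sequences.
#' @param max_mismatch binding-site mismatch tolerance for the screen.
#' @param max_product maximum product size considered.
#' @return the \code{MarkerSet} with \code{unique_flag} and a
#'   \code{hit_loci} count filled in.
#' @export
checkUniqueness <- function(markers, genome, max_mismatch = 2,
                            max_product = 2000) {
  mk <- markerTable(markers)
  pr <- primerTable(markers)
  uniq <- logical(nrow(mk)); nloci <- integer(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    pp <- pr$seq[pr$marker_id == mk$marker_id[i]]
    prod <- inSilicoPcr(pp, genome, max_mismatch = max_mismatch,
                        max_product = max_product)
    if (!nrow(prod)) { uniq[i] <- FALSE; nloci[i] <- 0L; next }
    loci <- reduce(GRanges(prod$chrom, IRanges(prod$start, prod$end)))
    nloci[i] <- length(loci)
    uniq[i] <- length(loci) == 1L
  }
  mk$unique_flag <- uniq
  mk$hit_loci <- nloci
  MarkerSet(markers = mk, primers = pr, products = productTable(markers))
}
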