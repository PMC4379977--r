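## Primer picking with nearest-neighbour melting temperatures.
##
## Unified NN parameter set (dH kcal/mol, dS cal/mol/K), duplex initiation
## split by terminal base, entropic salt correction 0.368 * N * ln[Na+];
## defaults 50 mM monovalent salt, 50 nM oligo.

.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbour melting temperature
#'
#' @param seq primer sequence(s), 5' to 3'.
#' @param oligo_conc oligo concentration (M).
#' @param na_conc monovalent salt concentration (M).
#' @return Tm in degrees Celsius.
#' @export
tmNearestNeighbor <- function(seq, oligo_conc = 5e-8, na_conc = 0.05) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(b)
    if (n < 2) return(NA_real_)
    nn <- paste0(b[-n], b[-1])
    dH <- sum(.NN_DH[nn])
    dS <- sum(.NN_DS[nn])
    for (term in c(b[1], b[n])) {
      key <- if (term %in% c("G", "C")) "GC" else "AT"
      dH <- dH + .NN_INIT_DH[[key]]
      dS <- dS + .NN_INIT_DS[[key]]
    }
    dS <- dS + 0.368 * (n - 1) * log(na_conc)
    dH * 1000 / (dS + 1.987 * log(oligo_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Wallace-rule melting temperature (2AT + 4GC), for cross-checks
#' @param seq primer sequence(s).
#' @export
tmWallace <- function(seq) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer design constraints
#'
#' Defaults mirror common Primer3-style settings: length 18-27 (optimum
#' 20), Tm 57-63 degrees C (optimum 60), GC 40-60 percent, homopolymer runs
#' of at most 4, product size 100-1,000 bp, and primers at most 500 bp from
#' their junction.
#'
#' @param len_min,len_opt,len_max primer length bounds.
#' @param tm_min,tm_opt,tm_max melting-temperature bounds (C).
#' @param gc_min,gc_max GC percentage bounds.
#' @param max_homopolymer longest allowed single-base run.
#' @param product_min,product_max amplicon size bounds (bp).
#' @param junction_window maximum primer distance from its junction (bp).
#' @export
primerConstraints <- function(len_min = 18L, len_opt = 20L, len_max = 27L,
                              tm_min = 57, tm_opt = 60, tm_max = 63,
                              gc_min = 40, gc_max = 60, max_homopolymer = 4L,
                              product_min = 100L, product_max = 1000L,
                              junction_window = 500L) {
  stopifnot(len_min <= len_opt, len_opt <= len_max, tm_min <= tm_opt,
            tm_opt <= tm_max)
  list(len_min = as.integer(len_min), len_opt = as.integer(len_opt),
       len_max = as.integer(len_max), tm_min = tm_min, tm_opt = tm_opt,
       tm_max = tm_max, gc_min = gc_min, gc_max = gc_max,
       max_homopolymer = as.integer(max_homopolymer),
       product_min = as.integer(product_min),
       product_max = as.integer(product_max),
       junction_window = as.integer(junction_window))
}

#' Pick the best primer in a window
#'
#' Enumerates every substring of the window satisfying the length, GC and
#' homopolymer constraints, computes nearest-neighbour Tm, and returns the
#' candidate minimising \code{|Tm - tm_opt| + 0.5 |len - len_opt|}; ties go
#' to the leftmost start, then the shortest primer.  For
#' \code{direction = "reverse"} the primer sequence is the reverse
#' complement of the genome slice.
#'
#' @param seq chromosome sequence (character).
#' @param window integer c(start, end), 1-based inclusive.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param constraints from \code{\link{primerConstraints}}.
#' @return a one-row data.frame (\code{seq}, \code{start}, \code{end},
#'   \code{strand}, \code{tm_c}, \code{gc_pct}) or \code{NULL} when no
#'   candidate passes.
#' @export
pickPrimer <- function(seq, window, direction = c("forward", "reverse"),
                       constraints = primerConstraints()) {
  direction <- match.arg(direction)
  cn <- constraints
  w0 <- max(1L, as.integer(window[1]))
  w1 <- min(nchar(seq), as.integer(window[2]))
  if (w1 - w0 + 1L < cn$len_min) stop("window shorter than minimum primer length")
  cand <- list()
  for (len in seq(cn$len_min, cn$len_max)) {
    if (w1 - w0 + 1L < len) break
    sts <- seq.int(w0, w1 - len + 1L)
    slices <- substring(seq, sts, sts + len - 1L)
    gc <- vapply(slices, gcFraction, numeric(1), USE.NAMES = FALSE) * 100
    ok <- gc >= cn$gc_min & gc <= cn$gc_max & !grepl("N", slices, fixed = TRUE)
    if (!any(ok)) next
    hp <- vapply(slices[ok], maxHomopolymer, numeric(1), USE.NAMES = FALSE)
    ok2 <- which(ok)[hp <= cn$max_homopolymer]
    if (!length(ok2)) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = sts[ok2], len = len, slice = slices[ok2], gc = gc[ok2])
  }
  if (!length(cand)) return(NULL)
  df <- do.call(rbind, cand)
  pseq <- ifelse(rep(direction == "reverse", nrow(df)), revComp(df$slice),
                 df$slice)
  tm <- tmNearestNeighbor(pseq)
  okt <- tm >= cn$tm_min & tm <= cn$tm_max
  if (!any(okt)) return(NULL)
  df <- df[okt, , drop = FALSE]; pseq <- pseq[okt]; tm <- tm[okt]
  score <- abs(tm - cn$tm_opt) + 0.5 * abs(df$len - cn$len_opt)
  i <- order(score, df$start, df$len)[1]
  data.frame(seq = pseq[i], start = df$start[i],
             end = df$start[i] + df$len[i] - 1L,
             strand = if (direction == "forward") "+" else "-",
             tm_c = tm[i], gc_pct = df$gc[i], stringsAsFactors = FALSE)
}
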