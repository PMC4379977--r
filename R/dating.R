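#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via \code{Biostrings::pairwiseAlignment}
#' with match +2, mismatch -2, gap opening -5 and gap extension -1 by
#' default (a length-1 gap costs 6).  Tie-breaking among equal-score
#' alignments is deterministic.
#'
#' @param a,b DNA sequences (character).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; signs as
#'   conventionally written (penalties negative).
#' @return a list with \code{aligned_a}, \code{aligned_b} (equal-length
#'   strings over A,C,G,T,-; no column has two gaps) and \code{score}.
#' @export
alignGlobal <- function(a, b, match = 2, mismatch = -2, gap_open = -5,
                        gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = -gap_open, gapExtension = -gap_extend)
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

.alignmentColumns <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned strings must have equal length")
  keep <- a != "-" & b != "-"
  list(a = a[keep], b = b[keep])
}

#' Nucleotide distance from a pairwise alignment
#'
#' Gapped columns are excluded.  Models: \code{p} (raw proportion of
#' differing sites), \code{JC} (Jukes-Cantor,
#' \eqn{d = -3/4 \log(1 - 4p/3)}) and \code{K2P} (Kimura two-parameter from
#' transition proportion P and transversion proportion Q,
#' \eqn{d = -\log((1-2P-Q)\sqrt{1-2Q})/2}).
#'
#' @param alignment result of \code{\link{alignGlobal}}.
#' @param model \code{"p"}, \code{"JC"} or \code{"K2P"}.
#' @return the distance (substitutions/site).
#' @export
nucleotideDistance <- function(alignment, model = c("K2P", "JC", "p")) {
  model <- match.arg(model)
  cols <- .alignmentColumns(alignment)
  n <- length(cols$a)
  if (n < 1) stop("no ungapped columns in alignment")
  diff <- cols$a != cols$b
  p <- mean(diff)
  if (model == "p") return(p)
  if (model == "JC") {
    if (p >= 0.75) stop("saturated: p >= 0.75, Jukes-Cantor undefined")
    return(-0.75 * log(1 - 4 * p / 3))
  }
  purine <- c("A", "G")
  transition <- diff & ((cols$a %in% purine) == (cols$b %in% purine))
  P <- mean(transition)
  Q <- p - P
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) stop("saturated: K2P log-domain violation")
  -0.5 * log(arg1 * sqrt(arg2))
}

## --------------------------------------------------------------------------
## NG86 synonymous / non-synonymous analysis
## --------------------------------------------------------------------------

.CODON_TABLE <- NULL  # built lazily from the standard genetic code

.codonTable <- function() {
  if (is.null(.pkgCache$codon_table))
    .pkgCache$codon_table <- Biostrings::GENETIC_CODE
  .pkgCache$codon_table
}

# per-codon synonymous site count: at each position, the fraction of
# counted one-step changes (changes to stop codons excluded from the
# counted set) that are synonymous
.codonSynSites <- function(codon, tab) {
  aa <- tab[[codon]]
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    syn <- 0L; counted <- 0L
    for (nb in setdiff(c("A", "C", "G", "T"), base)) {
      mut <- codon
      substr(mut, pos, pos) <- nb
      maa <- tab[[mut]]
      if (maa == "*") next
      counted <- counted + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (counted > 0) s <- s + syn / counted
  }
  s
}

# Sd/Nd contribution of one codon pair: average over all orderings of the
# differing positions; pathways through stop codons are excluded and the
# weights renormalised
.codonPairSubs <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else
    if (k == 2) list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  tot_sd <- 0; tot_nd <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- c1; sd <- 0L; nd <- 0L; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab[[nxt]] == "*") { ok <- FALSE; break }
      if (tab[[nxt]] == tab[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) { tot_sd <- tot_sd + sd; tot_nd <- tot_nd + nd; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(sd = 0, nd = 0))  # all pathways pass through stops
  c(sd = tot_sd / n_ok, nd = tot_nd / n_ok)
}

#' Nei-Gojobori (1986) synonymous/non-synonymous analysis
#'
#' Counts synonymous (S) and non-synonymous (N) sites per sequence as the
#' per-position fraction of counted one-step changes that are synonymous
#' (changes to stop codons excluded from the counted set); S is the mean of
#' the two sequences' totals and N = 3L - S.  Observed synonymous (Sd) and
#' non-synonymous (Nd) substitutions are averaged over all mutational
#' pathways between each codon pair, excluding pathways through stop codons
#' and renormalising.  pS = Sd/S and pN = Nd/N are Jukes-Cantor corrected
#' to dS (= Ks) and dN (= Ka); omega = dN/dS (NA when dS = 0).
#'
#' @param coding_a,coding_b equal-length coding sequences, length a multiple
#'   of 3, no internal stop codons.
#' @return a list with S, N, Sd, Nd, pS, pN, dS, dN, omega and sites_used.
#' @export
ng86 <- function(coding_a, coding_b) {
  coding_a <- toupper(coding_a); coding_b <- toupper(coding_b)
  if (nchar(coding_a) != nchar(coding_b))
    stop("sequences must have equal length")
  if (nchar(coding_a) %% 3 != 0) stop("length must be a multiple of 3")
  tab <- .codonTable()
  nc <- nchar(coding_a) / 3
  cod_a <- substring(coding_a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cod_b <- substring(coding_b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  if (any(tab[cod_a] == "*") || any(tab[cod_b] == "*"))
    stop("internal stop codon")
  s_a <- sum(vapply(cod_a, .codonSynSites, numeric(1), tab = tab))
  s_b <- sum(vapply(cod_b, .codonSynSites, numeric(1), tab = tab))
  S <- (s_a + s_b) / 2
  N <- 3 * nc - S
  subs <- vapply(seq_len(nc),
                 function(i) .codonPairSubs(cod_a[i], cod_b[i], tab),
                 numeric(2))
  Sd <- sum(subs["sd", ]); Nd <- sum(subs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75 || pN >= 0.75) stop("saturated: pS or pN >= 0.75")
  dS <- -0.75 * log(1 - 4 * pS / 3) + 0  # + 0 avoids IEEE negative zero
  dN <- -0.75 * log(1 - 4 * pN / 3) + 0
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
       omega = if (dS > 0) dN / dS else NA_real_, sites_used = 3L * nc)
}

#' Insertion time from LTR-LTR divergence
#'
#' \eqn{T = d / (2r)}: the two LTRs are identical at insertion and diverge
#' independently at rate r substitutions/site/year.
#'
#' @param divergence nucleotide distance between the two LTRs.
#' @param rate_r substitution rate (substitutions/site/year); the default
#'   1.3e-8 is a commonly used rate for grass intergenic DNA.
#' @return a list with \code{divergence_used}, \code{rate_r},
#'   \code{T_years}, \code{T_mya}.
#' @export
insertionTime <- function(divergence, rate_r = 1.3e-8) {
  if (any(divergence < 0)) stop("divergence must be >= 0")
  if (rate_r <= 0) stop("rate_r must be > 0")
  T_years <- divergence / (2 * rate_r)
  list(divergence_used = divergence, rate_r = rate_r, T_years = T_years,
       T_mya = T_years / 1e6)
}

#' Date LTR elements from their LTR pair
#'
#' For each element: extract the LTR pair, align globally, compute the
#' chosen distance and convert to an insertion time.  Saturated pairs are
#' reported with status "saturated" rather than dropped.
#'
#' @param genome sequences (see \code{\link{findLtrPairs}}).
#' @param elements an \code{\link{LtrElementSet}}.
#' @param model \code{"K2P"} (default), \code{"JC"}, \code{"p"} or
#'   \code{"ngKs"} (NG86 dS on the LTR pair read in frame, trimmed to a
#'   multiple of 3).
#' @param rate_r substitution rate (substitutions/site/year).
#' @return a data.frame with element_id, divergence, model, T_years, T_mya,
#'   status.
#' @export
dateElements <- function(genome, elements, model = c("K2P", "JC", "p", "ngKs"),
                         rate_r = 1.3e-8) {
  model <- match.arg(model)
  ltrs <- extractLtrPairSequences(genome, elements)
  n <- length(elements)
  out <- data.frame(element_id = if (n) mcols(elements)$id else character(),
                    divergence = numeric(n), model = rep(model, n),
                    T_years = numeric(n), T_mya = numeric(n),
                    status = rep("ok", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- tryCatch({
      if (model == "ngKs") {
        aln <- alignGlobal(ltrs[i, "ltr5"], ltrs[i, "ltr3"])
        cols <- .alignmentColumns(aln)
        len <- length(cols$a) - length(cols$a) %% 3
        a <- paste(cols$a[seq_len(len)], collapse = "")
        b <- paste(cols$b[seq_len(len)], collapse = "")
        # LTRs are non-coding: drop codon columns where either strand shows
        # a stop so the NG86 machinery applies
        tab <- .codonTable()
        nc <- nchar(a) / 3
        ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
        cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
        keep <- tab[ca] != "*" & tab[cb] != "*"
        ng86(paste(ca[keep], collapse = ""),
             paste(cb[keep], collapse = ""))$dS
      } else {
        nucleotideDistance(alignGlobal(ltrs[i, "ltr5"], ltrs[i, "ltr3"]),
                           model)
      }
    }, error = function(e) NA_real_)
    if (is.na(d)) {
      out$status[i] <- "saturated"
      out$divergence[i] <- NA_real_
      out$T_years[i] <- NA_real_
      out$T_mya[i] <- NA_real_
    } else {
      it <- insertionTime(d, rate_r)
      out$divergence[i] <- d
      out$T_years[i] <- it$T_years
      out$T_mya[i] <- it$T_mya
    }
  }
  out
}
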