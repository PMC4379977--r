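#' Detection parameters for the structural LTR finder
#'
#' Defaults implement the structural definition of a full-length LTR
#' retrotransposon used throughout the package: LTR length 100-3,500 bp,
#' inter-LTR gap at most 10,000 bp, TG...CA termini, target-site
#' duplication 4-6 bp, primer-binding site searched in a 20 bp window with
#' at least 12 contiguous matching bases, polypurine tract of at least
#' 15 bp with purine fraction >= 0.80 in a 20 bp window.
#'
#' @param min_ltr_len,max_ltr_len LTR length bounds (bp).
#' @param max_ltr_distance maximum distance between the LTRs (bp); by
#'   default the inter-LTR gap (internal-region length), see
#'   \code{distance_mode}.
#' @param distance_mode \code{"gap"} (gap between the LTRs) or
#'   \code{"span"} (whole-element span) interpretation of
#'   \code{max_ltr_distance}.
#' @param min_ltr_identity minimum LTR-LTR identity fraction in (0, 1].
#' @param terminal_motifs start/end dinucleotides enforced on each LTR.
#' @param enforce_termini require the terminal motifs (with up to
#'   \code{snap_bp} boundary adjustment) rather than rejecting outright.
#' @param snap_bp boundary adjustment radius when snapping to the terminal
#'   motifs.
#' @param tsd_len_range target-site-duplication length range searched.
#' @param pbs_window,pbs_min_match PBS search window downstream of the 5'
#'   LTR and minimum contiguous match to a tRNA 3' terminus.
#' @param ppt_window,ppt_min_len,ppt_min_purine PPT search window upstream
#'   of the 3' LTR, minimum tract length, minimum purine (A/G) fraction
#'   (threshold inclusive).
#' @param seed_kmer exact seed length for LTR-pair discovery.
#' @return a named list of validated parameters.
#' @export
ltrParams <- function(min_ltr_len = 100L, max_ltr_len = 3500L,
                      max_ltr_distance = 10000L,
                      distance_mode = c("gap", "span"),
                      min_ltr_identity = 0.80,
                      terminal_motifs = c("TG", "CA"),
                      enforce_termini = TRUE, snap_bp = 15L,
                      tsd_len_range = c(4L, 6L),
                      pbs_window = 20L, pbs_min_match = 12L,
                      ppt_window = 20L, ppt_min_len = 15L,
                      ppt_min_purine = 0.80, seed_kmer = 20L) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(min_ltr_len < max_ltr_len, min_ltr_len > 0,
            max_ltr_distance > 0, pbs_window > 0, ppt_window > 0,
            min_ltr_identity > 0, min_ltr_identity <= 1,
            length(terminal_motifs) == 2, seed_kmer >= 8)
  list(min_ltr_len = as.integer(min_ltr_len),
       max_ltr_len = as.integer(max_ltr_len),
       max_ltr_distance = as.integer(max_ltr_distance),
       distance_mode = distance_mode,
       min_ltr_identity = min_ltr_identity,
       terminal_motifs = terminal_motifs,
       enforce_termini = enforce_termini, snap_bp = as.integer(snap_bp),
       tsd_len_range = as.integer(tsd_len_range),
       pbs_window = as.integer(pbs_window),
       pbs_min_match = as.integer(pbs_min_match),
       ppt_window = as.integer(ppt_window),
       ppt_min_len = as.integer(ppt_min_len),
       ppt_min_purine = ppt_min_purine, seed_kmer = as.integer(seed_kmer))
}

# snap a position pair (same offset on both LTR copies) to a dinucleotide
# motif within +/- snap bp; smallest |delta| wins, ties to the left
.snapMotif <- function(s, posA, posB, motif, snap, at_start) {
  deltas <- order(abs(seq(-snap, snap)), seq(-snap, snap) > 0)
  cand <- seq(-snap, snap)[deltas]
  for (d in cand) {
    pA <- if (at_start) posA + d else posA + d - 1L
    pB <- if (at_start) posB + d else posB + d - 1L
    if (pA < 1 || pB + 1 > nchar(s)) next
    if (substr(s, pA, pA + 1L) == motif && substr(s, pB, pB + 1L) == motif)
      return(d)
  }
  NA_integer_
}

# gapless seed-and-extend detection of direct LTR pairs on one sequence
.findLtrPairsOne <- function(s, chrom, params) {
  n <- nchar(s)
  p <- params
  k <- p$seed_kmer
  w <- 20L
  min_match <- ceiling(p$min_ltr_identity * w)
  if (n < 2 * p$min_ltr_len) return(NULL)

  # 1. index all k-mers, keep duplicated ones
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  dupval <- unique(kmers[duplicated(kmers)])
  if (!length(dupval)) return(NULL)
  sel <- which(kmers %in% dupval)
  grp <- split(sel, kmers[sel])

  # 2. seed pairs at an admissible LTR5/LTR3 start distance (same diagonal
  # offset on both copies since the alignment is gapless)
  d_max <- if (p$distance_mode == "gap") p$max_ltr_len + p$max_ltr_distance
           else p$max_ltr_distance
  pairs <- list()
  for (g in grp) {
    if (length(g) > 25L) next  # low-complexity k-mer, not an LTR signal
    cmb <- combn(g, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    keep <- d > p$min_ltr_len & d <= d_max
    if (any(keep)) pairs[[length(pairs) + 1L]] <- cmb[, keep, drop = FALSE]
  }
  if (!length(pairs)) return(NULL)
  pairs <- do.call(cbind, pairs)

  rv <- charToRaw(s)
  cands <- list()
  # 3. per diagonal, extend the leftmost uncovered seed both ways while the
  # sliding 20 bp window identity stays above threshold
  diag <- pairs[2L, ] - pairs[1L, ]
  for (D in unique(diag)) {
    iis <- sort(unique(pairs[1L, diag == D]))
    covered_hi <- -Inf
    for (i in iis) {
      if (i <= covered_hi) next
      j <- i + D
      lo <- max(1L - i, -p$max_ltr_len)
      hi <- min(n - j, D - 2L, p$max_ltr_len)
      off <- seq.int(lo, hi)
      eq <- rv[i + off] == rv[j + off]
      s0 <- 1L - lo  # index of offset 0 within eq
      ne <- length(eq)
      cs <- c(0L, cumsum(!eq))
      winBad <- function(t_idx) cs[pmin(t_idx + w, ne) + 1L] - cs[t_idx + 1L]
      # right: first failing window starting at/after the seed
      t <- s0
      while (t + w - 1L <= ne && winBad(t) <= w - min_match) t <- t + 1L
      r_idx <- min(t + w - 2L, ne)
      while (r_idx > s0 && !eq[r_idx]) r_idx <- r_idx - 1L
      # left: first failing window ending at/before the seed end
      t <- s0 + k - 1L
      while (t - w + 1L >= 1L && winBad(t - w + 1L) <= w - min_match) t <- t - 1L
      l_idx <- max(t - w + 2L, 1L)
      while (l_idx < s0 && !eq[l_idx]) l_idx <- l_idx + 1L
      covered_hi <- i + (r_idx - s0)
      a <- i + (l_idx - s0); a_end <- i + (r_idx - s0)
      cands[[length(cands) + 1L]] <- list(a = a, a_end = a_end, D = D)
    }
  }

  # 4. snap boundaries to the terminal motifs, validate invariants
  out <- list()
  for (cd in cands) {
    a <- cd$a; a_end <- cd$a_end; D <- cd$D
    if (p$enforce_termini) {
      d1 <- .snapMotif(s, a, a + D, p$terminal_motifs[[1]], p$snap_bp, TRUE)
      d2 <- .snapMotif(s, a_end, a_end + D, p$terminal_motifs[[2]], p$snap_bp, FALSE)
      if (is.na(d1) || is.na(d2)) next
      a <- a + d1; a_end <- a_end + d2
    }
    L <- a_end - a + 1L
    if (L < p$min_ltr_len || L > p$max_ltr_len) next
    b <- a + D; b_end <- a_end + D
    gap <- b - a_end - 1L
    if (gap < 1L) next
    if (p$distance_mode == "gap" && gap > p$max_ltr_distance) next
    if (p$distance_mode == "span" && (b_end - a + 1L) > p$max_ltr_distance) next
    if (b_end > nchar(s)) next
    ident <- mean(charToRaw(substr(s, a, a_end)) ==
                  charToRaw(substr(s, b, b_end)))
    if (is.na(ident) || ident < p$min_ltr_identity) next
    out[[length(out) + 1L]] <-
      data.frame(a = a, a_end = a_end, b = b, b_end = b_end, ident = ident)
  }
  if (!length(out)) return(NULL)
  df <- unique(do.call(rbind, out))

  # 5. overlap resolution: identity x LTR-length score, ties to the left
  score <- df$ident * (df$a_end - df$a + 1L)
  ord <- order(-score, df$a)
  keep <- logical(nrow(df))
  taken <- IRanges()
  for (i in ord) {
    r <- IRanges(df$a[i], df$b_end[i])
    if (!length(findOverlaps(r, taken))) {
      keep[i] <- TRUE
      taken <- c(taken, r)
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$a), , drop = FALSE]
  df$chrom <- chrom
  df
}

#' Find paired-LTR candidates by structural search
#'
#' Seed-and-extend discovery of direct long terminal repeat pairs: exact
#' k-mer seeds at an admissible distance are extended by gapless alignment
#' while the 20 bp sliding-window identity stays at or above
#' \code{min_ltr_identity}; boundaries are then snapped to the nearest
#' TG...CA within \code{snap_bp}; candidates violating any structural
#' invariant are dropped and overlaps are resolved by the
#' identity-times-length score (ties to the leftmost start).
#'
#' @param genome a named \code{DNAStringSet}, a \code{\link{PlantedGenome}},
#'   or a character vector of sequences.
#' @param params parameters from \code{\link{ltrParams}}.
#' @return an \code{\link{LtrElementSet}} (features such as TSD/PBS/PPT and
#'   superfamily unfilled; see \code{\link{annotateLtrFeatures}}).
#' @export
findLtrPairs <- function(genome, params = ltrParams()) {
  seqs <- .asGenome(genome)
  res <- list()
  for (chrom in names(seqs)) {
    df <- .findLtrPairsOne(as.character(seqs[[chrom]]), chrom, params)
    if (!is.null(df)) res[[length(res) + 1L]] <- df
  }
  if (!length(res)) return(LtrElementSet())
  df <- do.call(rbind, res)
  gr <- GRanges(df$chrom, IRanges(df$a, df$b_end))
  mcols(gr) <- DataFrame(id = sprintf("ltr_%s_%d", df$chrom,
                                      ave(df$a, df$chrom, FUN = seq_along)),
                         ltr5_start = df$a, ltr5_end = df$a_end,
                         ltr3_start = df$b, ltr3_end = df$b_end,
                         ltr_identity = df$ident)
  LtrElementSet(gr)
}

.asGenome <- function(genome) {
  if (is(genome, "PlantedGenome")) return(genomeSequences(genome))
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("chr", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) {
    out <- Biostrings::DNAStringSet(genome)
    names(out) <- "chr1"
    return(out)
  }
  stop("cannot interpret 'genome' as sequences")
}

#' Detect the target-site duplication of an element
#'
#' Longest exact match between the windows immediately 5' of the 5' LTR and
#' immediately 3' of the 3' LTR, searching lengths from the maximum to the
#' minimum of \code{tsd_len_range}.
#'
#' @param genome sequences (see \code{\link{findLtrPairs}}).
#' @param elements an \code{\link{LtrElementSet}}.
#' @param tsd_len_range integer length range searched (max first match wins).
#' @return character vector of TSDs (NA where none found or at a contig end).
#' @export
detectTsd <- function(genome, elements, tsd_len_range = c(4L, 6L)) {
  seqs <- .asGenome(genome)
  lens <- sort(as.integer(tsd_len_range))
  vapply(seq_along(elements), function(i) {
    s <- chromSeq(seqs, as.character(seqnames(elements)[i]))
    a <- start(elements)[i]; e <- end(elements)[i]
    for (L in seq(lens[2], lens[1])) {
      if (a - L < 1 || e + L > nchar(s)) next
      left <- substr(s, a - L, a - 1L)
      right <- substr(s, e + 1L, e + L)
      if (left == right) return(left)
    }
    NA_character_
  }, character(1))
}

#' Detect the primer-binding site of an element
#'
#' Best contiguous match of at least \code{pbs_min_match} bases, within
#' \code{pbs_window} bp downstream of the 5' LTR, to the reverse complement
#' of any library tRNA 3' terminus.
#'
#' @inheritParams detectTsd
#' @param trna_library path to a FASTA of tRNA 3' termini, or a
#'   \code{DNAStringSet}; empty library skips the search with a warning.
#' @param params \code{\link{ltrParams}} list.
#' @return a \code{DataFrame} with \code{pbs_start}, \code{pbs_end},
#'   \code{pbs_trna} (NA where none).
#' @export
detectPbs <- function(genome, elements, trna_library = defaultTrnaLibrary(),
                      params = ltrParams()) {
  seqs <- .asGenome(genome)
  trna <- if (is.character(trna_library) && length(trna_library) == 1 &&
              file.exists(trna_library)) .readFastaCached(trna_library)
          else .asGenome(trna_library)
  n_el <- length(elements)
  res <- DataFrame(pbs_start = rep(NA_integer_, n_el),
                   pbs_end = rep(NA_integer_, n_el),
                   pbs_trna = rep(NA_character_, n_el))
  if (!length(trna)) {
    warning("empty tRNA library; PBS detection skipped")
    return(res)
  }
  # reverse complement of each tRNA 3' terminus (last pbs_window bases)
  targets <- vapply(seq_along(trna), function(t) {
    x <- as.character(trna[[t]])
    revComp(substr(x, max(1L, nchar(x) - params$pbs_window + 1L), nchar(x)))
  }, character(1))
  names(targets) <- names(trna)
  for (i in seq_len(n_el)) {
    s <- chromSeq(seqs, as.character(seqnames(elements)[i]))
    w0 <- mcols(elements)$ltr5_end[i] + 1L
    w1 <- min(w0 + params$pbs_window - 1L, nchar(s))
    if (w0 > w1) next
    window <- substr(s, w0, w1)
    best_len <- 0L
    for (t in seq_along(targets)) {
      tg <- targets[[t]]
      for (L in seq(nchar(tg), params$pbs_min_match)) {
        if (L <= best_len) break
        found <- FALSE
        for (st in seq_len(nchar(tg) - L + 1L)) {
          m <- regexpr(substr(tg, st, st + L - 1L), window, fixed = TRUE)
          if (m > 0) {
            res$pbs_start[i] <- w0 + as.integer(m) - 1L
            res$pbs_end[i] <- res$pbs_start[i] + L - 1L
            res$pbs_trna[i] <- names(targets)[t]
            best_len <- L
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }
  res
}

#' Detect the polypurine tract of an element
#'
#' Longest run of length at least \code{ppt_min_len} with purine (A/G)
#' fraction at or above \code{ppt_min_purine} (inclusive) within
#' \code{ppt_window} bp upstream of the 3' LTR; ties to the leftmost.
#'
#' @inheritParams detectPbs
#' @return a \code{DataFrame} with \code{ppt_start}, \code{ppt_end},
#'   \code{ppt_purine}.
#' @export
detectPpt <- function(genome, elements, params = ltrParams()) {
  seqs <- .asGenome(genome)
  n_el <- length(elements)
  res <- DataFrame(ppt_start = rep(NA_integer_, n_el),
                   ppt_end = rep(NA_integer_, n_el),
                   ppt_purine = rep(NA_real_, n_el))
  for (i in seq_len(n_el)) {
    s <- chromSeq(seqs, as.character(seqnames(elements)[i]))
    w1 <- mcols(elements)$ltr3_start[i] - 1L
    w0 <- max(1L, w1 - params$ppt_window + 1L)
    if (w0 > w1) next
    win <- strsplit(substr(s, w0, w1), "", fixed = TRUE)[[1]]
    pur <- win %in% c("A", "G")
    nwin <- length(pur)
    cs <- c(0L, cumsum(pur))
    best <- NULL
    for (L in seq(nwin, min(params$ppt_min_len, nwin))) {
      for (st in seq_len(nwin - L + 1L)) {
        frac <- (cs[st + L] - cs[st]) / L
        if (frac >= params$ppt_min_purine) { best <- c(st, L, frac); break }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best) && best[2] >= params$ppt_min_len) {
      res$ppt_start[i] <- w0 + as.integer(best[1]) - 1L
      res$ppt_end[i] <- res$ppt_start[i] + as.integer(best[2]) - 1L
      res$ppt_purine[i] <- best[3]
    }
  }
  res
}

#' Classify an element into Copia/Gypsy by pol domain order
#'
#' Translates the internal region in all six frames, locates short peptide
#' consensus motifs (GAG, PR, integrase core and C-terminus, reverse
#' transcriptase, RNase H; user-extensible), and calls Copia when the
#' integrase occurs upstream of the reverse transcriptase on the coding
#' strand, Gypsy when RT (and RH) occur upstream of the integrase, and
#' unknown otherwise.
#'
#' @inheritParams detectPbs
#' @param motif_library named character vector of peptide motifs; must
#'   contain \code{INT_core} and \code{RT}.
#' @return character vector: \code{"Copia"}, \code{"Gypsy"} or
#'   \code{"unknown"}.
#' @export
classifySuperfamily <- function(genome, elements,
                                motif_library = .DOMAIN_MOTIFS) {
  seqs <- .asGenome(genome)
  stopifnot(all(c("INT_core", "RT") %in% names(motif_library)))
  vapply(seq_along(elements), function(i) {
    s <- chromSeq(seqs, as.character(seqnames(elements)[i]))
    int0 <- mcols(elements)$ltr5_end[i] + 1L
    int1 <- mcols(elements)$ltr3_start[i] - 1L
    if (int1 - int0 + 1L < 30L) return("unknown")
    internal <- Biostrings::DNAString(substr(s, int0, int1))
    for (strand_seq in list(internal, Biostrings::reverseComplement(internal))) {
      pos <- setNames(rep(NA_integer_, length(motif_library)),
                      names(motif_library))
      for (frame in 0:2) {
        len <- length(strand_seq) - frame
        len <- len - (len %% 3L)
        if (len < 3L) next
        pep <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::subseq(strand_seq, frame + 1L, frame + len),
          if.fuzzy.codon = "solve")))
        for (m in names(motif_library)) {
          hit <- regexpr(motif_library[[m]], pep, fixed = TRUE)
          if (hit > 0) {
            nt <- frame + (as.integer(hit) - 1L) * 3L + 1L
            if (is.na(pos[[m]]) || nt < pos[[m]]) pos[[m]] <- nt
          }
        }
      }
      if (!is.na(pos[["INT_core"]]) && !is.na(pos[["RT"]])) {
        return(if (pos[["INT_core"]] < pos[["RT"]]) "Copia" else "Gypsy")
      }
    }
    "unknown"
  }, character(1))
}

#' Extract the paired LTR sequences of elements
#'
#' @inheritParams detectTsd
#' @return a two-column character matrix (\code{ltr5}, \code{ltr3}).
#' @export
extractLtrPairSequences <- function(genome, elements) {
  seqs <- .asGenome(genome)
  m <- mcols(elements)
  out <- t(vapply(seq_along(elements), function(i) {
    s <- chromSeq(seqs, as.character(seqnames(elements)[i]))
    c(ltr5 = substr(s, m$ltr5_start[i], m$ltr5_end[i]),
      ltr3 = substr(s, m$ltr3_start[i], m$ltr3_end[i]))
  }, character(2)))
  dimnames(out) <- list(NULL, c("ltr5", "ltr3"))
  out
}

#' Fill TSD/PBS/PPT/superfamily features of LTR elements
#'
#' @inheritParams detectPbs
#' @return the \code{\link{LtrElementSet}} with feature columns filled.
#' @export
annotateLtrFeatures <- function(genome, elements,
                                trna_library = defaultTrnaLibrary(),
                                params = ltrParams()) {
  if (!length(elements)) return(elements)
  mcols(elements)$tsd <- detectTsd(genome, elements, params$tsd_len_range)
  pbs <- detectPbs(genome, elements, trna_library, params)
  ppt <- detectPpt(genome, elements, params)
  for (col in colnames(pbs)) mcols(elements)[[col]] <- pbs[[col]]
  for (col in colnames(ppt)) mcols(elements)[[col]] <- ppt[[col]]
  mcols(elements)$superfamily <- classifySuperfamily(genome, elements)
  elements
}

#' One-call structural LTR retrotransposon discovery
#'
#' \code{\link{findLtrPairs}} followed by \code{\link{annotateLtrFeatures}}.
#'
#' @inheritParams detectPbs
#' @export
findLtrElements <- function(genome, params = ltrParams(),
                            trna_library = defaultTrnaLibrary()) {
  annotateLtrFeatures(genome, findLtrPairs(genome, params), trna_library,
                      params)
}

#' Convert LTR elements to repeat annotations
#'
#' @param elements an \code{\link{LtrElementSet}}.
#' @return a \code{\link{RepeatAnnotations}} object (source
#'   \code{structural}, completeness \code{full}); unknown superfamilies map
#'   to te_class \code{Unknown}.
#' @export
ltrAsRepeatAnnotations <- function(elements) {
  gr <- granges(elements)
  sf <- mcols(elements)$superfamily
  cls <- ifelse(is.na(sf) | sf == "unknown", "Unknown", sf)
  mcols(gr) <- DataFrame(id = mcols(elements)$id, te_class = cls,
                         subclass = NA_character_,
                         completeness = "full", source = "structural")
  RepeatAnnotations(gr)
}

#' Export LTR elements as GFF3 with child features
#'
#' Writes one parent feature per element plus LTR5/LTR3 (and PBS/PPT when
#' present) child features linked by ID/Parent.
#'
#' @param elements an \code{\link{LtrElementSet}}.
#' @param path output path.
#' @export
writeLtrGff3 <- function(elements, path) {
  m <- mcols(elements)
  feats <- list()
  for (i in seq_along(elements)) {
    chrom <- as.character(seqnames(elements)[i])
    id <- m$id[i]
    add <- function(type, st, en, suffix) {
      g <- GRanges(chrom, IRanges(st, en))
      mcols(g) <- DataFrame(type = type,
                            ID = paste0(id, suffix),
                            Parent = if (suffix == "") NA_character_ else id)
      g
    }
    feats[[length(feats) + 1L]] <- add("LTR_retrotransposon",
                                       start(elements)[i], end(elements)[i], "")
    feats[[length(feats) + 1L]] <- add("long_terminal_repeat",
                                       m$ltr5_start[i], m$ltr5_end[i], ".ltr5")
    feats[[length(feats) + 1L]] <- add("long_terminal_repeat",
                                       m$ltr3_start[i], m$ltr3_end[i], ".ltr3")
    if (!is.na(m$pbs_start[i]))
      feats[[length(feats) + 1L]] <- add("primer_binding_site",
                                         m$pbs_start[i], m$pbs_end[i], ".pbs")
    if (!is.na(m$ppt_start[i]))
      feats[[length(feats) + 1L]] <- add("RR_tract",
                                         m$ppt_start[i], m$ppt_end[i], ".ppt")
  }
  gr <- if (length(feats)) do.call(c, feats) else GRanges()
  writeGff3(gr, path)
}
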