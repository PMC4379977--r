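suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

revComp <- temark:::revComp

# random DNA string
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# best accuracy over all label permutations (small K)
permAccuracy <- function(assign, truth, K) {
  perms <- if (K == 2) list(1:2, 2:1) else
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
         c(3, 2, 1))
  max(vapply(perms, function(p) mean(p[assign] == truth), numeric(1)))
}

# hand-rolled RepeatAnnotations builder for interval-logic tests
mkAnn <- function(chrom, starts, ends, ids = NULL, te_class = "DNA",
                  subclass = "PIF-Harbinger", strand = "+", ...) {
  n <- length(starts)
  gr <- GRanges(chrom, IRanges(starts, ends), strand = strand)
  mcols(gr) <- DataFrame(id = ids %||% paste0("a", seq_len(n)),
                         te_class = rep_len(te_class, n),
                         subclass = rep_len(subclass, n),
                         completeness = "full", source = "file", ...)
  RepeatAnnotations(gr)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## independent oracles
## ---------------------------------------------------------------------------

# exhaustive affine-gap global alignment score by recursion over all
# alignment paths (tiny sequences only)
oracleAlignScore <- function(a, b, match = 2, mismatch = -2, gap_open = -5,
                             gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  gap1 <- gap_open + gap_extend
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      sc <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      sc <- if (state == "a") gap_extend else gap1
      best <- max(best, sc + rec(i + 1, j, "a"))
    }
    if (j <= length(bv)) {
      sc <- if (state == "b") gap_extend else gap1
      best <- max(best, sc + rec(i, j + 1, "b"))
    }
    best
  }
  rec(1, 1, "m")
}

# NG86 oracle: explicit enumeration over one-step neighbours (site counts)
# and recursive pathway enumeration (substitution counts)
oracleNg86 <- function(a, b) {
  tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  syn_sites <- function(codon) {
    total <- 0
    for (pos in 1:3) {
      nb <- setdiff(bases, substr(codon, pos, pos))
      muts <- vapply(nb, function(x) {
        m <- codon; substr(m, pos, pos) <- x; m
      }, character(1))
      aas <- tab[muts]
      counted <- muts[aas != "*"]
      if (length(counted))
        total <- total + mean(tab[counted] == tab[[codon]])
    }
    total
  }
  paths <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    acc <- list()
    walk <- function(cur, remaining, sd, nd) {
      if (!length(remaining)) {
        acc[[length(acc) + 1L]] <<- c(sd, nd)
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (tab[[nxt]] == "*") next
        walk(nxt, setdiff(remaining, p),
             sd + (tab[[nxt]] == tab[[cur]]), nd + (tab[[nxt]] != tab[[cur]]))
      }
    }
    walk(c1, pos, 0, 0)
    if (!length(acc)) return(c(0, 0))
    colMeans(do.call(rbind, acc))
  }
  ca <- codons(a); cb <- codons(b)
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
        sum(vapply(cb, syn_sites, numeric(1)))) / 2
  sub <- rowSums(vapply(seq_along(ca),
                        function(i) paths(ca[i], cb[i]), numeric(2)))
  list(S = S, N = 3 * length(ca) - S, Sd = sub[1], Nd = sub[2])
}

# random codon pair fixture: L codons, up to max_diff substitutions per
# codon, no stop codons in either sequence
randomCodingPair <- function(L = 30, max_diff = 2) {
  tab <- Biostrings::GENETIC_CODE
  sense <- names(tab)[tab != "*"]
  repeat {
    ca <- sample(sense, L, replace = TRUE)
    cb <- vapply(ca, function(c1) {
      k <- sample(0:max_diff, 1, prob = c(0.5, 0.35, 0.15))
      if (k == 0) return(c1)
      pos <- sample(1:3, k)
      c2 <- c1
      for (p in pos) {
        substr(c2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(c2, p, p)), 1)
      }
      c2
    }, character(1))
    if (all(tab[cb] != "*")) break
  }
  list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""))
}

# brute-force junction oracle from an annotation bitmask
oracleJunctions <- function(starts, ends, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  pos <- integer(0)
  for (b in seq_len(chrom_len - 1)) {
    if (mask[b] != mask[b + 1]) pos <- c(pos, b)
  }
  pos
}

# brute-force SSR oracle: every maximal perfect tandem run, then the same
# longest-first / smaller-motif overlap resolution
oracleSsrs <- function(s, min_total_len = 12,
                       min_copies = c(`1` = 10, `2` = 6, `3` = 5, `4` = 5,
                                      `5` = 5, `6` = 4)) {
  n <- nchar(s)
  cand <- list()
  for (m in 1:6) {
    for (st in seq_len(max(0, n - 2 * m + 1))) {
      motif <- substr(s, st, st + m - 1L)
      if (st > m && substr(s, st - m, st - 1L) == motif) next  # not maximal
      len <- m
      while (st + len + m - 1L <= n &&
             substr(s, st + len, st + len + m - 1L) ==
             substr(s, st + len - m, st + len - 1L)) len <- len + m
      # extend by partial unit
      extra <- 0L
      while (st + len + extra <= n &&
             substr(s, st + len + extra, st + len + extra) ==
             substr(s, st + len + extra - m, st + len + extra - m)) {
        extra <- extra + 1L
      }
      len <- len + extra
      copies <- len / m
      motif_here <- substr(s, st, st + m - 1L)
      period_ok <- !any(vapply(seq_len(m - 1), function(p)
        m %% p == 0 && motif_here == strrep(substr(motif_here, 1, p), m / p),
        logical(1)))
      if (len >= min_total_len && copies >= min_copies[[as.character(m)]] &&
          period_ok)
        cand[[length(cand) + 1L]] <- data.frame(start = st,
                                                end = st + len - 1L,
                                                motif_len = m,
                                                copies = copies)
    }
  }
  if (!length(cand)) return(NULL)
  df <- unique(do.call(rbind, cand))
  df <- df[order(-(df$end - df$start + 1L), df$motif_len, df$start), ,
           drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  taken <- IRanges()
  for (i in seq_len(nrow(df))) {
    r <- IRanges(df$start[i], df$end[i])
    if (!length(findOverlaps(r, taken))) { keep[i] <- TRUE; taken <- c(taken, r) }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

# naive full-scan primer site finder (uniqueness oracle)
oraclePrimerSites <- function(primer, s, max_mismatch) {
  n <- nchar(s); L <- nchar(primer)
  hits <- list()
  pv <- strsplit(primer, "")[[1]]
  rv <- strsplit(revComp(primer), "")[[1]]
  sv <- strsplit(s, "")[[1]]
  for (st in seq_len(n - L + 1)) {
    seg <- sv[st:(st + L - 1)]
    mm <- sum(seg != pv)
    if (mm <= max_mismatch && seg[L] == pv[L])
      hits[[length(hits) + 1L]] <- data.frame(start = st, end = st + L - 1,
                                              strand = "+")
    mm <- sum(seg != rv)
    if (mm <= max_mismatch && seg[1] == rv[1])
      hits[[length(hits) + 1L]] <- data.frame(start = st, end = st + L - 1,
                                              strand = "-")
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}
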