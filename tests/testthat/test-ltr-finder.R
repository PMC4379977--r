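test_that("a single planted element is recovered with exact boundaries", {
  pg <- simulateBackground(15000, seed = 21)
  pg <- plantLtrElement(pg, pos = 6000, ltr_len = 300, internal_len = 1500,
                        divergence = 0, id = "e1", seed = 2)
  el <- findLtrPairs(pg)
  truth <- plantedElements(pg)
  expect_length(el, 1L)
  expect_equal(start(el), start(truth))
  expect_equal(end(el), end(truth))
  expect_equal(mcols(el)$ltr5_end, mcols(truth)$ltr5_end)
  expect_equal(mcols(el)$ltr3_start, mcols(truth)$ltr3_start)
  expect_equal(mcols(el)$ltr_identity, 1)
})

test_that("LTRs below the minimum length are not reported", {
  pg <- simulateBackground(15000, seed = 22)
  pg <- plantLtrElement(pg, pos = 6000, ltr_len = 90, internal_len = 1500,
                        divergence = 0, id = "short", seed = 2)
  expect_length(findLtrPairs(pg), 0L)
})

test_that("diverged multi-element genomes are recovered accurately", {
  hits <- 0L; total <- 0L; extra <- 0L
  for (seed in 1:3) {
    pg <- simulateTeGenome(length = 120000, n_elements = 6,
                           divergence = 0.02, seed = seed)
    el <- findLtrPairs(pg)
    truth <- plantedElements(pg)
    ov <- findOverlaps(granges(el), granges(truth))
    total <- total + length(truth)
    extra <- extra + (length(el) - length(unique(queryHits(ov))))
    for (k in seq_len(length(ov))) {
      i <- queryHits(ov)[k]; j <- subjectHits(ov)[k]
      if (abs(start(el)[i] - start(truth)[j]) <= 5 &&
          abs(end(el)[i] - end(truth)[j]) <= 5) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(extra, 1L)
})

test_that("every reported element satisfies the structural invariants", {
  p <- ltrParams()
  for (seed in c(31, 32)) {
    pg <- simulateTeGenome(length = 60000, n_elements = 3,
                           divergence = 0.05, seed = seed)
    el <- findLtrPairs(pg)
    s <- as.character(genomeSequences(pg)[[1]])
    m <- mcols(el)
    for (i in seq_along(el)) {
      L5 <- m$ltr5_end[i] - m$ltr5_start[i] + 1L
      L3 <- m$ltr3_end[i] - m$ltr3_start[i] + 1L
      expect_true(L5 >= p$min_ltr_len && L5 <= p$max_ltr_len)
      expect_true(L3 >= p$min_ltr_len && L3 <= p$max_ltr_len)
      expect_lte(m$ltr3_start[i] - m$ltr5_end[i] - 1L, p$max_ltr_distance)
      expect_lt(m$ltr5_end[i], m$ltr3_start[i])
      expect_match(substr(s, m$ltr5_start[i], m$ltr5_start[i] + 1L), "TG")
      expect_match(substr(s, m$ltr3_end[i] - 1L, m$ltr3_end[i]), "CA")
      expect_gte(m$ltr_identity[i], p$min_ltr_identity)
    }
  }
})

test_that("detection is strand-symmetric", {
  pg <- simulateTeGenome(length = 50000, n_elements = 2, divergence = 0.02,
                         seed = 9)
  el <- findLtrPairs(pg)
  n <- nchar(as.character(genomeSequences(pg)[[1]]))
  rc <- Biostrings::reverseComplement(genomeSequences(pg))
  names(rc) <- names(genomeSequences(pg))
  el_rc <- findLtrPairs(rc)
  expect_equal(length(el_rc), length(el))
  # mirrored coordinates: start' = n - end + 1
  expect_equal(sort(n - end(el) + 1L), sort(start(el_rc)))
  expect_equal(sort(n - start(el) + 1L), sort(end(el_rc)))
})

test_that("raising the identity threshold never adds elements", {
  for (seed in c(51, 52)) {
    pg <- simulateTeGenome(length = 60000, n_elements = 3, divergence = 0.1,
                           seed = seed)
    n_loose <- length(findLtrPairs(pg, ltrParams(min_ltr_identity = 0.8)))
    n_strict <- length(findLtrPairs(pg, ltrParams(min_ltr_identity = 0.95)))
    expect_lte(n_strict, n_loose)
  }
})

test_that("TSD detection returns the longest shared flank", {
  pg <- simulateBackground(9000, seed = 61)
  pg <- plantLtrElement(pg, pos = 4000, ltr_len = 150, internal_len = 400,
                        divergence = 0, tsd_len = 5, id = "e1", seed = 3)
  el <- findLtrPairs(pg)
  truth <- plantedElements(pg)
  expect_identical(detectTsd(pg, el), mcols(truth)$tsd)

  # randomized flanks: no TSD
  s <- paste0(rdna(300, seed = 1), "TG", rdna(146), "CA", rdna(400), "TG",
              rdna(146), "CA", rdna(300))
  fake <- LtrElementSet(GRanges("chr1", IRanges(301, 301 + 150 + 400 + 150 - 1),
                                id = "f", ltr5_start = 301L, ltr5_end = 450L,
                                ltr3_start = 851L, ltr3_end = 1000L,
                                ltr_identity = 1))
  expect_true(is.na(detectTsd(s, fake)))

  # flanks sharing a 4-mer and a 5-mer: the longest wins; verified against
  # exhaustive window enumeration
  core <- paste0("TG", rdna(146, seed = 8), "CA", rdna(200), "TG", rdna(146),
                 "CA")
  s2 <- paste0(rdna(100), "GATTC", core, "GATTC", rdna(100))
  fake2 <- LtrElementSet(GRanges("chr1",
                                 IRanges(106, 105 + nchar(core)),
                                 id = "f2", ltr5_start = 106L,
                                 ltr5_end = 255L,
                                 ltr3_start = as.integer(105 + nchar(core) - 149),
                                 ltr3_end = as.integer(105 + nchar(core)),
                                 ltr_identity = 1))
  found <- detectTsd(s2, fake2)
  oracle <- NULL
  for (L in 6:4) {
    left <- substr(s2, 106 - L, 105)
    right <- substr(s2, 106 + nchar(core), 105 + nchar(core) + L)
    if (left == right) { oracle <- left; break }
  }
  expect_identical(found, oracle)
  expect_identical(found, "GATTC")
})

test_that("PBS and PPT detection honour their thresholds", {
  pg <- simulateBackground(9000, seed = 71)
  pg <- plantLtrElement(pg, pos = 4000, ltr_len = 200, internal_len = 600,
                        divergence = 0, id = "e1", seed = 4)
  el <- findLtrPairs(pg)
  pbs <- detectPbs(pg, el)
  expect_equal(pbs$pbs_trna, "trna_iMet")
  expect_gte(pbs$pbs_end - pbs$pbs_start + 1L, 12L)
  expect_warning(detectPbs(pg, el, Biostrings::DNAStringSet()), "empty")

  ppt <- detectPpt(pg, el)
  expect_false(is.na(ppt$ppt_start))
  expect_gte(ppt$ppt_purine, 0.8)

  # hand-built windows: all-pyrimidine -> none; 15 bp with exactly 12
  # purines (fraction 0.80) -> detected, threshold inclusive
  mkfake <- function(window20) {
    s <- paste0(rdna(50, seed = 5), "TG", rdna(146), "CA",
                paste(rep("C", 30), collapse = ""), window20,
                "TG", rdna(146), "CA", rdna(50))
    l3s <- 50 + 150 + 30 + 20 + 1
    fk <- LtrElementSet(GRanges("chr1", IRanges(51, l3s + 149),
                                id = "w", ltr5_start = 51L, ltr5_end = 200L,
                                ltr3_start = as.integer(l3s),
                                ltr3_end = as.integer(l3s + 149),
                                ltr_identity = 1))
    list(seq = s, el = fk)
  }
  pyr <- mkfake(paste(rep(c("C", "T"), 10), collapse = ""))
  expect_true(is.na(detectPpt(pyr$seq, pyr$el)$ppt_start))

  win <- paste0("CCTTT", "AGAGAGAGAGAG", "TTT")  # 20bp; best run = 15bp, 12 purines
  bnd <- mkfake(win)
  res <- detectPpt(bnd$seq, bnd$el)
  expect_false(is.na(res$ppt_start))
  expect_equal(res$ppt_end - res$ppt_start + 1L, 15L)
  expect_equal(res$ppt_purine, 0.8)
})

test_that("superfamily classification follows pol domain order", {
  for (sf in c("Copia", "Gypsy")) {
    pg <- simulateBackground(9000, seed = 81)
    pg <- plantLtrElement(pg, pos = 4000, ltr_len = 200, internal_len = 700,
                          divergence = 0, superfamily = sf, id = "e1",
                          seed = 6)
    el <- findLtrPairs(pg)
    expect_equal(classifySuperfamily(pg, el), sf)
  }
  # motif-free internal region: unknown
  s <- paste0(rdna(200, seed = 9), "TG", rdna(146), "CA", rdna(500), "TG",
              rdna(146), "CA", rdna(200))
  fake <- LtrElementSet(GRanges("chr1", IRanges(201, 1000),
                                id = "f", ltr5_start = 201L, ltr5_end = 350L,
                                ltr3_start = 851L, ltr3_end = 1000L,
                                ltr_identity = 1))
  expect_equal(classifySuperfamily(s, fake), "unknown")
})

test_that("LTR pair extraction slices the recorded intervals exactly", {
  pg <- simulateBackground(9000, seed = 91)
  pg <- plantLtrElement(pg, pos = 4000, ltr_len = 180, internal_len = 500,
                        divergence = 0, id = "e1", seed = 7)
  el <- findLtrPairs(pg)
  pair <- extractLtrPairSequences(pg, el)
  expect_identical(unname(pair[1, "ltr5"]), unname(pair[1, "ltr3"]))
  expect_equal(unname(nchar(pair[1, "ltr5"])),
               mcols(el)$ltr5_end - mcols(el)$ltr5_start + 1L)
  truth <- plantedElements(pg)
  s <- as.character(genomeSequences(pg)[[1]])
  expect_identical(unname(pair[1, "ltr5"]),
                   substr(s, mcols(truth)$ltr5_start, mcols(truth)$ltr5_end))
})
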