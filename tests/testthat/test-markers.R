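# shared fixture: one DNA transposon and two LTR elements on 40 kb
markerFixture <- function() {
  pg <- simulateBackground(40000, seed = 401)
  set.seed(402)
  dna_seq <- rdna(600)
  pg <- plantRepeat(pg, pos = 5000, seq = dna_seq, te_class = "DNA",
                    subclass = "PIF-Harbinger", id = "dna1")
  pg <- plantLtrElement(pg, pos = 15000, ltr_len = 300, internal_len = 1200,
                        divergence = 0, id = "ltrA", seed = 403)
  pg <- plantLtrElement(pg, pos = 19000, ltr_len = 300, internal_len = 1200,
                        divergence = 0, id = "ltrB", seed = 404)
  el <- findLtrElements(pg)
  truth <- plantedElements(pg)
  dna <- truth[mcols(truth)$id == "dna1"]
  ann <- suppressWarnings(c(
    granges(ltrAsRepeatAnnotations(el)),
    GRanges("chr1", IRanges(start(dna), end(dna)))))
  mcols(ann) <- rbind(mcols(ltrAsRepeatAnnotations(el)),
                      DataFrame(id = "dna1", te_class = "DNA",
                                subclass = "PIF-Harbinger",
                                completeness = "full", source = "file"))
  list(pg = pg, el = el, ann = RepeatAnnotations(ann),
       chrom_len = nchar(as.character(genomeSequences(pg)[[1]])))
}

test_that("junction markers have the required geometry and precedence", {
  fx <- markerFixture()
  j <- findRepeatJunctions(fx$ann, c(chr1 = fx$chrom_len))
  mk <- designJunctionMarkers(genomeSequences(fx$pg), j, fx$ann,
                              types = c("RJM", "ISBP"))
  tab <- markerTable(mk)
  prod <- productTable(mk)

  # the DNA transposon contributes RJMs, the LTR junctions ISBPs
  dna_j <- j$pos[!is.na(j$left_annotation) & j$left_annotation == "dna1" |
                   !is.na(j$right_annotation) & j$right_annotation == "dna1"]
  rjm <- tab[tab$type == "RJM", ]
  expect_equal(nrow(rjm), 2L)
  expect_setequal(unlist(rjm$junctions), dna_j)
  expect_true(all(tab$type[tab$te_type %in% c("Copia", "Gypsy")] == "ISBP"))

  # every amplicon contains its junction position(s)
  for (i in seq_len(nrow(tab))) {
    p <- prod[prod$marker_id == tab$marker_id[i] &
                prod$configuration == "primary", ]
    for (jp in unlist(tab$junctions[i]))
      expect_true(p$start <= jp && jp + 1 <= p$end)
  }

  # type labels match a brute-force classifier from primer/annotation
  # geometry: exactly one junction spanned; repeat side LTR -> ISBP
  pr <- primerTable(mk)
  for (i in seq_len(nrow(tab))) {
    p <- prod[prod$marker_id == tab$marker_id[i] &
                prod$configuration == "primary", ]
    spanned <- j$pos[j$chrom == p$chrom & j$pos >= p$start &
                       j$pos + 1 <= p$end]
    expect_equal(length(spanned), length(unlist(tab$junctions[i])))
    side_ids <- c(j$left_annotation[j$pos %in% spanned],
                  j$right_annotation[j$pos %in% spanned])
    side_cls <- mcols(fx$ann)$te_class[mcols(fx$ann)$id %in% side_ids]
    want <- if (any(side_cls %in% c("Copia", "Gypsy"))) "ISBP" else "RJM"
    expect_equal(tab$type[i], want)
  }
})

test_that("a short repeat with unique flanks yields an RJJM over both junctions", {
  pg <- simulateBackground(20000, seed = 405)
  set.seed(406)
  pg <- plantRepeat(pg, pos = 9000, seq = rdna(150), te_class = "DNA",
                    subclass = "Stowaway", id = "short1")
  ann <- mkAnn("chr1", 9000, 9149, ids = "short1", subclass = "Stowaway")
  j <- findRepeatJunctions(ann, c(chr1 = 20150L))
  mk <- designJunctionMarkers(genomeSequences(pg), j, ann, types = "RJJM")
  tab <- markerTable(mk)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$type, "RJJM")
  expect_equal(sort(unlist(tab$junctions)), c(8999L, 9149L))
  p <- productTable(mk)
  expect_true(p$start <= 8999 && p$end >= 9150)
})

test_that("RBIP / IRAP / REMAP follow their distance rules", {
  fx <- markerFixture()
  s <- as.character(genomeSequences(fx$pg)[[1]])
  ssrs <- findSsrs(s)
  ssrs$chrom <- rep("chr1", nrow(ssrs))
  mk <- designRetroelementMarkers(genomeSequences(fx$pg), fx$el, ssrs)
  tab <- markerTable(mk)

  # RBIP: one per element, three primers, two predicted configurations
  rbip <- tab[tab$type == "RBIP", ]
  expect_equal(nrow(rbip), 2L)
  for (id in rbip$marker_id) {
    expect_equal(sum(primerTable(mk)$marker_id == id), 3L)
    cfg <- productTable(mk)$configuration[productTable(mk)$marker_id == id]
    expect_setequal(cfg, c("occupied", "empty_site"))
  }

  # IRAP: gap between the two planted elements is ~2.2 kb (< 3 kb default)
  irap <- tab[tab$type == "IRAP", ]
  expect_equal(nrow(irap), 1L)
  # raising the elements' separation beyond the cap removes the IRAP
  mk_tight <- designRetroelementMarkers(genomeSequences(fx$pg), fx$el,
                                        types = "IRAP", irap_max_gap = 1000)
  expect_equal(nrow(markerTable(mk_tight)), 0L)
})

test_that("REMAP pairs an LTR primer with an anchored SSR primer", {
  pg <- simulateBackground(20000, seed = 407)
  pg <- plantLtrElement(pg, pos = 8000, ltr_len = 300, internal_len = 1200,
                        divergence = 0, id = "e1", seed = 408)
  el0 <- findLtrElements(pg)
  pg <- plantSsr(pg, pos = end(el0)[1] + 800, motif = "GA", copies = 12,
                 id = "s1")
  el <- findLtrElements(pg)
  s <- as.character(genomeSequences(pg)[[1]])
  ssrs <- findSsrs(s)
  ssrs <- ssrs[ssrs$motif == "AG", , drop = FALSE]
  ssrs$chrom <- "chr1"
  mk <- designRetroelementMarkers(genomeSequences(pg), el, ssrs,
                                  types = "REMAP")
  tab <- markerTable(mk)
  expect_equal(nrow(tab), 1L)
  pr <- primerTable(mk)
  expect_setequal(pr$role, c("ltr_out", "ssr_anchor"))
  # product covers the LTR-to-SSR interval
  p <- productTable(mk)
  truth <- plantedElements(pg)
  ssr_t <- truth[mcols(truth)$id == "s1"]
  expect_lte(p$start, end(el)[1])
  expect_gte(p$end, start(ssr_t))
  # anchored primer matches the genome exactly at its recorded site
  anch <- pr[pr$role == "ssr_anchor", ]
  expect_identical(revComp(anch$seq), substr(s, anch$start, anch$end))
})

test_that("in-silico PCR reproduces designed products and their absence", {
  fx <- markerFixture()
  j <- findRepeatJunctions(fx$ann, c(chr1 = fx$chrom_len))
  mk <- designJunctionMarkers(genomeSequences(fx$pg), j, fx$ann,
                              types = "RJM")
  tab <- markerTable(mk)
  pr <- primerTable(mk)
  id <- tab$marker_id[1]
  rec <- productTable(mk)
  rec <- rec[rec$marker_id == id, ]
  prod <- inSilicoPcr(pr$seq[pr$marker_id == id], genomeSequences(fx$pg))
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$start, rec$start)
  expect_equal(prod$end, rec$end)
  expect_equal(prod$size, rec$size)

  # deleting the element (flanks rejoined) removes the RJM product
  pg_del <- deletePlantedElement(fx$pg, "dna1")
  prod_del <- inSilicoPcr(pr$seq[pr$marker_id == id],
                          genomeSequences(pg_del))
  expect_equal(nrow(prod_del), 0L)

  # a duplicated locus yields two products
  s <- as.character(genomeSequences(fx$pg)[[1]])
  locus <- substr(s, rec$start - 50, rec$end + 50)
  dup <- Biostrings::DNAStringSet(paste0(s, locus))
  names(dup) <- "chr1"
  prod_dup <- inSilicoPcr(pr$seq[pr$marker_id == id], dup)
  expect_equal(nrow(prod_dup), 2L)
})

test_that("marker closure holds for every designed marker", {
  fx <- markerFixture()
  j <- findRepeatJunctions(fx$ann, c(chr1 = fx$chrom_len))
  s <- as.character(genomeSequences(fx$pg)[[1]])
  ssrs <- findSsrs(s); ssrs$chrom <- rep("chr1", nrow(ssrs))
  mk_j <- designJunctionMarkers(genomeSequences(fx$pg), j, fx$ann)
  mk_r <- designRetroelementMarkers(genomeSequences(fx$pg), fx$el, ssrs)
  for (mk in list(mk_j, mk_r)) {
    tab <- markerTable(mk)
    pr <- primerTable(mk)
    prod_rec <- productTable(mk)
    for (id in tab$marker_id) {
      rec <- prod_rec[prod_rec$marker_id == id &
                        prod_rec$configuration %in% c("primary", "occupied"), ]
      got <- inSilicoPcr(pr$seq[pr$marker_id == id],
                         genomeSequences(fx$pg),
                         max_product = max(3000, rec$size))
      hit <- got[got$start == rec$start & got$end == rec$end, ]
      expect_equal(nrow(hit), 1L, info = id)
    }
  }
})

test_that("uniqueness flags flip with planted duplications", {
  pg <- simulateBackground(30000, seed = 409)
  set.seed(410)
  pg <- plantRepeat(pg, pos = 8000, seq = rdna(600), te_class = "DNA",
                    subclass = "hAT-Ac", id = "d1")
  ann <- mkAnn("chr1", 8000, 8599, ids = "d1", subclass = "hAT-Ac")
  j <- findRepeatJunctions(ann, c(chr1 = 30600L))
  mk <- designJunctionMarkers(genomeSequences(pg), j, ann, types = "RJM")
  mku <- checkUniqueness(mk, genomeSequences(pg))
  expect_true(all(markerTable(mku)$unique_flag))
  expect_true(all(markerTable(mku)$hit_loci == 1L))

  # plant an exact second copy of TE + flanks: markers become non-unique
  s <- as.character(genomeSequences(pg)[[1]])
  copy <- substr(s, 7300, 9300)
  dup <- Biostrings::DNAStringSet(paste0(s, rdna(500), copy))
  names(dup) <- "chr1"
  mkd <- checkUniqueness(mk, dup)
  expect_false(any(markerTable(mkd)$unique_flag))
  expect_true(all(markerTable(mkd)$hit_loci == 2L))
})

test_that("uniqueness screening equals the full-scan oracle on 50 kb", {
  pg <- simulateBackground(50000, seed = 411)
  set.seed(412)
  pg <- plantRepeat(pg, pos = 20000, seq = rdna(500), te_class = "DNA",
                    subclass = "MULE-MuDR", id = "d1")
  ann <- mkAnn("chr1", 20000, 20499, ids = "d1", subclass = "MULE-MuDR")
  j <- findRepeatJunctions(ann, c(chr1 = 50500L))
  mk <- designJunctionMarkers(genomeSequences(pg), j, ann, types = "RJM")
  s <- as.character(genomeSequences(pg)[[1]])
  mku <- checkUniqueness(mk, genomeSequences(pg))
  tab <- markerTable(mku)
  pr <- primerTable(mku)
  for (i in seq_len(nrow(tab))) {
    pp <- pr$seq[pr$marker_id == tab$marker_id[i]]
    sites <- lapply(pp, oraclePrimerSites, s = s, max_mismatch = 2)
    prods <- list()
    for (a in seq_along(pp)) for (b in seq_along(pp)) {
      fa <- sites[[a]]; rb <- sites[[b]]
      if (is.null(fa) || is.null(rb)) next
      fa <- fa[fa$strand == "+", , drop = FALSE]
      rb <- rb[rb$strand == "-", , drop = FALSE]
      for (x in seq_len(nrow(fa))) for (y in seq_len(nrow(rb))) {
        sz <- rb$end[y] - fa$start[x] + 1
        if (sz >= 1 && sz <= 2000 && rb$start[y] >= fa$start[x])
          prods[[length(prods) + 1L]] <- c(fa$start[x], rb$end[y])
      }
    }
    loci <- reduce(IRanges(vapply(prods, `[`, numeric(1), 1),
                           vapply(prods, `[`, numeric(1), 2)))
    expect_equal(tab$unique_flag[i], length(loci) == 1L)
    expect_equal(tab$hit_loci[i], length(loci))
  }
})

test_that("deleting a planted TE flips marker bands as expected", {
  pg <- simulateBackground(30000, seed = 413)
  pg <- plantLtrElement(pg, pos = 12000, ltr_len = 300, internal_len = 1200,
                        divergence = 0, id = "e1", seed = 414)
  el <- findLtrElements(pg)
  mk <- designRetroelementMarkers(genomeSequences(pg), el, types = "RBIP")
  pr <- primerTable(mk)
  rec <- productTable(mk)
  occ <- rec[rec$configuration == "occupied", ]
  emp <- rec[rec$configuration == "empty_site", ]

  on_src <- inSilicoPcr(pr$seq, genomeSequences(pg))
  expect_true(any(on_src$size == occ$size))     # occupied band present
  expect_false(any(on_src$size == emp$size))    # empty-site band absent

  pg_del <- deletePlantedElement(pg, "e1")
  on_del <- inSilicoPcr(pr$seq, genomeSequences(pg_del))
  expect_false(any(on_del$size == occ$size))    # occupied band gone
  expect_true(any(on_del$size == emp$size))     # empty-site band appears
})

test_that("LINE RJMs anchor one primer in a flanking exon", {
  pg <- simulateBackground(20000, seed = 415)
  pg <- plantGeneModel(pg, pos = 8000, exon_lengths = c(600, 600),
                       intron_lengths = 400, gene_id = "g1")
  set.seed(416)
  pg <- plantRepeat(pg, pos = 8800, seq = rdna(700), te_class = "LINE",
                    id = "L1")
  truth <- plantedElements(pg)
  lr <- truth[mcols(truth)$id == "L1"]
  lines_ann <- mkAnn("chr1", start(lr), end(lr), ids = "L1",
                     te_class = "LINE", subclass = NA_character_)
  mk <- designLineRjm(genomeSequences(pg), lines_ann, plantedGenes(pg))
  tab <- markerTable(mk)
  expect_equal(nrow(tab), 1L)
  pr <- primerTable(mk)
  exons <- plantedGenes(pg)
  in_exon <- vapply(seq_len(nrow(pr)), function(i)
    any(pr$start[i] >= start(exons) & pr$end[i] <= end(exons)), logical(1))
  in_te <- pr$start >= start(lr) & pr$end <= end(lr)
  expect_equal(sum(in_exon), 1L)
  expect_equal(sum(in_te), 1L)
  # the amplicon spans the exon-side TE junction
  p <- productTable(mk)
  jp <- unlist(tab$junctions)
  expect_true(p$start <= jp && jp + 1 <= p$end)

  # a LINE with no nearby gene yields nothing
  pg2 <- simulateBackground(20000, seed = 417)
  set.seed(418)
  pg2 <- plantRepeat(pg2, pos = 10000, seq = rdna(700), te_class = "LINE",
                     id = "L2")
  lines2 <- mkAnn("chr1", 10000, 10699, ids = "L2", te_class = "LINE",
                  subclass = NA_character_)
  mk2 <- designLineRjm(genomeSequences(pg2), lines2, GRanges())
  expect_equal(nrow(markerTable(mk2)), 0L)
})
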