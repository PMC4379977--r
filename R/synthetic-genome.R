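## Synthetic genomes with planted ground truth.
##
## Every planted feature records its exact interval so detector recall,
## precision and boundary error can be scored against truth with no other
## state.  Insertions shift previously planted coordinates: any recorded
## base coordinate c becomes c + L when an insert of length L lands at a
## position <= c.

# conserved pol-domain peptide motifs used both by the generator (encoded
# with random synonymous codons) and by the superfamily classifier; a small
# built-in consensus set, user-extensible in classifySuperfamily()
.DOMAIN_MOTIFS <- c(GAG = "MAQSKG", PR = "LLDSGA", INT_core = "HETGHW",
                    INT_cterm = "WKEPFK", RT = "LYVDDM", RH = "IDSGAS")
.DOMAIN_ORDER <- list(
  Copia = c("GAG", "PR", "INT_core", "INT_cterm", "RT", "RH"),
  Gypsy = c("GAG", "PR", "RT", "RH", "INT_core", "INT_cterm"))

.randomDna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# encode a peptide with uniformly sampled synonymous codons
.encodePeptide <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  aas <- strsplit(pep, "", fixed = TRUE)[[1]]
  paste(vapply(aas, function(a) {
    cods <- names(gc)[gc == a]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

#' Path to the bundled tRNA 3'-terminus library
#'
#' A minimal synthetic library of tRNA 3' termini (each ending in CCA) used
#' for primer-binding-site detection; replace with a species-specific
#' library for real genomes.
#' @export
defaultTrnaLibrary <- function() {
  system.file("extdata", "trna_3prime_synthetic.fasta", package = "temark",
              mustWork = TRUE)
}

#' Simulate an i.i.d. background genome
#'
#' @param length sequence length in bp.
#' @param gc GC content in \code{[0,1]}; P(G)+P(C) = gc.
#' @param seed integer seed; the same seed reproduces the same sequence.
#'   \code{NULL} leaves the RNG state untouched.
#' @param name chromosome name.
#' @return a \code{\link{PlantedGenome}} with one chromosome and no planted
#'   features.
#' @export
simulateBackground <- function(length, gc = 0.44, seed = NULL, name = "chr1") {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  seqs <- Biostrings::DNAStringSet(.randomDna(length, gc))
  names(seqs) <- name
  PlantedGenome(seqs)
}

# insert `insert` before the base at `pos` (1-based); shift recorded truth.
# Returns list(pg, hosts): ids of planted elements strictly containing pos.
.insertAt <- function(pg, chrom, pos, insert) {
  seqs <- pg@sequences
  s <- chromSeq(seqs, chrom)
  n <- nchar(s)
  if (pos < 1 || pos > n + 1) stop("insertion position out of range")
  L <- nchar(insert)
  s2 <- paste0(substr(s, 1, pos - 1), insert, substr(s, pos, n))
  seqs[[chrom]] <- Biostrings::DNAString(s2)

  shift1 <- function(c) ifelse(!is.na(c) & c >= pos, c + L, c)
  el <- pg@elements
  hosts <- character(0)
  if (length(el)) {
    on_chrom <- as.character(seqnames(el)) == chrom
    hosts <- mcols(el)$id[on_chrom & start(el) < pos & end(el) >= pos]
    st <- start(el); en <- end(el)
    st[on_chrom] <- shift1(st[on_chrom])
    en[on_chrom] <- shift1(en[on_chrom])
    IRanges::ranges(el) <- IRanges(st, en)
    for (col in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
      if (!is.null(mcols(el)[[col]]))
        mcols(el)[[col]][on_chrom] <- shift1(mcols(el)[[col]][on_chrom])
  }
  gn <- pg@genes
  if (length(gn)) {
    on_chrom <- as.character(seqnames(gn)) == chrom
    st <- start(gn); en <- end(gn)
    st[on_chrom] <- shift1(st[on_chrom])
    en[on_chrom] <- shift1(en[on_chrom])
    IRanges::ranges(gn) <- IRanges(st, en)
  }
  list(pg = new("PlantedGenome", sequences = seqs, elements = el, genes = gn),
       hosts = hosts)
}

.elementGr <- function(chrom, start, end, meta) {
  gr <- GRanges(chrom, IRanges(start, end))
  base <- list(id = NA_character_, kind = NA_character_, tsd = NA_character_,
               divergence = NA_real_, ltr5_start = NA_integer_,
               ltr5_end = NA_integer_, ltr3_start = NA_integer_,
               ltr3_end = NA_integer_, tir_len = NA_integer_,
               subclass = NA_character_, motif = NA_character_,
               copies = NA_real_, host_id = NA_character_, seed = NA_integer_)
  base[names(meta)] <- meta
  mcols(gr) <- DataFrame(base)
  gr
}

.addElement <- function(pg, gr) {
  el <- if (length(pg@elements)) suppressWarnings(c(pg@elements, gr)) else gr
  new("PlantedGenome", sequences = pg@sequences, elements = el,
      genes = pg@genes)
}

.checkNotInsideElement <- function(pg, chrom, pos, what) {
  el <- pg@elements
  if (!length(el)) return(invisible())
  on_chrom <- as.character(seqnames(el)) == chrom
  inside <- on_chrom & start(el) < pos & end(el) >= pos
  if (any(inside))
    stop(what, " position ", pos, " lies inside planted element ",
         mcols(el)$id[inside][1])
}

# substitute bases at per-site rate `rate`; first/last `protect` bp untouched
# so the terminal dinucleotides always survive
.mutate <- function(seq, rate, protect = 2L) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  idx <- which(runif(n) < rate)
  idx <- idx[idx > protect & idx <= n - protect]
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Plant a full-length LTR retrotransposon
#'
#' Inserts \code{[TSD][LTR5][internal][LTR3][TSD]} at \code{pos}.  Both LTRs
#' start with TG and end with CA; the 3' LTR is the 5' LTR with point
#' substitutions at per-site rate \code{divergence} (the terminal
#' dinucleotides are protected so planted elements always satisfy the
#' full-length definition).  The internal region carries a primer-binding
#' site complementary to the bundled tRNA-iMet 3' terminus just inside the
#' 5' LTR, superfamily-ordered pol domain motifs, and a polypurine tract
#' just inside the 3' LTR.  The target-site duplication is duplicated
#' exactly.
#'
#' @param pg a \code{\link{PlantedGenome}}.
#' @param chrom chromosome name.
#' @param pos 1-based insertion point (insert goes before this base).
#' @param ltr_len LTR length (>= 10).
#' @param internal_len internal region length (>= 120).
#' @param divergence per-site substitution rate between the LTRs, in
#'   \code{[0, 0.5)}.
#' @param tsd_len target-site duplication length.
#' @param superfamily \code{"Copia"} or \code{"Gypsy"} (domain order).
#' @param seed optional integer seed (recorded in truth metadata).
#' @param id element id; autogenerated when \code{NULL}.
#' @return the updated \code{PlantedGenome}; the new truth row records the
#'   element span (TSDs excluded) and both LTR intervals.
#' @export
plantLtrElement <- function(pg, chrom = "chr1", pos, ltr_len = 300,
                            internal_len = 2000, divergence = 0.02,
                            tsd_len = 5, superfamily = c("Copia", "Gypsy"),
                            seed = NULL, id = NULL) {
  superfamily <- match.arg(superfamily)
  if (ltr_len < 10) stop("ltr_len must be >= 10")
  if (divergence < 0 || divergence >= 0.5) stop("divergence must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  .checkNotInsideElement(pg, chrom, pos, "LTR element")

  ltr5 <- paste0("TG", .randomDna(ltr_len - 4), "CA")
  ltr3 <- .mutate(ltr5, divergence)

  trna <- .readFastaCached(defaultTrnaLibrary())
  imet <- as.character(trna[["trna_iMet"]])
  pbs <- revComp(substr(imet, nchar(imet) - 17, nchar(imet)))  # 18 bp
  ppt <- paste(sample(c("A", "G"), 16, replace = TRUE), collapse = "")
  doms <- vapply(.DOMAIN_ORDER[[superfamily]],
                 function(d) .encodePeptide(.DOMAIN_MOTIFS[[d]]), character(1))
  dom_dna <- paste(vapply(doms, function(d) paste0(d, .randomDna(9)),
                          character(1)), collapse = "")
  core <- paste0(pbs, .randomDna(10), dom_dna)
  filler <- internal_len - nchar(core) - nchar(ppt) - 4
  if (filler < 0)
    stop("internal_len too short; need >= ", nchar(core) + nchar(ppt) + 4)
  internal <- paste0(core, .randomDna(filler), ppt, .randomDna(4))
  tsd <- .randomDna(tsd_len)

  ins <- paste0(tsd, ltr5, internal, ltr3, tsd)
  res <- .insertAt(pg, chrom, pos, ins)
  pg <- res$pg

  el_start <- pos + tsd_len
  l5s <- el_start
  l5e <- l5s + ltr_len - 1L
  l3s <- l5e + internal_len + 1L
  l3e <- l3s + ltr_len - 1L
  if (is.null(id)) id <- paste0("planted_ltr", length(pg@elements) + 1L)
  gr <- .elementGr(chrom, el_start, l3e,
                   list(id = id, kind = paste0("LTR_", superfamily),
                        tsd = tsd, divergence = divergence,
                        ltr5_start = as.integer(l5s), ltr5_end = as.integer(l5e),
                        ltr3_start = as.integer(l3s), ltr3_end = as.integer(l3e),
                        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  .addElement(pg, gr)
}

#' Plant a DNA transposon (terminal inverted repeats + TSD)
#'
#' The element is \code{[TIR][core][revcomp(TIR)]} flanked by an exact
#' target-site duplication.  Planting inside a previously planted element is
#' allowed and recorded as a nested insertion (\code{host_id} set); the host
#' interval widens to contain the insert.
#'
#' @inheritParams plantLtrElement
#' @param length total element length (TIRs included).
#' @param tir_len terminal-inverted-repeat length.
#' @param subclass DNA-transposon subclass label (e.g. "PIF-Harbinger").
#' @export
plantDnaTransposon <- function(pg, chrom = "chr1", pos, length = 500,
                               tir_len = 20, tsd_len = 8,
                               subclass = "PIF-Harbinger", seed = NULL,
                               id = NULL) {
  if (length < 2 * tir_len + 1) stop("length must exceed twice tir_len")
  if (!is.null(seed)) set.seed(seed)
  tir <- .randomDna(tir_len)
  core <- .randomDna(length - 2 * tir_len)
  tsd <- .randomDna(tsd_len)
  ins <- paste0(tsd, tir, core, revComp(tir), tsd)
  res <- .insertAt(pg, chrom, pos, ins)
  pg <- res$pg
  el_start <- pos + tsd_len
  if (is.null(id)) id <- paste0("planted_dna", length(pg@elements) + 1L)
  gr <- .elementGr(chrom, el_start, el_start + length - 1L,
                   list(id = id, kind = "DNA_TIR", tsd = tsd,
                        tir_len = as.integer(tir_len), subclass = subclass,
                        host_id = if (length(res$hosts)) res$hosts[[1]] else NA_character_,
                        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  .addElement(pg, gr)
}

#' Plant a perfect microsatellite (SSR)
#'
#' @inheritParams plantLtrElement
#' @param motif repeat unit (1-6 bp).
#' @param copies integer number of copies.
#' @export
plantSsr <- function(pg, chrom = "chr1", pos, motif = "AG", copies = 10,
                     id = NULL) {
  .checkNotInsideElement(pg, chrom, pos, "SSR")
  ins <- strrep(motif, copies)
  res <- .insertAt(pg, chrom, pos, ins)
  pg <- res$pg
  if (is.null(id)) id <- paste0("planted_ssr", length(pg@elements) + 1L)
  gr <- .elementGr(chrom, pos, pos + nchar(ins) - 1L,
                   list(id = id, kind = "SSR", motif = motif,
                        copies = as.numeric(copies)))
  .addElement(pg, gr)
}

#' Plant an arbitrary repeat copy (e.g. a library element or fragment)
#'
#' Used to plant homology-detectable copies such as LINEs or truncated
#' library elements.  Nesting into a planted element records the host.
#'
#' @inheritParams plantLtrElement
#' @param seq the repeat sequence to insert.
#' @param te_class repeat class label recorded in truth.
#' @param subclass subclass label.
#' @export
plantRepeat <- function(pg, chrom = "chr1", pos, seq, te_class = "LINE",
                        subclass = NA_character_, id = NULL) {
  seq <- toupper(seq)
  res <- .insertAt(pg, chrom, pos, seq)
  pg <- res$pg
  if (is.null(id)) id <- paste0("planted_rep", length(pg@elements) + 1L)
  gr <- .elementGr(chrom, pos, pos + nchar(seq) - 1L,
                   list(id = id, kind = "repeat", subclass = subclass,
                        motif = te_class,
                        host_id = if (length(res$hosts)) res$hosts[[1]] else NA_character_))
  .addElement(pg, gr)
}

#' Plant a gene model (exons separated by introns)
#'
#' Inserts a random sequence of total length \code{sum(exon_lengths) +
#' sum(intron_lengths)} and records the exon intervals; introns are the
#' inter-exon gaps.
#'
#' @inheritParams plantLtrElement
#' @param exon_lengths integer vector of exon lengths (5' to 3').
#' @param intron_lengths integer vector of intron lengths; length must be
#'   \code{length(exon_lengths) - 1}.
#' @param gene_id gene identifier.
#' @export
plantGeneModel <- function(pg, chrom = "chr1", pos, exon_lengths,
                           intron_lengths = integer(0), gene_id = NULL,
                           seed = NULL) {
  if (length(intron_lengths) != length(exon_lengths) - 1)
    stop("need one intron length between each pair of exons")
  if (!is.null(seed)) set.seed(seed)
  .checkNotInsideElement(pg, chrom, pos, "gene model")
  total <- sum(exon_lengths) + sum(intron_lengths)
  res <- .insertAt(pg, chrom, pos, .randomDna(total))
  pg <- res$pg
  if (is.null(gene_id))
    gene_id <- paste0("gene", length(unique(mcols(pg@genes)$gene_id)) + 1L)
  starts <- pos + cumsum(c(0L, head(exon_lengths, -1) + intron_lengths))
  ex <- GRanges(chrom, IRanges(starts, width = exon_lengths), strand = "+")
  mcols(ex) <- DataFrame(gene_id = gene_id,
                         exon_rank = seq_along(exon_lengths))
  gn <- if (length(pg@genes)) suppressWarnings(c(pg@genes, ex)) else ex
  new("PlantedGenome", sequences = pg@sequences, elements = pg@elements,
      genes = gn)
}

#' Simulate a genome with planted full-length LTR retrotransposons
#'
#' Convenience generator for detector benchmarking: a background of
#' \code{length - n_elements * element_total} bp plus \code{n_elements}
#' planted elements at uniformly sampled, non-overlapping positions
#' (superfamilies alternate Copia/Gypsy), giving a final genome of
#' approximately \code{length} bp.
#'
#' @param length target total genome length (bp).
#' @param n_elements number of elements to plant.
#' @param min_gap minimum spacing between planted elements (bp).
#' @inheritParams plantLtrElement
#' @return a \code{\link{PlantedGenome}}.
#' @export
simulateTeGenome <- function(length = 200000, n_elements = 10, ltr_len = 300,
                             internal_len = 2000, divergence = 0.02,
                             tsd_len = 5, min_gap = 500, seed = 1) {
  set.seed(seed)
  el_total <- 2 * ltr_len + internal_len + 2 * tsd_len
  bg_len <- length - n_elements * el_total
  if (bg_len < (n_elements + 1) * min_gap)
    stop("genome too short for the requested elements")
  pg <- simulateBackground(bg_len, gc = 0.44)
  # positions in background coordinates, enforced spacing, planted
  # right-to-left so earlier positions stay valid
  repeat {
    pos <- sort(sample.int(bg_len - 2 * min_gap, n_elements) + min_gap)
    if (n_elements < 2 || all(diff(pos) >= min_gap)) break
  }
  for (i in rev(seq_len(n_elements))) {
    sf <- if (i %% 2 == 1) "Copia" else "Gypsy"
    pg <- plantLtrElement(pg, "chr1", pos[i], ltr_len = ltr_len,
                          internal_len = internal_len,
                          divergence = divergence, tsd_len = tsd_len,
                          superfamily = sf,
                          id = sprintf("planted_ltr%02d", i))
  }
  pg
}

#' Delete a planted element, rejoining the flanks
#'
#' Removes the element span plus one copy of its target-site duplication
#' (clean excision, the empty-allele convention used for RBIP scoring), or
#' both copies with \code{tsd_copies_removed = 2}.  Coordinates of the
#' remaining features shift accordingly; elements overlapping the deleted
#' range are dropped.
#'
#' @param pg a \code{\link{PlantedGenome}}.
#' @param id id of the element to delete.
#' @param tsd_copies_removed 1 (default) or 2.
#' @return the updated \code{PlantedGenome}.
#' @export
deletePlantedElement <- function(pg, id, tsd_copies_removed = 1) {
  el <- pg@elements
  i <- which(mcols(el)$id == id)
  if (!length(i)) stop("no planted element with id ", id)
  chrom <- as.character(seqnames(el)[i])
  tsd <- mcols(el)$tsd[i]
  tsd_len <- if (is.na(tsd)) 0L else nchar(tsd)
  del0 <- start(el)[i]
  del1 <- end(el)[i] + tsd_len
  if (tsd_copies_removed == 2) del0 <- del0 - tsd_len
  L <- del1 - del0 + 1L
  seqs <- pg@sequences
  s <- chromSeq(seqs, chrom)
  seqs[[chrom]] <- Biostrings::DNAString(
    paste0(substr(s, 1, del0 - 1L), substr(s, del1 + 1L, nchar(s))))
  shift1 <- function(c) ifelse(!is.na(c) & c > del1, c - L, c)
  keep <- rep(TRUE, length(el))
  on_chrom <- as.character(seqnames(el)) == chrom
  keep[on_chrom & start(el) <= del1 & end(el) >= del0] <- FALSE
  el2 <- el[keep]
  on2 <- as.character(seqnames(el2)) == chrom
  st <- start(el2); en <- end(el2)
  st[on2] <- shift1(st[on2]); en[on2] <- shift1(en[on2])
  IRanges::ranges(el2) <- IRanges(st, en)
  for (col in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
    if (!is.null(mcols(el2)[[col]]))
      mcols(el2)[[col]][on2] <- shift1(mcols(el2)[[col]][on2])
  gn <- pg@genes
  if (length(gn)) {
    ong <- as.character(seqnames(gn)) == chrom
    st <- start(gn); en <- end(gn)
    st[ong] <- shift1(st[ong]); en[ong] <- shift1(en[ong])
    IRanges::ranges(gn) <- IRanges(st, en)
  }
  new("PlantedGenome", sequences = seqs, elements = el2, genes = gn)
}

#' Write a planted genome and its ground truth to disk
#'
#' Emits \code{genome.fasta}, \code{truth.gff3} (planted elements and gene
#' exons) and \code{truth.json} (full element metadata).
#'
#' @param pg a \code{\link{PlantedGenome}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePlantedGenome <- function(pg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(pg@sequences, file.path(dir, "genome.fasta"))
  parts <- list()
  if (length(pg@elements)) {
    f <- granges(pg@elements)
    mcols(f)$type <- mcols(pg@elements)$kind
    mcols(f)$ID <- mcols(pg@elements)$id
    mcols(f)$Parent <- IRanges::CharacterList(vector("list", length(f)))
    parts$elements <- f
  }
  if (length(pg@genes)) {
    gene_ids <- unique(mcols(pg@genes)$gene_id)
    parents <- do.call(c, lapply(gene_ids, function(g) {
      ex <- pg@genes[mcols(pg@genes)$gene_id == g]
      GRanges(seqnames(ex)[1], IRanges(min(start(ex)), max(end(ex))),
              strand(ex)[1])
    }))
    mcols(parents)$type <- "gene"
    mcols(parents)$ID <- gene_ids
    mcols(parents)$Parent <- IRanges::CharacterList(
      vector("list", length(parents)))
    g <- granges(pg@genes)
    mcols(g)$type <- "exon"
    mcols(g)$ID <- paste0(mcols(pg@genes)$gene_id, ".exon",
                          mcols(pg@genes)$exon_rank)
    mcols(g)$Parent <- IRanges::CharacterList(
      as.list(mcols(pg@genes)$gene_id))
    parts$genes <- parents
    parts$exons <- g
  }
  feats <- if (length(parts)) do.call(c, unname(parts)) else GRanges()
  writeGff3(feats, file.path(dir, "truth.gff3"))
  jsonlite::write_json(
    as.data.frame(mcols(pg@elements)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
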