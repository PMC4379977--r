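## Homology-based repeat annotation.
##
## Masking runs NCBI blastn (bundled with the environment's BLAST+) in
## bl2seq mode with low-complexity filtering disabled, mirroring a
## RepeatMasker-style BLAST search that does not mask simple repeats or
## low-complexity DNA.

# parse te_class/subclass from library headers; supported forms:
#   name#Class/Subclass   (RepeatMasker library convention)
#   ... te_class=DNA subclass=PIF-Harbinger ltr=1-300  (key=value tags)
.libraryClass <- function(ids, descs = NULL) {
  n <- length(ids)
  cls <- rep("Unknown", n); sub <- rep(NA_character_, n)
  ltr0 <- rep(NA_integer_, n); ltr1 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    id <- ids[[i]]
    if (grepl("#", id, fixed = TRUE)) {
      tag <- sub("^[^#]*#", "", id)
      map <- .parseRmClass(tag)
      cls[i] <- map[, 1]; sub[i] <- map[, 2]
    }
    d <- if (!is.null(descs)) descs[[i]] else ""
    if (!is.na(d) && nzchar(d)) {
      kv <- regmatches(d, gregexpr("\\b[a-z_]+=[^ ]+", d))[[1]]
      for (x in kv) {
        key <- sub("=.*", "", x); val <- sub("^[^=]+=", "", x)
        if (key == "te_class") cls[i] <- val
        if (key == "subclass") sub[i] <- val
        if (key == "ltr") {
          parts <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
          ltr0[i] <- parts[1]; ltr1[i] <- parts[2]
        }
      }
    }
  }
  DataFrame(te_class = cls, subclass = sub, ltr_start = ltr0, ltr_end = ltr1)
}

# split library headers into id token + description so that ids match the
# qseqid tokens blast reports, whether the library came from a file (where
# readFasta already separates the description) or from memory
.normalizeLibrary <- function(lib) {
  full <- names(lib)
  ids <- sub("\\s.*$", "", full)
  extra <- ifelse(grepl("\\s", full), sub("^\\S+\\s*", "", full), "")
  meta <- metadata(lib)$description
  desc <- ifelse(nzchar(extra), extra,
                 if (!is.null(meta)) as.character(meta[ids]) else "")
  desc[is.na(desc)] <- ""
  names(lib) <- ids
  metadata(lib)$description <- setNames(desc, ids)
  lib
}

.blastn <- function(query_path, subject_path, word_size, evalue) {
  exe <- Sys.which("blastn")
  if (exe == "") stop("blastn not found on PATH")
  out <- system2(exe, c("-query", query_path, "-subject", subject_path,
                        "-word_size", word_size, "-evalue",
                        format(evalue, scientific = TRUE),
                        "-dust", "no", "-soft_masking", "false",
                        "-outfmt",
                        shQuote(paste("6 qseqid sseqid pident length qstart",
                                      "qend sstart send evalue bitscore qlen"))),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("blastn failed: ", paste(out, collapse = "\n"))
  out <- out[!grepl("^Warning", out)]
  if (!length(out)) return(NULL)
  df <- read.delim(text = out, header = FALSE,
                   col.names = c("qseqid", "sseqid", "pident", "length",
                                 "qstart", "qend", "sstart", "send",
                                 "evalue", "bitscore", "qlen"))
  df
}

#' Annotate a genome by homology to a repeat library
#'
#' Local alignment (blastn, word size \code{word_size}, no low-complexity
#' masking) of each library entry against the genome.  Hits with e-value at
#' most \code{min_evalue_all} are reported; within each locus (overlapping
#' hit block) the best hit is flagged \code{top} only when its e-value is at
#' most \code{min_evalue_top}.  Completeness is \code{full} when the hit
#' covers at least \code{full_coverage_min} of the library entry (see
#' \code{\link{callSoloPartial}} for solo-LTR refinement).
#'
#' @param genome sequences (see \code{\link{findLtrPairs}}).
#' @param library repeat library: path to FASTA or named
#'   \code{DNAStringSet}; class labels are parsed from headers
#'   (\code{name#Class/Subclass}) or \code{te_class=}/\code{subclass=}/
#'   \code{ltr=start-end} tags.
#' @param min_evalue_top e-value cutoff for the top hit (1e-50).
#' @param min_evalue_all maximum e-value for any reported hit (1e-5).
#' @param word_size blast word size.
#' @param full_coverage_min library-coverage fraction for completeness
#'   \code{full} (inclusive).
#' @return a \code{\link{RepeatAnnotations}} object with extra columns
#'   \code{lib_start}, \code{lib_end}, \code{lib_len}, \code{coverage},
#'   \code{pident}, \code{bitscore}, \code{top}, \code{fragment_count}.
#' @export
maskWithLibrary <- function(genome, library, min_evalue_top = 1e-50,
                            min_evalue_all = 1e-5, word_size = 11,
                            full_coverage_min = 0.9) {
  seqs <- .asGenome(genome)
  lib <- if (is.character(library) && length(library) == 1 &&
             file.exists(library)) readFasta(library) else .asGenome(library)
  if (!length(lib)) stop("repeat library is empty")
  lib <- .normalizeLibrary(lib)
  if (!length(seqs) || sum(Biostrings::width(seqs)) == 0)
    return(RepeatAnnotations())
  qf <- tempfile(fileext = ".fasta"); sf <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  writeFasta(lib, qf)
  writeFasta(seqs, sf)
  df <- .blastn(qf, sf, word_size, min_evalue_all)
  if (is.null(df) || !nrow(df)) return(RepeatAnnotations())
  df <- df[df$evalue <= min_evalue_all, , drop = FALSE]
  if (!nrow(df)) return(RepeatAnnotations())

  strand <- ifelse(df$send >= df$sstart, "+", "-")
  g0 <- pmin(df$sstart, df$send); g1 <- pmax(df$sstart, df$send)
  desc <- metadata(lib)$description
  clsinfo <- .libraryClass(names(lib), desc[names(lib)])
  qi <- match(df$qseqid, names(lib))
  coverage <- df$length / df$qlen
  gr <- GRanges(as.character(df$sseqid), IRanges(g0, g1), strand = strand)
  mcols(gr) <- DataFrame(
    id = paste0("hit", seq_len(nrow(df))),
    te_class = clsinfo$te_class[qi],
    subclass = ifelse(clsinfo$te_class[qi] %in% c("DNA", "RC") &
                        is.na(clsinfo$subclass[qi]),
                      "unknown", clsinfo$subclass[qi]),
    completeness = ifelse(coverage >= full_coverage_min, "full",
                          "partial_or_solo"),
    source = "homology",
    library_hit = df$qseqid,
    score_evalue = df$evalue,
    lib_start = pmin(df$qstart, df$qend),
    lib_end = pmax(df$qstart, df$qend),
    lib_len = df$qlen,
    coverage = coverage,
    pident = df$pident,
    bitscore = df$bitscore,
    fragment_count = 1L)
  ann <- RepeatAnnotations(gr)
  # flag the best hit per overlapping locus
  top <- logical(length(ann))
  red <- reduce(granges(ann), ignore.strand = TRUE)
  ov <- findOverlaps(granges(ann), red, ignore.strand = TRUE)
  for (b in unique(S4Vectors::subjectHits(ov))) {
    idx <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == b]
    best <- idx[order(mcols(ann)$score_evalue[idx],
                      -mcols(ann)$bitscore[idx])][1]
    if (mcols(ann)$score_evalue[best] <= min_evalue_top) top[best] <- TRUE
  }
  mcols(ann)$top <- top
  ann
}

#' Merge collinear same-family fragments
#'
#' Same-family (library hit), same-strand hits whose genomic gap is at most
#' \code{max_gap} and whose library coordinates are collinear are merged;
#' the merged annotation records its fragment count and the union of
#' library coverage.  Different families are never merged.
#'
#' @param annotations a \code{\link{RepeatAnnotations}} from
#'   \code{\link{maskWithLibrary}}.
#' @param max_gap maximum genomic gap (bp) between merged fragments.
#' @return a \code{\link{RepeatAnnotations}}.
#' @export
mergeFragments <- function(annotations, max_gap = 50) {
  if (length(annotations) < 2) return(annotations)
  m <- mcols(annotations)
  key <- paste(as.character(seqnames(annotations)),
               as.character(strand(annotations)),
               m$library_hit %||% m$te_class)
  ord <- order(key, start(annotations))
  ann <- annotations[ord]
  m <- mcols(ann)
  key <- key[ord]
  group <- integer(length(ann))
  gid <- 0L
  for (i in seq_along(ann)) {
    newgrp <- TRUE
    if (i > 1 && key[i] == key[i - 1] && group[i - 1] > 0) {
      prev <- max(which(group == group[i - 1]))
      gap <- start(ann)[i] - end(ann)[prev] - 1L
      collinear <- is.na(m$lib_start[i]) || is.na(m$lib_end[prev]) ||
        (as.character(strand(ann)[i]) != "-" &&
           m$lib_start[i] >= m$lib_start[prev]) ||
        (as.character(strand(ann)[i]) == "-" &&
           m$lib_end[i] <= m$lib_end[prev])
      if (gap <= max_gap && gap >= -5 && collinear) newgrp <- FALSE
    }
    if (newgrp) gid <- gid + 1L
    group[i] <- gid
  }
  out <- lapply(split(seq_along(ann), group), function(idx) {
    one <- ann[idx[1]]
    IRanges::ranges(one) <- IRanges(min(start(ann)[idx]), max(end(ann)[idx]))
    mcols(one)$fragment_count <- length(idx)
    if (!is.null(m$lib_start)) {
      mcols(one)$lib_start <- min(m$lib_start[idx])
      mcols(one)$lib_end <- max(m$lib_end[idx])
      if (!is.null(m$coverage) && !is.na(mcols(one)$lib_len))
        mcols(one)$coverage <-
          (mcols(one)$lib_end - mcols(one)$lib_start + 1) / mcols(one)$lib_len
      if (!is.null(m$score_evalue))
        mcols(one)$score_evalue <- min(m$score_evalue[idx])
    }
    one
  })
  merged <- do.call(c, unname(out))
  sort(new("RepeatAnnotations", merged), ignore.strand = TRUE)
}

#' Refine completeness into full / partial / solo for LTR-class hits
#'
#' An LTR-class (Copia/Gypsy) hit whose library-coordinate span lies at
#' least 90 percent inside the library entry's annotated LTR sub-interval
#' is a solo LTR; a hit covering less than \code{full_coverage_min}
#' (inclusive boundary) of the library entry is partial; otherwise full.
#' Both solo and partial map to completeness \code{partial_or_solo}; the
#' finer call is recorded in a \code{solo} logical column.
#'
#' @param annotations a \code{\link{RepeatAnnotations}} with library
#'   coordinates.
#' @param library the repeat library used for masking (for LTR sub-interval
#'   tags \code{ltr=start-end}).
#' @param full_coverage_min coverage threshold for \code{full} (inclusive).
#' @return the annotations with \code{completeness} and \code{solo} set.
#' @export
callSoloPartial <- function(annotations, library, full_coverage_min = 0.9) {
  lib <- if (is.character(library) && length(library) == 1 &&
             file.exists(library)) readFasta(library) else .asGenome(library)
  lib <- .normalizeLibrary(lib)
  desc <- metadata(lib)$description
  info <- .libraryClass(names(lib), desc[names(lib)])
  rownames(info) <- names(lib)
  m <- mcols(annotations)
  solo <- rep(FALSE, length(annotations))
  for (i in seq_along(annotations)) {
    if (is.na(m$library_hit[i]) || !m$library_hit[i] %in% names(lib)) next
    li <- info[m$library_hit[i], ]
    cov <- m$coverage[i]
    is_ltr_class <- m$te_class[i] %in% c("Copia", "Gypsy")
    if (is_ltr_class && !is.na(li$ltr_start) && !is.na(m$lib_start[i])) {
      span <- m$lib_end[i] - m$lib_start[i] + 1
      inside <- max(0, min(m$lib_end[i], li$ltr_end) -
                       max(m$lib_start[i], li$ltr_start) + 1)
      if (inside / span >= 0.9) {
        solo[i] <- TRUE
        m$completeness[i] <- "partial_or_solo"
        next
      }
    }
    if (!is.na(cov))
      m$completeness[i] <- if (cov >= full_coverage_min) "full"
                           else "partial_or_solo"
  }
  m$solo <- solo
  mcols(annotations) <- m
  annotations
}

# overlap resolution: lowest e-value (then highest bitscore, then leftmost)
# wins; returns a non-overlapping subset
.resolveAnnotationOverlaps <- function(annotations, warn = TRUE) {
  if (length(annotations) < 2) return(annotations)
  gr <- granges(annotations)
  has_ov <- any(IRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1)
  if (!has_ov) return(annotations)
  if (warn) warning("overlapping annotations resolved: higher score wins")
  m <- mcols(annotations)
  ev <- m$score_evalue %||% rep(0, length(annotations))
  bs <- m$bitscore %||% (end(annotations) - start(annotations))
  ord <- order(ifelse(is.na(ev), 0, ev), -ifelse(is.na(bs), 0, bs),
               start(annotations))
  keep <- logical(length(annotations))
  taken <- GRanges()
  for (i in ord) {
    if (!length(findOverlaps(gr[i], taken, ignore.strand = TRUE))) {
      keep[i] <- TRUE
      taken <- c(taken, gr[i])
    }
  }
  sort(annotations[keep], ignore.strand = TRUE)
}

#' Find repeat junctions from an annotation set
#'
#' Every boundary of every (overlap-resolved) annotated interval yields a
#' junction: a boundary abutting another annotation (gap 0) is a
#' \code{repeat_repeat} junction, a boundary abutting unannotated sequence
#' is \code{repeat_unique}, and boundaries at contig ends are suppressed.
#' Junction positions are 0-based boundary offsets (the number of bases to
#' the left; equal to the 1-based end coordinate of the left-hand block).
#'
#' @param annotations a \code{\link{RepeatAnnotations}}.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a data.frame with \code{chrom}, \code{pos}, \code{kind},
#'   \code{left_annotation}, \code{right_annotation}.
#' @export
findRepeatJunctions <- function(annotations, chrom_lengths) {
  ann <- .resolveAnnotationOverlaps(annotations)
  out <- list()
  for (chrom in unique(as.character(seqnames(ann)))) {
    idx <- which(as.character(seqnames(ann)) == chrom)
    idx <- idx[order(start(ann)[idx])]
    st <- start(ann)[idx]; en <- end(ann)[idx]
    ids <- mcols(ann)$id[idx]
    clen <- chrom_lengths[[chrom]]
    if (is.null(clen) || is.na(clen)) stop("no length for chromosome ", chrom)
    for (j in seq_along(idx)) {
      # left boundary of block j at pos st[j]-1
      pos <- st[j] - 1L
      if (pos > 0L) {
        abut <- j > 1 && en[j - 1] == pos
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = pos,
          kind = if (abut) "repeat_repeat" else "repeat_unique",
          left_annotation = if (abut) ids[j - 1] else NA_character_,
          right_annotation = ids[j], stringsAsFactors = FALSE)
      }
      # right boundary at pos en[j]
      pos <- en[j]
      if (pos < clen) {
        abut <- j < length(idx) && st[j + 1] == pos + 1L
        if (!abut)  # shared boundaries are emitted once (as a left boundary)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, pos = pos, kind = "repeat_unique",
            left_annotation = ids[j], right_annotation = NA_character_,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      kind = character(), left_annotation = character(),
                      right_annotation = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Write repeat junctions as BED (0-based)
#'
#' @param junctions data.frame from \code{\link{findRepeatJunctions}}.
#' @param path output path.
#' @export
writeJunctionsBed <- function(junctions, path) {
  bed <- data.frame(junctions$chrom, junctions$pos, junctions$pos + 1L,
                    junctions$kind)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
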