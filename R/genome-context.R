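## Nested-TE detection, intron-insertion tables and per-chromosome density
## summaries.

# family key used to decide "different family" for nesting
.familyKey <- function(ann) {
  m <- mcols(ann)
  lib <- m$library_hit %||% rep(NA_character_, length(ann))
  ifelse(is.na(lib), paste(m$te_class, m$subclass, sep = "/"), lib)
}

#' Find nested TE insertions
#'
#' An annotation counts as inserted when it is strictly contained in
#' another annotation's span and belongs to a different family, or when it
#' exactly fills the gap between two collinear fragments of the same host
#' family.  Events are grouped per host, so a host with two inserts yields
#' one event with two inserted ids.
#'
#' @param annotations a \code{\link{RepeatAnnotations}}.
#' @param max_frag_gap maximum distance between an insert and the host
#'   fragments it separates (bp) for the split-host criterion.
#' @return a \code{DataFrame} with \code{host_id} and \code{inserted_ids}
#'   (CharacterList), one row per host.
#' @export
findNestedTes <- function(annotations, max_frag_gap = 50) {
  ann <- annotations
  n <- length(ann)
  events <- list()
  if (n >= 2) {
    fam <- .familyKey(ann)
    ids <- mcols(ann)$id
    chrom <- as.character(seqnames(ann))
    st <- start(ann); en <- end(ann)
    # strict containment, different family
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || chrom[i] != chrom[j]) next
      if (st[j] > st[i] && en[j] < en[i] && fam[i] != fam[j])
        events[[length(events) + 1L]] <- c(host = ids[i], ins = ids[j])
    }
    # insert filling the gap between two collinear same-family fragments
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b || chrom[a] != chrom[b]) next
      if (fam[a] != fam[b] || en[a] >= st[b]) next
      for (x in seq_len(n)) {
        if (x == a || x == b || chrom[x] != chrom[a]) next
        if (fam[x] == fam[a]) next
        if (st[x] > en[a] && en[x] < st[b] &&
            st[x] - en[a] - 1L <= max_frag_gap &&
            st[b] - en[x] - 1L <= max_frag_gap)
          events[[length(events) + 1L]] <- c(host = ids[a], ins = ids[x])
      }
    }
  }
  if (!length(events))
    return(DataFrame(host_id = character(),
                     inserted_ids = IRanges::CharacterList()))
  df <- unique(do.call(rbind, events))
  hosts <- unique(df[, "host"])
  DataFrame(host_id = hosts,
            inserted_ids = IRanges::CharacterList(
              lapply(hosts, function(h) unique(df[df[, "host"] == h, "ins"]))))
}

#' Compute introns from gene-model exons
#'
#' Introns are the gaps between consecutive exons of a gene (union over
#' transcripts when ranks repeat); abutting exons yield no zero-length
#' intron.
#'
#' @param gene_models \code{GRanges} of exons with a \code{gene_id} column.
#' @return a \code{GRanges} of introns with \code{gene_id}.
#' @export
computeIntrons <- function(gene_models) {
  if (!length(gene_models)) return(GRanges())
  out <- list()
  for (g in unique(mcols(gene_models)$gene_id)) {
    ex <- gene_models[mcols(gene_models)$gene_id == g]
    exr <- reduce(IRanges::ranges(ex))
    if (length(exr) < 2) next
    gaps <- IRanges::gaps(exr, start = min(IRanges::start(exr)),
                          end = max(IRanges::end(exr)))
    if (!length(gaps)) next
    gr <- GRanges(seqnames(ex)[1], gaps, strand = strand(ex)[1])
    mcols(gr)$gene_id <- g
    out[[length(out) + 1L]] <- gr
  }
  if (!length(out)) return(GRanges())
  do.call(c, out)
}

# class label used for intron tables: superfamily for retroelements,
# subclass for DNA transposons, RC/Helitron spelled out
.contextClassLabel <- function(ann) {
  m <- mcols(ann)
  ifelse(m$te_class %in% c("DNA"), m$subclass,
         ifelse(m$te_class == "RC", paste0("RC/", m$subclass), m$te_class))
}

#' Tabulate TE insertions into intronic regions
#'
#' A TE counts for a (gene, class) pair when its interval overlaps any
#' intron of the gene by at least \code{min_overlap} bp.  By default cells
#' count interrupted genes (a gene counts once per class regardless of how
#' many insertions hit it); \code{mode = "events"} counts TE-intron
#' overlap events instead.  The result has one row per class, one column
#' per chromosome, and a Total row.
#'
#' @param annotations a \code{\link{RepeatAnnotations}}.
#' @param introns \code{GRanges} from \code{\link{computeIntrons}}.
#' @param min_overlap minimum overlap (bp).
#' @param mode \code{"genes"} or \code{"events"}.
#' @return a list with \code{counts} (integer matrix, classes x
#'   chromosomes, Total row last) and \code{interrupted_genes} (list of
#'   gene-id sets per class).
#' @export
intersectTeIntrons <- function(annotations, introns, min_overlap = 1,
                               mode = c("genes", "events")) {
  mode <- match.arg(mode)
  chroms <- sort(unique(as.character(seqnames(annotations))))
  if (!length(annotations) || !length(introns)) {
    counts <- matrix(0L, nrow = 1, ncol = length(chroms),
                     dimnames = list("Total", chroms))
    return(list(counts = counts, interrupted_genes = list()))
  }
  ov <- findOverlaps(granges(annotations), introns,
                     minoverlap = min_overlap, ignore.strand = TRUE)
  lab <- .contextClassLabel(annotations)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  df <- data.frame(chrom = as.character(seqnames(annotations))[qh],
                   class = lab[qh],
                   gene = mcols(introns)$gene_id[sh],
                   te = mcols(annotations)$id[qh],
                   stringsAsFactors = FALSE)
  if (mode == "genes") df <- unique(df[, c("chrom", "class", "gene")])
  classes <- sort(unique(df$class))
  counts <- matrix(0L, nrow = length(classes) + 1L, ncol = length(chroms),
                   dimnames = list(c(classes, "Total"), chroms))
  for (cl in classes) for (ch in chroms)
    counts[cl, ch] <- sum(df$class == cl & df$chrom == ch)
  counts["Total", ] <- colSums(counts[seq_along(classes), , drop = FALSE])
  genes <- lapply(split(df$gene, df$class), unique)
  list(counts = counts, interrupted_genes = genes)
}

#' Per-chromosome repeat density summary
#'
#' For each chromosome and class: count, percentage of the class total and
#' density per Mb; a genome-average row is appended per class.
#'
#' @param annotations a \code{\link{RepeatAnnotations}}.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @return a data.frame with \code{chrom}, \code{te_class}, \code{count},
#'   \code{pct}, \code{per_mb}.
#' @export
densitySummary <- function(annotations, chrom_lengths) {
  chroms <- names(chrom_lengths)
  classes <- sort(unique(mcols(annotations)$te_class))
  out <- list()
  for (cl in classes) {
    sel <- mcols(annotations)$te_class == cl
    total <- sum(sel)
    for (ch in chroms) {
      cnt <- sum(sel & as.character(seqnames(annotations)) == ch)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, te_class = cl, count = cnt,
        pct = if (total > 0) 100 * cnt / total else 0,
        per_mb = cnt / (chrom_lengths[[ch]] / 1e6))
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = "genome", te_class = cl, count = total, pct = if (total > 0) 100 else 0,
      per_mb = total / (sum(chrom_lengths) / 1e6))
  }
  do.call(rbind, out)
}
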