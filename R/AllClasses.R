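#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges findOverlaps reduce
NULL

## ---------------------------------------------------------------------------
## RepeatAnnotations: classified repeat intervals on a genome
## ---------------------------------------------------------------------------

.REPEAT_MCOLS <- c("id", "te_class", "subclass", "completeness", "source")
.TE_CLASSES <- c("Copia", "Gypsy", "LINE", "SINE", "DNA", "RC", "Unknown")

#' Classified repeat intervals
#'
#' A \code{GRanges} subclass holding homology- or structure-derived repeat
#' annotations.  Required metadata columns: \code{id}, \code{te_class}
#' (Copia, Gypsy, LINE, SINE, DNA, RC or Unknown), \code{subclass}
#' (e.g. \code{PIF-Harbinger} for DNA transposons), \code{completeness}
#' (\code{full} or \code{partial_or_solo}) and \code{source}
#' (\code{structural}, \code{homology} or \code{file}).  Optional columns:
#' \code{library_hit}, \code{score_evalue}, \code{fragment_count}.
#'
#' @aliases RepeatAnnotations-class
#' @export
setClass("RepeatAnnotations", contains = "GRanges")

setValidity("RepeatAnnotations", function(object) {
  m <- mcols(object)
  miss <- setdiff(.REPEAT_MCOLS, colnames(m))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (anyDuplicated(m$id))
      return("annotation ids must be unique")
    if (!all(m$te_class %in% .TE_CLASSES))
      return(paste("te_class must be one of", paste(.TE_CLASSES, collapse = ", ")))
    if (!all(m$completeness %in% c("full", "partial_or_solo")))
      return("completeness must be 'full' or 'partial_or_solo'")
    if (!all(m$source %in% c("structural", "homology", "file")))
      return("source must be 'structural', 'homology' or 'file'")
    dna <- m$te_class == "DNA"
    if (any(dna & (is.na(m$subclass) | m$subclass == "")))
      return("subclass must be non-empty when te_class is 'DNA'")
  }
  TRUE
})

#' Construct a RepeatAnnotations object
#'
#' @param gr a \code{GRanges} carrying the required metadata columns; missing
#'   optional columns are filled with defaults.
#' @return a \code{RepeatAnnotations} object.
#' @export
RepeatAnnotations <- function(gr = GRanges()) {
  m <- mcols(gr)
  if (is.null(m$id)) m$id <- if (length(gr)) paste0("rep", seq_along(gr)) else character()
  if (is.null(m$te_class)) m$te_class <- rep("Unknown", length(gr))
  if (is.null(m$subclass)) m$subclass <- rep(NA_character_, length(gr))
  if (is.null(m$completeness)) m$completeness <- rep("full", length(gr))
  if (is.null(m$source)) m$source <- rep("file", length(gr))
  mcols(gr) <- m
  new("RepeatAnnotations", gr)
}

setMethod("show", "RepeatAnnotations", function(object) {
  cat("RepeatAnnotations with", length(object), "annotation(s)\n")
  if (length(object)) {
    tab <- table(mcols(object)$te_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  callNextMethod()
})

## ---------------------------------------------------------------------------
## LtrElementSet: full-length LTR retrotransposon calls
## ---------------------------------------------------------------------------

.LTR_MCOLS <- c("id", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                "ltr_identity")

#' Full-length LTR retrotransposon calls
#'
#' A \code{GRanges} subclass; the range is the element span (5' LTR start to
#' 3' LTR end, target-site duplication excluded).  Required metadata columns
#' give the paired LTR intervals (\code{ltr5_start} .. \code{ltr3_end}) and
#' \code{ltr_identity}.  Feature columns filled by
#' \code{\link{annotateLtrFeatures}}: \code{tsd}, \code{pbs_start},
#' \code{pbs_end}, \code{pbs_trna}, \code{ppt_start}, \code{ppt_end},
#' \code{ppt_purine}, \code{superfamily}.
#'
#' @aliases LtrElementSet-class
#' @export
setClass("LtrElementSet", contains = "GRanges")

setValidity("LtrElementSet", function(object) {
  m <- mcols(object)
  miss <- setdiff(.LTR_MCOLS, colnames(m))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (!all(m$ltr5_start == start(object)) || !all(m$ltr3_end == end(object)))
      return("element span must run from ltr5_start to ltr3_end")
    if (!all(m$ltr5_end < m$ltr3_start))
      return("5' LTR must end before the 3' LTR starts")
    if (!all(m$ltr_identity >= 0 & m$ltr_identity <= 1))
      return("ltr_identity must lie in [0, 1]")
  }
  TRUE
})

#' Construct an LtrElementSet
#' @param gr a \code{GRanges} with the required LTR metadata columns.
#' @return an \code{LtrElementSet}.
#' @export
LtrElementSet <- function(gr = GRanges()) {
  m <- mcols(gr)
  if (length(gr) == 0L) {
    for (col in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
      if (is.null(m[[col]])) m[[col]] <- integer(0)
    if (is.null(m$ltr_identity)) m$ltr_identity <- numeric(0)
  }
  for (col in c("tsd", "pbs_trna", "superfamily"))
    if (is.null(m[[col]])) m[[col]] <- rep(NA_character_, length(gr))
  for (col in c("pbs_start", "pbs_end", "ppt_start", "ppt_end"))
    if (is.null(m[[col]])) m[[col]] <- rep(NA_integer_, length(gr))
  if (is.null(m$ppt_purine)) m$ppt_purine <- rep(NA_real_, length(gr))
  if (is.null(m$id)) m$id <- if (length(gr)) paste0("ltr", seq_along(gr)) else character()
  mcols(gr) <- m
  new("LtrElementSet", gr)
}

setMethod("show", "LtrElementSet", function(object) {
  cat("LtrElementSet with", length(object), "element(s)\n")
  if (length(object)) {
    sf <- table(mcols(object)$superfamily, useNA = "ifany")
    cat("  superfamilies:", paste(names(sf), sf, sep = "=", collapse = ", "), "\n")
    cat("  mean LTR identity:", round(mean(mcols(object)$ltr_identity), 4), "\n")
  }
  callNextMethod()
})

## ---------------------------------------------------------------------------
## MarkerSet: designed TE-based markers (marker table + primer table)
## ---------------------------------------------------------------------------

.MARKER_TYPES <- c("RBIP", "IRAP", "RJM", "RJJM", "ISBP", "REMAP")

#' A set of designed TE-based markers
#'
#' Two parallel tables: \code{markers} (one row per marker: \code{marker_id},
#' \code{type}, \code{te_type}, \code{te_source}, \code{junctions}
#' (IntegerList), \code{unique_flag}) and \code{primers} (one row per primer:
#' \code{marker_id}, \code{role}, \code{seq}, \code{chrom}, \code{start},
#' \code{end}, \code{strand}, \code{tm_c}, \code{gc_pct}).  Predicted
#' products are stored in \code{products} (one row per predicted product:
#' \code{marker_id}, \code{configuration}, \code{chrom}, \code{start},
#' \code{end}, \code{size}).
#'
#' @aliases MarkerSet-class
#' @export
setClass("MarkerSet", representation(markers = "DataFrame",
                                     primers = "DataFrame",
                                     products = "DataFrame"))

setValidity("MarkerSet", function(object) {
  mk <- object@markers
  pr <- object@primers
  if (nrow(mk)) {
    if (!all(mk$type %in% .MARKER_TYPES))
      return(paste("marker type must be one of", paste(.MARKER_TYPES, collapse = ", ")))
    if (anyDuplicated(mk$marker_id))
      return("marker_id must be unique")
    n_primers <- table(factor(pr$marker_id, levels = mk$marker_id))
    want <- ifelse(mk$type == "RBIP", 3L, 2L)
    if (!all(as.integer(n_primers) == want))
      return("markers must have 2 primers (3 for RBIP)")
  }
  TRUE
})

#' @export
MarkerSet <- function(markers = DataFrame(), primers = DataFrame(),
                      products = DataFrame()) {
  new("MarkerSet", markers = markers, primers = primers, products = products)
}

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet with", nrow(object@markers), "marker(s),",
      nrow(object@primers), "primer(s)\n")
  if (nrow(object@markers)) {
    tab <- table(object@markers$type)
    tab <- tab[tab > 0]
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  unique:", sum(object@markers$unique_flag, na.rm = TRUE), "of",
        nrow(object@markers), "\n")
  }
})

#' Marker-level table of a MarkerSet
#' @param x a \code{MarkerSet}
#' @return a \code{DataFrame}, one row per marker.
#' @export
markerTable <- function(x) x@markers

#' Primer-level table of a MarkerSet
#' @param x a \code{MarkerSet}
#' @return a \code{DataFrame}, one row per primer.
#' @export
primerTable <- function(x) x@primers

#' Predicted-product table of a MarkerSet
#' @param x a \code{MarkerSet}
#' @return a \code{DataFrame}, one row per predicted product.
#' @export
productTable <- function(x) x@products

## ---------------------------------------------------------------------------
## BinaryGenotypeMatrix: individuals x loci presence/absence scores
## ---------------------------------------------------------------------------

#' Binary (dominant) marker genotype matrix
#'
#' Individuals in rows, loci in columns; entries 0 (band absent), 1 (band
#' present) or NA (missing).
#'
#' @aliases BinaryGenotypeMatrix-class
#' @export
setClass("BinaryGenotypeMatrix", representation(values = "matrix"))

setValidity("BinaryGenotypeMatrix", function(object) {
  v <- object@values
  if (nrow(v) < 2) return("at least 2 individuals required")
  if (ncol(v) < 1) return("at least 1 locus required")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("individual and locus names required")
  ok <- v %in% c(0L, 1L) | is.na(v)
  if (!all(ok)) return("values must be 0, 1 or NA")
  TRUE
})

#' @param values integer/numeric matrix of 0/1/NA with row and column names.
#' @rdname BinaryGenotypeMatrix-class
#' @export
BinaryGenotypeMatrix <- function(values) {
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("locus", seq_len(ncol(values)))
  new("BinaryGenotypeMatrix", values = values)
}

#' Genotype values of a BinaryGenotypeMatrix
#' @param x a \code{BinaryGenotypeMatrix}
#' @return the underlying integer matrix.
#' @export
genotypeValues <- function(x) x@values

setMethod("show", "BinaryGenotypeMatrix", function(object) {
  v <- object@values
  cat("BinaryGenotypeMatrix:", nrow(v), "individuals x", ncol(v), "loci;",
      sum(is.na(v)), "missing\n")
})

setMethod("dim", "BinaryGenotypeMatrix", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## StructureResult: one no-admixture clustering run
## ---------------------------------------------------------------------------

#' Result of a no-admixture Bayesian clustering run
#'
#' @slot K number of clusters.
#' @slot q posterior membership matrix (individuals x K), rows sum to 1.
#' @slot assignments hard assignment per individual (argmax of q).
#' @slot lnPD estimated Ln P(D) (mean log-likelihood minus half its variance
#'   over post-burn-in sweeps, the STRUCTURE approximation).
#' @slot lambda Beta prior parameter on band frequencies.
#' @slot trace per-sweep log-likelihood (post-burn-in).
#'
#' @aliases StructureResult-class
#' @export
setClass("StructureResult",
         representation(K = "integer", q = "matrix", assignments = "integer",
                        lnPD = "numeric", lambda = "numeric",
                        trace = "numeric"))

setValidity("StructureResult", function(object) {
  if (ncol(object@q) != object@K) return("q must have K columns")
  if (any(abs(rowSums(object@q) - 1) > 1e-6)) return("q rows must sum to 1")
  if (!all(object@assignments == max.col(object@q, ties.method = "first")))
    return("assignments must be the argmax of q")
  TRUE
})

setMethod("show", "StructureResult", function(object) {
  cat("StructureResult: K =", object@K, ",", nrow(object@q), "individuals\n")
  cat("  Ln P(D) =", round(object@lnPD, 2), "; lambda =", object@lambda, "\n")
  cat("  cluster sizes:", paste(tabulate(object@assignments, object@K),
                                collapse = ", "), "\n")
})

#' Membership probabilities of a StructureResult
#' @param x a \code{StructureResult}
#' @export
membershipMatrix <- function(x) x@q

#' Hard cluster assignments of a StructureResult
#' @param x a \code{StructureResult}
#' @export
clusterAssignments <- function(x) x@assignments

#' Estimated Ln P(D) of a StructureResult
#' @param x a \code{StructureResult}
#' @export
lnProbData <- function(x) x@lnPD

## ---------------------------------------------------------------------------
## PlantedGenome: synthetic genome plus ground truth
## ---------------------------------------------------------------------------

#' A synthetic genome with planted ground truth
#'
#' @slot sequences the genome as a \code{DNAStringSet}.
#' @slot elements planted repeat elements as a \code{GRanges} with metadata:
#'   \code{id}, \code{kind} (LTR_Copia, LTR_Gypsy, DNA_TIR, SSR, repeat),
#'   \code{tsd}, \code{divergence}, \code{ltr5_start}/\code{ltr5_end}/
#'   \code{ltr3_start}/\code{ltr3_end} (LTR kinds), \code{tir_len},
#'   \code{subclass}, \code{motif}, \code{host_id}, \code{seed}.
#'   Element spans exclude the flanking TSD copies.
#' @slot genes planted gene models as a \code{GRanges} of exons with
#'   \code{gene_id} and \code{exon_rank} metadata.
#'
#' @aliases PlantedGenome-class
#' @export
setClass("PlantedGenome",
         representation(sequences = "DNAStringSet", elements = "GRanges",
                        genes = "GRanges"))

setValidity("PlantedGenome", function(object) {
  if (length(object@elements)) {
    if (anyDuplicated(mcols(object@elements)$id))
      return("planted element ids must be unique")
    lens <- setNames(Biostrings::width(object@sequences),
                     names(object@sequences))
    el <- object@elements
    if (any(end(el) > lens[as.character(seqnames(el))]))
      return("planted elements must lie within the genome")
  }
  TRUE
})

#' @export
PlantedGenome <- function(sequences, elements = GRanges(), genes = GRanges()) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("PlantedGenome", sequences = sequences, elements = elements,
      genes = genes)
}

setMethod("show", "PlantedGenome", function(object) {
  cat("PlantedGenome:", length(object@sequences), "sequence(s),",
      sum(Biostrings::width(object@sequences)), "bp total\n")
  if (length(object@elements)) {
    tab <- table(mcols(object@elements)$kind)
    cat("  planted:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@genes))
    cat("  gene models:", length(unique(mcols(object@genes)$gene_id)), "\n")
})

#' Genome sequences of a PlantedGenome
#' @param x a \code{PlantedGenome}
#' @export
genomeSequences <- function(x) x@sequences

#' Planted-element truth of a PlantedGenome
#' @param x a \code{PlantedGenome}
#' @export
plantedElements <- function(x) x@elements

#' Planted gene models (exon ranges) of a PlantedGenome
#' @param x a \code{PlantedGenome}
#' @export
plantedGenes <- function(x) x@genes
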