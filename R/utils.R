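#' @importFrom methods new is validObject setValidity slot
#' @importFrom stats var sd median setNames runif rbinom
#' @importFrom utils head tail read.delim write.table
NULL

# reverse complement for plain character vectors
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# single chromosome sequence as a plain upper-case character scalar
chromSeq <- function(sequences, chrom) {
  if (!chrom %in% names(sequences))
    stop("unknown chromosome '", chrom, "'")
  as.character(sequences[[chrom]])
}

gcFraction <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(b %in% c("G", "C"))
}

maxHomopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

# seeds derived from a user seed stay below 2^31
deriveSeed <- function(seed, i) {
  (as.integer(seed) * 1009L + as.integer(i) * 9973L) %% 2147483647L
}

isDna <- function(seq) {
  grepl("^[ACGTN]+$", seq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# session cache for small bundled files (tRNA library)
.pkgCache <- new.env(parent = emptyenv())

.readFastaCached <- function(path) {
  key <- normalizePath(path)
  if (is.null(.pkgCache[[key]])) .pkgCache[[key]] <- readFasta(path)
  .pkgCache[[key]]
}
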