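#' Read a FASTA file
#'
#' Sequences are uppercased (soft-masking is discarded) and validated:
#' ids must be unique and sequences may contain only A, C, G, T or N.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read raw first: DNAStringSet import silently drops non-IUPAC letters
  seqs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) stop("not FASTA-formatted: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  # keep only the id token; the rest of the header is the description
  ids <- sub("\\s.*$", "", names(seqs))
  desc <- sub("^\\S+\\s*", "", names(seqs))
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1]])
  chr <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGTN]", chr)
  if (any(bad > 0)) {
    i <- which(bad > 0)[[1]]
    stop("non-IUPAC character in '", ids[[i]], "' at position ", bad[[i]])
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  metadata(out)$description <- setNames(desc, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = 70L)
  invisible(path)
}
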