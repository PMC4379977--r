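# Map a RepeatMasker class/family string to (te_class, subclass).
# Known prefixes map directly; anything else keeps the prefix before "/" as
# te_class candidate and is flagged unmapped so nothing is lost on ingestion.
.parseRmClass <- function(cls) {
  parts <- strsplit(cls, "/", fixed = TRUE)
  t(vapply(parts, function(p) {
    pre <- p[[1]]
    sub <- if (length(p) > 1) paste(p[-1], collapse = "/") else NA_character_
    if (pre == "LTR" && !is.na(sub) && sub %in% c("Copia", "Gypsy"))
      c(sub, NA_character_, "FALSE")
    else if (pre %in% c("LINE", "SINE", "DNA", "RC"))
      c(pre, if (pre %in% c("DNA", "RC")) (if (is.na(sub)) "unknown" else sub) else sub,
        "FALSE")
    else
      c(if (pre %in% .TE_CLASSES) pre else "Unknown",
        if (is.na(sub)) pre else sub, "TRUE")
  }, character(3)))
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard RepeatMasker \code{.out} column layout (three header
#' lines followed by whitespace-separated records) into a
#' \code{\link{RepeatAnnotations}} object.  The repeat class/family string is
#' mapped to \code{te_class}/\code{subclass} (\code{LTR/Copia} to class
#' \code{Copia}, \code{DNA/PIF-Harbinger} to class \code{DNA} subclass
#' \code{PIF-Harbinger}, ...); unrecognised strings keep the prefix before
#' \code{/} and are flagged in the \code{unmapped} column.  The trailing
#' \code{*} (overlapped by a higher-scoring hit) is kept as a logical.
#'
#' @param path path to a RepeatMasker \code{.out} file.
#' @return a \code{RepeatAnnotations} object with extra columns
#'   \code{sw_score}, \code{pct_div}, \code{repeat_name}, \code{unmapped},
#'   \code{higher_scoring_overlap}.
#' @export
readRepeatMaskerOut <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(RepeatAnnotations())
  rec <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 14)
      stop("malformed RepeatMasker record at line ", i + 3L, ": ", body[[i]])
    f
  })
  n <- length(rec)
  fld <- function(j) vapply(rec, `[[`, character(1), j)
  qbeg <- suppressWarnings(as.integer(fld(6)))
  qend <- suppressWarnings(as.integer(fld(7)))
  if (anyNA(qbeg) || anyNA(qend) || any(qbeg > qend))
    stop("malformed RepeatMasker record at line ",
         which(is.na(qbeg) | is.na(qend) | qbeg > qend)[1] + 3L)
  strand <- ifelse(fld(9) == "C", "-", "+")
  clsmap <- .parseRmClass(fld(11))
  star <- vapply(rec, function(f) f[[length(f)]] == "*", logical(1))
  gr <- GRanges(fld(5), IRanges(qbeg, qend), strand = strand)
  mcols(gr) <- DataFrame(
    id = paste0("rm", seq_len(n)),
    te_class = clsmap[, 1],
    subclass = clsmap[, 2],
    completeness = rep("partial_or_solo", n),
    source = rep("file", n),
    library_hit = fld(10),
    sw_score = as.numeric(fld(1)),
    pct_div = as.numeric(fld(2)),
    repeat_name = fld(10),
    unmapped = as.logical(clsmap[, 3]),
    higher_scoring_overlap = star)
  RepeatAnnotations(gr)
}
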