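## Design of the six TE-based marker classes.
##
## Operational geometry:
##  RJM  - one primer wholly inside a repeat, mate in the unique flank; the
##         amplicon spans exactly one repeat/unique junction (any class).
##  ISBP - same geometry, but the repeat side is an LTR-retrotransposon
##         annotation (takes precedence over RJM for such junctions).
##  RJJM - the amplicon spans exactly two adjacent junctions.
##  RBIP - three primers: left/right flank primers converging across the
##         insertion site plus one te_internal primer near the 5' LTR; the
##         occupied-site product is flank+TE, the empty-site product is
##         flank+flank (clean excision leaving one TSD copy by default).
##  IRAP - outward-facing primers in the facing LTRs of two nearby elements.
##  REMAP- one LTR primer paired with an anchored SSR primer (motif repeated
##         to >= 18 bp plus one 3' anchor base).

.tryPick <- function(seq, window, direction, constraints) {
  if (window[2] - window[1] + 1L < constraints$len_min) return(NULL)
  tryCatch(pickPrimer(seq, window, direction, constraints),
           error = function(e) NULL)
}

.newMarkerAcc <- function() {
  list(markers = list(), primers = list(), products = list())
}

.accAdd <- function(acc, marker_id, type, te_type, te_source, junctions,
                    primers, products) {
  mk <- DataFrame(marker_id = marker_id, type = type, te_type = te_type,
                  te_source = te_source, unique_flag = NA)
  mk$junctions <- IRanges::IntegerList(list(as.integer(junctions)))
  acc$markers[[length(acc$markers) + 1L]] <- mk
  acc$primers[[length(acc$primers) + 1L]] <- primers
  acc$products[[length(acc$products) + 1L]] <- products
  acc
}

.accFinish <- function(acc) {
  if (!length(acc$markers)) return(MarkerSet())
  MarkerSet(markers = do.call(rbind, acc$markers),
            primers = do.call(rbind, acc$primers),
            products = do.call(rbind, acc$products))
}

.primerDf <- function(marker_id, role, p, chrom) {
  DataFrame(marker_id = marker_id, role = role, seq = p$seq, chrom = chrom,
            start = p$start, end = p$end, strand = p$strand, tm_c = p$tm_c,
            gc_pct = p$gc_pct)
}

.productDf <- function(marker_id, configuration, chrom, start, end, size) {
  DataFrame(marker_id = marker_id, configuration = configuration,
            chrom = chrom, start = as.integer(start), end = as.integer(end),
            size = as.integer(size))
}

#' Design junction-spanning markers (RJM / ISBP / RJJM)
#'
#' See the operational definitions in the package vignette: RJM and ISBP
#' amplicons span exactly one repeat/unique junction (ISBP when the repeat
#' side is an LTR retrotransposon, taking precedence over RJM); RJJM
#' amplicons span exactly two adjacent junctions.  Junctions with no
#' feasible primer pair are skipped.
#'
#' @param genome sequences (see \code{\link{findLtrPairs}}).
#' @param junctions data.frame from \code{\link{findRepeatJunctions}}.
#' @param annotations the \code{\link{RepeatAnnotations}} the junctions came
#'   from.
#' @param constraints \code{\link{primerConstraints}}.
#' @param types subset of \code{c("RJM", "ISBP", "RJJM")}.
#' @return a \code{\link{MarkerSet}}.
#' @export
designJunctionMarkers <- function(genome, junctions, annotations,
                                  constraints = primerConstraints(),
                                  types = c("RJM", "ISBP", "RJJM")) {
  types <- match.arg(types, several.ok = TRUE)
  seqs <- .asGenome(genome)
  ann <- suppressWarnings(.resolveAnnotationOverlaps(annotations, warn = FALSE))
  idmap <- setNames(seq_along(ann), mcols(ann)$id)
  cn <- constraints
  acc <- .newMarkerAcc()
  ltr_classes <- c("Copia", "Gypsy")

  if (any(c("RJM", "ISBP") %in% types)) {
    ru <- junctions[junctions$kind == "repeat_unique", , drop = FALSE]
    for (r in seq_len(nrow(ru))) {
      j <- ru[r, ]
      chrom <- j$chrom
      s <- chromSeq(seqs, chrom)
      jx <- sort(junctions$pos[junctions$chrom == chrom])
      prev_j <- max(c(0L, jx[jx < j$pos]))
      next_j <- min(c(nchar(s), jx[jx > j$pos]))
      rep_left <- !is.na(j$left_annotation)
      rep_id <- if (rep_left) j$left_annotation else j$right_annotation
      a <- ann[idmap[[rep_id]]]
      cls <- mcols(a)$te_class
      type <- if (cls %in% ltr_classes && "ISBP" %in% types) "ISBP"
              else if ("RJM" %in% types) "RJM" else next
      if (rep_left) {
        rw <- c(max(start(a), j$pos - cn$junction_window + 1L), j$pos)
        rp <- .tryPick(s, rw, "forward", cn)
        if (is.null(rp)) next
        uw <- c(max(j$pos + 1L, rp$start + cn$product_min - cn$len_max),
                min(next_j, j$pos + cn$junction_window,
                    rp$start + cn$product_max - 1L))
        up <- .tryPick(s, uw, "reverse", cn)
        if (is.null(up)) next
        fwd <- rp; rev <- up
        roles <- c("te_internal", "flank_right")
      } else {
        rw <- c(j$pos + 1L, min(end(a), j$pos + cn$junction_window))
        rp <- .tryPick(s, rw, "reverse", cn)
        if (is.null(rp)) next
        uw <- c(max(prev_j + 1L, j$pos - cn$junction_window + 1L,
                    rp$end - cn$product_max + 1L),
                min(j$pos, rp$end - cn$product_min + cn$len_max))
        up <- .tryPick(s, uw, "forward", cn)
        if (is.null(up)) next
        fwd <- up; rev <- rp
        roles <- c("flank_left", "te_internal")
      }
      size <- rev$end - fwd$start + 1L
      if (size < cn$product_min || size > cn$product_max) next
      id <- sprintf("%s_%s_%d", type, chrom, j$pos)
      acc <- .accAdd(acc, id, type, cls, rep_id, j$pos,
                     rbind(.primerDf(id, if (rep_left) roles[1] else roles[1],
                                     if (rep_left) rp else up, chrom),
                           .primerDf(id, roles[2],
                                     if (rep_left) up else rp, chrom)),
                     .productDf(id, "primary", chrom, fwd$start, rev$end, size))
    }
  }

  if ("RJJM" %in% types) {
    for (chrom in unique(junctions$chrom)) {
      s <- chromSeq(seqs, chrom)
      jc <- junctions[junctions$chrom == chrom, , drop = FALSE]
      jc <- jc[order(jc$pos), , drop = FALSE]
      if (nrow(jc) < 2) next
      for (r in seq_len(nrow(jc) - 1L)) {
        j1 <- jc[r, ]; j2 <- jc[r + 1L, ]
        if (j2$pos - j1$pos > cn$product_max - 2L * cn$len_min) next
        prev_j <- if (r > 1) jc$pos[r - 1L] else 0L
        next_j <- if (r + 2L <= nrow(jc)) jc$pos[r + 2L] else nchar(s)
        lw <- c(max(prev_j + 1L, j1$pos - cn$junction_window + 1L), j1$pos)
        lp <- .tryPick(s, lw, "forward", cn)
        if (is.null(lp)) next
        rw <- c(j2$pos + 1L, min(next_j, j2$pos + cn$junction_window,
                                 lp$start + cn$product_max - 1L))
        rp <- .tryPick(s, rw, "reverse", cn)
        if (is.null(rp)) next
        size <- rp$end - lp$start + 1L
        if (size < cn$product_min || size > cn$product_max) next
        mid_id <- j1$right_annotation
        cls <- if (!is.na(mid_id) && mid_id %in% names(idmap))
          mcols(ann)$te_class[idmap[[mid_id]]] else NA_character_
        id <- sprintf("RJJM_%s_%d_%d", chrom, j1$pos, j2$pos)
        acc <- .accAdd(acc, id, "RJJM", cls,
                       if (is.na(mid_id)) NA_character_ else mid_id,
                       c(j1$pos, j2$pos),
                       rbind(.primerDf(id, "flank_left", lp, chrom),
                             .primerDf(id, "flank_right", rp, chrom)),
                       .productDf(id, "primary", chrom, lp$start, rp$end,
                                  size))
      }
    }
  }
  .accFinish(acc)
}

#' Design retroelement markers (RBIP / IRAP / REMAP)
#'
#' RBIP: three primers per element (converging flank pair plus a
#' te_internal primer in the 5' LTR); records both diagnostic products -
#' occupied site (flank + TE) and empty site (flank + flank; size assumes
#' clean excision leaving one TSD copy, or none with
#' \code{empty_site_tsd = "zero"}).  IRAP: element pairs whose inter-element
#' gap is at most \code{irap_max_gap} get outward-facing primers in the
#' facing LTRs.  REMAP: an LTR primer paired with an anchored SSR primer
#' (motif repeated to at least 18 bp plus one 3' anchor base) for SSRs
#' within \code{remap_max_gap} of an LTR terminus.
#'
#' @param genome sequences.
#' @param elements an \code{\link{LtrElementSet}}.
#' @param ssrs data.frame from \code{\link{findSsrs}} with an added
#'   \code{chrom} column (required for REMAP).
#' @param constraints \code{\link{primerConstraints}}.
#' @param types subset of \code{c("RBIP", "IRAP", "REMAP")}.
#' @param irap_max_gap maximum inter-element gap for IRAP (bp).
#' @param remap_max_gap maximum SSR-to-LTR distance for REMAP (bp).
#' @param empty_site_tsd \code{"one"} (default) or \code{"zero"} TSD copies
#'   retained in the RBIP empty allele.
#' @return a \code{\link{MarkerSet}}.
#' @export
designRetroelementMarkers <- function(genome, elements, ssrs = NULL,
                                      constraints = primerConstraints(),
                                      types = c("RBIP", "IRAP", "REMAP"),
                                      irap_max_gap = 3000,
                                      remap_max_gap = 2000,
                                      empty_site_tsd = c("one", "zero")) {
  types <- match.arg(types, several.ok = TRUE)
  empty_site_tsd <- match.arg(empty_site_tsd)
  seqs <- .asGenome(genome)
  cn <- constraints
  acc <- .newMarkerAcc()
  m <- mcols(elements)

  if ("RBIP" %in% types) {
    for (i in seq_along(elements)) {
      chrom <- as.character(seqnames(elements)[i])
      s <- chromSeq(seqs, chrom)
      st <- start(elements)[i]; en <- end(elements)[i]
      fl <- .tryPick(s, c(max(1L, st - cn$junction_window), st - 1L),
                     "forward", cn)
      if (is.null(fl)) next
      ti <- .tryPick(s, c(m$ltr5_start[i],
                          min(m$ltr5_end[i], fl$start + cn$product_max - 1L)),
                     "reverse", cn)
      if (is.null(ti)) next
      fr <- .tryPick(s, c(en + 1L, min(nchar(s), en + cn$junction_window)),
                     "reverse", cn)
      if (is.null(fr)) next
      occ_size <- ti$end - fl$start + 1L
      if (occ_size < cn$product_min || occ_size > cn$product_max) next
      tsd_len <- if (!is.null(m$tsd) && !is.na(m$tsd[i])) nchar(m$tsd[i]) else 0L
      removed <- (en - st + 1L) +
        if (empty_site_tsd == "one") tsd_len else 2L * tsd_len
      empty_size <- (fr$end - fl$start + 1L) - removed
      id <- paste0("RBIP_", m$id[i])
      sf <- m$superfamily[i] %||% NA_character_
      acc <- .accAdd(acc, id, "RBIP",
                     if (is.na(sf)) "LTR" else sf, m$id[i],
                     c(st - 1L, en),
                     rbind(.primerDf(id, "flank_left", fl, chrom),
                           .primerDf(id, "te_internal", ti, chrom),
                           .primerDf(id, "flank_right", fr, chrom)),
                     rbind(.productDf(id, "occupied", chrom, fl$start, ti$end,
                                      occ_size),
                           .productDf(id, "empty_site", chrom, NA, NA,
                                      empty_size)))
    }
  }

  if ("IRAP" %in% types && length(elements) >= 2) {
    for (chrom in unique(as.character(seqnames(elements)))) {
      idx <- which(as.character(seqnames(elements)) == chrom)
      idx <- idx[order(start(elements)[idx])]
      s <- chromSeq(seqs, chrom)
      for (k in seq_len(length(idx) - 1L)) {
        i1 <- idx[k]; i2 <- idx[k + 1L]
        gap <- start(elements)[i2] - end(elements)[i1] - 1L
        if (gap < 1L || gap > irap_max_gap) next
        w1 <- c(max(m$ltr3_start[i1],
                    end(elements)[i1] - cn$junction_window + 1L),
                end(elements)[i1])
        p1 <- .tryPick(s, w1, "forward", cn)
        if (is.null(p1)) next
        w2 <- c(start(elements)[i2],
                min(m$ltr5_end[i2],
                    start(elements)[i2] + cn$junction_window - 1L))
        p2 <- .tryPick(s, w2, "reverse", cn)
        if (is.null(p2)) next
        size <- p2$end - p1$start + 1L
        id <- paste0("IRAP_", m$id[i1], "_", m$id[i2])
        acc <- .accAdd(acc, id, "IRAP", "LTR",
                       paste(m$id[i1], m$id[i2], sep = ","),
                       c(end(elements)[i1], start(elements)[i2] - 1L),
                       rbind(.primerDf(id, "ltr_out", p1, chrom),
                             .primerDf(id, "ltr_out", p2, chrom)),
                       .productDf(id, "primary", chrom, p1$start, p2$end,
                                  size))
      }
    }
  }

  if ("REMAP" %in% types && !is.null(ssrs) && nrow(ssrs)) {
    if (is.null(ssrs$chrom)) ssrs$chrom <- names(seqs)[[1]]
    for (i in seq_along(elements)) {
      chrom <- as.character(seqnames(elements)[i])
      s <- chromSeq(seqs, chrom)
      sc <- ssrs[ssrs$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(sc))) {
        ss <- sc[r, ]
        span <- ceiling(18 / ss$motif_len) * ss$motif_len
        if (span + 1L > ss$end - ss$start + 2L) next  # SSR too short to anchor
        if (ss$start > end(elements)[i] &&
            ss$start - end(elements)[i] - 1L <= remap_max_gap) {
          # SSR right of the element: LTR primer faces right
          lw <- c(max(m$ltr3_start[i],
                      end(elements)[i] - cn$junction_window + 1L),
                  end(elements)[i])
          lp <- .tryPick(s, lw, "forward", cn)
          if (is.null(lp)) next
          a0 <- ss$start - 1L
          slice <- substr(s, a0, a0 + span)
          ap <- data.frame(seq = revComp(slice), start = a0,
                           end = a0 + span, strand = "-",
                           tm_c = tmNearestNeighbor(revComp(slice)),
                           gc_pct = gcFraction(slice) * 100)
          size <- ap$end - lp$start + 1L
          id <- paste0("REMAP_", m$id[i], "_", ss$start)
          acc <- .accAdd(acc, id, "REMAP",
                         m$superfamily[i] %||% "LTR", m$id[i],
                         end(elements)[i],
                         rbind(.primerDf(id, "ltr_out", lp, chrom),
                               .primerDf(id, "ssr_anchor", ap, chrom)),
                         .productDf(id, "primary", chrom, lp$start, ap$end,
                                    size))
        } else if (ss$end < start(elements)[i] &&
                   start(elements)[i] - ss$end - 1L <= remap_max_gap) {
          # SSR left of the element: LTR primer faces left
          lw <- c(start(elements)[i],
                  min(m$ltr5_end[i],
                      start(elements)[i] + cn$junction_window - 1L))
          lp <- .tryPick(s, lw, "reverse", cn)
          if (is.null(lp)) next
          a1 <- ss$end + 1L
          slice <- substr(s, a1 - span, a1)
          ap <- data.frame(seq = slice, start = a1 - span, end = a1,
                           strand = "+", tm_c = tmNearestNeighbor(slice),
                           gc_pct = gcFraction(slice) * 100)
          size <- lp$end - ap$start + 1L
          id <- paste0("REMAP_", m$id[i], "_", ss$start)
          acc <- .accAdd(acc, id, "REMAP",
                         m$superfamily[i] %||% "LTR", m$id[i],
                         start(elements)[i] - 1L,
                         rbind(.primerDf(id, "ssr_anchor", ap, chrom),
                               .primerDf(id, "ltr_out", lp, chrom)),
                         .productDf(id, "primary", chrom, ap$start, lp$end,
                                    size))
        }
      }
    }
  }
  .accFinish(acc)
}

#' Design RJMs anchored in exons for LINE insertions
#'
#' RJM design where the unique-side primer must lie in an exon of a gene
#' model overlapping the junction flank (mirrors manual LINE marker
#' design); the amplicon spans the exon/TE junction.
#'
#' @param genome sequences.
#' @param line_annotations \code{\link{RepeatAnnotations}} of LINE elements.
#' @param gene_models \code{GRanges} of exons with a \code{gene_id} column.
#' @param constraints \code{\link{primerConstraints}}.
#' @return a \code{\link{MarkerSet}} (type RJM, te_type LINE).
#' @export
designLineRjm <- function(genome, line_annotations, gene_models,
                          constraints = primerConstraints()) {
  seqs <- .asGenome(genome)
  cn <- constraints
  acc <- .newMarkerAcc()
  lines <- line_annotations[mcols(line_annotations)$te_class == "LINE"]
  for (i in seq_along(lines)) {
    chrom <- as.character(seqnames(lines)[i])
    s <- chromSeq(seqs, chrom)
    st <- start(lines)[i]; en <- end(lines)[i]
    ex <- gene_models[as.character(seqnames(gene_models)) == chrom]
    done <- FALSE
    # left junction: exon-side primer upstream, TE primer inside the LINE
    for (side in c("left", "right")) {
      if (done) break
      b <- if (side == "left") st - 1L else en
      flank <- if (side == "left")
        IRanges(max(1L, b - cn$junction_window + 1L), b)
      else IRanges(b + 1L, min(nchar(s), b + cn$junction_window))
      hits <- ex[IRanges::overlapsAny(IRanges::ranges(ex), flank)]
      if (!length(hits)) next
      exw <- IRanges::pintersect(IRanges::ranges(hits)[1], flank)
      exw <- c(IRanges::start(exw), IRanges::end(exw))
      if (side == "left") {
        ep <- .tryPick(s, exw, "forward", cn)
        if (is.null(ep)) next
        tw <- c(b + 1L, min(en, b + cn$junction_window,
                            ep$start + cn$product_max - 1L))
        tp <- .tryPick(s, tw, "reverse", cn)
        if (is.null(tp)) next
        fwd <- ep; rev <- tp
      } else {
        tp <- .tryPick(s, c(max(st, b - cn$junction_window + 1L), b),
                       "forward", cn)
        if (is.null(tp)) next
        ew <- c(max(exw[1], tp$start + cn$product_min - cn$len_max),
                min(exw[2], tp$start + cn$product_max - 1L))
        ep <- .tryPick(s, ew, "reverse", cn)
        if (is.null(ep)) next
        fwd <- tp; rev <- ep
      }
      size <- rev$end - fwd$start + 1L
      if (size < cn$product_min || size > cn$product_max) next
      id <- sprintf("RJM_LINE_%s_%d", chrom, b)
      gene <- mcols(hits)$gene_id[1]
      acc <- .accAdd(acc, id, "RJM", "LINE", mcols(lines)$id[i], b,
                     rbind(.primerDf(id, if (side == "left") "flank_left"
                                         else "te_internal", fwd, chrom),
                           .primerDf(id, if (side == "left") "te_internal"
                                         else "flank_right", rev, chrom)),
                     .productDf(id, "primary", chrom, fwd$start, rev$end,
                                size))
      done <- TRUE
    }
  }
  .accFinish(acc)
}
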