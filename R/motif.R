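#' Scan a genome for an IUPAC consensus motif
#'
#' Both strands are scanned (the reverse strand by matching the reverse
#' complement of the consensus on the forward sequence) and all occurrences
#' are reported, including overlapping ones. Each occurrence is anchored at
#' its center, `start + floor(length/2)` in 0-based coordinates, so that
#' positional curves built from it are symmetric.
#'
#' @param sequence A [Biostrings::DNAStringSet-class] genome.
#' @param consensus Non-empty IUPAC consensus string.
#' @return Data frame `chrom`, `center` (0-based), `strand`.
#' @export
scan_consensus <- function(sequence, consensus) {
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  letters <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters %in% names(Biostrings::IUPAC_CODE_MAP)))
    stop("invalid IUPAC code in consensus: ",
         paste(unique(setdiff(letters, names(Biostrings::IUPAC_CODE_MAP))),
               collapse = ", "))
  pat <- Biostrings::DNAString(consensus)
  half <- floor(nchar(consensus) / 2)
  one_strand <- function(p, strand) {
    m <- Biostrings::vmatchPattern(p, sequence, fixed = FALSE)
    do.call(rbind, lapply(seq_along(m), function(i) {
      st <- Biostrings::startIndex(m)[[i]]
      if (is.null(st) || !length(st)) return(NULL)
      data.frame(chrom = names(sequence)[i],
                 center = (st - 1L) + half,
                 strand = strand, stringsAsFactors = FALSE)
    }))
  }
  fwd <- one_strand(pat, "+")
  rev <- one_strand(Biostrings::reverseComplement(pat), "-")
  out <- rbind(fwd, rev)
  if (is.null(out))
    out <- data.frame(chrom = character(0), center = integer(0),
                      strand = character(0))
  out <- out[order(out$chrom, out$center), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif positional-probability curve around summits
#'
#' For each offset `o` in `-W..W`, the raw probability is the fraction of
#' summits with at least one motif occurrence centered exactly at
#' `summit + o` (strand collapsed). The smoothed curve is a centered moving
#' average; the background level is the mean smoothed probability over the
#' flanks `|o|` in `[flank_from, W]`.
#'
#' @param occurrences Output of [scan_consensus()].
#' @param summits Data frame `chrom`, `summit` (0-based positions), or a
#'   [peak_set()].
#' @param W Half-window (bp, default 250; must be > 0).
#' @param smooth_window Moving-average window (odd, bp; default 5).
#' @param flank_from Inner edge of the background flank (bp, default 200).
#' @return Object of class `positional_curve`: data frame `offset`, `raw`,
#'   `smoothed`, with attributes `background`, `background_sd`, `n_summits`.
#' @export
positional_curve <- function(occurrences, summits, W = 250,
                             smooth_window = 5, flank_from = 200) {
  if (W <= 0) stop("W must be > 0")
  if (!nrow(summits)) stop("positional_curve: need >= 1 summit")
  n <- nrow(summits)
  counts <- integer(2 * W + 1)
  for (ch in unique(summits$chrom)) {
    cen <- sort(unique(occurrences$center[occurrences$chrom == ch]))
    ss <- summits$summit[summits$chrom == ch]
    if (!length(cen)) next
    for (s in ss) {
      lo <- findInterval(s - W - 1L, cen) + 1L
      hi <- findInterval(s + W, cen)
      if (hi < lo) next
      offs <- cen[lo:hi] - s
      counts[offs + W + 1L] <- counts[offs + W + 1L] + 1L
    }
  }
  raw <- counts / n
  kern <- rep(1 / smooth_window, smooth_window)
  smoothed <- as.numeric(stats::filter(raw, kern, sides = 2))
  smoothed[is.na(smoothed)] <- raw[is.na(smoothed)]
  offset <- seq(-W, W)
  flank <- abs(offset) >= flank_from
  bg <- if (any(flank)) mean(smoothed[flank]) else 0
  bg_sd <- if (sum(flank) > 1) stats::sd(smoothed[flank]) else 0
  out <- data.frame(offset = offset, raw = raw, smoothed = smoothed)
  attr(out, "background") <- bg
  attr(out, "background_sd") <- bg_sd
  attr(out, "n_summits") <- n
  class(out) <- c("positional_curve", "data.frame")
  out
}

#' Enriched-region width, apex offsets and bimodality of a positional curve
#'
#' The enriched region is the maximal contiguous run of offsets where the
#' smoothed probability exceeds `background + z * background_sd` and which
#' contains the global maximum of the smoothed curve (ties toward the offset
#' closest to zero). The apex on each side of zero is the argmax of the
#' smoothed curve over that side of the enriched region. The curve is called
#' bimodal when both side apexes reach at least 70 percent of the global
#' maximum *and* the curve dips below half of the lower apex between them
#' (the valley requirement keeps a smoothed single central peak, whose
#' plateau spans both signs, unimodal).
#'
#' @param curve A [positional_curve()].
#' @param z Enrichment threshold in flank standard deviations (default 2).
#' @return List of class `curve_metrics`: `width` (bp), `apexes` (signed
#'   offsets, length 1 or 2), `bimodal`, `threshold`.
#' @export
curve_metrics <- function(curve, z = 2) {
  sm <- curve$smoothed
  off <- curve$offset
  thr <- attr(curve, "background") + z * attr(curve, "background_sd")
  above <- sm > thr
  if (!any(above) || max(sm) <= 0)
    return(structure(list(width = 0L, apexes = integer(0), bimodal = FALSE,
                          threshold = thr), class = "curve_metrics"))
  peak_i <- which(sm == max(sm))
  peak_i <- peak_i[order(abs(off[peak_i]), off[peak_i])][1]
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- which(r$values & starts <= peak_i & ends >= peak_i)
  region <- starts[run]:ends[run]
  width <- length(region)

  gmax <- sm[peak_i]
  side <- function(sel) {
    if (!length(sel)) return(NULL)
    i <- sel[order(-sm[sel], abs(off[sel]))][1]
    list(i = i, val = sm[i])
  }
  left <- side(region[off[region] < 0])
  right <- side(region[off[region] > 0])
  bimodal <- FALSE
  apexes <- off[peak_i]
  if (!is.null(left) && !is.null(right) &&
      left$val >= 0.7 * gmax && right$val >= 0.7 * gmax) {
    between <- region[region > left$i & region < right$i]
    valley <- if (length(between)) min(sm[between]) else Inf
    if (valley < 0.5 * min(left$val, right$val)) {
      bimodal <- TRUE
      apexes <- c(off[left$i], off[right$i])
    }
  }
  structure(list(width = width, apexes = apexes, bimodal = bimodal,
                 threshold = thr), class = "curve_metrics")
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("curve_metrics: enriched width %d bp; apex offset(s) %s; bimodal %s\n",
              x$width, paste(x$apexes, collapse = ", "), x$bimodal))
  invisible(x)
}

#' Write a positional curve as TSV
#' @param curve A [positional_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
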