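#' Filter peaks by strength thresholds and a blacklist
#'
#' Retains peaks with `pileup >= min_pileup` and
#' `fold_enrichment >= min_fe` that share no base with any blacklist
#' interval (the whole peak interval is tested, not just the summit, because
#' blacklists flag artifact regions rather than points). Input order is
#' preserved and the operation is idempotent. The default thresholds are the
#' stringent criteria used to call the peak universes analysed here
#' (pileup >= 50, fold enrichment over input >= 5).
#'
#' @param peaks A [peak_set()].
#' @param blacklist Optional blacklist as a `GRanges` or a data.frame with
#'   0-based half-open `chrom`, `start`, `end` (see [read_blacklist()]).
#' @param min_pileup,min_fe Thresholds (>= 0).
#' @return The filtered [peak_set()].
#' @export
filter_peaks <- function(peaks, blacklist = NULL, min_pileup = 50,
                         min_fe = 5) {
  stopifnot(min_pileup >= 0, min_fe >= 0)
  keep <- peaks$pileup >= min_pileup & peaks$fold_enrichment >= min_fe
  if (!is.null(blacklist) && nrow(peaks)) {
    bl <- if (inherits(blacklist, "GRanges")) blacklist
          else GenomicRanges::GRanges(blacklist$chrom,
                 IRanges::IRanges(start = blacklist$start + 1L,
                                  end = blacklist$end))
    if (length(bl)) {
      hits <- GenomicRanges::countOverlaps(.peaks_granges(peaks), bl)
      keep <- keep & hits == 0L
    }
  }
  out <- peaks[keep, , drop = FALSE]
  attr(out, "factor") <- attr(peaks, "factor")
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Read a blacklist BED file
#'
#' @param path BED file of artifact-prone regions.
#' @return A `GRanges` of blacklist intervals.
#' @export
read_blacklist <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Select the strongest peaks at a pileup threshold
#'
#' @param peaks A non-empty [peak_set()].
#' @param pileup_threshold Retain peaks with `pileup >= pileup_threshold`.
#' @return List with `peaks` (the retained [peak_set()]) and
#'   `retained_fraction`, the percentage retained rounded to one decimal
#'   (e.g. 3797 of 18385 gives 20.7).
#' @export
select_top <- function(peaks, pileup_threshold) {
  if (!nrow(peaks)) stop("select_top: empty peak set")
  keep <- peaks$pileup >= pileup_threshold
  out <- peaks[keep, , drop = FALSE]
  attr(out, "factor") <- attr(peaks, "factor")
  class(out) <- c("peak_set", "data.frame")
  list(peaks = out,
       retained_fraction = round(100 * sum(keep) / nrow(peaks), 1))
}

#' Group peaks into equal-size strength cohorts
#'
#' Peaks are sorted by pileup descending (ties broken by fold enrichment
#' descending, then chromosome, then start) and split into `n_cohorts`
#' cohorts of exactly `floor(N / n_cohorts)` peaks; cohort 1 is the
#' strongest. The `N %% n_cohorts` weakest peaks are discarded, which
#' reproduces equal cohort sizes such as 1838 per cohort from 18,385 peaks.
#'
#' @param peaks A [peak_set()] with at least `n_cohorts` peaks.
#' @param n_cohorts Number of cohorts (default 10).
#' @return An object of class `cohort_table`: data.frame `name`, `pileup`,
#'   `cohort` plus attributes `cohort_size` and `discarded` (names).
#' @export
assign_cohorts <- function(peaks, n_cohorts = 10) {
  n <- nrow(peaks)
  if (n < n_cohorts)
    stop(sprintf("assign_cohorts: %d peaks < %d cohorts", n, n_cohorts))
  ord <- order(-peaks$pileup, -peaks$fold_enrichment, peaks$chrom,
               peaks$start)
  size <- n %/% n_cohorts
  kept <- ord[seq_len(size * n_cohorts)]
  discarded <- peaks$name[ord[-seq_len(size * n_cohorts)]]
  tab <- data.frame(name = peaks$name[kept],
                    pileup = peaks$pileup[kept],
                    cohort = rep(seq_len(n_cohorts), each = size),
                    stringsAsFactors = FALSE)
  attr(tab, "cohort_size") <- size
  attr(tab, "discarded") <- discarded
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d cohorts x %d peaks (%d discarded)\n",
              max(x$cohort), attr(x, "cohort_size"),
              length(attr(x, "discarded"))))
  rng <- stats::aggregate(pileup ~ cohort, data = x, FUN = function(v)
    sprintf("[%.1f, %.1f]", min(v), max(v)))
  print.data.frame(rng, row.names = FALSE)
  invisible(x)
}

#' Annotate peak summits against gene models
#'
#' Assigns each peak's summit to one category with precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > TTS > intergenic. The promoter
#' is the strand-aware window `[TSS-1000, TSS+100)` and the TTS region
#' `[TES-100, TES+1000)`. When the gene table carries exon structure
#' (`exon_starts`/`exon_ends`), the first exon in transcription order is
#' treated as 5'UTR and the last as 3'UTR; without exon structure the
#' exon/UTR categories collapse to `gene_body`. Peaks on chromosomes absent
#' from the gene table raise a warning and are classified against the
#' remaining genes (hence intergenic).
#'
#' @param peaks A [peak_set()].
#' @param genes Gene table data.frame: `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `tes` (0-based positions), optionally
#'   `exon_starts`, `exon_ends` (comma-separated 0-based half-open).
#' @param promoter_window,tts_window Length-2 signed windows in
#'   transcription orientation relative to TSS and TES.
#' @return List of class `annotation_result`: `category` (named character,
#'   one per peak) and `counts` (table over all categories).
#' @export
annotate_peaks <- function(peaks, genes,
                           promoter_window = c(-1000, 100),
                           tts_window = c(-100, 1000)) {
  has_exons <- all(c("exon_starts", "exon_ends") %in% names(genes))
  cats <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "TTS",
            "intergenic")
  if (!has_exons)
    cats <- c("promoter", "gene_body", "TTS", "intergenic")
  unknown <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unknown))
    warning("peak chromosome(s) absent from gene table: ",
            paste(unknown, collapse = ", "))
  category <- rep("intergenic", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    p <- peaks$summit[i]
    sgn <- ifelse(g$strand == "+", 1L, -1L)
    d_tss <- (p - g$tss) * sgn
    d_tes <- (p - g$tes) * sgn
    in_prom <- d_tss >= promoter_window[1] & d_tss < promoter_window[2]
    in_tts <- d_tes >= tts_window[1] & d_tes < tts_window[2]
    lo <- pmin(g$tss, g$tes); hi <- pmax(g$tss, g$tes)
    in_body <- p >= lo & p < hi
    if (any(in_prom)) { category[i] <- "promoter"; next }
    if (has_exons && any(in_body)) {
      sub <- g[in_body, , drop = FALSE]
      lab <- NULL
      for (k in seq_len(nrow(sub))) {
        es <- as.integer(strsplit(sub$exon_starts[k], ",")[[1]])
        ee <- as.integer(strsplit(sub$exon_ends[k], ",")[[1]])
        hit <- which(p >= es & p < ee)
        this <- if (!length(hit)) "intron"
          else {
            # exon order along genome; transcription order depends on strand
            first_tx <- if (sub$strand[k] == "+") 1L else length(es)
            last_tx <- if (sub$strand[k] == "+") length(es) else 1L
            if (hit[1] == first_tx) "5'UTR"
            else if (hit[1] == last_tx) "3'UTR"
            else "exon"
          }
        lab <- c(lab, this)
      }
      # precedence within overlapping genes
      for (cand in c("5'UTR", "3'UTR", "exon", "intron"))
        if (cand %in% lab) { category[i] <- cand; break }
      next
    }
    if (!has_exons && any(in_body)) { category[i] <- "gene_body"; next }
    if (any(in_tts)) { category[i] <- "TTS"; next }
  }
  names(category) <- peaks$name
  counts <- table(factor(category, levels = cats))
  structure(list(category = category, counts = counts),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("Peak summit annotation (n =", sum(x$counts), "):\n")
  pct <- round(100 * x$counts / max(1, sum(x$counts)), 1)
  print(data.frame(category = names(x$counts),
                   n = as.integer(x$counts), pct = as.numeric(pct)),
        row.names = FALSE)
  invisible(x)
}
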