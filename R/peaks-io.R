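#' Construct a peak set
#'
#' Internal coordinates are 0-based half-open throughout; `summit` is a
#' 0-based absolute position with `start <= summit < end`. `pileup` is the
#' MACS2 per-peak read-depth statistic used as peak strength;
#' `fold_enrichment` is signal relative to the input library (may be `Inf`
#' when the source format carries none, so it never filters).
#'
#' @param chrom,start,end,name,pileup,fold_enrichment,summit Peak fields.
#' @param factor Factor label for the whole set.
#' @return A data.frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, name, pileup,
                     fold_enrichment = Inf, summit, factor = "") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name),
                   pileup = as.numeric(pileup),
                   fold_enrichment = as.numeric(fold_enrichment),
                   summit = as.integer(summit),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$end <= df$start))
      stop("peak_set: end must be > start")
    if (any(df$summit < df$start | df$summit >= df$end))
      stop("peak_set: start <= summit < end violated")
    if (anyDuplicated(df$name))
      stop("peak_set: peak names must be unique within a set")
    if (any(df$pileup < 0) || any(df$fold_enrichment < 0))
      stop("peak_set: pileup and fold_enrichment must be >= 0")
  }
  attr(df, "factor") <- factor
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s)",
              attr(x, "factor"), nrow(x), length(unique(x$chrom))))
  if (nrow(x))
    cat(sprintf("; pileup range [%.1f, %.1f]",
                min(x$pileup), max(x$pileup)))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# 0-based half-open peak intervals as GRanges (1-based closed internally).
.peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Read an ENCODE narrowPeak file
#'
#' Ten-column BED6+4. Pileup is taken from the signalValue column (column
#' 7); narrowPeak carries no fold-enrichment field, so fold enrichment is set
#' to `Inf` (never filters) unless a sidecar MACS2 xls is supplied, in which
#' case it is joined by peak name. Column 10 is the summit offset from
#' `start`; an offset of -1 maps to the interval midpoint.
#'
#' @param path narrowPeak file.
#' @param factor Factor label.
#' @param xls_sidecar Optional MACS2 xls path supplying fold enrichment.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, factor = "", xls_sidecar = NULL) {
  nf <- utils::count.fields(path, sep = "", comment.char = "")
  bad <- which(!is.na(nf) & nf != 10L)
  if (length(bad))
    stop(sprintf("malformed narrowPeak line %d in %s: expected 10 columns, found %d",
                 bad[1], path, nf[bad[1]]))
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- utils::read.table(path, sep = "", col.names = cols,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer"))
  summit <- ifelse(df$peak >= 0L, df$start + df$peak,
                   (df$start + df$end) %/% 2L)
  fe <- rep(Inf, nrow(df))
  if (!is.null(xls_sidecar)) {
    side <- read_macs2_xls(xls_sidecar)
    fe <- side$fold_enrichment[match(df$name, side$name)]
    fe[is.na(fe)] <- Inf
  }
  peak_set(df$chrom, df$start, df$end, df$name, df$signalValue,
           fe, summit, factor = factor)
}

#' Write a peak set as narrowPeak
#'
#' Pileup is written to signalValue (column 7) and the summit as an offset
#' from start (column 10); pValue/qValue are written as -1 (not available).
#'
#' @param peaks A [peak_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   0L, ".", peaks$pileup, -1, -1,
                   peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MACS2 .xls peak table
#'
#' The MACS2 "xls" dialect is a tab-separated text table with `#` comment
#' lines and a header row including `chr`, `start`, `end`, `abs_summit`,
#' `pileup`, `fold_enrichment` and `name`. MACS2 coordinates are 1-based
#' inclusive; they are converted to the package's 0-based half-open
#' convention at this boundary (`start - 1`, `abs_summit - 1`).
#'
#' @param path MACS2 xls file.
#' @param factor Factor label.
#' @return A [peak_set()]; comment-only files give an empty set.
#' @export
read_macs2_xls <- function(path, factor = "") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(peak_set(character(0), integer(0), integer(0), character(0),
                    numeric(0), numeric(0), integer(0), factor = factor))
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("chr", "start", "end", "abs_summit", "pileup",
            "fold_enrichment", "name")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MACS2 xls missing required column(s): ",
         paste(miss, collapse = ", "))
  peak_set(df$chr, df$start - 1L, df$end, df$name, df$pileup,
           df$fold_enrichment, df$abs_summit - 1L, factor = factor)
}

#' Write a peak set in the MACS2 .xls dialect
#'
#' @param peaks A [peak_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_macs2_xls <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# peaks written by cooccupy (MACS2 xls dialect)", con)
  df <- data.frame(chr = peaks$chrom, start = peaks$start + 1L,
                   end = peaks$end, length = peaks$end - peaks$start,
                   abs_summit = peaks$summit + 1L, pileup = peaks$pileup,
                   X.log10.pvalue. = -1,
                   fold_enrichment = peaks$fold_enrichment,
                   X.log10.qvalue. = -1, name = peaks$name,
                   check.names = FALSE)
  names(df)[7] <- "-log10(pvalue)"
  names(df)[9] <- "-log10(qvalue)"
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}
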