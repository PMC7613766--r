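#' Construct a signal track object
#'
#' A `signal_track` is per-chromosome binned, non-negative coverage for one
#' factor or mark in one condition: bin `j` (0-based) covers
#' `[j*bin_size, (j+1)*bin_size)` and its value is attached to the bin
#' center.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width (bp).
#' @param factor Factor or mark label.
#' @param condition Condition label (e.g. `"ntc"`, `"kd"`).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, factor = "", condition = "") {
  if (bin_size <= 0) stop("bin_size must be > 0")
  stopifnot(is.list(values), !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("signal track values must be >= 0")
  structure(list(values = values, bin_size = bin_size,
                 factor = factor, condition = condition),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  tot <- sum(vapply(x$values, sum, numeric(1)))
  cat(sprintf("signal_track '%s' (%s): %d chrom(s), bin %d bp, total signal %.3g\n",
              x$factor, x$condition, length(x$values),
              as.integer(x$bin_size), tot))
  invisible(x)
}

# Bin index range and values of one Gaussian bump (height at summit, sd in
# bp), truncated at cutoff standard deviations.
.bump_bins <- function(nbins, bin_size, summit, height, sd, cutoff = 8) {
  lo <- max(0L, as.integer(floor((summit - cutoff * sd) / bin_size)))
  hi <- min(nbins - 1L, as.integer(ceiling((summit + cutoff * sd) / bin_size)))
  if (hi < lo || height <= 0)
    return(list(idx = integer(0), add = numeric(0)))
  j <- lo:hi
  centers <- j * bin_size + bin_size / 2
  list(idx = j + 1L, add = height * exp(-(centers - summit)^2 / (2 * sd^2)))
}

#' Render binned signal tracks from the ground truth
#'
#' Per-site signal is a Gaussian bump centered on the factor's summit with
#' height proportional to its strength; the knockdown condition multiplies
#' the bump by the site's retention fraction. The knockdown tracks of the
#' three repressor-complex factors are additionally scaled by the configured
#' global condition scale, emulating a shared between-condition depth
#' difference that downstream anchored normalization removes via the anchor
#' factor's own signal (the anchor's biological retention is 1). Acetylation
#' and
#' accessibility bumps are centered on the site and follow the planted
#' inverse-strength baseline and knockdown-gain rules; the `h3k4me1` mark is
#' strength-neutral. Per-bin Poisson noise is applied to the expected counts
#' when `config$poisson_noise` is `TRUE`.
#'
#' @param truth Ground-truth table from [plant_sites()].
#' @param genome_model Data frame `chrom`, `length` (see [generate_genome()]).
#' @param config A [sim_config()].
#' @param what Tracks to render, a subset of
#'   `c("hmg20b","lsd1","gfi1","control","h3k27ac","atac","h3k4me1")`.
#' @return Nested list `tracks[[what]][[condition]]` of [signal_track()]
#'   objects with conditions `ntc` and `kd`.
#' @export
render_tracks <- function(truth, genome_model, config,
                          what = c("hmg20b", "lsd1", "gfi1", "control",
                                   "h3k27ac", "atac")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$bin_size <= 0) stop("bin_size must be > 0")
  set.seed(.stage_seed(config, "tracks"))
  bs <- config$bin_size
  sd <- config$bump_sd
  empty <- function() {
    v <- lapply(genome_model$length, function(L) numeric(ceiling(L / bs)))
    names(v) <- genome_model$chrom
    v
  }
  site <- truth[!truth$control, , drop = FALSE]
  ctrl <- truth[truth$control, , drop = FALSE]

  spec <- list(
    hmg20b  = list(rows = site, summit = "hmg20b_summit",
                   height = site$strength_hmg20b,
                   ret = site$retention_hmg20b,
                   scale_kd = config$gfi1_condition_scale),
    lsd1    = list(rows = site, summit = "lsd1_summit",
                   height = site$strength_lsd1,
                   ret = site$retention_lsd1,
                   scale_kd = config$gfi1_condition_scale),
    gfi1    = list(rows = site, summit = "gfi1_summit",
                   height = site$strength_gfi1,
                   ret = site$retention_gfi1,
                   scale_kd = config$gfi1_condition_scale),
    control = list(rows = ctrl, summit = "gfi1_summit",
                   height = ctrl$strength_hmg20b,
                   ret = rep(1, nrow(ctrl)), scale_kd = 1),
    h3k27ac = list(rows = truth, summit = "gfi1_summit",
                   height = truth$acet_baseline,
                   ret = truth$acet_kd_gain, scale_kd = 1),
    atac    = list(rows = truth, summit = "gfi1_summit",
                   height = truth$atac_baseline,
                   ret = truth$acet_kd_gain, scale_kd = 1),
    h3k4me1 = list(rows = truth, summit = "gfi1_summit",
                   height = rep(config$acet_baseline, nrow(truth)),
                   ret = rep(1, nrow(truth)), scale_kd = 1))
  what <- match.arg(what, names(spec), several.ok = TRUE)

  out <- list()
  for (w in what) {
    sp <- spec[[w]]
    rows <- sp$rows
    for (cond in c("ntc", "kd")) {
      vals <- empty()
      if (nrow(rows)) {
        h <- if (cond == "ntc") sp$height else sp$height * sp$ret * sp$scale_kd
        for (ch in names(vals)) {
          sel <- which(rows$chrom == ch & !is.na(rows[[sp$summit]]))
          if (!length(sel)) next
          v <- vals[[ch]]
          for (i in sel) {
            b <- .bump_bins(length(v), bs, rows[[sp$summit]][i], h[i], sd)
            v[b$idx] <- v[b$idx] + b$add
          }
          vals[[ch]] <- v
        }
      }
      if (isTRUE(config$poisson_noise))
        vals <- lapply(vals, function(v) as.numeric(stats::rpois(length(v), v)))
      out[[w]][[cond]] <- signal_track(vals, bs, factor = w, condition = cond)
    }
  }
  out
}

#' Write a signal track as bedGraph
#'
#' Zero-valued bins are omitted, matching common bedGraph practice.
#'
#' @param track A [signal_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  bs <- track$bin_size
  dfl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    j <- which(v != 0) - 1L
    if (!length(j)) return(NULL)
    data.frame(chrom = ch, start = j * bs + 1L, score = v[j + 1L],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfl)
  gr <- if (!is.null(df) && nrow(df))
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start, width = bs),
                           score = df$score)
  else GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a signal track
#'
#' Intervals must be aligned to a uniform bin grid of width `bin_size`;
#' missing bins become zero.
#'
#' @param path bedGraph file.
#' @param bin_size Bin width (bp).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param factor,condition Labels for the returned track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths,
                          factor = "", condition = "") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(chrom_lengths, function(L) numeric(ceiling(L / bin_size)))
  names(vals) <- names(chrom_lengths)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = gr$score, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% names(vals)) next
    j0 <- df$start[i] %/% bin_size
    j1 <- (df$end[i] - 1L) %/% bin_size
    vals[[ch]][(j0:j1) + 1L] <- df$score[i]
  }
  signal_track(vals, bin_size, factor = factor, condition = condition)
}
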