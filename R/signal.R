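#' Mean signal in windows around peak summits
#'
#' For each peak, the mean of the track bins whose center lies in
#' `[summit - h, summit + h)` (membership by bin center, half-open on the
#' right). Windows partially off the chromosome use the available bins; a
#' window entirely off the chromosome is an error.
#'
#' @param track A [signal_track()].
#' @param peaks A [peak_set()].
#' @param h Half-window (bp, > 0); the analyses here use 1000 bp for
#'   acetylation fold changes and 300 bp for factor-ratio windows.
#' @return Object of class `window_signal`: named numeric vector (peak name
#'   -> mean signal) with attributes `h` and `condition`.
#' @export
window_signal <- function(track, peaks, h) {
  stopifnot(inherits(track, "signal_track"), h > 0)
  bs <- track$bin_size
  out <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v))
      stop("window_signal: chromosome ", ch, " absent from track")
    s <- peaks$summit[i]
    j_lo <- ceiling((s - h - bs / 2) / bs)
    j_hi <- ceiling((s + h - bs / 2) / bs) - 1
    if (j_hi < 0 || j_lo > length(v) - 1)
      stop("window_signal: window entirely off chromosome for peak ",
           peaks$name[i])
    j_lo <- max(j_lo, 0); j_hi <- min(j_hi, length(v) - 1)
    if (j_hi < j_lo) {
      # degenerate window narrower than one bin: use the summit's bin
      j_lo <- j_hi <- min(max(s %/% bs, 0), length(v) - 1)
    }
    out[i] <- mean(v[(j_lo:j_hi) + 1L])
  }
  names(out) <- peaks$name
  attr(out, "h") <- h
  attr(out, "condition") <- track$condition
  class(out) <- "window_signal"
  out
}

#' @export
print.window_signal <- function(x, ...) {
  cat(sprintf("window_signal (+/-%d bp, %s): %d peaks, mean %.3g\n",
              attr(x, "h"), attr(x, "condition"), length(x),
              mean(unclass(x))))
  invisible(x)
}

# Per-cohort mean/SEM/n of a per-peak statistic, with one-way ANOVA and
# Tukey HSD across cohorts.
.cohort_summary <- function(stat, cohorts) {
  m <- match(cohorts$name, names(stat))
  if (anyNA(m)) stop("cohort peaks missing from the per-peak statistic")
  df <- data.frame(value = as.numeric(stat[m]),
                   cohort = factor(cohorts$cohort))
  summ <- do.call(rbind, lapply(split(df$value, df$cohort), function(v)
    data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               n = length(v))))
  summ$cohort <- as.integer(rownames(summ))
  summ <- summ[order(summ$cohort), c("cohort", "mean", "sem", "n")]
  rownames(summ) <- NULL
  aov_fit <- stats::aov(value ~ cohort, data = df)
  st <- summary(aov_fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(aov_fit)$cohort)
  tk$comparison <- rownames(tk)
  structure(list(summary = summ, anova_f = st[["F value"]][1],
                 anova_p = st[["Pr(>F)"]][1], tukey = tk,
                 per_peak = stats::setNames(df$value, cohorts$name)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: ANOVA F = %.2f, p = %.3g\n",
              x$anova_f, x$anova_p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract Tukey-adjusted p-values for cohort-vs-cohort contrasts
#'
#' Convenience accessor used for the "each of the top cohorts versus each of
#' the bottom cohorts" contrasts reported alongside cohort analyses.
#'
#' @param cs A `cohort_summary` (from [fold_change()] etc.).
#' @param top,bottom Integer cohort indices to contrast.
#' @return Data frame `top`, `bottom`, `diff`, `p_adj`.
#' @export
cohort_contrasts <- function(cs, top = 1:3, bottom = 6:10) {
  tk <- cs$tukey
  pairs <- expand.grid(top = top, bottom = bottom)
  key1 <- paste0(pairs$top, "-", pairs$bottom)
  key2 <- paste0(pairs$bottom, "-", pairs$top)
  i <- match(key1, tk$comparison)
  j <- match(key2, tk$comparison)
  use2 <- is.na(i)
  idx <- ifelse(use2, j, i)
  sign <- ifelse(use2, -1, 1)
  data.frame(top = pairs$top, bottom = pairs$bottom,
             diff = sign * tk$diff[idx], p_adj = tk$`p adj`[idx])
}

#' Knockdown fold change per peak, summarized by cohort
#'
#' `FC = (kd + pseudocount) / (ntc + pseudocount)` per peak, then per-cohort
#' mean +/- SEM (on the FC scale, matching how such results are plotted; a
#' log2 option is available) with one-way ANOVA and Tukey HSD across
#' cohorts.
#'
#' @param kd,ntc [window_signal()]s over the same peak universe.
#' @param cohorts A `cohort_table` from [assign_cohorts()].
#' @param pseudocount Stabilizing pseudocount (signal units, default 0.5).
#' @param log2_scale Summarize log2(FC) instead of FC.
#' @return A `cohort_summary` (see [cohort_contrasts()]); the per-peak FC is
#'   in `$per_peak`.
#' @export
fold_change <- function(kd, ntc, cohorts, pseudocount = 0.5,
                        log2_scale = FALSE) {
  if (!identical(names(kd), names(ntc)))
    stop("fold_change: KD and NTC peak universes differ")
  fc <- (unclass(kd) + pseudocount) / (unclass(ntc) + pseudocount)
  if (log2_scale) fc <- log2(fc)
  .cohort_summary(fc, cohorts)
}

#' Anchor normalization factor from the anchor factor's ChIP signal
#'
#' A single global scalar, `sum(ntc) / sum(kd)` over all peak windows,
#' normalizing the knockdown condition to assume constant anchor (GFI1-like)
#' ChIP signal across conditions. Applied multiplicatively to the knockdown
#' LSD1-like window signals before ratio analyses. A global scalar (rather
#' than per-peak anchoring) is used because per-peak anchoring would cancel
#' the biological partner-factor effect being measured.
#'
#' @param gfi1_kd,gfi1_ntc [window_signal()]s over the same peak universe.
#' @return Scalar anchoring factor.
#' @export
gfi1_anchor_factor <- function(gfi1_kd, gfi1_ntc) {
  if (!identical(names(gfi1_kd), names(gfi1_ntc)))
    stop("gfi1_anchor_factor: peak universes differ")
  s_kd <- sum(unclass(gfi1_kd))
  if (s_kd == 0) stop("gfi1_anchor_factor: knockdown signal sums to zero")
  sum(unclass(gfi1_ntc)) / s_kd
}

#' Apply a scalar anchoring factor to a window signal
#' @param ws A [window_signal()].
#' @param factor Scalar from [gfi1_anchor_factor()].
#' @return The rescaled [window_signal()].
#' @export
apply_anchor <- function(ws, factor) {
  out <- unclass(ws) * factor
  attributes(out) <- attributes(ws)
  out
}

#' LSD1:GFI1 signal ratio change after knockdown, by cohort
#'
#' Per peak and condition, `ratio = (lsd1 + pseudocount) /
#' (gfi1 + pseudocount)`; the per-peak statistic summarized by cohort is
#' `ratio_kd / ratio_ntc`. The anchoring factor is expected to have been
#' applied to the knockdown LSD1 window signal beforehand (see
#' [gfi1_anchor_factor()]).
#'
#' @param lsd1_kd,lsd1_ntc,gfi1_kd,gfi1_ntc [window_signal()]s over the same
#'   peak universe.
#' @param cohorts A `cohort_table`.
#' @param pseudocount Stabilizing pseudocount (default 0.5).
#' @return A `cohort_summary` of the per-peak ratio change, with the
#'   per-condition ratios attached as attributes `ratio_kd`, `ratio_ntc`.
#' @export
lsd1_gfi1_ratio <- function(lsd1_kd, lsd1_ntc, gfi1_kd, gfi1_ntc, cohorts,
                            pseudocount = 0.5) {
  nm <- names(lsd1_kd)
  if (!identical(nm, names(lsd1_ntc)) || !identical(nm, names(gfi1_kd)) ||
      !identical(nm, names(gfi1_ntc)))
    stop("lsd1_gfi1_ratio: peak universes differ")
  r_kd <- (unclass(lsd1_kd) + pseudocount) / (unclass(gfi1_kd) + pseudocount)
  r_ntc <- (unclass(lsd1_ntc) + pseudocount) /
    (unclass(gfi1_ntc) + pseudocount)
  out <- .cohort_summary(r_kd / r_ntc, cohorts)
  attr(out, "ratio_kd") <- r_kd
  attr(out, "ratio_ntc") <- r_ntc
  out
}

#' Correlation of per-cohort absolute signal losses
#'
#' Absolute loss per cohort is `mean(NTC) - mean(KD)` of the window signal
#' (the partner factor anchored beforehand); the Pearson correlation is
#' computed over the cohort points.
#'
#' @param kd_a,ntc_a,kd_b,ntc_b [window_signal()]s for factors A and B over
#'   the same peak universe.
#' @param cohorts A `cohort_table` (>= 3 cohorts).
#' @return List `r`, `p`, `loss_a`, `loss_b` (per-cohort losses).
#' @export
loss_correlation <- function(kd_a, ntc_a, kd_b, ntc_b, cohorts) {
  loss <- function(kd, ntc) {
    d <- unclass(ntc) - unclass(kd)
    m <- match(cohorts$name, names(d))
    vapply(split(d[m], cohorts$cohort), mean, numeric(1))
  }
  la <- loss(kd_a, ntc_a)
  lb <- loss(kd_b, ntc_b)
  if (length(la) < 3) stop("loss_correlation: need >= 3 cohorts")
  ct <- stats::cor.test(la, lb)
  list(r = unname(ct$estimate), p = ct$p.value, loss_a = la, loss_b = lb)
}

#' Per-cohort distribution of a mark's window signal
#'
#' Boxplot statistics (median, quartiles, 5th/95th centiles) of the mark
#' signal per strength cohort, plus a Spearman monotonicity test of cohort
#' index against cohort median over a chosen cohort range (default the
#' strongest three cohorts, where the inverse strength/acetylation relation
#' is planted).
#'
#' @param mark A [window_signal()] of the mark (e.g. H3K27Ac or ATAC).
#' @param cohorts A `cohort_table`.
#' @param trend_cohorts Cohort indices for the monotonicity test.
#' @return List with `stats` (data frame cohort, p5, q25, median, q75, p95,
#'   n) and `trend` (`rho`, `p`).
#' @export
strength_signal_relation <- function(mark, cohorts, trend_cohorts = 1:3) {
  m <- match(cohorts$name, names(mark))
  vals <- split(as.numeric(unclass(mark)[m]), cohorts$cohort)
  st <- do.call(rbind, lapply(names(vals), function(k) {
    q <- stats::quantile(vals[[k]], c(0.05, 0.25, 0.5, 0.75, 0.95))
    data.frame(cohort = as.integer(k), p5 = q[1], q25 = q[2],
               median = q[3], q75 = q[4], p95 = q[5],
               n = length(vals[[k]]))
  }))
  st <- st[order(st$cohort), ]
  rownames(st) <- NULL
  sel <- st$cohort %in% trend_cohorts
  trend <- list(rho = NA_real_, p = NA_real_)
  if (sum(sel) >= 3) {
    ct <- suppressWarnings(stats::cor.test(st$cohort[sel], st$median[sel],
                                           method = "spearman"))
    trend <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(stats = st, trend = trend)
}
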