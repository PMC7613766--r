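#' Match peak summits between two factors
#'
#' For every A-peak, finds the nearest B-peak summit on the same chromosome
#' within `max_dist` bp. Equidistant candidates are broken toward the smaller
#' coordinate; A-peaks with no candidate are absent from the output. Matching
#' is not one-to-one: two A-peaks may share a B-peak.
#'
#' @param A,B [peak_set()]s (non-empty).
#' @param max_dist Maximum absolute summit separation (bp, default 100).
#' @return Data frame `name_a`, `name_b`, `distance`
#'   (`summit_B - summit_A`, signed), `pileup_a`, `pileup_b`.
#' @export
match_summits <- function(A, B, max_dist = 100) {
  if (!nrow(A) || !nrow(B)) stop("match_summits: empty peak set")
  out <- vector("list", length(unique(A$chrom)))
  k <- 0L
  for (ch in unique(A$chrom)) {
    a <- A[A$chrom == ch, , drop = FALSE]
    b <- B[B$chrom == ch, , drop = FALSE]
    if (!nrow(b)) next
    b <- b[order(b$summit), , drop = FALSE]
    idx <- findInterval(a$summit, b$summit)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(b))
    d_lo <- abs(b$summit[lo] - a$summit)
    d_hi <- abs(b$summit[hi] - a$summit)
    # tie (equal distance) -> smaller coordinate, i.e. the lower neighbour
    use_lo <- d_lo <= d_hi
    pickb <- ifelse(use_lo, lo, hi)
    dist <- b$summit[pickb] - a$summit
    ok <- abs(dist) <= max_dist
    if (!any(ok)) next
    k <- k + 1L
    out[[k]] <- data.frame(name_a = a$name[ok],
                           name_b = b$name[pickb][ok],
                           distance = dist[ok],
                           pileup_a = a$pileup[ok],
                           pileup_b = b$pileup[pickb][ok],
                           stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(name_a = character(0), name_b = character(0),
                      distance = integer(0), pileup_a = numeric(0),
                      pileup_b = numeric(0)))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Summit-overlap fractions and Venn counts
#'
#' Fraction of the (caller-filtered, typically strong) reference peak set H
#' whose summit lies within `max_dist` bp of a G summit, of an L summit, and
#' of either; plus the four Venn regions partitioning H.
#'
#' @param H,G,L [peak_set()]s; H is the reference set.
#' @param max_dist Maximum summit separation (bp).
#' @return List with `pct_g`, `pct_l`, `pct_either` (percent, one decimal)
#'   and `venn` (named counts `both`, `g_only`, `l_only`, `neither`).
#' @export
overlap_fractions <- function(H, G, L, max_dist = 100) {
  in_g <- H$name %in% match_summits(H, G, max_dist)$name_a
  in_l <- H$name %in% match_summits(H, L, max_dist)$name_a
  n <- nrow(H)
  list(pct_g = round(100 * sum(in_g) / n, 1),
       pct_l = round(100 * sum(in_l) / n, 1),
       pct_either = round(100 * sum(in_g | in_l) / n, 1),
       venn = c(both = sum(in_g & in_l), g_only = sum(in_g & !in_l),
                l_only = sum(!in_g & in_l), neither = sum(!in_g & !in_l)))
}

#' Correlation of peak strengths across matched summits
#'
#' Pearson correlation (with Spearman alongside) of the paired pileups of
#' matched peaks, with two-sided p-values.
#'
#' @param pairs Output of [match_summits()] (>= 3 pairs).
#' @return List `r`, `p` (Pearson) and `rho`, `p_spearman`.
#' @export
strength_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop("strength_correlation: need >= 3 pairs")
  ct <- stats::cor.test(pairs$pileup_a, pairs$pileup_b)
  cs <- suppressWarnings(stats::cor.test(pairs$pileup_a, pairs$pileup_b,
                                         method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value,
       rho = unname(cs$estimate), p_spearman = cs$p.value)
}

#' Anchored triple inter-summit distance analysis
#'
#' Builds triples around strong anchor (GFI1-like) peaks: for each G peak
#' with `pileup >= gfi1_min_pileup`, the nearest H and L summits within
#' `max_dist`, requiring all three pairwise summit separations to be within
#' `max_dist`. Reports the correlation of signed H->G vs L->G distances, the
#' (expectedly weak) correlations involving H->L, and per-pair-type absolute
#' distance statistics with a one-way ANOVA and Tukey HSD post hoc test.
#'
#' Signed distances satisfy the triangle identity
#' `signed(H->L) = signed(H->G) - signed(L->G)` by construction.
#'
#' @param G,H,L [peak_set()]s; H and L should be pre-filtered to strong
#'   peaks by the caller.
#' @param gfi1_min_pileup Anchor pileup floor (default 300).
#' @param max_dist Maximum pairwise summit separation (bp, default 100).
#' @return List of class `triple_analysis` with `triples` (data frame) and
#'   `stats` (distance summaries, correlations, ANOVA and Tukey tables);
#'   `stats` is `NULL` when no triples are found.
#' @export
triple_analysis <- function(G, H, L, gfi1_min_pileup = 300, max_dist = 100) {
  g <- G[G$pileup >= gfi1_min_pileup, , drop = FALSE]
  empty <- structure(list(triples = data.frame(), stats = NULL),
                     class = "triple_analysis")
  if (!nrow(g) || !nrow(H) || !nrow(L)) return(empty)
  attr(g, "factor") <- attr(G, "factor")
  class(g) <- c("peak_set", "data.frame")
  mh <- match_summits(g, H, max_dist)
  ml <- match_summits(g, L, max_dist)
  common <- intersect(mh$name_a, ml$name_a)
  if (!length(common)) return(empty)
  mh <- mh[match(common, mh$name_a), , drop = FALSE]
  ml <- ml[match(common, ml$name_a), , drop = FALSE]
  d_hg <- mh$distance           # summit_H - summit_G
  d_lg <- ml$distance           # summit_L - summit_G
  d_hl <- d_hg - d_lg           # summit_H - summit_L
  ok <- abs(d_hl) <= max_dist
  if (!any(ok)) return(empty)
  triples <- data.frame(gfi1 = common, hmg20b = mh$name_b,
                        lsd1 = ml$name_b,
                        d_hg = d_hg, d_lg = d_lg, d_hl = d_hl,
                        pileup_gfi1 = mh$pileup_a,
                        pileup_hmg20b = mh$pileup_b,
                        pileup_lsd1 = ml$pileup_b,
                        stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(triples) <- NULL

  corr <- function(x, y) {
    if (nrow(triples) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  ad <- data.frame(
    dist = abs(c(triples$d_hg, triples$d_lg, triples$d_hl)),
    pair = factor(rep(c("H-G", "L-G", "H-L"), each = nrow(triples)),
                  levels = c("H-G", "L-G", "H-L")))
  summ <- do.call(rbind, lapply(split(ad$dist, ad$pair), function(v)
    data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               median = stats::median(v), iqr = stats::IQR(v),
               n = length(v))))
  summ$pair <- rownames(summ)
  aov_fit <- NULL; tukey <- NULL; anova_f <- NA_real_; anova_p <- NA_real_
  if (nrow(triples) >= 2 && stats::var(ad$dist) > 0) {
    aov_fit <- stats::aov(dist ~ pair, data = ad)
    st <- summary(aov_fit)[[1]]
    anova_f <- st[["F value"]][1]; anova_p <- st[["Pr(>F)"]][1]
    tukey <- as.data.frame(stats::TukeyHSD(aov_fit)$pair)
    tukey$comparison <- rownames(tukey)
  }
  stats_out <- list(
    cor_hg_lg = corr(triples$d_hg, triples$d_lg),
    cor_hl_hg = corr(triples$d_hl, triples$d_hg),
    cor_hl_lg = corr(triples$d_hl, triples$d_lg),
    distance_summary = summ,
    anova_f = anova_f, anova_p = anova_p, tukey = tukey)
  structure(list(triples = triples, stats = stats_out),
            class = "triple_analysis")
}

#' @export
print.triple_analysis <- function(x, ...) {
  cat(sprintf("triple_analysis: %d anchored triples\n", nrow(x$triples)))
  if (!is.null(x$stats)) {
    cat(sprintf("  corr(signed H->G, L->G): r = %.3f (p = %.3g)\n",
                x$stats$cor_hg_lg$r, x$stats$cor_hg_lg$p))
    print(x$stats$distance_summary[, c("pair", "mean", "sem", "median",
                                       "iqr", "n")], row.names = FALSE)
  }
  invisible(x)
}
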