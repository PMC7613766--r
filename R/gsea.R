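#' Map peaks to their nearest gene and classify the binding site
#'
#' Nearest gene by summit-to-TSS distance (ties broken toward the smaller
#' gene identifier). The site class follows the annotation categories:
#' promoter and 5'UTR peaks are "promoter", intergenic and intronic peaks
#' "enhancer", everything else "other". This nearest-TSS mapping stands in
#' for regulatory-domain tools; enhancers do not necessarily control the
#' nearest gene, so downstream conclusions are drawn at cohort level.
#'
#' @param peaks A [peak_set()].
#' @param genes Gene table (see [annotate_peaks()]); must be non-empty.
#' @param annotation Optional precomputed [annotate_peaks()] result.
#' @return Data frame `name`, `gene_id`, `distance` (bp, summit to TSS),
#'   `class`.
#' @export
map_nearest_gene <- function(peaks, genes, annotation = NULL) {
  if (is.null(genes) || !nrow(genes)) stop("map_nearest_gene: empty gene table")
  if (is.null(annotation))
    annotation <- annotate_peaks(peaks, genes)
  gene_id <- character(nrow(peaks))
  distance <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) g <- genes   # classify by remaining genes
    dd <- abs(g$tss - peaks$summit[i])
    cand <- g$gene_id[dd == min(dd)]
    gene_id[i] <- sort(cand)[1]
    distance[i] <- min(dd)
  }
  cat2class <- function(x) {
    ifelse(x %in% c("promoter", "5'UTR"), "promoter",
           ifelse(x %in% c("intergenic", "intron"), "enhancer", "other"))
  }
  data.frame(name = peaks$name, gene_id = gene_id, distance = distance,
             class = cat2class(as.character(annotation$category[peaks$name])),
             stringsAsFactors = FALSE)
}

#' Build per-cohort gene sets from a peak-to-gene mapping
#'
#' One gene set per strength cohort, restricted to peaks of the requested
#' class; duplicate genes within a set are collapsed. Empty cohorts yield
#' empty sets (retained and flagged with a warning).
#'
#' @param cohorts A `cohort_table`.
#' @param mapping Output of [map_nearest_gene()].
#' @param class Peak class filter: `"promoter"`, `"enhancer"`, `"other"` or
#'   `"all"`.
#' @return Named list of character vectors (`cohort01` ... strongest first).
#' @export
build_cohort_gene_sets <- function(cohorts, mapping, class = "all") {
  sel <- if (class == "all") mapping else mapping[mapping$class == class, ]
  sets <- lapply(sort(unique(cohorts$cohort)), function(k) {
    nm <- cohorts$name[cohorts$cohort == k]
    sort(unique(sel$gene_id[sel$name %in% nm]))
  })
  names(sets) <- sprintf("cohort%02d", sort(unique(cohorts$cohort)))
  if (any(lengths(sets) == 0))
    warning("empty cohort gene set(s): ",
            paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param description Description field (second GMT column).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "cooccupy") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Preranked gene-set enrichment score
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranked list, hits increment the running sum by `|score|^p / sum_hits
#' |score|^p` and misses decrement it by `1 / (N - N_hits)`; the enrichment
#' score is the signed maximum deviation from zero. ES always lies in
#' [-1, 1].
#'
#' @param ranked Data frame `gene_id`, `score`, or a named numeric vector of
#'   scores. Ties are broken by gene identifier for a strict ordering.
#' @param set Character vector of member genes; must intersect the list and
#'   not cover it entirely.
#' @param p Hit weight exponent (default 1; 0 gives the classic KS form).
#' @return Scalar ES.
#' @export
preranked_es <- function(ranked, set, p = 1) {
  if (is.data.frame(ranked)) {
    ord <- order(-ranked$score, ranked$gene_id)
    genes <- ranked$gene_id[ord]
    scores <- ranked$score[ord]
  } else {
    ord <- order(-ranked, names(ranked))
    genes <- names(ranked)[ord]
    scores <- as.numeric(ranked)[ord]
  }
  .es_core(genes, scores, set, p)
}

# ES on a pre-sorted ranking (descending score, ties by gene id).
.es_core <- function(genes, scores, set, p = 1) {
  hit <- genes %in% set
  n_hit <- sum(hit)
  N <- length(genes)
  if (n_hit == 0) stop("preranked_es: empty intersection with the ranking")
  if (n_hit == N) stop("preranked_es: gene set covers the entire ranking")
  w <- abs(scores)^p
  inc <- numeric(N)
  tot <- sum(w[hit])
  inc[hit] <- if (tot > 0) w[hit] / tot else 1 / n_hit
  inc[!hit] <- -1 / (N - n_hit)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Preranked GSEA with a gene-set permutation null
#'
#' For each gene set, `n_perm` size-matched random gene sets drawn from the
#' ranked universe form the null. NES is ES divided by the mean absolute
#' null ES of the same sign; the nominal p-value is one-sided against the
#' same-sign null; FDR q follows the standard NES-ratio procedure with
#' monotonicity in |NES| enforced. Deterministic for a given `seed`.
#'
#' @param ranked Data frame `gene_id`, `score` (see [preranked_es()]).
#' @param sets Named list of gene sets.
#' @param n_perm Permutations per set (>= 100 recommended).
#' @param seed Integer RNG seed.
#' @param p Hit weight exponent.
#' @return Data frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`.
#' @export
run_gsea <- function(ranked, sets, n_perm = 1000, seed = 1, p = 1) {
  set.seed(as.integer(seed))
  universe <- ranked$gene_id
  sets <- lapply(sets, function(s) intersect(s, universe))
  if (any(lengths(sets) > length(universe) / 2))
    warning("gene set(s) larger than half the ranked list")
  keep <- lengths(sets) > 0
  if (!all(keep))
    warning("dropping empty gene set(s): ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  ord <- order(-ranked$score, ranked$gene_id)
  genes <- ranked$gene_id[ord]
  scores <- ranked$score[ord]
  es <- vapply(sets, function(s) .es_core(genes, scores, s, p), numeric(1))
  null_es <- lapply(sets, function(s) {
    k <- length(s)
    vapply(seq_len(n_perm), function(i)
      .es_core(genes, scores, sample(universe, k), p), numeric(1))
  })
  nes <- numeric(length(es)); pval <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_es[[i]]
    same <- nul[sign(nul) == sign(es[i])]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nul))
    nes[i] <- es[i] / denom
    pval[i] <- if (length(same))
      (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1) else
        1 / (length(nul) + 1)
    # normalize each sign of the null by its own mean |ES|
    pos <- nul[nul > 0]; neg <- nul[nul < 0]
    null_nes[[i]] <- c(if (length(pos)) pos / mean(abs(pos)),
                       if (length(neg)) neg / mean(abs(neg)))
  }
  all_null_nes <- unlist(null_nes)
  q <- vapply(seq_along(nes), function(i) {
    s <- sign(nes[i])
    nn <- all_null_nes[sign(all_null_nes) == s]
    oo <- nes[sign(nes) == s]
    num <- if (length(nn)) sum(abs(nn) >= abs(nes[i])) / length(nn) else 0
    den <- sum(abs(oo) >= abs(nes[i])) / length(oo)
    min(1, num / den)
  }, numeric(1))
  # FDR monotone non-increasing in |NES|
  ord <- order(-abs(nes))
  q[ord] <- cummax(q[ord])
  out <- data.frame(set = names(sets), size = lengths(sets), es = es,
                    nes = nes, p = pval, q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: %d gene set(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$es <- round(df$es, 3); df$nes <- round(df$nes, 3)
  df$p <- signif(df$p, 3); df$q <- signif(df$q, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
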