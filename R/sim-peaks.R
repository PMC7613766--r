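#' Emit called peaks from the ground truth
#'
#' One peak per planted site per factor (for the sites where the factor is
#' planted present). Pileup is the planted strength plus bounded uniform
#' noise (never below half the planted strength floor), fold enrichment is
#' drawn at or above the configured floor, and the summit is the planted
#' summit. Peak intervals span `summit +/- half_width`.
#'
#' @param truth Ground-truth table from [plant_sites()].
#' @param config A [sim_config()].
#' @param half_width Half peak width (bp).
#' @return Named list of [peak_set()]s: `hmg20b`, `lsd1`, `gfi1`, `control`.
#' @export
emit_peaks <- function(truth, config, half_width = 150) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "peaks"))
  site <- truth[!truth$control, , drop = FALSE]
  ctrl <- truth[truth$control, , drop = FALSE]
  mk <- function(rows, summit_col, strength_col, present, label) {
    rows <- rows[present, , drop = FALSE]
    n <- nrow(rows)
    su <- rows[[summit_col]]
    pil <- pmax(rows[[strength_col]] +
                  stats::runif(n, -config$pileup_noise, config$pileup_noise),
                0)
    fe <- config$fe_floor + stats::rexp(n, rate = 0.5)
    nm <- if (n) paste0(label, "_", rows$site_id) else character(0)
    peak_set(rows$chrom, su - half_width, su + half_width,
             nm, pil, fe, su, factor = label)
  }
  list(hmg20b = mk(site, "hmg20b_summit", "strength_hmg20b",
                   site$present_hmg20b, "hmg20b"),
       lsd1 = mk(site, "lsd1_summit", "strength_lsd1",
                 site$present_lsd1, "lsd1"),
       gfi1 = mk(site, "gfi1_summit", "strength_gfi1",
                 site$present_gfi1, "gfi1"),
       control = mk(ctrl, "gfi1_summit", "strength_hmg20b",
                    rep(TRUE, nrow(ctrl)), "control"))
}

#' Place genes and generate a knockdown-response ranked list
#'
#' Places `n_genes` genes: a fraction get a TSS within 1 kb of a planted
#' site, the rest distal (>= 1.5 kb from any site). Each gene has two exons
#' (first and last 200 bp) so intronic and exonic annotation categories
#' exist. Baseline expression (FPKM) is lognormal; the ranked list contains
#' only genes passing the expressed-gene filter (`fpkm >= fpkm_min`). Genes
#' nearest (by TSS) to sites in the strongest strength quantile are planted
#' as knockdown-responsive and receive a positive mean expression score; ties
#' in the ranking are broken by gene identifier so the ordering is strict.
#'
#' @param truth Ground-truth table from [plant_sites()].
#' @param genome_model Data frame `chrom`, `length`.
#' @param config A [sim_config()].
#' @return List with `genes` (gene table data.frame with planted
#'   `responsive`/`fpkm` columns) and `ranked` (data.frame `gene_id`,
#'   `score`, ordered by decreasing score).
#' @export
generate_genes_and_expression <- function(truth, genome_model, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "genes"))
  site <- truth[!truth$control, , drop = FALSE]
  n_genes <- config$n_genes
  n_prox <- round(config$gene_promoter_frac * n_genes)
  if (n_prox > nrow(site))
    stop(sprintf("generate_genes_and_expression: %d promoter-proximal genes requested but only %d sites",
                 n_prox, nrow(site)))
  lens <- stats::setNames(genome_model$length, genome_model$chrom)

  prox_sites <- sample.int(nrow(site), n_prox)
  chrom <- character(n_genes); tss <- integer(n_genes)
  chrom[seq_len(n_prox)] <- site$chrom[prox_sites]
  tss[seq_len(n_prox)] <- site$gfi1_summit[prox_sites] +
    sample(seq(-999L, 999L), n_prox, replace = TRUE)

  # distal genes: uniform positions at least 1.5 kb from every site (clear
  # of the 1 kb promoter-proximal band)
  n_dist <- n_genes - n_prox
  got <- 0L
  iter <- 0L
  dchrom <- character(n_dist); dtss <- integer(n_dist)
  while (got < n_dist) {
    iter <- iter + 1L
    if (iter > 1000L)
      stop("generate_genes_and_expression: could not place distal genes; genome too crowded")
    m <- (n_dist - got) * 4L
    ch <- sample(names(lens), m, replace = TRUE,
                 prob = lens / sum(lens))
    pos <- as.integer(floor(stats::runif(m, 20000, lens[ch] - 20000)))
    ok <- vapply(seq_len(m), function(k) {
      s <- truth$gfi1_summit[truth$chrom == ch[k]]
      !any(abs(s - pos[k]) < 1500)
    }, logical(1))
    take <- min(sum(ok), n_dist - got)
    if (take > 0) {
      sel <- which(ok)[seq_len(take)]
      dchrom[got + seq_len(take)] <- ch[sel]
      dtss[got + seq_len(take)] <- pos[sel]
      got <- got + take
    }
  }
  chrom[n_prox + seq_len(n_dist)] <- dchrom
  tss[n_prox + seq_len(n_dist)] <- dtss

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- as.integer(round(stats::runif(n_genes, 2000, 10000)))
  tes <- ifelse(strand == "+", tss + glen, tss - glen)
  # keep genes within bounds by flipping strand at the edges
  flip <- tes < 1000 | tes > lens[chrom] - 1000
  strand[flip] <- ifelse(strand[flip] == "+", "-", "+")
  tes <- ifelse(strand == "+", tss + glen, tss - glen)

  lo <- pmin(tss, tes); hi <- pmax(tss, tes)
  exon_starts <- paste(lo, hi - 200L, sep = ",")
  exon_ends <- paste(lo + 200L, hi, sep = ",")

  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = chrom, strand = strand,
    tss = as.integer(tss), tes = as.integer(tes),
    exon_starts = exon_starts, exon_ends = exon_ends,
    stringsAsFactors = FALSE)
  genes$fpkm <- exp(stats::rnorm(n_genes, config$fpkm_meanlog,
                                 config$fpkm_sdlog))

  # responsive genes: nearest gene (by TSS) of each strongest-quantile site
  q_top <- stats::quantile(site$strength_hmg20b, config$responsive_quantile)
  top <- site[site$strength_hmg20b >= q_top, , drop = FALSE]
  resp <- character(0)
  for (i in seq_len(nrow(top))) {
    g <- genes[genes$chrom == top$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    dd <- abs(g$tss - top$gfi1_summit[i])
    cand <- g$gene_id[dd == min(dd)]
    resp <- c(resp, sort(cand)[1])  # tie -> smaller gene id
  }
  genes$responsive <- genes$gene_id %in% resp

  expressed <- genes[genes$fpkm >= config$fpkm_min, , drop = FALSE]
  score <- stats::rnorm(nrow(expressed), 0, config$expression_noise_sd) +
    ifelse(expressed$responsive, config$expression_effect, 0)
  ranked <- data.frame(gene_id = expressed$gene_id, score = score,
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$score, ranked$gene_id), , drop = FALSE]
  rownames(ranked) <- NULL
  list(genes = genes, ranked = ranked)
}

#' Run the whole synthetic generator
#'
#' Convenience wrapper chaining [generate_genome()], [plant_sites()],
#' [render_tracks()], [emit_peaks()] and
#' [generate_genes_and_expression()]. All randomness derives from
#' `config$seed`, so identical configs give identical outputs.
#'
#' @param config A [sim_config()].
#' @param tracks Which tracks to render (see [render_tracks()]); `NULL`
#'   skips track rendering.
#' @return List with `genome`, `truth`, `tracks`, `peaks`, `genes`,
#'   `ranked`.
#' @export
simulate_cooccupancy <- function(config,
                                 tracks = c("hmg20b", "lsd1", "gfi1",
                                            "control", "h3k27ac", "atac")) {
  genome <- generate_genome(config)
  planted <- plant_sites(genome, config)
  genome$sequence <- planted$sequence
  truth <- planted$truth
  trk <- if (is.null(tracks)) NULL
         else render_tracks(truth, genome$model, config, what = tracks)
  peaks <- emit_peaks(truth, config)
  ge <- generate_genes_and_expression(truth, genome$model, config)
  list(genome = genome, truth = truth, tracks = trk, peaks = peaks,
       genes = ge$genes, ranked = ge$ranked)
}

#' Write a gene table as TSV
#' @param genes Gene table data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#' @param path TSV with at least `gene_id`, `chrom`, `strand`, `tss`, `tes`.
#' @return Gene table data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a ranked gene list in RNK format
#' @param ranked Data frame `gene_id`, `score`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene_id", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an RNK ranked gene list
#' @param path Two-column tab-separated file (gene, score), no header.
#' @return Data frame `gene_id`, `score` sorted by decreasing score.
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "score"),
                          stringsAsFactors = FALSE)
  df[order(-df$score, df$gene_id), , drop = FALSE]
}

#' Write the ground-truth table as TSV
#' @param truth Truth table from [plant_sites()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
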