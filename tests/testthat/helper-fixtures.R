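# Shared fixtures and independent oracles for the test suite.

# Small convenience constructor for peak sets used across tests.
make_peaks <- function(summits, pileup = 100, fe = 10, chrom = "chr1",
                       half = 50, names = NULL, factor = "test") {
  n <- length(summits)
  if (is.null(names)) names <- sprintf("%s_p%03d", factor, seq_len(n))
  peak_set(chrom = rep_len(chrom, n), start = summits - half,
           end = summits + half, name = names,
           pileup = rep_len(pileup, n), fold_enrichment = rep_len(fe, n),
           summit = summits, factor = factor)
}

# Lazily cached medium-scale default simulation shared across test files.
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 42, n_sites = 800, n_control_sites = 300,
                      chrom_lengths = c(chrA = 3000000, chrB = 3000000),
                      n_genes = 600)
    .sim_cache$cfg <- cfg
    .sim_cache$sim <- simulate_cooccupancy(
      cfg, tracks = c("hmg20b", "lsd1", "gfi1", "control", "h3k27ac",
                      "atac", "h3k4me1"))
  }
  list(cfg = .sim_cache$cfg, sim = .sim_cache$sim)
}

# Brute-force all-pairs nearest-summit matcher (oracle for match_summits).
bf_match <- function(A, B, max_dist = 100) {
  rows <- list()
  for (i in seq_len(nrow(A))) {
    b <- B[B$chrom == A$chrom[i], , drop = FALSE]
    if (!nrow(b)) next
    d <- b$summit - A$summit[i]
    cand <- which(abs(d) <= max_dist)
    if (!length(cand)) next
    best <- cand[order(abs(d[cand]), b$summit[cand])][1]
    rows[[length(rows) + 1]] <- data.frame(
      name_a = A$name[i], name_b = b$name[best], distance = d[best],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(name_a = character(0), name_b = character(0),
                      distance = integer(0)))
  do.call(rbind, rows)
}

# Independent enrichment-score oracle: explicit position-by-position walk
# with separate hit and miss bookkeeping (no cumsum shortcut).
bf_es <- function(ranked, set, p = 1) {
  ord <- order(-ranked$score, ranked$gene_id)
  genes <- ranked$gene_id[ord]
  scores <- ranked$score[ord]
  n <- length(genes)
  in_set <- genes %in% set
  n_hit <- sum(in_set)
  w_total <- sum(abs(scores[in_set])^p)
  best <- 0
  hit_sum <- 0
  miss_count <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      hit_sum <- hit_sum + (if (w_total > 0) abs(scores[i])^p / w_total
                            else 1 / n_hit)
    } else {
      miss_count <- miss_count + 1
    }
    dev <- hit_sum - miss_count / (n - n_hit)
    if (abs(dev) > abs(best)) best <- dev
  }
  best
}

# Random ranked list with strictly unique gene ids.
random_ranked <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             score = stats::rnorm(n), stringsAsFactors = FALSE)
}
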