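#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic co-occupancy data
#' generator. The defaults describe the statistical structure the analysis
#' modules assume: motif-anchored sites where an accessory pair (HMG20B- and
#' LSD1-like) binds to one side or the other of a sequence-specific anchor
#' (GFI1-like) at a modal offset of 9 bp, lognormal peak strengths strongly
#' rank-correlated across the three factors, knockdown attenuation restricted
#' to the strongest sites, histone-acetylation/accessibility signal inversely
#' related to repressor strength at strong sites, and a strength-neutral
#' control factor.
#'
#' @param seed Integer seed; mandatory. Every generator stage derives its own
#'   substream from it, so identical configs give byte-identical outputs.
#' @param n_sites Number of planted repressor-complex sites.
#' @param n_control_sites Number of control-factor (CEBPA-like) sites with no
#'   motif and no knockdown response.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param offset_modal Modal accessory-factor offset distance from the anchor
#'   summit (bp).
#' @param offset_sd Standard deviation of the truncated-normal offset noise
#'   (bp); the shared per-site distance is `offset_modal + N(0, offset_sd)`
#'   truncated at zero.
#' @param factor_jitter Half-width of the independent integer jitter (bp)
#'   added to each accessory factor's summit on top of the shared offset.
#' @param strength_meanlog,strength_sdlog Lognormal parameters of peak
#'   strength (pileup units).
#' @param strength_rho Gaussian-copula correlation tying the three factors'
#'   strengths at a site.
#' @param presence_prob Named probabilities that a planted site carries a
#'   called peak for each factor; `hmg20b` sites are the anchor universe.
#' @param pileup_noise Half-width of bounded uniform noise added to strength
#'   when emitting peak pileup values.
#' @param fe_floor Minimum fold enrichment assigned to emitted peaks.
#' @param motif IUPAC consensus planted at each non-control anchor summit.
#' @param bin_size Signal-track bin size (bp).
#' @param bump_sd Gaussian ChIP bump standard deviation (bp).
#' @param poisson_noise Apply per-bin Poisson noise to expected track counts?
#' @param spacing Minimum inter-site spacing (bp); 2 kb keeps +/-1 kb windows
#'   disjoint.
#' @param margin Chromosome-end margin within which no site is placed (bp).
#' @param hmg20b_retention Length-2 range; per-site knockdown retention of the
#'   HMG20B-like factor is drawn uniformly from it.
#' @param lsd1_coupling Fraction of the HMG20B retention deficit transmitted
#'   to the LSD1-like factor at affected sites (1 = fully coupled, 0 =
#'   uncoupled).
#' @param lsd1_affected_quantile Strength quantile above which LSD1 retention
#'   is attenuated (0.6 = strongest 40 percent of sites, i.e. decile cohorts
#'   1-4).
#' @param gfi1_condition_scale Global multiplicative scale applied to the
#'   knockdown tracks of the three repressor-complex factors, emulating a
#'   shared between-condition depth difference (the anchor factor's
#'   biological retention is 1, so anchored normalization recovers it).
#' @param acet_baseline Acetylation/accessibility bump height at unaffected
#'   sites (signal units).
#' @param acet_inverse_quantile Strength quantile above which the baseline
#'   follows the planted inverse-strength rule.
#' @param acet_inverse_power Exponent of the inverse rule:
#'   `baseline * (q/strength)^power` for strengths above quantile `q`.
#' @param acet_kd_gain Multiplicative acetylation gain after knockdown at
#'   affected sites.
#' @param acet_gain_quantile Strength quantile above which the knockdown gain
#'   applies (0.7 = strongest 30 percent, decile cohorts 1-3).
#' @param atac_baseline Accessibility bump height analogue of `acet_baseline`.
#' @param n_genes Number of genes to place.
#' @param gene_promoter_frac Fraction of genes given a TSS within 1 kb of a
#'   planted site.
#' @param expression_effect Mean expression score added to planted responsive
#'   genes in the ranked list.
#' @param expression_noise_sd Standard deviation of the ranked-list noise.
#' @param responsive_quantile Strength quantile above which a site's nearest
#'   gene is planted as knockdown-responsive (0.9 = strongest decile).
#' @param fpkm_meanlog,fpkm_sdlog Lognormal parameters of baseline gene
#'   expression (FPKM) used by the expressed-gene filter.
#' @param fpkm_min Expressed-gene filter threshold (FPKM) applied when
#'   building the ranked list.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_sites = 1000,
                       n_control_sites = 500,
                       chrom_lengths = c(chrS1 = 4000000, chrS2 = 4000000),
                       offset_modal = 9,
                       offset_sd = 3,
                       factor_jitter = 2,
                       strength_meanlog = log(70),
                       strength_sdlog = 0.8,
                       strength_rho = 0.9,
                       presence_prob = c(hmg20b = 1, gfi1 = 0.91, lsd1 = 0.95),
                       pileup_noise = 2,
                       fe_floor = 5,
                       motif = "TAAATCACWGC",
                       bin_size = 10,
                       bump_sd = 75,
                       poisson_noise = TRUE,
                       spacing = 2000,
                       margin = 1000,
                       hmg20b_retention = c(0.25, 0.45),
                       lsd1_coupling = 1,
                       lsd1_affected_quantile = 0.6,
                       gfi1_condition_scale = 0.7,
                       acet_baseline = 50,
                       acet_inverse_quantile = 0.7,
                       acet_inverse_power = 0.5,
                       acet_kd_gain = 2,
                       acet_gain_quantile = 0.7,
                       atac_baseline = 30,
                       n_genes = 800,
                       gene_promoter_frac = 0.6,
                       expression_effect = 2,
                       expression_noise_sd = 1,
                       responsive_quantile = 0.9,
                       fpkm_meanlog = 1,
                       fpkm_sdlog = 1.5,
                       fpkm_min = 0.25) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config: 'seed' is mandatory")
  seed <- as.integer(seed)
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("sim_config: chromosome names must be present and unique")
  if (any(chrom_lengths <= 0))
    stop("sim_config: chromosome lengths must be > 0")
  if (offset_sd < 0 || factor_jitter < 0 || expression_noise_sd < 0)
    stop("sim_config: standard deviations and jitter must be >= 0")
  if (!nzchar(motif))
    stop("sim_config: motif consensus must be non-empty")
  if (bin_size <= 0)
    stop("sim_config: bin_size must be > 0")
  if (any(presence_prob < 0 | presence_prob > 1))
    stop("sim_config: presence probabilities must lie in [0, 1]")
  stopifnot(length(hmg20b_retention) == 2L,
            all(hmg20b_retention >= 0 & hmg20b_retention <= 1))
  cfg <- list(
    seed = seed, n_sites = n_sites, n_control_sites = n_control_sites,
    chrom_lengths = chrom_lengths,
    offset_modal = offset_modal, offset_sd = offset_sd,
    factor_jitter = factor_jitter,
    strength_meanlog = strength_meanlog, strength_sdlog = strength_sdlog,
    strength_rho = strength_rho, presence_prob = presence_prob,
    pileup_noise = pileup_noise, fe_floor = fe_floor, motif = motif,
    bin_size = bin_size, bump_sd = bump_sd, poisson_noise = poisson_noise,
    spacing = spacing, margin = margin,
    hmg20b_retention = hmg20b_retention, lsd1_coupling = lsd1_coupling,
    lsd1_affected_quantile = lsd1_affected_quantile,
    gfi1_condition_scale = gfi1_condition_scale,
    acet_baseline = acet_baseline,
    acet_inverse_quantile = acet_inverse_quantile,
    acet_inverse_power = acet_inverse_power,
    acet_kd_gain = acet_kd_gain, acet_gain_quantile = acet_gain_quantile,
    atac_baseline = atac_baseline,
    n_genes = n_genes, gene_promoter_frac = gene_promoter_frac,
    expression_effect = expression_effect,
    expression_noise_sd = expression_noise_sd,
    responsive_quantile = responsive_quantile,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    fpkm_min = fpkm_min)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic co-occupancy simulation config\n")
  cat(sprintf("  seed %d | %d sites + %d control sites on %d chromosome(s) (%.1f Mb)\n",
              x$seed, x$n_sites, x$n_control_sites,
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  cat(sprintf("  offsets: modal %d bp, sd %.1f bp, jitter +/-%d bp | motif %s\n",
              x$offset_modal, x$offset_sd, x$factor_jitter, x$motif))
  cat(sprintf("  strengths: lognormal(meanlog %.2f, sdlog %.2f), copula rho %.2f\n",
              x$strength_meanlog, x$strength_sdlog, x$strength_rho))
  invisible(x)
}

# Per-stage RNG substream so each generator stage is individually
# deterministic for a given config.
.stage_seed <- function(config, stage) {
  offs <- c(genome = 11L, sites = 23L, tracks = 37L, peaks = 53L,
            genes = 71L)
  (abs(config$seed) %% 2000000000L) + offs[[stage]]
}
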