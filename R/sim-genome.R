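#' Generate a random genome
#'
#' Draws a uniform-composition random sequence for each configured
#' chromosome. Motif instances are inserted later by [plant_sites()], which
#' edits the returned sequence at each planted anchor summit.
#'
#' @param config A [sim_config()].
#' @return A list with `model` (data.frame of `chrom`, `length`) and
#'   `sequence` (a [Biostrings::DNAStringSet-class]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "genome"))
  lens <- config$chrom_lengths
  bases <- utf8ToInt("ACGT")
  seqs <- vapply(lens, function(n) {
    intToUtf8(bases[sample.int(4L, n, replace = TRUE)])
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(lens)
  list(model = data.frame(chrom = names(lens), length = as.integer(lens),
                          stringsAsFactors = FALSE),
       sequence = dna)
}

# Sample one concrete sequence from an IUPAC consensus.
.sample_motif_instance <- function(consensus) {
  codes <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters %in% names(codes)))
    stop("invalid IUPAC code in consensus: ",
         paste(setdiff(letters, names(codes)), collapse = ", "))
  paste(vapply(letters, function(l) {
    alts <- strsplit(codes[[l]], "")[[1]]
    alts[sample.int(length(alts), 1L)]
  }, character(1)), collapse = "")
}

#' Plant motif-anchored binding sites and build the ground-truth table
#'
#' Places `n_sites` repressor-complex sites and `n_control_sites`
#' control-factor sites on the genome with at least `spacing` bp between
#' sites and `margin` bp clear of chromosome ends. Each non-control site gets
#' one motif instance written into the genome sequence, centered on the
#' anchor (GFI1-like) summit. The two accessory factors share a per-site side
#' `s` in `{-1, +1}` and a per-site distance `d` (modal value plus truncated
#' normal noise), each plus independent integer jitter. Strengths are
#' lognormal with a Gaussian-copula correlation across factors; knockdown
#' retention fractions, acetylation/accessibility baselines and knockdown
#' gains follow the configured strength-quantile rules.
#'
#' The genome sequence inside `genome$sequence` is modified in place
#' (planted motifs); the returned list carries the updated sequence.
#'
#' @param genome Output of [generate_genome()].
#' @param config A [sim_config()].
#' @return A list with `truth` (data.frame of class `truth_table`) and
#'   `sequence` (motif-edited `DNAStringSet`).
#' @export
plant_sites <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "sites"))
  model <- genome$model
  n_total <- config$n_sites + config$n_control_sites

  # Slot-based placement: slot pitch 1.5x spacing with +/- spacing/4 jitter
  # guarantees >= spacing between any two sites while avoiding a lattice.
  pitch <- 1.5 * config$spacing
  slots <- lapply(seq_len(nrow(model)), function(i) {
    usable <- model$length[i] - 2 * config$margin
    k <- floor(usable / pitch)
    if (k < 1) return(NULL)
    data.frame(chrom = model$chrom[i],
               pos = config$margin + (seq_len(k) - 0.5) * pitch,
               stringsAsFactors = FALSE)
  })
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_total)
    stop(sprintf("genome too small: %d sites requested but only %d slots of %.0f bp available",
                 n_total, if (is.null(slots)) 0L else nrow(slots), pitch))
  pick <- sort(sample.int(nrow(slots), n_total))
  sites <- slots[pick, , drop = FALSE]
  sites$pos <- round(sites$pos +
                       stats::runif(n_total, -config$spacing / 4,
                                    config$spacing / 4))
  is_control <- rep(FALSE, n_total)
  if (config$n_control_sites > 0)
    is_control[sample.int(n_total, config$n_control_sites)] <- TRUE

  n <- config$n_sites
  idx <- which(!is_control)
  cidx <- which(is_control)

  # Side-consistent offsets for the accessory factors.
  side <- sample(c(-1L, 1L), n, replace = TRUE)
  d <- config$offset_modal + stats::rnorm(n, 0, config$offset_sd)
  d <- pmax(d, 0)
  j <- config$factor_jitter
  jit_h <- if (j > 0) sample(seq(-j, j), n, replace = TRUE) else integer(n)
  jit_l <- if (j > 0) sample(seq(-j, j), n, replace = TRUE) else integer(n)
  gsum <- as.integer(sites$pos[idx])
  hsum <- as.integer(round(gsum + side * d + jit_h))
  lsum <- as.integer(round(gsum + side * d + jit_l))

  # Correlated lognormal strengths via a Gaussian copula; sqrt(rho) factor
  # loadings give pairwise latent correlation rho between any two factors.
  a <- sqrt(config$strength_rho)
  z0 <- stats::rnorm(n)
  zf <- function() a * z0 + sqrt(1 - a^2) * stats::rnorm(n)
  str_h <- exp(config$strength_meanlog + config$strength_sdlog * zf())
  str_l <- exp(config$strength_meanlog + config$strength_sdlog * zf())
  str_g <- exp(config$strength_meanlog + config$strength_sdlog * zf())

  # Knockdown retention: the depleted factor loses signal everywhere; its
  # partner's loss is coupled at the strongest sites only; the anchor stays.
  ret_h <- stats::runif(n, config$hmg20b_retention[1], config$hmg20b_retention[2])
  q_lsd <- stats::quantile(str_h, config$lsd1_affected_quantile)
  ret_l <- ifelse(str_h >= q_lsd, 1 - config$lsd1_coupling * (1 - ret_h), 1)
  ret_g <- rep(1, n)

  # Acetylation/accessibility: inverse-strength baseline and knockdown gain
  # restricted to strong sites.
  q_inv <- stats::quantile(str_h, config$acet_inverse_quantile)
  inv_scale <- ifelse(str_h >= q_inv,
                      (q_inv / str_h)^config$acet_inverse_power, 1)
  acet_base <- config$acet_baseline * inv_scale
  atac_base <- config$atac_baseline * inv_scale
  q_gain <- stats::quantile(str_h, config$acet_gain_quantile)
  acet_gain <- ifelse(str_h >= q_gain, config$acet_kd_gain, 1)

  pp <- config$presence_prob
  pres_h <- stats::runif(n) < pp[["hmg20b"]]
  pres_g <- stats::runif(n) < pp[["gfi1"]]
  pres_l <- stats::runif(n) < pp[["lsd1"]]

  truth <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    chrom = sites$chrom[idx],
    gfi1_summit = gsum,
    side = side,
    offset = d,
    hmg20b_summit = hsum,
    lsd1_summit = lsum,
    strength_hmg20b = str_h,
    strength_lsd1 = str_l,
    strength_gfi1 = str_g,
    present_hmg20b = pres_h,
    present_gfi1 = pres_g,
    present_lsd1 = pres_l,
    retention_hmg20b = ret_h,
    retention_lsd1 = ret_l,
    retention_gfi1 = ret_g,
    acet_baseline = acet_base,
    acet_kd_gain = acet_gain,
    atac_baseline = atac_base,
    control = FALSE,
    stringsAsFactors = FALSE)

  if (length(cidx)) {
    str_c <- exp(config$strength_meanlog +
                   config$strength_sdlog * stats::rnorm(length(cidx)))
    med_c <- stats::median(str_c)
    ctrl <- data.frame(
      site_id = sprintf("ctrl%05d", seq_along(cidx)),
      chrom = sites$chrom[cidx],
      gfi1_summit = as.integer(sites$pos[cidx]),
      side = NA_integer_, offset = NA_real_,
      hmg20b_summit = NA_integer_, lsd1_summit = NA_integer_,
      strength_hmg20b = str_c, strength_lsd1 = NA_real_,
      strength_gfi1 = NA_real_,
      present_hmg20b = FALSE, present_gfi1 = FALSE, present_lsd1 = FALSE,
      retention_hmg20b = 1, retention_lsd1 = 1, retention_gfi1 = 1,
      # Positive strength/acetylation level relation, no knockdown response.
      acet_baseline = config$acet_baseline * sqrt(str_c / med_c),
      acet_kd_gain = 1,
      atac_baseline = config$atac_baseline * sqrt(str_c / med_c),
      control = TRUE,
      stringsAsFactors = FALSE)
    truth <- rbind(truth, ctrl)
  }

  # Bounds check (accessory summits may drift a few bp off the anchor).
  lens <- stats::setNames(genome$model$length, genome$model$chrom)
  smax <- pmax(truth$gfi1_summit,
               ifelse(is.na(truth$hmg20b_summit), 0, truth$hmg20b_summit),
               ifelse(is.na(truth$lsd1_summit), 0, truth$lsd1_summit))
  stopifnot(all(smax < lens[truth$chrom]), all(truth$gfi1_summit >= 0))

  # Write one motif instance centered on each non-control anchor summit.
  seqs <- genome$sequence
  mlen <- nchar(config$motif)
  half <- mlen %/% 2
  nonctrl <- truth[!truth$control, , drop = FALSE]
  for (ch in unique(nonctrl$chrom)) {
    rows <- nonctrl[nonctrl$chrom == ch, , drop = FALSE]
    inst <- vapply(seq_len(nrow(rows)), function(i)
      .sample_motif_instance(config$motif), character(1))
    at <- IRanges::IRanges(start = rows$gfi1_summit - half + 1L,
                           width = mlen)
    seqs[[ch]] <- Biostrings::replaceAt(seqs[[ch]], at, inst)
  }

  class(truth) <- c("truth_table", "data.frame")
  list(truth = truth, sequence = seqs)
}
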