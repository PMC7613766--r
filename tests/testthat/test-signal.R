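test_that("window means follow bin-center membership", {
  trk <- signal_track(list(c1 = rep(3, 100)), bin_size = 10,
                      condition = "ntc")
  pk <- make_peaks(c(500L), chrom = "c1")
  expect_equal(as.numeric(window_signal(trk, pk, 300)), 3)

  # half-window below the bin size returns the summit's bin value
  vals <- seq_len(100)
  trk2 <- signal_track(list(c1 = as.numeric(vals)), bin_size = 10)
  w <- window_signal(trk2, pk, 4)
  expect_equal(as.numeric(w), vals[500 %/% 10 + 1])

  off <- make_peaks(5000L, chrom = "c1", half = 10)
  expect_error(window_signal(trk2, off, 300), "off chromosome")
})

test_that("window mean of an isolated bump equals its integral over the bins", {
  cfg <- sim_config(seed = 6, n_sites = 1, n_control_sites = 0,
                    chrom_lengths = c(c1 = 200000), poisson_noise = FALSE)
  g <- generate_genome(cfg)
  tr <- plant_sites(g, cfg)$truth
  tk <- render_tracks(tr, g$model, cfg, what = "gfi1")
  v <- tk$gfi1$ntc$values$c1
  s <- tr$gfi1_summit
  h <- 300
  centers <- (seq_along(v) - 1) * 10 + 5
  sel <- centers >= s - h & centers < s + h
  pk <- make_peaks(s, chrom = "c1")
  expect_equal(as.numeric(window_signal(tk$gfi1$ntc, pk, h)),
               sum(v[sel]) / sum(sel))
})

test_that("fold change is unity when conditions are identical and errors on mismatch", {
  x <- stats::setNames(runif(50, 1, 10), sprintf("p%02d", 1:50))
  co <- assign_cohorts(make_peaks(seq(500L, by = 1000L, length.out = 50),
                                  pileup = 50:1,
                                  names = names(x)), 10)
  ws <- structure(x, h = 300, condition = "ntc", class = "window_signal")
  fc <- fold_change(ws, ws, co)
  expect_true(all(abs(fc$per_peak - 1) < 1e-12))
  expect_true(all(abs(fc$summary$mean - 1) < 1e-12))

  y <- ws[c(2:50, 1)]
  attributes(y) <- attributes(ws)
  names(y) <- names(x)[c(2:50, 1)]
  expect_error(fold_change(y, ws, co), "universes differ")
})

test_that("ANOVA across cohorts behaves at both extremes", {
  nm <- sprintf("p%03d", 1:200)
  co <- assign_cohorts(make_peaks(seq(500L, by = 1000L, length.out = 200),
                                  pileup = 200:1, names = nm), 10)
  mkws <- function(v) structure(stats::setNames(v, nm), h = 300,
                                condition = "kd", class = "window_signal")
  ones <- mkws(rep(1, 200))
  # identical groups: F = 0, p = 1
  set.seed(3)
  noise <- rep(rnorm(20, 10, 1), 10)   # same values in every cohort
  same <- fold_change(mkws(noise), ones, co, pseudocount = 0)
  expect_gt(same$anova_p, 0.99)
  # separation of 5 sigma between cohort 1 and the rest
  sep <- noise
  sep[match(co$name[co$cohort == 1], nm)] <-
    sep[match(co$name[co$cohort == 1], nm)] + 5
  diff <- fold_change(mkws(sep), ones, co, pseudocount = 0)
  expect_lt(diff$anova_p, 1e-6)
})

test_that("anchor factor recovers global scaling exactly", {
  nm <- sprintf("p%02d", 1:20)
  mkws <- function(v, cond) structure(stats::setNames(v, nm), h = 300,
                                      condition = cond,
                                      class = "window_signal")
  g <- mkws(runif(20, 5, 50), "ntc")
  expect_equal(gfi1_anchor_factor(mkws(unclass(g), "kd"), g), 1)
  halved <- mkws(unclass(g) / 2, "kd")
  expect_equal(gfi1_anchor_factor(halved, g), 2)
  expect_error(gfi1_anchor_factor(mkws(rep(0, 20), "kd"), g), "zero")
})

test_that("anchored ratios are exactly one per cohort in a noise-free run", {
  cfg <- sim_config(seed = 17, n_sites = 200, n_control_sites = 0,
                    chrom_lengths = c(c1 = 2000000),
                    poisson_noise = FALSE, pileup_noise = 0,
                    hmg20b_retention = c(1, 1), lsd1_coupling = 0)
  g <- generate_genome(cfg)
  tr <- plant_sites(g, cfg)$truth
  tk <- render_tracks(tr, g$model, cfg, what = c("gfi1", "lsd1"))
  pk <- emit_peaks(tr, cfg)$hmg20b
  co <- assign_cohorts(pk, 10)
  g_kd <- window_signal(tk$gfi1$kd, pk, 300)
  g_ntc <- window_signal(tk$gfi1$ntc, pk, 300)
  fac <- gfi1_anchor_factor(g_kd, g_ntc)
  expect_equal(fac, 1 / cfg$gfi1_condition_scale, tolerance = 1e-9)
  anchored <- apply_anchor(g_kd, fac)
  ratio <- unclass(anchored) / unclass(g_ntc)
  per_cohort <- tapply(ratio[co$name], co$cohort, mean)
  expect_true(all(abs(per_cohort - 1) <= 1e-6))
})

test_that("ratios are scale invariant as the pseudocount vanishes", {
  nm <- sprintf("p%03d", 1:100)
  co <- assign_cohorts(make_peaks(seq(500L, by = 1000L, length.out = 100),
                                  pileup = 100:1, names = nm), 10)
  mkws <- function(v) structure(stats::setNames(v, nm), h = 300,
                                condition = "x", class = "window_signal")
  set.seed(4)
  l_kd <- mkws(runif(100, 1, 20)); l_ntc <- mkws(runif(100, 1, 20))
  g_kd <- mkws(runif(100, 1, 20)); g_ntc <- mkws(runif(100, 1, 20))
  r1 <- lsd1_gfi1_ratio(l_kd, l_ntc, g_kd, g_ntc, co, pseudocount = 0)
  r2 <- lsd1_gfi1_ratio(mkws(2 * unclass(l_kd)), mkws(2 * unclass(l_ntc)),
                        mkws(2 * unclass(g_kd)), mkws(2 * unclass(g_ntc)),
                        co, pseudocount = 0)
  expect_equal(r1$per_peak, r2$per_peak)
  # lsd1 = gfi1 everywhere -> all ratios one
  same <- lsd1_gfi1_ratio(g_kd, g_ntc, g_kd, g_ntc, co, pseudocount = 0)
  expect_true(all(abs(attr(same, "ratio_kd") - 1) < 1e-12))
})

test_that("knockdown acetylation gain is detected in exactly the planted cohorts", {
  d <- default_sim()
  pk <- d$sim$peaks$hmg20b
  co <- assign_cohorts(pk, 10)
  ws <- function(f, cond, h) window_signal(d$sim$tracks[[f]][[cond]], pk, h)
  fc <- fold_change(ws("h3k27ac", "kd", 1000), ws("h3k27ac", "ntc", 1000), co)
  ct <- cohort_contrasts(fc, top = 1:3, bottom = 6:10)
  expect_true(all(ct$p_adj < 0.01))
  expect_true(all(ct$diff > 0))
  # cohorts 4 and 5 carry no planted gain
  ct45 <- cohort_contrasts(fc, top = 4:5, bottom = 6:10)
  expect_true(all(abs(fc$summary$mean[4:10] - 1) < 0.1))
})

test_that("the LSD1:GFI1 ratio drops in exactly the planted cohorts after anchoring", {
  d <- default_sim()
  pk <- d$sim$peaks$hmg20b
  co <- assign_cohorts(pk, 10)
  ws <- function(f, cond) window_signal(d$sim$tracks[[f]][[cond]], pk, 300)
  g_kd <- ws("gfi1", "kd"); g_ntc <- ws("gfi1", "ntc")
  fac <- gfi1_anchor_factor(g_kd, g_ntc)
  rr <- lsd1_gfi1_ratio(apply_anchor(ws("lsd1", "kd"), fac), ws("lsd1", "ntc"),
                        apply_anchor(g_kd, fac), g_ntc, co)
  detected <- vapply(1:5, function(k) {
    ct <- cohort_contrasts(rr, top = k, bottom = setdiff(6:10, k))
    all(ct$p_adj < 0.01) && all(ct$diff < 0)
  }, logical(1))
  expect_true(all(detected[1:4]))
  expect_false(detected[5])
})

test_that("control-factor peaks show no cohort trend in fold change", {
  d <- default_sim()
  pk <- d$sim$peaks$control
  co <- assign_cohorts(pk, 10)
  ws <- function(cond) window_signal(d$sim$tracks$h3k27ac[[cond]], pk, 1000)
  fc <- fold_change(ws("kd"), ws("ntc"), co)
  fit <- stats::lm(mean ~ cohort, data = fc$summary)
  expect_gt(summary(fit)$coefficients["cohort", 4], 0.05)
  expect_true(all(abs(fc$summary$mean - 1) < 0.1))
})

test_that("per-cohort signal losses correlate when coupled and not when uncoupled", {
  d <- default_sim()
  pk <- d$sim$peaks$hmg20b
  co <- assign_cohorts(pk, 10)
  ws <- function(f, cond) window_signal(d$sim$tracks[[f]][[cond]], pk, 300)
  g_kd <- ws("gfi1", "kd"); g_ntc <- ws("gfi1", "ntc")
  fac <- gfi1_anchor_factor(g_kd, g_ntc)
  lc <- loss_correlation(apply_anchor(ws("lsd1", "kd"), fac),
                         ws("lsd1", "ntc"),
                         apply_anchor(ws("hmg20b", "kd"), fac),
                         ws("hmg20b", "ntc"), co)
  expect_gte(lc$r, 0.9)

  # equal losses by construction give r = 1
  nm <- sprintf("p%03d", 1:100)
  co2 <- assign_cohorts(make_peaks(seq(500L, by = 1000L, length.out = 100),
                                   pileup = 100:1, names = nm), 10)
  mkws <- function(v) structure(stats::setNames(v, nm), h = 300,
                                condition = "x", class = "window_signal")
  set.seed(5)
  ntc <- mkws(runif(100, 10, 50)); kd <- mkws(unclass(ntc) * 0.6)
  eq <- loss_correlation(kd, ntc, kd, ntc, co2)
  expect_equal(eq$r, 1)

  # independent random losses across ten cohorts stay weakly correlated
  kd_a <- mkws(unclass(ntc) - rep(runif(10, 0, 5), each = 10))
  kd_b <- mkws(unclass(ntc) - rep(runif(10, 0, 5), each = 10))
  un <- loss_correlation(kd_a, ntc, kd_b, ntc, co2)
  expect_lt(abs(un$r), 0.5)
})

test_that("mark distributions reflect the planted inverse-strength relation", {
  d <- default_sim()
  pk <- d$sim$peaks$hmg20b
  co <- assign_cohorts(pk, 10)
  mark <- window_signal(d$sim$tracks$h3k27ac$ntc, pk, 1000)
  sr <- strength_signal_relation(mark, co)
  med <- sr$stats$median
  expect_lt(med[1], med[2])
  expect_lt(med[2], med[3])
  expect_equal(sr$trend$rho, 1)

  # constant mark: all cohort medians equal
  flat <- structure(stats::setNames(rep(7, nrow(pk)), pk$name),
                    h = 1000, condition = "ntc", class = "window_signal")
  sr_flat <- strength_signal_relation(flat, co)
  expect_true(all(sr_flat$stats$median == 7))

  # H3K4Me1-like strength-neutral mark shows no inverse relation
  me1 <- window_signal(d$sim$tracks$h3k4me1$ntc, pk, 1000)
  sr_me1 <- strength_signal_relation(me1, co)
  expect_gt(min(sr_me1$stats$median) / max(sr_me1$stats$median), 0.9)
})
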