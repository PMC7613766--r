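test_that("narrowPeak parsing maps summit offsets and the signalValue pileup", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t8.0\t5.0\t3.0\t50",
               "chr1\t300\t400\tp2\t0\t.\t6.0\t5.0\t3.0\t-1"), path)
  pk <- read_narrowpeak(path)
  expect_equal(pk$summit, c(150L, 350L))
  expect_equal(pk$pileup, c(8, 6))
  expect_true(all(is.infinite(pk$fold_enrichment)))

  bad <- tempfile()
  writeLines("chr1\t100\t200\tp1\t0\t.\t8.0\t5.0\t3.0", bad)
  expect_error(read_narrowpeak(bad), "line 1")
})

test_that("MACS2 xls coordinates convert to 0-based and degenerate files are empty", {
  path <- tempfile(fileext = ".xls")
  writeLines(c("# comment",
               paste("chr", "start", "end", "length", "abs_summit", "pileup",
                     "-log10(pvalue)", "fold_enrichment", "-log10(qvalue)",
                     "name", sep = "\t"),
               paste("chr1", 101, 200, 100, 151, 60.5, 10, 7.5, 8, "m1",
                     sep = "\t")), path)
  pk <- read_macs2_xls(path)
  expect_equal(pk$start, 100L)
  expect_equal(pk$summit, 150L)
  expect_equal(pk$pileup, 60.5)
  expect_equal(pk$fold_enrichment, 7.5)

  empt <- tempfile(fileext = ".xls")
  writeLines(c("# only", "# comments"), empt)
  expect_equal(nrow(read_macs2_xls(empt)), 0L)

  miss <- tempfile(fileext = ".xls")
  writeLines(c(paste("chr", "start", "end", sep = "\t"),
               paste("chr1", 1, 10, sep = "\t")), miss)
  expect_error(read_macs2_xls(miss), "missing required")
})

test_that("coordinate round trips preserve summit, pileup and fold enrichment", {
  pk <- make_peaks(c(500L, 1500L, 2500L), pileup = c(60, 120, 300),
                   fe = c(6, 8, 12))
  xls <- tempfile(fileext = ".xls"); np <- tempfile(fileext = ".narrowPeak")
  write_macs2_xls(pk, xls)
  via_xls <- read_macs2_xls(xls)
  expect_equal(via_xls$summit, pk$summit)
  expect_equal(via_xls$pileup, pk$pileup)
  expect_equal(via_xls$fold_enrichment, pk$fold_enrichment)
  write_narrowpeak(via_xls, np)
  back <- read_narrowpeak(np, xls_sidecar = xls)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$pileup, pk$pileup)
  expect_equal(back$fold_enrichment, pk$fold_enrichment)
})

test_that("filter_peaks applies both thresholds and whole-interval blacklist exclusion", {
  pk <- make_peaks(c(500L, 1500L, 2500L), pileup = c(60, 40, 55),
                   fe = c(6, 6, 4))
  kept <- filter_peaks(pk)           # defaults 50 / 5
  expect_equal(kept$name, pk$name[1])

  expect_equal(nrow(filter_peaks(pk, min_pileup = 0, min_fe = 0)), 3L)

  # blacklist overlapping the first peak by a single base removes it
  bl <- data.frame(chrom = "chr1", start = pk$end[1] - 1L,
                   end = pk$end[1] + 10L)
  kept2 <- filter_peaks(pk, blacklist = bl, min_pileup = 0, min_fe = 0)
  expect_equal(kept2$name, pk$name[2:3])
})

test_that("filter_peaks is idempotent and monotone in its thresholds", {
  set.seed(1)
  pk <- make_peaks(seq(500L, by = 1000L, length.out = 50),
                   pileup = runif(50, 0, 200), fe = runif(50, 0, 15))
  for (thr in list(c(0, 0), c(50, 5), c(120, 8))) {
    f1 <- filter_peaks(pk, min_pileup = thr[1], min_fe = thr[2])
    f2 <- filter_peaks(f1, min_pileup = thr[1], min_fe = thr[2])
    expect_identical(as.data.frame(f1), as.data.frame(f2))
  }
  counts <- sapply(c(0, 25, 50, 100, 150),
                   function(t) nrow(filter_peaks(pk, min_pileup = t,
                                                 min_fe = 0)))
  expect_true(all(diff(counts) <= 0))
  counts_fe <- sapply(c(0, 3, 6, 9, 12),
                      function(t) nrow(filter_peaks(pk, min_pileup = 0,
                                                    min_fe = t)))
  expect_true(all(diff(counts_fe) <= 0))
})

test_that("select_top reproduces the published strongest-fraction arithmetic", {
  # 18,385 peaks of which 3,797 have pileup >= 110 -> 20.7%
  mk <- function(n_total, n_top, thr) {
    pil <- c(rep(thr + 1, n_top), rep(thr - 10, n_total - n_top))
    make_peaks(seq(500L, by = 500L, length.out = n_total), pileup = pil)
  }
  r1 <- select_top(mk(18385, 3797, 110), 110)
  expect_equal(r1$retained_fraction, 20.7)
  expect_equal(nrow(r1$peaks), 3797L)
  # 12,221 GFI1 peaks of which 2,479 have pileup >= 135 -> 20.3%
  expect_equal(select_top(mk(12221, 2479, 135), 135)$retained_fraction, 20.3)
  # threshold 0 keeps everything
  expect_equal(select_top(mk(100, 10, 50), 0)$retained_fraction, 100.0)
  expect_error(select_top(make_peaks(integer(0)), 10), "empty")
})

test_that("assign_cohorts uses floor-and-discard equal cohort sizes", {
  set.seed(2)
  pk <- make_peaks(seq(500L, by = 500L, length.out = 18385),
                   pileup = runif(18385, 10, 500))
  co <- assign_cohorts(pk, 10)
  expect_equal(attr(co, "cohort_size"), 1838L)
  expect_equal(length(attr(co, "discarded")), 5L)
  expect_equal(unname(table(co$cohort)), rep(1838L, 10),
               ignore_attr = TRUE)

  # 23 peaks over 10 cohorts: cohorts of 2, 3 discarded
  pk23 <- make_peaks(seq(500L, by = 500L, length.out = 23),
                     pileup = runif(23, 10, 500))
  co23 <- assign_cohorts(pk23, 10)
  expect_equal(attr(co23, "cohort_size"), 2L)
  expect_equal(length(attr(co23, "discarded")), 3L)

  # 10 peaks -> singleton cohorts in strength order
  pk10 <- make_peaks(seq(500L, by = 500L, length.out = 10),
                     pileup = 10 * (10:1))
  co10 <- assign_cohorts(pk10, 10)
  expect_equal(co10$cohort, 1:10)
  expect_equal(co10$pileup, sort(co10$pileup, decreasing = TRUE))

  expect_error(assign_cohorts(pk10, 11), "cohorts")
})

test_that("cohorts partition the input and are ordered by strength", {
  pk <- default_sim()$sim$peaks$hmg20b
  co <- assign_cohorts(pk, 10)
  expect_setequal(c(co$name, attr(co, "discarded")), pk$name)
  ranges <- lapply(split(co$pileup, co$cohort), range)
  for (k in 1:9)
    expect_gte(ranges[[k]][1], ranges[[k + 1]][2])
  # discarded peaks are the weakest
  if (length(attr(co, "discarded"))) {
    disc_max <- max(pk$pileup[pk$name %in% attr(co, "discarded")])
    expect_lte(disc_max, min(co$pileup))
  }
})

test_that("summit annotation follows the window rules with promoter precedence", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 50000L),
                      tes = c(15000L, 45000L),
                      exon_starts = c("10000,14800", "45000,49800"),
                      exon_ends = c("10200,15000", "45200,50000"),
                      stringsAsFactors = FALSE)
  pk <- make_peaks(c(9700L,   # 300 bp upstream of + TSS -> promoter
                     50500L,  # 500 bp upstream of - strand TSS -> promoter
                     12000L,  # mid gene body, between exons -> intron
                     10050L,  # inside first exon but within promoter window
                     10150L,  # first exon past the promoter window -> 5'UTR
                     14900L,  # last exon of gA -> 3'UTR
                     15500L,  # just downstream of gA TES -> TTS
                     120000L))  # far from everything -> intergenic
  ann <- annotate_peaks(pk, genes)
  expect_equal(unname(ann$category),
               c("promoter", "promoter", "intron", "promoter", "5'UTR",
                 "3'UTR", "TTS", "intergenic"))
  expect_equal(sum(ann$counts), nrow(pk))

  # unknown chromosome warns and falls back to intergenic
  pk2 <- make_peaks(5000L, chrom = "chrZ")
  expect_warning(ann2 <- annotate_peaks(pk2, genes), "absent")
  expect_equal(unname(ann2$category), "intergenic")

  # without exon structure the gene-body categories collapse
  ann3 <- annotate_peaks(pk, genes[, 1:5])
  expect_equal(unname(ann3$category[3]), "gene_body")
})

test_that("annotation recovers planted placements on a constructed genome", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 20000L, tes = 30000L,
                      exon_starts = "20000,29800", exon_ends = "20200,30000",
                      stringsAsFactors = FALSE)
  planted <- c(promoter = 19500L, intron = 25000L, intergenic = 80000L,
               TTS = 30500L)
  ann <- annotate_peaks(make_peaks(unname(planted)), genes)
  expect_equal(unname(ann$category), names(planted))
  expect_equal(as.integer(ann$counts[names(planted)]),
               rep(1L, 4), ignore_attr = TRUE)
})
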