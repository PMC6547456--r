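# The scanning-window caller: binning, background fit, multiple-testing
# control, peak localization, intensities, depth equalization, constitutive
# activity.

test_that("read binning uses half-open windows and conserves counts", {
  g <- genome_ref(c(c1 = strrep("A", 1200)))
  tr <- read_track(list(c1 = c(10L, 499L, 500L)), g)
  wc <- bin_reads(tr, g, 500L)
  expect_equal(wc$counts$c1, c(2L, 1L, 0L))
  expect_equal(sum(wc$counts$c1), tr$total_reads)
  expect_error(bin_reads(tr, g, 0L), "positive")

  empty <- read_track(list(c1 = integer(0)), g)
  expect_equal(bin_reads(empty, g, 500L)$counts$c1, c(0L, 0L, 0L))

  # partially mappable window flagged excluded but still counted
  g2 <- genome_ref(c(c1 = strrep("A", 1000)),
                   list(c1 = data.frame(start = 0L, end = 600L)))
  tr2 <- read_track(list(c1 = c(100L, 700L, 800L)), g2)
  wc2 <- bin_reads(tr2, g2, 500L)
  expect_equal(wc2$mappable_fraction$c1, c(1, 0.2))
  expect_equal(wc2$included$c1, c(TRUE, FALSE))
  expect_equal(sum(wc2$counts$c1), 3L)
})

test_that("background fit recovers Poisson and negative-binomial truths", {
  g <- genome_ref(c(c1 = strrep("A", 500 * 50000)))
  mk_wc <- function(x) {
    tr <- read_track(list(c1 = integer(0)), g)
    wc <- bin_reads(tr, g, 500L)
    wc$counts$c1 <- x
    wc
  }
  set.seed(1)
  bg_p <- fit_background(mk_wc(rpois(50000, 14)))
  expect_equal(bg_p$family, "poisson")
  expect_lt(abs(bg_p$mean_per_window - 14), 0.5)

  bg_nb <- fit_background(mk_wc(rnbinom(50000, size = 5, mu = 14)))
  expect_equal(bg_nb$family, "nbinom")
  expect_lt(abs(bg_nb$dispersion - 0.2) / 0.2, 0.2)  # phi = 1/size

  bg_c <- fit_background(mk_wc(rep(7L, 50000)))
  expect_equal(bg_c$dispersion, 0)
  expect_equal(bg_c$mean_per_window, 7)
})

test_that("caller flags an isolated spike and stays silent on flat data", {
  g <- genome_ref(c(c1 = strrep("A", 500 * 100000)))
  tr <- read_track(list(c1 = integer(0)), g)
  wc <- bin_reads(tr, g, 500L)
  set.seed(2)
  wc$counts$c1 <- rpois(100000, 14)
  wc$counts$c1[40000] <- 280L   # 20x background
  bg <- fit_background(wc)
  ori <- call_origins(wc, bg, caller_config(), genome = g)
  expect_equal(nrow(ori), 1L)
  expect_equal(ori$start, (40000L - 1L) * 500L)
  expect_equal(ori$end, 40000L * 500L)
  # the spike window's analytic p-value would survive even Bonferroni
  expect_lt(ppois(279, 14, lower.tail = FALSE) * 1e5, 1e-100)

  wc$counts$c1 <- rep(14L, 100000)
  expect_equal(nrow(call_origins(wc, fit_background(wc), caller_config())),
               0L)
})

test_that("significant runs merge across small gaps into one origin", {
  g <- genome_ref(c(c1 = strrep("A", 500 * 5000)))
  tr <- read_track(list(c1 = integer(0)), g)
  wc <- bin_reads(tr, g, 500L)
  set.seed(3)
  wc$counts$c1 <- rpois(5000, 10)
  wc$counts$c1[100:102] <- 300L
  wc$counts$c1[104] <- 300L      # gap of one window -> merged
  wc$counts$c1[300] <- 300L      # far away -> separate origin
  ori <- call_origins(wc, fit_background(wc), caller_config(merge_gap = 1L))
  expect_equal(nrow(ori), 2L)
  expect_equal(ori$start[1], 99L * 500L)
  expect_equal(ori$end[1], 104L * 500L)
  # merged origins never overlap
  expect_true(all(ori$start[-1] >= ori$end[-nrow(ori)]))
})

test_that("peak localization is exact on symmetric pileups", {
  g <- genome_ref(c(c1 = strrep("A", 5000)))
  ori <- data.frame(chrom = "c1", start = 500L, end = 1500L)
  tr <- read_track(list(c1 = c(980L, 990L, 1000L, 1010L, 1020L)), g)
  expect_equal(locate_sns_peak(ori, tr), 1000L)
  tr1 <- read_track(list(c1 = 777L), g)
  expect_equal(locate_sns_peak(ori, tr1), 777L)
  tr0 <- read_track(list(c1 = 4000L), g)
  expect_error(locate_sns_peak(ori, tr0), "degenerate")
})

test_that("RPKM follows its definition and scales with total depth", {
  g <- genome_ref(c(c1 = strrep("A", 1e6)))
  ori <- data.frame(chrom = "c1", start = 1000L, end = 2000L)
  pos <- c(seq(1000L, 1990L, length.out = 10),
           seq(10000L, 999000L, length.out = 999990))
  tr <- read_track(list(c1 = as.integer(pos)), g)
  expect_equal(compute_intensity(ori, tr), 10)
  # doubling total reads (extra reads outside the origin) halves RPKM
  extra <- as.integer(seq(10000L, 999000L, length.out = 1e6))
  tr2 <- read_track(list(c1 = as.integer(c(pos, extra))), g)
  expect_equal(compute_intensity(ori, tr2), 5)
  tr3 <- read_track(list(c1 = 500000L), g)
  expect_equal(compute_intensity(ori, tr3), 0)
  expect_error(compute_intensity(data.frame(chrom = "c1", start = 5L,
                                            end = 5L), tr))
})

test_that("depth equalization subsamples uniformly and deterministically", {
  g <- genome_ref(c(c1 = strrep("A", 1e5)))
  set.seed(4)
  tr <- read_track(list(c1 = sort(sample.int(1e5, 14000)) - 1L), g)
  sub <- subsample_to_depth(tr, g, 28, seed = 9)
  expect_equal(sub$total_reads, 2800L)
  expect_true(all(sub$positions$c1 %in% tr$positions$c1))
  sub2 <- subsample_to_depth(tr, g, 28, seed = 9)
  expect_identical(sub$positions, sub2$positions)
  expect_identical(subsample_to_depth(tr, g, 140, seed = 1), tr)
  expect_error(subsample_to_depth(tr, g, 150, seed = 1), "above current")
})

test_that("constitutive activity is 100% for identical and 0% for disjoint sets", {
  set.seed(5)
  ref <- origin_set(data.frame(chrom = "c1",
                               start = seq(0L, 99000L, by = 1000L),
                               end = seq(500L, 99500L, by = 1000L),
                               rpkm = runif(100)))
  same <- constitutive_activity(ref, list(ref, ref), n_classes = 20L)
  expect_true(all(same$fraction_active_in_all == 1))
  expect_equal(sum(same$n), 100L)
  in_gaps <- origin_set(data.frame(chrom = "c1", start = ref$start + 510L,
                                   end = ref$start + 990L,
                                   rpkm = ref$rpkm))
  none <- constitutive_activity(ref, list(in_gaps), n_classes = 20L)
  expect_true(all(none$fraction_active_in_all == 0))
  expect_error(constitutive_activity(ref[1:10, ], list(ref), 20L),
               "fewer origins")
})

test_that("detection probability is non-decreasing in planted enrichment", {
  cfg0 <- sim_config(genome_length = 5e6, origin_density = 20,
                     intensity_sdlog = 0, seed = 6)
  g <- make_genome(cfg0)
  truth <- plant_origins(g, cfg0)
  rates <- vapply(c(10, 60, 400), function(fold) {
    cfg <- cfg0; cfg$peak_enrichment <- fold
    tr <- simulate_reads(g, truth, cfg)
    wc <- bin_reads(tr, g, 500L)
    called <- call_origins(wc, fit_background(wc), caller_config(),
                           genome = g)
    mean(overlaps_any(as.data.frame(truth), as.data.frame(called)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("called origins stay inside mappable territory", {
  s <- smoke_sim()
  called <- s$called
  expect_true(all(called$start >= 0 &
                    called$end <= s$genome$chrom_lengths[called$chrom]))
  expect_true(all(called$start[-1] >= called$end[-nrow(called)]))
})
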