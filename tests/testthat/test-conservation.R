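# Conservation and turnover logic: concentration curves, quartiles, CGS
# overlap, interval mapping, functional conservation, randomization,
# TSS conservation, homologous profiles, score profiles, categorization.

test_that("concentration curve behaves at its extremes", {
  g <- genome_ref(c(c1 = strrep("A", 2e6)))
  all_one <- read_track(list(c1 = rep(50L, 1000L)), g)
  cc <- concentration_curve(all_one, g, window = 1e5)
  expect_equal(cc$read_fraction[1], 1)
  expect_equal(concentration_share(cc, 0.05), 1)
  expect_equal(cc$n_windows, 20L)
  expect_true(all(diff(cc$read_fraction) >= 0))

  g2 <- genome_ref(c(c1 = strrep("A", 5e5)))
  expect_error(concentration_curve(read_track(list(c1 = 1L), g2), g2,
                                   window = 1e5), "at least 10")
})

test_that("top-quartile selection keeps ties and orders correctly", {
  set.seed(16)
  ori <- origin_set(data.frame(chrom = "c1",
                               start = seq(0L, 99000L, by = 1000L),
                               end = seq(500L, 99500L, by = 1000L),
                               rpkm = sample(100)))
  top <- select_top_quartile(ori)
  expect_equal(nrow(top), 25L)
  expect_gte(min(top$rpkm), max(ori$rpkm[-attr(top, "orig_idx")]))

  tied <- ori; tied$rpkm <- 5
  top2 <- select_top_quartile(tied)
  expect_equal(nrow(top2), 100L)
  expect_true(attr(top2, "all_tied"))
  expect_error(select_top_quartile(ori[1:3, ]), "at least 4")
})

test_that("CGS overlap matches a brute-force all-pairs oracle", {
  map <- homology_map(data.frame(
    chrom_a = "c1", start_a = c(100L, 500L), end_a = c(200L, 900L),
    chrom_b = "cB", start_b = c(0L, 100L), end_b = c(100L, 500L),
    orientation = "+"))
  inside <- origin_set(data.frame(chrom = "c1", start = 120L, end = 150L))
  expect_true(overlaps_cgs(inside, map))
  edge <- origin_set(data.frame(chrom = "c1", start = 199L, end = 300L))
  expect_true(overlaps_cgs(edge, map))     # 1-bp overlap counts
  off <- origin_set(data.frame(chrom = "c2", start = 120L, end = 150L))
  expect_false(overlaps_cgs(off, map))     # absent chromosome -> FALSE

  set.seed(17)
  q <- data.frame(chrom = "c1", start = sample.int(1000, 300))
  q$end <- q$start + sample.int(50, 300, replace = TRUE)
  got <- overlaps_cgs(origin_set(q), map)
  want <- vapply(seq_len(nrow(q)), function(i)
    any(q$start[i] < map$end_a & map$start_a < q$end[i]), logical(1))
  expect_identical(got, want)
})

test_that("interval mapping is orientation-aware, clipped and invertible", {
  idmap <- homology_map(data.frame(chrom_a = "c1", start_a = 0L,
                                   end_a = 1000L, chrom_b = "c1",
                                   start_b = 0L, end_b = 1000L,
                                   orientation = "+"))
  iv <- data.frame(chrom = "c1", start = 100L, end = 200L)
  expect_equal(map_interval(idmap, iv)[, c("start", "end")],
               data.frame(start = 100L, end = 200L))

  minus <- homology_map(data.frame(chrom_a = "c1", start_a = 100L,
                                   end_a = 200L, chrom_b = "cB",
                                   start_b = 1000L, end_b = 1100L,
                                   orientation = "-"))
  # A [110,130) sits 10..30 bp into the segment; reversed it occupies the
  # mirror offsets 70..90 from the B start: [1070, 1090)
  m <- map_interval(minus, data.frame(chrom = "c1", start = 110L,
                                      end = 130L))
  expect_equal(m$start, 1070L)
  expect_equal(m$end, 1090L)
  # point at segment start maps to B start (+) or B end-1 (-)
  pt <- data.frame(chrom = "c1", start = 100L, end = 101L)
  expect_equal(map_interval(minus, pt)$start, 1099L)
  plus <- minus; plus$orientation <- "+"
  expect_equal(map_interval(plus, pt)$start, 1000L)
  # spanning interval clipped to the overlapping part
  sp <- map_interval(plus, data.frame(chrom = "c1", start = 50L,
                                      end = 150L))
  expect_equal(sp$end - sp$start, 50L)
  expect_null(map_interval(plus, data.frame(chrom = "c1", start = 300L,
                                            end = 350L)))

  # round trip through the reversed map
  rev_map <- homology_map(data.frame(chrom_a = "cB", start_a = 1000L,
                                     end_a = 1100L, chrom_b = "c1",
                                     start_b = 100L, end_b = 200L,
                                     orientation = "-"))
  back <- map_interval(rev_map, m)
  expect_equal(back[, c("chrom", "start", "end")],
               data.frame(chrom = "c1", start = 110L, end = 130L))
})

test_that("functional conservation is bounded by CGS overlap", {
  idmap <- homology_map(data.frame(chrom_a = "c1", start_a = 0L,
                                   end_a = 100000L, chrom_b = "c1",
                                   start_b = 0L, end_b = 100000L,
                                   orientation = "+"))
  ori <- origin_set(data.frame(chrom = "c1",
                               start = seq(0L, 90000L, by = 10000L),
                               end = seq(500L, 90500L, by = 10000L),
                               rpkm = 1:10))
  same <- functional_conservation(ori, ori, idmap)
  expect_equal(same$pct_functionally_conserved, 100)
  shifted <- origin_set(data.frame(chrom = "c1", start = ori$start + 1000L,
                                   end = ori$end + 1000L))
  none <- functional_conservation(ori, shifted, idmap)
  expect_equal(none$pct_functionally_conserved, 0)
  expect_true(all(!none$conserved | none$in_cgs))

  # random data: conserved is always a subset of CGS-overlapping
  s <- smoke_sim()
  cfg <- s$cfg
  hom <- with_cache("smoke_hom",
                    simulate_homology(s$genome, s$truth, cfg))
  rep <- functional_conservation(select_top_quartile(s$truth),
                                 hom$origins_b, hom$map)
  expect_true(all(!rep$conserved | rep$in_cgs))
  expect_error(functional_conservation(empty_origins(), ori, idmap),
               "empty")
})

test_that("random origin sets preserve per-chromosome counts and sizes", {
  cfg <- sim_config(genome_length = 2e6, n_chroms = 2L, origin_density = 40,
                    seed = 25)
  g <- make_genome(cfg)
  ori <- plant_origins(g, cfg)
  sets <- random_origin_sets(ori, g, n_sets = 5L, seed = 3)
  expect_length(sets, 5L)
  for (s in sets) {
    expect_identical(table(s$chrom), table(ori$chrom))
    for (ch in unique(ori$chrom)) {
      lens <- s$end[s$chrom == ch] - s$start[s$chrom == ch]
      pool <- ori$end[ori$chrom == ch] - ori$start[ori$chrom == ch]
      expect_true(all(lens %in% pool))
    }
  }
})

test_that("TSS regions extend 5'-ward by origin-sized lengths", {
  ori <- origin_set(data.frame(chrom = "c1",
                               start = seq(0L, 9000L, by = 1000L),
                               end = seq(0L, 9000L, by = 1000L) + 700L))
  idmap <- homology_map(data.frame(chrom_a = "c1", start_a = 0L,
                                   end_a = 100000L, chrom_b = "c1",
                                   start_b = 0L, end_b = 100000L,
                                   orientation = "+"))
  tss <- data.frame(chrom = "c1", pos = c(20000L, 50000L),
                    strand = c("+", "-"))
  res <- tss_activity_conservation(tss, tss, ori, idmap, seed = 4)
  # + strand extends toward smaller coordinates, - strand toward larger
  expect_equal(res$regions_a$end[1], 20001L)
  expect_equal(res$regions_a$end[1] - res$regions_a$start[1] - 1L, 700L)
  expect_equal(res$regions_a$start[2], 50000L)
  expect_equal(res$regions_a$end[2] - res$regions_a$start[2] - 1L, 700L)
  # identical TSS sets through the identity map: fully conserved
  expect_equal(res$report$pct_functionally_conserved, 100)
  bad <- tss; bad$strand <- NULL
  expect_error(tss_activity_conservation(bad, tss, ori, idmap), "oriented")
})

test_that("homologous profiles are flat at expectation for uniform B reads", {
  set.seed(18)
  gb <- genome_ref(c(cB = strrep("A", 1e6)))
  tb <- read_track(list(cB = sort(sample.int(1e6, 50000)) - 1L), gb)
  map <- homology_map(data.frame(chrom_a = "c1", start_a = 0L,
                                 end_a = 1000000L, chrom_b = "cB",
                                 start_b = 0L, end_b = 1000000L,
                                 orientation = "+"))
  pk <- data.frame(chrom = "c1",
                   peak = seq(10000L, 990000L, length.out = 200))
  pk$peak <- as.integer(pk$peak)
  prof <- homologous_profile(pk, map, tb, gb, window = 3000L, bin = 50L)
  expectation <- attr(prof, "expectation")
  expect_equal(expectation, 50000 / 1e6 * 50)
  expect_lt(max(abs(prof$value - expectation)),
            5 * sqrt(expectation / 200))
  # counts are conserved: profile totals the reads captured in windows
  total_in_windows <- sum(vapply(pk$peak, function(p)
    sum(tb$positions$cB >= p - 1500 & tb$positions$cB <= p + 1500),
    numeric(1)))
  expect_equal(sum(prof$value) * attr(prof, "n_anchors"),
               total_in_windows, tolerance = 0.01)

  nomap <- homology_map(data.frame(chrom_a = "c9", start_a = 0L,
                                   end_a = 100L, chrom_b = "cB",
                                   start_b = 0L, end_b = 100L,
                                   orientation = "+"))
  expect_error(homologous_profile(pk, nomap, tb, gb), "no peak maps")
})

test_that("score profiles average per bin, handle gaps and orientation", {
  sc <- data.frame(chrom = "c1", start = 0L, end = 10000L, value = 0.42)
  an <- data.frame(chrom = "c1", pos = c(3000L, 7000L))
  prof <- score_profile(an, sc, halfwidth = 500L, bin = 50L)
  expect_true(all(abs(prof$value - 0.42) < 1e-12))

  # score only at the anchor position: delta at offset 0
  sc2 <- data.frame(chrom = "c1", start = c(3000L, 7000L),
                    end = c(3001L, 7001L), value = 1)
  prof2 <- score_profile(an, sc2, halfwidth = 100L, bin = 10L)
  expect_equal(sum(!is.na(prof2$value)), 1L)
  expect_equal(prof2$value[!is.na(prof2$value)], 1)

  # a step upstream of a minus-strand anchor appears at negative offsets
  sc3 <- data.frame(chrom = "c1", start = c(0L, 5000L),
                    end = c(5000L, 10000L), value = c(0, 1))
  an3 <- data.frame(chrom = "c1", pos = 5000L, strand = "-")
  prof3 <- score_profile(an3, sc3, halfwidth = 200L, bin = 50L)
  up <- prof3$value[prof3$offset < -25]
  dn <- prof3$value[prof3$offset > 25]
  expect_true(all(up == 1))   # 5' of a minus-strand anchor = larger coords
  expect_true(all(dn == 0))
  expect_error(score_profile(data.frame(chrom = "c9", pos = 1L), sc,
                             100L, 10L), "covers no anchor")
})

test_that("CGI/TSS categories partition origins with inclusive boundaries", {
  ori <- origin_set(data.frame(
    chrom = "c1", start = c(100L, 5000L, 9000L, 20000L),
    end = c(600L, 5500L, 9500L, 20500L)))
  cgi <- data.frame(chrom = "c1", start = c(550L, 9100L),
                    end = c(700L, 9200L))
  tss <- data.frame(chrom = "c1", pos = c(1349L, 9400L, 21249L))
  cat <- categorize_origins(ori, cgi, tss, tss_distance = 750L)
  # origin 1: CGI overlap, TSS at exactly 750 bp (inclusive boundary)
  expect_equal(as.character(cat),
               c("CGI[+]TSS[+]", "CGI[-]TSS[-]", "CGI[+]TSS[+]",
                 "CGI[-]TSS[+]"))
  expect_equal(sum(table(cat)), nrow(ori))
})
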