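# The synthetic-data generators: determinism, compositional regimes,
# origin placement, read pileups, planted skew/depletion/homology structure.

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 5e5, seed = 42)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  o1 <- plant_origins(g1, cfg)
  o2 <- plant_origins(g2, cfg)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  r1 <- simulate_reads(g1, o1, cfg)
  r2 <- simulate_reads(g2, o2, cfg)
  expect_identical(r1$positions, r2$positions)
  v1 <- simulate_variants(g1, o1, cfg)
  v2 <- simulate_variants(g2, o2, cfg)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("two compositional regimes alternate at the configured GC", {
  cfg <- sim_config(genome_length = 2e6, regime_gc = c(0.35, 0.55),
                    regime_block = 1e5, seed = 7)
  g <- make_genome(cfg)
  blocks <- seq(0L, 1.9e6, by = 1e5)
  gc <- vapply(blocks, function(b) {
    s <- get_seq(g, "chr1", b, b + 1e5)
    sum(Biostrings::letterFrequency(Biostrings::DNAStringSet(s),
                                    c("G", "C"))) / 1e5
  }, numeric(1))
  want <- rep(c(0.35, 0.55), 10)
  expect_true(all(abs(gc - want) < 0.02))
})

test_that("a single regime gives homogeneous k-mer usage across blocks", {
  cfg <- sim_config(genome_length = 1e6, regime_gc = 0.45,
                    regime_block = 1e5, seed = 8)
  g <- make_genome(cfg)
  counts <- t(vapply(seq(0L, 9e5, by = 1e5), function(b) {
    s <- Biostrings::DNAStringSet(get_seq(g, "chr1", b, b + 1e5))
    as.numeric(Biostrings::oligonucleotideFrequency(s, width = 2))
  }, numeric(16)))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("planted origins respect density, spacing and intensity tails", {
  cfg <- sim_config(genome_length = 10e6, origin_density = 34, seed = 11)
  g <- make_genome(cfg)
  ori <- plant_origins(g, cfg)
  # ~340 expected, Poisson band
  expect_lt(abs(nrow(ori) - 340) / sqrt(340), 4)
  expect_true(all(diff(sort(ori$peak)) >= cfg$min_spacing))
  expect_true(all(ori$peak >= ori$start & ori$peak < ori$end))

  cfg0 <- sim_config(genome_length = 1e6, origin_density = 0, seed = 1)
  expect_equal(nrow(plant_origins(make_genome(cfg0), cfg0)), 0L)

  cfg_bad <- sim_config(genome_length = 1e6, origin_density = 400, seed = 1)
  expect_error(plant_origins(make_genome(cfg_bad), cfg_bad), "infeasible")
})

test_that("read simulation matches the background rate and peaks at centers", {
  cfg <- sim_config(genome_length = 2e6, background_rate = 28, seed = 13)
  g <- make_genome(cfg)
  tr <- simulate_reads(g, empty_origins(), cfg)
  lambda <- 28 / 1000 * 2e6
  expect_lt(abs(tr$total_reads - lambda), 3 * sqrt(lambda))

  # one huge origin: the modal 500-bp window contains the true center
  one <- origin_set(data.frame(chrom = "chr1", start = 999000L,
                               end = 1001000L, peak = 1000250L,
                               rpkm = 50))
  tr2 <- simulate_reads(g, one, cfg)
  wc <- bin_reads(tr2, g, 500L)
  modal <- which.max(wc$counts$chr1) - 1L
  expect_true(1000250 >= modal * 500 && 1000250 < (modal + 1) * 500)
})

test_that("planted skew plateaus at the configured amplitude and flips", {
  sim <- with_cache("skew_sim", {
    cfg <- sim_config(genome_length = 6e6, skew_amplitude = 0.2, seed = 11)
    g0 <- make_genome(cfg)
    tr <- plant_origins(g0, cfg)
    list(cfg = cfg, truth = tr, genome = simulate_skew(g0, tr, cfg))
  })
  # empirical (G-C)/(G+C) in the pooled [-500, 0) windows
  win <- Biostrings::DNAStringSet(vapply(seq_len(nrow(sim$truth)),
    function(i) get_seq(sim$genome, sim$truth$chrom[i],
                        sim$truth$peak[i] - 500L, sim$truth$peak[i]),
    character(1)))
  cnt <- colSums(Biostrings::letterFrequency(win, c("G", "C", "A", "T")))
  expect_lt(abs((cnt["G"] - cnt["C"]) / (cnt["G"] + cnt["C"]) - 0.2), 0.03)
  expect_lt(abs((cnt["A"] - cnt["T"]) / (cnt["A"] + cnt["T"]) - 0.2), 0.03)

  # sign flips exactly at the center bin
  sk <- skew_profile(sim$truth, sim$genome, halfwidth = 500L, bin = 25L)
  first_dn <- sk$S_GC$value[sk$S_GC$offset > 0][1]
  last_up <- tail(sk$S_GC$value[sk$S_GC$offset < 0], 1)
  expect_gt(last_up, 0)
  expect_lt(first_dn, 0)

  # amplitude zero leaves the genome untouched
  cfg0 <- sim$cfg; cfg0$skew_amplitude <- 0
  expect_identical(simulate_skew(make_genome(sim$cfg), sim$truth, cfg0),
                   make_genome(sim$cfg))
})

test_that("variant simulation plants core depletion of common variants only", {
  cfg <- sim_config(genome_length = 5e6, origin_density = 100,
                    common_depletion = 1, seed = 19)
  g <- make_genome(cfg)
  tr <- plant_origins(g, cfg)
  v <- simulate_variants(g, tr, cfg)
  lab <- classify_variants(v)
  common <- lab[lab$freq_class == "common", ]
  # depletion 1.0: no common variants left in any core
  for (ch in unique(tr$chrom)) {
    pk <- tr$peak[tr$chrom == ch]
    cp <- common$pos[common$chrom == ch]
    expect_false(any(vapply(cp, function(p) any(abs(p - pk) <= 20),
                            logical(1))))
  }
  # rare variants remain at the genome-wide rate inside cores
  rare <- lab[lab$freq_class == "rare", ]
  core_bp <- nrow(tr) * 41
  n_core_rare <- sum(vapply(seq_len(nrow(tr)), function(i) {
    cp <- rare$pos[rare$chrom == tr$chrom[i]]
    sum(abs(cp - tr$peak[i]) <= 20)
  }, numeric(1)))
  expected <- nrow(rare) / mappable_length(g) * core_bp
  expect_lt(abs(n_core_rare - expected), 4 * sqrt(expected))

  expect_true(all(is.na(
    simulate_variants(g, tr, cfg, with_daf = FALSE)$daf)))
})

test_that("homology simulation plants exact conservation structure", {
  cfg <- sim_config(genome_length = 2e6, origin_density = 50,
                    cgs_fraction = 1, conserved_fraction = 1,
                    b_origin_density = 0, seed = 23)
  g <- make_genome(cfg)
  tr <- plant_origins(g, cfg)
  hom <- simulate_homology(g, tr, cfg)
  # every conserved segment pair is co-linear by construction (validated in
  # homology_map); full coverage + full conservation means every top origin
  # is functionally conserved
  top <- select_top_quartile(tr)
  rep <- functional_conservation(top, hom$origins_b, hom$map)
  expect_equal(rep$pct_overlapping_cgs, 100)
  expect_equal(rep$pct_conserved_of_cgs, 100)

  cfg_bad <- sim_config(cgs_fraction = 0, conserved_fraction = 0.3)
  expect_error(simulate_homology(g, tr, cfg_bad), "requires cgs_fraction")
})
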