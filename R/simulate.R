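# Synthetic-data generators. These define the study conditions under which
# the pipeline is exercised: planted origins with peak-shaped read pileups
# over a Poisson background, strand-asymmetric compositional skew inverting
# at origin centers, SNPs with a rare/intermediate/common DAF mixture and a
# configurable depletion of common variants in a ~40-bp core, and homology
# maps with a controlled fraction of functionally conserved origins.

#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults are anchored to the
#' vertebrate SNS-seq setting the package targets: ~55 origins/Mb, 28
#' reads/kb sequencing depth, ~800-bp origins, a 40-bp core with 25%
#' common-variant depletion, skew amplitude 0.2 extending ~2 kb, and a DAF
#' mixture with 76.2% rare (<1%), 9.5% common (>10%) variants.
#'
#' @param genome_length total genome length in bp.
#' @param n_chroms number of equally sized chromosomes.
#' @param regime_gc GC content of the alternating compositional regimes.
#' @param regime_block regime block length in bp.
#' @param mask_fraction fraction of each chromosome made non-mappable.
#' @param origin_density origins per Mb of mappable sequence.
#' @param min_spacing minimum distance between origin centers (bp).
#' @param origin_width_meanlog,origin_width_sdlog log-normal origin widths.
#' @param intensity_meanlog,intensity_sdlog log-normal origin intensities
#'   (long-tailed, so a top-25% class is well defined).
#' @param background_rate background read depth, reads per kb of mappable
#'   sequence.
#' @param peak_enrichment expected extra reads per origin per unit intensity.
#' @param peak_sd standard deviation (bp) of the truncated-normal read
#'   displacement law around the true center.
#' @param skew_amplitude plateau value of the planted GC and AT skews.
#' @param skew_extent bp over which the skew plateau holds on each side.
#' @param skew_taper bp over which the skew decays linearly to zero beyond
#'   the plateau.
#' @param core_width width (bp) of the origin core region.
#' @param snp_rate SNPs per bp.
#' @param indel_rate indels per bp.
#' @param common_depletion fraction of common variants removed inside cores.
#' @param daf_weights mixture weights for rare (<0.01), intermediate, and
#'   common (>0.10) variant classes.
#' @param cgs_fraction fraction of genome A covered by conserved segments.
#' @param cgs_block conserved-segment block length (bp).
#' @param inversion_prob probability a conserved segment is inverted in B.
#' @param conserved_fraction fraction of top-25% A origins inside conserved
#'   segments that receive a functionally conserved B origin.
#' @param b_origin_density density (per Mb) of additional random B origins.
#' @param seed base seed; every generator derives its own stream from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 10e6,
                       n_chroms = 1L,
                       regime_gc = c(0.35, 0.55),
                       regime_block = 1e5,
                       mask_fraction = 0,
                       origin_density = 55,
                       min_spacing = 3000,
                       origin_width_meanlog = log(800),
                       origin_width_sdlog = 0.25,
                       intensity_meanlog = 0,
                       intensity_sdlog = 1,
                       background_rate = 28,
                       peak_enrichment = 200,
                       peak_sd = 100,
                       skew_amplitude = 0.2,
                       skew_extent = 2000,
                       skew_taper = 1000,
                       core_width = 40,
                       snp_rate = 0.027,
                       indel_rate = snp_rate * 0.043,
                       common_depletion = 0.25,
                       daf_weights = c(rare = 0.762, intermediate = 0.143,
                                       common = 0.095),
                       cgs_fraction = 0.6,
                       cgs_block = 20000,
                       inversion_prob = 0.2,
                       conserved_fraction = 0.30,
                       b_origin_density = 10,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(origin_density, background_rate, snp_rate, indel_rate,
             peak_enrichment, peak_sd)
  if (any(rates < 0)) stop_oriturn("rates must be >= 0")
  fracs <- c(mask_fraction, common_depletion, cgs_fraction,
             conserved_fraction, inversion_prob)
  if (any(fracs < 0 | fracs > 1)) stop_oriturn("fractions must be in [0,1]")
  if (skew_amplitude < 0 || skew_amplitude > 1)
    stop_oriturn("skew_amplitude must be in [0,1]")
  if (any(regime_gc <= 0 | regime_gc >= 1))
    stop_oriturn("regime_gc must be in (0,1)")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome
#'
#' Sequence is drawn in alternating blocks from the configured compositional
#' regimes (distinct GC contents, hence distinct k-mer usage), so background
#' clustering has signal. Fully mappable unless `mask_fraction > 0`, in which
#' case randomly chosen 10-kb tiles are masked.
#'
#' @param cfg a [sim_config()].
#' @param seed seed; defaults to the config seed.
#' @return a [genome_ref()].
#' @export
make_genome <- function(cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, "genome"))
  chrom_len <- floor(cfg$genome_length / cfg$n_chroms)
  nms <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    starts <- seq(0, chrom_len - 1, by = cfg$regime_block)
    blocks <- vapply(seq_along(starts), function(j) {
      gc <- cfg$regime_gc[((j - 1L) %% length(cfg$regime_gc)) + 1L]
      n <- min(cfg$regime_block, chrom_len - starts[j])
      random_dna(n, c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }, character(1))
    paste(blocks, collapse = "")
  }, character(1))
  names(seqs) <- nms
  mappable <- NULL
  if (cfg$mask_fraction > 0) {
    tile <- 10000L
    mappable <- lapply(seqs, function(s) {
      L <- nchar(s)
      starts <- seq(0L, L - 1L, by = tile)
      n_mask <- round(cfg$mask_fraction * length(starts))
      masked <- sample(seq_along(starts), n_mask)
      keep <- setdiff(seq_along(starts), masked)
      reduce_intervals(data.frame(start = starts[keep],
                                  end = pmin(starts[keep] + tile, L)))
    })
  }
  genome_ref(seqs, mappable)
}

#' Plant a truth set of replication origins
#'
#' Origin centers are uniform on mappable sequence subject to a minimum
#' spacing; widths and intensities are log-normal, the latter long-tailed so
#' the top-25% class is well defined.
#'
#' @param genome a [genome_ref()].
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @return an [origin_set()] with `peak` at the true center and `rpkm`
#'   holding the planted intensity.
#' @export
plant_origins <- function(genome, cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, "origins"))
  mb <- mappable_length(genome) / 1e6
  n <- rpois(1, cfg$origin_density * mb)
  if (n == 0L)
    return(origin_set(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0))))
  if (n * cfg$min_spacing > 0.8 * mappable_length(genome))
    stop_oriturn("origin density infeasible given min spacing")
  univ <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    m <- genome$mappable[[ch]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(chrom = ch, start = m$start, end = m$end)
  }))
  accepted <- stats::setNames(
    replicate(length(genome$chrom_names), integer(0), simplify = FALSE),
    genome$chrom_names)
  n_found <- 0L
  tries <- 0L
  while (n_found < n && tries < 50L) {
    tries <- tries + 1L
    m <- max(2L * (n - n_found), 100L)
    cw <- cumsum(as.numeric(univ$end - univ$start))
    u <- runif(m, 0, cw[length(cw)])
    iv <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
    iv[iv > nrow(univ)] <- nrow(univ)
    pos <- as.integer(univ$start[iv] + floor(u - c(0, cw)[iv]))
    ch <- univ$chrom[iv]
    for (j in seq_len(m)) {
      if (n_found >= n) break
      a <- accepted[[ch[j]]]
      if (length(a) == 0L || min(abs(a - pos[j])) >= cfg$min_spacing) {
        accepted[[ch[j]]] <- c(a, pos[j])
        n_found <- n_found + 1L
      }
    }
  }
  if (n_found < n)
    stop_oriturn("origin density infeasible given min spacing")
  df <- do.call(rbind, lapply(names(accepted), function(ch) {
    ctr <- sort(accepted[[ch]])
    if (length(ctr) == 0L) return(NULL)
    data.frame(chrom = ch, center = ctr)
  }))
  w <- pmax(100L, as.integer(round(
    rlnorm(nrow(df), cfg$origin_width_meanlog, cfg$origin_width_sdlog))))
  L <- genome$chrom_lengths[df$chrom]
  start <- pmax(0L, as.integer(df$center - w %/% 2L))
  end <- pmin(as.integer(L), as.integer(start + w))
  origin_set(data.frame(chrom = df$chrom, start = start, end = end,
                        peak = as.integer(df$center),
                        rpkm = rlnorm(nrow(df), cfg$intensity_meanlog,
                                      cfg$intensity_sdlog)))
}

#' Simulate an SNS read track
#'
#' Background reads are Poisson-uniform over mappable bp at
#' `background_rate`; each origin adds `rpois(rpkm * peak_enrichment)` reads
#' displaced from its true center by a rounded normal (sd `peak_sd`),
#' truncated to the chromosome.
#'
#' @param genome a [genome_ref()].
#' @param origins truth [origin_set()] (may be empty).
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @return a [read_track()].
#' @export
simulate_reads <- function(genome, origins, cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, "reads"))
  pos <- stats::setNames(
    replicate(length(genome$chrom_names), integer(0), simplify = FALSE),
    genome$chrom_names)
  for (ch in genome$chrom_names) {
    m <- genome$mappable[[ch]]
    n_bg <- rpois(1, cfg$background_rate / 1000 *
                       sum(as.numeric(m$end - m$start)))
    pos[[ch]] <- sample_positions_in_intervals(m, n_bg)
  }
  if (nrow(origins) > 0) {
    n_extra <- rpois(nrow(origins), origins$rpkm * cfg$peak_enrichment)
    for (i in seq_len(nrow(origins))) {
      if (n_extra[i] == 0L) next
      ch <- origins$chrom[i]
      L <- genome$chrom_lengths[[ch]]
      p <- origins$peak[i] + as.integer(round(rnorm(n_extra[i], 0,
                                                    cfg$peak_sd)))
      bad <- p < 0L | p >= L
      while (any(bad)) {
        p[bad] <- origins$peak[i] +
          as.integer(round(rnorm(sum(bad), 0, cfg$peak_sd)))
        bad <- p < 0L | p >= L
      }
      pos[[ch]] <- c(pos[[ch]], p)
    }
  }
  read_track(pos, genome)
}

# Planted skew value at signed offset d from an origin center: +a on the
# upstream plateau, -a downstream, linear taper to 0 beyond the plateau.
planted_skew <- function(d, a, extent, taper) {
  s <- numeric(length(d))
  s[d >= -extent & d < 0] <- a
  s[d >= 0 & d < extent] <- -a
  lo <- d >= -(extent + taper) & d < -extent
  s[lo] <- a * (d[lo] + extent + taper) / taper
  hi <- d >= extent & d < extent + taper
  s[hi] <- -a * (extent + taper - d[hi]) / taper
  s
}

#' Rewrite sequence to plant GC/AT skew inverting at origin centers
#'
#' Around each origin center the sequence is redrawn so that both strand
#' skews, S_GC = (G-C)/(G+C) and S_AT = (A-T)/(A+T), equal `+a` on the
#' upstream side and `-a` downstream, decaying linearly to zero beyond
#' `skew_extent`. Local GC content is preserved. Overlapping windows are
#' resolved by nearest-origin assignment.
#'
#' @param genome a [genome_ref()].
#' @param origins truth [origin_set()].
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @return a new [genome_ref()] with rewritten sequence.
#' @export
simulate_skew <- function(genome, origins, cfg, seed = cfg$seed) {
  if (cfg$skew_amplitude <= 0) return(genome)
  set.seed(derive_seed(seed, "skew"))
  half <- cfg$skew_extent + cfg$skew_taper
  seqs <- genome$seqs
  for (ch in unique(origins$chrom)) {
    L <- genome$chrom_lengths[[ch]]
    r <- charToRaw(seqs[[ch]])
    ctr <- sort(origins$peak[origins$chrom == ch])
    # nearest-origin assignment: cut overlapping windows at midpoints
    mids <- floor((ctr[-length(ctr)] + ctr[-1]) / 2)
    lo <- pmax(ctr - half, c(0L, mids))
    hi <- pmin(ctr + half, c(mids, L))
    for (i in seq_along(ctr)) {
      p <- seq.int(lo[i], hi[i] - 1L)
      if (length(p) == 0L) next
      d <- p - ctr[i]
      s <- planted_skew(d, cfg$skew_amplitude, cfg$skew_extent,
                        cfg$skew_taper)
      win <- rawToChar(r[p + 1L])
      gc_local <- mean(seq_chars(win) %in% c("G", "C"))
      is_gc <- runif(length(p)) < gc_local
      up <- runif(length(p)) < (1 + s) / 2   # G or A carry the + skew
      base <- ifelse(is_gc, ifelse(up, "G", "C"), ifelse(up, "A", "T"))
      r[p + 1L] <- charToRaw(paste(base, collapse = ""))
    }
    seqs[[ch]] <- rawToChar(r)
  }
  genome_ref(seqs, genome$mappable)
}

# Draw DAFs from the rare/intermediate/common mixture: rare variants below
# 0.01 and common above 0.10, with Beta-smoothed point masses.
draw_daf <- function(n, weights) {
  w <- weights / sum(weights)
  cls <- sample.int(3L, n, replace = TRUE, prob = w)
  daf <- numeric(n)
  daf[cls == 1L] <- 0.01 * rbeta(sum(cls == 1L), 1, 3)
  daf[cls == 2L] <- 0.01 + 0.09 * rbeta(sum(cls == 2L), 2, 2)
  daf[cls == 3L] <- 0.10 + 0.90 * rbeta(sum(cls == 3L), 1, 3)
  daf
}

# Signed distance from each position to the nearest peak on its chromosome
# (Inf when the chromosome has no peak).
dist_to_nearest_peak <- function(chrom, pos, peaks) {
  d <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    pk <- sort(peaks$peak[peaks$chrom == ch])
    if (length(pk) == 0L) next
    i <- which(chrom == ch)
    j <- findInterval(pos[i], pk)
    lo <- ifelse(j >= 1L, pos[i] - pk[pmax(j, 1L)], Inf)
    hi <- ifelse(j < length(pk), pk[pmin(j + 1L, length(pk))] - pos[i], Inf)
    d[i] <- pmin(abs(lo), abs(hi))
  }
  d
}

#' Simulate a polarized variant table
#'
#' SNPs (and indels) are Poisson-uniform over mappable sequence; DAF comes
#' from the configured rare/intermediate/common mixture. Inside the
#' `core_width` window around each true origin center, common variants (DAF
#' > 0.10) are thinned by `common_depletion` while rare variants are left
#' untouched, emulating purifying selection restricted to the origin core.
#'
#' @param genome a [genome_ref()].
#' @param origins truth [origin_set()] whose `peak` positions define cores.
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @param with_daf set `FALSE` to blank DAFs (species where frequency
#'   classes cannot be distinguished).
#' @return a [variant_table()].
#' @export
simulate_variants <- function(genome, origins, cfg, seed = cfg$seed,
                              with_daf = TRUE) {
  set.seed(derive_seed(seed, "variants"))
  univ <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    m <- genome$mappable[[ch]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(chrom = ch, start = m$start, end = m$end)
  }))
  draw_sites <- function(rate) {
    n <- rpois(1, rate * mappable_length(genome))
    if (n == 0L)
      return(data.frame(chrom = character(0), pos = integer(0)))
    cw <- cumsum(as.numeric(univ$end - univ$start))
    u <- runif(n, 0, cw[length(cw)])
    iv <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
    iv[iv > nrow(univ)] <- nrow(univ)
    data.frame(chrom = univ$chrom[iv],
               pos = as.integer(univ$start[iv] + floor(u - c(0, cw)[iv])))
  }
  base_at <- function(chrom, pos) {
    out <- character(length(pos))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      out[i] <- substring(genome$seqs[[ch]], pos[i] + 1L, pos[i] + 1L)
    }
    out
  }
  bases <- c("A", "C", "G", "T")
  other_base <- function(b) {
    # ancestral index + uniform offset in 1..3, wrapped: uniform over the
    # three non-ancestral bases
    i <- match(b, bases)
    bases[((i - 1L + sample.int(3L, length(b), replace = TRUE)) %% 4L) + 1L]
  }
  snp <- draw_sites(cfg$snp_rate)
  if (nrow(snp) > 0) {
    snp$ancestral <- base_at(snp$chrom, snp$pos)
    snp <- snp[snp$ancestral != "N", , drop = FALSE]
    snp$derived <- other_base(snp$ancestral)
  } else snp$ancestral <- snp$derived <- character(0)
  ind <- draw_sites(cfg$indel_rate)
  if (nrow(ind) > 0) {
    anc1 <- base_at(ind$chrom, ind$pos)
    ind <- ind[anc1 != "N", , drop = FALSE]
    anc1 <- anc1[anc1 != "N"]
    ins <- runif(nrow(ind)) < 0.5
    extra <- random_dna(nrow(ind))
    extra <- substring(extra, seq_len(nrow(ind)), seq_len(nrow(ind)))
    ind$ancestral <- ifelse(ins, anc1, paste0(anc1, extra))
    ind$derived <- ifelse(ins, paste0(anc1, extra), anc1)
  } else ind$ancestral <- ind$derived <- character(0)
  tab <- rbind(snp, ind)
  tab$daf <- draw_daf(nrow(tab), cfg$daf_weights)
  # thin common variants inside cores
  if (nrow(origins) > 0 && cfg$common_depletion > 0 && nrow(tab) > 0) {
    d <- dist_to_nearest_peak(tab$chrom, tab$pos, origins)
    in_core <- d <= cfg$core_width / 2
    drop <- in_core & tab$daf > 0.10 &
      runif(nrow(tab)) < cfg$common_depletion
    tab <- tab[!drop, , drop = FALSE]
  }
  if (!with_daf) tab$daf <- NA_real_
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  variant_table(tab)
}

#' Simulate a sister genome, homology map and conserved origins
#'
#' Genome B is a block shuffle of genome A: A is cut into `cgs_block`-bp
#' blocks, the blocks are permuted (a fraction `inversion_prob` inverted)
#' and concatenated into a single B chromosome. A fraction `cgs_fraction` of
#' blocks is recorded as conserved genomic segments (exact, ungapped
#' homology). Among top-25% A origins whose peak falls in a conserved block,
#' exactly `round(conserved_fraction * n)` receive a functionally conserved
#' B origin planted at the mapped peak position; additional random B origins
#' are placed at `b_origin_density`. B reads are then simulated.
#'
#' @param genome_a a [genome_ref()].
#' @param truth_a truth [origin_set()] for species A.
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @return list with `map` ([homology_map()]), `genome_b`, `origins_b`,
#'   `track_b`, and `conserved_a` (row indices of `truth_a` that were planted
#'   as conserved).
#' @export
simulate_homology <- function(genome_a, truth_a, cfg, seed = cfg$seed) {
  if (cfg$conserved_fraction > 0 && cfg$cgs_fraction == 0)
    stop_oriturn("conserved_fraction > 0 requires cgs_fraction > 0")
  set.seed(derive_seed(seed, "homology"))
  blocks <- do.call(rbind, lapply(genome_a$chrom_names, function(ch) {
    L <- genome_a$chrom_lengths[[ch]]
    st <- seq(0L, L - 1L, by = cfg$cgs_block)
    data.frame(chrom = ch, start = st, end = pmin(st + cfg$cgs_block, L))
  }))
  nb <- nrow(blocks)
  ord <- sample.int(nb)             # position of each block in B
  inverted <- runif(nb) < cfg$inversion_prob
  is_cgs <- seq_len(nb) %in% sample.int(nb, round(cfg$cgs_fraction * nb))
  widths <- blocks$end - blocks$start
  b_start <- c(0, cumsum(as.numeric(widths[ord])))[seq_len(nb)]
  b_of_a <- integer(nb); b_of_a[ord] <- seq_len(nb)  # rank in B of block i
  blocks$b_start <- as.integer(b_start[b_of_a])
  blocks$b_end <- as.integer(blocks$b_start + widths)
  blocks$inverted <- inverted
  pieces <- vapply(ord, function(i) {
    s <- get_seq(genome_a, blocks$chrom[i], blocks$start[i], blocks$end[i])
    if (blocks$inverted[i]) reverse_complement(s) else s
  }, character(1))
  genome_b <- genome_ref(c(chrB = paste(pieces, collapse = "")))
  map <- homology_map(data.frame(
    chrom_a = blocks$chrom[is_cgs],
    start_a = blocks$start[is_cgs],
    end_a = blocks$end[is_cgs],
    chrom_b = "chrB",
    start_b = blocks$b_start[is_cgs],
    end_b = blocks$b_end[is_cgs],
    orientation = ifelse(blocks$inverted[is_cgs], "-", "+")))
  # conserved B origins at mapped peaks of a fixed fraction of eligible A
  # origins (top quartile, peak inside a CGS)
  top <- select_top_quartile(truth_a)
  top_idx <- attr(top, "orig_idx")
  pk_map <- vapply(seq_len(nrow(top)), function(i) {
    m <- map_interval(map, data.frame(chrom = top$chrom[i],
                                      start = top$peak[i],
                                      end = top$peak[i] + 1L))
    if (is.null(m)) NA_integer_ else m$start
  }, integer(1))
  eligible <- which(!is.na(pk_map))
  n_cons <- round(cfg$conserved_fraction * length(eligible))
  cons <- if (n_cons > 0) sample(eligible, n_cons) else integer(0)
  w <- pmax(100L, as.integer(round(rlnorm(length(cons),
                                          cfg$origin_width_meanlog,
                                          cfg$origin_width_sdlog))))
  LB <- genome_b$chrom_lengths[["chrB"]]
  df_cons <- if (length(cons) > 0) {
    st <- pmax(0L, as.integer(pk_map[cons]) - w %/% 2L)
    data.frame(chrom = "chrB", start = st,
               end = pmin(LB, as.integer(st + w)),
               peak = as.integer(pk_map[cons]),
               rpkm = rlnorm(length(cons), cfg$intensity_meanlog,
                             cfg$intensity_sdlog))
  } else NULL
  cfg_b <- cfg
  cfg_b$origin_density <- cfg$b_origin_density
  rand_b <- plant_origins(genome_b, cfg_b,
                          seed = derive_seed(seed, "b-origins"))
  ob <- rbind(df_cons,
              as.data.frame(rand_b)[, c("chrom", "start", "end", "peak",
                                        "rpkm")])
  ob <- ob[order(ob$start), , drop = FALSE]
  # drop random origins colliding with a planted conserved one
  if (nrow(ob) > 1) {
    keep <- c(TRUE, diff(ob$peak) >= cfg$min_spacing)
    ob <- ob[keep, , drop = FALSE]
  }
  origins_b <- origin_set(ob)
  track_b <- simulate_reads(genome_b, origins_b, cfg,
                            seed = derive_seed(seed, "b-reads"))
  list(map = map, genome_b = genome_b, origins_b = origins_b,
       track_b = track_b,
       conserved_a = sort(top_idx[cons]))
}
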