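# Selection signatures around SNS peaks: DAF-stratified variant density
# profiles, base-specific densities and the core-region depletion statistic.

#' Variant classing thresholds
#'
#' Rare variants have DAF strictly below `daf_rare_max`, common variants
#' strictly above `daf_common_min`; everything in between (including the
#' boundaries) is intermediate.
#'
#' @param daf_rare_max rare-variant DAF upper bound (exclusive).
#' @param daf_common_min common-variant DAF lower bound (exclusive).
#' @return list of class `variant_classing`.
#' @export
variant_classing <- function(daf_rare_max = 0.01, daf_common_min = 0.10) {
  if (daf_rare_max >= daf_common_min)
    stop_oriturn("daf_rare_max must be < daf_common_min")
  structure(list(daf_rare_max = daf_rare_max,
                 daf_common_min = daf_common_min),
            class = "variant_classing")
}

#' Classify variants by frequency and mutation class
#'
#' Adds `freq_class` (rare / intermediate / common / unknown-frequency) and,
#' for SNPs, `mut_class`: GC->AT for \{G,C\} to \{A,T\}, AT->GC for \{A,T\}
#' to \{G,C\}, otherwise GC-conservative (the class used to separate
#' selection from GC-biased gene conversion).
#'
#' @param table a [variant_table()].
#' @param classing a [variant_classing()].
#' @return the table with `freq_class` and `mut_class` columns.
#' @export
classify_variants <- function(table, classing = variant_classing()) {
  daf <- table$daf
  fc <- rep("intermediate", nrow(table))
  fc[is.na(daf)] <- "unknown-frequency"
  fc[!is.na(daf) & daf < classing$daf_rare_max] <- "rare"
  fc[!is.na(daf) & daf > classing$daf_common_min] <- "common"
  table$freq_class <- fc
  mc <- rep(NA_character_, nrow(table))
  snp <- table$kind == "snp"
  anc_gc <- table$ancestral %in% c("G", "C")
  der_gc <- table$derived %in% c("G", "C")
  mc[snp & anc_gc & !der_gc] <- "GC->AT"
  mc[snp & !anc_gc & der_gc] <- "AT->GC"
  mc[snp & (anc_gc == der_gc)] <- "GC-conservative"
  table$mut_class <- mc
  table
}

# Per-anchor offset of variants relative to peaks; returns data.frame
# (anchor index, offset) for variants within halfwidth of an anchor peak.
variant_offsets <- function(peaks, table, halfwidth) {
  out <- NULL
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    vp <- table$pos[table$chrom == ch]
    if (length(vp) == 0L || nrow(pk) == 0L) next
    ov <- sort(vp)
    lo <- pk$peak - halfwidth
    hi <- pk$peak + halfwidth
    i1 <- findInterval(lo - 0.5, ov) + 1L
    i2 <- findInterval(hi + 0.5, ov)
    n_i <- pmax(0L, i2 - i1 + 1L)
    if (sum(n_i) == 0L) next
    anchor <- rep(pk$anchor_id, n_i)
    vidx <- unlist(lapply(which(n_i > 0L),
                          function(i) seq.int(i1[i], i2[i])))
    out <- rbind(out, data.frame(anchor = anchor,
                                 offset = ov[vidx] - rep(pk$peak, n_i)))
  }
  out %||% data.frame(anchor = integer(0), offset = integer(0))
}

prepare_anchors <- function(peaks) {
  pk <- as.data.frame(peaks)[, c("chrom", "peak")]
  pk$anchor_id <- seq_len(nrow(pk))
  pk
}

#' Variant density profile around SNS peaks
#'
#' Density per bp per anchor of the selected variant class, in offset bins
#' around the peaks, plus the genome-wide baseline (class count divided by
#' mappable genome length).
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param table classified variant table (see [classify_variants()]).
#' @param freq_class one of "rare", "intermediate", "common",
#'   "unknown-frequency", or `NULL` for all.
#' @param kind "snp", "indel" or `NULL` for both.
#' @param genome optional [genome_ref()] for the baseline.
#' @param halfwidth half-width in bp.
#' @param bin bin width in bp.
#' @return an [anchored_profile()] with attribute `baseline` (density per
#'   bp, `NA` without a genome).
#' @export
snp_density_profile <- function(peaks, table, freq_class = NULL,
                                kind = "snp", genome = NULL,
                                halfwidth = 500L, bin = 10L) {
  if (nrow(peaks) < 1L) stop_oriturn("need at least one anchor")
  tab <- table
  if (!is.null(kind)) tab <- tab[tab$kind == kind, , drop = FALSE]
  if (!is.null(freq_class))
    tab <- tab[tab$freq_class == freq_class, , drop = FALSE]
  pk <- prepare_anchors(peaks)
  off <- variant_offsets(pk, tab, halfwidth)
  edges <- seq(-halfwidth, halfwidth, by = bin)
  counts <- tabulate(findInterval(off$offset[off$offset < halfwidth],
                                  edges),
                     nbins = length(edges) - 1L)
  dens <- counts / (nrow(pk) * bin)
  prof <- anchored_profile(edges[-length(edges)] + bin / 2, dens,
                           nrow(pk), bin)
  attr(prof, "baseline") <- if (is.null(genome)) NA_real_ else
    nrow(tab) / mappable_length(genome)
  prof
}

#' Indel density profile around SNS peaks
#'
#' [snp_density_profile()] restricted to indels.
#'
#' @inheritParams snp_density_profile
#' @return an [anchored_profile()].
#' @export
indel_density_profile <- function(peaks, table, freq_class = NULL,
                                  genome = NULL, halfwidth = 500L,
                                  bin = 10L) {
  snp_density_profile(peaks, table, freq_class = freq_class, kind = "indel",
                      genome = genome, halfwidth = halfwidth, bin = bin)
}

#' Base-specific variant density
#'
#' Number of observed x -> y SNPs in a window around the peaks divided by
#' the number of ancestral x bases in the same windows.
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param table classified variant table.
#' @param genome a [genome_ref()].
#' @param x,y single ancestral and derived bases, `x != y`.
#' @param halfwidth window half-width in bp.
#' @return density (numeric), or `NA` when no x bases are present.
#' @export
base_specific_density <- function(peaks, table, genome, x, y,
                                  halfwidth = 250L) {
  if (x == y || nchar(x) != 1L || nchar(y) != 1L)
    stop_oriturn("x and y must be distinct single bases")
  tab <- table[table$kind == "snp" & table$ancestral == x &
                 table$derived == y, , drop = FALSE]
  pk <- prepare_anchors(peaks)
  n_var <- nrow(variant_offsets(pk, tab, halfwidth))
  win <- anchor_windows(peaks, genome, halfwidth)
  n_x <- sum(Biostrings::letterFrequency(win, x))
  if (n_x == 0L) return(NA_real_)
  n_var / n_x
}

#' Core-region depletion of variant density
#'
#' Ratio of variant density in the origin core (`peak +/- core_halfwidth`)
#' to the density in the flanks (`flank[1]` to `flank[2]` bp on each side),
#' for one variant class, with a 95% bootstrap confidence interval obtained
#' by resampling anchors (origins, not variants, are the resampling unit:
#' variant counts within an origin are dependent).
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param table classified variant table.
#' @param freq_class variant frequency class to measure (default "common").
#' @param kind "snp" or "indel".
#' @param core_halfwidth core half-width in bp (core width = 2*halfwidth).
#' @param flank numeric length-2, flank window `[flank[1], flank[2]]` bp on
#'   each side of the peak.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return list of class `core_depletion`: densities, `ratio`, `ci` and the
#'   per-anchor count matrix.
#' @export
core_depletion <- function(peaks, table, freq_class = "common",
                           kind = "snp", core_halfwidth = 20L,
                           flank = c(100L, 500L), n_boot = 1000L,
                           seed = 1L) {
  tab <- table[table$kind == kind, , drop = FALSE]
  if (!is.null(freq_class))
    tab <- tab[tab$freq_class == freq_class, , drop = FALSE]
  if (nrow(tab) == 0L) stop_oriturn("variant class is empty")
  pk <- prepare_anchors(peaks)
  off <- variant_offsets(pk, tab, flank[2])
  a <- abs(off$offset)
  core_n <- tabulate(off$anchor[a <= core_halfwidth], nbins = nrow(pk))
  flank_n <- tabulate(off$anchor[a >= flank[1] & a <= flank[2]],
                      nbins = nrow(pk))
  core_w <- 2 * core_halfwidth + 1
  flank_w <- 2 * (flank[2] - flank[1] + 1)
  if (sum(flank_n) == 0L) stop_oriturn("no variants in flank windows")
  ratio_of <- function(i) {
    fl <- sum(flank_n[i]) / flank_w
    if (fl == 0) return(NA_real_)
    (sum(core_n[i]) / core_w) / fl
  }
  n <- nrow(pk)
  ratio <- ratio_of(seq_len(n))
  set.seed(derive_seed(seed, "depletion-boot"))
  boot <- vapply(seq_len(n_boot),
                 function(b) ratio_of(sample.int(n, n, replace = TRUE)),
                 numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(core_density = sum(core_n) / (n * core_w),
                 flank_density = sum(flank_n) / (n * flank_w),
                 ratio = ratio, ci = ci,
                 core_halfwidth = core_halfwidth, flank = flank,
                 n_anchors = n,
                 counts = data.frame(core = core_n, flank = flank_n)),
            class = "core_depletion")
}

#' @export
print.core_depletion <- function(x, ...) {
  cat(sprintf(
    "<core_depletion> ratio %.3f (95%% CI %.3f-%.3f), %d anchors\n",
    x$ratio, x$ci[1], x$ci[2], x$n_anchors))
  invisible(x)
}
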