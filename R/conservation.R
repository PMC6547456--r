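# Cross-species conservation and turnover: read-concentration curves,
# top-quartile selection, conserved-segment overlap, interval mapping
# between assemblies, functional conservation with randomization nulls, TSS
# activity conservation, homologous read profiles and conservation-score
# profiles.

#' Read-concentration curve over large windows
#'
#' Tiles each chromosome with `window`-bp windows from its start (the last
#' partial window is dropped), sorts windows by descending read count and
#' reports the cumulative read fraction against the window-count fraction: a
#' Lorenz-style summary of how concentrated initiation activity is.
#'
#' @param track a [read_track()].
#' @param genome a [genome_ref()].
#' @param window window size in bp (default 100 kb).
#' @return list of class `concentration_curve` with `window_fraction`,
#'   `read_fraction` and `n_windows`.
#' @export
concentration_curve <- function(track, genome, window = 100000L) {
  counts <- unlist(lapply(genome$chrom_names, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    nb <- L %/% window
    if (nb == 0L) return(numeric(0))
    p <- track$positions[[ch]] %||% integer(0)
    p <- p[p < nb * window]
    tabulate(p %/% window + 1L, nbins = nb)
  }), use.names = FALSE)
  if (length(counts) < 10L) stop_oriturn("need at least 10 full windows")
  cs <- cumsum(sort(counts, decreasing = TRUE))
  structure(list(window_fraction = seq_along(cs) / length(cs),
                 read_fraction = cs / cs[length(cs)],
                 n_windows = length(cs)),
            class = "concentration_curve")
}

#' Share of reads in the richest fraction of windows
#'
#' @param curve a [concentration_curve()].
#' @param fraction genome (window-count) fraction, e.g. 0.05.
#' @return cumulative read fraction at that rank (linearly interpolated).
#' @export
concentration_share <- function(curve, fraction = 0.05) {
  stats::approx(c(0, curve$window_fraction), c(0, curve$read_fraction),
                xout = fraction, rule = 2)$y
}

#' Select the top 25% most active origins
#'
#' Keeps origins whose RPKM is at or above the 75th percentile; ties are
#' included, so the count may slightly exceed 25% (an attribute flags the
#' all-tied case). The attribute `orig_idx` maps back to row indices of the
#' input.
#'
#' @param origins an [origin_set()] with `rpkm`.
#' @return the top-quartile [origin_set()].
#' @export
select_top_quartile <- function(origins) {
  if (nrow(origins) < 4L) stop_oriturn("need at least 4 origins")
  thr <- quantile(origins$rpkm, 0.75)
  keep <- which(origins$rpkm >= thr)
  out <- origins[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "orig_idx") <- keep
  attr(out, "all_tied") <- length(keep) == nrow(origins)
  out
}

#' Conserved-segment overlap per origin
#'
#' `TRUE` iff the origin interval intersects >= 1 bp of any conserved
#' genomic segment on the A side of the map. Origins on chromosomes absent
#' from the map are `FALSE`.
#'
#' @param origins an [origin_set()] (A-side coordinates).
#' @param map a [homology_map()].
#' @return logical vector.
#' @export
overlaps_cgs <- function(origins, map) {
  cgs <- data.frame(chrom = map$chrom_a, start = map$start_a,
                    end = map$end_a)
  overlaps_any(as.data.frame(origins), cgs)
}

#' Map an interval into the sister genome
#'
#' Offset arithmetic within the conserved segment containing the interval,
#' orientation-aware; an interval spanning a segment boundary is first
#' clipped to the overlapping part. When several segments overlap, the one
#' with the largest overlap is used.
#'
#' @param map a [homology_map()].
#' @param interval one-row data.frame with `chrom`, `start`, `end`
#'   (A-side).
#' @return data.frame with `chrom`, `start`, `end`, `orientation` in B
#'   coordinates, or `NULL` when the interval overlaps no segment.
#' @export
map_interval <- function(map, interval) {
  cand <- map[map$chrom_a == interval$chrom &
                map$start_a < interval$end &
                map$end_a > interval$start, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ov <- pmin(cand$end_a, interval$end) - pmax(cand$start_a, interval$start)
  seg <- cand[which.max(ov), , drop = FALSE]
  s <- max(interval$start, seg$start_a)
  e <- min(interval$end, seg$end_a)
  if (seg$orientation == "+") {
    bs <- seg$start_b + (s - seg$start_a)
    be <- seg$start_b + (e - seg$start_a)
  } else {
    bs <- seg$start_b + (seg$end_a - e)
    be <- seg$start_b + (seg$end_a - s)
  }
  data.frame(chrom = seg$chrom_b, start = as.integer(bs),
             end = as.integer(be), orientation = seg$orientation)
}

# Map every interval of a data.frame; returns mapped data.frame with NA rows
# for unmapped intervals.
map_intervals <- function(map, intervals) {
  out <- data.frame(chrom = rep(NA_character_, nrow(intervals)),
                    start = NA_integer_, end = NA_integer_,
                    orientation = NA_character_)
  for (i in seq_len(nrow(intervals))) {
    m <- map_interval(map, intervals[i, , drop = FALSE])
    if (!is.null(m)) out[i, ] <- m
  }
  out
}

#' Functional conservation of origins across species
#'
#' An A origin is functionally conserved iff it overlaps a conserved
#' segment and its mapped interval overlaps >= 1 bp of any B origin (an
#' origin conserved via several B origins counts once). Report both the
#' percentage over all A origins considered and over the CGS-overlapping
#' subset.
#'
#' @param origins_a A-side [origin_set()] (typically the top quartile,
#'   called on depth-equalized data).
#' @param origins_b B-side [origin_set()].
#' @param map a [homology_map()].
#' @return list of class `conservation_report`: `n_origins_considered`,
#'   `pct_overlapping_cgs`, `pct_functionally_conserved`,
#'   `pct_conserved_of_cgs`, and the per-origin logical vectors `in_cgs`,
#'   `conserved`.
#' @export
functional_conservation <- function(origins_a, origins_b, map) {
  if (nrow(origins_a) == 0L) stop_oriturn("empty origin set")
  in_cgs <- overlaps_cgs(origins_a, map)
  conserved <- logical(nrow(origins_a))
  idx <- which(in_cgs)
  if (length(idx) > 0) {
    mapped <- map_intervals(map, as.data.frame(origins_a)[idx, , drop = FALSE])
    ok <- !is.na(mapped$start)
    conserved[idx[ok]] <- overlaps_any(mapped[ok, , drop = FALSE],
                                       as.data.frame(origins_b))
  }
  structure(list(
    n_origins_considered = nrow(origins_a),
    pct_overlapping_cgs = 100 * mean(in_cgs),
    pct_functionally_conserved = 100 * mean(conserved),
    pct_conserved_of_cgs = if (any(in_cgs))
      100 * mean(conserved[in_cgs]) else NA_real_,
    in_cgs = in_cgs, conserved = conserved),
    class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<conservation_report> %d origins; %.1f%% overlap a CGS; ",
    "%.1f%% functionally conserved (%.1f%% of CGS-overlapping)\n"),
    x$n_origins_considered, x$pct_overlapping_cgs,
    x$pct_functionally_conserved, x$pct_conserved_of_cgs))
  invisible(x)
}

#' Random interval sets matching an origin set
#'
#' Generates `n_sets` random interval sets in mappable regions: on each
#' chromosome, exactly as many loci as there are origins, start positions
#' uniform, lengths drawn uniformly from the size distribution of origins
#' of the same chromosome.
#'
#' @param origins the observed [origin_set()].
#' @param genome a [genome_ref()].
#' @param n_sets number of random sets.
#' @param seed seed.
#' @return list of data.frames (`chrom`, `start`, `end`, `peak` at the
#'   interval midpoint).
#' @export
random_origin_sets <- function(origins, genome, n_sets = 10L, seed = 1L) {
  set.seed(derive_seed(seed, "random-sets"))
  lapply(seq_len(n_sets), function(s) {
    out <- do.call(rbind, lapply(unique(origins$chrom), function(ch) {
      o <- origins[origins$chrom == ch, , drop = FALSE]
      m <- genome$mappable[[ch]]
      if (is.null(m) || nrow(m) == 0L)
        stop_oriturn("chromosome with origins but no mappable space: ", ch)
      lens <- sample(o$end - o$start, nrow(o), replace = TRUE)
      st <- sample_positions_in_intervals(m, nrow(o))
      en <- pmin(st + lens, genome$chrom_lengths[[ch]])
      data.frame(chrom = ch, start = st, end = as.integer(en))
    }))
    out$peak <- out$start + (out$end - out$start) %/% 2L
    rownames(out) <- NULL
    out
  })
}

#' Randomization baseline and fold enrichment for conservation
#'
#' Recomputes the functional-conservation fractions on `n_sets` random
#' interval sets (per-chromosome counts and size distributions preserved)
#' and reports the observed/expected fold enrichment with a confidence
#' interval. The CI treats the observed fraction as one draw with sampling
#' spread estimated from the random sets, so under null placement it covers
#' 1 at roughly the nominal rate.
#'
#' @param origins observed A-side [origin_set()].
#' @param genome A-side [genome_ref()].
#' @param map a [homology_map()].
#' @param origins_b B-side [origin_set()].
#' @param n_sets number of random sets.
#' @param seed seed.
#' @param level CI level.
#' @return list of class `randomization_baseline`: observed and random
#'   percentages, `fold_cgs`, `fold_conserved`, and CIs.
#' @export
randomized_baseline <- function(origins, genome, map, origins_b,
                                n_sets = 10L, seed = 1L, level = 0.95) {
  obs <- functional_conservation(origins, origins_b, map)
  rnd <- random_origin_sets(origins, genome, n_sets, seed)
  rnd_rep <- lapply(rnd, function(r)
    functional_conservation(origin_set(r), origins_b, map))
  r_cgs <- vapply(rnd_rep, `[[`, numeric(1), "pct_overlapping_cgs")
  r_con <- vapply(rnd_rep, `[[`, numeric(1), "pct_functionally_conserved")
  fold_ci <- function(obs_pct, rand) {
    mu <- mean(rand)
    s <- sd(rand) * sqrt(1 + 1 / length(rand))
    tq <- qt(1 - (1 - level) / 2, df = length(rand) - 1)
    if (mu == 0) return(c(NA_real_, NA_real_))
    c((obs_pct - tq * s) / mu, (obs_pct + tq * s) / mu)
  }
  structure(list(
    observed = obs,
    random_pct_cgs = r_cgs, random_pct_conserved = r_con,
    fold_cgs = obs$pct_overlapping_cgs / mean(r_cgs),
    fold_conserved = if (mean(r_con) > 0)
      obs$pct_functionally_conserved / mean(r_con) else NA_real_,
    fold_cgs_ci = fold_ci(obs$pct_overlapping_cgs, r_cgs),
    fold_conserved_ci = fold_ci(obs$pct_functionally_conserved, r_con),
    n_sets = n_sets),
    class = "randomization_baseline")
}

#' TSS activity conservation
#'
#' Each oriented A-side TSS is extended on its 5' side by a length drawn
#' (seeded) from the origin size distribution, producing regions with the
#' same sizes as origins; the same CGS-overlap and functional-conservation
#' logic as for origins is then applied, "functional" meaning the mapped
#' interval overlaps a similarly extended B-side TSS region.
#'
#' @param tss_a,tss_b data.frames with `chrom`, `pos` (0-based TSS
#'   position) and `strand` (+/-).
#' @param origins origin set providing the size distribution.
#' @param map a [homology_map()].
#' @param genome A-side genome (for the randomization baseline; optional).
#' @param seed seed for the length draws.
#' @return list with `regions_a`, `regions_b` and the
#'   `conservation_report`.
#' @export
tss_activity_conservation <- function(tss_a, tss_b, origins, map,
                                      genome = NULL, seed = 1L) {
  extend_tss <- function(tss, tag) {
    if (is.null(tss$strand) || anyNA(tss$strand) ||
        !all(tss$strand %in% c("+", "-")))
      stop_oriturn("TSSs must be oriented (+/-)")
    set.seed(derive_seed(seed, tag))
    lens <- sample(origins$end - origins$start, nrow(tss), replace = TRUE)
    plus <- tss$strand == "+"
    # 5' side: upstream is smaller coordinates for +, larger for -
    start <- ifelse(plus, tss$pos - lens, tss$pos)
    end <- ifelse(plus, tss$pos + 1L, tss$pos + 1L + lens)
    data.frame(chrom = tss$chrom, start = pmax(0L, as.integer(start)),
               end = as.integer(end))
  }
  ra <- extend_tss(tss_a, "tss-a")
  rb <- extend_tss(tss_b, "tss-b")
  rep <- functional_conservation(
    origin_set(cbind(ra, peak = ra$start + (ra$end - ra$start) %/% 2L)),
    origin_set(cbind(rb, peak = rb$start + (rb$end - rb$start) %/% 2L)),
    map)
  list(regions_a = ra, regions_b = rb, report = rep)
}

#' Homologous SNS read accumulation profile
#'
#' Maps each A-side SNS peak through the homology map and profiles the
#' B-track read counts in a window centred on the mapped position, summed
#' per offset bin over all mappable peaks. Peaks outside conserved segments
#' are skipped (count reported as an attribute). The genome-wide
#' expectation per bin is `B depth per bp x bin x n_peaks`.
#'
#' @param peaks_a A-side anchors with `chrom`, `peak`.
#' @param map a [homology_map()].
#' @param track_b B-side [read_track()].
#' @param genome_b B-side [genome_ref()] (for the expectation line).
#' @param window full window width in bp (default 3 kb).
#' @param bin bin width in bp.
#' @return an [anchored_profile()] of mean read counts per bin per anchor,
#'   with attributes `expectation` and `n_skipped`.
#' @export
homologous_profile <- function(peaks_a, map, track_b, genome_b,
                               window = 3000L, bin = 50L) {
  half <- window %/% 2L
  mapped <- map_intervals(map, data.frame(chrom = peaks_a$chrom,
                                          start = peaks_a$peak,
                                          end = peaks_a$peak + 1L))
  ok <- !is.na(mapped$start)
  if (!any(ok)) stop_oriturn("no peak maps into the sister genome")
  edges <- seq(-half, half, by = bin)
  counts <- numeric(length(edges) - 1L)
  for (i in which(ok)) {
    p <- track_b$positions[[mapped$chrom[i]]]
    d <- p[p >= mapped$start[i] - half & p < mapped$start[i] + half] -
      mapped$start[i]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges),
                                  nbins = length(counts))
  }
  prof <- anchored_profile(edges[-length(edges)] + bin / 2,
                           counts / sum(ok), sum(ok), bin)
  attr(prof, "expectation") <-
    track_b$total_reads / mappable_length(genome_b) * bin
  attr(prof, "n_skipped") <- sum(!ok)
  prof
}

#' Average score profile around anchors
#'
#' Mean of a per-base score track (bedGraph intervals) per offset bin
#' across anchors; bases not covered by the track are excluded from the
#' means. Oriented anchors (strand "-") are flipped before averaging so
#' that negative offsets are 5' of the anchor.
#'
#' @param anchors data.frame with `chrom`, `pos` and optional `strand`.
#' @param score bedGraph data.frame (`chrom`, `start`, `end`, `value`).
#' @param halfwidth half-width in bp.
#' @param bin bin width in bp.
#' @return an [anchored_profile()].
#' @export
score_profile <- function(anchors, score, halfwidth = 700L, bin = 10L) {
  edges <- seq(-halfwidth, halfwidth, by = bin)
  nb <- length(edges) - 1L
  sums <- cnts <- numeric(nb)
  for (ch in unique(anchors$chrom)) {
    sc <- score[score$chrom == ch, , drop = FALSE]
    if (nrow(sc) == 0L) next
    sc <- sc[order(sc$start), , drop = FALSE]
    an <- anchors[anchors$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(an))) {
      pos <- seq.int(an$pos[i] - halfwidth, an$pos[i] + halfwidth)
      j <- findInterval(pos, sc$start)
      val <- rep(NA_real_, length(pos))
      okj <- j >= 1L
      okj[okj] <- pos[okj] < sc$end[j[okj]]
      val[okj] <- sc$value[j[okj]]
      off <- pos - an$pos[i]
      if (!is.null(an$strand) && identical(an$strand[i], "-"))
        off <- -off
      b <- findInterval(off, edges)
      keep <- !is.na(val)
      if (any(keep)) {
        bk <- b[keep]
        vk <- val[keep]
        sums <- sums + vapply(seq_len(nb),
                              function(k) sum(vk[bk == k]), numeric(1))
        cnts <- cnts + tabulate(bk, nbins = nb)
      }
    }
  }
  if (all(cnts == 0)) stop_oriturn("score track covers no anchor positions")
  anchored_profile(edges[-length(edges)] + bin / 2,
                   ifelse(cnts > 0, sums / cnts, NA_real_),
                   nrow(anchors), bin)
}

#' Categorize origins by CGI and TSS association
#'
#' CGI[+] means >= 1 bp overlap with a CpG-island interval; TSS[+] means a
#' TSS point lies within `tss_distance` bp of the origin interval (distance
#' 0 when overlapping; the boundary is inclusive). The four categories
#' partition the set.
#'
#' @param origins an [origin_set()].
#' @param cgi data.frame of CGI intervals (`chrom`, `start`, `end`).
#' @param tss data.frame of TSS points (`chrom`, `pos`).
#' @param tss_distance distance threshold in bp.
#' @return factor with levels `CGI[-]TSS[-]`, `CGI[+]TSS[-]`,
#'   `CGI[-]TSS[+]`, `CGI[+]TSS[+]`.
#' @export
categorize_origins <- function(origins, cgi, tss, tss_distance = 750L) {
  has_cgi <- overlaps_any(as.data.frame(origins), cgi)
  has_tss <- logical(nrow(origins))
  for (ch in unique(origins$chrom)) {
    tp <- sort(tss$pos[tss$chrom == ch])
    if (length(tp) == 0L) next
    i <- which(origins$chrom == ch)
    for (k in i) {
      # interval-to-point distance, 0 when the TSS is inside the origin
      d <- pmax(origins$start[k] - tp, tp - (origins$end[k] - 1L), 0L)
      has_tss[k] <- any(d <= tss_distance)
    }
  }
  factor(paste0("CGI[", ifelse(has_cgi, "+", "-"), "]TSS[",
                ifelse(has_tss, "+", "-"), "]"),
         levels = c("CGI[-]TSS[-]", "CGI[+]TSS[-]", "CGI[-]TSS[+]",
                    "CGI[+]TSS[+]"))
}
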