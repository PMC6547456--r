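# Origin detection: scanning-window read enrichment with multiple-testing
# control, interval merging, kernel peak localization, RPKM intensities and
# depth equalization.

#' Caller configuration
#'
#' @param window_size scanning window size in bp.
#' @param alpha controlled multiple error rate (default 1%).
#' @param method multiple-testing control: `"fdr"` (Benjamini-Hochberg) or
#'   `"bonferroni"` (family-wise).
#' @param merge_gap maximum number of non-significant windows bridged when
#'   merging significant runs into one origin.
#' @param min_windows minimum run length (windows) for a call.
#' @param peak_bandwidth Gaussian kernel bandwidth (bp) for SNS-peak
#'   localization; default `sqrt(500)` (~22.4 bp).
#' @param min_mappable_fraction windows with a smaller mappable fraction are
#'   excluded from testing.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(window_size = 500L, alpha = 0.01,
                          method = c("fdr", "bonferroni"),
                          merge_gap = 1L, min_windows = 1L,
                          peak_bandwidth = sqrt(500),
                          min_mappable_fraction = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop_oriturn("alpha must be in (0,1)")
  structure(list(window_size = as.integer(window_size), alpha = alpha,
                 method = match.arg(method), merge_gap = as.integer(merge_gap),
                 min_windows = as.integer(min_windows),
                 peak_bandwidth = peak_bandwidth,
                 min_mappable_fraction = min_mappable_fraction),
            class = "caller_config")
}

#' Bin read positions into fixed windows
#'
#' Window `i` covers `[i*w, (i+1)*w)`; the last window may be partial.
#' Windows with mappable fraction below `min_mappable_fraction` are flagged
#' excluded but their counts are retained (total count conservation).
#'
#' @param track a [read_track()].
#' @param genome a [genome_ref()].
#' @param window_size window size in bp.
#' @param min_mappable_fraction exclusion threshold.
#' @return object of class `window_counts`: per-chromosome `counts`,
#'   `mappable_fraction` and `included` flags, plus `window_size`.
#' @export
bin_reads <- function(track, genome, window_size = 500L,
                      min_mappable_fraction = 0.5) {
  if (window_size <= 0L) stop_oriturn("window_size must be positive")
  w <- as.integer(window_size)
  chroms <- genome$chrom_names
  counts <- mapfrac <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    L <- genome$chrom_lengths[[ch]]
    nb <- as.integer(ceiling(L / w))
    p <- track$positions[[ch]] %||% integer(0)
    counts[[ch]] <- tabulate(p %/% w + 1L, nbins = nb)
    m <- genome$mappable[[ch]]
    if (nrow(m) == 0L) {
      mp <- numeric(nb)
    } else {
      cov <- IRanges::coverage(df_to_iranges(m), width = L)
      csum <- c(0, cumsum(as.numeric(S4Vectors::runValue(cov)) *
                            S4Vectors::runLength(cov)))
      bnd <- pmin(seq(0L, nb) * w, L)
      # cumulative mappable bp at each window boundary
      cum_at <- function(x) {
        rl <- S4Vectors::runLength(cov)
        ends <- cumsum(rl)
        i <- findInterval(x, c(0, ends), rightmost.closed = TRUE)
        i[i > length(rl)] <- length(rl)
        base <- csum[i]
        prev_end <- c(0, ends)[i]
        base + (x - prev_end) * as.numeric(S4Vectors::runValue(cov))[i]
      }
      cm <- cum_at(bnd)
      width_i <- diff(bnd)
      mp <- diff(cm) / pmax(width_i, 1)
    }
    mapfrac[[ch]] <- mp
  }
  structure(list(window_size = w, chroms = chroms, counts = counts,
                 mappable_fraction = mapfrac,
                 included = lapply(mapfrac,
                                   function(x) x >= min_mappable_fraction)),
            class = "window_counts")
}

#' Fit the background read-count model
#'
#' Method-of-moments negative-binomial fit on included windows after
#' trimming the top 1% of counts, so origin signal does not inflate the
#' background; falls back to Poisson when the trimmed variance does not
#' exceed the mean. The trimmed mean is then corrected for truncation bias
#' under the fitted model (fixed-point on the conditional mean below the
#' trim quantile), so null p-values stay calibrated. The mean is stored per
#' mappable bp, so partially mappable windows get proportionally smaller
#' expectations.
#'
#' @param counts a [bin_reads()] result.
#' @param trim fraction of highest-count windows dropped before fitting.
#' @return list of class `background_model` with `family` ("poisson" or
#'   "nbinom"), `mean_per_bp`, `mean_per_window` and `dispersion` (phi in
#'   Var = mu + phi mu^2).
#' @export
fit_background <- function(counts, trim = 0.01) {
  inc <- unlist(counts$included, use.names = FALSE)
  x <- unlist(counts$counts, use.names = FALSE)[inc]
  mf <- unlist(counts$mappable_fraction, use.names = FALSE)[inc]
  if (length(x) == 0L) stop_oriturn("all windows excluded")
  if (length(x) < 100L)
    warning("fewer than 100 included windows; background fit is unstable")
  keep <- x <= quantile(x, 1 - trim, type = 1)
  xt <- x[keep]
  m <- mean(xt)
  v <- var(xt)
  if (is.na(v)) v <- 0
  if (v > m) {
    phi <- (v - m) / m^2
    family <- "nbinom"
  } else {
    phi <- 0
    family <- "poisson"
  }
  # correct the truncation bias of the trimmed mean: solve for mu such that
  # the model's conditional mean below its (1 - trim) quantile matches the
  # observed trimmed mean (fixed point, a few iterations suffice)
  mu <- m
  if (m > 0 && v > 0) {
    for (it in 1:6) {
      q <- if (family == "poisson") stats::qpois(1 - trim, mu)
           else stats::qnbinom(1 - trim, size = 1 / phi, mu = mu)
      k <- 0:q
      dens <- if (family == "poisson") stats::dpois(k, mu)
              else stats::dnbinom(k, size = 1 / phi, mu = mu)
      cond <- sum(k * dens) / sum(dens)
      if (cond <= 0) break
      mu <- mu * m / cond
    }
  }
  structure(list(family = family,
                 mean_per_bp = mu / (counts$window_size * mean(mf[keep])),
                 mean_per_window = mu, dispersion = phi),
            class = "background_model")
}

# Upper-tail p-value P(X >= c) for each window under the background model.
window_pvalues <- function(cnt, mu, bg) {
  if (bg$family == "poisson" || bg$dispersion <= 0) {
    ppois(cnt - 1, mu, lower.tail = FALSE)
  } else {
    pnbinom(cnt - 1, size = 1 / bg$dispersion, mu = mu, lower.tail = FALSE)
  }
}

#' Call origins from window counts
#'
#' Per-window upper-tail p-values under the background model are adjusted
#' genome-wide across all included windows (BH by default); windows at
#' adjusted p <= alpha are significant, and runs of significant windows
#' separated by at most `merge_gap` windows merge into one origin whose
#' boundaries are the outer window edges. When `track` is given, each origin
#' also gets its kernel-smoothed SNS peak and RPKM intensity.
#'
#' @param counts a [bin_reads()] result.
#' @param bg a [fit_background()] model fitted on the same counts.
#' @param cfg a [caller_config()].
#' @param track optional [read_track()] for peak/intensity annotation.
#' @param genome optional [genome_ref()] (needed only to clip final windows).
#' @return an [origin_set()]; attribute `n_significant_windows` records the
#'   number of significant windows and `n_tested_windows` the number tested.
#' @export
call_origins <- function(counts, bg, cfg = caller_config(), track = NULL,
                         genome = NULL) {
  w <- counts$window_size
  all_p <- all_mu <- list()
  for (ch in counts$chroms) {
    inc <- counts$included[[ch]]
    mu <- bg$mean_per_bp * counts$mappable_fraction[[ch]] * w
    p <- rep(NA_real_, length(inc))
    p[inc] <- window_pvalues(counts$counts[[ch]][inc], mu[inc], bg)
    all_p[[ch]] <- p
  }
  pvec <- unlist(all_p, use.names = FALSE)
  tested <- !is.na(pvec)
  padj <- rep(NA_real_, length(pvec))
  padj[tested] <- p.adjust(pvec[tested],
                           method = if (cfg$method == "fdr") "BH"
                                    else "bonferroni")
  sig <- !is.na(padj) & padj <= cfg$alpha
  # split back per chromosome
  offs <- c(0L, cumsum(lengths(all_p)))
  out <- NULL
  for (k in seq_along(counts$chroms)) {
    ch <- counts$chroms[k]
    s <- sig[(offs[k] + 1L):offs[k + 1L]]
    if (!any(s)) next
    idx <- which(s)
    grp <- cumsum(c(1L, diff(idx) > cfg$merge_gap + 1L))
    for (g in unique(grp)) {
      win <- idx[grp == g]
      if (length(win) < cfg$min_windows) next
      out <- rbind(out, data.frame(chrom = ch,
                                   start = (win[1] - 1L) * w,
                                   end = win[length(win)] * w))
    }
  }
  if (is.null(out)) {
    res <- origin_set(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)))
  } else {
    if (!is.null(genome))
      out$end <- pmin(out$end, as.integer(genome$chrom_lengths[out$chrom]))
    res <- origin_set(out)
    if (!is.null(track)) {
      res$peak <- locate_peaks(res, track, cfg)
      res$rpkm <- vapply(seq_len(nrow(res)), function(i)
        compute_intensity(res[i, ], track), numeric(1))
    }
  }
  attr(res, "n_significant_windows") <- sum(sig)
  attr(res, "n_tested_windows") <- sum(tested)
  res
}

#' Locate the SNS peak of one origin
#'
#' The peak is the bp position inside `[start, end)` maximizing the
#' Gaussian-kernel-smoothed density of read 5' positions (bandwidth
#' `peak_bandwidth`, default sqrt(500) bp), evaluated at integer bp on a grid
#' covering the origin plus 3 bandwidths. Ties break to the leftmost
#' position.
#'
#' @param origin one-row [origin_set()] (or list with `chrom`, `start`,
#'   `end`).
#' @param track a [read_track()].
#' @param cfg a [caller_config()].
#' @return integer peak position.
#' @export
locate_sns_peak <- function(origin, track, cfg = caller_config()) {
  bw <- cfg$peak_bandwidth
  pad <- ceiling(3 * bw)
  p <- track$positions[[origin$chrom]]
  reads <- p[p >= origin$start - pad & p < origin$end + pad]
  if (length(reads) == 0L)
    stop_oriturn("degenerate call: no reads in origin ",
                 origin$chrom, ":", origin$start, "-", origin$end)
  grid <- seq.int(origin$start, origin$end - 1L)
  dens <- colSums(dnorm(outer(reads, grid, "-") / bw))
  grid[which.max(dens)]
}

#' Locate SNS peaks for a whole origin set
#' @param origins an [origin_set()].
#' @param track a [read_track()].
#' @param cfg a [caller_config()].
#' @return integer vector of peak positions.
#' @export
locate_peaks <- function(origins, track, cfg = caller_config()) {
  vapply(seq_len(nrow(origins)), function(i)
    locate_sns_peak(origins[i, ], track, cfg), integer(1))
}

#' Origin intensity in RPKM
#'
#' Reads per kb of origin length per million mapped reads.
#'
#' @param origin one-row origin (with `chrom`, `start`, `end`).
#' @param track a [read_track()].
#' @return numeric RPKM.
#' @export
compute_intensity <- function(origin, track) {
  len_kb <- (origin$end - origin$start) / 1000
  if (len_kb <= 0) stop_oriturn("zero-length origin")
  if (track$total_reads <= 0) stop_oriturn("track has no reads")
  p <- track$positions[[origin$chrom]]
  n <- sum(p >= origin$start & p < origin$end)
  n / (len_kb * track$total_reads / 1e6)
}

#' Subsample a read track to a target depth
#'
#' Uniform sampling without replacement down to `target_reads_per_kb` over
#' the mappable genome; used to equalize sequencing depth between datasets
#' before cross-species comparisons.
#'
#' @param track a [read_track()].
#' @param genome a [genome_ref()].
#' @param target_reads_per_kb target depth.
#' @param seed seed (sampling is deterministic given the seed).
#' @return a [read_track()].
#' @export
subsample_to_depth <- function(track, genome, target_reads_per_kb, seed = 1L) {
  n_target <- round(target_reads_per_kb * mappable_length(genome) / 1000)
  if (n_target > track$total_reads)
    stop_oriturn("target depth above current depth")
  if (n_target == track$total_reads) return(track)
  set.seed(derive_seed(seed, "subsample"))
  keep <- sort(sample.int(track$total_reads, n_target))
  offs <- c(0L, cumsum(lengths(track$positions)))
  pos <- stats::setNames(vector("list", length(track$positions)),
                         names(track$positions))
  for (k in seq_along(pos)) {
    kk <- keep[keep > offs[k] & keep <= offs[k + 1L]] - offs[k]
    pos[[k]] <- track$positions[[k]][kk]
  }
  read_track(pos)
}

#' Constitutive activity by intensity class
#'
#' Origins of a reference dataset are grouped into `n_classes` equal-count
#' intensity (RPKM) classes; for each class the fraction of origins also
#' active (>= 1 bp overlap) in every other dataset is reported.
#'
#' @param reference an [origin_set()] with `rpkm`.
#' @param others list of [origin_set()]s.
#' @param n_classes number of quantile classes.
#' @return data.frame with `class`, `rpkm_min`, `rpkm_max`, `n`,
#'   `fraction_active_in_all`.
#' @export
constitutive_activity <- function(reference, others, n_classes = 20L) {
  if (length(others) < 1L) stop_oriturn("need at least one other origin set")
  n <- nrow(reference)
  if (n < n_classes) stop_oriturn("fewer origins than classes")
  cls <- ceiling(rank(reference$rpkm, ties.method = "first") /
                   n * n_classes)
  active <- rep(TRUE, n)
  for (o in others) active <- active & overlaps_any(reference, o)
  out <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    i <- which(cls == k)
    data.frame(class = k,
               rpkm_min = min(reference$rpkm[i]),
               rpkm_max = max(reference$rpkm[i]),
               n = length(i),
               fraction_active_in_all = mean(active[i]))
  }))
  out
}
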