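# Background compositional clustering: 5-mer counts of random 40-bp
# segments, non-negative matrix factorization for dimension reduction,
# k-means clustering, maximum-a-posteriori assignment of origin cores, and
# cluster-wise motif fold enrichment.

#' Sample random genomic segments
#'
#' Segment starts are uniform over mappable bp; segments never cross a
#' chromosome end (draws are redrawn until the whole segment fits in the
#' chromosome).
#'
#' @param genome a [genome_ref()].
#' @param n number of segments.
#' @param length segment length in bp.
#' @param seed seed.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
sample_random_segments <- function(genome, n, length = 40L, seed = 1L) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  if (mappable_length(genome) < n * length)
    stop_oriturn("mappable genome too small for ", n, " segments")
  set.seed(derive_seed(seed, "segments"))
  # uniform over valid start positions: mappable intervals shrunk so the
  # whole segment fits inside one interval (hence inside the chromosome)
  univ <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    m <- genome$mappable[[ch]]
    if (nrow(m) == 0L) return(NULL)
    keep <- m$end - m$start >= length
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = m$start[keep],
               end = m$end[keep] - length + 1L)
  }))
  if (is.null(univ)) stop_oriturn("no mappable interval can hold a segment")
  cw <- cumsum(as.numeric(univ$end - univ$start))
  u <- runif(n, 0, cw[length(cw)])
  iv <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
  iv[iv > nrow(univ)] <- nrow(univ)
  st <- as.integer(univ$start[iv] + floor(u - c(0, cw)[iv]))
  out <- data.frame(chrom = univ$chrom[iv], start = st,
                    end = st + as.integer(length))
  rownames(out) <- NULL
  out
}

#' K-mer count matrix of genomic segments
#'
#' Overlapping k-mers on the given strand only; windows containing N are
#' skipped (they count toward no column), so row sums equal
#' `segment_length - k + 1` minus N-containing windows.
#'
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @param genome a [genome_ref()].
#' @param k k-mer size.
#' @return integer matrix, rows = segments, columns = the 4^k k-mers.
#' @export
kmer_counts <- function(segments, genome, k = 5L) {
  if (nrow(segments) > 0 && any(segments$end - segments$start < k))
    stop_oriturn("segment shorter than k")
  seqs <- vapply(seq_len(nrow(segments)), function(i)
    get_seq(genome, segments$chrom[i], segments$start[i], segments$end[i]),
    character(1))
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = k)
}

# Multiplicative-update NMF (Frobenius loss): X ~ W %*% H with W, H >= 0.
# The update rule makes the reconstruction error non-increasing at every
# iteration; the error trace is returned for verification.
nmf_factorize <- function(X, rank, n_iter = 200L, seed = 1L, eps = 1e-10) {
  set.seed(derive_seed(seed, "nmf"))
  n <- nrow(X); m <- ncol(X)
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  err <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err[it] <- sqrt(sum((X - W %*% H)^2))
  }
  list(W = W, H = H, error_trace = err)
}

# Project rows of X2 onto a fixed basis H (non-negative least squares via
# multiplicative updates on W only); deterministic flat initialization.
nmf_project <- function(X2, H, n_iter = 200L, eps = 1e-10) {
  W <- matrix(mean(X2) / max(mean(H), eps), nrow(X2), nrow(H))
  HHt <- tcrossprod(H)
  XHt <- X2 %*% t(H)
  for (it in seq_len(n_iter)) {
    W <- W * XHt / (W %*% HHt + eps)
  }
  W
}

#' Fit background compositional clusters
#'
#' Reduces the k-mer count matrix to `n_axes` non-negative components
#' (multiplicative-update NMF, seeded, reconstruction error non-increasing
#' per iteration), then k-means with `n_clusters` centers on the component
#' loadings (`nstart >= 10`, best inertia kept). Per-cluster Gaussian
#' parameters (centroid, pooled spherical variance) and empirical priors are
#' stored for maximum-a-posteriori assignment of new segments.
#'
#' @param matrix k-mer count matrix from [kmer_counts()].
#' @param n_axes number of NMF components.
#' @param n_clusters number of k-means clusters.
#' @param seed seed (NMF init, k-means starts).
#' @param n_iter NMF iterations.
#' @return list of class `background_cluster_model`: `basis` (H), `loadings`
#'   (W), `assignment`, `centroids`, `priors`, `sigma2`, `cluster_sizes`,
#'   `error_trace`.
#' @export
fit_background_clusters <- function(matrix, n_axes = 6L, n_clusters = 6L,
                                    seed = 1L, n_iter = 200L) {
  zero <- rowSums(matrix) == 0
  if (any(zero))
    stop_oriturn("all-zero k-mer rows (segments of Ns?): ",
                 paste(head(which(zero), 10), collapse = ", "))
  if (nrow(matrix) < n_clusters * 10L)
    stop_oriturn("need at least ", n_clusters * 10L, " segments")
  fac <- nmf_factorize(matrix, n_axes, n_iter = n_iter, seed = seed)
  set.seed(derive_seed(seed, "kmeans"))
  km <- kmeans(fac$W, centers = n_clusters, nstart = 10L, iter.max = 100L)
  sizes <- as.integer(table(factor(km$cluster, levels = seq_len(n_clusters))))
  # pooled spherical variance per cluster in the reduced space
  sigma2 <- vapply(seq_len(n_clusters), function(c) {
    i <- km$cluster == c
    if (sum(i) < 2L) return(NA_real_)
    mean(rowSums((fac$W[i, , drop = FALSE] -
                    matrix(km$centers[c, ], sum(i), n_axes,
                           byrow = TRUE))^2)) / n_axes
  }, numeric(1))
  pooled <- mean(sigma2, na.rm = TRUE)
  sigma2[is.na(sigma2) | sigma2 <= 0] <- pooled
  structure(list(basis = fac$H, loadings = fac$W,
                 assignment = km$cluster, centroids = km$centers,
                 priors = sizes / sum(sizes), sigma2 = sigma2,
                 cluster_sizes = sizes, n_axes = n_axes,
                 n_clusters = n_clusters, error_trace = fac$error_trace),
            class = "background_cluster_model")
}

#' Assign segments to background clusters (MAP rule)
#'
#' Projects the k-mer counts into the model's reduced space (non-negative
#' projection against the fixed basis) and assigns each segment to the
#' cluster maximizing the Gaussian-per-cluster posterior with empirical
#' priors. Ties break to the larger prior, then the lower cluster index.
#'
#' @param model a [fit_background_clusters()] model.
#' @param matrix k-mer count matrix of the segments to assign (same k).
#' @return integer vector of cluster labels.
#' @export
assign_map <- function(model, matrix) {
  W2 <- nmf_project(matrix, model$basis)
  k <- model$n_clusters
  logpost <- vapply(seq_len(k), function(c) {
    d2 <- rowSums((W2 - matrix(model$centroids[c, ], nrow(W2),
                               model$n_axes, byrow = TRUE))^2)
    log(model$priors[c] + 1e-12) -
      model$n_axes / 2 * log(2 * pi * model$sigma2[c]) -
      d2 / (2 * model$sigma2[c])
  }, numeric(nrow(W2)))
  logpost <- matrix(logpost, nrow = nrow(W2))
  apply(logpost, 1L, function(lp) {
    best <- which(lp == max(lp))
    if (length(best) > 1L) {
      pr <- model$priors[best]
      best <- best[pr == max(pr)]
    }
    best[1L]
  })
}

#' Cluster-wise motif fold enrichment
#'
#' For each background cluster, the per-bp occurrence rate of each literal
#' motif (counted on both strands, overlapping matches included) in origin
#' cores is divided by the rate in random background segments of the same
#' cluster; a Fisher count test p-value is attached. Clusters with fewer
#' than 20 random segments are flagged unstable; an infinite fold (motif
#' absent from the background) is flagged capped.
#'
#' @param core_seqs character vector of core sequences.
#' @param core_clusters their cluster labels.
#' @param random_seqs character vector of background segment sequences.
#' @param random_clusters their cluster labels.
#' @param motifs character vector of literal motifs (<= 6 bp).
#' @return data.frame: `cluster`, `motif`, `core_rate`, `random_rate`,
#'   `fold`, `p_value`, `capped`, `unstable`.
#' @export
motif_fold_enrichment <- function(core_seqs, core_clusters, random_seqs,
                                  random_clusters,
                                  motifs = c("CG", "CCC", "GAG", "ACAC")) {
  if (any(nchar(motifs) > min(nchar(c(core_seqs, random_seqs)))))
    stop_oriturn("motif longer than the shortest segment")
  both_strand_count <- function(seqs, motif) {
    rc <- reverse_complement(motif)
    n <- sum(count_motif(seqs, motif))
    if (rc != motif) n <- n + sum(count_motif(seqs, rc))
    n
  }
  clusters <- sort(unique(c(core_clusters, random_clusters)))
  out <- NULL
  for (cl in clusters) {
    cs <- core_seqs[core_clusters == cl]
    rs <- random_seqs[random_clusters == cl]
    core_bp <- sum(nchar(cs))
    rand_bp <- sum(nchar(rs))
    for (mo in motifs) {
      cc <- if (length(cs)) both_strand_count(cs, mo) else 0L
      rc <- if (length(rs)) both_strand_count(rs, mo) else 0L
      core_rate <- if (core_bp > 0) cc / core_bp else NA_real_
      rand_rate <- if (rand_bp > 0) rc / rand_bp else NA_real_
      fold <- if (!is.na(rand_rate) && rand_rate > 0)
        core_rate / rand_rate else Inf
      capped <- is.infinite(fold) && !is.na(core_rate) && core_rate > 0
      pv <- if (core_bp > 0 && rand_bp > 0)
        fisher.test(matrix(c(cc, max(core_bp - cc, 0),
                             rc, max(rand_bp - rc, 0)), 2))$p.value
      else NA_real_
      out <- rbind(out, data.frame(
        cluster = cl, motif = mo, core_rate = core_rate,
        random_rate = rand_rate, fold = fold, p_value = pv,
        capped = capped, unstable = length(rs) < 20L))
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract core-region sequences around SNS peaks
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param genome a [genome_ref()].
#' @param width core width in bp (window `peak - width/2` to
#'   `peak + width/2`).
#' @return data.frame with `chrom`, `start`, `end` clipped to chromosomes.
#' @export
core_segments <- function(peaks, genome, width = 40L) {
  half <- width %/% 2L
  st <- pmax(0L, as.integer(peaks$peak) - half)
  en <- pmin(as.numeric(genome$chrom_lengths[peaks$chrom]),
             st + width)
  data.frame(chrom = peaks$chrom, start = st, end = as.integer(en))
}
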