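# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fix <- new.env(parent = emptyenv())

with_cache <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

empty_origins <- function() {
  origin_set(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
}

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
random_dna_test <- random_seq

# Brute-force G-quadruplex oracle: greedy leftmost scan; at each position,
# spacer lengths (n1, n2, n3) are tried in descending lexicographic order
# (n3 fastest), mirroring greedy backtracking; first match wins and
# scanning resumes after its end. Direct character comparisons only.
oracle_g4_plus <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  isg <- ch == "G"
  acgt <- ch %in% c("A", "C", "G", "T")
  hits <- list()
  i <- 1L
  while (i <= n - 11L) {
    found <- NULL
    if (isg[i] && isg[i + 1L] && isg[i + 2L]) {
      for (n1 in 7:1) {
        for (n2 in 7:1) {
          for (n3 in 7:1) {
            len <- 12L + n1 + n2 + n3
            if (i + len - 1L > n) next
            p <- i + 3L
            if (!all(acgt[p:(p + n1 - 1L)])) next
            p <- p + n1
            if (!(isg[p] && isg[p + 1L] && isg[p + 2L])) next
            p <- p + 3L
            if (!all(acgt[p:(p + n2 - 1L)])) next
            p <- p + n2
            if (!(isg[p] && isg[p + 1L] && isg[p + 2L])) next
            p <- p + 3L
            if (!all(acgt[p:(p + n3 - 1L)])) next
            p <- p + n3
            if (!(isg[p] && isg[p + 1L] && isg[p + 2L])) next
            found <- len
            break
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
    }
    if (!is.null(found)) {
      hits[[length(hits) + 1L]] <- c(i - 1L, found)
      i <- i + found
    } else {
      i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), length = integer(0)))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], length = m[, 2])
}

# Both-strand oracle in genome coordinates, same hit summary as scan_g4().
oracle_g4 <- function(seq) {
  plus <- oracle_g4_plus(seq)
  plus$strand <- rep("+", nrow(plus))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  minus <- oracle_g4_plus(rc)
  L <- nchar(seq)
  minus <- data.frame(start = L - (minus$start + minus$length),
                      length = minus$length,
                      strand = rep("-", nrow(minus)))
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Overlapping literal motif counter independent of the package internals.
oracle_motif_count <- function(seqs, motif) {
  sum(vapply(seqs, function(s) {
    n <- 0L
    k <- nchar(motif)
    for (i in seq_len(max(nchar(s) - k + 1L, 0L)))
      if (substr(s, i, i + k - 1L) == motif) n <- n + 1L
    n
  }, integer(1)))
}

# Small called-origin fixture reused by calling and conservation tests.
smoke_sim <- function() {
  with_cache("smoke_sim", {
    cfg <- sim_config(genome_length = 4e6, seed = 3)
    g <- make_genome(cfg)
    truth <- plant_origins(g, cfg)
    track <- simulate_reads(g, truth, cfg)
    wc <- bin_reads(track, g, 500L)
    bg <- fit_background(wc)
    called <- call_origins(wc, bg, caller_config(), track = track,
                           genome = g)
    list(cfg = cfg, genome = g, truth = truth, track = track, wc = wc,
         bg = bg, called = called)
  })
}
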