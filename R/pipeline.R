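# End-to-end pipeline driver: simulate -> call -> features -> selection ->
# composition -> conserve, as a configured, seeded, resumable run writing a
# single report directory with a checksum manifest.

#' Pipeline configuration
#'
#' Either pass the pieces directly or point `yaml` at a YAML file whose
#' top-level keys mirror the arguments (`sim`, `caller`, `classing` hold the
#' corresponding constructor arguments).
#'
#' @param outdir report directory (created if missing).
#' @param sim a [sim_config()].
#' @param caller a [caller_config()].
#' @param classing a [variant_classing()].
#' @param n_random_sets random sets for the conservation baseline.
#' @param n_axes,n_clusters background-clustering dimensions.
#' @param n_background_segments random 40-bp segments for clustering; by
#'   default the number of called origins (matched counts).
#' @param seed global seed; every stage derives its own stream.
#' @param yaml optional YAML file path overriding the other arguments.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(),
                            caller = caller_config(),
                            classing = variant_classing(),
                            n_random_sets = 10L, n_axes = 6L,
                            n_clusters = 6L,
                            n_background_segments = NULL,
                            seed = 1L, yaml = NULL) {
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    sim <- do.call(sim_config, y$sim %||% list())
    caller <- do.call(caller_config, y$caller %||% list())
    classing <- do.call(variant_classing, y$classing %||% list())
    n_random_sets <- y$n_random_sets %||% n_random_sets
    n_axes <- y$n_axes %||% n_axes
    n_clusters <- y$n_clusters %||% n_clusters
    n_background_segments <- y$n_background_segments
    seed <- y$seed %||% seed
    outdir <- y$outdir %||% outdir
  }
  structure(list(outdir = outdir, sim = sim, caller = caller,
                 classing = classing, n_random_sets = n_random_sets,
                 n_axes = n_axes, n_clusters = n_clusters,
                 n_background_segments = n_background_segments,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_profile_tsv <- function(prof, path) {
  write.table(as.data.frame(prof), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

read_manifest <- function(path) {
  if (!file.exists(path))
    return(data.frame(file = character(0), md5 = character(0)))
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Stages: `simulate` (synthetic genomes, reads, variants, homology),
#' `call` (depth equalization and origin calling in both species),
#' `features` (nucleotide/skew/G4 profiles), `selection` (DAF-stratified
#' density profiles and core depletion), `composition` (background
#' clustering and motif folds) and `conserve` (concentration curve,
#' conservation report with randomization baseline). Every stage derives
#' its seed from the global seed, so two runs with the same config are
#' byte-identical. A stage whose output files all exist with checksums
#' matching the manifest is skipped; corrupted or missing outputs trigger
#' recomputation. On failure, partial outputs are kept with a `.partial`
#' suffix.
#'
#' @param config a [pipeline_config()].
#' @param force recompute all stages even when outputs are current.
#' @param quiet suppress progress messages.
#' @return `config$outdir`, invisibly; the directory contains a
#'   `manifest.tsv` listing every artifact with its md5 checksum.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.tsv")
  manifest <- read_manifest(manifest_path)
  say <- function(...) if (!quiet) message(...)
  env <- new.env(parent = emptyenv())

  stage_current <- function(files) {
    if (force) return(FALSE)
    paths <- file.path(out, files)
    if (!all(file.exists(paths))) return(FALSE)
    rec <- manifest$md5[match(files, manifest$file)]
    if (anyNA(rec)) return(FALSE)
    all(unname(tools::md5sum(paths)) == rec)
  }
  record <- function(files) {
    md5 <- unname(tools::md5sum(file.path(out, files)))
    manifest <<- rbind(manifest[!(manifest$file %in% files), , drop = FALSE],
                       data.frame(file = files, md5 = md5))
    manifest <<- manifest[order(manifest$file), , drop = FALSE]
    write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  run_stage <- function(name, files, produce, load) {
    if (stage_current(files)) {
      say("stage ", name, ": up to date, skipping")
      load()
      return(invisible(NULL))
    }
    say("stage ", name, ": running")
    tmp_suffix <- ".partial"
    ok <- FALSE
    tryCatch({
      produce()
      ok <- TRUE
    }, finally = {
      if (!ok) {
        for (f in files) {
          p <- file.path(out, f)
          if (file.exists(p)) file.rename(p, paste0(p, tmp_suffix))
        }
      }
    })
    record(files)
  }
  cfg <- config$sim
  seed <- config$seed

  sim_files <- c("genome_a.fa", "mask_a.bed", "reads_a.bed", "truth_a.tsv",
                 "variants_a.tsv", "cgs_map.tsv", "genome_b.fa",
                 "reads_b.bed", "truth_b.tsv")
  run_stage("simulate", sim_files, produce = function() {
    genome0 <- make_genome(cfg, seed)
    truth_a <- plant_origins(genome0, cfg, seed)
    genome_a <- simulate_skew(genome0, truth_a, cfg, seed)
    track_a <- simulate_reads(genome_a, truth_a, cfg, seed)
    variants <- simulate_variants(genome_a, truth_a, cfg, seed)
    hom <- simulate_homology(genome_a, truth_a, cfg, seed)
    write_fasta(genome_a, file.path(out, "genome_a.fa"),
                file.path(out, "mask_a.bed"))
    write_reads_bed(track_a, file.path(out, "reads_a.bed"))
    write_origins(truth_a, file.path(out, "truth_a.tsv"))
    write_variant_table(variants, file.path(out, "variants_a.tsv"))
    write_homology_map(hom$map, file.path(out, "cgs_map.tsv"))
    write_fasta(hom$genome_b, file.path(out, "genome_b.fa"))
    write_reads_bed(hom$track_b, file.path(out, "reads_b.bed"))
    write_origins(hom$origins_b, file.path(out, "truth_b.tsv"))
    env$genome_a <- genome_a; env$track_a <- track_a
    env$variants <- variants; env$map <- hom$map
    env$genome_b <- hom$genome_b; env$track_b <- hom$track_b
  }, load = function() {
    env$genome_a <- read_fasta(file.path(out, "genome_a.fa"),
                               file.path(out, "mask_a.bed"))
    env$track_a <- read_reads_bed(file.path(out, "reads_a.bed"),
                                  env$genome_a)
    env$variants <- read_variant_table(file.path(out, "variants_a.tsv"))
    env$map <- read_homology_map(file.path(out, "cgs_map.tsv"))
    env$genome_b <- read_fasta(file.path(out, "genome_b.fa"))
    env$track_b <- read_reads_bed(file.path(out, "reads_b.bed"),
                                  env$genome_b)
  })

  call_files <- c("origins_a.tsv", "origins_b.tsv")
  run_stage("call", call_files, produce = function() {
    # depth equalization before cross-species calling
    depth <- function(tr, g) tr$total_reads / (mappable_length(g) / 1000)
    target <- min(depth(env$track_a, env$genome_a),
                  depth(env$track_b, env$genome_b))
    eq_a <- subsample_to_depth(env$track_a, env$genome_a, target,
                               derive_seed(seed, "eq-a"))
    eq_b <- subsample_to_depth(env$track_b, env$genome_b, target,
                               derive_seed(seed, "eq-b"))
    call_one <- function(tr, g) {
      wc <- bin_reads(tr, g, config$caller$window_size,
                      config$caller$min_mappable_fraction)
      call_origins(wc, fit_background(wc), config$caller, track = tr,
                   genome = g)
    }
    env$origins_a <- call_one(eq_a, env$genome_a)
    env$origins_b <- call_one(eq_b, env$genome_b)
    env$track_a_eq <- eq_a; env$track_b_eq <- eq_b
    write_origins(env$origins_a, file.path(out, "origins_a.tsv"))
    write_origins(env$origins_b, file.path(out, "origins_b.tsv"))
  }, load = function() {
    env$origins_a <- read_origins(file.path(out, "origins_a.tsv"))
    env$origins_b <- read_origins(file.path(out, "origins_b.tsv"))
  })

  feat_files <- c("nt_profile.tsv", "skew_profile.tsv",
                  "skew_inversion.tsv", "g4_hits.bed", "g4_profile.tsv")
  run_stage("features", feat_files, produce = function() {
    ori <- env$origins_a
    np <- nucleotide_profile(ori, env$genome_a, 250L)
    nt <- data.frame(offset = np$A$offset, A = np$A$value, C = np$C$value,
                     G = np$G$value, T = np$T$value)
    write.table(nt, file.path(out, "nt_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sk <- skew_profile(ori, env$genome_a)
    write.table(data.frame(offset = sk$S_GC$offset, s_gc = sk$S_GC$value,
                           s_at = sk$S_AT$value),
                file.path(out, "skew_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    inv <- find_skew_inversion(sk$S_GC)
    write.table(as.data.frame(inv), file.path(out, "skew_inversion.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hits <- scan_g4(env$genome_a)
    write_g4_bed(hits, file.path(out, "g4_hits.bed"))
    write_profile_tsv(g4_density_profile(ori, hits),
                      file.path(out, "g4_profile.tsv"))
  }, load = function() NULL)

  sel_files <- c("snp_profile_common.tsv", "snp_profile_rare.tsv",
                 "core_depletion.tsv")
  run_stage("selection", sel_files, produce = function() {
    lab <- classify_variants(env$variants, config$classing)
    ori <- env$origins_a
    write_profile_tsv(
      snp_density_profile(ori, lab, "common", genome = env$genome_a),
      file.path(out, "snp_profile_common.tsv"))
    write_profile_tsv(
      snp_density_profile(ori, lab, "rare", genome = env$genome_a),
      file.path(out, "snp_profile_rare.tsv"))
    cd <- core_depletion(ori, lab, "common",
                         seed = derive_seed(seed, "cd"))
    write.table(data.frame(core_density = cd$core_density,
                           flank_density = cd$flank_density,
                           ratio = cd$ratio, ci_lo = cd$ci[1],
                           ci_hi = cd$ci[2], n_anchors = cd$n_anchors),
                file.path(out, "core_depletion.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }, load = function() NULL)

  comp_files <- c("background_clusters.tsv", "core_clusters.tsv",
                  "motif_folds.tsv")
  run_stage("composition", comp_files, produce = function() {
    ori <- env$origins_a
    nseg <- config$n_background_segments %||% max(nrow(ori), 100L)
    segs <- sample_random_segments(env$genome_a, nseg, 40L,
                                   derive_seed(seed, "bg-seg"))
    km_bg <- kmer_counts(segs, env$genome_a)
    model <- fit_background_clusters(km_bg, config$n_axes,
                                     config$n_clusters,
                                     derive_seed(seed, "cluster"))
    cores <- core_segments(ori, env$genome_a)
    km_core <- kmer_counts(cores, env$genome_a)
    core_cl <- assign_map(model, km_core)
    write.table(cbind(segs, cluster = model$assignment),
                file.path(out, "background_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(cores, cluster = core_cl),
                file.path(out, "core_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    core_seqs <- vapply(seq_len(nrow(cores)), function(i)
      get_seq(env$genome_a, cores$chrom[i], cores$start[i], cores$end[i]),
      character(1))
    seg_seqs <- vapply(seq_len(nrow(segs)), function(i)
      get_seq(env$genome_a, segs$chrom[i], segs$start[i], segs$end[i]),
      character(1))
    folds <- motif_fold_enrichment(core_seqs, core_cl, seg_seqs,
                                   model$assignment)
    write.table(folds, file.path(out, "motif_folds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }, load = function() NULL)

  cons_files <- c("concentration.tsv", "conservation_report.tsv")
  run_stage("conserve", cons_files, produce = function() {
    cc <- concentration_curve(env$track_a, env$genome_a)
    write.table(data.frame(
      top_fraction = c(0.01, 0.05, 0.10, 0.25),
      read_share = vapply(c(0.01, 0.05, 0.10, 0.25),
                          function(f) concentration_share(cc, f),
                          numeric(1))),
      file.path(out, "concentration.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    top <- select_top_quartile(env$origins_a)
    rb <- randomized_baseline(top, env$genome_a, env$map, env$origins_b,
                              config$n_random_sets,
                              derive_seed(seed, "baseline"))
    write.table(data.frame(
      n_top = rb$observed$n_origins_considered,
      pct_cgs = rb$observed$pct_overlapping_cgs,
      pct_conserved = rb$observed$pct_functionally_conserved,
      pct_conserved_of_cgs = rb$observed$pct_conserved_of_cgs,
      fold_cgs = rb$fold_cgs, fold_conserved = rb$fold_conserved,
      random_mean_cgs = mean(rb$random_pct_cgs),
      random_mean_conserved = mean(rb$random_pct_conserved)),
      file.path(out, "conservation_report.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }, load = function() NULL)

  invisible(out)
}
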