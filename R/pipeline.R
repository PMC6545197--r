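#' Run the full synthetic analysis pipeline
#'
#' simulate -> enumerate junctions -> classify reads -> splicing report,
#' in one deterministic call. All outputs land under `outdir`; a report is
#' regenerable byte-identically from the run directory plus config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created). `NULL` to keep everything in
#'   memory only.
#' @param k Junction flank length.
#' @param min_overlap Minimum read overlap on each side of a junction
#'   midpoint.
#' @param max_mismatch_rate Maximum substitution rate for classification.
#' @param assign_features Also place junction-unassigned reads on the
#'   genome for per-feature abundance (slower; off by default).
#' @return A list with `gen` (genome+annotation), `pool`, `sim`
#'   (reads+truth), `library`, `assignments`, `counts`, `report`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, k = 25L,
                         min_overlap = 10L, max_mismatch_rate = 0.04,
                         assign_features = FALSE) {
  gen <- generate_genome(config)
  pool <- generate_transcript_pool(gen)
  sim <- simulate_reads(pool, config)
  jx <- rbind(
    enumerate_junctions(gen$genome, gen$introns$giant, k = k),
    enumerate_junctions(gen$genome, gen$introns$small, k = k,
                        circle_offsets = config$circle_offsets_small))
  lib <- build_junction_library(jx, k = k)
  assignments <- classify_reads(sim$reads, lib, min_overlap,
                                max_mismatch_rate)
  feats <- NULL
  if (assign_features) {
    una <- assignments$outcome == "UNASSIGNED"
    feats <- assign_reads_to_features(
      list(id = sim$reads$id[una], seq = sim$reads$seq[una]),
      gen$genome, gen$features, max_mismatch_rate = max_mismatch_rate)
  }
  counts <- count_by_category(assignments, feats)
  report <- splicing_report(counts, gen$genome, gen$features)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(gen$genome, file.path(outdir, "genome.fasta"))
    write_gff3(gen$genome, gen$features, file.path(outdir, "features.gff3"))
    pool_seqs <- vapply(pool, function(p) species_sequence(p$species),
                        character(1))
    names(pool_seqs) <- vapply(pool, function(p)
      sprintf("%s class=%s weight=%g", p$name, p$species$species_class,
              p$weight), character(1))
    write_seqs_fasta(pool_seqs, file.path(outdir, "species_pool.fasta"))
    write_fastq(sim$reads$id, sim$reads$seq,
                file.path(outdir, "reads.fastq"))
    utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$weights <- NULL
    writeLines(c(sprintf("%s = %s", names(cfg),
                         vapply(cfg, function(v)
                           paste(as.character(v), collapse = ","),
                           character(1))),
                 sprintf("weight.%s = %g", names(config$weights),
                         unlist(config$weights))),
               file.path(outdir, "config.txt"))
    write_splicing_report(report, file.path(outdir, "report"))
  }
  list(gen = gen, pool = pool, sim = sim, library = lib,
       assignments = assignments, counts = counts, report = report)
}

#' Estimate per-intron splicing efficiency from a pipeline run
#'
#' Convenience extractor: the "mean"-formula efficiency rows of the run's
#' splicing report.
#'
#' @param run Output of [run_pipeline()].
#' @return Data frame with one row per intron.
#' @export
pipeline_efficiencies <- function(run) {
  ir <- run$report$introns
  ir[ir$formula == "mean", , drop = FALSE]
}

#' Parameter-recovery study across seeds
#'
#' The calibration experiment for the whole pipeline: for each seed,
#' simulate the study (genome, transcript pool, reads), classify the reads
#' against the junction library, estimate each intron's spliced fraction
#' with its Wilson 95% interval, and record whether the interval covers
#' the configured truth. Lean by design (no feature assignment, no file
#' output) so that many replicates are affordable.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_reads Reads per replicate.
#' @param spliced_fraction_giant,spliced_fraction_small Configured truths.
#' @param k,min_overlap,max_mismatch_rate Classifier settings.
#' @return A `data.frame` with one row per seed and intron: `seed`,
#'   `intron_id`, `truth`, `estimate`, `ci_lower`, `ci_upper`, `covered`,
#'   `n_spliced`, plus the per-seed spliced-read ratio small/giant.
#' @export
recovery_study <- function(seeds, n_reads = 50000L,
                           spliced_fraction_giant = 0.30,
                           spliced_fraction_small = 0.98,
                           k = 25L, min_overlap = 10L,
                           max_mismatch_rate = 0.04) {
  rows <- list()
  for (s in seeds) {
    cfg <- sim_config(seed = s, n_reads = n_reads,
                      spliced_fraction_giant = spliced_fraction_giant,
                      spliced_fraction_small = spliced_fraction_small)
    gen <- generate_genome(cfg)
    pool <- generate_transcript_pool(gen)
    sim <- simulate_reads(pool, cfg)
    jx <- rbind(
      enumerate_junctions(gen$genome, gen$introns$giant, k = k),
      enumerate_junctions(gen$genome, gen$introns$small, k = k,
                          circle_offsets = cfg$circle_offsets_small))
    lib <- build_junction_library(jx, k = k)
    asg <- classify_reads(sim$reads, lib, min_overlap, max_mismatch_rate)
    counts <- count_by_category(asg)
    jc <- counts$junction_counts
    get_n <- function(iid, cat) {
      w <- jc$intron_id == iid & jc$category == cat
      if (any(w)) sum(jc$reads[w]) else 0L
    }
    truths <- c("ND5-717" = spliced_fraction_giant,
                "COI-884" = spliced_fraction_small)
    ns <- c("ND5-717" = get_n("ND5-717", "E1E2_LIGATION"),
            "COI-884" = get_n("COI-884", "E1E2_LIGATION"))
    ratio <- ns[["COI-884"]] / ns[["ND5-717"]]
    for (iid in names(truths)) {
      eff <- splicing_efficiency(get_n(iid, "E1E2_LIGATION"),
                                 get_n(iid, "UNSPLICED_5SS"),
                                 get_n(iid, "UNSPLICED_3SS"))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, intron_id = iid, truth = truths[[iid]],
        estimate = eff$spliced_fraction, ci_lower = eff$ci_lower,
        ci_upper = eff$ci_upper,
        covered = !is.na(eff$spliced_fraction) &&
          eff$ci_lower <= truths[[iid]] && truths[[iid]] <= eff$ci_upper,
        n_spliced = eff$n_spliced, ratio_small_over_giant = ratio,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
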