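# larger toy for classification: exons comfortably wider than k
class_fixture <- function(k = 10L) {
  set.seed(2024)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  g <- circular_genome("cls", s)
  # exon2 [0,60), linker [60,80), exon1 [80,140), intron [140 -> 0)
  intron <- intron_model(g, "cls-1", 140L, 0L,
                         exon1_span = c(80L, 140L),
                         exon2_span = c(0L, 60L))
  jx <- enumerate_junctions(g, intron, k = k, circle_offsets = 0L)
  list(genome = g, intron = intron, jx = jx,
       lib = build_junction_library(jx, k = k))
}

test_that("junction library collapses duplicate contexts", {
  fx <- class_fixture()
  expect_s3_class(fx$lib, "junction_library")
  expect_equal(nrow(fx$lib$entries), nrow(fx$jx))
  expect_true(all(nchar(fx$lib$entries$context) == 20L))
  dup <- rbind(fx$jx, fx$jx[fx$jx$category == "E1E2_LIGATION", ])
  libd <- build_junction_library(dup, k = 10L)
  expect_equal(nrow(libd$entries), nrow(fx$jx))
  e <- libd$entries[grepl("E1E2", libd$entries$categories), ]
  expect_equal(e$n_sources, 2L)
  expect_equal(nrow(build_junction_library(fx$jx[0, ], 10L)$entries), 0L)
  bad <- fx$jx
  bad$left_flank[1] <- substr(bad$left_flank[1], 1, 5)
  expect_error(build_junction_library(bad, 10L), "inconsistent")
})

test_that("reads are assigned, rejected, or flagged ambiguous as specified", {
  fx <- class_fixture()
  e <- fx$lib$entries[grepl("E1E2", fx$lib$entries$categories), ]
  ctx <- e$context
  # read equal to the central 2m window
  read <- substr(ctx, 1, 20)
  r <- classify_read(read, fx$lib, min_overlap = 10L)
  expect_equal(r$outcome, "ASSIGNED")
  expect_equal(r$mismatches, 0L)
  expect_match(r$category, "E1E2_LIGATION")
  # read matching only the left flank stops at the midpoint
  left_only <- subsequence(fx$genome, 110, 140)  # exon1 interior + tail
  r2 <- classify_read(left_only, fx$lib, min_overlap = 10L)
  expect_equal(r2$outcome, "UNASSIGNED")
  # read shorter than 2m
  expect_equal(classify_read("ACGTACGTACGTACG", fx$lib,
                             min_overlap = 10L)$outcome, "UNASSIGNED")
  # equal match to two different junction contexts: they share a central
  # 12-mer and differ only in their outer flanks
  set.seed(88)
  shared <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                  collapse = "")
  jx2 <- data.frame(
    junction_id = c("x:A", "y:B"), intron_id = c("x", "y"),
    category = c("E1E2_LIGATION", "INTRON_CIRCLE"),
    donor_offset = c(NA_integer_, 0L),
    left_flank = c(paste0("AAAA", substr(shared, 1, 6)),
                   paste0("CCCC", substr(shared, 1, 6))),
    right_flank = c(paste0(substr(shared, 7, 12), "GGGG"),
                    paste0(substr(shared, 7, 12), "TTTT")),
    stringsAsFactors = FALSE)
  lib2 <- build_junction_library(jx2, k = 10L)
  amb <- classify_read(shared, lib2, min_overlap = 6L)
  expect_equal(amb$outcome, "AMBIGUOUS")
  # a multi-source (collapsed) context classifies as ambiguous too
  dup <- rbind(fx$jx, transform(fx$jx[fx$jx$category == "E1E2_LIGATION", ],
                                intron_id = "other",
                                junction_id = "other:E1E2_LIGATION"))
  libd <- build_junction_library(dup, k = 10L)
  r3 <- classify_read(read, libd, min_overlap = 10L)
  expect_equal(r3$outcome, "AMBIGUOUS")
})

test_that("simulated error-bearing junction reads classify at the closed-form rate", {
  fx <- class_fixture(k = 25L)
  # ligated mRNA; reads fully contain the 50-nt junction context, so a
  # read fails only when it carries more substitutions in that window
  # than the 4% budget allows: P(fail) = P(Binom(50, 0.01) > 2)
  cis <- cis_splice(build_conventional_precursor(fx$genome, fx$intron, 60L),
                    fx$intron, fx$genome)
  mseq <- species_sequence(cis$mrna)  # 120 nt; junction at position 60
  p_expect <- stats::pbinom(2, 50, 0.01)
  set.seed(313)
  n_ok <- 0L
  n_trials <- 1000L
  for (i in seq_len(n_trials)) {
    start <- sample(10:35, 1)  # context [35, 85) always inside the read
    read <- mutate_read(substr(mseq, start + 1, start + 100), 0.01)
    r <- classify_read(read, fx$lib, min_overlap = 10L,
                       max_mismatch_rate = 0.04)
    if (r$outcome == "ASSIGNED" && grepl("E1E2", r$category)) n_ok <- n_ok + 1L
  }
  rate <- n_ok / n_trials
  expect_gte(rate, 0.97)
  # Monte-Carlo agrees with the closed-form binomial oracle
  expect_lt(abs(rate - p_expect), 3 * sqrt(p_expect * (1 - p_expect) /
                                             n_trials) + 0.005)
})

test_that("classification is invariant to reverse-complementing the read", {
  fx <- class_fixture()
  set.seed(55)
  for (i in 1:40) {
    entry <- fx$lib$entries[sample(nrow(fx$lib$entries), 1), ]
    a <- sample(0:8, 1)
    read <- substr(entry$context, 1 + a, 12 + a)
    if (i %% 3 == 0) read <- mutate_read(read, 0.05)
    r_f <- classify_read(read, fx$lib, min_overlap = 6L)
    r_r <- classify_read(revcomp(read), fx$lib, min_overlap = 6L)
    expect_equal(r_f$outcome, r_r$outcome)
    expect_equal(r_f$junction_id, r_r$junction_id)
    expect_equal(r_f$mismatches, r_r$mismatches)
  }
})

test_that("error-free reads covering a junction midpoint are always assigned", {
  cfg <- sim_config(seed = 5, n_reads = 3000L, substitution_rate = 0)
  gen <- generate_genome(cfg)
  pool <- generate_transcript_pool(gen)
  sim <- simulate_reads(pool, cfg)
  jx <- rbind(
    enumerate_junctions(gen$genome, gen$introns$giant, k = 25L),
    enumerate_junctions(gen$genome, gen$introns$small, k = 25L,
                        circle_offsets = cfg$circle_offsets_small))
  lib <- build_junction_library(jx, k = 25L)
  asg <- classify_reads(sim$reads, lib, min_overlap = 10L)
  m <- 10L
  truth_cat <- vapply(seq_along(sim$reads$id), function(i) {
    js <- sim$truth$junctions[i]
    if (!nzchar(js)) return(NA_character_)
    parts <- strsplit(js, ";", fixed = TRUE)[[1]]
    for (p in parts) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1]]
      left <- as.integer(kv[2])
      if (left >= m && sim$truth$length[i] - left >= m) return(kv[1])
    }
    NA_character_
  }, character(1))
  covered <- !is.na(truth_cat)
  expect_gt(sum(covered), 20L)
  expect_true(all(asg$outcome[covered] == "ASSIGNED"))
  expect_equal(asg$category[covered], truth_cat[covered])
  # and conservation holds
  counts <- count_by_category(asg)
  expect_equal(sum(counts$junction_counts$reads) + counts$n_ambiguous +
                 counts$n_unassigned + counts$n_feature_assigned,
               counts$total)
})

test_that("feature assignment places reads by majority overlap and strand", {
  gen <- generate_genome(sim_config(seed = 2))
  g <- gen$genome; f <- gen$features
  # verbatim read from inside a feature
  nd1 <- f[f$id == "ND1", ]
  read1 <- subsequence(g, nd1$start + 100L, nd1$start + 300L)
  # read spanning a feature boundary 60/40
  cytb <- f[f$id == "CYTB", ]
  read2 <- subsequence(g, cytb$start - 80L, cytb$start + 120L)
  # read from the antisense ORF strand
  aorf <- f[f$id == "aORF", ]
  read3 <- revcomp(subsequence(g, aorf$start + 30L, aorf$start + 230L))
  res <- assign_reads_to_features(c(read1, read2, read3), g, f)
  expect_equal(res$outcome, rep("ASSIGNED", 3))
  expect_equal(res$feature_id, c("ND1", "CYTB", "aORF"))
  expect_equal(res$strand, c("+", "+", "-"))
  # junk read stays unassigned
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  expect_equal(assign_reads_to_features(junk, g, f)$outcome, "UNASSIGNED")
  expect_error(assign_reads_to_features(junk, g, f, min_match = 10L),
               ">= 20")
})

test_that("count bookkeeping conserves reads", {
  df <- data.frame(
    read_id = sprintf("r%d", 1:12),
    outcome = c(rep("ASSIGNED", 8), rep("UNASSIGNED", 2),
                rep("AMBIGUOUS", 2)),
    junction_id = NA, category = c(rep("E1E2_LIGATION", 5),
                                   rep("UNSPLICED_5SS", 3), NA, NA, NA, NA),
    intron_id = c(rep("i1", 5), rep("i2", 3), NA, NA, NA, NA),
    donor_offset = NA, mismatches = 0, left_overlap = 10,
    right_overlap = 10, strand = "+", stringsAsFactors = FALSE)
  counts <- count_by_category(df)
  expect_equal(counts$total, 12L)
  expect_equal(sum(counts$junction_counts$reads), 8L)
  expect_equal(counts$n_unassigned, 2L)
  expect_equal(counts$n_ambiguous, 2L)
  expect_equal(sort(unique(counts$junction_counts$intron_id)),
               c("i1", "i2"))
  empty <- count_by_category(df[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(sum(empty$junction_counts$reads), 0L)
})

test_that("back-splice support needs ligation AND permuted contiguity", {
  set.seed(77)
  g <- circular_genome("toy44",
                       paste(sample(c("A", "C", "G", "T"), 44,
                                    replace = TRUE), collapse = ""))
  intron <- intron_model(g, "toy44-1", 18L, 0L,
                         exon1_span = c(11L, 18L), exon2_span = c(0L, 7L))
  perm <- build_permuted_precursor(g, intron, 39L, 24L)
  bs <- back_splice(perm, intron, g)
  circ <- species_sequence(bs$circle)
  mrna <- species_sequence(
    cis_splice(build_conventional_precursor(g, intron, 7L), intron, g)$mrna)
  k <- 6L; m <- 4L
  # doubled circle supports, under every rotation
  set.seed(9)
  for (rot in sample(0:(nchar(circ) - 1L), 8)) {
    r <- paste0(substr(circ, rot + 1, nchar(circ)), substr(circ, 1, rot))
    dd <- paste0(r, r)
    det <- detect_backsplice_support(dd, intron, g, k = k, m = m)
    expect_equal(det$n_support, 1L)
  }
  # ligated mRNA alone: ligation without permuted contiguity
  det_m <- detect_backsplice_support(mrna, intron, g, k = k, m = m)
  expect_equal(det_m$n_support, 0L)
  expect_true(det_m$evidence$has_e1e2)
  expect_false(det_m$evidence$has_permuted)
  # linear permuted precursor: contiguity without ligation
  det_p <- detect_backsplice_support(species_sequence(perm), intron, g,
                                     k = k, m = m)
  expect_equal(det_p$n_support, 0L)
  expect_false(det_p$evidence$has_e1e2)
  expect_true(det_p$evidence$has_permuted)
})
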