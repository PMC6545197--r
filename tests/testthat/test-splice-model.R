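test_that("intron validation passes omega-G, warns omega-A, fails zero length", {
  g <- toy_genome("G")
  rep_g <- validate_intron(g, toy_intron(g))
  expect_true(all(rep_g$status == "pass"))
  g_a <- toy_genome("A")
  rep_a <- validate_intron(g_a, toy_intron(g_a))
  expect_equal(sum(rep_a$status == "warn"), 1L)
  expect_match(rep_a$message[rep_a$status == "warn"], "A, not omega-G")
  expect_false(any(rep_a$status == "fail"))
  zero <- intron_model(g, "z", 15L, 15L, exon1_span = c(10L, 15L),
                       exon2_span = c(15L, 21L))
  rep_z <- validate_intron(g, zero)
  expect_true(any(rep_z$status == "fail" &
                    grepl("zero-length", rep_z$message)))
})

test_that("conventional precursor assembles exon1-tail + intron + exon2-head", {
  g <- toy_genome()
  intron <- toy_intron(g)
  p <- build_conventional_precursor(g, intron, pad = 5L)
  expect_equal(p$species_class, "PRECURSOR_CONVENTIONAL")
  expect_equal(species_length(p), 5L + 25L + 5L)
  expect_equal(p$transcript$sequence,
               paste0(subsequence(g, 10, 15), subsequence(g, 15, 0),
                      subsequence(g, 0, 5)))
  expect_error(build_conventional_precursor(g, intron, 0L), "positive")
  expect_error(build_conventional_precursor(g, intron, 7L),
               "exceeds available exon")
})

test_that("permuted precursor walks intron-3' tail, exons, intron-5' head", {
  g <- toy_genome()
  intron <- toy_intron(g)
  p <- build_permuted_precursor(g, intron, tx_start = 35L, tx_end = 20L)
  expect_equal(p$species_class, "PRECURSOR_PERMUTED")
  expect_equal(species_length(p), 25L)  # 5 + 6 + 4 + 5 + 5
  expect_equal(p$transcript$sequence, subsequence(g, 35, 20))
  # junction positions along the molecule
  jx <- setNames(vapply(p$junctions, `[[`, numeric(1), "pos"),
                 vapply(p$junctions, `[[`, character(1), "category"))
  expect_equal(jx[["UNSPLICED_3SS"]], 5)
  expect_equal(jx[["PERMUTED_GENOMIC"]], 11)
  expect_equal(jx[["UNSPLICED_5SS"]], 20)
  expect_error(build_permuted_precursor(g, intron, 3L, 20L),
               "inside the intron")  # tx_start inside exon 2
  expect_error(build_permuted_precursor(g, intron, 20L, 35L),
               "ordering")
})

test_that("cis-splicing conserves nucleotides and caps the intron with exo-G", {
  g <- toy_genome()
  intron <- toy_intron(g)
  p <- build_conventional_precursor(g, intron, pad = 5L)
  out <- cis_splice(p, intron, g)
  expect_equal(out$mrna$species_class, "MRNA_LIGATED")
  expect_equal(species_length(out$mrna), 10L)
  expect_equal(out$intron_rna$species_class, "INTRON_LINEAR")
  expect_equal(species_length(out$intron_rna), 26L)
  expect_equal(substr(species_sequence(out$intron_rna), 1, 1), "G")
  expect_equal(species_length(p),
               species_length(out$mrna) +
                 species_length(out$intron_rna) - 1L)
  expect_error(cis_splice(out$mrna, intron, g), "PRECURSOR_CONVENTIONAL")
})

test_that("back-splicing yields a circle and two intron segments, conserving nt", {
  g <- toy_genome()
  intron <- toy_intron(g)
  p <- build_permuted_precursor(g, intron, 35L, 20L)
  out <- back_splice(p, intron, g)
  expect_equal(out$circle$species_class, "CIRC_INTERMEDIATE")
  expect_equal(out$circle$transcript$topology, "circular")
  expect_equal(species_length(out$circle), 15L)
  expect_equal(species_length(out$seg3p), 5L)
  expect_equal(species_length(out$seg5p), 6L)
  expect_equal(substr(species_sequence(out$seg5p), 1, 1), "G")
  expect_equal(25L, 15L + 5L + (6L - 1L))
  expect_error(back_splice(out$circle, intron, g), "PRECURSOR_PERMUTED")
})

test_that("both splicing pathways create the identical exon-ligation junction", {
  for (seed in 1:25) {
    ly <- random_layout(seed, k = 6L, pad_max = 8L)
    g <- ly$genome; intron <- ly$intron
    conv <- build_conventional_precursor(g, intron, pad = 6L)
    cis <- cis_splice(conv, intron, g)
    tx_start <- (intron$three_ss - 8L) %% ly$L
    tx_end <- (intron$five_ss + 8L) %% ly$L
    perm <- build_permuted_precursor(g, intron, tx_start, tx_end)
    bs <- back_splice(perm, intron, g)
    ctx_cis <- species_junction_contexts(cis$mrna, k = 6L)
    ctx_bs <- species_junction_contexts(bs$circle, k = 6L)
    cis_e <- ctx_cis[ctx_cis$category == "E1E2_LIGATION", ]
    bs_e <- ctx_bs[ctx_bs$category == "E1E2_LIGATION", ]
    expect_equal(cis_e$left_flank, bs_e$left_flank)
    expect_equal(cis_e$right_flank, bs_e$right_flank)
    # and both agree with the genome-level enumeration
    jx <- enumerate_junctions(g, intron, k = 6L)
    e <- jx[jx$category == "E1E2_LIGATION", ]
    expect_equal(cis_e$left_flank, e$left_flank)
    expect_equal(cis_e$right_flank, e$right_flank)
  }
})

test_that("splicing bookkeeping is exact on randomized layouts", {
  for (seed in 100:160) {
    ly <- random_layout(seed)
    g <- ly$genome; intron <- ly$intron
    pad <- sample(2:6, 1)
    conv <- build_conventional_precursor(g, intron, pad = pad)
    cis <- cis_splice(conv, intron, g)
    expect_equal(species_length(conv),
                 species_length(cis$mrna) +
                   species_length(cis$intron_rna) - 1L)
    expect_equal(species_length(cis$intron_rna) - 1L, ly$ilen)
    tx_start <- (intron$three_ss - sample(2:8, 1)) %% ly$L
    tx_end <- (intron$five_ss + sample(2:8, 1)) %% ly$L
    perm <- build_permuted_precursor(g, intron, tx_start, tx_end)
    bs <- back_splice(perm, intron, g)
    expect_equal(species_length(perm),
                 species_length(bs$circle) + species_length(bs$seg3p) +
                   (species_length(bs$seg5p) - 1L))
    expect_equal(species_length(bs$circle),
                 ly$e1len + ly$e2len + ly$lnk)
    # every species' sequence is reproducible from segments + extra_5p
    for (sp in list(conv, cis$mrna, cis$intron_rna, perm, bs$circle,
                    bs$seg3p, bs$seg5p)) {
      rebuilt <- paste0(sp$extra_5p,
                        paste(vapply(sp$transcript$segments, function(s)
                          subsequence(g, s[1], s[2]), character(1)),
                          collapse = ""))
      expect_equal(species_sequence(sp), rebuilt)
    }
  }
})

test_that("intron circularization needs omega-G and shrinks with donor offset", {
  g <- toy_genome("G")
  intron <- toy_intron(g)
  cis <- cis_splice(build_conventional_precursor(g, intron, 5L), intron, g)
  full <- circularize_intron(cis$intron_rna, 0L)
  expect_equal(full$species_class, "INTRON_CIRCLE_FULL")
  expect_equal(species_length(full), 25L)
  tr <- circularize_intron(cis$intron_rna, 6L)
  expect_equal(tr$species_class, "INTRON_CIRCLE_TRUNCATED")
  expect_equal(species_length(tr), 19L)
  lens <- vapply(0:10, function(d)
    species_length(circularize_intron(cis$intron_rna, d)), numeric(1))
  expect_true(all(diff(lens) == -1))
  expect_error(circularize_intron(cis$intron_rna, 25L), "donor_offset")
  # omega-A chemistry block
  g_a <- toy_genome("A")
  intron_a <- toy_intron(g_a)
  cis_a <- cis_splice(build_conventional_precursor(g_a, intron_a, 5L),
                      intron_a, g_a)
  err <- tryCatch(circularize_intron(cis_a$intron_rna, 0L),
                  condition = function(c) c)
  expect_s3_class(err, "chemistry_error")
  expect_match(conditionMessage(err), "not omega-G")
  forced <- circularize_intron(cis_a$intron_rna, 0L, force = TRUE)
  expect_equal(species_length(forced), 25L)
})

test_that("junction enumeration slices exact 2k contexts", {
  set.seed(77)
  g <- circular_genome("toy44",
                       paste(sample(c("A", "C", "G", "T"), 44,
                                    replace = TRUE), collapse = ""))
  # exon2 [0,7), linker [7,11), exon1 [11,18), intron [18 -> 0): 26 nt
  intron <- intron_model(g, "toy44-1", 18L, 0L,
                         exon1_span = c(11L, 18L), exon2_span = c(0L, 7L))
  jx <- enumerate_junctions(g, intron, k = 6L, circle_offsets = c(0L, 3L))
  expect_setequal(jx$category,
                  c("E1E2_LIGATION", "UNSPLICED_5SS", "UNSPLICED_3SS",
                    "PERMUTED_GENOMIC", "INTRON_CIRCLE"))
  expect_equal(nrow(jx), 6L)
  expect_true(all(nchar(jx$left_flank) == 6L))
  expect_true(all(nchar(jx$right_flank) == 6L))
  u5 <- jx[jx$category == "UNSPLICED_5SS", ]
  expect_equal(u5$left_flank, subsequence(g, 12, 18))
  expect_equal(u5$right_flank, subsequence(g, 18, 24))
  circ0 <- jx[jx$category == "INTRON_CIRCLE" & jx$donor_offset == 0, ]
  expect_equal(circ0$left_flank, subsequence(g, 38, 0))
  expect_equal(circ0$right_flank, subsequence(g, 18, 24))
  e <- jx[jx$category == "E1E2_LIGATION", ]
  expect_equal(e$left_flank, subsequence(g, 12, 18))
  expect_equal(e$right_flank, subsequence(g, 0, 6))
  expect_error(enumerate_junctions(g, intron, k = 8L), "exon shorter")
  expect_error(enumerate_junctions(g, intron, k = 4L), ">= 6")
})
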