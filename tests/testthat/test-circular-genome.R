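test_that("subsequence walks the circle, wrapping through the origin", {
  g <- circular_genome("toy", "ACGTACGTAC")
  expect_equal(subsequence(g, 0, 4), "ACGT")
  expect_equal(subsequence(g, 8, 3), "ACACG")  # indices 8,9,0,1,2
  # start == end returns the full rotation starting there
  expect_equal(subsequence(g, 3, 3), "TACGTACACG")
  expect_equal(nchar(subsequence(g, 3, 3)), 10L)
  expect_error(subsequence(g, 0, 10), "out of range")
  expect_error(subsequence(g, -1, 3), "out of range")
})

test_that("circular distances are modular and complementary", {
  g <- circular_genome("toy", "ACGTACGTAC")
  expect_equal(circular_distance(g, 8, 3), 5L)
  expect_equal(circular_distance(g, 3, 3), 0L)
  expect_equal(circular_distance(g, 0, 9), 9L)
  expect_error(circular_distance(g, 0, 10), "out of range")
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:9, 1); b <- sample(0:9, 1)
    if (a == b) next
    expect_equal(circular_distance(g, a, b) + circular_distance(g, b, a),
                 10L)
    # the two complementary walks concatenate to a rotation of the genome
    w <- paste0(subsequence(g, a, b), subsequence(g, b, a))
    expect_equal(nchar(w), 10L)
    expect_true(grepl(w, paste0(g$sequence, g$sequence), fixed = TRUE))
  }
})

test_that("genome construction rejects bad alphabets", {
  expect_error(circular_genome("x", "ACGRT"), "outside")
  expect_silent(circular_genome("x", "ACGNT"))
})

test_that("intergenic regions are the circular gaps between features", {
  g <- circular_genome("g20", strrep("ACGTA", 4))
  f <- feature_table(c("a", "b"), c("CDS", "CDS"), c(0L, 12L), c(8L, 16L))
  igrs <- compute_igrs(g, f)
  expect_equal(nrow(igrs), 2L)
  expect_equal(igrs$id, c("IGR-1", "IGR-2"))
  expect_equal(igrs$start, c(8L, 16L))
  expect_equal(igrs$end, c(12L, 0L))
  expect_equal(feature_length(g, igrs), c(4L, 4L))
  # single feature: one wrap-around gap
  f1 <- feature_table("a", "CDS", 5L, 10L)
  igr1 <- compute_igrs(g, f1)
  expect_equal(nrow(igr1), 1L)
  expect_equal(igr1$start, 10L)
  expect_equal(igr1$end, 5L)
  expect_equal(feature_length(g, igr1), 15L)
  # features tiling the whole circle leave no gaps
  ftile <- feature_table(c("a", "b"), c("CDS", "CDS"), c(0L, 9L),
                         c(9L, 0L))
  expect_equal(nrow(compute_igrs(g, ftile)), 0L)
  expect_error(compute_igrs(g, f[0, ]), "no features")
})

test_that("IGR lengths and feature spans partition the circle", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(50:120, 1)
    g <- circular_genome("r", paste(sample(c("A", "C", "G", "T"), L,
                                           replace = TRUE), collapse = ""))
    # non-overlapping features laid out left to right with gaps
    cuts <- sort(sample(0:(L - 1L), sample(4:8, 1)))
    starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
    ends <- cuts[seq(2, length(cuts), by = 2)]
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) < 1) next
    f <- feature_table(sprintf("f%d", seq_along(starts)),
                       rep("CDS", length(starts)), starts, ends)
    igrs <- compute_igrs(g, f)
    tot <- sum(feature_length(g, f)) +
      (if (nrow(igrs)) sum(feature_length(g, igrs)) else 0L)
    expect_equal(tot, L)
  }
})

test_that("GTG initiation fraction is counted strand-aware", {
  s <- paste0("ATG", strrep("A", 7), "GTG", strrep("C", 7))
  g <- circular_genome("g", s)
  cds <- feature_table(c("a", "b"), c("CDS", "CDS"), c(0L, 10L),
                       c(9L, 19L))
  expect_equal(gtg_start_fraction(g, cds), 0.5)
  cds2 <- feature_table(c("a"), "CDS", 0L, 9L)
  expect_equal(gtg_start_fraction(g, cds2), 0)
  # five CDS, two GTG-initiated
  s5 <- paste0("ATGAAATAA", "GTGAAATAA", "ATGAAATAA", "GTGAAATAA",
               "ATGAAATAA")
  g5 <- circular_genome("g5", s5)
  cds5 <- feature_table(sprintf("c%d", 1:5), rep("CDS", 5),
                        seq(0L, 36L, by = 9L), seq(9L, 45L, by = 9L) %% 45L)
  expect_equal(gtg_start_fraction(g5, cds5), 0.4)
  expect_error(gtg_start_fraction(g5, cds5[0, ]), "no CDS")
})

test_that("FASTA round trip preserves the genome", {
  g <- toy_genome()
  path <- tempfile(fileext = ".fasta")
  write_fasta(g, path)
  g2 <- read_fasta(path)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$name, g$name)
  expect_equal(g2$length, g$length)
})

test_that("GFF3 writes origin-spanning features as two ID-joined lines", {
  g <- toy_genome()
  f <- feature_table(c("wrapper", "plain"), c("intron", "CDS"),
                     c(35L, 5L), c(5L, 20L), c("+", "+"),
                     c("Name=giant", ""))
  path <- tempfile(fileext = ".gff3")
  write_gff3(g, f, path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  expect_equal(length(lines), 3L)  # wrapper split into two lines
  wrap_lines <- grep("ID=wrapper", lines, value = TRUE)
  expect_equal(length(wrap_lines), 2L)
  cols <- do.call(rbind, strsplit(wrap_lines, "\t"))
  expect_setequal(paste(cols[, 4], cols[, 5]), c("36 40", "1 5"))
  f2 <- read_gff3(path, g)
  f2 <- f2[match(f$id, f2$id), ]
  expect_equal(f2$start, f$start)
  expect_equal(f2$end, f$end)
  expect_equal(f2$type, f$type)
  expect_equal(f2$strand, f$strand)
})

test_that("GFF3 round trip is the identity on randomized feature sets", {
  set.seed(99)
  for (i in 1:5) {
    L <- sample(60:150, 1)
    g <- circular_genome(sprintf("g%d", i),
                         paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
    n <- sample(2:5, 1)
    starts <- sample(0:(L - 1L), n)
    lens <- sample(3:20, n, replace = TRUE)
    f <- feature_table(sprintf("f%d", seq_len(n)),
                       sample(c("CDS", "rRNA", "tRNA", "exon"), n,
                              replace = TRUE),
                       starts, (starts + lens) %% L)
    path <- tempfile(fileext = ".gff3")
    write_gff3(g, f, path)
    f2 <- read_gff3(path, g)
    f2 <- f2[match(f$id, f2$id), ]
    rownames(f2) <- NULL
    expect_equal(f2$start, f$start)
    expect_equal(f2$end, f$end)
    expect_equal(f2$type, f$type)
  }
})

test_that("malformed GFF3 is rejected with a line number", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g\tsrc\tCDS\t10\t5\t.\t+\t.\tID=bad"), path)
  g <- toy_genome()
  expect_error(read_gff3(path, g), "line 2.*end.*<.*start")
  writeLines(c("##gff-version 3", "g\tsrc\tCDS\t10"), path)
  expect_error(read_gff3(path, g), "line 2.*9 tab-separated")
})

test_that("FASTQ round trip preserves ids and sequences", {
  ids <- c("r1", "r2")
  seqs <- c("ACGTACGTAA", "TTTTGGGGCC")
  path <- tempfile(fileext = ".fastq")
  write_fastq(ids, seqs, path)
  rd <- read_fastq(path)
  expect_equal(rd$id, ids)
  expect_equal(rd$seq, seqs)
})
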