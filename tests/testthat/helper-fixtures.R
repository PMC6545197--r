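# Shared fixtures: a 40-nt toy circular genome whose host gene is split by
# an origin-wrapping 25-nt intron, mirroring (at miniature scale) the
# permuted layout of the giant mitochondrial intron: exon 2 at [0,6),
# a 4-nt linker, exon 1 at [10,15), intron [15 -> 0) through the origin.

toy_genome <- function(omega = "G") {
  set.seed(4242)
  s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
             collapse = "")
  substr(s, 40, 40) <- omega  # intron terminal residue (position 39, 0-based)
  circular_genome("toy40", s)
}

toy_intron <- function(genome, id = "toy-1") {
  intron_model(genome, id, five_ss = 15L, three_ss = 0L,
               exon1_span = c(10L, 15L), exon2_span = c(0L, 6L))
}

# random circular genome with a permuted-style intron layout; exons and
# linker sized to support flank length k and pads up to `pad_max`
random_layout <- function(seed, k = 6L, pad_max = 8L) {
  set.seed(seed)
  e2len <- sample(k:(k + 10L), 1L)
  lnk <- sample(0:6, 1L)
  e1len <- sample(k:(k + 10L), 1L)
  ilen <- sample((2L * (pad_max + k) + 4L):(2L * (pad_max + k) + 30L), 1L)
  L <- e2len + lnk + e1len + ilen
  rot <- sample(0:(L - 1L), 1L)  # arbitrary origin
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = "")
  g <- circular_genome(sprintf("rand%d", seed), s)
  e2s <- rot
  e1s <- (e2s + e2len + lnk) %% L
  five <- (e1s + e1len) %% L
  intron <- intron_model(g, sprintf("rand%d-intron", seed), five, e2s,
                         exon1_span = c(e1s, five),
                         exon2_span = c(e2s, (e2s + e2len) %% L))
  list(genome = g, intron = intron, L = L, ilen = ilen,
       e1len = e1len, e2len = e2len, lnk = lnk)
}

# Independent oracle for direct repeats: longest-common-extension over all
# position pairs, keeping only left/right-maximal pairs.
brute_force_repeats <- function(seq, min_len) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  for (i in seq_len(n - min_len)) {
    for (j in seq.int(i + 1L, n - min_len + 1L)) {
      if (ch[i] != ch[j]) next
      if (i > 1L && ch[i - 1L] == ch[j - 1L]) next  # not left-maximal
      l <- 0L
      while (j + l <= n && ch[i + l] == ch[j + l]) l <- l + 1L
      if (l >= min_len)
        out[[length(out) + 1L]] <- c(i - 1L, j - 1L, l)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0)))
  m <- unique(do.call(rbind, out))
  df <- data.frame(pos1 = m[, 1L], pos2 = m[, 2L], length = m[, 3L])
  df[order(-df$length, df$pos1), , drop = FALSE]
}

# Rotation brute-force oracle for circular PCR: run the linear predictor on
# every rotation of the template and map site pairs back to original
# coordinates.
rotation_pcr_oracle <- function(template, fwd, rev, max_len = 100000L) {
  L <- nchar(template)
  seen <- character(0)
  lens <- integer(0)
  for (r in 0:(L - 1L)) {
    rot <- paste0(substr(template, r + 1L, L), substr(template, 1L, r))
    amps <- predict_amplicons(rot, "linear", fwd, rev, max_len = max_len)
    if (nrow(amps) == 0L) next
    for (i in seq_len(nrow(amps))) {
      f0 <- (amps$fwd_site[i] + r) %% L
      r0 <- (amps$rev_site[i] + r) %% L
      key <- paste(f0, r0, sep = "/")
      if (!key %in% seen) {
        seen <- c(seen, key)
        lens <- c(lens, amps$length[i])
      }
    }
  }
  o <- order(seen)
  data.frame(key = seen[o], length = lens[o], stringsAsFactors = FALSE)
}

mutate_read <- function(seq, rate) {
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  for (p in hits) {
    orig <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
  }
  seq
}
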