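#' Scan a region's opposite strand for open reading frames
#'
#' Corallimorpharian mtDNA encodes every conventional gene on one strand;
#' the one known exception is an ORF on the opposite strand (aORF) inside
#' an intergenic region. This scans the reverse complement of `region` in
#' all three frames for start-to-stop spans.
#'
#' @param genome A [circular_genome()].
#' @param region A single-row [feature_table()] (or a list with `start`,
#'   `end`) giving the genomic window to scan.
#' @param starts Allowed initiation codons, a subset of `c("ATG","GTG")`.
#'   GTG initiation is common in these genomes (~40% of reading frames).
#' @param min_aa Minimum amino-acid count (start codon included, stop
#'   excluded) for a hit.
#' @return A `data.frame` of hits sorted by `aa_length` descending, with
#'   genomic forward-strand coordinates (`start`, `end`, half-open,
#'   possibly wrapping), `strand = "-"`, `start_codon` and `aa_length`.
#'   Empty (not an error) when the region is too short.
#' @export
find_antisense_orfs <- function(genome, region, starts = c("ATG", "GTG"),
                                min_aa = 50L) {
  stopifnot(all(starts %in% c("ATG", "GTG")), min_aa >= 1L)
  rstart <- region$start[1L]; rend <- region$end[1L]
  seq_fwd <- subsequence(genome, rstart, rend)
  n <- nchar(seq_fwd)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), start_codon = character(0),
                      aa_length = integer(0), stringsAsFactors = FALSE)
  if (n < 3L * (min_aa + 1L)) return(empty)  # min_aa codons + stop
  rc <- revcomp(seq_fwd)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (frame in 0:2) {
    idx <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(rc, idx, idx + 2L)
    stop_at <- which(codons %in% stops)
    start_at <- which(codons %in% starts)
    for (s in start_at) {
      nxt <- stop_at[stop_at > s]
      if (length(nxt) == 0L) next
      e <- nxt[1L]
      aa <- e - s  # codons from start up to (not incl.) the stop
      if (aa < min_aa) next
      # rc indices (0-based nt): [3(s-1)+frame, 3e+frame+3)
      i0 <- idx[s] - 1L
      j0 <- idx[e] + 2L  # last nt of stop codon (1-based) -> 0-based excl = idx[e]+2
      # map rc [i0, j0) back to forward-region coords: fwd index = n - rc_index
      f_start <- n - j0
      f_end <- n - i0
      hits[[length(hits) + 1L]] <- data.frame(
        start = (rstart + f_start) %% genome$length,
        end = (rstart + f_end) %% genome$length,
        strand = "-", start_codon = codons[s], aa_length = aa,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out[order(-out$aa_length), , drop = FALSE]
}

#' Find exact direct repeats in a sequence
#'
#' Reports maximal exact repeated substrings of length at least `min_len`
#' occurring at two distinct positions, as maximal pairs sorted by length
#' descending. Each pair is maximal on its diagonal (cannot be extended
#' left or right), so sub-matches of a reported pair are not re-reported.
#' Imperfect (mismatch-tolerant) copies are out of scope.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum repeat length (>= 8).
#' @return A `data.frame` with 0-based columns `pos1`, `pos2`
#'   (`pos1 < pos2`), `length` and `motif`, sorted by length descending.
#' @export
find_direct_repeats <- function(seq, min_len = 8L) {
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 8L)
  n <- nchar(seq)
  out <- data.frame(pos1 = integer(0), pos2 = integer(0),
                    length = integer(0), motif = character(0),
                    stringsAsFactors = FALSE)
  if (n < 2L * 1L || n <= min_len) return(out)
  x <- utf8ToInt(seq)
  res <- list()
  for (d in seq_len(n - min_len)) {
    # diagonal comparison: positions i where seq[i] == seq[i+d]
    eq <- x[seq_len(n - d)] == x[seq.int(d + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values & r$lengths >= min_len)
    for (j in k) {
      res[[length(res) + 1L]] <- c(starts[j] - 1L, starts[j] - 1L + d,
                                   r$lengths[j])
    }
  }
  if (length(res) == 0L) return(out)
  m <- do.call(rbind, res)
  out <- data.frame(pos1 = m[, 1L], pos2 = m[, 2L], length = m[, 3L],
                    motif = substring(seq, m[, 1L] + 1L, m[, 1L] + m[, 3L]),
                    stringsAsFactors = FALSE)
  out[order(-out$length, out$pos1), , drop = FALSE]
}
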