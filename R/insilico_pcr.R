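#' PCR primer
#'
#' @param name Primer name.
#' @param sequence 15-35 nt nucleotide string, written 5' to 3'.
#' @return An object of class `pcr_primer`.
#' @export
pcr_primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 15L || nchar(sequence) > 35L)
    stop("primer must be 15-35 nt")
  if (grepl("[^ACGT]", sequence))
    stop("primer alphabet is {A,C,G,T}")
  structure(list(name = name, sequence = sequence), class = "pcr_primer")
}

#' Read primers from TSV
#'
#' Two-column (name, sequence) tab-separated file, with or without a
#' header line.
#'
#' @param path TSV file.
#' @return List of [pcr_primer()] objects, named by primer name.
#' @export
read_primers_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "sequence"))
  if (nrow(df) > 0 && grepl("[^ACGTacgt]", df$sequence[1L]))
    df <- df[-1L, , drop = FALSE]  # header line
  ps <- lapply(seq_len(nrow(df)), function(i)
    pcr_primer(df$name[i], df$sequence[i]))
  names(ps) <- df$name
  ps
}

.as_primer <- function(p) {
  if (inherits(p, "pcr_primer")) p else pcr_primer("primer", p)
}

#' Find primer binding sites on a template
#'
#' Matches the primer (plus strand) and its reverse complement (minus
#' strand) against the template with at most `max_mismatch` substitutions,
#' via [Biostrings::matchPattern()]. The primer's 3'-terminal
#' `anchor_3p` nucleotides must match exactly regardless of
#' `max_mismatch` (polymerase extension requires a matched 3' end).
#' Circular templates are searched on their doubled sequence and hits
#' deduplicated modulo the template length.
#'
#' @param template_seq Template nucleotide string.
#' @param topology "linear" or "circular".
#' @param primer A [pcr_primer()] or plain sequence.
#' @param max_mismatch Maximum substitutions outside the 3' anchor.
#' @param anchor_3p Exact-match 3' anchor length (default 5).
#' @return A `data.frame` with 0-based `position` (leftmost template
#'   coordinate of the site), `strand`, `five_prime` (0-based template
#'   coordinate of the primer's 5' end) and `mismatches`. Empty when no
#'   site exists.
#' @export
find_primer_sites <- function(template_seq, topology = c("linear",
                                                         "circular"),
                              primer, max_mismatch = 0L, anchor_3p = 5L) {
  topology <- match.arg(topology)
  primer <- .as_primer(primer)
  pseq <- primer$sequence
  plen <- nchar(pseq)
  tseq <- toupper(template_seq)
  L <- nchar(tseq)
  subject <- if (topology == "circular") paste0(tseq, tseq) else tseq
  subj <- Biostrings::DNAString(subject)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pseq else revcomp(pseq)
    hits <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = as.integer(max_mismatch))
    st <- Biostrings::start(hits)
    for (p in st) {
      pos0 <- p - 1L
      if (topology == "circular" && pos0 >= L) next  # dedup mod L
      site <- substr(subject, p, p + plen - 1L)
      if (nchar(site) < plen) next
      # 3' anchor exact: for "+" the anchor is the site's right end,
      # for "-" (revcomp pattern) the left end
      ok <- if (strand == "+")
        substr(site, plen - anchor_3p + 1L, plen) ==
          substr(pat, plen - anchor_3p + 1L, plen)
      else substr(site, 1L, anchor_3p) == substr(pat, 1L, anchor_3p)
      if (!ok) next
      mm <- sum(utf8ToInt(site) != utf8ToInt(pat))
      fp <- if (strand == "+") pos0 else (pos0 + plen - 1L) %% L
      out[[length(out) + 1L]] <- data.frame(
        position = pos0, strand = strand, five_prime = fp,
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(0), strand = character(0),
                      five_prime = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Predict PCR amplicons on a linear or circular template
#'
#' Emits one amplicon for every (forward-primer plus-strand site,
#' reverse-primer minus-strand site) pair whose extension distance along
#' the template is at most `max_len`. On a linear template a divergent
#' pair (reverse site upstream of the forward site) has no downstream
#' path and yields nothing; on a circular template the same pair yields
#' the around-the-circle product. This asymmetry is the in-silico analogue
#' of the divergent-primer RT-PCR test for circular RNA templates: a
#' divergent product is evidence the template was circular (or
#' rearranged). Only the shortest product per site pair is reported (no
#' rolling multimers).
#'
#' @param template_seq Template nucleotide string.
#' @param topology "linear" or "circular".
#' @param fwd,rev [pcr_primer()] objects (or plain sequences).
#' @param max_len Maximum amplicon length.
#' @param max_mismatch Maximum substitutions per primer site (3' anchor
#'   always exact).
#' @return A `data.frame` with `fwd_site`, `rev_site` (0-based 5'-end
#'   coordinates), `length` (fwd 5' end to rev 5' end along the walk,
#'   inclusive) and `sequence` (primer sequences at the ends, template in
#'   between). Empty when no product forms.
#' @export
predict_amplicons <- function(template_seq, topology = c("linear",
                                                         "circular"),
                              fwd, rev, max_len = 5000L,
                              max_mismatch = 0L) {
  topology <- match.arg(topology)
  fwd <- .as_primer(fwd); rev <- .as_primer(rev)
  tseq <- toupper(template_seq)
  L <- nchar(tseq)
  fs <- find_primer_sites(tseq, topology, fwd, max_mismatch)
  rs <- find_primer_sites(tseq, topology, rev, max_mismatch)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- rs[rs$strand == "-", , drop = FALSE]
  empty <- data.frame(fwd_site = integer(0), rev_site = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(empty)
  flen <- nchar(fwd$sequence); rlen <- nchar(rev$sequence)
  doubled <- paste0(tseq, tseq)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      f5 <- fs$five_prime[i]; r5 <- rs$five_prime[j]
      if (topology == "linear") {
        if (r5 < f5) next  # divergent: no downstream path
        len <- r5 - f5 + 1L
      } else {
        len <- ((r5 - f5) %% L) + 1L
      }
      if (len > max_len || len < flen + rlen) next
      walk <- substr(if (topology == "circular") doubled else tseq,
                     f5 + 1L, f5 + len)
      seq <- paste0(fwd$sequence,
                    substr(walk, flen + 1L, len - rlen),
                    revcomp(rev$sequence))
      out[[length(out) + 1L]] <- data.frame(
        fwd_site = f5, rev_site = r5, length = len, sequence = seq,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$length, res$fwd_site), , drop = FALSE]
}
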