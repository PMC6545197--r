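#' Circular genome container
#'
#' A circular nucleotide sequence with modular coordinate arithmetic. All
#' internal coordinates in this package are 0-based, half-open and taken
#' modulo the genome length; an interval with `end <= start` wraps through
#' the origin. Mitochondrial genomes of hexacorals are small (17-22 kb)
#' circles, and the giant ND5 group I intron spans most of the circle, so
#' origin-aware arithmetic is load-bearing rather than an edge case.
#'
#' @param name Text identifier.
#' @param sequence Nucleotide string over A/C/G/T/N (case-insensitive).
#'   Other IUPAC ambiguity characters are rejected.
#' @return An object of class `circular_genome` with fields `name`,
#'   `length`, `sequence` (uppercase) and `topology` (always `"circular"`).
#' @examples
#' g <- circular_genome("toy", "ACGTACGTAC")
#' subsequence(g, 8, 3)  # wraps through the origin: "ACACG"
#' @export
circular_genome <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(
    list(name = name, length = nchar(sequence), sequence = sequence,
         topology = "circular"),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (circular)\n", x$name, x$length))
  invisible(x)
}

.check_pos <- function(genome, pos, what = "position") {
  if (!is.numeric(pos) || any(is.na(pos)) || any(pos != floor(pos)))
    stop(sprintf("%s must be an integer", what))
  if (any(pos < 0L) || any(pos >= genome$length))
    stop(sprintf("%s out of range [0, %d)", what, genome$length))
  as.integer(pos)
}

#' Extract a subsequence from a circular genome
#'
#' Walks downstream (5' to 3') from `start` to `end`, wrapping through the
#' origin when `end <= start`. By convention `start == end` returns the
#' full-length rotation of the genome beginning at `start`.
#'
#' @param genome A [circular_genome()].
#' @param start,end 0-based positions in `[0, length)`; the interval is
#'   half-open.
#' @return Nucleotide string of length `(end - start) mod length`, or the
#'   genome length when `start == end`.
#' @export
subsequence <- function(genome, start, end) {
  stopifnot(inherits(genome, "circular_genome"))
  start <- .check_pos(genome, start, "start")
  end <- .check_pos(genome, end, "end")
  L <- genome$length
  len <- if (start == end) L else (end - start) %% L
  if (start + len <= L) {
    substr(genome$sequence, start + 1L, start + len)
  } else {
    paste0(substr(genome$sequence, start + 1L, L),
           substr(genome$sequence, 1L, start + len - L))
  }
}

#' Downstream distance between two positions on a circular genome
#'
#' @inheritParams subsequence
#' @param a,b 0-based positions.
#' @return `(b - a) mod length`; 0 only when `a == b`.
#' @export
circular_distance <- function(genome, a, b) {
  stopifnot(inherits(genome, "circular_genome"))
  a <- .check_pos(genome, a, "a")
  b <- .check_pos(genome, b, "b")
  (b - a) %% genome$length
}

#' Construct a feature table
#'
#' Features live on the genome's 0-based half-open modular coordinate
#' system; `end <= start` means the feature wraps through the origin.
#' All conventional mitochondrial genes sit on the "+" strand (a
#' hexacoral-wide property); "-" is permitted only for antisense-ORF
#' (`aORF`) features.
#'
#' @param id Character vector of unique feature identifiers.
#' @param type Feature type, one of CDS, rRNA, tRNA, exon, intron, ORF,
#'   aORF, IGR, repeat.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @param attributes Optional free-form `key=value;...` strings.
#' @return A `data.frame` with class `feature_table`.
#' @export
feature_table <- function(id, type, start, end, strand = "+",
                          attributes = "") {
  types <- c("CDS", "rRNA", "tRNA", "exon", "intron", "ORF", "aORF",
             "IGR", "repeat")
  if (!all(type %in% types))
    stop("unknown feature type(s): ",
         paste(setdiff(type, types), collapse = ", "))
  if (any(strand == "-" & type != "aORF"))
    stop("strand '-' is permitted only for aORF features")
  if (anyDuplicated(id))
    stop("feature ids must be unique")
  df <- data.frame(id = as.character(id), type = as.character(type),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(id)),
                   attributes = rep_len(as.character(attributes), length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Nucleotide length of features on a circular genome
#'
#' @param genome A [circular_genome()].
#' @param features A [feature_table()].
#' @return Integer vector of `(end - start) mod length` (must be > 0).
#' @export
feature_length <- function(genome, features) {
  len <- (features$end - features$start) %% genome$length
  if (any(len == 0L))
    stop("zero-length feature (end == start is not allowed for features)")
  as.integer(len)
}

#' Feature sequence (strand-aware)
#'
#' @inheritParams feature_length
#' @param i Row index or feature id.
#' @return Nucleotide string; reverse-complemented for "-" strand features.
#' @export
feature_sequence <- function(genome, features, i) {
  if (is.character(i)) i <- match(i, features$id)
  s <- subsequence(genome, features$start[i], features$end[i])
  if (features$strand[i] == "-") s <- revcomp(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string (DNA alphabet).
#' @return The reverse complement, via [Biostrings::reverseComplement()].
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Decompose one modular feature into 1 or 2 linear [start,end) intervals
.linear_spans <- function(start, end, L) {
  if (end > start) {
    cbind(start = start, end = end)
  } else {
    rbind(cbind(start = start, end = L),
          if (end > 0L) cbind(start = 0L, end = end))
  }
}

#' Compute intergenic regions on a circular genome
#'
#' Finds the maximal gaps, in genome order, between consecutive annotated
#' feature spans taken circularly. Gaps of length zero are omitted. IGRs
#' are labelled `IGR-1 .. IGR-n` starting from the gap that follows the
#' feature with the smallest start coordinate. Following the convention
#' that IGRs are gaps between conventional genes, intron-type
#' features (whose span covers embedded genes) and antisense ORFs are
#' excluded by default.
#'
#' @inheritParams feature_length
#' @param exclude_types Feature types ignored when computing gaps;
#'   default `c("intron", "aORF", "IGR", "repeat")`.
#' @return A [feature_table()] of type `IGR` (strand "+").
#' @export
compute_igrs <- function(genome, features,
                         exclude_types = c("intron", "aORF", "IGR",
                                           "repeat")) {
  stopifnot(inherits(genome, "circular_genome"))
  features <- features[!features$type %in% exclude_types, , drop = FALSE]
  if (nrow(features) == 0L)
    stop("no features left to compute intergenic regions against")
  L <- genome$length
  spans <- do.call(rbind, lapply(seq_len(nrow(features)), function(i)
    .linear_spans(features$start[i], features$end[i], L)))
  spans <- spans[order(spans[, "start"]), , drop = FALSE]
  # merge overlapping/adjacent linear spans
  merged <- list()
  cur <- spans[1L, ]
  for (i in seq_len(nrow(spans))[-1L]) {
    if (spans[i, "start"] <= cur["end"]) {
      cur["end"] <- max(cur["end"], spans[i, "end"])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- spans[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  if (nrow(m) == 1L && m[1L, "start"] == 0L && m[1L, "end"] == L)
    return(feature_table(character(0), character(0), integer(0), integer(0)))
  # circular wrap: a span touching L and a span starting at 0 are adjacent
  # through the origin; fold them into one wrapping span
  if (nrow(m) > 1L && m[1L, "start"] == 0L && m[nrow(m), "end"] == L) {
    m[nrow(m), "end"] <- m[1L, "end"]  # end kept un-reduced; taken mod L below
    m <- m[-1L, , drop = FALSE]
  }
  # gaps between circularly consecutive spans
  n <- nrow(m)
  gs <- integer(0); ge <- integer(0)
  for (i in seq_len(n)) {
    e <- m[i, "end"] %% L
    s_next <- m[(i %% n) + 1L, "start"]
    if ((s_next - e) %% L > 0L || (n == 1L && s_next != e)) {
      gs <- c(gs, e); ge <- c(ge, s_next)
    }
  }
  if (length(gs) == 0L)
    return(feature_table(character(0), character(0), integer(0), integer(0)))
  # order by circular distance from the anchor (feature with smallest start)
  anchor <- min(features$start)
  d <- (gs - anchor) %% L
  o <- order(d)
  gs <- gs[o]; ge <- ge[o] %% L
  feature_table(id = sprintf("IGR-%d", seq_along(gs)),
                type = rep("IGR", length(gs)),
                start = gs, end = ge, strand = "+")
}

#' Fraction of coding sequences initiating with GTG
#'
#' Hexacoral mitochondrial genomes use both ATG and GTG initiation codons
#' (tRNA-fMet is thought to recognize both); roughly 40% of the reading
#' frames in corallimorpharian mtDNA begin with GTG.
#'
#' @inheritParams feature_length
#' @param cds A [feature_table()] restricted to the CDS features to count
#'   (rows of other types are dropped with a warning).
#' @return Fraction in `[0, 1]` of CDS whose strand-aware first codon is GTG.
#' @export
gtg_start_fraction <- function(genome, cds) {
  if (any(cds$type != "CDS")) {
    warning("dropping non-CDS rows")
    cds <- cds[cds$type == "CDS", , drop = FALSE]
  }
  if (nrow(cds) == 0L) stop("no CDS features supplied")
  if (any(feature_length(genome, cds) < 3L))
    stop("CDS shorter than one codon")
  first <- vapply(seq_len(nrow(cds)), function(i)
    substr(feature_sequence(genome, cds, i), 1L, 3L), character(1))
  mean(first == "GTG")
}
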