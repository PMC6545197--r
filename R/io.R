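#' Read a genome from FASTA
#'
#' Reads the first record of a FASTA file as a circular genome. Ambiguity
#' characters other than N are rejected (the deposited corallimorpharian
#' genomes are unambiguous).
#'
#' @param path FASTA file.
#' @return A [circular_genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(ss)[1L])
  circular_genome(nm, as.character(ss[[1L]]))
}

#' Write a genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide strings.
#' @param path Output file.
#' @export
write_seqs_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write features to GFF3
#'
#' Coordinates are converted from the package's 0-based half-open modular
#' convention to GFF3 1-based inclusive. GFF3 has no native convention for
#' circular genomes, so an origin-spanning feature (`end <= start`) is
#' written as two lines sharing one `ID` attribute; [read_gff3()] re-joins
#' them.
#'
#' @param genome A [circular_genome()].
#' @param features A [feature_table()].
#' @param path Output file.
#' @export
write_gff3 <- function(genome, features, path) {
  L <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$name, L), con)
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]
    attrs <- sprintf("ID=%s", features$id[i])
    if (nzchar(features$attributes[i]))
      attrs <- paste(attrs, features$attributes[i], sep = ";")
    spans <- .linear_spans(s, e, L)
    for (r in seq_len(nrow(spans))) {
      writeLines(sprintf("%s\tbacksplicer\t%s\t%d\t%d\t.\t%s\t.\t%s",
                         genome$name, features$type[i],
                         spans[r, "start"] + 1L, spans[r, "end"],
                         features$strand[i], attrs), con)
    }
  }
  invisible(path)
}

# Validate raw GFF3 lines, reporting 1-based line numbers on failure.
.validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated columns, got %d",
                   i, length(f)))
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("GFF3 parse error at line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("GFF3 parse error at line %d: end (%d) < start (%d)", i, e, s))
    if (!f[7L] %in% c("+", "-", "."))
      stop(sprintf("GFF3 parse error at line %d: bad strand '%s'", i, f[7L]))
  }
  invisible(TRUE)
}

#' Read features from GFF3
#'
#' Parses with [rtracklayer::import()] after a line-level validation pass
#' that reports malformed records by line number. Pairs of lines sharing an
#' `ID` (the origin-split dialect written by [write_gff3()]) are re-joined
#' into one wrapping feature.
#'
#' @param path GFF3 file.
#' @param genome The [circular_genome()] the features live on (provides
#'   the length needed to re-join origin-spanning features).
#' @return A [feature_table()].
#' @export
read_gff3 <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  .validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  L <- genome$length
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  if (any(is.na(ids) | !nzchar(ids)))
    stop("GFF3 feature without an ID attribute")
  types <- as.character(mc$type)
  starts0 <- GenomicRanges::start(gr) - 1L
  ends0 <- GenomicRanges::end(gr)  # 1-based inclusive end == 0-based excl end
  strands <- as.character(GenomicRanges::strand(gr))
  strands[strands == "*"] <- "+"
  extra_cols <- setdiff(colnames(mc), c("ID", "type", "source", "phase",
                                        "score"))
  attr_of <- function(i) {
    kv <- vapply(extra_cols, function(k) {
      v <- mc[[k]][i]
      if (is.list(v)) v <- paste(unlist(v), collapse = ",")
      if (is.na(v) || !nzchar(as.character(v))) NA_character_
      else sprintf("%s=%s", k, as.character(v))
    }, character(1))
    paste(kv[!is.na(kv)], collapse = ";")
  }
  out <- list()
  for (id in unique(ids)) {
    w <- which(ids == id)
    if (length(w) == 1L) {
      i <- w
      out[[id]] <- data.frame(id = id, type = types[i],
                              start = starts0[i], end = ends0[i] %% L,
                              strand = strands[i], attributes = attr_of(i),
                              stringsAsFactors = FALSE)
    } else if (length(w) == 2L) {
      # origin-split: one part ends at L, the other starts at 1 (0-based 0)
      a <- w[which(ends0[w] == L)]
      b <- w[which(starts0[w] == 0L)]
      if (length(a) != 1L || length(b) != 1L || a == b)
        stop("cannot re-join split feature '", id,
             "': parts do not abut the origin")
      out[[id]] <- data.frame(id = id, type = types[a],
                              start = starts0[a], end = ends0[b] %% L,
                              strand = strands[a], attributes = attr_of(a),
                              stringsAsFactors = FALSE)
    } else {
      stop("feature id '", id, "' occurs on more than two GFF3 lines")
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  feature_table(df$id, df$type, df$start, df$end, df$strand, df$attributes)
}

#' Read single-end reads from FASTQ
#'
#' @param path FASTQ file.
#' @return A list with `id` and `seq` character vectors (qualities are
#'   parsed but not propagated; scoring downstream is quality-blind).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = names(ss), seq = unname(as.character(ss)))
}

#' Write single-end reads to FASTQ
#'
#' @param ids Read identifiers.
#' @param seqs Read sequences (DNA alphabet).
#' @param path Output file.
#' @param quality_char Constant per-base quality character (default "I").
#' @export
write_fastq <- function(ids, seqs, path, quality_char = "I") {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}
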