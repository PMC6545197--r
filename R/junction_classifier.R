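#' Build a junction library
#'
#' Turns enumerated junctions (from [enumerate_junctions()], possibly for
#' several introns) into the classification library: one entry per
#' distinct 2k context. Duplicate contexts collapse into a single entry
#' carrying all source categories; reads matching such an entry classify
#' as AMBIGUOUS, operationalizing the requirement that counted reads flank
#' their junction unambiguously.
#'
#' @param junctions A `data.frame` as returned by [enumerate_junctions()]
#'   (rows from several introns may be concatenated).
#' @param k Flank length; every flank must be exactly `k` nt.
#' @return An object of class `junction_library`: list with `entries`
#'   (data.frame: `junction_id`, `context`, `n_sources`, and
#'   comma-collapsed `categories`, `intron_ids`, `donor_offsets`) and `k`.
#' @export
build_junction_library <- function(junctions, k = 25L) {
  k <- as.integer(k)
  if (nrow(junctions) > 0 &&
      (any(nchar(junctions$left_flank) != k) ||
       any(nchar(junctions$right_flank) != k)))
    stop("inconsistent flank lengths: expected k = ", k)
  if (nrow(junctions) == 0L) {
    entries <- data.frame(junction_id = character(0), context = character(0),
                          categories = character(0), intron_ids = character(0),
                          donor_offsets = character(0),
                          n_sources = integer(0), stringsAsFactors = FALSE)
    return(structure(list(entries = entries, k = k),
                     class = "junction_library"))
  }
  ctx <- paste0(junctions$left_flank, junctions$right_flank)
  entries <- do.call(rbind, lapply(unique(ctx), function(cc) {
    w <- which(ctx == cc)
    data.frame(
      junction_id = paste(junctions$junction_id[w], collapse = ","),
      context = cc,
      categories = paste(unique(junctions$category[w]), collapse = ","),
      intron_ids = paste(unique(junctions$intron_id[w]), collapse = ","),
      donor_offsets = paste(junctions$donor_offset[w], collapse = ","),
      n_sources = length(w), stringsAsFactors = FALSE)
  }))
  structure(list(entries = entries, k = k), class = "junction_library")
}

#' @export
print.junction_library <- function(x, ...) {
  cat(sprintf("<junction_library> %d contexts (k = %d)\n",
              nrow(x$entries), x$k))
  invisible(x)
}

#' Classify reads against a junction library
#'
#' The computational replacement for manually counting junction-spanning
#' reads: each read (and its reverse complement) is slid ungapped across
#' every library context; a candidate placement is valid if it crosses the
#' junction midpoint with at least `min_overlap` nucleotides on both sides
#' and its substitution rate over the aligned span is at most
#' `max_mismatch_rate`. The unique best candidate (fewest mismatches, then
#' longest overlap) gives ASSIGNED; residual ties across different
#' junctions, or a hit on a multi-source context, give AMBIGUOUS; no valid
#' candidate gives UNASSIGNED. Ungapped only: indel (homopolymer) errors
#' are not modelled.
#'
#' @param reads Character vector of read sequences (DNA alphabet), or a
#'   list with `id` and `seq` as returned by [read_fastq()].
#' @param lib A [build_junction_library()] object.
#' @param min_overlap Minimum nucleotides required on each side of the
#'   junction midpoint (>= 6, <= k).
#' @param max_mismatch_rate Maximum substitution rate over the aligned
#'   span, in `[0, 0.2)`.
#' @return A `data.frame` with one row per read: `read_id`, `outcome`
#'   (ASSIGNED/AMBIGUOUS/UNASSIGNED), `junction_id`, `category`,
#'   `intron_id`, `donor_offset`, `mismatches`, `left_overlap`,
#'   `right_overlap`, `strand`.
#' @export
classify_reads <- function(reads, lib, min_overlap = 10L,
                           max_mismatch_rate = 0.04) {
  stopifnot(inherits(lib, "junction_library"))
  m <- as.integer(min_overlap)
  if (m < 6L) stop("min_overlap must be >= 6")
  if (m > lib$k) stop("min_overlap cannot exceed the flank length k")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.2)
    stop("max_mismatch_rate must be in [0, 0.2)")
  if (is.list(reads) && !is.null(reads$seq)) {
    ids <- if (!is.null(reads$id)) reads$id else
      sprintf("read_%d", seq_along(reads$seq))
    seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("read_%d", seq_along(seqs))
  }
  n <- length(seqs)
  if (n == 0L || nrow(lib$entries) == 0L) {
    return(data.frame(read_id = ids, outcome = rep("UNASSIGNED", n),
                      junction_id = NA_character_, category = NA_character_,
                      intron_id = NA_character_, donor_offset = NA_character_,
                      mismatches = NA_integer_, left_overlap = 0L,
                      right_overlap = 0L, strand = NA_character_,
                      stringsAsFactors = FALSE))
  }
  res <- classify_reads_cpp(toupper(seqs), lib$entries$context,
                            lib$k, m, max_mismatch_rate)
  idx <- res$best_idx
  hit <- idx > 0L
  multi <- rep(FALSE, n)
  multi[hit] <- lib$entries$n_sources[idx[hit]] > 1L
  outcome <- ifelse(!hit, "UNASSIGNED",
                    ifelse(res$tie | multi, "AMBIGUOUS", "ASSIGNED"))
  pick <- function(col) {
    v <- rep(NA_character_, n)
    v[hit] <- lib$entries[[col]][idx[hit]]
    v
  }
  data.frame(read_id = ids, outcome = outcome,
             junction_id = pick("junction_id"),
             category = pick("categories"),
             intron_id = pick("intron_ids"),
             donor_offset = pick("donor_offsets"),
             mismatches = res$mismatches,
             left_overlap = res$left_overlap,
             right_overlap = res$right_overlap,
             strand = res$strand, stringsAsFactors = FALSE)
}

#' Classify one read
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @inheritParams classify_reads
#' @param read One read sequence.
#' @return One-row `data.frame` (see [classify_reads()]).
#' @export
classify_read <- function(read, lib, min_overlap = 10L,
                          max_mismatch_rate = 0.04) {
  classify_reads(read, lib, min_overlap, max_mismatch_rate)
}

#' Assign reads to genomic features by full-length placement
#'
#' Near-exact ungapped placement of each read on the circular genome (both
#' strands, wrap-aware through the doubled sequence), then assignment to
#' the feature covering the majority of the placement. Used for abundance
#' tables; junction-spanning reads generally fail full-length placement
#' and stay UNASSIGNED here.
#'
#' @param reads Character vector of read sequences or a [read_fastq()]
#'   list.
#' @param genome A [circular_genome()].
#' @param features A [feature_table()].
#' @param min_match Minimum read length considered (>= 20).
#' @param max_mismatch_rate Maximum substitution rate over the full read.
#' @param exclude_types Feature types never assigned to; container spans
#'   (introns holding embedded genes) and derived annotations are excluded
#'   so reads land on the gene regions the abundance table is about.
#' @return A `data.frame`: `read_id`, `outcome`, `feature_id`, `pos`,
#'   `strand`, `mismatches`.
#' @export
assign_reads_to_features <- function(reads, genome, features,
                                     min_match = 20L,
                                     max_mismatch_rate = 0.04,
                                     exclude_types = c("intron", "IGR",
                                                       "repeat")) {
  if (min_match < 20L) stop("min_match must be >= 20")
  features <- features[!features$type %in% exclude_types, , drop = FALSE]
  if (is.list(reads) && !is.null(reads$seq)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("read_%d", seq_along(seqs))
  }
  n <- length(seqs)
  out <- data.frame(read_id = ids, outcome = rep("UNASSIGNED", n),
                    feature_id = NA_character_, pos = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  long <- nchar(seqs) >= min_match
  if (!any(long)) return(out)
  pl <- place_reads_cpp(toupper(seqs[long]), genome$sequence, TRUE,
                        max_mismatch_rate)
  L <- genome$length
  fl <- feature_length(genome, features)
  wl <- which(long)
  for (j in seq_along(wl)) {
    i <- wl[j]
    if (!pl$found[j]) next
    if (pl$tie[j]) { out$outcome[i] <- "AMBIGUOUS"; next }
    p <- pl$pos[j]; rl <- nchar(seqs[i])
    # circular overlap of read span [p, p+rl) with each feature
    ov <- vapply(seq_len(nrow(features)), function(f) {
      ds <- (features$start[f] - p) %% L
      # overlap of [0, rl) with [ds, ds + fl[f]) on the circle
      o1 <- max(0L, min(rl, ds + fl[f]) - ds)
      ds2 <- ds - L
      o2 <- max(0L, min(rl, ds2 + fl[f]) - max(0L, ds2))
      max(o1, o2)
    }, numeric(1))
    if (max(ov) <= 0) next
    cand <- which(ov == max(ov))
    if (length(cand) > 1L) {
      # prefer strand-concordant features
      conc <- cand[features$strand[cand] == pl$strand[j]]
      if (length(conc) >= 1L) cand <- conc
    }
    if (length(cand) > 1L) { out$outcome[i] <- "AMBIGUOUS"; next }
    out$outcome[i] <- "ASSIGNED"
    out$feature_id[i] <- features$id[cand]
    out$pos[i] <- p
    out$strand[i] <- pl$strand[j]
    out$mismatches[i] <- pl$mismatches[j]
  }
  out
}

#' Tabulate classification outcomes
#'
#' Bookkeeping over junction-level (and optionally feature-level)
#' assignments. The conservation invariant holds by construction: summed
#' category counts + feature-assigned + AMBIGUOUS + UNASSIGNED equals the
#' number of input reads (reads junction-UNASSIGNED but feature-ASSIGNED
#' count once, as feature-assigned).
#'
#' @param assignments Output of [classify_reads()].
#' @param feature_assignments Optional output of
#'   [assign_reads_to_features()] on the same reads (typically on the
#'   junction-unassigned subset; matched by `read_id`).
#' @return An object of class `classification_counts`: list with
#'   `junction_counts` (data.frame intron_id x category), `feature_counts`,
#'   `n_ambiguous`, `n_unassigned`, `n_feature_assigned`, `total`.
#' @export
count_by_category <- function(assignments, feature_assignments = NULL) {
  a <- assignments
  asg <- a[a$outcome == "ASSIGNED", , drop = FALSE]
  jc <- if (nrow(asg) == 0L) {
    data.frame(intron_id = character(0), category = character(0),
               donor_offset = character(0), reads = integer(0),
               stringsAsFactors = FALSE)
  } else {
    key <- data.frame(
      intron_id = as.character(asg$intron_id),
      category = as.character(asg$category),
      donor_offset = ifelse(is.na(asg$donor_offset), "",
                            as.character(asg$donor_offset)),
      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(reads = seq_len(nrow(asg))),
                            by = key, FUN = length)
    agg$reads <- as.integer(agg$reads)
    agg[order(agg$intron_id, agg$category), , drop = FALSE]
  }
  amb <- sum(a$outcome == "AMBIGUOUS")
  una_ids <- a$read_id[a$outcome == "UNASSIGNED"]
  n_feat <- 0L
  fc <- data.frame(feature_id = character(0), reads = integer(0),
                   stringsAsFactors = FALSE)
  if (!is.null(feature_assignments)) {
    f <- feature_assignments
    f <- f[f$read_id %in% una_ids & f$outcome == "ASSIGNED", , drop = FALSE]
    n_feat <- nrow(f)
    if (n_feat > 0L) {
      fc <- stats::aggregate(list(reads = f$read_id),
                             by = list(feature_id = f$feature_id),
                             FUN = length)
    }
    una_ids <- setdiff(una_ids, f$read_id)
  }
  structure(list(junction_counts = jc, feature_counts = fc,
                 n_ambiguous = amb, n_unassigned = length(una_ids),
                 n_feature_assigned = n_feat, total = nrow(a)),
            class = "classification_counts")
}

#' @export
print.classification_counts <- function(x, ...) {
  cat(sprintf("<classification_counts> %d reads: %d junction-assigned, %d feature-assigned, %d ambiguous, %d unassigned\n",
              x$total, sum(x$junction_counts$reads), x$n_feature_assigned,
              x$n_ambiguous, x$n_unassigned))
  if (nrow(x$junction_counts) > 0) print(x$junction_counts, row.names = FALSE)
  invisible(x)
}

#' Detect back-splicing support in long sequences
#'
#' A sequence (amplicon or long read) supports back-splicing iff it
#' contains BOTH the exon-ligation (E1E2) context and the permuted genomic
#' contiguity context (exon-2 3' end running into the linker), each
#' covered with at least `m` nucleotides on both sides of its junction
#' point. Either alone is insufficient: exon ligation is equally produced
#' by cis-splicing, and permuted contiguity is equally present in the
#' linear permuted precursor. Only their co-occurrence on one continuous
#' molecule pins down the circular intermediate. Circular molecules should
#' be presented as their doubled linear sequence.
#'
#' @param sequences Character vector of sequences (DNA alphabet; both
#'   strands are searched).
#' @param intron An [intron_model()].
#' @param genome A [circular_genome()].
#' @param k Flank length used to build the diagnostic contexts.
#' @param m Minimum flank nucleotides required each side (<= k); matching
#'   of the central `2m` window is exact (amplicons are Sanger-grade).
#' @return A list with `n_support` and `evidence` (data.frame with
#'   per-sequence logicals `has_e1e2`, `has_permuted`, `supports`).
#' @export
detect_backsplice_support <- function(sequences, intron, genome, k = 25L,
                                      m = 10L) {
  stopifnot(m <= k)
  jx <- enumerate_junctions(genome, intron, k = k)
  core <- function(cat) {
    r <- jx[jx$category == cat, ]
    paste0(substr(r$left_flank, k - m + 1L, k), substr(r$right_flank, 1L, m))
  }
  e1e2 <- core("E1E2_LIGATION")
  perm <- core("PERMUTED_GENOMIC")
  seqs <- toupper(sequences)
  has <- function(s, pat) {
    grepl(pat, s, fixed = TRUE) || grepl(revcomp(pat), s, fixed = TRUE)
  }
  ev <- data.frame(
    has_e1e2 = vapply(seqs, has, logical(1), pat = e1e2,
                      USE.NAMES = FALSE),
    has_permuted = vapply(seqs, has, logical(1), pat = perm,
                          USE.NAMES = FALSE))
  ev$supports <- ev$has_e1e2 & ev$has_permuted
  list(n_support = sum(ev$supports), evidence = ev)
}
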