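#' Group I intron model
#'
#' Describes one group I intron on a circular genome by its splice-site
#' coordinates. The intron runs from `five_ss` (first intron nucleotide)
#' to `three_ss` (first nucleotide of the downstream exon), circularly;
#' for the giant ND5 intron this walk covers most of the genome, wrapping
#' through the origin. The terminal intron residue (omega) is read off the
#' genome: canonical group I introns end in G (required for splicing step
#' 2 chemistry at the G-binding site and for intron circularization); the
#' giant ND5 intron ends in A, which blocks circularization but not exon
#' ligation.
#'
#' @param genome A [circular_genome()].
#' @param id Intron identifier; by field convention host gene plus the
#'   1-based insertion position in the host CDS (e.g. "ND5-717").
#' @param five_ss Genome position (0-based) of the first intron nucleotide.
#' @param three_ss Genome position immediately after the last intron
#'   nucleotide, i.e. the first nucleotide of exon 2.
#' @param exon1_span,exon2_span Length-2 integer vectors `c(start, end)`
#'   (0-based half-open, modular) of the host exons. `exon1_span` must end
#'   at `five_ss` and `exon2_span` must start at `three_ss`.
#' @param host_gene Host gene name (metadata).
#' @param insertion_pos 1-based insertion position in the host CDS
#'   (metadata; coordinates are authoritative).
#' @param p8_span Optional `c(start, end)` genome interval of the P8
#'   peripheral insertion.
#' @param embedded_ids Ids of features lying inside the intron.
#' @return An object of class `intron_model`.
#' @export
intron_model <- function(genome, id, five_ss, three_ss,
                         exon1_span, exon2_span,
                         host_gene = NA_character_,
                         insertion_pos = NA_integer_,
                         p8_span = NULL, embedded_ids = character(0)) {
  five_ss <- .check_pos(genome, five_ss, "five_ss")
  three_ss <- .check_pos(genome, three_ss, "three_ss")
  stopifnot(length(exon1_span) == 2L, length(exon2_span) == 2L)
  if (exon1_span[2L] %% genome$length != five_ss)
    stop("exon1_span must end at five_ss")
  if (exon2_span[1L] %% genome$length != three_ss)
    stop("exon2_span must start at three_ss")
  omega <- if (three_ss == five_ss) NA_character_ else
    subsequence(genome, (three_ss - 1L) %% genome$length, three_ss)
  structure(
    list(id = id, host_gene = host_gene, insertion_pos = insertion_pos,
         five_ss = five_ss, three_ss = three_ss,
         exon1_span = as.integer(exon1_span),
         exon2_span = as.integer(exon2_span),
         omega = omega, exo_g = "G", p8_span = p8_span,
         embedded_ids = embedded_ids),
    class = "intron_model")
}

#' Intron length (nucleotides)
#' @param genome A [circular_genome()].
#' @param intron An [intron_model()].
#' @export
intron_length <- function(genome, intron) {
  circular_distance(genome, intron$five_ss, intron$three_ss)
}

#' Validate an intron model against its genome
#'
#' Runs consistency checks and chemistry expectations. A non-G terminal
#' residue (omega) is a warning, not a failure: the giant ND5 intron ends
#' in A yet still ligates its exons; what an omega-A terminus does forbid
#' is intron circularization (see [circularize_intron()]).
#'
#' @param genome A [circular_genome()].
#' @param intron An [intron_model()].
#' @param features Optional [feature_table()]; embedded features named in
#'   `intron$embedded_ids` are then checked to lie wholly inside the intron.
#' @return A `data.frame` with columns `check`, `status`
#'   ("pass"/"warn"/"fail") and `message`. Never throws for coordinate
#'   inconsistencies; those become "fail" rows.
#' @export
validate_intron <- function(genome, intron, features = NULL) {
  rows <- list()
  add <- function(check, status, message)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, status = status,
                                             message = message,
                                             stringsAsFactors = FALSE)
  L <- genome$length
  ok_coord <- intron$five_ss >= 0L && intron$five_ss < L &&
    intron$three_ss >= 0L && intron$three_ss < L
  add("coordinates", if (ok_coord) "pass" else "fail",
      sprintf("5'SS=%d, 3'SS=%d on %d bp genome",
              intron$five_ss, intron$three_ss, L))
  if (ok_coord) {
    ilen <- circular_distance(genome, intron$five_ss, intron$three_ss)
    if (ilen == 0L) {
      add("length", "fail", "zero-length intron (three_ss == five_ss)")
    } else {
      add("length", "pass", sprintf("intron length %d nt", ilen))
      gom <- subsequence(genome, (intron$three_ss - 1L) %% L,
                         intron$three_ss)
      add("omega_consistent", if (identical(gom, intron$omega)) "pass"
          else "fail",
          sprintf("stored omega '%s', genome has '%s'", intron$omega, gom))
      add("omega_is_G", if (identical(gom, "G")) "pass" else "warn",
          if (identical(gom, "G")) "terminal residue is the canonical omega-G"
          else sprintf("terminal residue is %s, not omega-G", gom))
    }
  }
  n_emb <- length(intron$embedded_ids)
  if (!is.null(features) && n_emb > 0L) {
    inside <- vapply(intron$embedded_ids, function(fid) {
      i <- match(fid, features$id)
      if (is.na(i)) return(FALSE)
      ds <- circular_distance(genome, intron$five_ss, features$start[i])
      de <- circular_distance(genome, intron$five_ss,
                              (features$end[i] - 1L) %% L)
      ilen <- circular_distance(genome, intron$five_ss, intron$three_ss)
      ds < ilen && de < ilen && ds <= de
    }, logical(1))
    add("embedded_features",
        if (all(inside)) "pass" else "fail",
        sprintf("%d/%d embedded features lie wholly within the intron",
                sum(inside), n_emb))
  } else {
    add("embedded_features", "pass",
        sprintf("%d embedded feature ids declared", n_emb))
  }
  do.call(rbind, rows)
}

#' Transcript model: ordered genome segments walked 5' to 3'
#'
#' @param genome A [circular_genome()].
#' @param segments List of length-2 vectors `c(start, end)` (0-based
#'   half-open modular genome intervals) walked in order.
#' @param topology "linear" or "circular". A circular transcript's
#'   junction between its last and first segment is real (the molecule is
#'   covalently closed there).
#' @return An object of class `transcript_model` with the concatenated
#'   `sequence`.
#' @export
transcript_model <- function(genome, segments, topology = c("linear",
                                                            "circular")) {
  topology <- match.arg(topology)
  segs <- lapply(segments, as.integer)
  seq <- paste(vapply(segs, function(s)
    subsequence(genome, s[1L], s[2L]), character(1)), collapse = "")
  structure(list(segments = segs, sequence = seq, topology = topology),
            class = "transcript_model")
}

#' RNA species: a transcript molecule with provenance
#'
#' @param species_class One of PRECURSOR_CONVENTIONAL, PRECURSOR_PERMUTED,
#'   MRNA_LIGATED, INTRON_LINEAR, INTRON_CIRCLE_FULL,
#'   INTRON_CIRCLE_TRUNCATED, CIRC_INTERMEDIATE, INTRON_5P_SEGMENT,
#'   INTRON_3P_SEGMENT, GENIC_OTHER.
#' @param transcript A [transcript_model()].
#' @param extra_5p Non-genome-encoded nucleotides prepended to the 5' end;
#'   only the single exogenous G of excised 5'-containing intron products.
#' @param source_intron Intron id or `NA`.
#' @param junctions List of `list(category=, pos=, donor_offset=)`:
#'   diagnostic junction positions in molecule coordinates (`pos` = number
#'   of nucleotides 5' of the junction in the full molecule sequence,
#'   `extra_5p` included; a circular molecule's closure junction has
#'   `pos = 0`).
#' @return An object of class `rna_species`.
#' @export
rna_species <- function(species_class, transcript, extra_5p = "",
                        source_intron = NA_character_, junctions = list()) {
  classes <- c("PRECURSOR_CONVENTIONAL", "PRECURSOR_PERMUTED",
               "MRNA_LIGATED", "INTRON_LINEAR", "INTRON_CIRCLE_FULL",
               "INTRON_CIRCLE_TRUNCATED", "CIRC_INTERMEDIATE",
               "INTRON_5P_SEGMENT", "INTRON_3P_SEGMENT", "GENIC_OTHER")
  if (!species_class %in% classes)
    stop("unknown species class: ", species_class)
  if (nzchar(extra_5p) &&
      !species_class %in% c("INTRON_LINEAR", "INTRON_5P_SEGMENT"))
    stop("extra_5p (exo-G) is only carried by INTRON_LINEAR and ",
         "INTRON_5P_SEGMENT species")
  structure(list(species_class = species_class, transcript = transcript,
                 extra_5p = extra_5p, source_intron = source_intron,
                 junctions = junctions),
            class = "rna_species")
}

#' Full molecule sequence of an RNA species (extra 5' G included)
#' @param species An [rna_species()].
#' @export
species_sequence <- function(species) {
  paste0(species$extra_5p, species$transcript$sequence)
}

#' Molecule length of an RNA species
#' @param species An [rna_species()].
#' @export
species_length <- function(species) nchar(species_sequence(species))

#' Build the conventional (cis-splicing) precursor
#'
#' One linear unprocessed transcript: an exon-1 tail, the entire intron,
#' and an exon-2 head. For the giant ND5 intron this molecule would be
#' ~20 kb (the whole genome minus the exons' far ends), which is why
#' conventional cis-splicing of that intron is implausible in vivo; the
#' builder nevertheless supports it for any intron.
#'
#' @param genome A [circular_genome()].
#' @param intron An [intron_model()].
#' @param pad Exonic context length carried on both sides (> 0, at most
#'   the host exon lengths).
#' @return An [rna_species()] of class PRECURSOR_CONVENTIONAL with
#'   UNSPLICED_5SS and UNSPLICED_3SS junctions recorded.
#' @export
build_conventional_precursor <- function(genome, intron, pad) {
  L <- genome$length
  if (!is.numeric(pad) || pad < 1L) stop("pad must be a positive count")
  pad <- as.integer(pad)
  e1len <- (intron$exon1_span[2L] - intron$exon1_span[1L]) %% L
  e2len <- (intron$exon2_span[2L] - intron$exon2_span[1L]) %% L
  if (pad > e1len || pad > e2len)
    stop("pad exceeds available exon length")
  ilen <- intron_length(genome, intron)
  if (ilen == 0L) stop("zero-length intron")
  segs <- list(c((intron$five_ss - pad) %% L, intron$five_ss),
               c(intron$five_ss, intron$three_ss),
               c(intron$three_ss, (intron$three_ss + pad) %% L))
  tx <- transcript_model(genome, segs, "linear")
  rna_species("PRECURSOR_CONVENTIONAL", tx,
              source_intron = intron$id,
              junctions = list(
                list(category = "UNSPLICED_5SS", pos = pad),
                list(category = "UNSPLICED_3SS", pos = pad + ilen)))
}

#' Build the permuted (back-splicing) precursor
#'
#' On the circular genome, exon 2 of the giant-intron host gene lies
#' upstream-adjacent of exon 1 (across a short genomic linker). A single
#' short primary transcript starting inside the intron's 3' region and
#' ending inside its 5' region therefore carries the permuted order
#' `[intron 3' tail][exon 2][linker][exon 1][intron 5' head]` - the
#' natural permuted intron-exon (PIE) arrangement whose splicing
#' circularizes the exons.
#'
#' @param genome A [circular_genome()].
#' @param intron An [intron_model()].
#' @param tx_start Transcription start: genome position strictly inside
#'   the intron, upstream of `three_ss` (the intron's 3' region).
#' @param tx_end Transcription end (exclusive): strictly inside the
#'   intron, downstream of `five_ss` (the intron's 5' region).
#' @return An [rna_species()] of class PRECURSOR_PERMUTED with
#'   UNSPLICED_3SS, PERMUTED_GENOMIC and UNSPLICED_5SS junctions recorded.
#' @export
build_permuted_precursor <- function(genome, intron, tx_start, tx_end) {
  L <- genome$length
  tx_start <- .check_pos(genome, tx_start, "tx_start")
  tx_end <- .check_pos(genome, tx_end, "tx_end")
  ilen <- intron_length(genome, intron)
  if (ilen == 0L) stop("zero-length intron")
  d_in_start <- circular_distance(genome, intron$five_ss, tx_start)
  d_in_end <- circular_distance(genome, intron$five_ss, tx_end)
  if (d_in_start <= 0L || d_in_start >= ilen)
    stop("tx_start must lie strictly inside the intron")
  if (d_in_end <= 0L || d_in_end >= ilen)
    stop("tx_end must lie strictly inside the intron")
  d3 <- circular_distance(genome, tx_start, intron$three_ss)
  d5 <- circular_distance(genome, tx_start, intron$five_ss)
  dend <- circular_distance(genome, tx_start, tx_end)
  if (!(d3 < d5 && d5 < dend))
    stop("ordering violated: the walk from tx_start must pass three_ss, ",
         "the exons, then five_ss before tx_end")
  e2e <- intron$exon2_span[2L] %% L
  e1s <- intron$exon1_span[1L] %% L
  segs <- list(c(tx_start, intron$three_ss),
               c(intron$three_ss, e2e))
  if (e2e != e1s) segs <- c(segs, list(c(e2e, e1s)))
  segs <- c(segs, list(c(e1s, intron$five_ss),
                       c(intron$five_ss, tx_end)))
  tx <- transcript_model(genome, segs, "linear")
  rna_species("PRECURSOR_PERMUTED", tx, source_intron = intron$id,
              junctions = list(
                list(category = "UNSPLICED_3SS", pos = d3),
                list(category = "PERMUTED_GENOMIC",
                     pos = circular_distance(genome, tx_start, e2e)),
                list(category = "UNSPLICED_5SS", pos = d5)))
}

#' Cis-splice a conventional precursor
#'
#' The two-transesterification group I pathway: an exogenous guanosine
#' attacks the 5' splice site and stays covalently attached to the excised
#' intron's 5' end; exon 1's free 3'-OH then attacks the 3' splice site,
#' ligating the exons. Nucleotide bookkeeping is exact:
#' `len(precursor) = len(mRNA) + (len(intron product) - 1)` (the -1 is the
#' non-encoded exo-G).
#'
#' @param precursor An [rna_species()] of class PRECURSOR_CONVENTIONAL
#'   built for this intron.
#' @param intron The matching [intron_model()].
#' @param genome The [circular_genome()].
#' @return A list with `mrna` (MRNA_LIGATED, with its E1E2_LIGATION
#'   junction) and `intron_rna` (INTRON_LINEAR with `extra_5p = "G"`).
#' @export
cis_splice <- function(precursor, intron, genome) {
  if (!inherits(precursor, "rna_species") ||
      precursor$species_class != "PRECURSOR_CONVENTIONAL" ||
      !identical(precursor$source_intron, intron$id))
    stop("precursor must be a PRECURSOR_CONVENTIONAL built for this intron")
  segs <- precursor$transcript$segments
  mrna_tx <- transcript_model(genome, segs[c(1L, 3L)], "linear")
  pad <- (segs[[1L]][2L] - segs[[1L]][1L]) %% genome$length
  mrna <- rna_species("MRNA_LIGATED", mrna_tx, source_intron = intron$id,
                      junctions = list(list(category = "E1E2_LIGATION",
                                            pos = pad)))
  intron_tx <- transcript_model(genome, segs[2L], "linear")
  intron_rna <- rna_species("INTRON_LINEAR", intron_tx, extra_5p = "G",
                            source_intron = intron$id)
  list(mrna = mrna, intron_rna = intron_rna)
}

#' Back-splice a permuted precursor
#'
#' Splicing chemistry identical to [cis_splice()], but because the
#' precursor is permuted (exon 2 before exon 1), exon ligation closes the
#' exons into a covalently circular RNA - the hallmark intermediate of
#' back-splicing. The intron is released in two pieces (its 3' tail and
#' its exo-G-capped 5' head); the full-length intron is never produced as
#' one molecule. Bookkeeping:
#' `len(precursor) = len(circle) + len(3' segment) + (len(5' segment) - 1)`.
#'
#' @param precursor An [rna_species()] of class PRECURSOR_PERMUTED built
#'   for this intron.
#' @param intron The matching [intron_model()].
#' @param genome The [circular_genome()].
#' @return A list with `circle` (CIRC_INTERMEDIATE: exon2 + linker + exon1
#'   closed at the E1E2_LIGATION junction), `seg3p` (INTRON_3P_SEGMENT)
#'   and `seg5p` (INTRON_5P_SEGMENT, `extra_5p = "G"`).
#' @export
back_splice <- function(precursor, intron, genome) {
  if (!inherits(precursor, "rna_species") ||
      precursor$species_class != "PRECURSOR_PERMUTED" ||
      !identical(precursor$source_intron, intron$id))
    stop("precursor must be a PRECURSOR_PERMUTED built for this intron")
  L <- genome$length
  segs <- precursor$transcript$segments
  n <- length(segs)
  tx_start <- segs[[1L]][1L]
  tx_end <- segs[[n]][2L]
  exon_segs <- segs[seq.int(2L, n - 1L)]
  circle_tx <- transcript_model(genome, exon_segs, "circular")
  e2e <- intron$exon2_span[2L] %% L
  circle <- rna_species(
    "CIRC_INTERMEDIATE", circle_tx, source_intron = intron$id,
    junctions = list(
      list(category = "E1E2_LIGATION", pos = 0L),
      list(category = "PERMUTED_GENOMIC",
           pos = circular_distance(genome, intron$three_ss, e2e))))
  seg3p <- rna_species("INTRON_3P_SEGMENT",
                       transcript_model(genome, segs[1L], "linear"),
                       source_intron = intron$id)
  seg5p <- rna_species("INTRON_5P_SEGMENT",
                       transcript_model(genome, segs[n], "linear"),
                       extra_5p = "G", source_intron = intron$id)
  list(circle = circle, seg3p = seg3p, seg5p = seg5p)
}

#' Circularize an excised linear intron
#'
#' Joins the intron's 3' terminus (omega) to an internal donor site at the
#' 5' end, after shedding the exo-G. Full-length circles use donor offset
#' 0; Sanger reads of real intron circles also show truncated circles from
#' donor sites downstream of the 5' end. The chemistry requires a terminal
#' omega-G: an intron ending in A (the giant ND5 intron) refuses to
#' circularize unless `force = TRUE`.
#'
#' @param intron_product An [rna_species()] of class INTRON_LINEAR.
#' @param donor_offset 0-based offset from the intron start (exo-G
#'   removed); 0 gives a full-length circle.
#' @param force Override the omega-G requirement (for what-if analyses).
#' @return An [rna_species()] of class INTRON_CIRCLE_FULL (offset 0) or
#'   INTRON_CIRCLE_TRUNCATED, of length `intron length - donor_offset`,
#'   carrying an INTRON_CIRCLE junction at the closure.
#' @export
circularize_intron <- function(intron_product, donor_offset = 0L,
                               force = FALSE) {
  if (!inherits(intron_product, "rna_species") ||
      intron_product$species_class != "INTRON_LINEAR")
    stop("intron_product must be an INTRON_LINEAR species")
  iseq <- intron_product$transcript$sequence  # exo-G excluded by design
  ilen <- nchar(iseq)
  omega <- substr(iseq, ilen, ilen)
  if (!identical(omega, "G") && !force) {
    stop(structure(class = c("chemistry_error", "error", "condition"),
                   list(message = sprintf(
                     "terminal residue is %s, not omega-G: intron circularization requires omega-G (use force = TRUE to override)",
                     omega), call = sys.call(-1L))))
  }
  donor_offset <- as.integer(donor_offset)
  if (donor_offset < 0L || donor_offset >= ilen)
    stop("donor_offset must be in [0, intron length)")
  circ_seq <- substr(iseq, donor_offset + 1L, ilen)
  tx <- structure(list(segments = list(), sequence = circ_seq,
                       topology = "circular"), class = "transcript_model")
  # keep genomic provenance when the intron is a single genome segment
  segs <- intron_product$transcript$segments
  if (length(segs) == 1L) {
    tx$segments <- list(c((segs[[1L]][1L] + donor_offset), segs[[1L]][2L]))
  }
  rna_species(if (donor_offset == 0L) "INTRON_CIRCLE_FULL"
              else "INTRON_CIRCLE_TRUNCATED",
              tx, source_intron = intron_product$source_intron,
              junctions = list(list(category = "INTRON_CIRCLE", pos = 0L,
                                    donor_offset = donor_offset)))
}

#' Enumerate diagnostic splice junctions for an intron
#'
#' Emits the 2k-nucleotide sequence contexts that distinguish the splicing
#' states observable in junction-spanning reads:
#' \describe{
#'   \item{E1E2_LIGATION}{exon-1 3' terminus joined to exon-2 5' start -
#'     produced identically by cis-splicing and by back-splicing, which is
#'     why exon-ligation reads alone cannot discriminate the pathways.}
#'   \item{UNSPLICED_5SS}{exon-1 tail running into the intron head.}
#'   \item{UNSPLICED_3SS}{intron tail running into the exon-2 head.}
#'   \item{INTRON_CIRCLE}{intron 3' terminus joined to the donor site at
#'     `offset` nucleotides into the intron (one per requested offset).}
#'   \item{PERMUTED_GENOMIC}{exon-2 3' end running into its downstream
#'     genomic context (the linker) - plain genomic contiguity, present in
#'     both the permuted precursor and the circular intermediate.}
#' }
#'
#' @param genome A [circular_genome()].
#' @param intron An [intron_model()].
#' @param k Flank length on each side of the junction (>= 6).
#' @param circle_offsets Integer vector of intron-circle donor offsets.
#' @return A `data.frame` with columns `junction_id`, `intron_id`,
#'   `category`, `donor_offset`, `left_flank`, `right_flank` (each exactly
#'   `k` nt).
#' @export
enumerate_junctions <- function(genome, intron, k = 25L,
                                circle_offsets = integer(0)) {
  k <- as.integer(k)
  if (k < 6L) stop("k must be >= 6")
  L <- genome$length
  ilen <- intron_length(genome, intron)
  e1len <- (intron$exon1_span[2L] - intron$exon1_span[1L]) %% L
  e2len <- (intron$exon2_span[2L] - intron$exon2_span[1L]) %% L
  if (e1len < k || e2len < k) stop("exon shorter than flank length k")
  if (ilen < k) stop("intron shorter than flank length k")
  p5 <- intron$five_ss; p3 <- intron$three_ss
  e2e <- intron$exon2_span[2L] %% L
  sub <- function(a, b) subsequence(genome, a %% L, b %% L)
  exon1_tail <- sub(p5 - k, p5)
  exon2_head <- sub(p3, p3 + k)
  intron_head <- sub(p5, p5 + k)
  intron_tail <- sub(p3 - k, p3)
  rows <- list(
    data.frame(category = "E1E2_LIGATION", donor_offset = NA_integer_,
               left_flank = exon1_tail, right_flank = exon2_head,
               stringsAsFactors = FALSE),
    data.frame(category = "UNSPLICED_5SS", donor_offset = NA_integer_,
               left_flank = exon1_tail, right_flank = intron_head,
               stringsAsFactors = FALSE),
    data.frame(category = "UNSPLICED_3SS", donor_offset = NA_integer_,
               left_flank = intron_tail, right_flank = exon2_head,
               stringsAsFactors = FALSE),
    data.frame(category = "PERMUTED_GENOMIC", donor_offset = NA_integer_,
               left_flank = sub(e2e - k, e2e), right_flank = sub(e2e, e2e + k),
               stringsAsFactors = FALSE))
  for (d in as.integer(circle_offsets)) {
    if (d < 0L || d + k > ilen)
      stop("circle offset out of range for this intron")
    rows[[length(rows) + 1L]] <- data.frame(
      category = "INTRON_CIRCLE", donor_offset = d,
      left_flank = intron_tail,
      right_flank = sub(p5 + d, p5 + d + k),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$intron_id <- intron$id
  out$junction_id <- ifelse(is.na(out$donor_offset),
                            paste(out$intron_id, out$category, sep = ":"),
                            paste(out$intron_id, out$category,
                                  out$donor_offset, sep = ":"))
  out[, c("junction_id", "intron_id", "category", "donor_offset",
          "left_flank", "right_flank")]
}

#' Extract junction contexts from a built RNA molecule
#'
#' Reads the 2k context around each junction recorded on a species, from
#' the molecule sequence itself (wrapping across the closure for circular
#' molecules). Used to check that molecule-level junctions agree with the
#' genome-level contexts from [enumerate_junctions()].
#'
#' @param species An [rna_species()] with recorded junctions.
#' @param k Flank length.
#' @return A `data.frame` with `category`, `left_flank`, `right_flank`.
#' @export
species_junction_contexts <- function(species, k = 25L) {
  seq <- species_sequence(species)
  n <- nchar(seq)
  circ <- species$transcript$topology == "circular"
  dd <- if (circ) paste0(seq, seq, seq) else seq
  off <- if (circ) n else 0L
  rows <- lapply(species$junctions, function(j) {
    p <- j$pos + off
    if (!circ && (j$pos < k || j$pos + k > n)) return(NULL)
    data.frame(category = j$category,
               left_flank = substr(dd, p - k + 1L, p),
               right_flank = substr(dd, p + 1L, p + k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(0), left_flank = character(0),
                      right_flank = character(0), stringsAsFactors = FALSE)
  out
}
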