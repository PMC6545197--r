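#' Simulation configuration
#'
#' Defines the synthetic study: a corallimorpharian-like circular
#' mitochondrial genome whose ND5-like gene is split by a giant group I
#' intron spanning most of the circle (exon 2 upstream-adjacent of exon 1
#' across a short linker), a COI-like gene inside the giant intron
#' carrying a small intron with an internal ORF (HEG), an antisense ORF,
#' per-unit transcript abundances spread over three orders of magnitude
#' with rRNA-like units 5-20x typical mRNAs, intron-specific splicing
#' efficiencies, and Ion-Torrent-like single-end ~200 nt reads with
#' substitution errors.
#'
#' @param seed Root seed; per-stage streams are derived from it so stages
#'   are independently reproducible.
#' @param genome_length Genome size in nt (the full layout needs >= 21000;
#'   smaller values give a config error).
#' @param n_reads Number of simulated reads.
#' @param read_length Read length in nt.
#' @param substitution_rate Per-base substitution error rate (no indels:
#'   homopolymer errors are a documented non-goal, matching the ungapped
#'   classifier).
#' @param at_content A+T fraction of the random background (mtDNA-like).
#' @param spliced_fraction_giant Fraction of giant-intron (back-splicing)
#'   transcription-unit molecules that are spliced.
#' @param spliced_fraction_small Fraction of small-intron transcripts
#'   spliced.
#' @param circ_fraction_small Fraction of excised small-intron molecules
#'   that circularize.
#' @param circle_offsets_small Donor offsets of small-intron circles
#'   (0 = full length).
#' @param omega_giant,omega_small Terminal intron residues (the giant
#'   intron's omega-A versus the small intron's canonical omega-G).
#' @param tx_pad Nucleotides of intron sequence carried on each end of the
#'   permuted precursor beyond the splice sites. The termini of the real
#'   permuted transcript are not experimentally determined, only its
#'   approximate total size (~3000 nt); the default of 400 nt per side
#'   puts the simulated precursor at ~2.9 kb and keeps every diagnostic
#'   junction far enough from the molecule ends that junction-spanning
#'   reads sample all of them evenly.
#' @param precursor_pad_small Exon context carried by the conventional
#'   small-intron precursor.
#' @param weights Named list of per-transcription-unit relative molecule
#'   abundances.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 21000L,
                       n_reads = 50000L, read_length = 200L,
                       substitution_rate = 0.01, at_content = 0.62,
                       spliced_fraction_giant = 0.30,
                       spliced_fraction_small = 0.98,
                       circ_fraction_small = 0.2,
                       circle_offsets_small = c(0L, 50L),
                       omega_giant = "A", omega_small = "G",
                       tx_pad = 400L, precursor_pad_small = 250L,
                       weights = NULL) {
  if (is.null(weights))
    weights <- list(rns = 400, rnl = 600, ND5 = 40, COI = 120, ND1 = 30,
                    CYTB = 90, ATP6 = 15, ND2 = 60, ND4 = 8, HEG = 0.6,
                    aORF = 8)
  stopifnot(all(unlist(weights) > 0),
            spliced_fraction_giant >= 0, spliced_fraction_giant <= 1,
            spliced_fraction_small >= 0, spliced_fraction_small <= 1,
            circ_fraction_small >= 0, circ_fraction_small <= 1,
            n_reads >= 1, read_length >= 30,
            substitution_rate >= 0, substitution_rate < 0.2)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 at_content = at_content,
                 spliced_fraction_giant = spliced_fraction_giant,
                 spliced_fraction_small = spliced_fraction_small,
                 circ_fraction_small = circ_fraction_small,
                 circle_offsets_small = as.integer(circle_offsets_small),
                 omega_giant = omega_giant, omega_small = omega_small,
                 tx_pad = as.integer(tx_pad),
                 precursor_pad_small = as.integer(precursor_pad_small),
                 weights = weights),
            class = "sim_config")
}

# derived per-stage seed, kept below 2^31
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 16807) %% 2147483647)
}

.random_dna <- function(n, at = 0.62) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# overwrite genome string positions [start, start+nchar(what)) (0-based)
.plant <- function(seq, start, what) {
  substr(seq, start + 1L, start + nchar(what)) <- what
  seq
}

.random_orf <- function(n_aa) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  paste0("ATG", paste(sample(codons, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Generate the synthetic circular genome with annotation
#'
#' Deterministic given the config seed. The giant intron spans ~90% of the
#' genome (wrapping through the origin); the printed diagnostic sequences
#' of the real system are planted so string-level checks are meaningful:
#' the ND5-like exon 1 ends `...AGGGT` and exon 2 begins `CCAACT...` (the
#' exon-ligation site reads AGGGU/CCAACU in RNA space), exon 1 initiates
#' with GTG, exon 2 ends with a TAA stop, the giant intron terminates in
#' omega-A and the small intron in omega-G.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` ([circular_genome()]), `features`
#'   ([feature_table()]), `introns` (list of two [intron_model()]s, named
#'   `giant` and `small`) and `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  L <- config$genome_length
  if (L < 21000L)
    stop("config error: the full layout needs genome_length >= 21000 (got ",
         L, ")")
  set.seed(.stage_seed(config$seed, 1L))
  seq <- .random_dna(L, config$at_content)

  # layout (0-based half-open); gaps between elements become IGRs
  nd5_e2 <- c(100L, 1219L)    # exon 2 (downstream exon), upstream in genome
  trnW   <- c(1270L, 1340L)   # linker tRNA between the exons
  nd5_e1 <- c(1450L, 2167L)   # exon 1 (717 nt; intron named after this)
  five_ss <- 2167L; three_ss <- 100L
  rns    <- c(3000L, 4500L)
  rnl    <- c(5000L, 7300L)
  coi_e1 <- c(8000L, 8884L)
  coi_in <- c(8884L, 10084L)
  heg    <- c(9000L, 9900L)
  coi_e2 <- c(10084L, 10800L)
  nd1    <- c(11000L, 11990L)
  cytb   <- c(12500L, 13640L)
  atp6   <- c(14000L, 14699L)
  nd2    <- c(15500L, 16900L)
  aorf   <- c(17550L, 17928L)  # 125 aa + stop on the minus strand
  trnM   <- c(18050L, 18120L)
  rep_a  <- 18300L; rep_b <- 18600L; rep_len <- 123L
  nd4    <- c(19900L, 20900L)

  # plant diagnostic sequence content
  seq <- .plant(seq, nd5_e1[1L], "GTG")                 # ND5 GUG initiation
  seq <- .plant(seq, nd5_e1[2L] - 5L, "AGGGT")          # exon-1 3' terminus
  seq <- .plant(seq, nd5_e2[1L], "CCAACT")              # exon-2 5' start
  seq <- .plant(seq, nd5_e2[2L] - 3L, "TAA")            # exon-2 stop codon
  seq <- .plant(seq, (three_ss - 1L) %% L, config$omega_giant)
  seq <- .plant(seq, coi_in[2L] - 1L, config$omega_small)
  seq <- .plant(seq, coi_e1[1L], "ATG")
  seq <- .plant(seq, heg[1L], "ATG"); seq <- .plant(seq, heg[2L] - 3L, "TAA")
  starts <- c(nd1 = "GTG", cytb = "ATG", atp6 = "GTG", nd2 = "ATG",
              nd4 = "ATG")  # 2/5 GTG-initiated CDS
  for (g in list(nd1, cytb, atp6, nd2, nd4)) {
    seq <- .plant(seq, g[2L] - 3L, "TAA")
  }
  seq <- .plant(seq, nd1[1L], "GTG");  seq <- .plant(seq, cytb[1L], "ATG")
  seq <- .plant(seq, atp6[1L], "GTG"); seq <- .plant(seq, nd2[1L], "ATG")
  seq <- .plant(seq, nd4[1L], "ATG")
  aorf_seq <- .random_orf((aorf[2L] - aorf[1L]) / 3L - 1L)
  seq <- .plant(seq, aorf[1L], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(aorf_seq))))
  motif <- .random_dna(rep_len, config$at_content)
  seq <- .plant(seq, rep_a, motif); seq <- .plant(seq, rep_b, motif)

  genome <- circular_genome(sprintf("synthmito_seed%d", config$seed), seq)
  features <- feature_table(
    id = c("ND5_exon2", "trnW", "ND5_exon1", "ND5-717-intron",
           "rns", "rnl", "COI_exon1", "COI-884-intron", "HEG",
           "COI_exon2", "ND1", "CYTB", "ATP6", "ND2", "aORF", "trnM",
           "ND4"),
    type = c("exon", "tRNA", "exon", "intron", "rRNA", "rRNA", "exon",
             "intron", "ORF", "exon", "CDS", "CDS", "CDS", "CDS", "aORF",
             "tRNA", "CDS"),
    start = c(nd5_e2[1L], trnW[1L], nd5_e1[1L], five_ss, rns[1L], rnl[1L],
              coi_e1[1L], coi_in[1L], heg[1L], coi_e2[1L], nd1[1L],
              cytb[1L], atp6[1L], nd2[1L], aorf[1L], trnM[1L], nd4[1L]),
    end = c(nd5_e2[2L], trnW[2L], nd5_e1[2L], three_ss, rns[2L], rnl[2L],
            coi_e1[2L], coi_in[2L], heg[2L], coi_e2[2L], nd1[2L],
            cytb[2L], atp6[2L], nd2[2L], aorf[2L], trnM[2L], nd4[2L]),
    strand = c(rep("+", 14L), "-", "+", "+"))
  embedded <- c("rns", "rnl", "COI_exon1", "COI-884-intron", "HEG",
                "COI_exon2", "ND1", "CYTB", "ATP6", "ND2", "aORF", "trnM",
                "ND4")
  giant <- intron_model(genome, "ND5-717", five_ss, three_ss,
                        exon1_span = nd5_e1, exon2_span = nd5_e2,
                        host_gene = "ND5", insertion_pos = 717L,
                        p8_span = c(rns[1L], nd4[2L]),
                        embedded_ids = embedded)
  small <- intron_model(genome, "COI-884", coi_in[1L], coi_in[2L],
                        exon1_span = coi_e1, exon2_span = coi_e2,
                        host_gene = "COI", insertion_pos = 884L,
                        embedded_ids = "HEG")
  list(genome = genome, features = features,
       introns = list(giant = giant, small = small), config = config)
}

#' Generate the weighted RNA species pool
#'
#' Emits, per transcription unit, the RNA species implied by the
#' configured splicing parameters. The giant-intron unit transcribes the
#' short permuted precursor; with probability `spliced_fraction_giant` it
#' back-splices into the circular exon intermediate plus the two released
#' intron segments (the full-length giant intron is never one molecule,
#' and its omega-A forbids intron circles). The small-intron unit
#' transcribes a conventional precursor; spliced molecules yield ligated
#' mRNA plus a linear intron, of which `circ_fraction_small` circularize
#' at the configured donor offsets. Embedded genes and the antisense ORF
#' contribute plain transcripts. Weights are relative molecule copy
#' numbers.
#'
#' @param gen Output of [generate_genome()].
#' @return A `data.frame`-less pool: list of entries
#'   `list(name, species, weight)`.
#' @export
generate_transcript_pool <- function(gen) {
  config <- gen$config
  genome <- gen$genome
  giant <- gen$introns$giant
  small <- gen$introns$small
  w <- gen$config$weights
  L <- genome$length
  pool <- list()
  add <- function(name, species, weight) {
    if (weight > 0)
      pool[[length(pool) + 1L]] <<- list(name = name, species = species,
                                         weight = weight)
  }
  # giant-intron unit: permuted precursor, back-splicing
  sfg <- config$spliced_fraction_giant
  tx_start <- (giant$three_ss - config$tx_pad) %% L
  tx_end <- (giant$five_ss + config$tx_pad) %% L
  perm <- build_permuted_precursor(genome, giant, tx_start, tx_end)
  add("ND5_precursor_permuted", perm, w$ND5 * (1 - sfg))
  if (sfg > 0) {
    bs <- back_splice(perm, giant, genome)
    add("ND5_circ_intermediate", bs$circle, w$ND5 * sfg)
    add("ND5_intron_3p_segment", bs$seg3p, w$ND5 * sfg)
    add("ND5_intron_5p_segment", bs$seg5p, w$ND5 * sfg)
  }
  # small-intron unit: conventional precursor, cis-splicing, circles
  sfs <- config$spliced_fraction_small
  conv <- build_conventional_precursor(genome, small,
                                       config$precursor_pad_small)
  add("COI_precursor", conv, w$COI * (1 - sfs))
  if (sfs > 0) {
    cs <- cis_splice(conv, small, genome)
    add("COI_mRNA", cs$mrna, w$COI * sfs)
    cf <- config$circ_fraction_small
    add("COI_intron_linear", cs$intron_rna, w$COI * sfs * (1 - cf))
    offs <- config$circle_offsets_small
    if (cf > 0 && length(offs) > 0) {
      for (d in offs) {
        circ <- circularize_intron(cs$intron_rna, d)
        add(sprintf("COI_intron_circle_%d", d), circ,
            w$COI * sfs * cf / length(offs))
      }
    }
  }
  # plain transcripts of embedded genes and the antisense ORF
  utr <- 30L
  plain <- function(fid, weight, name = fid) {
    i <- match(fid, gen$features$id)
    s <- (gen$features$start[i] - utr) %% L
    e <- (gen$features$end[i] + utr) %% L
    tx <- transcript_model(genome, list(c(s, e)), "linear")
    if (gen$features$strand[i] == "-")
      tx$sequence <- revcomp(tx$sequence)
    add(name, rna_species("GENIC_OTHER", tx), weight)
  }
  plain("rns", w$rns); plain("rnl", w$rnl)
  plain("ND1", w$ND1); plain("CYTB", w$CYTB); plain("ATP6", w$ATP6)
  plain("ND2", w$ND2); plain("ND4", w$ND4)
  plain("HEG", w$HEG); plain("aORF", w$aORF)
  pool
}

#' Simulate single-end reads from the species pool
#'
#' Molecules are drawn proportionally to weight x length (fragmentation
#' yields reads in proportion to molecule mass), fragment starts are
#' uniform along each molecule (uniform mod length on circular molecules,
#' so fragments cross the closure), substitutions hit each base
#' independently at `substitution_rate`, and qualities are a constant "I"
#' (qualities are not used downstream). Linear molecules shorter than the
#' read length, or fragments starting near a linear 3' end, emit shorter
#' reads flagged in the truth table. Deterministic per seed.
#'
#' @param pool Output of [generate_transcript_pool()].
#' @param config The [sim_config()].
#' @return A list with `reads` (list: `id`, `seq`) and `truth`
#'   (data.frame: `read_id`, `source_name`, `source_class`,
#'   `source_intron`, `start`, `length`, `short`, `junctions` - per-read
#'   semicolon-joined `category:left_coverage` entries - `n_errors`,
#'   `error_positions`).
#' @export
simulate_reads <- function(pool, config) {
  set.seed(.stage_seed(config$seed, 2L))
  n <- config$n_reads
  rl <- config$read_length
  mol_seq <- vapply(pool, function(p) species_sequence(p$species),
                    character(1))
  mol_len <- nchar(mol_seq)
  mol_circ <- vapply(pool, function(p)
    p$species$transcript$topology == "circular", logical(1))
  wts <- vapply(pool, function(p) p$weight, numeric(1)) * mol_len
  mol <- sample.int(length(pool), n, replace = TRUE, prob = wts)
  start <- floor(stats::runif(n) * mol_len[mol])  # 0-based
  # sequence extraction (doubled text for circular molecules)
  text <- ifelse(mol_circ, paste0(mol_seq, mol_seq), mol_seq)[mol]
  stop_at <- ifelse(mol_circ[mol], start + rl,
                    pmin(start + rl, mol_len[mol]))
  # circular molecules shorter than the read: cap at one full pass
  stop_at <- pmin(stop_at, ifelse(mol_circ[mol], start + mol_len[mol],
                                  stop_at))
  seqs <- substring(text, start + 1L, stop_at)
  lens <- nchar(seqs)
  # substitution errors
  n_err <- stats::rbinom(n, lens, config$substitution_rate)
  err_pos <- character(n)
  we <- which(n_err > 0L)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G"))
  r3 <- sample.int(3L, sum(n_err[we]), replace = TRUE)
  ei <- 0L
  for (i in we) {
    ps <- sample.int(lens[i], n_err[i])
    s <- seqs[i]
    for (p in ps) {
      ei <- ei + 1L
      substr(s, p, p) <- alt[[substr(s, p, p)]][r3[ei]]
    }
    seqs[i] <- s
    err_pos[i] <- paste(sort(ps), collapse = ",")
  }
  # ground truth: junction coverage per read
  jx_str <- character(n)
  for (mi in unique(mol)) {
    sp <- pool[[mi]]$species
    if (length(sp$junctions) == 0L) next
    idx <- which(mol == mi)
    ml <- mol_len[mi]
    circ <- mol_circ[mi]
    parts <- rep("", length(idx))
    for (j in sp$junctions) {
      left <- if (circ) (j$pos - start[idx]) %% ml else j$pos - start[idx]
      cov <- left > 0L & left < lens[idx]
      parts <- ifelse(cov,
                      paste0(parts, ifelse(nzchar(parts), ";", ""),
                             j$category, ":", left),
                      parts)
    }
    jx_str[idx] <- parts
  }
  ids <- sprintf("r%06d", seq_len(n))
  truth <- data.frame(
    read_id = ids,
    source_name = vapply(pool, `[[`, character(1), "name")[mol],
    source_class = vapply(pool, function(p) p$species$species_class,
                          character(1))[mol],
    source_intron = vapply(pool, function(p)
      if (is.na(p$species$source_intron)) NA_character_
      else p$species$source_intron, character(1))[mol],
    start = start, length = lens, short = lens < rl,
    junctions = jx_str, n_errors = n_err, error_positions = err_pos,
    stringsAsFactors = FALSE)
  list(reads = list(id = ids, seq = seqs), truth = truth)
}
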