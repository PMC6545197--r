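---
title: "Modelling giant group I intron removal by RNA back-splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling giant group I intron removal by RNA back-splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backsplicer)
```

## The biological problem

Corallimorpharian (mushroom coral) mitochondrial genomes are small
(20–22 kb) circles in which every conventional gene sits on one strand.
Their ND5 gene carries an obligatory group I intron at codon position 717
whose P8 peripheral element has swallowed most of the genome: two rRNA
genes, a tRNA, a dozen OxPhos genes, a homing-endonuclease-bearing COI
intron, and an antisense ORF all live *inside* the intron, which therefore
spans ~90% of the circle. Conventional cis-splicing would demand a ~20 kb
unprocessed precursor and total repression of every embedded gene — an
implausible arrangement.

The resolution exploited here is geometric: on a circular genome the
downstream exon (exon 2) lies immediately *upstream* of exon 1, across a
short linker. A short (~3 kb) primary transcript starting in the intron's
3' region and ending in its 5' region has the permuted intron–exon (PIE)
order `[intron 3' tail][exon 2][linker][exon 1][intron 5' head]`. Ordinary
group I chemistry on that permuted precursor ligates the exons into a
covalently closed circle — RNA back-splicing — and releases the intron in
two pieces. The circular exon-containing intermediate is the discriminating
observable: exon-ligation junctions alone are produced identically by
cis-splicing.

This package implements that model end to end: circular-coordinate genome
arithmetic, the splicing state machine, a junction-spanning read
classifier with efficiency statistics, an in-silico PCR discriminator of
circular versus linear templates, and a synthetic read simulator that
makes the whole pipeline testable without any external data.

## The splicing state machine

Group I splicing is two transesterifications: an exogenous guanosine
(exo-G) attacks the 5' splice site and remains attached to the intron's
5' end; the freed exon-1 3'-OH then attacks the 3' splice site, ligating
the exons. The model keeps this bookkeeping exact:

* `cis_splice()`: `len(precursor) = len(mRNA) + (len(intron product) − 1)`
  — the −1 is the non-encoded exo-G.
* `back_splice()`: `len(precursor) = len(circle) + len(3' segment) +
  (len(5' segment) − 1)`. The full-length intron is never released as one
  molecule.
* `circularize_intron()` joins the intron's terminal residue (ω) to an
  internal donor site. The chemistry requires ωG; the giant ND5-type
  intron ends in ωA and therefore refuses (a classed `chemistry_error`)
  unless forced. Crucially ωA does *not* block exon ligation — step 2 acts
  at the 3' splice site — so the same intron back-splices happily. This
  asymmetry (ligated exons observed, intron circles never observed for the
  giant intron; both observed for the canonical ωG COI intron) is encoded
  in the tests.

Both pathways produce the identical exon-ligation (E1E2) junction context
— a property test asserts this — which is why the classifier's
back-splicing detector demands *co-occurrence* evidence: a single
continuous sequence carrying both the E1E2 ligation and the exon-2→linker
genomic contiguity. The ligated mRNA has the former, the linear permuted
precursor the latter; only the circular intermediate has both.

## Junction classification

Junction-spanning read counting is modelled after manual counting of reads
that unambiguously flank splice sites: every read (and its reverse
complement) is slid ungapped across each 2k-nt junction context (k = 25 by
default); a placement is valid if it crosses the junction midpoint with at
least m = 10 nt on both sides at a substitution rate ≤ 4%. The unique best
placement (fewest mismatches, then longest overlap) assigns the read;
residual ties and collapsed duplicate contexts yield AMBIGUOUS, never an
arbitrary choice. Parameters m and the mismatch budget are explicit
because the original manual procedure's implicit thresholds are unknowable;
10 nt on each side at ≤ 4% mismatches is conservative for ~200-nt
substitution-dominated reads.

The scan is implemented in C++ with a lossless pigeonhole prefilter: any
valid placement must share an exact 12-mer with some context (a span of
ov ≥ 2m nucleotides with at most `floor(0.04·ov)` mismatches always
contains an exact run of ≥ 12 matches for the permitted parameter ranges),
so reads without such a 12-mer are skipped. The filter is disabled
automatically if parameters are chosen for which the bound drops below 12.

Ungapped alignment is a deliberate limitation: Ion-Torrent-style
homopolymer indels are not modelled, in the simulator or the classifier.
With indel-bearing real reads the classifier would undercount junctions
roughly uniformly across categories; ratios and fractions are affected far
less than absolute counts.

## Splicing-efficiency statistics

Each *unspliced* precursor molecule presents two countable junctions (5'SS
and 3'SS flanks) while each *spliced* event presents one (the ligated
exons). The default unspliced summary is therefore the mean of the two
flank counts; the plain sum is also computed and reported side by side,
since published "fraction unspliced" figures rarely state their
arithmetic — on the worked example counts (ligated 6 with flanks 18/12,
and 4 with 9/13) both formulas agree that ≥ 70% of giant-intron precursors
are unspliced. Intervals are Wilson score intervals
(`prop.test(correct = FALSE)`), chosen over Wald because junction counts
are small; the intron-to-intron ratio of ligated-exon counts gets a
normal-approximation interval on the log scale (Poisson counts,
`var(log n) ≈ 1/n`). No hypothesis tests are attached: the quantities of
interest are descriptive fractions and ratios.

## In-silico PCR

`predict_amplicons()` pairs forward-primer plus-strand sites with
reverse-primer minus-strand sites. On a linear template a divergent pair
(reverse site upstream of the forward site) has no extension path and
yields nothing; on a circular template the same pair yields exactly the
around-the-circle product. That asymmetry is the in-silico analogue of the
divergent-primer RT-PCR test for circular RNA. Two design choices mirror
bench reality: the primer's 3'-terminal 5 nt must match exactly regardless
of the mismatch allowance (polymerase extension chemistry), and only the
shortest product per site pair is reported (single-band interpretation; no
rolling-circle multimers). Correctness on circles is pinned to an
independent oracle: predictions must equal the deduplicated union of
linear predictions over all rotations of the template.

## The synthetic study and what it does (not) show

`sim_config()`/`generate_genome()` build a 21 kb circular genome with the
full architecture: ND5-like exon 2 at the origin side, a tRNA linker, exon
1, and a giant ωA intron (~18.9 kb, 90% of the circle) embedding two
rRNAs, a COI-like gene split by a 1.2 kb ωG intron with an internal ORF,
further CDS (two of five GTG-initiated, echoing the ~40% GTG initiation of
these genomes), a minus-strand antisense ORF (125 aa), and an intergenic
region carrying a planted 123-nt direct repeat. The printed diagnostic
strings of the real system are planted so string-level checks are
meaningful: exon 1 ends `…AGGGU` and exon 2 begins `CCAACU…` (the ligation
site), exon 1 initiates with GUG, exon 2 ends with UAA.

Free parameters were fixed once, at values a practitioner would call
realistic, and are not tuned:

* **Permuted precursor termini** (`tx_pad = 400` nt beyond each splice
  site): the real transcript's ends are undetermined; only its ~3000 nt
  size is known. Exons plus linker are ~2.1 kb, implying ~400 nt of
  intron sequence per terminus (simulated precursor ~2.9 kb). This also
  keeps every junction ≥ `read_length − m` from a molecule end, so
  junction-spanning reads sample all junctions with equal window width —
  termini closer than that clip the window and bias flank counts.
* **Expression weights**: three orders of magnitude across units, with
  rRNA-like units 5–20× typical mRNAs.
* **Reads**: 200 nt single-end, 1% substitution errors, constant quality
  "I" (qualities are parsed, never scored); A+T-rich (62%) background.
* **Splicing**: giant intron 30% spliced (back-splicing), small intron
  98% spliced with 20% of excised introns circularizing at donor offsets
  {0, 50}.

Reads are drawn per molecule proportionally to weight × length
(fragmentation yields mass-proportional sampling) with uniform fragment
starts — uniform modulo length on circular molecules, so fragments cross
the closure. Under this model the expected junction-read count for any
junction is proportional to the carrying molecule's copy number alone,
which is what makes the flank-count efficiency estimator consistent.

The calibration experiment (`recovery_study()`) runs the full simulate →
classify → estimate loop over 100 seeds at 50,000 reads each and requires
the Wilson interval to cover each configured truth in ≥ 90 seeds, and the
small/giant spliced-read ratio to exceed 1 in every seed. Problem sizes
(50,000 reads, 100 seeds, 1000 conservation replicates, 100 oracle
templates ≤ 260 nt) were chosen as the smallest that make the statistical
assertions sharp.

What passing does **not** show about real data: no indels or flow-space
error structure, no library-prep or poly(A)-selection bias, no
transcription-unit boundaries beyond the modelled ones, no imperfect
repeat copies (the repeat finder reports exact maximal repeats only — the
real repeats are imperfect copies, whose alignment model the source
material does not define), and no secondary-structure constraints on the
ribozyme (P1–P10 folding is out of scope; only terminal-residue and
splice-flank identities are checked).

## Numerical and convention choices

* Coordinates are 0-based, half-open, modulo genome length; `end ≤ start`
  wraps through the origin. `subsequence(a, a)` returns the full rotation
  by declared convention. GFF3 I/O converts to 1-based inclusive and
  splits origin-spanning features into two lines joined by `ID`.
* IGRs are gaps between gene-level features; container introns and the
  antisense ORF are excluded by default (configurable) so the gap set
  matches a conventional gene map.
* RNA species carry DNA-alphabet sequences; U↔T conversion happens only at
  presentation. Circular molecules are matched through their doubled
  sequence everywhere (classification, primer sites, support detection),
  making every circular operation rotation-invariant by construction.
* Ambiguity characters other than N are rejected at genome input.
* The antisense ORF scanner reports every qualifying start→stop span
  (nested starts give nested hits), sorted by length; the minimum-length
  short-circuit is `3·(min_aa + 1)` nt, i.e. `min_aa` codons plus a stop.
* One root seed drives derived per-stage streams, so genome, pool, and
  reads are independently reproducible.

## Known limitations

Indel-free error model and ungapped classification; exact-only repeat
detection; no ribozyme folding; transcription termini of the permuted
precursor are configurable assumptions, not inferences; the GenBank
readers are exercised on synthetic fixtures when the deposited records are
not locally available.
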