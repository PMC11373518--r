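---
title: "Measuring rDNA repeat-unit size and structure from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rDNA repeat-unit size and structure from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnarray)
```

## The measurement model

Eukaryotic rRNA genes sit in tandem arrays; one repeat unit is
18S–ITS1–5.8S–ITS2–28S followed by the intergenic spacer (IGS). A long read
that spans two or more units carries the unit length directly: if the same
feature (by default the 18S gene) occurs at read positions $x_1 < x_2$ on
the same strand, then $x_2 - x_1$ is one unit length. No assembly is
involved, so the measurement inherits only the read's own error process.

Three properties of this estimator matter and are enforced by construction:

* **Start-to-start distances.** Each anchor contributes its *feature
  origin* — the read position corresponding to position 0 of the feature
  reference, projected through the alignment. Anchor-internal length errors
  cancel to first order, and anchors truncated at a read edge (still
  accepted when they cover ≥ 80% of the reference) agree with full anchors.
* **Substitution invariance.** Substitutions never move coordinates, so
  substitution-only noise leaves every measured length exactly equal to the
  true unit length. Only insertions and deletions bias the measurement:
  the expected measured length is $L(1 + p_{ins} - p_{del})$ with per-base
  variance $L(p_{ins} + p_{del})$, which the test suite checks against its
  binomial law.
* **Strand invariance.** Reverse-complementing a read mirrors every hit
  exactly (the minus-strand search *is* the plus-strand search of the
  reverse complement), so the multiset of measured lengths is unchanged.

Distributions are summarized the way the field reports them: mean, sample
SD ($n-1$ denominator), and the mode of a Gaussian kernel density estimate
on a 512-point grid with the `stats::density()` rule-of-thumb bandwidth
$0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$. When all observations
are equal the bandwidth rule degenerates to 0; a 1 bp floor is applied and
the peak is reported at the common value. A secondary peak is found by
restricting the same density to one side of an exclusion bound, emulating
re-plotting with an axis limit. Size classes follow the amniote
conventions: *normal* for 8–20 kb, *large* for > 30 kb; the 20–30 kb gap
between the published classes is reported as *intermediate* rather than
silently assigned, and anything below 8 kb as *out of range*.

## Feature scanning

The scanner is a deliberately small seed-and-extend matcher, adequate
because rDNA coding regions are long and well conserved:

* **DUST masking** (window 64, level 20) removes low-complexity seeds. The
  triplet score $S = \sum_t c_t(c_t-1)/2$ is computed per window and
  normalized by the number of triplets minus one; a window is masked when
  $10S/(l-1)$ exceeds the level. The normalization matters: an
  *unnormalized* score of 20 would mask nearly all natural DNA, since a
  random 64-mer already contains ~30 colliding triplet pairs. Soft-masked
  (lowercase) input bases are likewise excluded from seeding but retained
  in all sequence output.
* **Exact 15-mer seeds** rather than minimizers: inputs are desk-scale and
  exactness keeps the oracle tests sharp. Seeds are clustered by alignment
  diagonal with a band of 0.2 × feature length (roomy enough for ~15%
  indel noise).
* **Banded extension** by ends-free pairwise alignment
  (match 2, mismatch −3, gap open 4, gap extend 2) over the read window the
  cluster implies. A cluster whose seeds sit on a single diagonal and
  jointly tile the whole reference is an exact hit and skips alignment —
  on error-free data the scanner therefore reports identity exactly 1.0.
* **Chaining** merges co-linear same-feature fragments (ONT indels fragment
  long matches), with alignment-length-weighted identity; residual
  overlapping same-feature hits are redundant candidates and only the
  best-covered one is kept, so chained hits never overlap.

Hits can equally come from external BLAST tabular output through
`adapt_blast_hits()`; the two routes agree exactly on clean data, which the
tests assert. Reporting thresholds (identity ≥ 0.75, feature coverage
≥ 0.5, anchor coverage ≥ 0.8 for sizing) replace the manual read curation a
human would do on BLAST output; they are explicit parameters, not
hard-coded behaviour.

## Consensus and annotation

Up to 15 unit copies (longest anchors first, then lexical read id — a
deterministic stand-in for manual curation) are cut between adjacent 18S
anchors, reverse-complemented to plus orientation, and aligned star-wise
around the medoid (minimal summed Levenshtein distance). Star alignment
replaces a general multiple-sequence aligner because $n \le 15$ makes the
$O(n^2)$ pairwise step cheap and removes an external dependency; the
consensus is the per-column majority with the gap as a votable symbol,
gap-majority columns deleted, and base ties resolved alphabetically (gaps
lose all ties) so the output is deterministic. With 15 copies at 2%
independent substitution error, the per-column majority error probability
is far below $10^{-3}$, and the tests confirm < 0.1% consensus mismatch.

Coding regions are then located on the consensus by alignment of the
reference features (minimum identity 0.6 — below that the feature is
reported missing by name, which is a real outcome: variant units lacking a
recognizable 5.8S exist). Spacers are defined by subtraction, so
`18S + ITS1 + 5.8S + ITS2 + 28S + IGS = total` always. Because
transcription start sites cannot be read from DNA sequence, the IGS here
runs from the 28S end to the unit end and therefore includes both external
transcribed spacers; output headers state this.

## Sub-repeat detection and variance attribution

Tandem arrays are found from exact 12-mer self-matches (the dotplot's
"squares near the diagonal"). Within a clustered region the period is the
*smallest* candidate offset whose multiples explain ≥ 80% of observed
offsets — taking the modal offset alone would report $2p$ for a
$p$-periodic array whenever adjacent copies are more diverged than copies
two apart. The span is grown outward one period at a time while the
adjacent-copy identity stays ≥ 0.6. Classification follows the field's
conventions: period < 10 bp is a microsatellite (never counted in
sub-repeat totals); mean adjacent-copy identity < 0.7 is *degenerate*
(detected and reported, but too diverged to delimit copies reliably — the
0.7 default is a configuration knob, as the underlying notion is
qualitative); the rest are sub-repeats. k = 12 balances sensitivity on
diverged copies (two copies at 12% divergence each still share ~5% of
their 12-mers, dozens per copy for the periods of interest) against random
self-matches (expected $\ll 1$ per Mb² of dotplot).

Unit-length variance is attributed to sub-repeat copy number as
$1 - \mathrm{Var}(L_i - S_i)/\mathrm{Var}(L_i)$ with sample variances,
clamped to $[0,1]$, where $S_i$ is unit $i$'s total sub-repeat length.
Direct subtraction is preferred over a regression $R^2$ because $S_i$ is a
physical component of $L_i$; the two coincide when residuals are
uncorrelated with $S$. When $\mathrm{Var}(L) = 0$ the fraction is reported
as not applicable rather than 0 or 1.

## TE orthology

RepeatMasker records < 50 bp are discarded; fragments of one element
(same repeat name and orientation, co-linear consensus coordinates, query
gap occupied by other annotated elements) are rejoined with the interveners
as nested children. Orthology between two IGSs is the maximum-cardinality
common subsequence of the two ordered element lists, where tokens are equal
iff family *and* orientation agree — conservation of type, order and
orientation. Among equal-cardinality matchings the dynamic program prefers
the largest summed $\min(\ell_A, \ell_B)$: "maximum number" alone is
ambiguous, and matched length is a deterministic, biologically sensible
tie-break. Family-level tokens (e.g. `SINE/Alu`) are the default since
subfamily names churn across library versions; `by = "name"` gives the
strict mode. The DP is verified against exhaustive enumeration on all
random instances with ≤ 8 elements per side.

## What the simulator emulates — and what it does not

The generator builds flank + $n$ concatenated units + flank. All units
share master region sequences (mimicking the high intra-genomic homogeneity
maintained by concerted evolution) and differ only in per-unit sub-repeat
copy numbers, optional TE insertions and microsatellites. Coding-region
defaults (18S 1.8 kb, 5.8S 150 bp, 28S 4.5 kb) mimic vertebrate magnitudes;
only the relative layout matters to any algorithm here. The default spacer
cores give a 15 kb unit, a typical "normal" size; the bimodal scenario uses
IGS cores sized to give 40 kb and 44 kb units. Reads are drawn uniformly by
start, strand by fair coin, truncated at the genome ends, with independent
per-base substitutions and single-base indels.

Deliberately not modelled: homopolymer-biased ONT error profiles,
basecaller-specific artifacts, chimeric reads, real inter-unit haplotype
structure, and PacBio CCS profiles. Passing tests therefore demonstrate
correctness of the measurement machinery under the stated error model, not
robustness to every failure mode of real sequencing runs; on real data the
scanner's identity threshold and the anchor-coverage rule are the knobs to
revisit first. Simulation scales in the tests and the acceptance script
(10-unit arrays, 60 reads of 40 kb; two 5-unit arrays with 95 kb reads for
the bimodal design; 20 replicates for Monte-Carlo checks) were chosen as
the smallest designs that leave the statistical assertions comfortable
margins.

## Numerical and degenerate-input choices

* Internal coordinates are uniformly 0-based half-open on the forward
  strand; 1-based inclusive conventions (BLAST, RepeatMasker, GFF3) are
  converted exactly once, at the I/O boundary, and round-trip identically.
* In BLAST tables the query is the rDNA feature and the subject the read,
  matching how such searches are usually run against a read database; an
  adapter flag handles the reversed layout.
* FASTQ qualities are read and carried for provenance but never used.
* Empty inputs return empty, typed tables; a read shorter than $k$ yields
  no hits rather than an error; a single unit yields itself as "consensus"
  with a warning; `summarize_sizes()` on zero observations is an error.
* All randomness flows from explicit integer seeds; reruns of
  `run_pipeline()` with the same config and seed produce byte-identical
  files, which the manifest (md5 per stage output) makes checkable.

## A small end-to-end run

```{r example, eval = FALSE}
arch <- unit_architecture(len_igs_core = 2000,
  subrepeats = list(subrepeat_spec(105, 5, 15, divergence = 0.05,
                                   location = "IGS", offset = 500)))
locus <- simulate_locus(arch, n_units = 8, flank_length = 1000, seed = 101)
reads <- simulate_reads(locus$genome,
                        error_model(0.03, 0.01, 0.01, read_length = 30000),
                        n_reads = 40, seed = 102)
hits <- scan_reads(reads$reads, locus$truth$feature_refs["F18S"])
summarize_sizes(measure_all_units(hits))
```

## Known limitations

* The scanner is desk-scale: whole-genome ONT datasets should be reduced
  first (e.g. pre-filter reads with an external BLAST and feed the tabular
  output to `adapt_blast_hits()`).
* Period estimation assumes copies of near-constant length; arrays whose
  copies vary greatly in length are typically classified degenerate rather
  than resolved.
* The consensus is a majority call, not a polished assembly; resolving
  chromosome-specific unit haplotypes needs dedicated high-coverage
  approaches.
* Observations from different anchor features are not pooled (one anchor
  per call) to avoid double counting a unit.
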