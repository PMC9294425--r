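---
title: "ORFpi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORFpi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

ORFpi predicts open reading frames from the population-genetic structure
of per-site nucleotide diversity (π). Within coding sequence, selection
is weakest at the third (wobble) position of each codon, so segregating
sites are denser and π is on average higher there than at first/second
positions or in noncoding sequence. Reading frame is therefore
detectable from SNP data alone, with two statistical consequences the
package exploits:

1. **Metagene periodicity.** The positionwise mean of π over many
   aligned CDS windows oscillates with period 3. Thomson's multitaper
   harmonic F-test on the mean profile detects this as a phase-coherent
   line component at 1/3 cycles/nt.
2. **Frame-wise contrast per candidate ORF.** For one candidate
   (start…stop interval on a spliced transcript), the per-position π
   values split by frame give two one-sided pooled-variance t-tests
   (frame 2 > frame 0, frame 2 > frame 1). Codon usage adds two more
   (own reading > +1 shift, own reading > +2 shift) once a usage table
   has been trained. Fisher's method combines the four p-values.

Key modelling assumptions: π is a property of the genomic site
(strand-symmetric, so one track serves transcripts of both strands);
sites absent from the π table are invariant (π = 0), matching the
`--site-pi` convention of listing only VCF sites; and codon usage is
genome-wide (one table, shared tRNA pool), so a single trained table
applies to every candidate.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| start codons | `ATG` | near-cognates `CTG, GTG, TTG` may be added |
| min reported length | 60 nt | stop codon included; sORFs are not excluded |
| training min length | 300 nt | preliminary pass, ATG only, diversity tests only |
| α | 0.05 | threshold on the Fisher-combined p |
| combination | Fisher | Stouffer available |
| start policy | 5′-most | one candidate per (stop, frame); `all` enumerates nested starts |
| min informative sites | 2 | candidates with < 2 sites of π > 0 are untestable, skipped |
| taper parameters | nw = 4, k = 7 | the common default of the multitaper family |
| F-test threshold | 0.001 | significance of the p at 1/3 |
| zero padding | 6× | see numerical choices |

Length thresholds are treated as inclusive (≥ 300 nt, ≥ 60 nt). The
preliminary training pass reuses the final α; the training filter is
already stringent through the ATG-only and ≥ 300 nt restrictions, and a
separate knob would add a parameter without a criterion to set it by.

## Numerical choices

**Frequency grid.** The harmonic F statistic is evaluated on a
zero-padded Fourier grid. The padding factor is 6 because N = 6n is
divisible by 3 for every window length n, so the target frequency 1/3
lies *exactly* on the grid. On grids where 1/3 falls between two bins
(e.g. 4n with n = 50: bins 0.330 and 0.335), the F ridge — smooth over
the taper bandwidth W = nw/n — splits peak location between the two
neighbouring bins under noise, which makes "the peak is at 1/3" an
ill-posed readout. With 1/3 on-grid, peak location at two-decimal
precision is stable.

**Mean centering.** Profiles and series are mean-centered before the
F-test (the harmonic test targets periodic components, not the DC
level); the F statistic is then invariant to affine rescaling of the
input.

**Degenerate inputs.** A constant series yields a defined, flagged
result with p = 1 at every frequency. In the t-test, two zero-variance
samples yield p = 0 / 0.5 / 1 by the sign of the mean difference; this
matters when a uniform usage table makes all usage values equal
(p = 0.5, neutral under Fisher up to a constant offset). Zero p-values
are clamped to the smallest positive double before logs.

**Zero-π positions are data.** Diversity vectors keep π = 0 positions
(the track defines them as invariant); dropping them would discard the
frame-differential density of segregating sites, which is most of the
signal. A candidate with fewer than two positive sites is refused
rather than tested vacuously.

**Usage values are per triplet, not per nucleotide.** Repeating each
triplet's usage three times (once per base) triples the t-test sample
size without adding information; the default is one value per triplet,
with `usagePerNucleotide = TRUE` restoring the tripled variant.

**Ties and duplicates.** Identical ORFs reached through different
transcript isoforms (same seqid, strand, genomic block list) collapse to
one row; output order is sorted by genomic coordinates, making runs
byte-reproducible and independent of worker count. Overlapping
significant candidates in different frames are all reported — the
classifier labels the relationships.

## Classification

Categories are assigned with a fixed precedence: host-biotype labels
(transposable element, pseudogene, non-coding) first, then exact
identity with the annotated CDS, then stop-sharing in-frame cases
(truncated/extended), then UTR-relative cases (uORF, overlapped uORF,
dORF, overlapped dORF), then frame-shifted containment (internal). The
overlapped-dORF label requires an out-of-frame overlap; for ORFs whose
length is a multiple of 3, sharing the annotated stop coordinate forces
the annotated frame, so in-frame read-through past the stop cannot arise
from the scanner. CDS intervals written by this package include the stop
codon, so a frame-0 candidate shares the annotated stop exactly; "same
stop" comparisons are made in genomic coordinates on the same strand so
that they are isoform-robust. An ORF on a transcript unknown to the
annotation is classified through any annotated transcript whose exons
contain it, and is `novel` otherwise.

## The synthetic generator

`simulateGenome()` lays out protein-coding genes (multi-exon, with UTRs
and intergenic spacers, alternating strands) and `simulateDiversity()`
draws per-site π: each site segregates independently with a per-class
probability, and segregating sites draw π from an exponential with a
per-class mean. Defaults — 200 genes, CDS 300–1500 nt, segregating-site
probability 0.10 at wobble positions vs 0.03 elsewhere, mean π 0.15 at
wobble vs 0.05 elsewhere — give a strong but not trivial signal and run
the full pipeline in well under two minutes; these are the study
conditions every calibration and recovery test uses. UTRs are generated
free of the ATG trinucleotide so each planted start is the 5′-most in
its frame and boundary recovery is well-defined; planted uORFs/dORFs
(off by default) carry the same wobble elevation in their own frame.

What the generator does **not** emulate: linkage between sites (the
method only uses marginal per-site π, so LD is irrelevant to its
statistics), indels, paralogy and polyploid homeology, alignment or
variant-calling artefacts, and realistic codon-usage or π magnitude
distributions of any particular species. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under
the model's own assumptions, not performance on real resequencing data.

`subsamplePopulation()` emulates smaller populations by retaining each
segregating site with probability equal to the sampled fraction —
low-frequency variants drop out of small samples; the retained π values
are left unchanged, which is a simplification (real subsampling also
re-estimates π per site).

## Calibration behaviour

Two properties of the combined diversity test are worth knowing. First,
its two t-tests share the frame-2 sample, so Fisher's combination —
derived for independent p-values — is mildly anticonservative: at
α = 0.05 the candidate-level false-positive rate under the null sits
near 0.06–0.07 rather than 0.05. Second, with a uniform usage table the
two usage p-values are exactly 0.5, which makes the four-way combination
conservative. Both effects are inherited from the method's design (the
tests and their combination are prescribed); the test suite measures the
diversity-only combination against α at a Monte-Carlo size of 1000
candidates and checks the marginal p-values for approximate uniformity.

The harmonic F-test's type-I error at 1/3 on white noise is checked at
10 000 replicates against twice the nominal 0.001.

## Problem sizes in the test suite

Unit tests run on a 40-gene simulation (seed 7) shared across files; the
recovery and calibration checks use the 200-gene default (seed 1), 1000
null candidates for the false-positive rate, 2000 for uniformity, and
10 000 replicates for the F-test's type-I error; the acceptance script
uses 100 seeded profiles. These sizes were chosen to keep Monte-Carlo
standard errors meaningfully small while keeping a full run fast.

## Known limitations

* Splice-aware discovery is limited to annotated transcript structures;
  no de novo transcripts, no intron retention.
* No multiple-testing correction by default (a Benjamini–Hochberg
  switch exists); the reported α is per-candidate.
* The π reader accepts any non-negative value and does not assume
  biallelism; π is not capped at 1.
* Stop-codon read-through, selenocysteine recoding and overlapping gene
  structures on the same strand are not modelled.
* Real-data performance (mapping artefacts, population structure,
  selection on synonymous sites, polyploid homeologs) is outside what
  the synthetic evidence can establish.
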