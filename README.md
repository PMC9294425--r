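# ORFpi

ORF prediction from the 3-nt periodicity of population nucleotide
diversity.

## The problem

Protein-coding sequence leaves a population-genetic fingerprint: most
substitutions at the third position of a codon (the wobble position) are
synonymous and weakly selected, so per-site nucleotide diversity (π)
measured across a population of resequenced individuals is elevated at
every third base inside coding sequence. Along a CDS, π therefore
oscillates with a 3-nucleotide period — the same periodicity that
ribosome-profiling reads show, but obtained from ordinary whole-genome
SNP data, which maps uniquely far more often than short ribosome
footprints and covers genes that are transcriptionally silent under any
one condition.

ORFpi exploits this signal to predict open reading frames — including
small ORFs, uORFs and dORFs — genome-wide from three inputs: a genome
FASTA, a GTF annotation (transcript structures only; no CDS knowledge is
used for prediction), and a per-site π table in the dialect of
`vcftools --site-pi` (`CHROM POS PI`, 1-based positions; absent sites are
invariant, π = 0). It is aimed at groups with population resequencing
data who want translation-independent ORF annotation.

## The method

For each spliced transcript, genomic π is projected onto transcript
coordinates. Candidate ORFs (start codon … in-frame stop, length ≥ 60 nt,
5′-most start per stop by default) are scored with four one-sided
pooled-variance Student's t-tests:

* **diversity**: π at frame-2 (wobble) positions > frame 0, and > frame 1;
* **codon usage**: trained usage of the candidate's own reading frame >
  the +1 and +2 shifted readings.

The usage table is trained in a stringent preliminary pass that uses
only the diversity tests, ATG starts and candidates ≥ 300 nt. The four
p-values are combined with Fisher's method,
`X = -2 Σ log p ~ χ²(2m)`, and candidates with combined p < α (default
0.05) are reported, deduplicated by genomic identity and classified
against the annotation into the standard categories (annotated,
truncated, extended, uORF, overlapped uORF, dORF, overlapped dORF,
ncRNA/TE/pseudogene ORF, internal, novel).

The periodicity itself is assessed on metagene profiles (positionwise
mean π over the first 50 nt of every CDS, the 50 nt flanking start/stop
codons, and 10 000 random intergenic windows) with Thomson's multitaper
harmonic F-test on DPSS tapers (nw = 4, k = 7): at each grid frequency f
the statistic

```
F(f) = (k-1) |μ(f)|² Σ U_k(0)² / Σ |y_k(f) − μ(f) U_k(0)|²  ~  F(2, 2k−2)
```

tests for a phase-coherent line component; 3-nt periodicity appears as a
significant peak at 1/3 cycles/nt (printed as 0.33). Accuracy, recall
and F-score against a reference set use exact genomic-block identity:
`accuracy = TP / predicted`, `recall = TP / annotated`,
`F = 2·R·A / (R + A)`.

## Worked example

Everything below is synthetic and self-contained — the package ships a
generator that plants genes with wobble-elevated π and writes FASTA, GTF,
site-π and a truth manifest:

```r
library(ORFpi)

params <- simulationParams(nGenes = 40, seed = 7)
sim    <- simulateGenome(params)
track  <- simulateDiversity(sim$genome, sim$annotation, sim$manifest, params)
txs    <- buildTranscripts(sim$genome, sim$annotation)

cfg   <- callerConfig()                       # ATG, >= 60 nt, alpha 0.05
usage <- trainCodonUsage(txs, track, cfg)
#> CodonUsageTable: trained on 40 ORFs (11340 codons); top: TTT, TCG, TTA

orfs <- predictOrfs(txs, track, usage, cfg)
cl   <- classifyOrfs(orfs, sim$annotation, txs)
cl$summary[cl$summary > 0]
#>    annotated internal_ORF
#>           40            1

truth <- sim$manifest$orfs
cmp <- compareSets(orfIdentity(cl$orfs),
                   paste(truth$seqid, truth$strand, truth$blocks, sep = "|"))
predictionMetrics(cmp)
#> PredictionMetrics: accuracy 97.56%, recall 100%, F 98.77%
```

All 40 planted CDSs are recovered with exact boundaries; one
out-of-frame candidate slips through at α = 0.05 and is labelled
`internal_ORF`. The periodicity check behaves like the method requires —
coding regions carry the 3-nt signal, intergenic noise does not:

```r
reg <- extractMetageneRegions(txs, track, window = 50)
harmonicFtest(profileValues(metageneProfile(reg$CDS, "CDS")))
#> PeriodicityResult: peak at 0.3333 cycles/nt; p(0.333) = 1.15e-05 *

ig <- sampleIntergenicWindows(sim$genome, sim$annotation, track,
                              n = 2000, seed = 1)
harmonicFtest(profileValues(metageneProfile(ig, "intergenic")))
#> PeriodicityResult: peak at 0.0900 cycles/nt; p(0.333) = 0.257
```

The same pipeline is available from the shell via the installed wrapper
(`inst/cli/orfpi`): `orfpi predict --genome g.fa --gtf a.gtf --pi sites.pi
--out run`, plus `metagene`, `simulate` and `evaluate` subcommands
(`--startCodons ATG,CTG,GTG,TTG` enables near-cognate starts; `--nCores`
parallelises without changing output).

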