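---
title: "Methods: mutation spectra, strand asymmetry, and mutagenesis assays with mutasym"
author: "mutasym authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation spectra, strand asymmetry, and mutagenesis assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutasym)
```

# Scope and scientific setting

`mutasym` analyses mutation-accumulation experiments in budding yeast
chronically exposed to an alkylating agent such as MMS. MMS methylates DNA
to produce 3meA and 7meG in double-stranded DNA and, preferentially in
single-stranded DNA, 3meC and 1meA. Because yeast lacks AlkB-family
dioxygenases that directly demethylate 3meC, mutations arising from these
single-strand-specific adducts carry diagnostic signatures: an excess of
C mutations on strands that are transiently single-stranded during
transcription (the non-transcribed strand) and systematic strand trends
across replication units. The package turns whole-genome mutation catalogs,
reporter-gene (CAN1) colony counts, survival platings, and protein--DNA
anisotropy titrations into the summary statistics used to reason about
such lesions: per-genome burdens, purine-keyed substitution spectra,
strand-resolved asymmetry profiles, fluctuation-assay mutation rates, and
equilibrium dissociation constants.

Every stage can be exercised against synthetic data with known injected
structure, so the pipeline's statistical behaviour is testable without any
sequencing data.

# Mutation catalogs

## Call filters

Clonal mutation-accumulation isolates are (nearly) homozygous haploids, so
true mutations should be supported by about half of the reads in a
paired-lineage sequencing design. `filterGenomeCalls()` keeps a call iff

* depth $\ge$ 10 reads (a strict reading of "more than nine reads"), and
* alt-allele fraction in the closed interval $[0.45, 0.55]$.

Both boundaries are covered by tests. `filterCan1Calls()` implements the
amplicon-sequencing variant: at least 2 supporting reads comprising
strictly more than 30% of reads.

`removeRecurrent()` drops any (chrom, pos, ref, alt) key observed in two or
more samples, from *all* samples, as a likely inherited polymorphism or
systematic alignment artifact. Keying on the full allele (not the position
alone) means different substitutions at one site are kept: they are
independent mutations. The operation is idempotent. The order of
operations is a genuinely open choice; the package applies depth/support
filtering first and recurrence removal second, since support filtering is
per-record and cannot be confounded by other samples, while recurrence is
a cross-sample property best judged on confidently called records.

## Event clustering

Error-prone translesion synthesis produces clusters of nearby changes.
`clusterEvents()` chains records on the same chromosome and sample whose
start positions differ by at most 10 bp (single linkage, so records at
positions 100, 108, 116 form one event). Events with two or more records
are *complex mutations*; singletons are classified by allele lengths.
Equal-length multi-nucleotide alleles are treated as block substitutions
occupying their span — the minimal convention, since no finer definition is
forced by the data model. Clustering partitions its input: every record
belongs to exactly one event, a property tested against a brute-force
transitive-closure oracle.

# Spectra and burdens

Substitutions are keyed to the purine reference base: the six classes
A>C, A>G, A>T, G>A, G>C, G>T, with pyrimidine-reference calls complemented
(T>C is A>G). This is an involution-consistent convention — complementing
both alleles never changes the class.

`perGenomeBurden()` counts *events* per genome (a complex event counts
once; record-level counting is available behind `countRecords = TRUE`),
takes group medians and reports their ratio. Medians, not means, because
per-genome counts are overdispersed and a single jackpot genome should not
move the group estimate. `eventClassFractions()` and `spectrumMeans()`
summarise the class composition; `compareGroups()` wraps the standard
two-sided Mann-Whitney, t, and chi-square tests.

Reporter-gene frequency spectra (`can1FrequencySpectrum()`) are
reconstructed as class proportion among sequenced resistant isolates
multiplied by the total mutation rate. The source assays report only the
total rate and the isolate classes, so this product is the natural — and
here explicitly logged — interpretation of a per-class frequency.

# Strand asymmetry

## Transcriptional profile

Each transcript is divided into 5 fractional body bins (0.2 of the
transcript length each) in transcript orientation, plus three 500-bp bins
upstream of the TSS and three downstream of the TTS, ordered outward (bin
−1 abuts the TSS). For every A or C mutation the mutated-base identity and
strand are derived from the top-strand reference base and the transcript
strand; the *non-transcribed strand* is the mRNA-like (coding) strand,
i.e. the top strand of a `+` transcript. Densities are
opportunity-normalised: mutations of base X on strand S in bin b divided
by the number of X bases on S in b, summed over transcripts, so that base
composition differences between bins cannot masquerade as asymmetry.
Overlapping transcripts each count the mutation once, in their own frame;
bins with zero opportunity are flagged `NA`.

## Replicative profile

Between each pair of neighbouring replication origins, positions get a
fractional coordinate $(pos - o_i)/(o_{i+1} - o_i)$ and fall into ten 0.1
bins (`floor`, clipped to bin 9). A position exactly at an origin starts
bin 0 of the rightward interval; positions outside the first/last origin
of a chromosome are out of scope, since the analysed domain is "between
neighbouring origins". Per bin, the package reports the fraction of A (or
C) mutations whose mutated base sits on the top versus bottom strand —
complementary by construction — and fits ordinary least squares of
fraction against bin centre. Empty bins are excluded from the fit, never
imputed. For an exact or constant fit the residual sum of squares is ~0
and $R^2$ is reported as 1; otherwise the standard $1 - SS_{res}/SS_{tot}$
clipped to $[0, 1]$.

Origins are user-supplied (as a BED-style `GRanges` or a per-chromosome
midpoint list); no particular origin database is assumed.

# Fluctuation assays

`mutationFrequency()` implements resistant colonies divided by
(viable colonies × dilution), with duplicate plates averaged first.
`frequencyToRate()` converts counts to a rate via the Lea-Coulson method
of the median: solve
$$ \tilde r / m - \ln m = 1.24 $$
for the expected mutations per culture $m$ from the median resistant
count $\tilde r$, then $\mu = m / N$. The defining relation is solved
numerically (monotone in $m$, bracketed `uniroot`), and an approximate
95% CI uses Stewart's log-normal sigma $1.225\,m^{-0.315}/\sqrt{C}$ for
$C$ cultures. When the median is zero the $p_0$ method
($m = -\ln p_0$) substitutes, and with all-zero counts the reported rate
is an upper bound and flagged. A plain per-culture frequency mode is also
provided; the estimator used is always recorded in the result object.
The method-of-the-median default is the standard choice when the exact
historical conversion is not specified, and it is deliberately swappable.

# Equilibrium binding

Anisotropy titrations at fixed labeled-substrate concentration $D$
(5 nM in the motivating experiments, comparable to the measured $K_d$
values, so ligand depletion is not negligible) are fitted to the exact
quadratic one-site solution
$$ Y = M\,\frac{(x + D + K_d) - \sqrt{(x + D + K_d)^2 - 4 D x}}{2 D} $$
with $x$ the titrant (protein dimer) concentration in nM. The curve
passes through $Y(0) = 0$: input anisotropy is assumed
baseline-subtracted, because the model has no offset term; a free-offset
variant (`offset = TRUE`) accommodates raw anisotropy with a nonzero
free-probe value. Fits use Levenberg-Marquardt least squares with
positivity bounds on $K_d$ and $M$, no per-point weighting (per-point
SDs are typically not available), starting from $M = \max Y$ and $K_d$ at
the half-maximal $x$ with fallback starts should the initial Jacobian
degenerate. Replicates (protein preparations) are fitted independently
and summarised as mean ± SD by default; a pooled mode fits all points at
once. As $D \to 0$ the model collapses to the Langmuir isotherm
$Mx/(x + K_d)$; the leading deviation is of order $D K_d/(x + K_d)^2$,
which the numerical tests respect by probing the limit at
$D = K_d \times 10^{-8}$.

# The synthetic-data generator

The generator is first-class, tested code and defines the conditions under
which the pipeline is validated.

* **Reference** (`makeReference()`): random sequence at a set GC content;
  non-overlapping stranded transcripts with 1500-bp reserved flanks and a
  minimum intergenic gap, placed with random slack; origins laid out
  roughly evenly with jitter. Placement infeasibility is a sizing error,
  not a silent truncation.
* **Catalogs** (`simulateCatalog()`): events per genome are Poisson;
  classes follow a 6-vector of purine-keyed weights; complex events are
  exactly two substitution records 1–10 bp apart (the minimal generator
  satisfying the ≤10 bp definition); depth is Poisson and alt fraction is
  Normal(vafMode, 0.03) truncated to $[0,1]$, which yields a predictable
  share of filter-failing records. C:G mutations choose their mutated-C
  strand by rejection sampling against a per-site probability combining a
  linear inter-origin gradient (`repGradientC`, matching the
  linear-regression readout) with an odds multiplier on the
  non-transcribed strand inside transcripts (`txBiasC`), so both injected
  parameters are recoverable by the corresponding profiles.
* **Fluctuation counts** (`simulateFluctuation()`): Poisson mutation
  events with the classic $P(C \ge k) = 1/k$ clone-size law, capped at the
  culture size — validated against a naive generation-by-generation
  simulator.
* **Titrations** (`simulateTitration()`): the binding model plus Gaussian
  noise.

What the generator does **not** emulate: real yeast chromosome structure
and base composition, replication timing beyond the linear inter-origin
coordinate, read-level sequencing error, selection, and mutation-rate
heterogeneity along the genome. Passing tests therefore demonstrate that
the estimators recover what was injected under idealised sampling — not
that real data meet those assumptions.

## Default study conditions

Chosen once to mirror the motivating experimental design, and used by the
tests and the acceptance script: 75 wild-type-like and 22 mutant-like
genomes; wild-type burden mean 15 events/genome and a 12.7-fold elevated
mutant group; 95% substitutions, 4% indels, 1% complex events; wild-type
class weights dominated by A>G and A>T; depth mean 50×, alt-fraction mode
0.5; fluctuation assays with $\mu = 10^{-7}$, $N = 10^8$ cells, 24
cultures; titrations at $D = 5$ nM, amplitude 0.2, noise SD 2.5% of the
amplitude, three replicates. Asymmetry-recovery runs use a dedicated
high-transcript-coverage reference (2 × 200 kb, 16 transcripts of
12–15 kb) with ~10,000 C substitutions for the 2× transcriptional bias and
~8,000 for the 0.6 replicative gradient — sizes at which sampling error is
several times smaller than the tested tolerances, while the whole suite
stays fast.

# Worked example

```{r example, eval = FALSE}
ref <- makeReference(genomeSpec(seed = 101))
params <- catalogSimParams(seed = 1, nSamples = 5,
                           mutationsPerGenomeMean = 50)
cat1 <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, params)
kept <- filterGenomeCalls(cat1)
kept <- removeRecurrent(kept)
catalogs <- lapply(unique(kept$sample), function(s)
  SampleCatalog(kept[kept$sample == s, ], genotype = "WT"))
perGenomeBurden(catalogs)
transcriptionDensityProfile(kept, ref$transcripts, ref$genome)
```

# Known limitations

* Transcription profiles report per-bin densities only; no sub-bin
  localisation of where an asymmetry decays (e.g. within the first flank
  bin) is attempted.
* The fluctuation module implements the method of the median and the
  $p_0$ fallback; maximum-likelihood estimation with partial plating
  corrections is out of scope (the estimator slot leaves room for it).
* Replication asymmetry is the top/bottom-strand fraction between
  origins; leading/lagging template inference from fork direction is
  deliberately not performed.
* Trinucleotide-context (96-class) signatures are out of scope.
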