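---
title: "Methods: introgression and selection screens on transcriptome ortholog sets"
author: "retinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression and selection screens on transcriptome ortholog sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinet)
```

## The analysis

`retinet` implements a comparative-transcriptomics workflow for a clade of
eight species (seven ingroup lineages and one outgroup): conserved ortholog
clusters are built from per-species CDS sets by reciprocal best hits (RBH);
outgroup-polarized biallelic sites are extracted from the cluster
alignments; Patterson's D statistic is computed in two estimator forms to
detect introgression; and a pairwise Ka/Ks screen flags clusters as
candidates for positive selection, feeding a branch-site test plan.

The motivating setting is an eye-transcriptome study of *Heliconius*
butterflies (with *Dryas iulia* as outgroup), where the contested placement
of one lineage can reflect either incomplete lineage sorting (ILS) or
ancient hybridization. Everything here runs on synthetic data with known
ground truth, so each stage is testable end to end.

## Patterson's D

For a quartet $(P_1, P_2, P_3, O)$, a biallelic site polarized by the
outgroup is **ABBA** when $P_2$ and $P_3$ share the derived allele, **BABA**
when $P_1$ and $P_3$ share it, and **BBAA** when $P_1$ and $P_2$ do. Under
ILS alone ABBA and BABA are equally likely; gene flow between $P_3$ and one
of $P_1 / P_2$ makes them unequal.

**Count form** (transcriptome mode), summed over ortholog clusters $i$:

$$D = \frac{\sum_i \big(C_{ABBA}(i) - C_{BABA}(i)\big)}
           {\sum_i \big(C_{ABBA}(i) + C_{BABA}(i)\big)}$$

**Frequency form** (genome mode), with $\hat p_{ij}$ the derived-allele
frequency of SNP $i$ in population $j$:

$$D = \frac{\sum_i \big[(1-\hat p_{i1})\hat p_{i2}\hat p_{i3}(1-\hat p_{i4})
 - \hat p_{i1}(1-\hat p_{i2})\hat p_{i3}(1-\hat p_{i4})\big]}
 {\sum_i \big[(1-\hat p_{i1})\hat p_{i2}\hat p_{i3}(1-\hat p_{i4})
 + \hat p_{i1}(1-\hat p_{i2})\hat p_{i3}(1-\hat p_{i4})\big]}$$

Both are ratios of sums: numerator and denominator are pooled over blocks
*before* dividing. This matters — the mean of per-block D values is a
different (and worse) estimator; the package asserts the distinction on the
two-block example $[(3,0),(0,1)]$, where the pooled D is $0.5$ while the
per-block mean is $0$. When every frequency is 0 or 1 the frequency form
reduces to the count form exactly, which the tests check to machine
precision.

Standard errors use the **leave-one-out jackknife** over blocks (ortholog
clusters in count mode, 50-kb windows in genome mode): with
$\theta_{(i)}$ the ratio recomputed without block $i$,

$$SE = \sqrt{\tfrac{n-1}{n}\sum_i (\theta_{(i)} - \bar\theta)^2},$$

and significance is a two-tailed normal test on $z = D/SE$. The phrase
"z-test" is taken at face value: no small-sample $t$ correction is applied,
which is standard ABBA-BABA practice at thousands of blocks. Delete-one
replicates that would leave a zero denominator are skipped with the block
count adjusted, rather than imputed.

Two interpretation points were genuinely open and are resolved as follows:

* the test is read as testing $D \ne 0$ (the usual null), and
* the windowed scan reports a per-window $z$ from a delete-one jackknife
  over the *SNPs inside the window*, while the chromosome-level $D$ uses
  the windows themselves as jackknife blocks. Windows are non-overlapping
  0-based half-open tiles, $[kw, (k+1)w)$ with $w = 50$ kb by default.

## The synthetic generator

No public simulator reproduces this study design, so the package defines a
minimal generative model that makes every downstream estimator testable
with a closed-form expectation.

Each locus draws a hidden genealogy class. With internal branch length $t$
(coalescent units), each of the three ILS resolutions has probability
$q = e^{-t}/3$; an introgression event occurs with probability
$g = \gamma(1 - 3q)$; the locus is otherwise concordant. Informative-site
counts per locus are Poisson with mean `mutRate * sitesPerLocus`, and all
informative sites of a locus show its class's pattern (introgressed and
`ils_abba` loci give ABBA, `ils_baba` BABA, concordant and `ils_bbaa`
BBAA). Pooled over many loci,

$$E[D] = \frac{g}{g + 2q},$$

implemented as `expectedD()` and used as the recovery oracle: at
$\gamma \in \{0, 0.05, 0.1, 0.2\}$ and 5,000 loci the estimate falls within
3 jackknife SEs of this value in at least 95% of seeded replicates.

Defaults are `gamma = 0.1` and `tInternal = log(2)` (each ILS class has
probability 1/6). The real data's ILS/introgression mix is unknown, so
these are deliberate, exposed round numbers — moderate ILS with a
detectable but not overwhelming introgression excess — not estimates.

**Alignments.** Cluster mode evolves a random sense-codon root sequence
down an eight-taxon gene tree matching the locus's class (the derived pair
is placed sister). Mutations are single-nucleotide; changes creating stop
codons are rejected and resampled so alignments stay translatable;
alignments are gap-free by construction (no aligner is exercised — that is
out of scope). Per-locus selection applies $\omega$: nonsynonymous changes
are accepted with probability $\min(1, \omega)$ and synonymous ones with
$\min(1, 1/\omega)$. The second clause is the package's own extension of
the usual acceptance trick: acceptance of nonsynonymous changes alone
saturates at 1 and cannot produce Ka/Ks above 1, so suppressing synonymous
changes for $\omega > 1$ is what lets realized Ka/Ks track $\omega$ on both
sides of neutrality. One haploid sequence per taxon matches a
one-transcriptome-per-species design.

**Windowed frequencies.** Genome mode emits SNPs for the four quartet
populations along one synthetic chromosome. A contiguous tract of windows
(20% by default) is marked introgressed; inside it per-SNP classes use the
configured $\gamma$, outside $\gamma = 0$. Populations on the derived side
of a SNP's class have true derived frequency 0.9, others 0.05 (simulator-only
constants: polymorphic but strongly differentiated), and observed
frequencies are binomial over `nChromPerPop` haplotypes. With one haplotype
per population all frequencies are 0/1 and the two D estimators coincide
exactly.

What the generator does **not** emulate: recombination within loci,
demographic history, linked selection, sequencing error, assembly artifacts
and alignment error. Passing tests demonstrate estimator correctness and
calibration under the generative model, not robustness to those real-data
complications.

## Orthology

Per species, CDS records are reduced to the longest isoform per gene (ties:
lexicographically smallest isoform id). The similarity scorer replaces an
external aligner with a deterministic k-mer-seeded ungapped extension:
shared 11-mers seed diagonals, and each diagonal's best contiguous segment
(match $+1$, mismatch $-1$) is found by prefix sums. A hit qualifies at
score $\ge 30$; at that threshold unrelated random 500-bp sequences pass in
well under 1% of trials (checked by simulation) while a 5%-diverged copy
scores near full length. The significance surrogate
$m \cdot n \cdot 2^{-score}$ is monotone in the score and exists for
interface compatibility.

Clusters require *all eight species* and the full clique property: every
ordered species pair within a cluster must be mutually best-hitting, which
is stricter than a star around one reference species and independent of
input order. Multi-copy families that cross-map therefore drop out rather
than being collapsed — the conservative reading when single-copy status is
uncertain. Best-hit ties break by longer aligned length, then
lexicographic id, making output deterministic. The ortholog hit ratio
(aligned length over reference CDS length) is capped at 1 with overhangs
flagged.

## Ka/Ks and the selection screen

The pairwise rate estimator is Nei–Gojobori (1986), chosen over
Li-family methods because every step has a clean brute-force oracle:

* **Sites**: each codon position contributes the synonymous fraction of its
  single-base changes, with changes to stop codons excluded from numerator
  and denominator; the position keeps weight 1, so $S + N = 3\,L$ codons.
* **Substitutions**: per differing codon pair, synonymous/nonsynonymous
  assignments are averaged over all $k!$ orderings of single-base steps,
  orderings through stop codons excluded; codons with all orderings blocked
  are skipped and flagged.
* **Correction**: Jukes–Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$, with
  $p \ge 3/4$ flagged saturated.

Both countings are verified in the test suite against independent
exhaustive enumeration over all $61 \times 61$ sense-codon pairs, and the
worked pair `TTT GCA ATG GGG` vs `TTC GCA ATG GGG` gives
$\bar S = 7/3$, $K_a = 0$, $K_s = 0.6355$.

The screen retains (cluster, pair) results with ratio $> 1$, a gap-free
fragment of at least 100 bp and $K_s$ below a saturation cap of 2.0
(configurable). These automated filters stand in for manual curation of
poorly aligned candidates. Because a neutral locus sits exactly at the
ratio-1 decision boundary, roughly half of neutral pairs exceed 1 by
chance; recovery of simulated selection is therefore assessed as enrichment
(odds ratio of truth-flagged loci among retained pairs), not as a pure
false-positive rate. Note the mean of pairwise ratios under neutrality sits
slightly above 1 (both rates are noisy ratios; Jensen's inequality), while
the median is centered at 1 — the tests bound the mean within $[0.9, 1.1]$.

Branch-site likelihood machinery is deliberately out of scope: the package
enumerates the test *plan* — one row per (candidate cluster, foreground
branch) over the fixed topology
`(((((sara,hortense),erato),doris),((cydno,melpomene),hecale)),iulia)` with
8 terminal and 4 internal foregrounds, each row carrying a
foreground-tagged newick for an external engine. Benjamini–Hochberg FDR
control is provided as the standard step-up rule, returning the adjusted
threshold $p_{(k)}$ alongside the rejection set; it is cross-checked
against `stats::p.adjust` in the tests.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only where an
  output format requires it.
* Missing data: listwise deletion within the active quartet only; ambiguity
  codes are treated as missing; triallelic columns are excluded rather than
  recoded. Sites with an unusable outgroup call are dropped and counted.
* Polarization always follows the outgroup, even when the outgroup carries
  the globally rarer allele.
* Concordance majorities are the argmax of (BBAA, ABBA, BABA) counts; ties
  are reported `"unresolved"`.
* One master seed drives everything; the generators derive fixed per-stage
  offsets from it, so any subset of stages reruns identically.
* Problem sizes in the tests and the acceptance script (5,000 loci for
  recovery, 2,000-locus nulls over a few hundred seeds, 20–60 simulated
  clusters for alignment-level experiments, 300 windows for scan
  calibration) were chosen so the whole suite completes in a few minutes
  while leaving Monte-Carlo noise well inside the asserted bands.

## Limitations

* The RBH scorer is nucleotide-space and ungapped; highly diverged or
  indel-rich orthologs that a translated, gapped aligner would recover will
  be missed. The scorer is pluggable by design.
* NG86 is a counting method; it ignores transition/transversion bias and
  codon frequencies, so absolute ratios differ from ML estimators — the
  screen's decision rule (ratio $> 1$) is what the package commits to.
* The frequency-mode simulation plants tracts at window granularity;
  sub-window tracts and recombination breakpoints are not modeled.
* The jackknife normal approximation is slightly anticonservative for
  per-window tests at moderate SNP counts (the null rejection rate at
  $|z| > 1.96$ runs a point or two above 5%); chromosome-level tests over
  hundreds of blocks are well calibrated.

## A worked run

```{r example, eval = FALSE}
cfg <- simulationConfig(nLoci = 500, gamma = 0.2, seed = 1)
sim <- simulateLocusPatterns(cfg)
dTest(sim$counts, quartet = c("sara", "hortense", "erato", "iulia"))
expectedD(0.2, log(2))
```

The full pipeline (simulate, cluster, D suite, windowed scan, Ka/Ks screen,
branch-site plan, JSON report) runs from one config via `runPipeline()`;
see the README for the command-line acceptance run.
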