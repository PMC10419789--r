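---
title: "Models and methods behind methylscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methylscape` implements the post-alignment half of a plant whole-genome
bisulfite sequencing (WGBS) study: it consumes per-cytosine methylation
count reports (the output of a bisulfite aligner's methylation extractor),
quantifies methylation in the CG, CHG and CHH sequence contexts, calls
differential methylation between two samples, relates methylation to gene
expression and to 24-nt siRNA abundance, and ships a fully seeded
synthetic-data generator so that every stage can be validated against a
known ground truth. This vignette explains the statistical model of each
stage, the defaults and why they were chosen, and what the synthetic
validation does and does not demonstrate about real data.

## Methylation quantification

A cytosine's methylation level is the fraction of sequenced reads in which
it survived bisulfite conversion:

$$ \hat{m} = \frac{n_{\mathrm{C}}}{n_{\mathrm{C}} + n_{\mathrm{T}}} $$

where $n_\mathrm{C}$ and $n_\mathrm{T}$ are methylated and unmethylated
read calls. Levels are only estimated for sites covered by at least four
reads (`min_coverage = 4` throughout); the same filter applies to
histograms and to eligibility for differential testing, where it must hold
in *both* samples. Aggregate levels over a set of sites are *weighted*
(pooled counts divided by pooled counts) by default, which is the natural
extension of the count-ratio definition and is robust to shallow sites;
the site-averaged alternative is also computed (`mean_site_level`) because
the two estimators diverge when coverage correlates with methylation.

Context is classified from the two bases 3' of the cytosine on its own
strand: `CG`, then `CHG` (H = A, C or T), then `CHH`. The sub-context is
the full trinucleotide. A site within two bases of a chromosome end, or
whose trinucleotide contains an N, is undefined (`NA`) and excluded
everywhere — this applies even to a would-be CG at the penultimate base,
because the trinucleotide is not defined there. Strands are never merged:
the CX report is per strand and the siRNA analysis distinguishes sense
from antisense methylation.

The bisulfite conversion rate is estimated from an unmethylated spike-in
chromosome (classically lambda phage): one minus the pooled methylated
fraction over all spike-in cytosines, all contexts, with no coverage
filter (every call is informative for a rate estimate; filtering would
bias nothing but discard data).

**Calling methylated cytosines.** Whether a covered site "is methylated"
(mC) is not derivable from the level alone at finite depth. We test each
covered site's methylated count against the measured non-conversion rate
with a one-sided binomial test and control the false discovery rate at
0.05 per context (Benjamini–Hochberg). The simpler rule "at least one
methylated read" is available (`rule = "any_meth"`) because some published
analyses use it; the binomial rule is the default as it is the field
standard and self-calibrates to the spike-in.

## Metagene profiles and expression strata

Profiles use the standard 60-bin geometry: the 2-kb upstream flank, the
feature body, and the 2-kb downstream flank are each divided into 20 bins
— flank bins fixed at 100 bp, body bins proportional to feature length —
all oriented 5'→3' along the feature (minus-strand features are
reversed). Within a feature-bin, the level is weighted; across features,
each feature counts once (equal weight), and a feature contributes to a
bin's average only if it has a covered site there. Feature-level averaging
was chosen over site-level pooling because the profile is a statement
about the *typical gene*, not the typical read; the two weightings differ
whenever long features are systematically different from short ones.
Features shorter than 20 bases make body bins coarser than sites; they are
profiled anyway with a logged warning.

Expression strata follow the conventional FPKM ladder: silent
(FPKM = 0), (0, 1], (1, 10], (10, 50] and (50, ∞), all intervals
right-closed. The (1, 10] boundary completes the decade ladder implied by
the printed boundaries of the other groups and is configurable. The
tertile scheme ranks genes by FPKM and labels the bottom and top thirds
low and high (ties broken by first occurrence; the middle third is
dropped). Promoter and downstream regions are the strand-aware 2-kb
flanks beyond the TSS and TES, truncated at chromosome ends rather than
extended into fabricated sequence.

## Differential methylation

Both differential units use Fisher's exact test on 2×2 count tables and
Benjamini–Hochberg FDR control, applied separately per context and per
comparison over tested units only:

* **DMC** — a cytosine covered ≥ 4× in both samples, tested on its
  (methylated, unmethylated) pairs; reported when q < 0.05 *and*
  |Δ level| ≥ 0.2.
* **DMR** — the genome is partitioned into fixed 1000-bp bins from
  coordinate 0 (a partition, not a sliding window); per bin the counts of
  eligible context cytosines are pooled into one table; reported when
  q < 0.01 and the pooled |Δ| exceeds the context threshold 0.2 (CG),
  0.15 (CHG) or 0.1 (CHH). The laddered thresholds reflect the lower
  dynamic range of non-CG methylation.

Bins additionally need at least 4 eligible cytosines (`min_sites`,
configurable): near-empty bins carry almost no information but would
enter the BH pool and can produce spuriously confident calls from two or
three deep sites. "Hyper" always means higher in the *test* sample.

The two-sided Fisher p-value uses the minimum-likelihood rule — the sum of
hypergeometric probabilities of all tables no more probable than the
observed one, with a 1e−7 relative tie tolerance. This is the dominant
convention (it is what `stats::fisher.test` implements, and the test
suite cross-checks against it); the alternative "double the smaller tail"
convention can differ and is not offered. The implementation is
vectorised over sites by flattening each table's hypergeometric support
into one `dhyper` call, which is what makes genome-wide per-cytosine
testing practical in R.

DMR–gene assignment is by ≥ 1 bp interval overlap with the gene body, the
strand-aware 2-kb promoter, or the 2-kb downstream flank; one DMR may hit
several genes and several regions of the same gene. Term enrichment of
the resulting gene sets is the hypergeometric upper tail against a flat
gene→term map, BH-corrected across terms, with the default universe being
all annotated genes (using expressed genes only is a choice the caller
can make by passing a different universe).

## Small-RNA integration

Reads are mapped by exact full-length match, both strands, and only reads
with exactly **one** occurrence genome-wide are kept — a read matching
both strands, or two loci, is ambiguous and dropped (tallies are
reported). At desk scale this is implemented with Biostrings dictionary
matching rather than an external aligner; the policy ("no mismatch,
unique") is fully specified, so nothing is lost by not shelling out.

The positional association around 24-nt siRNA loci indexes genome
positions −10 … 33 in the read's 5'→3' orientation and counts, per
position, alignments whose sense-strand base is a called mC and whose
antisense-strand base is a called mC (mC*). Under RNA-directed DNA
methylation, mC tracks the read's cytosines and mC* its guanines. The mC
definition defaults to the binomial caller above and can be switched to
`any_meth`.

The genome-wide association is a Spearman rank correlation between
per-2-kb-bin siRNA abundance (reads-per-million, copies-weighted, a read
assigned to the bin containing its 5' end) and the bin's weighted
methylation level per context; bins with no covered context cytosine are
excluded. RPM's denominator is the total copy count of uniquely mapped
reads of all lengths (configurable), and abundance metaprofiles over
genes/TEs reuse the 60-bin geometry with per-kb normalisation so flank
and body bins are comparable.

## The synthetic-data generator

The generator emulates the study design the package targets: two
conditions of one plant methylome with planted differences, an
unmethylated spike-in, siRNA reads coupled to CHH methylation, and
expression anti-correlated with promoter methylation.

* **Genome and annotation** — i.i.d. uniform A/C/G/T chromosomes; genes
  and TEs placed without overlap, strands random; a spike-in chromosome
  (default name `lambda`) appended.
* **Site model** — each cytosine's true level is drawn once from a Beta
  distribution centred on its compartment × context mean with a
  per-context concentration. Defaults (gene/TE/intergenic CG
  0.35/0.85/0.50, CHG 0.10/0.65/0.30, CHH 0.05/0.30/0.10; concentrations
  CG = CHG = 0.35, CHH = 2) give bimodal CG/CHG site-level histograms and
  mostly-low CHH, the qualitative shape of real plant methylomes.
  Degenerate means (exactly 0 or 1) bypass the Beta draw so the
  boundary cases are exact.
* **Reads** — coverage is Poisson (mean 20); methylated calls are
  binomial with success probability
  $m(1-\epsilon_m) + (1-m)\,\epsilon_c$, where $\epsilon_c$ is the
  conversion error (default 0.004, i.e. a 99.6 % conversion rate, in the
  QC regime real libraries report) and $\epsilon_m$ (methylated read as
  T) defaults to 0.
* **Planted DMRs** — both conditions share the per-site Beta draw;
  condition B's level is shifted by ±δ (clipped to [0, 1]) inside planted
  regions only. Sharing the draw is what makes a no-DMR pair genuinely
  null for a read-count test: independent redraws would add biological
  variance that Fisher's test does not model, and the type-I control
  checks would (correctly) fail. A planted region containing no cytosine
  of its context is recorded as a warning in the manifest.
* **siRNA** — 24-nt read intensity per 2-kb bin is
  `base + slope × (bin true CHH level)`; 21–23-nt background is uniform.
  Read sequences are copied from the genome strand of origin, so mapping
  them back is exact by construction.
* **Expression** — `log(1 + FPKM) = baseline − slope × (promoter mCG) +
  N(0, sd)`, truncated at zero; the truncation populates the silent
  stratum.

Every derived stream (genome, truth, per-condition reads, siRNA,
expression) draws from an independent sub-seeded generator, so any stage
is reproducible in isolation and adding a stage never perturbs another.

**What the synthetic validation shows — and what it does not.** Passing
recovery tests on this generator demonstrates that the estimators and
tests are *correct under their own model*: conversion-rate recovery,
nominal type-I control on null pairs, high sensitivity on planted 1-kb
DMRs of Δ = 0.3 at 20× coverage, and rank-correlation recovery of the
siRNA–CHH coupling. Real WGBS data violate this model in known ways the
generator deliberately omits: PCR duplicates and M-bias, mapping bias in
repeats, copy-number variation, batch effects between libraries, and
biological replicate variance (the Fisher test treats counts as the only
noise source, so with real replicates its p-values are anti-conservative
— the 1-kb binning and delta thresholds mitigate but do not remove this).
Conclusions about real tissue comparisons should rest on the delta
thresholds and on replication, not on the q-values alone.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; only the I/O
  layer converts (CX reports and GFF3 are 1-based on disk, BED and
  bedGraph are not). This removes off-by-one ambiguity between dialects.
* CX reports covering all cytosines and reports restricted to covered
  sites are both accepted; absent sites are never imputed.
* Histogram bins over [0, 1] are right-closed with 0 assigned to the
  first bin, so the "fully unmethylated" and "fully methylated" modes sit
  in the terminal bins.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite checks it against an independently written step-up reference.
* Spearman correlation uses average ranks for ties and the asymptotic
  p-value (`exact = FALSE`), as tied RPM values are routine.
* All-zero-margin Fisher tables return p = 1 by convention; empty inputs
  return empty outputs rather than errors wherever a downstream stage can
  proceed (e.g. a context with no DMRs).
* Validation scale: the shipped checks run on genomes of 0.1–1 Mb with
  ~50k–500k cytosines, 20× coverage, 100 planted DMRs and 10^5 siRNA
  reads — sizes chosen so the full statistical battery (enumeration
  oracles, 20 null pairs, 500-bin correlations) completes on a laptop
  while leaving every estimator in its asymptotic working range.

## Limitations

The package consumes extractor output and never touches reads: trimming,
alignment, duplicate marking and M-bias trimming are upstream concerns.
Differential testing is two-sample without replicates or covariates; for
replicated designs a beta-binomial or GLM framework would be needed.
GO structure is not modelled — enrichment uses a flat gene→term map
without DAG propagation. sRNA analysis makes no attempt at miRNA
annotation or phasing; the 21–23-nt fraction is carried only as
background.
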