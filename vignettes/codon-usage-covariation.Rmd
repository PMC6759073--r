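---
title: "Codon usage, codon-pair covariation, and taxonomic signal in coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage, codon-pair covariation, and taxonomic signal in coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# The model

Synonymous codons are not used uniformly. Two forces shape their usage:
genomic GC content, which pushes every family toward GC- or AT-ended
codons, and lineage-specific preferences, of which the arginine family
(AGA, AGG, CGA, CGC, CGG, CGT) carries the strongest domain-of-life
signal — Archaea favor AGA/AGG, Bacteria CGC/CGT, Eukarya sit in
between. `codonbias` quantifies both axes and adds two within-transcript
statistics: a Z score for codon autocorrelation and the RSCPU ratio for
codon-pair usage.

## RSCU

For codon $c$ of amino acid $a$ with synonymous-family size $k_a$ and
family count $n_a$,

$$\mathrm{RSCU}(c) = \frac{x_c}{n_a / k_a},$$

the observed count over the count expected under equal synonymous usage.
A sequence or pooled collection becomes a 59-dimensional vector (Met,
Trp and stops excluded) in a fixed canonical order: amino acids
alphabetically by three-letter code, codons alphabetically within each
family. Families absent from a sequence carry no information; their
entries are imputed at the neutral value 1 and flagged, so downstream
ordination sees "no signal" rather than a spurious extreme. A species
profile pools codon counts across all its genes before computing RSCU
(count-weighted); the unweighted mean of per-gene vectors is available
as a mode, but pooling is the default because it is robust to short
genes and matches the notion of a genome-wide usage bias.

## PCA, the scree rule, and the classifier

Per-sequence RSCU matrices are mean-centred (not scaled — RSCU values
already share a scale) and decomposed with PCA. Component signs are
fixed (largest-magnitude loading positive) so results are
deterministic. The first component tracks GC content: GC-ended codons
load with one sign, AT-ended with the other. The taxonomic signal sits
in the following components.

The scree rule retains components before the elbow of the
explained-variance profile, operationalised as the interior point of
maximal second difference (curvature). On per-sequence RSCU data the
GC component is so dominant that this rule alone often retains a single
component — which is exactly the component that carries *no* domain
information. Domain classification therefore floors the retention at
three components by default (`k_min = 3` in
`train_domain_classifier()`), the retention appropriate for
per-sequence analysis of this kind of data; the floor is a parameter.

The classifier is a C-classification SVM (radial kernel) on the PCA
scores with class weights inversely proportional to class frequency.
Cost and kernel width are tuned by grid search
(cost $\in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.001, 0.01, 0.1, 1\}$)
under 5-fold cross-validation; training is deterministic given a seed.
Held-out sequences are projected with the *training* centring and
loadings before prediction. Evaluation reports accuracy, a one-vs-rest
ROC/AUC per class from the SVM class probabilities, and accuracy per
sequence-length bin (default bins 100–200, 200–500, 500–1000, 1000+ nt).

## Codon autocorrelation

For each amino acid, successive occurrences along a transcript form
ordered codon pairs (other amino acids may intervene; an
adjacent-codons-only mode exists for sensitivity analysis). Pairs never
cross gene boundaries. Pooled over a corpus, each cell of the
per-amino-acid pair matrix is compared with the count expected if
successive choices were independent draws from the corpus within-family
codon frequencies, $E(c_1, c_2) = n \, f(c_1) f(c_2)$, and Z-transformed:

$$z = \frac{O - E}{\sqrt{n\,p\,(1 - p) + 2\,O_v\,\delta}}, \qquad p = E / n,$$

where the correction term accounts for *overlapping pair slots*: when an
amino acid occurs three or more times in one gene, consecutive pairs
share their middle occurrence and cell counts are no longer sums of
independent pairs. With $O_v$ the number of such overlapping slot pairs,
$\delta = p^{3/2} - p^2$ on the diagonal (the expected diagonal
frequency is a squared codon frequency) and $\delta = -p^2$ off it.
`pair_zscores()` defaults to the plain binomial ($O_v = 0$);
`codon_autocorrelation()` counts $O_v$ and passes it. The correction
matters: on realistic corpora the plain binomial misstates $z$ by up to
a quarter of its magnitude, while the corrected form agrees with a
$10^5$-replicate Monte-Carlo simulation of the null (codons redrawn
independently from the family frequencies at every occurrence slot,
gene boundaries preserved) to within 0.05.

Pairs are shaded as in covariation tables: `strong` for $z > 3$,
`slight` for $0 < z \le 3$, `none` for $z \le 0$ (both boundaries
closed on the lower category). tRNA labels, when supplied, are merged
into exports as pass-through annotation only.

## RSCPU

The Z statistic grows with corpus size, which makes it unsuitable for
comparing species. The relative synonymous codon pair usage is the
scale-free alternative:

$$\mathrm{RSCPU}(c_1, c_2) =
  \frac{f^{\mathrm{obs}}_{\mathrm{pair}}(c_1, c_2)}
       {f^{\mathrm{obs}}(c_1)\, f^{\mathrm{obs}}(c_2)},$$

with pair frequencies taken within each amino acid (pair count over the
amino acid's total pairs) and codon frequencies within the synonymous
family. A value of 1 means pair usage is fully explained by individual
codon usage. Whether the original formulation normalised within family
or over all codons is ambiguous; within-family is the default and a
global-frequency mode is exposed. Pairs whose expected frequency is
zero (a codon never used) are undefined and reported as `NA`; for
cross-species clustering only, they are imputed at the neutral value 1.

## Expression-stratified optimality

Genes matched to a protein-abundance table are ranked by abundance
(ties broken by gene id) and split into equal-size quantile bins
(default quintiles); codon counts are pooled per bin. A codon is called
`optimal` when its RSCU in the high stratum is at least $1 + \delta$
and exceeds its low-stratum value, `nonoptimal` when at most
$1 - \delta$ and below it, `intermediate` otherwise; $\delta = 0.1$ by
default. The neutral band gives the intermediate category a concrete
rule. A *preference switch* occurs when a family's most-used codon
differs between the low and high strata (alphabetical tie-break, ties
flagged). A loess trend of per-gene RSCU against log abundance
(degree 2, span 0.75, fitted values clamped at 0) is provided for
description and plotting; calls use the binned RSCU, which is the
testable quantity.

The overlap statistic connects the two analyses: among pairs with
$z \ge 3$ SD, the fraction formed by two codons of the same optimality
class. Pairs touching an intermediate codon cannot be assigned either
way; the default accounting excludes them from numerator and
denominator and lists them separately, and an `include` mode keeps them
in the denominator, since the original accounting of such pairs is
ambiguous.

# The synthetic corpus generator

Corpus-scale CDS collections with known structure replace any external
download. Each species is a `species_spec`; `generate_species()` is
byte-reproducible from the spec's seed.

Per gene: a length (uniform over 300–1500 nt in codons), a log-normal
abundance (sd 1.5 natural-log units — roughly three orders of magnitude
across a proteome), an amino-acid sequence drawn from one fixed
reference composition (so codon-level effects are isolated from
amino-acid effects), an ATG start and a TAA stop.

Codon choice within each family interpolates linearly in scaled log
abundance $e \in [0,1]$ between a point mass on the family's
low-expression preferred codon and one on its optimal codon:

$$p = (1 - c)\,\mathrm{base} + c\,[\,e \cdot \mathbf{1}_{\mathrm{opt}}
      + (1 - e) \cdot \mathbf{1}_{\mathrm{nonopt}}\,],$$

with coupling $c = 0.9$. Preferences thus *reverse* along the
expression gradient, which is what expression-stratified codon usage
shows and what makes planted switches recoverable; a plain
uniform-to-optimal interpolation leaves the bottom quintile with enough
optimal mixing that its argmax is ambiguous. With probability
`stickiness` a repeated occurrence of an amino acid reuses the previous
codon, planting autocorrelation without changing marginal frequencies.

GC content is targeted by a per-species factor $e^{\beta w(c)}$ on the
family weights, where $w$ counts G/C at codon positions 1–2 once and at
the synonymous third position twice (GC pressure acts most freely at
the third position; the double weight also makes every family's
GC-ended codons respond strictly more than AT-ended ones, which is why
the first principal component's loading signs partition by ending
nucleotide). $\beta$ is calibrated by root-finding so the expected
corpus GC matches the target; with the amino-acid composition fixed the
attainable range is roughly 0.30–0.65, and infeasible targets warn and
clamp. The optimal/nonoptimal codons of each species are sampled from
that species' calibrated baseline usage, so the expression coupling
does not pull the corpus off its GC target.

Arginine is the exception throughout: its six-codon profile is the
planted domain signature (values modeled on real genomes — an
AGA/AGG-heavy archaeon, an E. coli-like bacterium, a human-like
eukaryote; per-species log-normal jitter sd 0.10) and it keeps that
profile at all expression levels and under GC pressure, apart from a
weak fixed third-position preference $(g/(1-g))^{1/2}$ on GC-ended
arginine codons. That robustness is precisely what makes arginine a
usable domain marker. The default three-domain corpus shares one GC
range (0.30–0.70) across domains, so GC cannot separate them, and adds
a mild (×1.25) domain-consistent preferred codon in the other families.

What the generator does **not** emulate: phylogenetic correlation among
species, amino-acid composition variation, length–expression coupling,
horizontal transfer, sequencing error, or any tRNA-level mechanism.
Passing tests therefore show that the statistics recover the structure
they are defined on — not that real corpora contain that structure.

# Numerical choices

- Canonical codon order fixed (alphabetical within family, families
  alphabetical); every matrix and export uses it.
- Sequences with length not a multiple of three are rejected by
  default; internal in-frame stops warn but the sequence is kept
  (public CDS sets contain them); codons with ambiguity characters are
  skipped and counted, never imputed.
- The species filter keeps species with strictly more than 1000 genes
  by default.
- The train/test split is at sequence level (fraction 0.10 by default,
  `round(N × fraction)` training sequences); a species-level mode
  exists for leakage-controlled evaluation. Stratification is off;
  class imbalance is handled by the SVM class weights. Training
  excludes sequences with more than 30% imputed families.
- Degenerate cells ($p \in \{0, 1\}$) have $z$ defined as 0 and are
  flagged; a flat variance profile retains one component with a
  warning; probability ties in prediction break alphabetically.
- Phylum-level classification reuses the same machinery with phylum
  labels, one model per domain.

# Scale of the validation suite

The test suite exercises the full pipeline at desk scale: the
three-domain corpus is 30 species × 100 genes (~900 nt average), the
optimality corpus one species × 500 genes, the Monte-Carlo comparison
$10^5$ replicates on a 40-gene corpus, and the null calibrations 10
species × 100 genes. The whole suite runs in well under a minute on one
CPU. Sizes are chosen so every statistic operates in the regime where
its asymptotics hold (hundreds of pairs per family, dozens of genes per
abundance bin) while staying quick to regenerate.

# Known limitations

- Per-sequence domain accuracy depends on length; very short CDS
  (one-to-two hundred nt) carry mostly imputation and are excluded from
  training by default.
- The binomial-with-overlap variance model assumes within-family codon
  draws are exchangeable across genes; strong per-gene composition
  heterogeneity (beyond what the expression gradient creates) inflates
  diagonal $z$ values for reasons unrelated to within-gene
  autocorrelation. The within-gene permutation property tests
  therefore use homogeneous (stickiness-0, uncoupled) corpora.
- RSCPU is defined over same-amino-acid pairs only; cross-family pair
  statistics are out of scope.
- The genetic code is the standard table by default; per-species code
  variants are configurable but untested beyond table lookup.
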