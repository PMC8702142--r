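---
title: "Kinship inference on a forensic SNP capture panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship inference on a forensic SNP capture panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`forcekin` implements the computational workflow around an all-in-one forensic
SNP capture panel: designing the kinship marker set, calling genotypes from
per-site coverage and allele counts, computing likelihood-ratio kinship
statistics on linked markers, simulating expected likelihood-ratio
distributions, and producing ancestry, Y-haplogroup and phenotype-encoding
reports. This vignette describes the models, their assumptions, the tunable
parameters, and the design decisions taken where the choices were genuinely
open.

## The panel and its selection cascade

The panel contains 5422 SNPs: 3931 autosomal kinship SNPs, 134
identity-informative, 241 ancestry-informative and 41 phenotype-informative
SNPs, 246 X-chromosomal and 829 Y-chromosomal SNPs. Kinship SNPs are selected
by a six-step cascade (`design_kinship_panel()`):

1. presence on all major genotyping chips (exact set intersection);
2. alt-allele frequency in [0.2, 0.8] in each of the five continental
   populations (AFR, AMR, EAS, EUR, SAS);
3. at least 0.5 cM between consecutive retained SNPs (greedy left-to-right
   scan per chromosome; a gap of exactly 0.5 cM is retained);
4. LD pruning at r² < 0.1;
5. maximum pairwise population frequency difference strictly below 0.35;
6. exclusion of SNPs in clinically relevant regions (user-supplied blocklist;
   no gene list is bundled).

Three points here were under-determined and are package decisions. First, a
literal minor-allele frequency cannot exceed 0.5, so "MAF 0.2–0.8" is read as
the *designated alt-allele* frequency lying in [0.2, 0.8] per population,
matching chip-annotation convention; `design_params(folded = TRUE)` selects
the folded reading instead. Second, the LD estimator and window are not
dictated by the criterion itself; we use composite LD — squared Pearson
correlation of genotype dosages, which needs no phase information — within a
10 cM window, scanning left to right and removing the later SNP of an
offending pair. Third, genetic positions for markers absent from the map are
linearly interpolated between flanking anchors; markers outside the anchored
range are excluded rather than extrapolated.

## Genotype calling

`call_site()` converts coverage and allele counts into calls with three
thresholds (defaults in parentheses): minimum coverage (10 reads), maximum
minor-read fraction for a homozygote (0.10), and minimum minor-read fraction
for a heterozygote (0.30), where the minor fraction is computed over the top
two alleles only (third-allele reads count toward coverage but never the
genotype — tri-allelic sites are excluded from the panel by design). Sites in
the open band (0.10, 0.30) are "imbalanced": reported, never analysed. At the
boundaries the homozygote rule wins at exactly 0.10 and the heterozygote rule
at exactly 0.30, so every observation lands in exactly one category.
Hemizygous sites (Y, male X) are called under the homozygote rule alone; a
hemizygous site with minor fraction above 0.10 can only be an artifact and is
marked imbalanced. Whether hemizygous sites should use different thresholds is
not settled; applying the same thresholds is our interpretation.

Base-quality and strand information is abstracted into a per-site boolean
"low-quality minor" flag: `resolve_artifact_minor()` uses it to note a
majority-homozygote genotype at imbalanced sites *for concordance accounting
only* — the site status never changes and imbalanced sites are never used in
kinship, ancestry or phenotype analyses.

Completeness is reported against a sex-adjusted denominator: 5422 for males
and 5422 − 829 = 4593 for females, who carry no Y targets. Sex can be
declared or inferred (male iff ≥ 50 Y sites reach 10X).

## The multipoint likelihood engine

Kinship statistics are likelihood ratios LR = Pr(genotypes | H1) /
Pr(genotypes | H2), with H2 always "unrelated". Because the kinship markers
are dense enough to be genetically linked, likelihoods are computed with a
hidden Markov model on the inheritance-vector space of the hypothesis's
pedigree: one bit per modeled meiosis records which grandparental allele was
transmitted, transitions between adjacent markers factorize per meiosis with
recombination fraction given by the Haldane map function
θ = (1 − e^(−2d/100))/2 for a gap of d cM (no interference — the standard
assumption of multipoint engines; the choice of map function is a package
decision as none is dictated), and chromosomes combine additively in log
space with running rescaling against underflow.

The emission at a marker marginalizes founder alleles: given an inheritance
vector, each typed allele position maps to a founder allele slot, and the
probability of the observed genotypes depends only on the *partition* of
typed positions into identical-slot blocks. The engine therefore
pre-classifies the state space into descent partitions (a few dozen classes
at most) and evaluates one emission per class per marker, vectorised over
markers; the forward pass itself is compiled code. Two exact reductions keep
the state space small: meioses from untyped founders with a single child
(married-in spouses) can never affect the partition and receive no bit, and
any remaining bit under which the partition is invariant is collapsed before
the forward pass. Pedigrees requiring more than 16 bits after reduction are
rejected with a clear message rather than silently approximated.

Numerical choices: population allele frequencies are clamped to
[1e-4, 1 − 1e-4] before any likelihood so a mis-specified private allele
cannot zero out a profile; a single user-selected population's frequencies
(default EUR) are used per analysis. Mendelian conflicts are strict by
default — a marker impossible under every inheritance vector yields
likelihood 0 (LR = 0), mirroring the practice of excluding genotypes
inconsistent with known relationships rather than modeling them — and an
optional per-genotype error rate mixes each observed genotype with a uniform
draw over the genotype space to absorb conflicts when wanted.

Pairwise hypotheses (parent/offspring, full siblings, half siblings, first
cousins, first cousins once removed, second cousins, second cousins once
removed) are realised as minimal template pedigrees with untyped connectors.
The second-degree template is half siblings even where a real case reference
is avuncular; grandparental/avuncular configurations remain expressible
through the missing-person pedigree mode. Missing-person LRs place the
unknown in the pedigree's missing slot:
log10 LR = logL(pedigree with unknown placed) − logL(references alone) −
logL(unknown under Hardy–Weinberg). X-chromosomal LRs use X inheritance
(males hemizygous, father-to-daughter transmission deterministic, only
maternal meioses carry bits).

Posteriors are flat-prior normalizations over a hypothesis set computed in
log space. The default pairwise report normalizes over the two-hypothesis
pair, which reproduces posterior = LR/(1 + LR); `posteriors()` accepts any
hypothesis set, and `blind_search()` normalizes over all tested hypotheses
plus unrelated. "Strong support" is the joint criterion log10 LR ≥ 4 and
posterior ≥ 0.9999. Co-located markers (zero cM gap) are handled exactly by
the forward pass (θ = 0) and need no perturbation.

The engine is validated two independent ways, both exhaustive: enumeration
over inheritance vectors × founder-allele assignments with explicit
Kronecker-product transition matrices (feasible through first cousins), and
enumeration over the connecting-path meiosis bits with per-relationship
coalescence logic and textbook P(g1, g2 | alleles shared IBD) conditionals
(all seven relationships). Agreement is at 1e-9 relative tolerance, and the
unlinked limit reproduces the kappa-coefficient closed forms
(parent/offspring (0,1,0), full siblings (¼,½,¼), half siblings (½,½,0),
first cousins (¾,¼,0), 1C1R (⅞,⅛,0), 2C (15/16,1/16,0), 2C1R (31/32,1/32,0)).

## The synthetic-data generators

No genotype data accompany the study design, so every input is generated:

* **Population frequencies** follow the Balding–Nichols model: ancestral
  frequency p ~ Uniform, population frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F).
  Kinship-class markers use F = 0.05 with p in [0.3, 0.7] — mimicking markers
  that survived the frequency and differentiation filters — while
  ancestry-informative markers use F = 0.3 to produce clear continental
  separation.
* **Pedigree genotypes** are gene-dropped: founder haplotypes are drawn
  independently per marker (Hardy–Weinberg, linkage equilibrium — defensible
  here precisely because the panel is LD-pruned by design), and meioses
  transmit recombinant gametes with Haldane switch probabilities over a
  synthetic genetic map (22 autosomes + X, ~3540 cM of autosome, 1 cM/Mb).
  X markers follow X inheritance and Y markers are patrilineal without
  mutation.
* **Sequencing observations** use negative-binomial coverage with per-site
  dropout; each read reports one of the two gene copies uniformly and flips
  to the other allele with a per-read error rate. Two presets bracket the
  quality range seen in practice: `reference` (mean 225X, dispersion 5,
  error 0.005, dropout 0.005 — near-complete profiles) and `bone` (mean 8X,
  dispersion 1, error 0.01, dropout 0.3 — roughly half the panel callable,
  like degraded skeletal samples).

What the generators deliberately do not emulate: residual LD between panel
markers, index hopping or contamination, reference-allele capture bias,
population substructure within continents, and genotyping error that is
correlated along reads. Passing tests therefore demonstrate correctness of
the inference machinery under its own model assumptions and realistic
marker/coverage scales — not robustness to every artifact of real capture
data.

## Simulation studies and their scale

`run_scenario()` reproduces the panel-performance design: per replicate a
pair is gene-dropped from the relationship's template (related arm) or as two
independent individuals (unrelated arm — simulating H2 exactly rather than
permuting related genotypes), the kinship set is optionally subsampled to a
75% or 25% fraction, and the pairwise LR is computed with linkage. The
original design used 10,000 replicates per scenario; the package default is
500 and the test suite runs 200 per arm, which bounds the Monte-Carlo error
of the exceedance fractions at a few percent while keeping the full suite in
minutes on one CPU. Per-replicate seeds derive from the scenario seed by
counter, so either arm reproduces independently.

At full panel scale the half-sibling and first-cousin scenarios separate
completely from unrelated (related-arm P(log10 LR ≥ 4) ≈ 1), while second
cousins and beyond overlap — `overlap_summary()` quantifies this as the
fraction of related-arm values below the unrelated arm's 99th percentile.

## Predictions

Ancestry uses two views. The naive Bayes classifier computes, per continental
population, the sum of log Hardy–Weinberg genotype probabilities of the
called ancestry SNPs under that population's frequencies, then normalizes
with a flat prior; markers absent from the reference are excluded, and the
1e-4 frequency clamp keeps a single private allele from vetoing a population.
No admixture model is fitted — the likelihood is per-population by
construction. PCA (via `prcomp`) is trained on reference genotypes only, with
reference-mean imputation and scaling; queries are projected with the same
statistics and must share at least half the reference markers.

Y haplogroups are assigned from derived (non-reference) calls against a
haplogroup tree: the reported haplogroup maximizes on-path minus off-path
derived support, ties breaking toward the shallower node; off-path derived
calls are reported as conflicts and on-path ancestral calls as possible
back-mutations. This scoring automates what is otherwise a manual review
step. Phenotype markers are encoded as effect-allele counts (0/1/2/NA) after
strand normalization and exported in the row-per-sample batch layout of the
phenotype-prediction webtool; the prediction model itself is out of scope.

## The bundled fixture

`make_fixture()` writes a complete miniature input set: a ~10%-scale panel
(400 kinship, 40 identity, 40 ancestry, 20 phenotype, 30 X, 60 Y SNPs), the
genetic map, five reference families spanning first- to fifth-degree
relationships to a missing person, a synthetic Y tree and phenotype
effect-allele table (both labelled synthetic), reference-preset observations
for every family reference and bone-preset observations for every missing
person. The reduced scale keeps the end-to-end workflow and its tests fast;
full-scale panels are a single `synthetic_panel()` call. Note that some
statistics are scale-sensitive: the X-chromosomal sibling comparison, for
example, needs the full 246-SNP X set for reliable power, and the package's
validation uses full scale there.

## Known limitations

Inbred or looped pedigrees are not supported (the founder-partition emission
assumes founders are unrelated); mutation models are absent (a true
parent-child mutation would read as a Mendelian conflict unless the error
rate is enabled); pedigrees beyond 16 effective meioses are rejected;
likelihoods use one population's frequencies at a time; and the blind search
is quadratic in the number of profiles.
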