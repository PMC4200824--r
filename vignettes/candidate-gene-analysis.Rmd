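---
title: "Methods: candidate-gene diversity, LD and Q+K association analysis"
author: "candgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene diversity, LD and Q+K association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candgene)
```

`candgene` implements the statistical core of a candidate-gene association
study: diversity and neutrality statistics on a small resequencing panel,
LD decay at the scale of a single gene, single-SNP mixed-model association
in a large structured population, and haplotype trend regression. This
vignette records the models, the tunable parameters, the numerical
choices, and the limits of what the simulation-based tests demonstrate.

## 1. Diversity statistics on the resequencing panel

**Data model.** A panel is a multiple alignment of *n* haplotype
sequences (one FASTA record per sequenced allele, so *n* is the record
count). Any column containing a gap in any sequence is removed before any
statistic is computed — the strictest reading of excluding indel regions —
and `N` bases are dropped column-wise from allele counts. Coordinates are
0-based half-open internally and 1-based closed in printed reports.

**Estimators.** π is the mean proportion of differing sites over all
C(*n*, 2) sequence pairs, computed column-wise from allele counts
(algebraically identical to exhaustive pair enumeration, which the test
suite verifies). Watterson's estimator is θ_w = S/(a_n · L_eff) with
a_n = Σ_{i<n} 1/i. Tajima's D contrasts the pairwise and segregating-site
estimates of θ with the 1989 variance constants; Fu & Li's D* (the
outgroup-free variant) contrasts total segregating sites with singleton
variants. Both are *flagged undefined* — never reported as 0 — when S = 0
or n < 4. We chose D* over the outgroup-based D because the panel carries
no outgroup sequence; a config hook reserves room for D if one is added.

**Coding-region partition.** Synonymous and non-synonymous site counts
follow Nei–Gojobori fractional counting: each codon position contributes
the fraction of its three single-base changes that preserve the amino
acid, averaged over all sequences, so syn + nonsyn = 3 × codons exactly
(tested to 1e-9). Pairwise synonymous/non-synonymous differences average
over all shortest mutational pathways between codons; pathways through a
stop codon are discarded, and codons that are themselves stops are skipped
with a warning (random neutral sequence contains stops; real coding
sequence should not). Changes *to* a stop codon are classified
`"nonsense"` and counted with the non-synonymous class in region tables.
Segregating coding sites are classified against the majority-background
codon; when a tied background exists the site is classified under every
tied background and reported `"mixed"` if they disagree. The genetic code
is the standard nuclear table.

**Reporting.** Per-region tables carry fractional effective lengths for
the synonymous/non-synonymous sub-rows; percent polymorphism is
100·S/L_eff. Display precision is 2 decimals for percentages and 5 for
π/θ_w, with a full-precision JSON sidecar.

## 2. Linkage disequilibrium

LD is computed from haplotype-level 0/1 matrices (the sequencing panel or
simulator output); composite genotype LD is out of scope. For sites *i*,
*j*: D = p_AB − p_A p_B, r² = D²/(p_A p_a p_B p_b), D′ = D/D_max with the
standard bounds. r² equals the squared Pearson correlation of the two
binary columns — an identity the tests exercise as an oracle.

Permutation significance shuffles one site's alleles across haplotypes
and uses the add-one estimator p = (1 + #{r²_perm ≥ r²_obs})/(1 + n_perm)
so p is never 0. Every permutation stream is derived from the global seed
with a counter-based splitter, so results do not depend on evaluation
order.

**Decay model.** The decay of r² with physical distance is fitted with
the Hill–Weir drift expectation

E[r²] = (10+C)/((2+C)(11+C)) · [1 + (3+C)(12+12C+C²) / (n(2+C)(11+C))],

with C = ρ·d and *n* the number of sampled haplotypes. The source
workflow named only "nonlinear regression"; Hill–Weir is the standard
functional form that produces such decay curves and is recorded as an
informed substitution. Fitting is deterministic: a 120-point log-spaced
grid on ρ (plus ρ = 0) followed by Brent refinement between the
bracketing grid points; ρ ≥ 0 is enforced. The threshold-crossing
distance (default threshold r² = 0.1) is found by bisection to ±1 bp and
reported as "beyond range" — not a number — if the fitted curve never
reaches the threshold within 10× the largest observed distance.

**Blocks.** The block finder deliberately replaces the Gabriel
confidence-interval method with a documented simple rule: extend a block
while every adjacent within-block pair has |D′| ≥ 0.8, report blocks of
≥ 2 markers. Block counts on real data are therefore not comparable with
Haploview output.

## 3. Q+K mixed-model association

**Model.** *y* = μ + *Q*υ + *Zu* + *e* with Var(*u*) = σ²ₐK and
Var(*e*) = σ²ₑI. Q is an input (membership proportions; one column is
dropped against the intercept — the model is otherwise rank-deficient,
a point on which association-tool conventions differ). K is the Ritland
marker-based kinship estimator with allele frequencies taken from the
panel itself: per biallelic locus the correlation-type estimate
(P_i P_j/p + Q_i Q_j/q − 1), summed over loci against one degree of
freedom per locus. Negative pairwise estimates are truncated to 0
(documented; relatedness below the panel average carries no usable signal
for this model) and the matrix is conditioned to PSD by clipping negative
eigenvalues at 0 and re-symmetrising. Results are invariant to individual
ordering.

**REML.** With K = UDU′ the rotated model has diagonal covariance
σ²ₐ(D + δI), δ = σ²ₑ/σ²ₐ. The restricted likelihood is profiled on a
60-point grid over log δ ∈ [−10, 10] followed by golden-section
refinement; fixed effects come from generalised least squares at the
optimum and the SNP coefficient is tested with a Wald F(1, n−p). With
K = I and no Q the fit collapses *exactly* to ordinary least squares
(tested to 1e-6 in p). The SNP enters additively as 0/1/2 dosage;
missing calls are per-SNP mean-imputed, and SNPs with > 20% missingness
are dropped. The upstream workflow mentioned permutations inside the
mixed model, which is nonstandard and ambiguous; analytic Wald p-values
are primary here.

**Variance explained.** r²% = 100·(RSS_reduced − RSS_full)/TSS on the
rotated, variance-weighted scale, both models at the full fit's δ,
clipped at 0. The exact definition used by association GUIs is not
published; this RSS-difference definition is the documented choice.

**Multiple testing.** Storey's positive-FDR q-values: π₀ estimated on the
λ grid 0.05–0.95 with a cubic smoothing spline evaluated at λ = 0.95
(single-point λ = 0.5 estimate below 100 tests), then
q_i = min_{p_j ≥ p_i} π₀ m p_j / rank(p_j). With π₀ = 1 this is exactly
Benjamini–Hochberg, which the tests use as a reduction oracle.

**Gene action.** From raw genotypic class means (not model-adjusted —
matching the definition of the published effect tables):
2a = |G_BB − G_bb|, d = G_Bb − (G_BB+G_bb)/2, and d/a = d/(2a/2). The
ratio uses the *unsigned* additive span, so it carries the sign of the
dominance deviation; the published effect tables are internally consistent
only under this convention, which is why it was preferred over signing a
by G_BB − G_bb. Modes: |d/a| ≤ 0.50 codominant, < 1.25 dominant, ≥ 1.25
over/underdominance; a = 0 or an unobserved class yields `"undefined"`.
The allele-substitution effect a_add = p_B G_BB + p_b G_Bb − G is
reported with respect to the dosage-counted allele.

**Subset validation** reruns the entire scan (kinship re-estimated,
Q re-subset and renormalised) inside each labelled subset; a marker is
"validated" when p ≤ 0.05 in at least one subset. Note the null
expectation of that event across three subsets is 1 − 0.95³ ≈ 0.14, so
validation is a replication heuristic, not an error-controlled test.

## 4. Haplotype analysis

Windows are defined on the genotyped-marker index (default width 3,
step 1); named marker subsets are accepted since published windows vary
in width. Within a window, haplotype frequencies are estimated by the
standard EM over phase configurations: enumeration is explicit (window
width capped at 8 markers, 2⁸ haplotypes), the deterministic start is the
product of marker allele frequencies, and iteration stops at a
log-likelihood gain below 1e-8 or 1000 iterations. The likelihood is
provably non-decreasing per iteration and the tests assert it. Expected
per-individual haplotype dosages always sum to 2; individuals missing any
window genotype are excluded from that window (complete-case per window).
One caveat the tests document: with *only* double heterozygotes the
product start is a stationary saddle of the symmetric likelihood, and EM
stays there; any asymmetry in the data (present in all realistic windows)
breaks the tie.

Haplotype trend regression regresses the phenotype on expected dosages of
the common haplotypes (frequency strictly > 5%); rare haplotypes are
pooled into one column — never dropped, preserving dosage conservation —
and one column is absorbed into the intercept for identifiability. The
overall haplotype effect is F-tested and also permutation-tested (1000
phenotype shuffles by default, seeded per window from the global seed +
window index); per-haplotype marginal trend tests and dosage-weighted
trait means are reported. Expected dosages (the canonical HTR
formulation) are used rather than best-guess phases.

## 5. Synthetic data and what the calibrations show

The generators mirror the analysis assumptions, by design:

* `sim_coalescent_haplotypes()` — single-locus Kingman coalescent,
  infinite sites (distinct integer positions, error on saturation), no
  recombination: adequate for a ~2 kb candidate gene, and it keeps E[S] =
  θ·L·a_n exact for calibration. LD structure is delegated to
  `sim_ld_haplotypes()`, a founder copying model with per-gap switch
  probability 1 − exp(−rate·distance) — two small generators instead of
  one ancestral-recombination-graph simulator.
* `sim_structured_genotypes()` — Balding–Nichols Beta-distributed
  subpopulation frequencies around ancestral frequencies with divergence
  F, Hardy–Weinberg within subpopulations, exact indicator Q.
* `sim_phenotypes()` — *y* = μ + Qυ + Σ_j(a_j·dos_j + d_j·het_j) + u + e,
  the generative mirror of the fitted model, with u drawn from σ²ₐK.

Default study conditions used by the calibration suite: a 43-haplotype,
2,266-bp panel at θ ≈ 0.0139 per site (the scale of the motivating
locus); 2,000 coalescent replicates at n = 20, θ·L = 10 for neutrality
calibration; an association population of 400–426 individuals in 2–3
subpopulations at F = 0.1–0.25 with a structure effect of ~1 phenotypic
SD for the confounding demonstration; causal effects of 0.3–0.5 SD;
copying-model switch rate 0.002/bp over a 2.3 kb locus. Problem sizes
were chosen as representative of the study design they emulate.

The calibrations demonstrate: unbiasedness of S and approximate
neutrality of Tajima's D/D* under the coalescent; exact ρ recovery on
noiseless Hill–Weir curves and rate-monotone crossing distances under the
copying model; type-I error control of the Q+K model under a structured
null that inflates naive regression above 0.10; ~95% coverage of
2-SE intervals for causal effects; EM recovery of realized haplotype
frequencies within ±0.02 at n = 400; and realized Weir–Cockerham F_ST
within ±0.02 of the Balding–Nichols F. They do **not** demonstrate
robustness to features absent from the generators: genotyping error,
phenotype measurement structure (block designs, spatial effects),
admixture gradients (Q here is a hard partition), selection, or
recombination within the gene. Conclusions about real data inherit those
caveats.

## 6. Degenerate inputs and numerical conventions

* Statistics undefined at S = 0 or n < 4 are flagged `NA` with an
  `undefined` attribute, never silently 0.
* Monomorphic sites: LD errors (undefined), kinship and association drop
  them, EM retains them (haplotypes collapse) with a warning.
* A SNP collinear with Q is skipped and flagged, not forced.
* Q rows off unit sum by ≤ 0.05 are renormalised with a warning; larger
  deviations are errors.
* All file formats are plain text (FASTA, TSV, JSON); VCF positions are
  converted to the internal 0-based convention in one reader.
* One global seed governs every stochastic step; per-window/per-stage
  streams are derived with a counter-based splitter so results are
  independent of evaluation order. R's 32-bit integer seed range is
  respected.
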