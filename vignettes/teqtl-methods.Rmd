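---
title: "Mapping translational-efficiency QTLs in a recombinant inbred panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping translational-efficiency QTLs in a recombinant inbred panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`teqtl` maps genetic loci that change how efficiently mRNAs are translated,
in a two-founder recombinant inbred (RI) panel profiled with paired
mRNA-seq and Ribo-seq. The pipeline has six statistical stages:

1. **Genotype map.** Biallelic marker calls are filtered (markers near
   indels, with missing or heterozygous calls, monomorphic, or with call
   rate < 0.99 are removed) and collapsed into *strain distribution
   patterns* (SDPs): maximal runs of markers whose across-line founder
   pattern is identical. Patterns recurring elsewhere in the genome are
   merged into one multi-location test unit, and identical patterns
   separated by a single alternating block (a typical genotyping-error
   signature) are span-merged. The SDP, not the marker, is the unit of
   association testing.
2. **Joint normalization and TE.** mRNA and Ribo count matrices are pooled
   and normalized against a common median-of-ratios reference
   (`DESeq2::estimateSizeFactorsForMatrix` on the column-bound matrix), so
   the two assays are on a comparable scale. A gene's translational
   efficiency (TE) trait is the residual vector of the per-gene ordinary
   least-squares regression of normalized Ribo counts on normalized mRNA
   counts across lines. Residual TE keeps a quantitative per-line range
   (unlike ratios) and removes the transcriptional component of any
   genotype effect.
3. **Association scan.** Every trait (mRNA, Ribo, TE) is regressed on
   every SDP genotype coded 0/1; slope, t and p come from the closed-form
   simple regression. Benjamini-Hochberg correction runs separately within
   the local stratum (SDP location overlaps the gene) and the distant
   stratum (all SDP locations on other chromosomes); associations on the
   gene's chromosome but outside its block join neither stratum and are
   reported separately. Empirical significance comes from a permutation
   null: each run permutes the line labels of the whole trait matrix once
   (preserving inter-gene correlation) and the full scan is recomputed; the
   empirical p of a pair is k/n_perm with k the permuted |t| values at or
   above the observed one, significant at p <= 0.0015 (the 15-in-10,000
   convention).
4. **Hotspot detection.** Distant master regulators are found with a
   hierarchical Bayesian variable-selection model: per gene a spike-and-slab
   regression over all SDPs under a Zellner g-prior (effects and error
   variance marginalized), with the multiplicative inclusion prior
   pi_kj = min(pi_k * rho_j, 1). The locus propensity rho_j is shared
   across genes, so a locus that many genes select raises its own prior
   odds — the mechanism that pools evidence for a hotspot. Posterior
   inclusion probabilities (selection frequencies over retained MCMC
   states) are thresholded by a two-component beta-mixture FDR, and an SDP
   is called a hotspot when at least 5 significantly associated distant
   genes span at least 2 chromosomes.
5. **CDS-length effect.** The central phenotype is a fold-change shift
   that is linear in log10 coding-sequence length. Its strength is
   summarized by the squared Pearson correlation and a standardized major
   axis (SMA) line (slope = sign(r) * sd(y)/sd(x)), fitted over genes with
   CDS >= 100 nt and mean normalized count > 10. Two conditions are
   compared with Fisher's r-to-z test; direction classes use the +-0.1
   rule; a correlation of mRNA fold change with length (r > 0.15) that the
   Ribo data do not share flags a technical RNA-seq length artifact.
6. **Thin-filament stoichiometry.** Normalized footprint counts of the
   five thin-filament subunits are converted to production values by
   (count / CDS length) x turnover days — synthesis per message length
   scaled by protein lifetime — and expressed as percentages against the
   7:1:1:1:1 composition optimum (actin = 700/11 ~ 63.6%).

# The synthetic panel

The generator provides the study conditions for every test: a 30-line RI
panel over 5 chromosomes of 100 Mb with 200 markers each, founder mosaics
from a homogeneous Poisson crossover process (rate 1.7 crossovers per
chromosome per line, chosen so the collapsed map has roughly 200 SDPs, the
desk-scale analogue of a dense panel map), and allele balance 0.5 so each
locus is carried by about 15 of 30 lines per founder. Counts are negative
binomial (dispersion 0.05) around log-normal gene means (median 250), with
log-normal per-sample size factors (sdlog 0.2) to exercise the joint
normalization. CDS lengths are log-normal with median 1.5 kb so both tails
of the length distribution are populated.

Planted effects: cis effects multiply the mRNA mean and propagate to the
Ribo mean (an extra Ribo-only term makes a cis teQTL); the trans hotspot
multiplies Ribo means only, with per-gene log2 effect
`intercept + slope * (log10 CDS - median log10 CDS)`. The default slope
(-0.22 per decade, translatome-wide) was calibrated once so that the
panel-wide SMA r^2 between log10 CDS length and Ribo-seq fold change is
about 0.26 under the default count model; recovery tests instead plant 20
target genes with a uniform |log2 effect| of 1.5. The generator does not
emulate read-level structure (no positional coverage, splice isoforms, or
footprint periodicity), batch effects, or biological strain variance beyond
the planted genetic effects — so passing tests certify the statistical
machinery under the stated noise model, not robustness to artifacts real
tissue data can carry.

# Numerical and design choices

**TE on the count scale.** The regression of Ribo on mRNA is fitted on
normalized counts, not logs, following the verbatim model the trait
definition is based on; `compute_te(log_scale = TRUE)` provides the
alternative. A consequence worth knowing: with heavy counting noise the
mRNA predictor is measured with error, the fitted slope is attenuated, and
a fraction of a purely transcriptional (propagated) effect leaks into the
TE residuals (classical regression dilution). At the default dispersion
0.05 this leakage is detectable for strong cis effects; at dispersion 0.01
it disappears. Genes with zero counts in more than half the lines are
excluded from TE entirely.

**Permutation conventions.** Empirical p is k/n_perm (0 is attainable),
matching the 15/10,000 = 0.0015 arithmetic; the add-one convention is a
flag. "More extreme" is two-sided on |t|. One permutation per run is shared
across all genes, preserving the trait correlation structure.

**Multi-location SDPs.** A significant association to a repeated SDP is
attributed to the candidate location whose immediate flanking SDPs carry
the strongest association to the same gene (summed -log10 p, one flank per
side); ties and flankless candidates fall back to the first genomic
location with an ambiguity flag.

**Sampler defaults.** pi_k ~ Beta(1, p) with p the number of SDPs
(expected model size about one predictor per gene); rho_j ~ Gamma(1, 1)
(mean 1, so propensities only move when the data demand it); g = n
(unit-information). The full evolutionary search used by the original
multi-gene selection software is replaced by a plain Gibbs/Metropolis
sampler with the same prior structure: at desk scale (1000 genes x 200
SDPs) mixing is adequate (split-half selection-frequency correlation is
monitored and warned below 0.9) and the estimand — the selection frequency
— is identical. The pi_k update treats the indicator count as if the prior
were exactly Beta, which is conjugate only when rho_j = 1; with the sparse
defaults the approximation error is negligible against sampler noise (the
single-predictor posterior matches the exact closed form within 0.05).
Runs are reproducible from the seed. Alternatives we evaluated and
rejected: the benchmark prior g = max(n, p^2) sharpens the null but costs
target recovery at realistic per-gene signal strengths, and tighter rho
priors (e.g. Gamma(4, 4)) lower the mixture cutoff and worsen the realized
FDR.

**Beta-mixture FDR.** Selection frequencies from a finite chain pile up at
exactly 0 (never-selected pairs), while a 30-line panel scanning ~200,000
pairs inevitably contains chance trait-genotype correlations with R^2 up
to ~0.4 whose posterior inclusion is appreciably positive. An
unconstrained two-beta EM collapses its null component onto the zero mass,
hands that chance tail to the alternative, and produces cutoffs near 0.02
with catastrophic realized FDR. The null component is therefore
constrained to be decreasing with bounded concentration (shape1 <= 1,
1 <= shape2 <= 5) and the alternative to be genuinely right-concentrated
(shape1 >= 2, shape2 <= 1). The concentration bound was calibrated on
planted-truth simulations: shape2 <= 5 places cutoffs near 0.9 and
realizes FDR ~ 0.05 at target 0.05 with ~90% target recovery; looser
bounds under-threshold, tighter ones over-shrink recovery. On
well-specified beta mixtures the constrained EM still recovers component
weights to within a few percent. Values are clamped to (1e-6, 1 - 1e-6)
before fitting.

**Chance correlations are the null's tail, not a bug.** With n = 30 lines,
|r| > 0.6 occurs by chance at rate ~ 6e-4 per pair; any per-pair guarantee
("no null pair above 0.5 inclusion") therefore holds only at modest
dimensionality, and the package's defense at scale is the FDR cutoff
landing above such pairs, not their absence.

**Coordinates and formats.** All tabular I/O is tab-separated text;
intervals are 1-based inclusive except BED export (0-based half-open). The
pipeline derives one seed per stage from the global seed and writes a JSON
manifest with row counts and a config hash.

**Cross-mappability.** The 29-mer, <= 2 mismatch filter is an exact
all-pairs scan, quadratic in sequence length — appropriate for the handful
of distant candidates it must vet, not for transcriptome-wide screens.

# Problem sizes used in the test-suite

Unit tests run on panels of 3 chromosomes x 60 markers (~85 SDPs) with
tens to hundreds of genes. The end-to-end statistical checks use the full
default panel: 1000 genes x ~200 SDPs x 30 lines, 1000 permutations for
null calibration, and 2000-iteration selection fits (500 burn-in) repeated
over 20 seeds for recovery and FDR, and 20 seeds for the length-effect
calibration; these sizes give stable averages for the stochastic
quantities while keeping a laptop-scale runtime. The acceptance script
reports the same quantities from 12 recovery seeds and 10 length-effect
seeds.

# Known limitations

- Residual TE inherits regression dilution under heavy counting noise
  (above); a mixed-model or errors-in-variables TE is out of scope.
- Kinship/population structure are not modeled in the scan (subpopulation
  labels only enter the fixation-index diagnostic); the panel emulated is
  balanced by construction.
- The hotspot sampler evaluates one indicator sweep per iteration with no
  model-size cap; severe multicollinearity among SDPs is handled by
  skipping numerically singular additions rather than by reparameterizing.
- Power statements are simulation-based at the stated sizes; no analytic
  power model is provided.
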