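---
title: "Genomic selection with low-density panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with low-density panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowdense)
```

## The problem

Genomic selection needs genome-wide SNP genotypes on every selection
candidate, and routine high-density genotyping is the dominant cost in pig
and other non-dairy breeding programmes. A standard remedy is to genotype
candidates with a much smaller panel (a few hundred markers) and impute the
remaining genotypes from relatives and population haplotypes. `lowdense`
implements a complete workflow for the family structure typical of sire-line
programmes:

* the **training animals** (progeny-tested boars) are genotyped at high
  density and phased, forming a **haplotype library**;
* every **selection candidate** has a high-density genotyped **sire**;
* **dams are not genotyped** at all.

The components are: marker QC, LD-based approximation of unknown marker
positions, design of the low-density panel, pedigree-aware imputation,
weighted GBLUP for direct genomic values (DGV), and estimation of unbiased
DGV accuracies from cross-validation.

## Marker QC and coding

Markers are filtered on call rate (< 0.95 removed), parent-progeny
conflicts (> 2% of genotyped pairs removed), minor allele frequency
(< 0.03 removed) and Hardy-Weinberg equilibrium (chi-square p < 1e-4
removed). Alleles are recoded so allele 1 is always the minor allele and
dosages count minor-allele copies.

Two details are genuinely open and are implemented as defaults with flags:

* the HWE test is a 1-df chi-square goodness of fit on genotype counts; at
  a cutoff of 1e-4 on hundreds of animals an exact test adds nothing;
* the conflict rate is normalised by the number of parent-offspring pairs
  with both genotypes called at the marker.

Missing genotypes are excluded pairwise from MAF and correlation
computations throughout, the standard choice for array data.

## Position approximation from LD

Markers without a physical position are still useful for prediction but not
for imputation, which needs an ordered map. Positions are approximated from
genotype correlations (the LD proxy available without haplotypes):

1. **Equivalence classes.** Two markers belong together when a chain of
   markers connects them with absolute genotype correlation > 0.4 between
   adjacent links and all *interior* chain markers having MAF > 0.15. The
   MAF condition stops rare markers — whose correlation estimates are
   noisy — from relaying spurious links; they may terminate a chain but not
   continue one.
2. **Chromosome assignment.** A class is mapped to a chromosome only when
   strictly more than 95% of its known-position members agree on it.
3. **Position.** Each unknown marker takes the known position of its
   best-correlated same-chromosome partner, and is flagged as *estimated*
   (weight u = 0.8 in panel design). Known markers whose class contradicts
   their mapped chromosome are remapped the same way.

The chain rule is not transitive once low-MAF markers sit at chain ends: a
rare marker can be linked to two classes that are not linked to each other.
We resolve this deterministically: connected components are built over the
high-MAF markers, then each low-MAF marker joins the component of its
strongest admissible neighbour (ties to the lowest marker index). For
high-MAF markers this reproduces the chain definition exactly; for low-MAF
markers it picks the best-supported of the admissible assignments and makes
the partition invariant to input order. Absolute correlations are used
everywhere because the LD sign is arbitrary under minor-allele coding.
Remapped known markers are treated as estimated (u = 0.8), since their
positions are inferred, not observed; a flag restores u = 1 for them.

## Panel design

The panel is grown greedily: with markers \(m_1,\dots,m_n\) selected, the
next marker maximises

\[\mathrm{Score}_{m} \cdot \min_k d(m, m_k),\]

with \(\mathrm{Score}_m = \mathrm{MAF}_m \, u_m\) and a distance that
blends physical separation with genotype correlation,

\[d(m',m'') = \lambda\,|loc_{m'}-loc_{m''}| +
  (1-\lambda)\,\kappa\,(1 - 0.99\,|\mathrm{Cor}(G_{m'},G_{m''})|),
  \qquad \lambda = \min(1, |loc_{m'}-loc_{m''}|/\kappa),\]

with \(\kappa = 5\) Mb and \(d = \infty\) across chromosomes. Within the
\(\kappa\) window two co-located markers in linkage equilibrium keep a
usable distance (\(\approx\kappa\)), so the panel can hold both; perfectly
correlated neighbours collapse to \(d = 0.05\,\kappa\) and are never both
chosen. The score reads \(\mathrm{MAF}_m u_m\) as a *product*: with
\(u = 0.8\) for estimated positions this penalises them, which is the
stated intent (an exponent reading \(\mathrm{MAF}^{0.8}\) would reward
them; a flag offers that reading anyway).

Because candidates on chromosomes not yet represented have infinite minimum
distance, initialisation is emergent: the first picks are the top-score
marker of each chromosome. Ties anywhere break to the lowest marker index,
so the procedure is fully deterministic. The naive comparison design —
equally spaced markers — is the exact limit \(\kappa = 0\), uniform scores,
known positions only; each pick then lands in the centre of the largest
remaining gap. We implement \(\kappa = 0\) exactly rather than a small
epsilon, avoiding floating-point tie ambiguity. Incremental bookkeeping of
per-candidate minimum distances makes selection \(O(\text{size} \times
\text{candidates})\); tests verify it equals naive recomputation.

## Imputation

For each candidate, imputation proceeds in two stages.

**Paternal alleles** are traced through the sire. At a panel marker where
the candidate is homozygous and the sire heterozygous, the transmitted sire
haplotype is known with certainty (`Which` = 0 for the sire's paternal,
1 for his maternal strand). Between determined markers of equal origin the
origin is constant; between markers of different origin a single crossover
is assumed at the interval midpoint (markers at or beyond the midpoint take
the right-hand origin — the half-open side is a convention; both flanks are
equally supported). Beyond the outermost determined markers the nearest
origin extends to the chromosome end. A chromosome with no determined
marker falls back to the sire strand with fewer conflicts against the
observed genotypes (tie: paternal). A candidate homozygous for an allele
the sire lacks is a Mendelian conflict; the marker is treated as
uninformative and counted, rather than aborting the individual.

**Maternal alleles** follow by subtraction at the panel markers
(dosage − paternal allele, where that is a valid allele), then the gaps are
filled from the haplotype library. For a focal panel marker \(m\), every
library haplotype \(h\) is scored against the partial maternal haplotype
\(i\):

\[\mathrm{Score}_{i,m}(h) = \sum_{k=0}^{4} c_{h,i}^m(k)\, 0.75^k\,(1 + a_{i,h}),\]

where \(c_{h,i}^m(k)\) counts the panel markers \(\tilde m\) with exactly
\(k\) conflicting panel markers between \(m\) and \(\tilde m\), and
\(a_{i,h}\) is the additive relationship between the candidate's dam and
the haplotype carrier. Distant agreement discounted by 0.75 per intervening
conflict keeps the score robust to sporadic phasing errors; the
relationship factor favours the dam's relatives — e.g. a maternal grandsire
(\(a = 0.5\)) beats an unrelated haplotype with the identical conflict
profile by a factor 1.5. The winning haplotype is copied over the largest
window around \(m\) bounded by the nearest panel markers where it conflicts
with \(i\) (or the chromosome ends).

Conventions we had to fix (each is a flag or documented tie-break):

* **Interval endpoints.** Conflicts are counted in the *open* interval —
  endpoints excluded, so a conflict at \(\tilde m\) itself does not count
  against \(\tilde m\); a `half-open` option includes it. The worked
  profile \(c = (6,5,5,3,3)\) used in the tests is consistent with either
  convention, so both are provided rather than guessed.
* **Focal conflicts.** A winning haplotype conflicting at the focal marker
  itself has that conflict ignored for its window bounds, consistent with
  the score, which never counts the focal marker.
* **Ordering and overwriting.** Panel markers are processed in ascending
  position; windows write only still-missing positions, so an earlier
  (higher-scoring in its own neighbourhood) fill is never overwritten.
* **Ties** in the score break by larger relationship, then lowest carrier
  id, then paternal before maternal strand — imputation is bit-for-bit
  deterministic.
* Residual positions no window reaches are filled from the best-scoring
  haplotype seen on the chromosome and flagged `fallback`; carriers absent
  from the pedigree get \(a = 0\) (the `1 +` keeps their score positive).

## GBLUP with heterogeneous residual variance

DGV are estimated from deregressed EBV (`dEBV = EBV / r²`; externally
deregressed records pass through) in the mixed model
\(y = \mathbf{1}\mu + g + e\), \(\mathrm{Var}(g) \propto G\),
\(\mathrm{Var}(e) \propto \mathrm{diag}(w_i)\), with

\[w_i = C + \frac{1 - r_i^2}{r_i^2}, \qquad C = 0.25,\]

so records backed by little progeny information get large error variance.
\(C\), the fraction of additive variance not captured by markers, defaults
to 0.25. The weight expression is grouped as \(C + (1-r^2)/r^2\) (the
structure of the deregression literature it comes from); a flag offers
\((C + 1 - r^2)/r^2\). The GRM is VanRaden method 1 — centred cross-product
scaled by \(2\sum p(1-p)\) — the default any practitioner would assume
where no construction is specified. A ridge of \(10^{-6}\times\) the mean
diagonal makes \(G\) invertible when markers are few. The residual-to-
genetic variance ratio is user-supplied; we deliberately do not run a
silent REML. The solver uses the mixed-model equations; an independent
dense GLS solve (`gblup_direct()`) exists purely as a cross-check and the
two agree to 1e-8 in the tests.

## Accuracy estimation

Imputation is scored by masking off-panel markers in a validation set:
the **error rate** is the proportion of masked genotypes restored
incorrectly on the 0/1/2 scale, and the **accuracy** is the squared
correlation between true and imputed dosages per individual, with every
marker entered twice — once as coded, once coding-swapped — making the
statistic exactly invariant to which allele is labelled 1.

For DGV accuracy, the naive ratio
\(\widehat{\mathrm{cor}}(DGV,TBV) = \mathrm{cor}(DGV,EBV)/r^{Val}\)
requires DGV errors independent of EBV prediction errors. When training
and validation animals come from one joint evaluation their prediction
errors are correlated and the ratio is biased upwards. The regression
approach fits, across traits,

\[\mathrm{cor}(DGV, EBV)_t = a_0 + a_1 r_t^{Val} + a_2 r_t^{Train} + e_t,\]

and evaluates it at \(r^{Val} = 1\), where EBV coincide with TBV:
\(a_0 + a_1 + a_2 r^{Train}\) for a random trait, and
\(\mathrm{cor}(DGV,EBV)_t - \hat a_1 (r_t^{Val} - 1)\) per trait (adding
back the trait residual, assuming the residual does not depend on
\(r^{Val}\)). With a single trait, replicates with varying validation
accuracy replace traits and the \(a_2\) term is dropped. Mean set
accuracies are computed as means of individual accuracies
\(\sqrt{r^2}\) (matching how evaluation reports tabulate them); a flag
averages reliabilities instead. The linear form is an extrapolation to
\(r^{Val}=1\); with few traits the coefficients are noisy, which is why
the simulation-based checks below matter.

## What the simulator emulates — and what it does not

`simulate_population()` gene-drops haplotypes through a random-mating
burn-in (default 20 generations at constant size) before the study
families, so that marker-marker LD and co-ancestry exist for the library
and position approximation to exploit; founders start in linkage
equilibrium with MAF uniform on a configurable range. Recombination is
Haldane (Poisson crossovers, no interference) at 1 cM/Mb. The study layer
reproduces the assumed design exactly: HD sires, distinct ungenotyped
dams, LD candidates, maternal grandsires reachable through the pedigree.
EBV are a deliberate shrinkage construction
(\(EBV = r^2\,TBV + r\sqrt{1-r^2}\,e\)) with an optional shared
within-family error component — enough to give EBV their target accuracy
and to induce the correlated prediction errors the regression approach
corrects, but *not* a BLUP evaluation: passing tests show the estimators
behave as designed under their own assumptions, not that real evaluations
satisfy them. Real genomes also differ in ways the simulator ignores:
non-uniform recombination, mutation, selection, X-chromosome dosage (the
package treats X as autosomal and says so in the QC log), and genotyping
error.

Problem sizes in the test-suite were chosen to exercise the methods at
desk scale: the density study uses 50 sire families (200 candidates) on 2
chromosomes of 1,000 markers with panels of 40/80/300; the accuracy study
uses 12 traits with validation accuracies spread over 0.55-0.92; position
recovery uses a small-Ne (120), long-burn-in (30 generations) population
whose short-range genotype correlations exceed the 0.4 chaining threshold,
with 10% of positions masked. Error rates at these densities are larger
than a 50k-chip application would see — what the tests pin down are the
orderings (denser panels and closer relatives help; the regression
correction beats the naive ratio) and the exact algebra on fixtures where
the truth is enumerable.

## Known limitations

* Phasing of the library is an input (any phaser producing phased VCF
  works); phasing errors degrade the maternal step in ways the 0.75
  discount only partly absorbs.
* Dosage output is hard-called; no genotype probabilities.
* The deregression is the simple `EBV / r²`; full parent-average removal
  must be done upstream if required.
* Variance components are not estimated; the user supplies the ratio.
* Relationship computation is exact but dense; pedigrees of hundreds of
  thousands would need a sparse-inverse implementation.
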