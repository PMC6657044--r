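---
title: "Methods: gene-level LoF association with EMR traits and expression concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level LoF association with EMR traits and expression concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analytic problem

Predicted loss-of-function (LoF) variants — frameshifts, stop-gains and
splice-disrupting changes — abolish the function of one gene copy, so their
carriers approximate a human gene-knockdown experiment. In a genotyped,
EMR-linked cohort this suggests a simple design: partition subjects into
carriers and non-carriers of LoFs in each gene and compare clinical trait
levels. Three obstacles make the naive version unreliable, and this package
is organized around them:

1. **LoF prediction is noisy.** Annotators disagree on both effect calls and
   affected transcripts, and imputed genotypes add uncertainty.
2. **EMR trait data are opportunistic.** Measurements are repeated,
   unit-inconsistent, sometimes mislabeled, and systematically shifted by
   medication.
3. **Carriers are rare.** With a handful of carriers per gene, skewed trait
   distributions inflate false positives, and individual associations need
   orthogonal (here: expression) corroboration.

# Consensus LoF classification and variant QC

`harmonizeCalls()` maps each annotator's raw vocabulary into the canonical
classes *frameshift*, *stop_gained*, *splice_disrupting*. The default
mapping (`lofVocabulary()`) encodes three annotator styles: one requiring a
predicted "full" effect (VAT-like labels `frameshift_indel`, `stop_gained`,
`splice_site`), one with gene-based labels (`frameshift substitution`,
`stopgain`, `exonic;splicing`), and one with impact metadata
(`FRAME_SHIFT`, `STOP_GAINED`, `SPLICE_SITE_ACCEPTOR/DONOR`, requiring
`HIGH` impact and `protein-coding` biotype). Unmapped labels are counted
and dropped, never fatal: annotator vocabularies drift and a hard failure
on an unknown label would make the harmonizer brittle.

Consensus has two layers, mirroring how the evidence degrades:
`any_two` (two or more annotators call the variant LoF anywhere) defines
the eligible pool, and the `consensus` flag additionally requires a shared
transcript. The same-transcript requirement then appears in the QC cascade
as its own filter with its own fail count, so the accounting distinguishes
"annotators disagree entirely" from "annotators agree but on different
transcripts".

`applyVariantQC()` evaluates, on the eligible pool:

| filter | rule | default |
|---|---|---|
| `info` | imputation INFO strictly > threshold | 0.3 |
| `completeness` | fraction of confident calls ≥ threshold | 0.90 |
| `consensus_transcript` | ≥ 2 annotators share ≥ 1 transcript | — |
| `final_exon` | fails only if **every** supporting transcript places the variant in its final exon | — |
| `af` | alternate allele frequency strictly < threshold | 0.02 |
| `carrier` | ≥ 1 carrier after hard-calling | — |

Boundary conventions: INFO at exactly 0.3 fails (the filter keeps
strictly greater values); completeness at exactly 0.90 passes; a genotype
probability at exactly 0.95 is retained by `hardCallGenotypes()` (the rule
masks calls *below* the threshold). The final-exon rule is per supporting
transcript because a variant escaping nonsense-mediated decay on one
transcript may still truncate another; only a variant final-exonic on all
of them is removed. Filters are evaluated independently, so the retained
set is order-insensitive; the per-filter counts are reported for the
cascade order above, and a variant failing several filters contributes to
each count but is removed once (`unique_removed`).

Relatedness pruning (`pruneRelatives()`) removes one member, uniformly at
random under a seed, from each pair with PI-HAT > 0.2, processing pairs in
lexicographic order and skipping pairs already broken — deterministic
given the seed, and guaranteed to leave no related pair. Collapsing
(`collapseToGenes()`) unions carriers over a gene's retained variants: the
predicted consequence of any LoF in a gene is taken as identical, so
carrier status is binary per gene.

# Trait QC

`traitQC()` applies three filters in a fixed order and assigns each
excluded measurement exactly one first-cause reason:

1. **Mislabel**: recorded unit differs from the trait's expected unit, or
   the value is outside a hard physiological range (defaults in
   `defaultTraitConfig()`, e.g. SBP 50–260 mmHg).
2. **Medication**: the measurement date lies in `[start, end]` (end
   missing = ongoing) of an interval whose medication class affects the
   trait. Disease-driven exclusions use the same mechanism through
   pseudo-classes, since the interval semantics are identical.
3. **Outlier**: beyond 4 scaled MADs (`stats::mad`, normal-consistent)
   from the cohort-wide median of the values surviving the first two
   filters. Computing the MAD after the medication filter is deliberate:
   medication shifts are large (a statin moves LDL by tens of mg/dL) and
   would otherwise inflate the spread estimate. A zero MAD disables the
   rule rather than excluding everything off-median.

The exact outlier and medication algorithms used with real EMR data are
institution-specific; the 4-MAD rule and the interval map are explicit,
config-overridable defaults rather than claims about any particular
implementation. Survivors are reduced to one median per subject per trait
(even counts average the two middle values), and the per-filter
before/after counts are kept for reporting.

# Gene-trait association

With few carriers and skewed traits, Gaussian residual assumptions fail.
Per trait, the response is Box-Cox transformed,

$$y^{(\lambda)} = \begin{cases}(y^\lambda - 1)/\lambda & \lambda \neq 0\\ \ln y & \lambda = 0,\end{cases}$$

with λ selected from the grid −2 to 2 in steps of 0.5 by maximizing the
log-likelihood of the covariates-only model (sex, age, PC1–PC5; no gene
term, so one λ per trait rather than per test). Two selection modes exist:

* `jacobian = TRUE` (default) adds the change-of-variables term
  $(\lambda - 1)\sum_i \ln y_i$, giving the standard profile likelihood.
  Without it the criterion is scale-inconsistent across λ — multiplying the
  data by a constant changes which λ wins — so the Jacobian mode is the
  statistically defensible default.
* `jacobian = FALSE` scores the raw Gaussian log-likelihood of the
  transformed response, for compatibility with pipelines that select λ
  that way.

Ties (rare on continuous data) break toward smaller |λ|, then smaller λ:
prefer the milder transformation. Traits with non-positive medians
(possible in synthetic data; the clinical traits are positive) are shifted
by `1 - min(y)` before transformation, and the offset is logged.

Each gene with at least 3 carriers having the trait is then tested with a
Gaussian identity-link GLM fitted by iteratively reweighted least squares
(`fitIRLS()`; with unit weights the loop converges at the ordinary
least-squares solution, and the tests hold it to the normal-equations
answer at 1e-8 relative error). The carrier coefficient's two-sided
p-value uses the t reference distribution with n − p degrees of freedom —
deliberately not the normal approximation, which is anticonservative at
3–30 carriers. Effect size β and its t-statistic are re-estimated without
the transformation so that β is interpretable in trait units (mg/dL,
mmHg, …). No multiple-testing correction is applied at the default
α = 0.1: the design treats genotype significance as a screen whose hits
must independently replicate in expression, not as a final claim.

# Expression-trait association and concordance

For genotype-significant genes, each trait is regressed on normalized
expression with age, sex and BMI as covariates
(`Trait ~ Gene + Age + Gender + BMI`), per tissue, by unweighted OLS —
the trait-association model names no precision weights, and upstream
normalization (TMM/voom, batch residualization) is consumed, not
reimplemented. When raw counts are the starting point, `cpmFilter()`
drops genes with CPM < 1 in more than 90% of samples (a gene at exactly
90% survives).

The integration logic assumes LoF carriage and low expression act in the
same direction. Hence a gene-trait pair is **concordant** when some
significant (α = 0.05) tissue association has an expression slope of sign
opposite to the genotype β — e.g. genotype β = −19 on glucose with liver
slope +0.56 is concordant; genotype +40 with muscle slope −0.28 is too.
Tissue identity is deliberately ignored for the verdict (any tissue
counts) but preserved in the tally of gene-trait-tissue triples.
Discordant pairs are kept in the output with their verdict rather than
dropped — opposite-pattern associations may still be biologically real —
and a β of exactly 0 on a significant row is an input error, since the
sign rule is undefined there. Genes with no significant expression row
are `untested`, not discordant.

`goFilter()` finishes with a knowledge filter: stage 1 reports how many
concordant genes have any biological-process annotation; stage 2 passes
gene-traits whose gene has a BP term matching any keyword of a single
global CVD-metabolic set (`cvdGoKeywords()`: blood pressure, glucose,
glucagon, insulin, cholesterol, triglyceride, lipid, fatty acid,
lipoprotein). Matching is domain-level, not per-trait — a fatty-acid term
legitimately supports a glucose association — and the keyword set is a
configurable, explicit stand-in for the inherently informal notion of
"related to the traits of interest".

# The synthetic-data generator

`simulateStudy()` produces every pipeline input with known ground truth.
Its defaults define the package's reference study: 2000 subjects, 200
genes with a zero-truncated-Poisson number of variants (mean 1.3), allele
frequencies 0.05–0.6% (0.8% for the 20 planted-effect genes, so planted
genes comfortably clear the 3-carrier rule), ten traits with log-normal
(lipids, glucose, hsCRP, WBC) or normal (blood pressures, HbA1c)
generative families so Box-Cox selection is exercised at non-unit λ,
planted effects of roughly 1.3–2 between-subject SDs with 14 concordant,
3 discordant and 3 absent expression counterparts (slope ±0.4 SD in one
designated tissue of a 500-sample expression cohort), three medication
classes covering 20% of subjects each, 1% gross outliers, 0.5% unit
mislabels, 20 related pairs, and 2–6 dated measurements per subject-trait
(the measurement cadence is configuration, as no canonical value exists).
Every generator draws from `seed` plus a fixed stream offset, so a config
reproduces the study bit-identically while each component stays
individually reproducible.

Design choices worth knowing:

* **Dominant 0/1 genotypes.** The association model consumes only binary
  carrier status, so dosage detail would be dead weight.
* **Winsorized legitimate values.** Non-perturbed measurements are clipped
  at 3.6 cohort MADs (and medication-shifted values floored at the trait's
  plausibility minimum; planted outliers capped just inside the recordable
  maximum). This encodes physiological plausibility and gives the 4-MAD
  outlier rule a clean separation: planted outliers (5–8 MADs out) are
  always caught, legitimate values never are, so truth-table accounting is
  exact. The cost is mild attenuation of the largest planted effects in
  extreme carriers — visible as recovered |β| slightly under the planted
  value — accepted because recovery is judged by detection, not unbiased
  estimation.
* **Mutually exclusive perturbations.** Mislabels and outliers are planted
  only on measurements not inside a relevant medication interval, so each
  perturbed measurement has exactly one cause and the first-cause
  exclusion accounting can be checked for equality, not approximation.
* **Orthogonal QC plants.** Each variant planted to fail a QC filter fails
  exactly that filter (deterministic three-annotator calls, passing values
  elsewhere); non-planted variants are ascertained as segregating (≥ 1
  confident carrier) with passing INFO/completeness/AF. Per-filter fail
  counts therefore equal the planted counts exactly.
* **Gene models.** Each gene has two transcripts over three 200-bp exons
  with alternating strand; the middle genomic exon is never
  transcription-final on either strand, so pass-variants sit there and
  final-exon plants sit in the strand-appropriate terminal exon.
* **Dates are integer day offsets** from a fixed epoch — calendar
  arithmetic adds dialect without adding signal.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, imputation mechanics (INFO scores are drawn, not
earned), sequencing reads, pharmacokinetics (medication shifts are step
functions), ancestry structure (PCs are pure noise), and correlated traits.
Consequently, passing recovery tests show the pipeline correctly
implements its own rules and detects planted signals of the stated size
under clean confounding — they do not certify performance against real
LD-driven shadowing, imputation artifacts or population stratification.

# Test problem sizes

The end-to-end recovery check runs the reference study (2000 subjects,
200 genes, 20 planted effects, 7 tissues at n = 500); type-I error uses
550 null genes at n = 2000 on one trait with the significant fraction
judged against the binomial 99% band at 500 trials; λ recovery uses 50
replicates each for generative λ ∈ {0, 0.5, 1} at n = 2000 with residual
SD 0.8 on the transformed scale (enough curvature that the transform
matters, chosen a priori); the IRLS oracle uses 100 random designs; the
variant-QC fixture uses ~970 variants over 700 genes at n = 300; the
consensus oracle enumerates all 63 annotator-subset × transcript-overlap
configurations; the concordance oracle uses 100 randomized table pairs;
pruning is checked exhaustively on all pair subsets for 4–5 subjects and
on 300 random subsets of the 15 possible pairs for 6.

# Known limitations

* The trait-QC defaults (4-MAD rule, interval map) are explicit
  placeholders for institution-specific procedures; with real data both
  should be overridden to match local practice.
* The IRLS fitter is Gaussian/identity only — that is the model family
  used throughout — and does not implement other GLM families.
* Concordance treats any opposite-sign significant tissue as sufficient;
  with many tissues this is permissive by construction (the multi-tissue
  false-positive rate for a null gene-trait is 1 − (1 − α/2)^T), which is
  why tallies are reported alongside verdicts.
* λ selection is per trait on the covariates-only model; traits whose
  optimal transformation differs between carriers and non-carriers would
  need a per-test selection, not offered here.
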