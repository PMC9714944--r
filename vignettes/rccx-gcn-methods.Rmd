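---
title: "Determining RCCX copy numbers from duplex qPCR: models and methods"
author: "rccxgcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining RCCX copy numbers from duplex qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccxgcn)
```

## The problem

The RCCX module on chromosome 6p21 is a tandem copy-number variation in
which every segment carries one C4 gene (C4A or C4B), one CYP21 gene (the
functional CYP21A2 or the CYP21A1P pseudogene) and, inside C4 intron 9,
either the insertion or the deletion allele of the HERV-K(C4)
retrovirus. CYP21A2 copy number matters clinically for congenital adrenal
hyperplasia. Because every segment contributes exactly one member of each
paralog pair, a diploid genome obeys a four-way constraint:

$$
n_{C4A}+n_{C4B} \;=\; n_{A1P}+n_{A2} \;=\; n_{del}+n_{ins}
\;=\; n_{BP}+2 \;=\; T,
$$

where $T$ is the total segment count and $n_{BP}$ counts segment-segment
junctions (breakpoints). `rccxgcn` implements the full computation for
genotyping these loci from duplex qPCR quantification cycles (Cq): one
allele-specific target per assay, co-amplified with the RPPH1 internal
reference gene that occurs once per haploid genome.

## From Cq to measured copy number

With (near-)perfect amplification efficiency, template amount doubles per
cycle, so for a target with copy number $G$ against a two-copy reference,

$$
C_q^{target}-C_q^{ref} \;=\; 1-\log_2 G
\qquad\Longleftrightarrow\qquad
G \;=\; 2^{\,1-(C_q^{target}-C_q^{ref}-o)},
$$

where $o$ is a per-assay calibration offset in cycles (`gcn_from_cq`).
The inverted value is the *measured* GCN, a positive real number. The gap
between consecutive integers shrinks as $\log_2\frac{n+1}{n}$ — 1 cycle
between 1 and 2 copies but only 0.322 between 4 and 5 — which is the
fundamental resolution limit of single-target qPCR genotyping.

**Calibration.** Rather than normalising to arbitrarily chosen reference
samples (a ΔΔCq scheme), the offset of each assay is tuned so that the
mean relative error $(G_{meas}-n)/n$ over a calibration cohort with known
(or consistently rounded) integer GCNs is exactly zero. Since an offset
acts multiplicatively ($G \mapsto 2^{o}G$), the closed form is
$o=-\log_2 \overline{(G_{meas}/n)}$ (`tune_offset`). When integers are
not supplied, `calibrate_offsets` iterates round → tune → re-round (at
most 10 passes); this converges quickly because most samples start in the
correct rounding basin. Applying the offset in Cq space is equivalent to
re-tuning the instrument's fluorescence threshold under near-100%
efficiencies, and is the only surrogate available without raw curves.

**Aggregation and ambiguity.** The duplex design pairs each well's target
and reference Cq; the per-sample value is the mean of per-well GCNs (not
the GCN of mean Cqs), with SD, CV% and a normal-theory 95% CI
(`aggregate_replicates`). A measured GCN within ±0.3 of an integer is
unambiguous; otherwise ambiguous (`classify_ambiguity`). The window is
closed (|G − n| = 0.3 counts as unambiguous, with a 1e-9 float guard) and
configurable. The complementary misclassification boundary is 0.7 = 1 −
0.3 by construction. A fixed ±0.3 window deliberately tightens the
*relative* tolerance at higher copy numbers.

**Expected GCNs.** The four totals are combined by an equal-weight mean
into an expected total; each locus' expectation shares that total within
its paralog pair in proportion to the measured values, and a deviation
above 0.4 flags the locus as inconsistent (`expected_gcn`). A fitted
multi-locus regression could weight the totals unequally, but with four
near-exchangeable estimates of the same quantity the equal-weight mean is
reproducible, assumption-free and satisfies the same constraints; it is
the package's deliberate choice where the combination rule was open.

## Assay quality control

* **Standard curves** (`fit_calibration`): OLS of Cq on log10 template
  copies; efficiency $E = 10^{-1/slope}-1$, so the perfect slope −3.3219
  gives $E=1$. Copies derive from input mass via a 3.1 Gbp haploid
  genome and 650 g/mol per base pair (≈6.7 pg per diploid genome,
  `copies_from_mass`); the 2.5–80 ng dilution series corresponds to
  roughly 370–12,000 copies of a single-copy locus.
* **Limit of detection** (`lod_hubaux_vos`): the Hubaux–Vos construction
  assumes a response linear in concentration, so Cq is linearised to
  $y=2^{-C_q}$ before regression on copies. The decision limit is the
  upper one-sided $1-\alpha$ prediction bound at zero concentration; the
  LOD is the concentration whose lower $1-\beta$ prediction bound clears
  it (t bounds, $n-2$ df; defaults $\alpha=\beta=0.05$). LOD is reported
  for completeness: genomic-DNA inputs sit far above it in practice.
* **Precision** (`pooled_cv`, `precision_report`): per-group CVs pooled
  by degrees of freedom, $\sqrt{\sum (n_g-1)CV_g^2/\sum(n_g-1)}\times
  100$ — the conventional pooling; repeatability groups wells within a
  run, reproducibility groups all wells of a sample.
* **Normalisation efficiency** (`nrmse`): how faithfully the target Cq
  tracks the reference Cq, as RMSE of observed minus predicted target Cq
  (prediction: reference Cq + offset + $1-\log_2 n$) normalised by the
  mean observed target Cq. The normaliser is a convention; mean observed
  Cq keeps the quantity dimensionless and comparable across assays.
  Sample-level NRMSE correlates with accuracy when the dominant error is
  channel-asymmetric, which is exactly the regime in which normalisation
  fails.

## The normal error model for ambiguity and misclassification

Per-sample average relative errors are approximately normal,
$X\sim N(\mu,\sigma^2)$, so a sample with true copy number $n$ measures
$n(1+X)$. The ±0.3/0.7 geometry on the measured axis maps to windows
$0.3/n$ and $0.7/n$ on the relative-error axis:

$$
\mathrm{amb}(n)=P\!\left(\tfrac{0.3}{n}<|X|<\tfrac{0.7}{n}\right),
\qquad
\mathrm{mis}(n)=P\!\left(|X|\ge\tfrac{0.7}{n}\right),
$$

computed with the normal CDF (`rate_at_gcn`); both are symmetric in the
sign of $\mu$, misclassification is non-decreasing in $n$, and the three
rates (with unambiguous as the remainder) total 100% exactly. A
Monte-Carlo companion (`mc_rate_at_gcn`) simulates the nearest-integer
rule directly and serves as the independent check; the closed form
ignores wrap-around past the adjacent integers, which is negligible for
$\sigma \lesssim 0.12$ at $n\le 2$ but becomes visible for large
$\sigma$ at high $n$.

`fit_error_model` inverts two observed ambiguity cells into
$(|\mu|,\sigma)$ — only $|\mu|$ is identifiable. The solver is a
deterministic multi-start Nelder–Mead least-squares over the box
$|\mu|\in[0,0.5]$, $\sigma\in(10^{-6},0.5]$, polished by a damped
Gauss–Newton (Levenberg–Marquardt) iteration, with an exact $\mu=0$
fallback by 1-D root bracketing: the rates depend on $\mu$ only to
second order near the symmetric point, which defeats both plain Newton
steps and nested-bracketing schemes. A fit whose residual exceeds 1e-10
in probability units is reported as a failure rather than returned.

Two caveats this fit makes explicit. First, the two-cell inversion is
ill-conditioned in the direction that trades $|\mu|$ against $\sigma$:
predictions at the fitted cells are exact, while extrapolated cells
(especially the wide ambiguity window at $n=4$) inherit the largest
uncertainty. Second, published tables of this kind sometimes render
sub-threshold cells with an inverted symbol; `format_rate_table` prints
"<0.01%" and offers a `literal` switch for the inverted rendering.

## The multiplex integer caller

A from-scratch linear discriminant analysis (`train_lda`,
`classify_lda`, `loo_cross_validate`) is the estimation engine — means,
pooled within-class covariance ($N-K$ denominator), ridge
$\lambda\,\mathrm{tr}(\Sigma)/d$ on the diagonal (absolute $\lambda$ when
the trace is zero), discriminant scores and softmax posteriors. The ridge
default $\lambda=10^{-6}$ exists because realistic reference sets (tens
of samples) give near-singular covariances. Priors default to empirical
class frequencies, switchable to uniform.

`call_gcn` estimates integers in two stages. Stage 1 classifies the
4-vector of constraint totals into $T$. Stage 2 resolves each paralog
pair: a paralog measuring unambiguously zero assigns $(0,T)$ outright
(zero-copy template produces no amplification, so LDA has nothing to
model there); otherwise an LDA on (pair, breakpoint) features is
restricted to classes summing to $T$, renormalising the posterior over
the admissible classes. The breakpoint integer is $T-2$. Every emitted
call therefore satisfies the four-way constraint *by construction*, and
the function additionally asserts it. Calls are flagged ambiguous when
any stage's posterior falls below 0.95 (a configurable operating point —
the flag threshold, not a probability statement about the cohort) or any
leave-one-out cross-validation fails; `consistency_pass` records whether
the rounded per-locus totals agree with $T$. By default the cohort is
its own reference set with rounded input classes, mirroring how such
cohorts are analysed in practice; an external labelled reference is
accepted and is preferable when rare copy numbers (singleton classes,
which cannot be cross-validated) are expected.

## The synthetic-data generator

`simulate_cohort` emulates the statistical structure the analysis
assumes, so that every stage is testable without external data:

* **Genotypes** come from a 1–3-segment haplotype model
  (`default_haplotype_freqs`: monomodular/bimodular/trimodular at
  0.55/0.40/0.05, one CYP21A2 per haplotype), giving diploid totals 2–6
  with realistic skew and exercising zero-copy dropouts. The frequencies
  are a modelling choice, not a population estimate, and are fully
  configurable.
* **Noise** (`noise_spec`): reference Cq centred at 26.0724 at the 10 ng
  input; a per-sample matrix shift (SD 0.5 cycles) applied to both
  channels — large, but cancelling in ΔCq, as a genomic-DNA matrix
  effect mostly does; a channel-asymmetric component (SD 0.02 cycles)
  that does not cancel and therefore drives accuracy; between-run shifts
  (SD 0.1) shared by both channels of a well; independent per-channel
  well noise (SD 0.05), so within-well ΔCq noise is $\sqrt2\times$ the
  well SD; degraded ("bad quality") samples add a +0.05-cycle target
  bias and extra target noise. The reference gene never drops out;
  zero-copy targets always do.
* **Dilution series** (`simulate_dilution_series`) over 2.5–80 ng with a
  configurable efficiency, anchored to the same Cq conventions, so a
  noiseless series reproduces the −3.3219 slope exactly.
* A single seed controls everything; draws occur in a fixed documented
  order.

What the generator does **not** emulate: sequence-level effects (primer
mismatch, non-specific products), fluorescence-curve shape and threshold
mechanics, PCR inhibition gradients along dilutions, and inter-assay
correlation of the matrix effect beyond the shared shift. Tests passing
on synthetic data therefore validate the *computation* — calibration
algebra, the error-model geometry, the caller's decision theory — not
the wet-lab behaviour of any particular assay.

## Problem sizes and numerical choices

The shipped tests run cohorts of 12–200 samples with 3 wells × 3 runs,
1e4-draw genotype-constraint sweeps, 1e5–1e6-draw Monte-Carlo
comparisons and 1000 random LDA instances; these sizes make every
distributional claim testable in well under a minute each while keeping
binomial/Poisson error well below the asserted tolerances. Degenerate
inputs are handled deliberately: all-dropout replicate sets report mean 0
with undefined dispersion; non-negative calibration slopes return flagged
fits with a warning; a zero-trace pooled covariance falls back to an
absolute ridge; ties in `classify_lda` resolve to the first class in
sorted label order.

## Known limitations

* The two-cell error-model fit extrapolates poorly to wide windows (see
  above); fitting to more cells by least squares is possible but then no
  longer reproduces any cell exactly.
* With rounded (self-derived) input classes, a systematically biased
  assay can shift an entire class; supplying known integers for even a
  subset of samples anchors the calibration.
* The caller's posterior is a within-model quantity; under model
  misspecification (heavy-tailed errors, class covariance heterogeneity)
  it overstates confidence, which is why the ambiguity flag also
  consults cross-validation.
* Singleton classes train but cannot be cross-validated; their calls are
  reported with `cv_pass = NA`.
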