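---
title: "Models and methods behind fermscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fermscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermscope)
```

`fermscope` compares *E. coli* production strains across three levels —
batch process physiology, transcriptome and proteome. This vignette
explains the models it implements, the parameters that matter, the design
choices that were genuinely open, and what the synthetic-data validation
does and does not demonstrate.

## Batch kinetics and the carbon closure

One cultivation is described by the state (X, S, Ac) — cell dry mass
(CDM), glucose and acetate, all in g/L — evolving as

$$\mu(S) = \mu_{max}\,\frac{S}{K_s + S}, \qquad
  q_s = \frac{\mu}{Y_{X/S}}, \qquad
  q_{ac} = k_{overflow}\,\max(0,\; q_s - q_{s,crit}),$$

with $\mu = 0$ during the lag phase. Overflow acetate is produced whenever
the specific glucose uptake $q_s$ exceeds the oxidative capacity
$q_{s,crit}$. Acetate re-uptake at up to `q_ac_uptake_max` switches on
when glucose is depleted, or — for strains carrying a B-type acetate
control — when acetate exceeds `acetate_ctrl_threshold`. Two smoothing
devices keep the vector field continuous without changing the biology:
the activation ramps in linearly over 0.1 g/L above the threshold (a hard
switch makes the trajectory chatter at the set point, which degrades the
trapezoidal off-gas integration downstream), and a saturation factor
$Ac/(Ac + 0.01)$ prevents acetate from undershooting zero. The lag, by
contrast, is a deliberate hard switch: only a lag *duration* is
specified, not an adaptation mechanism.

The CO2 carbon evolution rate is not an independent model output. It is
*defined* as the residual of the elemental carbon balance at every
evaluation of the derivative:

$$r_{CO_2} = f_{glc}\,q_s X \;-\; f_X\,\dot X \;-\; f_{ac}\,\dot{Ac}
             \;-\; \textstyle\sum_i f_i\,\dot{P_i},$$

where $f$ are carbon mass fractions and $P_i$ the optional side products
(formate, pyruvate, lactate; constant fractions of the glucose flux,
default 0). Because total carbon is then a linear invariant of the ODE
system and Runge-Kutta schemes preserve linear invariants exactly,
noiseless trajectories close their carbon balance to floating-point
accuracy at every step — the test suite asserts conservation to 1e-6
relative and end-to-end recovery of 100% ± 0.5% through the independent
`integrate_offgas()` path.

Integration is fixed-step RK4 at `dt` ≤ 0.01 h, chosen for determinism
and simplicity: the dynamics are smooth and mild, and bit-identical
reproducibility for a given seed matters more here than adaptive
stepping. The final step is shortened (secant iteration on the glucose
coordinate) so glucose never becomes negative; the run stops at
exhaustion or at `duration`.

Measurement noise on the sampled "measured" series is multiplicative
lognormal with user CV (mean-one parameterisation), reflecting the
roughly constant relative error of gravimetric CDM and HPLC metabolite
assays. The noiseless state trajectory is retained alongside, which is
what makes planted-truth testing possible.

### Strain presets

`strain_preset()` ships three parameter sets tuned to typical phenotypes
on 40 g/L glucose with 0.4 g/L inoculum: a K-12 with strong overflow
(`K12_HMS_like`: $\mu_{max}$ 0.43/h, yield 0.34 g/g, ~6 g/L acetate), a
K-12 with a 2 h lag and intermediate yield (`K12_RV_like`), and a fast B
strain (`B_like`: $\mu_{max}$ 0.73/h, weak overflow, acetate held near
the ~1 g/L control point, glucose exhausted in ~5.3 h). The presets are
illustrative fixtures for the simulator, not parameter estimates; the
published replicate tables are carried separately as a data fixture and
analysed by the same summary functions.

## Process metrics

* **Growth rate** — primary estimator: OLS slope of $\ln$ CDM on time
  within a window (exact on exponential data, window-invariant there).
  The endpoint formula $\ln(X_e/X_s)/(t_e - t_s)$ is also reported,
  because "average growth rate" in routine bioprocess reporting is
  ambiguous between the two; both carry provenance labels.
* **Replicate summaries** — mean ± SEM with the sample (n−1) standard
  deviation. This convention reproduces published two-decimal summaries
  exactly (e.g. 13.72 ± 0.34 from 13.33/14.41/13.43); all rounding is
  confined to the reporting layer (`round_report()`).
* **Carbon fractions** — from elemental formulas with standard atomic
  masses; the biomass formula CH$_{1.77}$O$_{0.49}$N$_{0.24}$ gives a
  carbon fraction of 0.4805. Acetate uses the anion formula
  (fraction 0.4068); electron mass of charged species is neglected.
* **Acetate correction of yields** — homoacetate stoichiometry
  (1 glucose → 2 acetate by moles, factor $M_{glc}/2M_{HAc} = 1.50$ by
  mass): 6 g acetate ↔ 9 g glucose, and the corrected yield
  $X_{final}/(S_0 - 1.5\,Ac)$ reproduces the 0.46 / 0.51 / 0.44 g/g
  benchmark triple.
* **Carbon balance** — end concentrations × volume × carbon fraction per
  pool, CO2 by trapezoidal integration of the off-gas rate. The total
  input carbon is deliberately a *caller input*: in real cultivations it
  includes complex-media components whose carbon content is not derivable
  from the series itself, and published per-strain totals are generally
  not printed. The package refuses to guess it.

## Two-colour transcriptome pipeline

Spot statistics are the classical $M = \log_2(\text{sample}/\text{ref})$
and $A = \tfrac12 \log_2(\text{sample}\cdot\text{ref})$, computed from
foreground intensities only (no background correction — subtraction adds
noise at low intensities and the filter A > 7.5 removes that regime
anyway). Non-positive foregrounds flag the spot unusable rather than
being floored.

**Print-tip loess.** Intensity-dependent dye bias is removed per
print-tip group by robustified local-linear loess of M on A (span 0.4,
3 robustifying iterations, via `stats::loess`), subtracting the fitted
trend. Span and iterations are conventional defaults for this class of
normalization; on noiseless linear bias the fit is exact and the
operation idempotent (both asserted). Tip groups with fewer than 10
usable spots are median-centred with a warning; if the robust fit fails
numerically on a sparse group the code falls back to a plain
least-squares loess and then to median-centering.

**Dye swap.** Each sample is hybridised twice against the pooled
reference with dyes exchanged. `ma_transform()` orients every M
sample-over-reference from the channel annotations, so the swapped
member needs no further negation; consolidation averages replicate spots
within an array, then per gene across the arrays of a sample. Because
dye bias does not flip under the swap while the biological signal does,
averaging a swap pair cancels residual bias — the suite checks the
global-swap equivariance exactly.

**Moderated t.** Per strain, each gene's mean log-ratio across its
arrays is tested against zero with an empirical-Bayes variance shrinkage:
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, $t_g = \bar M_g /
(\tilde s_g/\sqrt{n_g})$ on $d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is
estimated by matching the mean and variance of $\log s_g^2$ to the
scaled-F sampling theory, solving $\psi'(d_0/2) = \widehat{var} -
\overline{\psi'(d_g/2)}$ with a Newton iteration on the trigamma inverse.
Genes with zero sample variance still get a positive posterior variance
(the prior dominates). The implementation is authored here and verified
in the tests against `limma::eBayes` to 1e-10, and its two limits are
asserted: $d_0 = 0$ recovers the ordinary t, $d_0 = \infty$ the fully
pooled statistic. Which of the moderated or ordinary p-values a given
published analysis used is often unknowable, so both are emitted;
unadjusted p-values drive the filter (matching the three-threshold
convention), with Benjamini-Hochberg values reported informationally.

**Filter and Venn.** DE in a strain iff A > 7.5 **and** |M| > 1.0
**and** p < 0.05, all strict (a gene at A = 7.5 exactly is excluded);
the DE union is over strains, and `venn_partition()` produces the 7
disjoint regions plus complement, whose counts provably sum to the
universe — the cross-platform commonset from `intersect_platforms()`
(case-normalised, deduplicated, sorted).

### Synthetic arrays: what they emulate, and what they do not

`simulate_microarray()` plants per-gene log-fold changes against the
pooled reference, per-tip linear intensity-dependent dye bias (which does
not flip under the dye swap — exactly what the swap design cancels) and
additive Gaussian log-scale spot noise. Planted effects are specified
directly against the reference pool, so recovery is exact in expectation;
the pooled-mean constraint on the reference is left to the truth
specification. The generator deliberately omits spatial artefacts,
saturation, carrier-specific probe effects and cross-hybridisation; a
pass on synthetic data therefore validates the *statistical machinery*
(orientation, normalization, shrinkage, filtering, partitioning), not
robustness to every physical artefact of real scans. Published region
counts from real arrays are consequently checked only for internal
consistency (they partition the commonset), not re-derived.

## DIGE proteome stage

Each gel carries two samples (Cy3/Cy5) plus the pooled internal standard
(Cy2); dividing by the Cy2 volume per spot per gel cancels gel-to-gel
effects, which the simulator injects and the tests confirm are removed.
Group ratios use the DeCyder-style convention: ratio of group means of
standardized abundance, mapped to a signed fold ($r$ if $r \ge 1$, else
$-1/r$), exactly antisymmetric under pair reversal. Ratios are computed
from group means rather than means of per-gel ratios — the latter is
biased upward for noisy small ratios; this is a declared convention since
reporting practice varies. Significance is a two-sample Student's t on
the standardized abundances (equal variance by default, Welch and
gel-paired variants available, since published workflows rarely state
which); a spot is altered iff |fold| > 2.0 *and* p < 0.01, strictly, and
altered spots are tallied per pI range (acidic 4–7 / basic 6–11) —
MW and pI are carried as metadata only.

## Transcript-protein integration

With a common-reference design, the contrast between strains X and Y at
the gene level is $M_X - M_Y$, which satisfies the cycle identity
$(X-Y) = (X-Z) - (Y-Z)$ exactly — asserted to 1e-12 and on the
benchmark contrast row (0.08 − (−3.96) = 4.04). The concordance rule is
a declared convention, since published examples illustrate rather than
define one: with the gene contrast beyond 1.0 log2 units the call is by
sign agreement; below it the gene is "flat" and a protein fold beyond
2.0 makes the pair discordant, otherwise both levels are unchanged and
agree. The 1.0 log2 threshold mirrors the |M| > 1 DE convention (and
makes the canonical divergent example — protein +15.6-fold with a gene
contrast of +0.97 — discordant); 0.5 remains available for a laxer
reading of "comparable". The call is invariant under simultaneous pair
reversal. Spots containing co-migrating proteins produce one row per
constituent gene.

## Annotation

`category_tally()` counts set members per category term from a
user-supplied two-column map (gene, term), with lexicographic tie-breaks
and an explicit "unannotated" count. Raw counts only by design: without
fixing a database snapshot, enrichment p-values suggest spurious
precision, and the category universe of any given GO/GenProtEC release is
not reproducible here.

## Pipeline, determinism and numerical choices

`run_pipeline()` chains the stages with per-stage seeds derived
deterministically from one master seed (all kept within the 32-bit
integer range) and writes a manifest with md5 hashes of every artifact;
two runs with the same config are byte-identical, which the tests check.
Degenerate inputs fail loudly: non-positive initial state, overshooting
gels, strains missing from truth, flags outside the universe, empty
platform lists, missing CO2 channels.

Default problem sizes in the test-suite and validation runs are chosen to
exercise every code path at desk scale: 1000-gene arrays (16 print-tip
groups, 3 strains × 3 replicates × dye swap = 18 hybridisations) for the
power/false-positive checks, 5000 genes × 6 arrays for the null
calibration of the moderated t, 24 Monte-Carlo repetitions of 6-replicate
DIGE experiments for ratio recovery, and a 3882-gene universe for the
Venn partitioning. With planted |lfc| = 2, spot sd 0.3 and n = 6 the
pipeline recovers ≥ 95% of planted DE genes with ≲ 1% false flags, and
the null type-I rate sits at 0.05 ± 0.01.

## Known limitations

* The batch model is unstructured and aerobic-only: no pH/DO dynamics, no
  mechanistic mixed-acid fermentation (side products are configurable
  constant fractions), no signalling (cAMP/ppGpp appear only as
  covariates in the study design this package serves, not in the model).
* Whether a B-type acetate decline reflects re-uptake, conversion or
  reduced formation is not resolved by the data this emulates; the
  simulator implements threshold re-uptake as one stated hypothesis, and
  the alternatives remain configuration choices.
* The array and gel noise models are deliberately simple (see above);
  conclusions about robustness to spatial or saturation artefacts cannot
  be drawn from the synthetic validation.
* Published absolute carbon-balance pool masses require the per-strain
  total input carbon, which is not derivable from printed data; the
  package exposes it as an input rather than guessing.
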