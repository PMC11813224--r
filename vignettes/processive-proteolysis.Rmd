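---
title: "Mass-balance analysis of processive proteolysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance analysis of processive proteolysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procleave)
```

## The measurement problem

γ-secretase trims its substrate processively: endoproteolysis of C99
produces a long Aβ intermediate (Aβ49 or Aβ48) that stays bound and is
shortened in tri-/tetrapeptide steps, down to secreted Aβ40 or Aβ38.
The Aβ intermediates are hydrophobic and resist direct quantification,
but each cleavage releases one soluble coproduct — an AICD fragment at
the ε step, a small peptide (ITL, VIV, IAT on the Aβ40 branch; VIT,
TVI, VVIA on the Aβ42 branch) at each trimming step. Coproduct
concentrations therefore *count cleavage events*, and everything about
the intermediates can be reconstructed from them.

`procleave` formalises this as a two-branch pathway graph
(`default_pathway()`) and two linear maps over it.

## The mass-balance maps

Write $c_i$ for the coproduct concentration of step $i$ of a branch and
$p_x$ for the final pool of intermediate $x$. Every molecule that ends
at or beyond the product of step $i$ passed through step $i$, so

$$c_i \;=\; \sum_{j \ge i} p_{x_j} \qquad\text{(branch suffix sums)},$$

and conversely

$$p_{x} \;=\; c_{\text{producing}(x)} - c_{\text{consuming}(x)},$$

with terminal species keeping their producing coproduct. The forward
map is a unitriangular linear map, so the inversion is exact (the test
suite asserts the round trip to $10^{-9}$ over 1,000 random pool
vectors, negatives included). Branch conservation — pools summing to
the ε coproduct — is a direct corollary and is also asserted.

Three representational rules matter more than the algebra:

* **Negative pools are data.** If a degradation coproduct is measured
  higher than the matching production coproduct the inferred pool is
  negative, which is physically impossible and therefore diagnostic of
  a quantification inconsistency. Pools are never clipped; they are
  flagged `NEGATIVE_POOL`.
* **Efficiencies are coproduct ratios.** The percent cleavage of a
  trimming step is the ratio of its coproduct to the coproduct of the
  step that produced its precursor, ×100. Values above 100 % are
  impossible in the same way and are returned unclipped with
  `EFFICIENCY_GT_100`. The packaged S170F row reproduces the
  canonical example: its Aβ48→Aβ45 efficiency evaluates to 230.1 %.
* **nd is neither zero nor silent NaN.** A concentration below the
  lowest calibration standard is `censored(limit)`; a value that was
  never measured is missing. Any pool or efficiency whose defining
  coproduct is censored/missing is nd (`NA` with status `"nd"`,
  flagged `BELOW_LOD` / `PRECURSOR_ND`) and is excluded — and counted —
  by downstream statistics. Censoring one coproduct never perturbs
  pools it does not define (asserted property).

## Calibration and isotope channels

Raw instrument responses are converted to concentrations through
internal-standard curves: ordinary least squares of the
analyte/internal-standard response ratio against the standard
concentration series. The default is a free intercept on the linear
scale; forced-origin and log–log fits are exposed as options because
detector linearity over a 40-fold concentration range (62.5–2500 nM
for the AICD standards) is an empirical question the data owner should
decide. Inversion below the lowest standard returns a censored value
carrying that standard as the limit — the censoring threshold is
always a property of the fitted curve, never a constant in the code.
A relative guard of $10^{-9}$ keeps the lowest standard itself
quantifiable despite fit-then-invert round-off.

Light and heavy channels come from substrate produced on
natural-abundance versus uniform ¹³C/¹⁵N media, so the heavy mass of a
peptide is its light monoisotopic mass plus
$n_C\,\Delta^{13}\mathrm{C} + n_N\,\Delta^{15}\mathrm{N}$
(1.0033548 and 0.9970349 Da per atom). Compositions are summed from
the standard residue formulas plus one water; atomic masses are
standard monoisotopic values to ≥ 4 decimals kept in a single table.
Channel assignment picks the nearer theoretical mass within a
tolerance, 0.02 Da by default — the ion-mass extraction width of the
small-peptide LC-MS/MS quantification; exact ties are `"unassigned"`.

## The kinetic simulator

The generator emulates the assay's study conditions: 30 nM enzyme,
saturating substrate (5 µM, three orders of magnitude above enzyme),
16 hr incubation, wild-type turnover number $k_{cat} = 2\,\mathrm{hr}^{-1}$,
four replicates, two isotope channels, eight coproducts. At saturating
substrate and these slow rates product formation stays linear, so
total turnovers are $N = k_{cat}[E]t$ (≤ ~1 µM of the 5 µM substrate
consumed; depletion is ignored). Each turnover commits to the Aβ49
branch with probability $p_{49}$ and then continues at trimming step
$i$ with probability $q_i$, giving the closed form

$$c^{branch}_0 = N p_{branch}, \qquad c^{branch}_i = N p_{branch}\prod_{j\le i} q_j.$$

Released intermediates are assumed not to re-bind — defensible at
saturating substrate, where free C99 outcompetes nanomolar Aβ — and
this is what makes the measured per-step efficiency *identify* $q_i$
exactly (asserted: noiseless efficiencies equal $100\,q$ to machine
precision, and full inference returns each scenario's own $p_{49}$ and
$q$).

Measurement noise is multiplicative mean-one lognormal with a
coefficient of variation (default 0.1), matching the
scale-proportional error of MS responses; a truncated-Gaussian mode is
available. An exact stochastic mode draws the turnover count as
Poisson($N$) and routes every turnover through binomial branch and
continuation choices (one turnover ≡ 1 nM at the nominal assay
volume); its mean converges to the closed form (asserted at 300
replicates within three standard errors). Simulated values under a
per-coproduct detection floor are emitted as censored; the default
floor is 62.5 nM for the two AICDs — the lowest AICD standard — and no
floor for the small peptides, whose lowest standards are not fixed by
the reference protocol. Seeds are explicit in `kinetic_params()`; the
simulator runs on a private RNG stream and never touches the global
state.

What the generator does **not** emulate: calibration-curve error
structure (replicate scatter enters after calibration), substrate
depletion, re-binding of released Aβ, Aβ aggregation, detergent/
membrane effects, or channel cross-talk. Passing tests therefore show
that the *inference machinery* is correct under the stated noise
model, not that real MS data meet that model.

## Occupancy of stalled complexes

For the stalled-complex picture each branch-committed
enzyme–intermediate state $E{\cdot}A\beta_x$ has one outgoing step with
rates $(k_{cleave}, k_{release})$, $q = k_{cleave}/(k_{cleave}+k_{release})$.
Visit probability is the chain product of branch probability and
upstream $q$; mean residence is $1/(k_{cleave}+k_{release})$; occupancy
fraction is visit × residence, normalised over visited states. Scaling
a state's two rates down at fixed $q$ changes no visit probability but
lengthens its residence, so its occupancy fraction strictly increases
— a mutant that slows a step *stalls* on that intermediate even when
the step's efficiency is unchanged. The E·C99 state is not modelled:
the parameterisation ties rate pairs to trimming steps, and
endoproteolysis has no release-versus-cleave competition in it.

## Scenarios and the packaged reference table

The packaged fixture (`table1_fixture()`) holds the calculated Aβ
pools of eight reference reactions — wild-type enzyme with light and
heavy substrate, plus six PSEN1 FAD mutants — with nd cells and
negative pools preserved verbatim. `implied_coproducts()` applies the
forward map to a row (censoring the AICDs of rows whose ε products
were unquantifiable) and is the canonical input for round-trip tests.
The two wild-type rows differ by ordinary measurement scatter; both
are kept, never averaged.

Named scenarios (`scenario()`) are illustrative parameter sets chosen
once to reproduce qualitative phenotype orderings, not fitted
estimates: `"wt"` uses continuation probabilities read off the
wild-type-implied efficiency profile (≈ 0.90/0.60/0.66 and
0.76/0.63/0.13) with an even branch split; `"f386s_like"` keeps normal
$k_{cat}$ but shifts the branch toward Aβ48 and lowers
$q(\mathrm{A\beta43{\to}40})$ and $q(\mathrm{A\beta48{\to}45})$, so
Aβ43 and Aβ48 accumulate; `"endo_deficient"` reduces $k_{cat}$
ten-fold; `"palp_like"` reduces it forty-fold, which puts AICD
production (24 nM in 16 hr) under the 62.5 nM floor. Back-fitting
per-mutant rate constants from the eight-row table is deliberately out
of scope — seven observables per branch pair with no time resolution
underdetermine the rate pairs.

## Statistics, pipeline, and numerical choices

Group comparisons are two-sided unpaired t-tests, pooled-variance
Student by default (Welch by option), with significance stars at
0.05/0.01/0.001 and no multiple-testing correction by default
(Bonferroni/BH would be easy to add downstream; the reference analysis
applies none). nd observations are excluded and counted; groups with
fewer than two numeric values yield an nd result with a reason.
Zero-variance groups are handled explicitly (identical ⇒ $t=0, p=1$;
separated constants ⇒ $p=0$) because the standard test errors on
constant data. Efficiencies are summarised per replicate and then
aggregated — computing them from averaged coproducts is also possible
through the pool/efficiency accessors, but the per-replicate route
propagates replicate variance into the tests.

The pipeline (`run_pipeline()`) is a pure function of (inputs, config,
seed): reruns produce byte-identical CSVs (asserted). CSV dialect:
UTF-8, "." decimal, `NA` for nd, `CENSORED<limit>` tokens for censored
cells; schema violations fail before any output is written, naming the
offending column or row.

Numerical conventions: round-trip assertions at $10^{-9}$ (the maps
are exact in exact arithmetic); comparisons against the packaged
printed pools at ±0.1 nM (one unit in the last printed digit); mass
arithmetic asserted at $10^{-4}$ Da.

## Problem sizes used by the test suite

The suite exercises: 1,000 random pool vectors for the round-trip and
conservation properties; 200 simulations (4 replicates, CV 0.1) each
for turnover-number recovery (median relative error < 10 %) and
per-step $q$ recovery (median absolute error ≤ 0.05); 300-replicate
runs for stochastic-mode convergence and mean-one noise checks; and
100 random peptides for the heavy-shift property. These sizes give
stable medians for the stochastic checks while keeping the full suite
fast.

## Known limitations

* The mass balance assumes every coproduct is stable and fully
  recovered; selective coproduct loss shows up as negative pools or
  impossible efficiencies (by design) but cannot be corrected.
* The linear-regime closed form is wrong near substrate exhaustion or
  for fast enzymes; no Michaelis–Menten titration is modelled.
* The occupancy model is a steady-state proxy — it ranks stalling
  across states and parameter sets but does not predict absolute
  complex concentrations, and it omits the E·C99 state.
* Only the two canonical trimming registers are represented; skip
  cleavages (e.g. Aβ49→Aβ45) and re-binding of released intermediates
  are out of scope.
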