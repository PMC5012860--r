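---
title: "Methods: propionylation-aware histone PTM post-processing and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propionylation-aware histone PTM post-processing and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneub)
```

## Scope and model

`histoneub` post-processes bottom-up proteomics identifications of histone
peptides from propionylated (derivatized) samples, with a focus on
ubiquitylation-remnant (GlyGly) site mapping, and bundles the small
quantitative models that accompany such a study: extracted-ion-chromatogram
(XIC) quantification with free-ubiquitin normalization,
fluorescence-polarization (FP) one-site K~d~ fits, linear reaction-rate
fits, size-exclusion calibration, Gaussian volume-histogram fits, and a
thresholded two-channel 5mC image statistic. Everything upstream of the PSM
table — spectral scoring, target–decoy competition, PEP/q estimation — is
consumed as input, not reimplemented.

## Mass model

Propionic-anhydride derivatization converts every free lysine
ε-amine (and the peptide N-terminus after digestion) to its propionyl
amide. A database search of such samples applies a *static* propionyl
(+C3H4O, monoisotopic 56.026215 Da) to every lysine. A variable
modification that occupies the ε-amine therefore *displaces* the static
propionyl, and its effective search delta is

$$\Delta_{\text{eff}} = \Delta_{\text{mod}} - \Delta_{\text{propionyl}}.$$

Mono-methylated lysine is the exception: it retains one propionylatable
N–H, so its delta is unchanged. Di- and tri-methylation block the amine and
are adjusted — their effective deltas are negative. The package derives all
deltas from Unimod-standard elemental compositions (methyl CH2, dimethyl
C2H4, trimethyl C3H6, acetyl C2H2O, GlyGly remnant C4H6N2O2, oxidation O,
phospho HPO3) rather than storing literals:

```{r}
sapply(mod_table()[c("ub", "me", "me2", "me3", "ac")],
       adjusted_mod_mass, scheme = "propionylated")
```

Average masses use the IUPAC conventional atomic weights (C 12.011,
H 1.008, N 14.007, O 15.999, S 32.06); monoisotopic masses use
principal-isotope values to at least six decimals. Mass assertions in the
test suite use an absolute tolerance of 1e-4 Da: composition-derived and
literature-printed deltas differ by up to 6e-6 Da (the acetylation delta is
a known example), and 1e-4 absorbs that without hiding real errors.
`peptide_mass()` is additive by construction — static propionyl on every
lysine plus scheme-adjusted variable deltas — which makes the two-route
identity (adjusted delta + propionyl = unadjusted delta) an exact test.

N-terminal propionylation is a config flag (`nterm_prop`, default on for
the propionylated scheme): standard for the derivatization protocol, but
not universal, so it is not hard-wired.

## deltaCn re-scoring and FDR

Low-mass-accuracy ion-trap MS/MS cannot distinguish trimethylation
(42.04695) from acetylation (42.01057) by fragment mass, so the two
candidates often receive *identical* XCorr. The conventional
deltaCn definition collapses to 0 in that case and penalizes both. The
package therefore recomputes, per spectrum and rank *i*,

$$\Delta C_{n,i} = 1 - \frac{x_1 - x_i}{x_1} = \frac{x_i}{x_1},$$

which is 1 for the top rank and for exact ties. Any deltaCn column in the
input is overwritten; rank gaps or non-monotone XCorr ladders are hard
errors rather than silently re-ranked, because they indicate a broken
upstream export. FDR filtering retains `q <= threshold` (inclusive
boundary; default 0.05), applied at the PSM level with peptide-level
aggregation afterwards.

## The retention-time consistency filter

Reversed-phase elution shifts with lysine state in a predictable
direction, giving a partial order over site states:

ubiquitin < dimethyl ≤ trimethyl < acetyl < propionyl-only < methyl <
unmodified, oxidation < unmodified, phosphorylation ≤ unmodified

(`<` strictly earlier, `≤` earlier-or-coeluting). `site_relation()` is the
transitive closure with strictness promotion (a path is strict if any link
is strict). Design choices where the procedure itself is underdetermined:

* **Multi-site composition.** Peptides differing at several sites combine
  per-site relations: agreement in direction promotes to the combined
  relation (strict if any site strict); conflicting directions yield no
  constraint. Ambiguous evidence never rejects.
* **Windows.** Strict relations carry zero slack (`s <= rt(Y)`);
  non-strict and coelution relations carry the tolerance window
  (default 2 min), which is where "expected to coelute" chromatographic
  variation lives.
* **Greedy order and ties.** Members are processed by ascending PEP; ties
  break by q-value then the serialized peptide string, so results are
  permutation-invariant and reproducible.
* **Representative RT.** An accepted peptide is represented by the scan RT
  that satisfied its own check (first member: its best-PSM scan). A
  `best_scan` mode pins the representative to the lowest-PEP scan instead;
  the tolerance-monotonicity property is guaranteed in that mode.
* **Overrides.** Whitelisted peptides (manual-inspection acceptances) pass
  unconditionally, are flagged in all outputs, and do *not* constrain
  later candidates — their RT carries no validated information.

The greedy filter is verified against an independently written brute-force
reference on 1,000 randomized groups, and on synthetic data with known
violators (below).

## Quantification

XIC areas are trapezoidal integrals over the supplied trace with a zero
baseline — no smoothing or peak picking, since traces arrive pre-extracted.
Charge states of one peptide are summed. The enrichment ratio is
numerator-sample AUC over denominator-sample AUC; normalization divides by
the arithmetic mean of the free-ubiquitin peptides' raw ratios (free
ubiquitin is produced in both reactions and should ratio to 1, so its mean
ratio estimates the sample-loading scale). Whether the original analysis
averaged ratios or ratioed sums is not derivable; both are implemented
(`mode = "mean_of_ratios"` default, `"ratio_of_sums"` alternative).
Zero-denominator peptides are flagged undefined and excluded from the
normalizer, never imputed. Enrichment filtering is strictly greater-than
(default 10-fold).

## Binding and calibration fits

* **FP.** P = (∥−⊥)/(∥+2⊥), A = 2P/(3−P). The one-site fit uses the
  ligand-excess hyperbola A(c) = A_free + (A_bound−A_free)·c/(K_d+c),
  appropriate when titrated protein ≫ tracer (10 nM); a quadratic
  tight-binding variant (`tracer > 0`) is available for K_d near the
  tracer concentration. Initialization: endpoints from the data range, K_d
  at the half-range concentration; bounds K_d ∈ [1e-12, 1e-2] M; port
  algorithm; fits on a bound or optimizer failures are flagged
  non-converged.
* **Rates.** Ordinary least squares on an optional time window, for time
  courses that are linear early and saturate late.
* **SEC.** log10(MW) regressed on retention time (globular-standard
  convention); a linear-on-MW mode exists but is not the default.
  Extrapolation outside the standards warns.
* **AFM volumes.** Single Gaussian least-squares on histogram counts
  (Freedman–Diaconis bins by default), seeded from the sample mean/SD.

## The 5mC image statistic

For signal channel *r* (5mC), nuclear channel *b* (DAPI), and background
threshold *t*:

$$\text{score} = \frac{\sum_i \mathbb{1}[b_i > t]\,\mathbb{1}[r_i > t]\,(r_i - t)}{\sum_i \mathbb{1}[b_i > t]}$$

with strict inequalities — pixels at the threshold are background. The
threshold is a required input (per-image or global); an Otsu-style
automatic mode exists for exploration but is never the default, since the
statistic's meaning depends on a deliberately chosen background level.
Channels are accepted as numeric-matrix CSVs; TIFF input is out of scope
here because no TIFF reader is available in the supported dependency set.
Percent-of-control averages per-condition field scores and warns below
four fields of view.

## Synthetic data: what it emulates, and what a green test means

Generators are pure functions of (seed, config); substream seeds are
derived per generator so outputs are byte-identical across runs.

* **PSM datasets** are built over the Arg-C digest of the histone H3
  N-terminal tail (residues 1–43), one peptidoform per chain state at the
  first lysine of each peptide. True members' RTs sit at block offsets
  (0, 4, 6, 10, 14, 18 min) honouring the elution chain; violators take an
  RT beyond the far end of the chain for their state, which is
  inconsistent at any tolerance below the block gap. PEPs are drawn from
  disjoint ranges (true 0.0001–0.002, violators 0.2–0.4): the spec of the
  generator requires only stochastic dominance, and clear separation is
  needed because q-values — cumulative means of PEPs — dilute quickly.
  Violator fractions above 0.5 are rejected by design: the wrong-side
  construction then can lose the strict anchor member that guarantees
  rejection.
* **XICs** are noiseless Gaussians with analytic areas; **FP titrations**
  are 12-point semi-log grids spanning 0.01–100× K_d with noise given in
  mP (applied ÷1000 on the anisotropy scale — exact at the small P values
  of FP tracers); **images** have closed-form scores k·(r0−t)/m by
  construction; **volumes** are Gaussian draws.

These emulate the *arithmetic* structure of real data, not its physics: no
chromatographic tailing, isotope envelopes, detector saturation, shared
scans between peptidoforms, or correlated noise. A green acceptance run
therefore establishes that the algorithms implement their definitions and
recover known ground truth under the stated noise models — not that the
pipeline reproduces any particular biological measurement, which would
require the deposited raw data.

## Numerical choices

* Mass comparisons: absolute 1e-4 Da (see above); internal identities to
  1e-9 or exact.
* The RT filter compares minutes as doubles with inclusive bounds; strict
  relations deliberately allow exact ties (s = rt(Y)), since equality of
  measured RTs is not evidence of mis-order.
* nls failures never raise from `fit_one_site()`/`fit_gaussian_hist()`;
  they return flagged non-converged results so simulation studies can
  count them.
* The FDR boundary, enrichment cutoff, and coelution window are inclusive,
  strict, and inclusive respectively — each matching its defining phrase
  ("5% threshold", "greater than ten-fold", "within 2 min").

## Known limitations

* The elution partial order is qualitative; the filter cannot reject a
  wrong identification whose RT happens to fall on the correct side of
  every accepted form.
* Peptide-level PEP/q aggregation uses the best PSM; no model-based
  peptide-level error estimation.
* Quantification assumes pre-extracted, background-subtracted XICs.
* The tight-binding FP variant shares the hyperbola's initialization,
  which can be poor when A_bound is not approached within the titration.
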