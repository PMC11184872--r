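---
title: "Voxel-wise maximum dose-rate metrics for PBS proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise maximum dose-rate metrics for PBS proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsmdr)
```

## The problem

In pencil-beam-scanned (PBS) proton therapy a narrow beam paints the target
spot by spot, energy layer by energy layer. Compared to passively scattered
delivery, each small tissue volume receives its dose in short, intense bursts:
the *instantaneous* dose rate seen by a voxel during the spot that covers it
can be orders of magnitude higher than the field-averaged dose rate. Rare,
severe late toxicities of the optic apparatus have been reported at dose
levels that conventional dose–volume metrics do not explain, which motivates
screening treatment plans for dose-rate structure as a complementary metric
family.

`pbsmdr` implements that screening pipeline end to end:

1. per-spot dose and dose-averaged LET on a voxel grid (analytic pencil-beam
   engine, pluggable behind a sparse per-spot contract);
2. spot beam-on durations from delivery-log files (parsed, or synthesized
   with realistic run-to-run jitter);
3. the voxel-wise maximum dose rate map (MDR), at plan and field level;
4. structure-level near-maximum metrics — D2, LET2, variable-RBE D2, MDR2 —
   and the cumulative dose delivered at or above a dose-rate threshold;
5. a cohort report that ranks fields by MDR2 and flags atypical ones.

Because no clinical dataset accompanies the method, the package ships a
synthetic-cohort generator that reproduces the *statistical shape* of an
8-case intracranial cohort, including a planted high-dose-rate signal, so
every stage is testable without patient data.

## Definitions

For spot $s$ with dose contribution $d_s(v)$ (Gy) to voxel $v$ and beam-on
duration $t_s$ (s), the spot dose rate is

$$\dot d_s(v) = \mathrm{RBE} \cdot d_s(v) / t_s \quad [\mathrm{Gy_{RBE}/s}],$$

with the clinical constant $\mathrm{RBE} = 1.1$ by default. The voxel-wise
maximum dose rate is the plan-level maximum over spots,

$$\mathrm{MDR}(v) = \max_s \dot d_s(v),$$

evaluated only on *valid* voxels — those whose total per-fraction
RBE-weighted dose reaches the dose threshold (default 1 cGy per fraction).
MDR deliberately ignores how much dose arrives at the maximal rate; the
complementary `dose_above_dose_rate()` reports the fraction of a structure's
dose delivered at or above a chosen rate.

Near-maximum structure metrics use the DVH convention: the value exceeded by
the hottest 2 % of the structure volume (`near_max()`, the k-th largest voxel
with $k = \lceil 0.02\,n \rceil$, whole-voxel volumes, no interpolation).
One routine therefore implements D2 on dose maps, LET2 on LET$_d$ maps, MDR2
on MDR maps and D2 under the variable-RBE weighting.

Dose-averaged LET is accumulated as
$\mathrm{LET}_d(v) = \sum_s d_s(v) L_s(v) / \sum_s d_s(v)$; voxels without
dose have no defined LET$_d$ and are excluded from metrics.

The variable-RBE weighting uses the McNamara phenomenological model at
$\alpha/\beta = 2$ Gy (the conventional value for optic structures):

$$\mathrm{RBE}(D, L) = \frac{1}{2D}\left(\sqrt{(\alpha/\beta)^2
 + 4D(\alpha/\beta)\,\mathrm{RBE}_{max}(L) + 4D^2\,\mathrm{RBE}_{min}(L)^2}
 - \alpha/\beta\right)$$

with $\mathrm{RBE}_{max/min}$ linear in LET$_d$. The coefficients are
configuration (`mcnamara_params()`), defaulting to the published fit values.
Note a genuine property of that fit: at very low LET the
$\mathrm{RBE}_{min}$ line lies *above* $\mathrm{RBE}_{max}$; the
constructor's sanity check therefore only rejects parameter sets whose lines
invert at the high-LET end, where the dose enhancement the model encodes
would turn unphysical.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `dose_threshold` | 0.01 | Gy/fraction | voxel validity gate of MDR; absolute MDR values are sensitive to it |
| `rbe_constant` | 1.1 | — | constant RBE weighting of doses and rates |
| `percentile_level` | 2 | % volume | the "near-maximum" level of D2/LET2/MDR2 |
| `display_threshold` | 3 | Gy$_{RBE}$/s | overlay exports only; never affects metrics |
| `alpha_beta` | 2 | Gy | LQ tissue parameter of the variable-RBE model |
| `cutoff` | 1e-4 | Gy/spot | sparse storage floor of the engine; far below the 1 cGy metric threshold |
| `t_typical_ms` | 8 | ms | target mean spot duration of the synthetic log |
| `jitter_sd` | 0.009 | — | run-to-run multiplicative duration jitter (0.9 %) |

Two threshold semantics are implemented (`threshold_mode`): the default gates
voxel *eligibility* by total per-fraction dose; the alternative drops
individual sub-threshold spot contributions. The default is used throughout
because the threshold belongs to the MDR metric's validity domain, not to
single spots.

The variable-RBE dose can be evaluated with the per-fraction dose in the RBE
argument (default, matching fractionated delivery at ~1.8 Gy$_{RBE}$ per
fraction) or with the total dose (`basis = "total"`); both are exposed
because published D2-style comparisons do not always state which convention
they use.

## The analytic dose engine

The engine replaces a Monte Carlo dose calculation with an analytic
pencil-beam model sharing the same per-spot output contract
(`spot_dose`: voxel indices, dose, LET). Per spot, dose is a depth-dose
curve times an isotropic lateral Gaussian of depth-dependent width, sampled
at voxel centers:

* range from energy by Bragg–Kleeman $R = aE^p$ ($a = 0.0022$ cm/MeV$^p$,
  $p = 1.77$; commissioned span 70–230 MeV);
* depth dose: a plateau with sigmoidal distal falloff plus a Gaussian Bragg
  peak, peak-to-entrance ratio ≈ 3.5, single global maximum;
* lateral spread $\sigma(z) = \sqrt{\sigma_0^2 + (cz)^2}$ with
  $\sigma_0 = 6$ mm, $c = 0.04$ — a broad, range-shifter-like spot;
* LET from residual range, monotone non-increasing, clamped to
  0.2–20 keV/µm; secondary-particle LET contributions are not modelled.

This engine is explicitly non-clinical: it exists so the metric layer —
which consumes only per-spot dose/LET grids — can be exercised and
oracle-tested at desk scale. A Monte Carlo backend producing the same sparse
records could be substituted without touching any metric.

## The synthetic cohort and the planted signal

`default_cohort_spec()` encodes an 8-case roster (prescriptions
55.8/50.4/50.4/50.4/54/50.4/50.4/50.4 Gy$_{RBE}$; 1.8 Gy$_{RBE}$ fractions,
1.93 for the 54 Gy case; 3–4 fields per plan, 28 fields in total; two index
cases with late visual toxicity grades 4 and 3). The phantom is a stylized
head geometry: a 14 mm-radius spherical CTV abutting a 4 mm-radius optic
chiasm, with 2.5 mm-radius optic-nerve tubes running anteriorly, all on a
60³ grid at 2 mm spacing (216 000 voxels).

Fields cover the CTV with energy layers every 5 mm of depth and a 4 mm
lateral spot grid, MU ramped toward distal layers; per-case MU is calibrated
so the CTV mean per-fraction physical dose matches the prescription under
constant RBE. Spot durations are MU/current with the current auto-derived
per field so mean durations sit at 8 ms regardless of the MU scale.

The planted high-dose-rate signal follows the mechanism the analysis is
designed to detect — *delivery time structure, not extra dose*. Each index
case has one hot field which is (a) a patch field, its spots confined to
within 12 mm of the left optic nerve's projection on the scanning plane,
(b) delivered at 1.5× beam current, shortening its durations at fixed MU,
and (c) mildly MU-boosted (×1.2). A MU boost alone cannot raise a spot's
dose rate here, because duration is proportional to MU at fixed current —
the boost exists to make hot fields identifiable in the spot map while the
current factor carries the rate signal. Generator defaults were chosen once
so that control-case optic structures see MDR2 of roughly 1–3.6
Gy$_{RBE}$/s while the hot fields produce clearly atypical values whose
≥3 Gy$_{RBE}$/s region touches the targeted nerve; they are not tuned per
analysis.

What the generator does **not** emulate: real anatomy and heterogeneous
stopping power, machine-specific log schemas, interlocks and field
resumptions (every synthetic log is a single uninterrupted delivery),
scanning transit dose between spots, secondary-particle LET, and planning
optimizers (the conformality heuristic is a stand-in). Passing tests
therefore demonstrate the correctness of the metric layer and the internal
consistency of the pipeline, not clinical fidelity of absolute values — in
particular, synthetic index-case MDR2 values come out higher than the
3.9–4.3 Gy$_{RBE}$/s scale reported for real plans.

## Numerical choices

* Volume percentiles count whole voxels; ties at the boundary value do not
  change the returned value (it *is* the boundary value). As the level tends
  to 0 the metric tends to the masked maximum; at 100 it is the minimum.
* Masks are binary, voxel centers decide membership, and structure volume is
  voxel count × voxel volume — consistent with a voxel-scored DVH.
* The sparse cutoff (1e-4 Gy/spot) is applied after MU calibration, so the
  stored sparse set is consistent with the final dose scale.
* Delivery logs are integer microseconds; durations are clamped to ≥ 1 µs.
* All randomness is explicitly seeded; child seeds are derived per case and
  per stage and stay within 32-bit integer range. No function perturbs the
  caller's RNG state.
* Per-fraction basis throughout: spot doses are per fraction, so dose rates
  are fraction-independent.

## Worked example

```{r example, eval = FALSE}
run <- run_cohort(cohort_run_config(), seed = 1)
run$summary                      # cohort medians per structure and metric
flag_atypical(run$metrics, "MDR2", 2)   # the two planted hot fields
```

A full default run (8 cases, 28 fields, ~5000 spots, 216k voxels) takes
well under a minute on a single CPU. The per-structure medians, the 84-row
field-wise MDR2 table and the index-case overlays (MDR masked below the
display threshold) are written by `run_cohort(..., out_dir = )`, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Known limitations

* The analytic engine has no nuclear halo, no range straggling through real
  CT, and a parametric LET curve; absolute LET2 values are indicative only.
* The MDR metric itself — as its proposers caution — is sensitive to the
  dose threshold, and absolute values should not be compared across
  different parameterizations.
* Whether a spot's "delivery time" should include dead time is a log-schema
  question; the beam-on interval is used here.
* The pooled "MDR2 over any optic structure" and the per-structure reports
  are both provided, since published figure conventions differ; the
  `"ANY"` rows in the metric table carry the pooled variant.
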