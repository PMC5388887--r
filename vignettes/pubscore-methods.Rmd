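---
title: "Staging peripubertal ovarian maturation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging peripubertal ovarian maturation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubscore)
```

## The staging model

The Pub-score is a deterministic, rule-based stage on an integer scale
with no zero. Its two halves rest on two biological clocks:

* **Pre-ovulatory (scores −5…−1).** The final days before the first
  ovulation are marked by antral follicle growth through discrete diameter
  classes (SF, F1…F4 in the mouse; SF, F1…F5 in the rat). The most
  advanced *healthy* follicle class present in the sections is the stage;
  atretic follicles are excluded because they have left the ovulatory
  trajectory. The key assumption is that immediately pre-pubertal follicle
  growth recapitulates the follicle growth of the adult estrous cycle, so
  each class can be read as "days until ovulation".

* **Post-ovulatory (scores +1…+8/+12).** Corpora lutea mature on a fixed
  4-day program (day 1: rupture site, non-luteinized granulosa; day 2:
  partial luteinization, abundant mitoses, marked vascular pattern; days
  3–4: full luteinization) and then regress over subsequent cycles with an
  increasing stromal-to-steroidogenic cell ratio and apoptotic bursts at
  each estrus. Dating the current-cycle CL (`d` in 1…4) and counting
  regressing generations (`g`) gives `score = 4·g + d`, the number of
  days since the first ovulation counting the ovulation day itself as
  day 1. Hence the retrodating identity
  `age at first ovulation = age − score + 1`.

The closed form `4·g + d` is provably equivalent to traversing the
species staging flowchart; the test suite checks this by exhaustive
enumeration of every (species, generations, day) combination against an
independently written flowchart traversal.

### CL dating: priority order and tie-breaking

Observed features can disagree (real sections are imperfect), so dating
applies discriminating signals in a fixed priority order, each narrowing
the candidate day set \{1,2,3,4\}:

1. **oocyte location** — cumulus–oocyte complexes in the ampulla (day 1),
   nude oocytes at the isthmus (day 2), at the utero-tubal junction or
   uterus (day 3, mouse only). "No oocytes found" is treated as
   *uninformative*, not as evidence for days 3–4, because oocytes are
   easily missed;
2. **apoptosis landmark** — abundant apoptotic cells in the current CL
   mark day 4 in the mouse; rat current-cycle CL show none, so the token
   is a conflict in a rat current CL;
3. **luteinization grade** (none → 1, partial → 2, full → \{3,4\}),
   refined by abundant mitoses (day 2) and the fibrous center (mouse
   day 3). `mitoses = "present"`/`"absent"` and the vascular pattern are
   treated as corroborating, not discriminating — they vary too gradually
   to pin a day on their own;
4. **companion follicle class** — the most advanced healthy class
   compatible with each day (in the rat, F5 is what separates day 4 from
   day 3; F2/F3 both sit at day 2).

A signal that would empty the candidate set is recorded as a conflict:
the result keeps the best-supported day but the status becomes
`inconsistent` and no first-ovulation date is issued — the engine never
chooses silently when cytology and companion follicles disagree by more
than the schedule allows. If several days remain after all signals, the
*earliest* is returned, so an ambiguous score always reads as a minimum
elapsed time.

### Censoring

Mouse regressing CL are eliminated within one cycle, so at most one
regressing generation is identifiable and +8 is the mouse ceiling; the
rat retains two identifiable regressing generations (+12 ceiling). An
observation recording more regressing generations than the species cap is
returned as `censored` at the ceiling score rather than as an error: the
score is then still a valid *minimum* elapsed time since ovulation and
cohort tables can report "≥ 8 days". Censored animals are never assigned
a first-ovulation date. A two-cycle-old mouse remnant cannot carry a
confident `R2` label (that generation identity exists only in the rat);
it is coded by its stromal ratio grade alone, which is how the simulator
renders it and how the reader accepts it.

### Day resolution

Ages are integer postnatal days (PND, birth = day 1). Animals are assumed
sacrificed in a fixed morning window, so sub-day timing is out of model;
all arithmetic is exact integer arithmetic and round-trip recovery of a
simulated first-ovulation age is required to be *exact*, not approximate.

## Species parameters

All species-specific knowledge lives in two annotated YAML files
(`inst/extdata/rat.yaml`, `mouse.yaml`): follicle class bounds (μm) and
class→score map, the 4-day CL feature schedule with companion classes and
oocyte transit, cycle length (4 d), the regressing-generation cap (rat 2,
mouse 1) and the ceiling (always `4·cap + 4`). Two points were genuinely
open and resolved as follows:

* **Rat follicle bounds.** Only the small-follicle ceiling (< 275 μm) is
  established for the rat in the source material for this scale; the
  shipped F1–F5 bounds are placeholders spanning the plausible
  preovulatory range and are flagged non-normative in the config header.
  Diameter-based classification in rats should be given strain-calibrated
  bounds; class labels and scores are unaffected.
* **Rat SF vs F1.** Six rat classes map onto five scores. SF and F1 both
  map to −5; an SF animal's result carries a `below_F1` evidence note so
  the distinction is never lost downstream.

## The simulator: what it emulates, what it does not

`simulate_cohort()` draws ground-truth trajectories: VO age and the
VO→first-ovulation lag are truncated normals (VO ≥ PND-25, lag ≥ 0)
rounded to integer days — cohort statistics in this field are reported as
means ± SD of integer daily observations, which a rounded truncated
normal reproduces; the shape beyond the first two moments is a modeling
choice, not a claim. Defaults are the validation cohort conditions: rats
n = 20, VO 33.2 ± 0.9, lag 0.8 ± 0.7, sacrifice at PND-37; mice n = 17,
VO 31.8 ± 1.8, lag 6.8 ± 2.3, sacrifice uniform 0–8 days after first
ovulation so animals land inside the mouse dating window. Optional 5-day
mouse cycles (`p_long_cycle`) insert the extra day in diestrus.

`render_observation()` maps elapsed time deterministically onto the
species schedules: day −k before ovulation carries the follicle class
scored −k; day k after it yields the current-CL day, companion class,
oocyte location and regressing generations with their estrus apoptotic
bursts. Rendering is *noise-free*: every feature matches its schedule. The
round-trip property (simulate → render → score → retrodate recovers the
true first-ovulation age exactly for all non-censored animals; verified
at n = 1000 plus 400 per species under varied sacrifice rules) therefore
demonstrates the internal consistency of the rule system and its
implementation — it does **not** demonstrate robustness to section
quality, inter-rater disagreement, missed oocytes or atypical cytology,
none of which the generator emulates. The `inconsistent` status exists
for exactly those real-data situations. With 5-day cycles enabled the
score is shown (property test over 300 mice) to underestimate elapsed
time by at most the accumulated extra diestrus days and never to
overestimate it — the "minimum elapsed time" reading.

## Cohort statistics

Group summaries use two-sided Student-t confidence intervals
(df = n − 1), appropriate for the n < 30 cohorts this method targets, and
the squared Pearson correlation between VO age and retrodated
first-ovulation age with the standard t-transform p-value. Under the
simulator's independent-lag model the expected R² is
`Var(VO) / (Var(VO) + Var(lag))`; the suite checks simulated R² against
this analytic value within three delta-method standard errors plus the
integer-rounding variance shift (rounding adds 1/12 to each variance).
Censored and prepubertal animals are excluded from first-ovulation
statistics with a logged count and surface in the reported ovulating
proportion instead; display rounding is one decimal, internal values keep
full precision.

Of the eight published follicle-diameter CI bounds available for
cross-checking the t method, two (440.5 ± 24.7 → lower 428.2 and
323.9 ± 28.3 → upper 338.0, both n = 18) recompute exactly to 0.1 μm and
are pinned in the tests; the remaining bounds do not all reproduce from
their printed mean/SD/n at that precision and are deliberately not
asserted.

## Known limitations

* Negative scores grade maturation but **cannot predict** when a
  non-ovulating animal will ovulate; ovulation also requires a competent
  hypothalamic–pituitary axis.
* The mouse window ends at +8; later sacrifices are censored by design.
* Rat cycles are modeled as strictly 4-day; uneven rat cycles are not
  modeled (the 4–5-day unevenness is a mouse phenomenon here, handled as
  the minimum-elapsed bound above).
* Scoring consumes *coded* observations; measuring diameters or
  recognizing mitoses/apoptosis on slides is upstream of this package.

## Problem sizes

Default test runs use cohorts of 300–1500 simulated animals for the
stochastic properties, 10⁴ draws for distribution-moment and large-n CI
checks, and exhaustive enumeration (≤ 4 days × 3 generations × 2 species)
for the flowchart equivalence; the full suite completes in well under a
minute on one CPU.
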