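---
title: "Matching patient needs to healthcare services on the ICF hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching patient needs to healthcare services on the ICF hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfmatch)
library(dplyr)
```

## The problem

General practitioners caring for older multimorbid patients face a wide and
shifting landscape of healthcare services, social-care offers and assistive
products. Which of them address a given patient's actual needs is hard to
keep in view. `icfmatch` implements a content-based recommender for this
setting: it codes a patient's functional limitations and a catalogue of
services in a shared vocabulary — the WHO International Classification of
Functioning, Disability and Health (ICF) — and ranks services by how directly
their treatment targets address the patient's coded needs.

Two properties of the ICF carry the whole construction. First, it is a
mono-hierarchy: every category has exactly one parent, read off the code
text itself (`d4500` *walking short distances* sits under `d450` *walking*,
which sits under chapter `d4` *mobility*), so a taxonomic proximity between
any two categories is well defined. Second, each coded limitation carries a
severity qualifier from 0 (no impairment) to 4 (complete loss of function),
which we read as the intensity of need.

## The matching model

A patient is a set of functional limitations $(c_i, q_i)$ — ICF code plus
qualifier. A service is a set of ICF treatment targets $T$. One limitation
matched against one target scores

$$ s(c, q, t) \;=\; \frac{q}{4}\;\cdot\;\operatorname{prox}(c, t), $$

and a service's total for a patient is, under the default `sum_best`
aggregation,

$$ S \;=\; \sum_i \max_{t \in T} s(c_i, q_i, t). $$

Services are ranked by $S$ descending, ties broken by ascending service id,
zero scorers dropped, and the top 20 (configurable) reported with
per-limitation provenance: which target matched, at what pair score.

### Proximity

The hierarchy motivates proximity but does not fix a formula, so the choice
is an explicit design point, exposed as a strategy argument. The default is
a Wu–Palmer-style measure restricted to a tree:

$$ \operatorname{prox}(a,b) \;=\;
   \frac{\operatorname{depth}(\operatorname{lca}(a,b))}
        {\max(\operatorname{depth}(a), \operatorname{depth}(b))}, $$

with chapter depth 1 up to fourth-level depth 4. It is bounded in $[0,1]$,
symmetric, equals 1 exactly on identical codes, and rewards
ancestor–descendant pairs: a severe short-distance walking limitation
`d4500.3` against the walker's target `d450` gives
$\tfrac{3}{4}\cdot\tfrac{2}{3} = 0.5$, while the same limitation against an
unrelated hearing target gives 0. An alternative strategy,
$1/(1+\text{edge distance})$, is available for sensitivity analysis; the two
agree on identity and disjointness and order ancestor chains the same way.

Codes from different components (e.g. a body function `b` against an
activity `d`) have no coded common ancestor and score 0: cross-component
matches are not meaningful without an explicit linkage table, which the ICF
does not provide. The same holds within a component across chapters, since
the component root is not itself a code. One consequence worth stating
plainly: proximity 0 does not only occur across components, but for any
pair without a shared coded ancestor.

### Aggregation

`sum_best` sums each limitation's best match, so a service addressing
several impaired functions outranks a single-function match — appropriate
for multimorbid patients, whose need is cumulative. The alternative `max`
(score only the single strongest match) is kept selectable because the
choice is substantive, not technical: `max` favours specialised services,
`sum_best` favours broad ones. Duplicate targets cannot inflate a score
under either rule, and raising any qualifier can only raise scores —
both properties are enforced by randomized tests.

## From assessments to coded limitations

Limitations usually arrive as raw geriatric-assessment scores, not ICF
codes. The mapping layer is a declarative table of half-open score bands
`[lo, hi)`, each assigning one code and qualifier; the bands for each
instrument partition its admissible range, which a sweep test verifies.
The shipped defaults follow the instruments' conventional cut-offs:

| Instrument | Band → code.qualifier |
|---|---|
| Timed Up-and-Go (s) | [0,10) → d450.0; [10,20) → d450.1; [20,30) → d450.2; [30,∞) → d450.3 |
| MMSE (points) | [27,31) → b144.0; [21,27) → b144.1; [11,21) → b144.2; [0,11) → b144.3 |
| GDS-15 (points) | [0,5) → b152.0; [5,9) → b152.1; [9,12) → b152.2; [12,16) → b152.3 |
| Clock test (Shulman) | [1,3) → b144.0; [3,4) → b144.1; [4,5) → b144.2; [5,7) → b144.3 |
| IADL (per item) | dependent item → qualifier 2 in the matching category (shopping d620, housekeeping d640, meals d630, transport d470, medication d5702, finances d860) |

These numeric bands are declared conventions, not recovered facts: the
anchors they must respect are qualitative (a Timed Up-and-Go of 14 s is a
*mild* mobility impairment, 25 s *limited* mobility; MMSE 25 indicates
*mild* dementia; GDS 7 makes a depressive disorder *likely*), and the
defaults are chosen so those labels land on qualifiers 1, 2, 1 and 1
respectively. Every band is overridable from a YAML/JSON file, and the
ANGELINA instrument deliberately ships no defaults — its content is not
standardised, so using it without user-supplied rules is a configuration
error rather than a silent guess.

Qualifier-0 outcomes are emitted and flagged `zero_need` rather than
discarded: they document that an instrument was administered and found
nothing, which matters for audit, but they never influence ranking. When
several results code the same category (MMSE and clock test both code
memory functions b144), the maximum qualifier wins.

## The bundled fixtures

Two case-vignette profiles ship with the package: an 81-year-old man with
polypharmacy, diabetes and hypertension (TUG 14 s, GDS 7, dependent in
shopping and housekeeping, pain-limited daily functions) and an 89-year-old
woman living alone with suspected dementia (TUG 25 s, MMSE 25, clock test 3,
hearing difficulties despite an aid). Diagnoses and drug lists are carried
as inert metadata — inventing diagnosis-to-ICF mappings would overreach the
assessment-driven design, so they are preserved for fidelity but never
scored.

The two expert-panel rating matrices record which of 19 (vignette 1) resp.
16 (vignette 2) recommendation types each of 8 GPs marked. Their row totals
(48 and 41 marks) follow the published tables row by row. The assignment of
marks to individual rater columns is not recoverable from the source text,
so it is a reconstruction constrained to reproduce every published
per-rater marginal simultaneously: ranges 3–10 and 1–9, means 6.0 and 5.1,
standard deviation 2.9 for both panels, pooled mean 5.6 and sd 2.8, and
exactly three majority-endorsed items per vignette. A regression test locks
all of these in; analyses that depend on the *within-column* pattern beyond
these marginals should not lean on this fixture.

The demonstration catalogue covers every distinct recommendation type from
both rating tables with curated ICF targets (physiotherapy → {d450, b710,
b770}, occupational therapy → {b144, d640}, personal emergency response
system → {d240}, ...). Except for the walker → d450 assignment, which is
the model's own worked example, these linkages are the implementers'
curation, documented in the catalogue file, and illustrative rather than
clinically validated.

## Evaluation statistics

The evaluation layer reproduces the plausibility-check arithmetic from
items-by-raters 0/1 matrices: per-rater counts, their summary (sample sd,
$n-1$ denominator, as SPSS reports it), and majority items (strictly more
than half the panel). For paired count comparisons it implements the
asymptotic Wilcoxon signed-rank test:

$$ z = \frac{W - n(n+1)/4}
       {\sqrt{n(n+1)(2n+1)/24 - \sum_g (t_g^3-t_g)/48}} $$

with $W$ the sum of positive ranks, mid-ranks for ties, zero differences
dropped (Pratt's zero handling is available behind a flag) and no
continuity correction by default — with the correction, eight uniformly
positive differences cannot reach $|z| \approx 2.52$, which is the regime
the method is meant for at panel sizes of 8. The implementation is checked
three ways: against a count-based Walsh-average oracle for $W$, against
exact enumeration of all $2^n$ sign patterns for the null moments, and
against `stats::wilcox.test(..., exact = FALSE)`. Effect size uses Cohen's
$d = (m_2-m_1)/\sqrt{(s_1^2+s_2^2)/2}$ on group summaries.

One note on naming: the evaluation design compares *paired* per-rater
counts, and the reported statistics ($z$ from $W$ at $n = 8$) identify the
signed-rank test with normal approximation, not the two-sample rank-sum
test; the package implements and documents the former.

## The synthetic cohort generator

`generate_cohort()` emulates the two multimorbidity profiles for property
testing. Scores are drawn in the impaired ranges typical of
community-dwelling multimorbid elders: the polypharmacy profile draws
Timed Up-and-Go from a normal (mean 18 s, sd 4) clamped to 10–40 s — that
floor encodes the profile's defining mobility-related need and guarantees
at least one coded limitation per patient — GDS uniformly over 0–12 and six
IADL items as independent failures (shopping and housekeeping most likely);
the dementia-suspect profile always draws MMSE below the 27-point
normal-cognition cut-off and a clock score of 3 or more, plus a pre-coded
hearing limitation in about half of the profiles. Generation is seeded,
order-stable and leaves the global RNG stream untouched.

What the generator does *not* emulate: correlations between instruments
within a patient, measurement error and retest variability, missing
assessments, and any rater behaviour. Tests passing on synthetic cohorts
therefore demonstrate the mechanics of mapping and ranking — determinism,
monotonicity, recovery of planted signal — not clinical validity on real
assessment data.

## Numerical and scale choices

Scoring is exact rational arithmetic on small grids (qualifier quarters
times proximity fractions), so ties are exact and the deterministic
tie-break (ascending service id) is meaningful. Randomized test batteries
use fixed seeds: the oracle-equivalence battery checks 1,000 random
(profile, service) instances against a brute-force all-pairs loop, the
monotonicity batteries 1,000 perturbation trials, and planted-service
recovery 1,000 seeded trials, which complete in well under a minute
together with the vectorized scorer. Sign-pattern enumeration for the
signed-rank oracle is done at $n \le 8$ (256 patterns per case). The
acceptance script's cohort check uses 200 patients.

## Known limitations

* Proximity on the ICF tree is one defensible choice among several; the
  original system this design follows does not publish its internal
  formula, so agreement with it cannot be claimed — only the documented
  properties of the measure chosen here.
* The mapping defaults encode conventional screening cut-offs, not a
  validated severity calibration; clinical use would require reviewing
  every band.
* Per-rater columns of the rating matrices are reconstructions (see above).
* There is no cross-component linkage: a service coded only with
  environmental-factor (`e`) targets can never match a body-function or
  activity limitation and will simply not be recommended.
* Patient priorities — which needs the patient themselves ranks highest —
  are not modelled; the configuration schema reserves a per-limitation
  weight field for that extension.
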