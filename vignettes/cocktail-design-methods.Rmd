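---
title: "Methods: evaluating and composing phage cocktails with phagemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating and composing phage cocktails with phagemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemix)
library(dplyr)
```

phagemix implements the quantitative backbone of a rational phage-cocktail
development programme against mastitis-associated *Escherichia coli* and
*Staphylococcus aureus*: estimating phage titers from plaque assays, scoring
lytic activity from plate-reader kinetics, calling host range from
serial-dilution spot tests, analysing resistance cross-sensitivity with
receptor-prediction confirmation, selecting cocktail components by
receptor-diverse set cover, and summarising biofilm, milk-model and
storage-stability efficacy. This vignette explains each model, the tunable
parameters, the numerical conventions, and what the synthetic assay
generators do and do not emulate.

## Titer estimation from dilution series

The titer estimator implements the weighted plate-count formula

$$M_f = \frac{\sum c}{V \cdot d \cdot (N_1 + 0.5\,N_2 + 0.25\,N_3 + \dots)}$$

with $\sum c$ the plaques summed over all countable plates, $V$ the
inoculated volume (0.1 mL by default), $d$ the dilution factor of the
least-dilute counted level, and $N_k$ the number of counted plates at the
$k$-th counted level. Three conventions were genuinely open and are fixed
here:

* **"the lowest dilution used"** is read as the dilution factor of the
  least-dilute counted plate (the largest factor). This makes the
  single-dilution case collapse to the classical $c/(V d N)$ estimator,
  which we consider non-negotiable.
* **Countability window**: plates with fewer than 3 or more than 300
  plaques are excluded before the formula is applied. The window is an
  argument (`countable =`) because counting-room practice varies.
* **Weights keep halving** (0.125, ...) beyond the third dilution.

A caveat worth stating plainly: the halving weights are exactly right for a
*two-fold* dilution step, where the expected per-plate count halves from one
level to the next. For a ten-fold series the classical weight for the next
level would be 0.1, and summing levels with weight 0.5 biases the estimate
downward whenever counts from more than one ten-fold level enter the sum. We
implement the formula verbatim rather than "fix" it, and the package's own
unbiasedness checks therefore use either a single counted level (which the
3--300 window often enforces naturally on a ten-fold series) or a two-fold
step design, where the estimator is exactly calibrated:

```{r titer}
estimate_titer(tibble::tibble(dilution = 1e-6, plaques = 50), volume_ml = 0.1)
```

## Lytic-activity classification

Growth inhibition is scored from OD620 kinetics measured every 20 min for
280 min: the replicate-averaged difference between untreated control and
phage-treated wells at the final shared timepoint. The thresholds are fixed
constants taken from prior calibration on avian pathogenic *E. coli*
absorbance panels: a difference above 0.1 is *strong* inhibition, below 0.05
*none*. "Between 0.1 and 0.05" is implemented as the closed interval
[0.05, 0.1] for *weak*, so strong requires strictly more than 0.1 and no
difference value falls in a gap. Duplicate wells are averaged before
differencing and blanks are not subtracted — the control and test arms are
differenced directly, so a common medium background cancels. The endpoint
(not area under the curve) is the v1 statistic; transiently inhibited
cultures that regrow to control kinetics by 280 min are therefore scored
*none*, by design.

Panel summaries report per-phage percentages of the strain collection
(rounded to one decimal) and an overlap row that takes each strain's best
call across phages — the coverage a cocktail of all panel phages would
achieve:

```{r panel}
calls <- tibble::tibble(
  phage_id = "348Ecol098PP",
  strain_id = sprintf("s%02d", 1:18),
  label = c(rep("strong", 9), "weak", rep("none", 8))
)
summarize_panel(calls)
```

## Host-range calling from spot tests

The spotting ladder is a ten-fold series of the cocktail starting at
2×10^8 PFU/mL. A replicate's lowest titer with a positive sign (clearance,
turbidity or plaques) is banded by order of magnitude — floor of log10 — and
bands 3--5 are *sensitive*, 6--8 *intermediate*, no positive spot
*insensitive*. Banding by magnitude is deliberate: the physical ladder
(2×10^k) never coincides with the stated power-of-ten band edges, and the
floor-log rule maps 2×10^4 into band 4 as intended. A strain positive only
at 2×10^8 falls in band 8 and is called intermediate; whether "insensitive
up to 10^8" should swallow that case is ambiguous, and we apply the banding
rule uniformly. Triplicate series are combined by majority, with ties
resolved toward the *less* sensitive label — the conservative choice for a
therapeutic claim.

## Resistance cross-sensitivity and receptor confirmation

Resistant variants are raised by exposing host strains to a phage overdose,
then spot-tested against the whole panel. `analyze_cross_sensitivity()`
summarises the variant × phage grid with not-tested cells excluded from
every denominator (never imputed): per-variant counts of phages that still
lyse it, the distribution over ≥2 / exactly 1 / 0, per-phage rescue counts,
and *core phages* — phages lytic against every variant they were tested on.
On the packaged grid (28 variants) the *S. aureus* phage 357Saur119PP is the
single core phage, rescuing all 8 variants raised against the other two
anti-staphylococcal components.

`confirm_receptors()` closes the loop between genome-based receptor
predictions and the genes actually mutated in resistant variants. Each
non-silent mutated gene is mapped to a receptor class through an editable
table (`default_gene_map()`: *ompC*, *ompA* to their porins, *wzzB*/*wbbD*
to LPS O-antigen synthesis, *tarS* to the wall-teichoic-acid β-GlcNAc
decoration); intergenic records (e.g. partial 5S rRNA hits) are silent and
ignored. A prediction is **confirmed** when some resistant variant has *all*
of its non-silent genes mapping into the predicted receptor set,
**partially_confirmed** when only a subset maps, **not_confirmed** when
sequenced resistant variants exist but nothing maps, and **no_data** without
sequenced variants. The strict all-genes rule means a variant carrying both
an *ompC* hit (in the prediction) and a *wzzB* O-antigen hit (not a
predicted receptor) yields only partial confirmation — we prefer an honest
"partial" over crediting the prediction with a gene it did not predict.
`not_confirmed` extends the obvious three-state vocabulary because a
mismatching mutant is evidence of a different kind than a missing mutant.

```{r confirm}
confirm_receptors(
  load_fixture("receptor_predictions"),
  load_fixture("mutations"),
  load_fixture("cross_sensitivity")
) |> select(phage_id, status, n_resistant_sequenced)
```

## Cocktail design

The published cocktail was composed by expert reasoning about receptor
complementarity; `design_cocktail()` is this package's formalisation of that
principle, documented as such. It is a greedy maximum-coverage selection: at
each step add the phage covering the most still-uncovered strains, breaking
ties by (1) fewest main-receptor classes shared with already-selected
phages, (2) most strongly inhibited strains, (3) lexicographic id, and stop
when coverage stops improving or the size budget is reached. A strain counts
as covered on a strong *or* weak call by default (`coverage = "strong"`
restricts it), mirroring the two ways a panel's combined activity can be
quoted. Because selection stops when coverage stalls, the design never adds
a phage purely for redundancy; redundancy is *reported*, not optimised:

* **redundancy depth** — covering phages counted once per distinct
  main-receptor class signature (two phages attacking the same porin add no
  depth; support receptors deliberately do not count);
* **resilience** — whether a strain stays covered after the loss of any
  single covering phage, requiring a receptor-distinct backup, and — where a
  cross matrix with parent-strain links is supplied — that each of the
  strain's resistant variants remains sensitive to at least one selected
  phage;
* **core phages** — selected phages that rescue every resistant variant
  they were tested on.

Greedy maximum coverage carries the standard $(1 - 1/e)$ worst-case
guarantee against the optimal same-size subset; the test suite verifies the
bound against exhaustive subset enumeration on random panels up to 12
phages, and exact optimality on 4-phage panels.

Formulation splits a component titer equally: five phages at
1×10^8 PFU/mL give 2×10^7 each; three give 3×10^7 after rounding to one
significant digit (the exact 3.33×10^7 is retained for audit). Storage
stability is the percentage of the log10 summed cocktail titer relative to
the first timepoint, integer-rounded for reporting:

```{r stability}
stability_percent(load_fixture("stability"))
```

## Biofilm and milk-model efficacy

Effectiveness of biofilm control is
$\mathrm{EBC} = 100 - \bar A_\mathrm{test} \times 100 / \bar A_\mathrm{control}$
from OD570 MTT readings, with replicate means in both numerator and
denominator; negative values (stimulated biofilm) are reported, not clamped.
Threshold summaries (`summarize_ebc()`) report the integer-rounded
percentage of strains at or above an EBC cutoff.

Milk-model efficacy is the percent log reduction
$100\,(1 - \overline{\log_{10} N_\mathrm{phage}} / \overline{\log_{10} N_\mathrm{control}})$
— the ratio of mean logs, not the mean of ratios, with the control log count
taken as 100%. Significance uses a two-sided two-sample Student t-test on
log10 counts (pooled variance by default; `var_equal = FALSE` gives Welch),
starred at exactly 0.05 / 0.01 / 0.001. With one replicate per arm the
reduction is still computed but the p-value is withheld rather than
fabricated from zero degrees of freedom.

## The synthetic assay generators

The generators exist so the whole pipeline is testable without laboratory
data; their defaults encode the study conditions rather than convenient
values.

* **Growth curves** are four-parameter logistic in OD units (baseline 0.05,
  plateau drawn in 0.9--1.3, midpoint ~140 min at 280-min lytic scale),
  because only curve shapes, not a fitted model, are available to emulate.
  The four response phenotypes — full, partial (reduced plateau, 30--60% of
  control), transient (suppressed early, rejoining control kinetics), none —
  default to the 22 : 6 : 4 : 4 mix observed across the 36 classifiable
  strains of the 24-h kinetic screen. Noise is Gaussian on OD (sd 0.02 by
  default), floored at zero.
* **Plaque counts** are Poisson with mean titer × volume × dilution — the
  canonical plating model.
* **Cross matrices** come from a receptor-knockout model: a variant raised
  against a phage loses one of that phage's main receptor classes and stays
  sensitive to any phage with another intact main receptor. This is the
  generative formalisation of why a receptor-diverse cocktail resists
  cross-resistance; a phage excluded from the inducing set plays the "most
  conserved receptor" core role.
* **Milk endpoints** are lognormal with log10 means at the midpoints of the
  observed 24-h control ranges (4×10^7--2×10^8 CFU/mL for *E. coli*,
  3×10^8--3×10^9 for *S. aureus*) and a planted percent-log-reduction
  effect (43% by default), so the estimator's parameter recovery can be
  measured.
* **Stability series** decay exponentially with lognormal measurement
  noise; **spot grids** are thresholded detection with random positive
  codes; **biofilm plates** scale a strain's capacity by a suppression
  factor.

One global seed fans out to per-assay substreams through a deterministic
hash of an assay label, so any single assay is reproducible in isolation
and assays are mutually independent. Within-assay replicate noise magnitudes
are package defaults — the published tables carry no replicate variances to
calibrate against — so passing recovery tests demonstrates correctness of
the estimators under plausible noise, not the field error of the assays.
Real plate-reader data also carry artefacts the generators omit: edge
effects, condensation spikes, drift, phage-lysis debris absorbance.

## Problem sizes and numerical conventions

The bundled checks run at desk scale, chosen to keep Monte-Carlo error well
inside the asserted margins: 500 replicate titer simulations (relative bias
asserted < 5%), 1000 curve pairs for classifier separation (accuracy
asserted ≥ 95%; noiseless separation is exact), 200 random 4-phage ×
8-strain design instances against exhaustive enumeration plus 50 size-
budgeted instances up to 12 phages for the $(1-1/e)$ bound, and 200 seeds
of the milk model (planted 43% effect recovered within ±5 points).
Percentages are rounded to one decimal in panel and host-range summaries
and to integers in EBC-threshold and stability reporting, matching how such
tables are printed; unrounded values are always retained in the returned
objects. Degenerate inputs fail loudly: all-uncountable plates, empty
panels, zero control absorbance and non-positive titers are errors, not
NAs.

## Limitations

The design objective covers coverage and receptor diversity but not phage
antagonism, dosing or pharmacokinetics. Host-range and lytic-activity
summaries at panel level depend on per-strain raw data that published
tables aggregate away, so those are validated by fraction arithmetic and
synthetic recovery rather than against per-strain ground truth. The titer
formula's weighting caveat above applies whenever multiple ten-fold levels
are countable. Genome assembly, annotation, variant calling and structural
receptor prediction are upstream of this package: mutation tables and
receptor predictions are consumed as curated inputs.
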