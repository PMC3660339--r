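---
title: "Methods: differential phosphorylation-impact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phosphorylation-impact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosimpact)
```

## The model

Kinase specificity is carried by the short recognition motif around the
phosphoacceptor. We model a kinase as a position-specific probability
matrix over offsets $-u..+d$ (default $\pm 5$, an eleven-residue window)
with an acceptor set $A \subseteq \{S, T, Y\}$. A window $w$ centred on a
candidate acceptor scores, in bits,

$$ S(w) \;=\; \sum_{k} \log_2 \frac{p_k(w_k)}{q(w_k)}, $$

the log-odds of the motif model against a background distribution $q$.
Scores at or above `score_threshold` (default 5) are reliable
predictions. Three modelling choices matter:

* **Terminus clipping.** Offsets clipped by a protein terminus contribute
  zero — no padding residue is invented — so scores stay comparable near
  the ends of a protein.
* **Not-an-acceptor is a signal, not a low score.** Scoring a window
  whose centre is outside the model's acceptor set returns `NA`, and
  `scan_site()` skips such models. A non-acceptor centre is a different
  fact than a poorly matching motif.
* **Finite log-odds.** Matrix rows containing zeros receive a
  background-scaled pseudocount (default 0.1) at load time and are
  renormalized, so scores are always finite.

## The differential

For each variant we compare predictions at every catalogued site within
`selection_radius` (default 10, inclusive: distance $\le 10$) of the
variant, between the wild-type and the mutated sequence.

* A kinase bound in the wild type whose mutant score falls below the
  threshold counts as **lost** — loss is threshold-crossing, not
  disappearance, so a prediction that survives with a degraded score is
  still lost.
* A site is **abolished** when the lost fraction of wild-type-bound
  kinases reaches `abolition_fraction` (default 0.8, applied as $\ge$;
  losing 4 of 5 kinases abolishes).
* Kinases newly bound at the *original* site never compensate for the
  loss of different kinases; they mark the site `strengthened` only when
  nothing was lost.
* If the alternate residue is S/T/Y, the mutant is scanned at the altered
  position; one or more reliable predictions there constitute a
  **created** site. A created site coinciding with a catalogued position
  is treated as gain-at-site, not creation.
* **Rescue** requires every abolished site's entire lost kinase set to
  re-bind at a created site under the *same kinase name*. Name identity
  is the default because the motivating examples distinguish a variant
  whose lost kinase re-binds one residue over (not counted as altering)
  from one that swaps in an unrelated kinase (counted). Family-level
  rescue is available behind `family_rescue` with a user-supplied
  name-to-family map, off by default.
* A variant paired with several sites receives one verdict aggregating
  all its site comparisons; one abolished site suffices for an
  abolishing category. Counted entities are distinct substitutions —
  repeat database reports collapse with frequencies summed.

The categories `abolishing`, `abolishing_and_creating`, `creating`,
`rescued`, `none` partition the verdict space; `rescued` and `none` are
excluded from "altering" counts.

## Replay backend

Where recorded predictor output must be reproduced exactly, a replay
table substitutes for live scoring. Recorded rows carry nominal scores —
threshold + 1 for bound predictions, threshold − 1 for predictions
recorded as sub-threshold — a declared convention, since the recording
carries only the binding decisions. Wild-type and mutant rows are stored
in the context of each variant query, mirroring how per-variant output is
matched against its wild-type run; the per-site wild-type sets implied by
different variant records need not be globally consistent, and the
packaged BRCA fixtures indeed are not (different variants at one site
record different wild-type kinase sets). Querying a variant absent from
the table is an error; a known variant with nothing recorded at a paired
site means "no change recorded there".

The packaged BRCA1/BRCA2 catalog transcribes only the sites named in the
recorded predictions, not the full catalogs the original site selection
ran against. Re-applying the 10-residue selection rule to this partial
catalog would wrongly drop creating-only variants far from any
transcribed site, so the fixture path keeps unpaired variants
(`keep_unpaired = TRUE`); with the live PSSM backend the selection rule
applies as stated. The per-gene denominators (191 and 43 analysed
variants) are inputs shipped with the fixture, because the fixture tables
list only the altering subset.

## Conservation layer

The tolerance caller is deliberately SIFT-*like*, not SIFT: plain
pseudocount column profiles
$p(a) = (n_a + \epsilon) / (N + 20\epsilon)$ instead of Dirichlet-mixture
regularizers, with the conventional 0.05 cutoff on the normalized
probability $p(\text{alt}) / \max_a p(a)$. It is a transparent stand-in;
recorded calls can be replayed where published output matters. Reliability
gating follows the median-conservation convention: per-column information
content $R = \log_2 20 - H$ (range 0 to $\log_2 20 \approx 4.32$ bits),
alignment median inside $[2.75, 3.25]$ bits required for an informative
call. The lower-median convention (for even column counts, the lower of
the two middle order statistics) keeps the median an observed value and
the gate deterministic. Gaps are excluded from profiles and from GV/GD
boxes; an all-gap column is a hard error, and columns with fewer than
`min_column_residues` (default 3) residues are not informative.

Grantham distances use the published composition/polarity/volume
constants ($\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$,
$\rho = 50.723$); the implementation returns unrounded values (the
familiar integer table rounds them: L–I = 5, R–K = 26). GV is the
Grantham-style metric applied to the component ranges observed in a
column; GD is the distance from the variant to the nearest point of that
component box, hence 0 whenever the variant residue is observed.

The A-GVGD decision grid is configuration data, not code: GD cutoffs
{15, 25, 35, 45, 55, 65} for C15–C65, with GV attenuation (effective GD
reduced by the GV excess over 61.3) and a hard C0 above GV 122.4. The
published classifier's exact numeric boundaries are not restated in the
transcribed annotation we reproduce, so the default grid is chosen to
match its documented qualitative behaviour — invariant position with
GD ≥ 65 is C65, a highly varied position is C0, and the class is monotone
in GD and antitone in GV — and can be replaced wholesale through
`pipeline_config()`. Fixture classes are always replayed, never
recomputed, so this choice only affects synthetic analyses.

The harmonizer maps two callers onto one label: both damaging-side ⇒
`damaging`; both benign-side ⇒ `benign`; split ⇒ `likely_damaging`; any
missing input ⇒ `not_informative`. Both damaging-side grades of the
second caller ("probably" and "possibly" damaging) are treated
identically — the harmonization convention we reproduce draws no finer
distinction. A structure-based second caller is out of scope; the second
slot takes recorded calls or, for generated data only, a clearly labelled
proxy that grades GD ≥ 65 as probably damaging.

## Reporting conventions

Percentages are reported at full precision alongside a printed-precision
column rounded **half-up** (not half-to-even) at `percent_decimals`
(default 2), matching how variant reports conventionally print 13.0890 as
13.09. A variant's stratum is decided by its abolished sites: any
abolished biologically characterized site places it in the characterized
stratum, otherwise it is uncharacterized (creating-only variants are
uncharacterized unless created at a characterized position, which cannot
occur by construction). Report writers sort internally by protein,
position and alternate residue, so output is byte-deterministic and
independent of input row order.

## What the synthetic generator emulates

The generator targets the pipeline's statistical assumptions, not
biological realism: uniform background composition (0.05 per residue, for
analytic tractability of expected scores — real proteomes are not
uniform), kinase models with a single informative non-anchor offset, and
i.i.d. alignment columns. With sharpness 0.9 an informative-offset match
is worth $\log_2(0.9/0.05) \approx 4.17$ bits and a mismatch
$\log_2((0.1/19)/0.05) \approx -3.25$, so a perfect two-offset motif
scores 8.34 bits and a single substitution drops it to 0.92 — across the
default threshold of 5. This geometry is what makes one-substitution
abolition, creation and rescue all representable; a model with two or
more informative non-anchor offsets at this sharpness could not be
abolished by any single substitution.

Planted scenarios are verified, not assumed: generation resamples the
background (cap 1000 attempts, then an error) until every planted site
binds exactly its model and no other S/T/Y position scores reliably, and
every generated variant is re-checked against the live engine before it
is returned. Rescue uses a shift-by-one support (the informative
consensus residues repeated one position downstream); creation uses
latent slots — consensus context with a non-acceptor centre planted 8
residues from a site, inside the selection radius but outside the scoring
window. Neutral controls come in two kinds: substitutions at
uninformative offsets (provably zero score change, since uninformative
matrix rows equal the background) and substitutions beyond the selection
radius of every site. All generators are pure functions of (parameters,
seed), with per-generator sub-streams fanned out from one global seed.

Consequently, passing the recovery benchmark shows the pipeline is exact
on data satisfying its assumptions; it does not show robustness to
compositional bias, overlapping motifs, correlated alignment columns or
miscalibrated thresholds on real data.

MSA generation holds each column at the reference residue with
probability $c$, else uniform over the 19 alternatives; expected column
information is the closed form
$R(c) = \log_2 20 + c \log_2 c + (1-c)\log_2\frac{1-c}{19}$, inverted by
bisection to hit the 3.00-bit centre of the reliability window
($c \approx 0.839$).

## Problem sizes and numerical choices

The test suite and acceptance script use a 300-residue protein with 20
planted sites and 20 variants per truth label (80 variants), 200-row
alignments for conservation checks, and 50–60 randomized model/window
pairs for the scoring oracle — sizes chosen so the full pipeline
benchmark completes in seconds while exercising every code path.
Floating-point comparisons in tests use absolute tolerances of 1e-9
(scoring, Grantham) or 1e-12 (analytic identities). Ties in `scan_site`
break by kinase name; verdicts sort by (protein, position, alt); the
tolerance cutoff is applied strictly (<), the score threshold and
abolition fraction inclusively (≥). Degenerate inputs fail loudly:
all-gap columns, single-row alignments, out-of-range positions,
reference mismatches (downgradable to warnings with `lenient = TRUE` for
fragmentary sequences), infeasible packings.

## Known limitations

* The PSSM engine is an interpretable stand-in for network-context
  predictors; its score scale is bits and the threshold of 5 is a
  configurable convention on that scale, not a calibrated probability.
* No quantitative binding affinity, no multi-variant (cis) haplotypes, no
  phosphosite cross-talk, no structural features, and no homolog search —
  alignments are inputs.
* Replay fixtures reproduce recorded decisions; they cannot answer
  counterfactual queries (e.g. a different threshold) at recorded sites.
* The A-GVGD grid defaults approximate the published classifier's
  behaviour; analyses hinging on exact class boundaries should supply the
  published grid explicitly.
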