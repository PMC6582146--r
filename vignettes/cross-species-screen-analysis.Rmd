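---
title: "Cross-species siRNA screen analysis: methods and design choices"
author: "crossScreen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species siRNA screen analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossScreen)
```

# The problem

Whole-genome RNA-interference screens knock down one gene per well and read
out a phenotype — here, total intracellular fluorescence of a secreted-GFP
reporter (a proxy for specific productivity) and luminescence after a
cell-viability assay (a proxy for viable cell number) in suspension CHO
cells. When no species-specific siRNA library exists, a library designed
against a related species (mouse) can be applied cross-species, but then
each siRNA must be checked against the host transcriptomes: only siRNAs
whose guide strand still finds a target (allowing a single mismatch) can be
interpreted. This package implements that analysis chain:

1. **Plate normalization** — divide each sample well by the median of the
   negative-control (non-targeting siRNA) wells of its own plate,
   channel-wise, removing multiplicative plate effects.
2. **Common-seed off-target correction** — remove the systematic shift
   shared by all siRNAs with the same seed (guide positions 2–7).
3. **Cross-species target mapping** — find every transcript window that is
   reverse-complementary to a guide with at most one mismatch, associate
   transcripts to genes, and group genes across transcriptomes by identical
   targeting siRNA sets.
4. **Hit calling** — rank genes by median corrected fluorescence, re-screen
   candidates with independent siRNAs in triplicate, and select genes whose
   secondary median exceeds the primary median plus three times the median
   absolute deviation (MAD).
5. **Batch-culture characterization** — growth rate, cumulative cell days,
   specific productivity and 2^−ΔΔCt knockdown quantification for
   validation cultures.

A synthetic-data generator with known ground truth accompanies every stage,
so the whole pipeline has planted-truth recovery tests.

# Models and rules

## Per-plate normalization

For each plate and channel, the normalized value of well $w$ is
$x_w = \mathrm{raw}_w / \mathrm{median}(\text{negative controls})$. The
median of the normalized negative controls is exactly 1 per plate; a
missing or non-positive control median is an error, never silently
imputed. Missing sample wells yield no measurement. Even-count medians are
the mean of the two central order statistics throughout the package. The
negative-control column also supplies the edge-well diagnostic: per row
position, the median and standard deviation of the normalized control
signal across all plates of a screen.

## Seed-based correction

All primary-screen siRNAs (before any mapping filter — off-target effects
do not require a valid on-target site) are grouped by their 6-nt seed. With
overall screen median $m$ and seed-group median $g_s$, the factor is
$f_s = g_s - m$ per channel. For a measurement $x$ with effect
$d = x - m$:

* same direction and larger ($\mathrm{sign}(d) = \mathrm{sign}(f_s)$,
  $|d| > |f_s|$): corrected to $x - f_s$;
* same direction and not larger: set to $m$;
* opposite direction (or $f_s = 0$, or $d = 0$): unchanged.

Two boundary conventions were open and are fixed as follows: "direction" is
measured relative to the overall median $m$ (the only reading consistent
with the set-to-the-overall-median branch), and the boundary case
$|d| = |f_s|$ falls into the set-to-median branch, which makes the rule
idempotent there. Corrected values therefore never cross $m$ and never move
away from it (shrinkage). Factors are fitted on the primary screen only;
secondary-screen seeds never seen in the primary screen get factor 0 with a
warning. Both conventions are enforced by property tests against an
independent enumeration of the rule.

## Target mapping

The library sequence is treated as the guide (antisense) strand; a target
site is a transcript sense-strand window whose reverse complement equals
the guide up to a Hamming distance of 1 (substitutions only, no indels —
end-to-end, bowtie `-v 1`-style semantics). Same-strand occurrences are
not hits. `N` counts as a mismatch at its position. Coordinates are
0-based window offsets on the transcript sense strand; the mismatch
position is reported 1-based in guide coordinates.

`matchSirna` is a direct windowed Hamming scan. `mapLibrary` locates
candidates by exact matching of the two pattern halves (with at most one
substitution, at least one half is intact — a pigeonhole argument) using
`Biostrings::PDict` over the concatenated transcripts, then verifies every
candidate base-by-base under the same N rule. Both routes are tested for
exact equality with a brute-force oracle over an exhaustive small grid.

Genes across transcriptomes targeted by *identical* siRNA sets are merged
into one distinguishable gene group (exact set equality, not overlap), and
per-group medians of corrected fluorescence/luminescence are the gene
scores. An siRNA targeting several groups contributes to all of them.

The mismatch-tolerance validation restricts a control gene set (in the
study design: proteasome-associated genes, whose knockdown lowers
viability) to genes targeted by at least one perfect-match and one
1-mismatch siRNA, and correlates the per-gene median luminescence of the
two classes; fewer than three qualifying genes withholds the coefficient.

## Hit calling

The threshold is `median(primary per-gene medians) + 3 * MAD`. The MAD
constant defaults to 1.4826 (normal consistency, the default of R's
`mad()`), with 1.0 supported and both thresholds printed in the `HitCall`
summary, since screening practice varies. Selection is strictly "higher
than" the threshold; values equal to the threshold up to a relative
tolerance of 1e-9 count as ties, not hits. This tolerance matters only in
the degenerate noiseless limit where the MAD is exactly 0 and secondary
values coincide with the threshold up to floating-point rounding; at any
realistic noise level it is far below measurement uncertainty. The
reference distribution uses genes with valid (mapped) siRNAs, i.e. the set
analyzed downstream.

## Culture metrics

With viable cell diameter $d$ (µm), the per-cell volume is
$\frac{4}{3}\pi (d/2)^3$ (perfect-sphere assumption), and the viable cell
volume is $\mathrm{VCV} = \text{volume per cell} \cdot 10^{-9} \cdot
\mathrm{VCD}$ (mm³/ml). Cumulative cell days use the log-mean interval
term

$$\mathrm{CCD} = \sum_i \frac{(V_{i+1} - V_i)(t_{i+1} - t_i)}
{(\ln V_{i+1} - \ln V_i) \cdot 24},$$

with $t$ in hours post transfection. The degenerate interval
$V_{i+1} = V_i$ uses the continuous limit $V_i \Delta t / 24$ (continuity
of the log-mean). On an exact exponential the sum equals the analytic
integral $(V(t)-V_0)/(24\mu)$ to machine precision, which is a frozen
test.

Growth rates: Pearson correlations between $\ln$ VCD (or VCV) and time are
computed for windows starting at the first analyzed time point and
containing at least 4 points; the window end with the highest coefficient
defines TPXY, and the growth rate is the OLS slope over TP01..TPXY.
Specific productivity uses the same machinery on (CCD, titer) windows
starting at the second measurement with at least 5 points, with the slope
fitted over TP01..TPXY; with titer in µg/ml and CCD in cells·days/ml the
slope is scaled by 10⁶ to pg/(cell·day) (10⁻³ to mg/(cm³·day) for the
volume-based variant — the regression is titer-on-CCD, the orientation
implied by those units). When arms are compared, every slope is refit on
the common interval ending at the minimum TPXY over the arms.

**Tie-break**: correlation coefficients are compared at a tolerance of
1e-10 and exact ties go to the *latest* eligible window end. In the
noiseless limit every all-exponential window has $r = 1$, so the latest
tie uses all collinear points; an earliest-tie rule would always stop at
the 4-point minimum window and would contradict the recovery behaviour the
package guarantees (TPXY at the last point of a pure exponential, and at
the breakpoint of an exponential-then-plateau series). On noisy data exact
ties do not occur and the rule is inert.

**Replicate anchoring**: replicates are "combined and corrected based on"
an anchor measurement — read here as seeding-density correction: each
replicate is rescaled by (reference anchor / its own anchor), with the
first VCD measurement anchoring growth quantities and the second-timepoint
CCD anchoring productivity (the first CCD value is identically 0), then
averaged pointwise on the first replicate's time grid (nearest-point
matching within a 2 h default tolerance). The alternative reading — reusing
the siRNA seed-sequence factors on culture data — is not meaningful for
mixed-siRNA transfections and is not implemented.

Knockdown efficiency is quantified with the 2^−ΔΔCt method against a
reference gene (Gapdh in the study design) and a mock calibrator;
per-timepoint arm-versus-mock comparisons use one-way ANOVA with Dunnett's
post hoc test (via `multcomp`), skipping arms with fewer than two
replicates.

# The synthetic generator

`synthConfig()` fixes the reference synthetic study; `generateLibrary()`,
`generateTranscriptomes()`, `generatePlates()`, `generateCulture()` and
`generateSecondaryLibrary()` are deterministic given `rng_seed` (each stage
derives its own sub-seed, so regenerating one stage never perturbs
another).

What it emulates, and the chosen defaults:

* **Library**: 500 genes × 3 siRNAs (desk-scale stand-in for a ~50k-siRNA
  whole-genome library), 21-nt RNA-alphabet guides whose positions 2–7
  carry one of 25 seeds, giving ~60 members per seed group — enough for
  stable group medians. Guides are globally unique; an infeasible request
  (alphabet too small) fails explicitly.
* **Mapping classes**: exact proportions 0.4 / 0.3 / 0.3 of siRNAs with a
  planted perfect target, a planted 1-mismatch target, or no target. Class
  labels are swapped between genes (preserving the exact global counts) so
  that planted hit genes have only mapped siRNAs and planted lethal genes
  carry both mismatch classes — otherwise hit recovery and the
  mismatch-tolerance validation would be vacuous by construction.
* **Transcriptomes**: two sets of i.i.d.-uniform 1500-nt background
  transcripts; each gene is carried by each transcriptome with probability
  0.8 (at least one), so gene grouping across transcriptomes is exercised.
  Planted windows are embedded in sense orientation; same-strand copies
  and 2-mismatch windows are planted as decoys that must never be hits.
  Hits are verified against ground truth by position, not by count.
* **Plates**: 16 × 24 layout, samples in columns 1–22, negative controls in
  column 23, positive (cell-death) controls in column 24. Signal =
  plate factor × gene effect × seed effect × lognormal noise; the
  lognormal plate factor (σ = 0.1) multiplies all wells including
  controls, so per-plate normalization is necessary and sufficient. Seed
  effects are lognormal with σ = 0.15 per family and channel; hit genes
  multiply fluorescence by 2.0; lethal genes multiply both channels by a
  per-gene lognormal effect centred at 0.3; well noise is lognormal with
  σ = 0.05. On-target effects apply only to siRNAs whose planted class has
  a target; seed-driven off-target shifts apply to every siRNA.
* **Cultures**: exponential growth at 0.03/h from 3×10⁵ cells/ml to a
  10⁷ cells/ml plateau, then a slow decline (0.005/h); constant 15 µm
  diameter; titer = q_P × CCD with q_P = 20 pg/(cell·day), computed with
  the same log-mean integral as the analysis so the planted parameters are
  exactly recoverable at zero noise; daily sampling for 9 days, two
  replicates per arm, 5% lognormal measurement noise.

What it does **not** emulate: realistic transcript structure (UTRs,
splicing, shared exons), sequence-composition bias, well-to-well
cross-talk, spatial plate gradients beyond the multiplicative factor,
transfection-efficiency variation, or death-phase kinetics beyond a simple
exponential decline. Passing recovery tests therefore demonstrates the
correctness of the computations under the stated generative model, not the
biological sensitivity of the screen on real data.

# Numerical choices and degenerate inputs

* Medians: even counts use the mean of the central order statistics.
* Seed correction at the boundary `|d| == |f|`: set to the overall median;
  at `d == 0`: unchanged.
* Hit selection at the threshold: strictly greater, with ties defined at
  relative 1e-9 (see above).
* CCD with `V_{i+1} == V_i`: log-mean limit `V dt / 24`; non-positive VCD
  or non-increasing time is an error.
* Window search: candidate ends are existing sampling points only; r
  compared at 1e-10, ties to the latest end; zero abscissa variance is an
  error, zero ordinate variance yields r = 0 (slope 0 follows).
* Replicate anchors must be positive; single replicates are returned
  unchanged with a warning.
* Unknown seeds at correction time: factor 0 with a warning; unknown
  transcripts at association time: orphan report, not an error.

# Problem sizes

The test suite and the acceptance script run the reference study at desk
scale — 500 genes (1500 siRNAs, five 384-well plates), two transcriptomes
of roughly 400 transcripts each, and 10-point culture series — which keeps
a full pipeline run under ten seconds while every stage still has
non-trivial structure (multi-plate normalization, ~60-member seed groups,
cross-transcriptome gene groups, triplicate secondary screening).
Integration tests use a 60-gene configuration. The matcher and the
correction rule are additionally verified exhaustively on small grids
(transcripts up to 60 nt, guides 15–25 nt; 10⁵ random correction triples).

# Known limitations

* `mapLibrary` supports at most one mismatch (the pipeline's contract);
  `matchSirna` accepts any bound and is the reference for sensitivity
  experiments.
* Gene grouping uses exact set equality; genes sharing most but not all
  siRNAs stay distinct groups, as in the study design.
* The hit threshold assumes the primary per-gene medians form a sensible
  reference distribution; with very few genes the MAD is unstable.
* Lethality (low-luminescence) hit calling, B-score/loess spatial
  correction and FDR-based selection are out of scope.
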