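---
title: "Methods: differential HDX-MS significance analysis and one-site binding thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential HDX-MS significance analysis and one-site binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxbind)
```

# What the package models

`hdxbind` analyzes pairwise hydrogen/deuterium-exchange mass-spectrometry
(HDX-MS) comparability experiments: the same protein measured in two
states (for example a membrane transporter free in solution versus
trapped in one conformation by a conformation-selective nanobody), each
labeled in D2O for a ladder of times and digested into overlapping
peptides whose centroid mass increase reports deuterium uptake in Da.
The scientific question is *where* the two states exchange differently,
and in which direction: less uptake in the bound state is protection
(reduced solvent accessibility or hydrogen-bond opening), more uptake is
deprotection.

The companion module implements the one-site independent-binding model
for isothermal titration calorimetry (ITC), used to quantify how a
binder shifts ligand affinities, summarized as a signed fold of affinity
change between dissociation constants.

# The hybrid significance criterion

For each peptide $j$, state $s$ and labeling time $t$, replicate uptake
values $D_{jst1},\dots,D_{jstn}$ give a cell mean $\bar D_{jst}$ and a
sample standard deviation $s_{jst}$ ($n-1$ denominator). The
differential uptake is

$$\Delta D_{jt} = \bar D_{j,\text{bound},t} - \bar D_{j,\text{free},t},$$

so protection is negative. A cell is called significant only when it
passes **two** criteria jointly:

1. **Global magnitude threshold.** Replicate standard deviations are
   pooled over every cell of both states with degrees-of-freedom
   weighting,
   $s_p = \sqrt{\sum_c (n_c-1) s_c^2 \big/ \sum_c (n_c-1)}$, and the
   two-sided critical difference of two replicate means is
   $$T = t_{1-\alpha/2,\,\nu}\; s_p \sqrt{1/n_\text{free} + 1/n_\text{bound}},$$
   with $\nu = \sum_c (n_c - 1)$. The cell must satisfy
   $|\Delta D_{jt}| \ge T$.
2. **Welch's t-test.** The per-cell unequal-variance t-test
   (Satterthwaite degrees of freedom) must give $p \le \alpha_t$.

The conjunction is deliberately conservative: the global threshold
filters differences that are small relative to the platform's replicate
noise even when a lucky variance estimate makes them nominally
"significant", and the per-cell test protects against single noisy
cells. Pooling is global — across peptides, timepoints and states —
because replicate noise in automated HDX platforms is dominated by
instrument and handling variation, not by the peptide identity; this is
also the established convention for hybrid-criterion testing.

Both levels are separately configurable (`alpha_global`, `alpha_ttest`,
both default 0.05; the stricter $p<0.01$ convention is available by
argument) and a manual threshold override is accepted so a published
threshold (for example 0.3184 Da or 0.3071 Da, two values that circulate
for the same experiment) can be replayed on any data set. We chose
defaults matching the criterion actually used for headline residue
mapping in this type of study; nothing is hard-coded as truth.

# From peptides to residues

Peptide-level flags are mapped to residues through the overlap
structure of the peptide map. A residue receives status only from
peptides that observe its backbone amide — positions
$\text{start}+1,\dots,\text{end}$ of each peptide, excluding prolines
(no amide hydrogen) and each peptide's first residue (too-fast
back-exchange). Three consensus rules are provided:

* `any` (default): one significant covering peptide suffices. This
  union-style rule matches how significant-position counts are
  typically derived from sets of overlapping significant peptides.
* `majority`: more than half of the covering peptides must be
  significant.
* `all`: every covering peptide must be significant.

Direction conflicts at a residue (protected and deprotected
contributors) are rare in protection-dominant data sets; they are
resolved toward protection and reported via a message. Residues with
contributors but no qualifying significance are `insignificant`;
residues never observed by any amide are `uncovered`. Counts over the
four statuses always sum to the protein length.

Annotation onto structure models writes a per-residue value (mean
differential uptake of covering peptides, or a status code) into the
B-factor column of a PDB file; structure residue numbers are matched
against display numbering (internal position plus a configurable
offset, e.g. $-1$ when the initiator methionine is processed), and
unmatched residues receive the sentinel $-99$.

# Dynamic groups and fast exchangers

Peptides are classified on their D% curves — uptake as percent of the
theoretic maximum $N_\text{max} = L - 1 - \#\{\text{internal Pro}\}$ —
in both states plus their significance flags. The four groups are
narrative categories in the experimental literature; we made them
operational with explicit cutoffs, all configurable
(`classification_params()`):

* **III** — high exchangers: both states $\ge$ 60% D% already at the
  first timepoint (disordered tails).
* **IV** — medium-level free-state uptake (40–50% band) at all times
  with significant deprotection somewhere (allosterically loosened
  patches).
* **I** — significant protection at every timepoint with the bound
  state pinned at $\le$ 10% D% (binding fully suppresses exchange).
* **II** — significant protection at $\ge 1$ timepoint with strictly
  rising free-state uptake (dynamic regions partially shielded).

Precedence is III, IV, I, II: the absolute-uptake bands are more
specific than the protection-based definitions, so they are tested
first. Boundary comparisons for the fast-exchanger flag — free-state D%
strictly above 5% at the first timepoint — are strict, a deliberate
tie-break so that "exactly at the cutoff" is not flagged. Whether group
I should require significance at *every* timepoint is genuinely
ambiguous in qualitative descriptions ("complete inhibition" versus a
per-timepoint test); we require every timepoint and expose the bound
ceiling as a parameter rather than resolving the ambiguity silently.

# The synthetic-data generator

Because raw spectra and thermograms of such studies are rarely
deposited, the package ships a forward simulator that generates the
*statistical* structure the analysis assumes, so that every downstream
stage is testable without downloads:

* **EX2 kinetics.** Each residue exchanges at
  $k_\text{obs} = k_\text{int}/\mathrm{PF}$ and its deuterated fraction
  is $1 - e^{-k_\text{obs} t}$. EX1 behavior is not modeled — the
  analysis is centroid-level, where EX2 is the standard operating
  assumption.
* **Sampled intrinsic rates.** $\log_{10} k_\text{int}$ is uniform in
  $[-3, 0]$ and $\log_{10}\mathrm{PF}$ uniform in $[0.5, 3]$ per
  residue, rather than computed from the sequence-based intrinsic-rate
  model; no back-exchange correction is applied anywhere in the
  analysis, so sampled rates are sufficient to exercise the inference
  machinery. D% consequently plateaus near $100 \times$ the labeling
  D2O fraction (default 0.9, a tenfold dilution into labeling buffer) —
  matching real uptake plots that never reach 100%.
* **Two states.** The bound state adds $+1.5\ \log_{10}\mathrm{PF}$
  units on one contiguous footprint (default 15% of residues) and
  removes protection on a 3-residue patch right after the N-terminus,
  mirroring the protection-dominant pattern with slight N-terminal
  deprotection seen when a conformation-selective binder clamps a
  transporter.
* **Digestion.** Contiguous gap blocks totalling 14% of the construct
  are excluded (real maps have uncovered loops), each remaining segment
  is tiled end-to-end with abutting peptides of random length 5–15, and
  random overlapping peptides are added until the redundancy target
  (default 2.9) is met. This reproduces the design statistics of a
  typical nonspecific-digestion pool: ~86% coverage, mean peptide
  length near 9–10, redundancy near 2.9 — about 150 peptides on a
  600-residue construct.
* **Replicate noise.** Homoscedastic Gaussian noise (default sd 0.13
  Da) on peptide uptake, truncated to the physical range
  $[0, \text{d2o} \times N_\text{max}]$ — homoscedasticity matches the
  pooled-SD assumption of the hybrid test.

What the simulator does **not** emulate: isotope envelopes and spectral
curation, peptide-dependent noise, back-exchange gradients along the
LC run, carry-over, or EX1 bimodality. Tests passing on synthetic data
therefore validate the statistical machinery, not the mass-spectrometry
preprocessing upstream of it.

All generation is seeded; a fixed seed reproduces systems, maps and
tables bit-for-bit.

# The one-site ITC model

For injections $i = 1,\dots,m$ of titrant at syringe concentration
$X_s$ into an overflow cell of volume $V_0$ holding titrand at $M_0$,
with cumulative injected-volume fraction $v_i$, the dilution-corrected
totals are

$$[M]_i = M_0\,\frac{1 - v_i/2}{1 + v_i/2}, \qquad
  [X]_i = X_s\,\frac{v_i}{1 + v_i/2},$$

the bound fraction $\Theta_i$ solves the single-site quadratic, the
cumulative heat is $Q_i = N \Theta_i [M]_i V_0 \Delta H$, and the
per-injection heat uses the trapezoidal displaced-volume correction

$$q_i = Q_i - Q_{i-1} + \frac{\mathrm{d}V_i}{V_0}\,
        \frac{Q_i + Q_{i-1}}{2}.$$

These are the standard overflow-cell equations; instrument vendors use
closely related but proprietary variants, so fits of real exported
thermograms can differ in the third significant figure. The heat of
dilution is estimated as the mean of the last few injections (default
3), past saturation, and subtracted. Heats may be declared
exothermic-positive (releases plotted as positive peaks) or
exothermic-negative; fits are invariant to the declared convention.

Fitting minimizes squared residuals of per-injection heats normalized
per mole of injectant, with $N$ fixed to 1 by default (the usual choice
when the titrand concentration is accurately known). Because the
isotherm's least-squares surface has local minima in $K_a$, the
Levenberg–Marquardt optimizer is restarted from a log-spaced grid of
eight $K_a$ values spanning $K_d$ 1 nM–10 mM and the lowest-RSS solution
is kept; every reported fit satisfies $K_a K_d = 1$ exactly. A c-value
($N K_a M_0$) outside $[0.1, 1000]$ triggers a warning because the
isotherm shape then constrains $K_a$ only weakly. An all-zero
thermogram is rejected rather than "fit".

Affinity comparisons report the **signed fold of affinity change**
between a reference and a modulated condition:
$-(K_d^\text{mod}/K_d^\text{ref})$ when affinity decreases,
$+(K_d^\text{ref}/K_d^\text{mod})$ when it increases, rounded to two
decimals to match how binding tables print it; replicate $K_d$ sets are
compared with an unpaired two-sided Student's t-test.

# Numerical choices and degenerate inputs

* Sample standard deviations use the $n-1$ denominator throughout;
  cells with one replicate are excluded (with a warning), as are
  peptide/timepoint cells present in only one state.
* Welch's test with zero variance in both groups returns $t=0, p=1$ for
  equal means and $p=0$ otherwise, instead of erroring mid-pipeline.
* Peptides with $N_\text{max}=0$ (e.g. an X–Pro dipeptide) have
  undefined D% (reported `NA`) and are never classified or flagged.
* Replicate-mean thresholds use the *average* replicate count per state
  rounded to an integer, which is exact for balanced designs.
* Uptake CSVs are printed at 4 decimals and p-values at 3 significant
  digits so repeated runs are byte-identical and diffable; the pipeline
  summary embeds the seed and an MD5 hash of the serialized
  configuration.

# Problem sizes used in the validation suite

The test suite validates the statistical properties at the scale of the
emulated study design: a 600-residue construct digested into ~150
peptides for the type-I-error study (200 null replications of the full
two-state experiment, triplicates, 0.13 Da noise), a 400-residue
construct for footprint recovery, 50 noisy refits for ITC parameter
recovery, and 1000-instance brute-force cross-checks for the Welch test
and the consensus mapping. These sizes were chosen to give stable
Monte-Carlo estimates for the properties asserted while keeping the
suite quick to run routinely.

# Known limitations

* Residue-level *rate* deconvolution (fitting per-residue protection
  factors from overlapping-peptide uptake) is out of scope; the
  consensus mapping propagates significance, not rates.
* No multiple-testing correction beyond the hybrid conjunction is
  applied — by design, since the hybrid criterion is itself the
  accepted guard in differential HDX practice.
* The redundancy definition (sum of peptide lengths over covered
  residues) is the common HDX-software convention, but published
  coverage tables do not always state theirs; small discrepancies
  against published redundancy values are expected.
* The ITC module fits a single independent site; binding polynomials,
  competitive displacement and multi-temperature $\Delta C_p$ analyses
  are not implemented.
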