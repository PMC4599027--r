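---
title: "Scoring exceptional residues and analysing catalytic-pocket geometry with residex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring exceptional residues and analysing catalytic-pocket geometry with residex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residex)
```

# Overview

When a protein has drifted so far from its family that BLAST-style sequence
similarity is uninformative, its identity and functional innovations have to
be argued from more robust signals: profile-HMM hits, structural alignment,
and the behaviour of individual residues against the family background.
`residex` packages the computational core of that workflow: an entropy-based
per-residue *exceptionality* score on a multiple alignment, E-value panel
classification, and the geometry analytics used to interrogate a modelled
catalytic pocket over a molecular-dynamics trajectory. A seeded
synthetic-data module generates inputs with known ground truth for every
stage, which is how the package tests itself.

# The exceptionality model

## Categories, entropy, score

Residues are reduced to six physicochemical categories (aliphatic
`AVLIMC`, aromatic `FWYH`, polar `STNQ`, positive `KR`, negative `DE`,
special `GP`; see `amino_acid_categories()`). The model treats a residue's
category, not its identity, as the evolutionarily meaningful unit: a column
that freely exchanges A, V and L is *conserved* at the category level, and
the score is invariant under replacing any homolog residue by another of
the same category (this "category sufficiency" is tested as a property).

For alignment column $l$, let $P_i(l)$ be the proportion of homolog
residues in category $i$, counted over non-gap, non-ambiguous residues
only. The column's diversity is the category entropy

$$ s(l) = -\sum_{i=1}^{6} P_i(l)\, \log P_i(l), $$

ignoring null categories. The query residue's exceptionality is

$$ S(l) = \frac{P_{\max}(l) - P_i(l)}{s(l)}, $$

where $P_i(l)$ is now the proportion of the *query's* category and
$P_{\max}(l)$ that of the most abundant category — the category one would
have expected. Large $S$ means an unexpected residue at an otherwise
well-behaved position.

## Conventions the formula does not fix

Several choices are open in the formula as stated; the package resolves
them as follows and exposes the ones worth varying.

* **Log base.** Natural log. The base cancels from every ranking because it
  rescales all finite scores by the same constant; the `base` argument
  exists so this invariance can be (and is) tested, e.g. with `base = 2`.
* **Query exclusion.** The homolog proportions exclude the query row, so a
  deviant query cannot dilute its own background. `include_query = TRUE`
  is available as a sensitivity check; with 23 homologs the difference is
  at most one count in the denominator. $P_{\max}$ is taken over the same
  homolog-only proportions as $P_i$.
* **Gap rule.** A column holding more than 50 % gaps (strict, measured over
  the same non-query rows used for the proportions) is *masked*: its
  entropy is reported as 0 and its score as missing. Dividing by that
  conventional 0 would manufacture infinities out of columns that merely
  lack data, so masked columns never enter rankings except at the bottom.
* **Zero entropy with a deviant query.** When every homolog agrees on one
  category and the query deviates, the numerator is positive and $s = 0$.
  The score is flagged `infinite` rather than clamped to a numeric
  sentinel, and infinite scores rank above all finite ones: a deviation at
  a perfectly conserved position is the strongest possible signal.
* **Hidden insertions.** Columns where the query has a gap are removed
  before scoring (`mask_query_insertions()`), so scores are indexed by
  1-based position along the ungapped query, matching residue numbering
  conventions such as `Y161`.
* **Ambiguity codes.** `X/B/Z/U/O` count as residues for gap fractions but
  belong to no category: they drop out of the proportions, and a query
  ambiguity code has $P_i = 0$.

Ranking (`rank_exceptional()`) orders infinite scores first, then finite
scores descending, ties broken by ascending position — a deterministic
order so that repeated runs agree.

# Alignment filtering

Phylogenetic-grade column filtering (`filter_columns()`) keeps a column iff
its gap fraction is *strictly below* 0.30 and its conservation score
*strictly above* 8. Both boundaries are deliberately strict: a column at
exactly 30 % gaps or score exactly 8 is removed, and the tests pin this
down on constructed alignments. The conservation score itself (0–10) is
taken verbatim from a per-column Stockholm annotation when one is present —
any `#=GC` tag whose name contains `cons`, digits `0`–`9`, with `*` read
as 10 — because an explicit annotation from the alignment producer is
better information than anything recomputable from the letters. Without an
annotation the package falls back to `floor(10 * p)` where `p` is the modal
non-gap residue's proportion among non-gap entries; ambiguity codes can
inflate the denominator but never be the mode. Filtering is idempotent and
the kept/removed sets always partition the original columns (both tested as
properties).

FASTA and Stockholm dialects are read and written; `.` gaps are normalised
to `-` on input, and Stockholm `#=GC` lines round-trip.

# E-value panel classification

`assign_family()` implements the argmin rule: the best family is the one
with the smallest present E-value, the call is *assigned* only when that
E-value is significant, and the best-vs-runner-up separation is summarised
as `round(log10(second/best))` orders of magnitude. Three conventions are
worth stating:

* the significance boundary is **inclusive** ($E \le \alpha$, default
  $\alpha = 0.05$), i.e. "greater than 0.05" is what disqualifies a hit;
* ties for best are broken by family list order and reported in the call;
* the separation is rounded to the nearest integer magnitude, so a ratio of
  $6.7 \times 10^{6}$ reports as $10^{7}$ — an order-of-magnitude summary,
  not a precise ratio.

The bundled fixture `inst/extdata/evalues_rnl2.tsv` is a small RNA/DNA
ligase panel (7 families × 4 proteins with 8 missing cells) used by the
tests and the acceptance script; on its query column the rule yields
PF09414 at $4.9 \times 10^{-12}$ with a $10^7$ separation over the
ATP-dependent DNA ligase model.

# Pocket geometry

All internal coordinates are Angstrom; the restraint machinery speaks nm
(the unit in which such restraints are conventionally specified) and every
field name carries its unit (`r0_nm`, `distance_cutoff` in Å) because
mixed-unit bugs are the dominant failure mode in this kind of code.

* **Superposition.** `kabsch_superpose()` is the SVD solution with the
  determinant correction that guarantees a proper rotation (no
  reflections). Collinear point sets are rejected rather than silently
  fitted. RMSD is symmetric in its arguments and invariant to rigid
  transforms of either input to well below 1e-9 Å; an exhaustive
  rotation-vector grid search serves as the independent oracle in the
  tests, and `bio3d::fit.xyz` as a second cross-check.
* **RMSD series / RMSF.** `rmsd_series()` superposes each frame's selection
  (default α-carbons) onto a reference frame. `rmsf()` superposes onto the
  *mean* structure, refined over two passes (fit to frame 1, re-fit to the
  resulting mean, and once more) — the reference choice is not canonical in
  the literature, and the two-pass mean is a stable, order-independent
  one. A static trajectory gives identically zero for both.
* **Hydrogen bonds.** Donors and acceptors are N and O heavy atoms — a
  purely element-based rule, with no residue-specific chemistry tables.
  A hydrogen belongs to the nearest N/O within 1.2 Å. The default criteria
  are a 3.0 Å donor–acceptor distance cutoff and a 30° cutoff on the
  deviation of D–H⋯A from linearity (the convention of the common
  trajectory-analysis tools); both are configurable via
  `hbond_criteria()`. Occupancy is per-frame existence of the pair — no
  smoothing windows — expressed as a percentage of frames.
* **π-stacking.** `ring_geometry()` fits the least-squares plane (normal
  canonicalised toward +z, then +y, then +x, so orientations are
  reproducible). `stacking_metrics()` reports per-frame centroid distance
  and acute inter-plane angle; the classification thresholds — stacked
  when distance ≤ 5.0 Å *and* angle ≤ 30° — are the package's own
  constants, chosen from the ranges typical of face-to-face aromatic
  contacts, and are exposed as arguments precisely because they are
  judgment calls. The verdict is `stacked` when at least half the frames
  qualify. One caution on units: angular spreads are reported in degrees;
  summaries of angle series are population SDs in degrees even where
  source material sometimes mislabels them with length units.
* **Flat-bottom restraints.** `restraint_spec(r_i)` derives
  $r_0 = r_i - 0.30$, $r_1 = r_i + 0.30$, $r_2 = r_1 + 1$ (nm). The
  potential is quadratic below $r_0$, zero on $[r_0, r_1]$, quadratic on
  $(r_1, r_2]$, and linear above $r_2$ with slope $k(r_2 - r_1)$ — the
  value and slope match at $r_2$, so the potential is $C^1$ everywhere,
  and the tests verify continuity and differentiability at all three
  breakpoints by finite differences at 1e-6 relative tolerance.
  `restraint_violation_fraction()` counts frames outside the flat bottom
  for a representative atom pair; a production MD code would restrain every
  inter-ring atom pair, but for usage accounting the single-pair summary is
  the quantity of interest.
* **Summary statistics.** `distance_stats()` and the stacking report use
  population SDs (divide by $n$): a trajectory is the full population of
  observed frames, not a sample whose SD needs an unbiasedness correction,
  and the two-frame example (3 Å, 5 Å → SD 1) fixes the convention.

# The synthetic-data module

The generators replace raw study data (genome assemblies, MD trajectories)
with seeded constructions whose ground truth is known *by construction*:

* `gen_alignment()` draws homolog residues per column from a prescribed
  category distribution (uniformly within a category). Defaults emulate a
  structural-neighbour panel: 23 homologs and, per column, a two-category
  mixture with an 0.87 dominant weight — roughly the 20:3 splits seen in
  real structural alignments of a diverged family. The query follows the
  realised modal category except at planted positions. Ground-truth scores
  are computed by straight-line closed-form code inside the generator file,
  deliberately duplicated rather than shared with the scoring module, so
  the two can check each other.
* `gen_evalue_table()` plants a winning family below
  $\alpha/10^m$ and a runner-up exactly $10^m$ (± a 0.8–1.2 jitter, which
  rounding absorbs) above it; all other cells are missing or
  non-significant.
* `gen_trajectory()` realises frame-by-frame schedules exactly: hydrogen
  bonds placed at 2.9 Å/5° (inside the criteria) or 3.5 Å or 45° (outside,
  alternating the two failure modes), idealised 1.4 Å-radius hexagonal
  rings at scheduled centroid distance and tilt, restrained pairs inside
  or outside the flat bottom, and an optional Gaussian distance process.
  Groups are placed 30 Å apart and a 0.8 Å minimum-separation check guards
  against accidental overlaps. Output is multi-model PDB text that
  round-trips through `read_trajectory()`.

Same seed, same output — byte-identical, which the tests assert.

What the generators do **not** emulate: real force-field dynamics, solvent,
correlated motions, non-ideal ring geometries, insertion-rich alignments,
or HMM score distributions. Passing the planted-truth tests therefore
demonstrates that the *computations* are correct, not that the biological
conclusions drawn from any particular real data set would be.

# Test and verification sizes

The suite checks the scoring arithmetic against an exhaustive-counting
oracle on 1,000 random columns of up to 8 rows (agreement to 1e-12),
recovers planted deviants in 100 seeded recipes of 30 columns with 1–3
planted positions each (the planted category is kept out of the column's
mixture so the true score margin over the zero background is at least 0.5),
and exercises trajectories of 50–1,000 frames. These sizes give exact,
fast, deterministic checks; the algorithms themselves have no size limits
beyond memory.

# Limitations

* The exceptionality score is only as good as the input alignment; it has
  no model of alignment uncertainty, and columns mis-aligned by the
  upstream structural aligner will produce confident-looking nonsense.
* The six-category partition is one of several in use; results are
  category-partition-dependent by design.
* Hydrogen-bond detection requires explicit hydrogens and uses element
  rules only — sulfur donors/acceptors and C–H⋯O contacts are out of
  scope.
* Trajectory I/O is limited to multi-model PDB text; binary MD formats
  (XTC/DCD) are out of scope, as are force-field energetics and
  secondary-structure assignment.
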