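---
title: "ProtSphere methods: fuzzy spherical truncation of multi-linear protein descriptors"
author: "ProtSphere authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProtSphere methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtSphere)
```

## The model

ProtSphere descriptors encode a protein's 3D geometry without alignment.
The chain is reduced to one point per residue under one of four
representations (`CA`, `CB`, `AB`, `AVG`), and the resulting point cloud is
embedded in a sphere centred at its arithmetic mean `o`. The spherical
radius `R = max_p d_p` is the distance of the outermost residue; by
construction at least one residue always sits exactly at `d = R`, which is
why the descending Gaussian and Bell functions attain their analytic
minima `exp(-2)` and `1/17` on any structure when the interval is `[0, R]`.

Relationships between two residues (a pairwise dissimilarity
`z_ij`) or three residues (a triple multi-metric `z_ijl`) populate order-1
tensors. Fuzzy spherical truncation replaces each entry `r` by

```
S(r) = r * F(W),    W = { mu_A(d_p) : residue p in the entry's tuple }
```

where `A = [d_on, d_off]` is a sub-interval of `[0, R]` expressed as
fractions `r_on < r_off` of the radius, `mu_A` is one of 16 truncation
functions, and the fusion rule `F` is the arithmetic mean by default
(`MIN` and `MAX` are provided but not used in any shipped default). The
truncated tensor then flows through a **fixed** pipeline:

1. order-1 tensor (metric / multi-metric),
2. spherical truncation (only legal at `k = 1`; enforced by error),
3. topological (`LGP`) and geometric (`LGL`) lag filters,
4. residue-group restriction,
5. `NS`/`SS`/`MP` normalization,
6. Hadamard power `k`.

The order of steps 3–5 is a design choice: filters act on raw coefficients
so that stochastic normalization is computed over the surviving entries.
Re-running the pipeline with a `NONE` truncation is bit-identical to
omitting step 2, a property the test suite asserts with `identical()`.

The per-residue split assigns entry `z` to residue `a` with weight
`m/N` (multiplicity of `a` in the index tuple over tuple size), so the
aa-level tensors partition the total tensor exactly. Consequently the sum
over residues of the bilinear/trilinear forms equals the form of the total
tensor — the additivity the test suite checks to 1e-9 relative. Global
descriptors are aggregations (sum, means, norms, central moments,
quantiles) of the per-residue form values.

## Truncation functions and parameter bindings

All interval parameters are in Angstrom after resolution
(`d_on = R * r_on`, `d_off = R * r_off`); memberships are dimensionless
degrees in `[0, 1]`.

* **S-shaped / Z-shaped** — the standard smooth step and its complement on
  `(a, b) = (d_on, d_off)`. The implementation returns 1 for `x >= b` for
  the S-shaped form (and 0 for the Z), which is the only convention
  consistent with the worked membership `mu(4.06) = 1` on `[0, 4.056]`;
  `Z(x) + S(x) = 1` holds to 1e-12 everywhere.
* **PI-shaped / trapezoidal** — shoulders at `0.45` and `0.55` of
  `(d_on + d_off)`. The PI-shaped function uses the MATLAB `pimf`
  convention (0 outside `[a, d]`, S-rise, plateau, Z-fall): a published
  table variant that returns 1 below `a` would contradict the worked value
  `mu(4.06) = 0`, so the `pimf` convention is used.
* **Triangular** — feet at the interval ends, peak at the midpoint.
* **Sigmoids** — logistic curves centred at the interval midpoint with
  slope `a = -1` (descending) or `+1` (ascending) in absolute reciprocal
  Angstrom. The slope is deliberately *not* scaled by the interval width;
  this is a documented quirk of the convention the package follows, and it
  makes sigmoid sharpness protein-size dependent.
* **Gaussians / generalized Bells** — three (width, centre) bindings each:
  descending (`a = (d_off - d_on)/2`, `c = d_on`), centralized
  (`a = (d_off - d_on)/4`, `c =` midpoint), ascending (`c = d_off`).
  Bell slope exponent is fixed at `b = 2`, giving `1/(1+t^4)`.
* **Shifting1 / Shifting2 / Switching** — the molecular-dynamics smoothing
  forms: `(1-(x/d_off)^2)^2`, `(1-x/d_off)^2`, and the switching form that
  is 1 below `d_on`, `(d_off^2-x^2)^2 (d_off^2+2x^2-3 d_on^2) /
  (d_off^2-d_on^2)^3` inside the interval, 0 beyond. Published summary
  statistics for a switching function with maximum 0.007 are inconsistent
  with any standard switching form (which reaches 1 at `d_on`); the
  package implements the standard form and makes no attempt to reproduce
  that outlier.

Distances slightly above `d_off` are legal inputs: printed worked values
round `R = 4.056` to a residue distance of `4.06`, and erroring there
would make the published example uncomputable. All memberships are clamped
into `[0, 1]` after evaluation to absorb floating-point spill.

Each function is tagged with a regime (`c` centre, `m` middle, `s`
surface). The property test locates the (plateau-averaged) argmax over
`[d_on, d_off]` and asserts it falls in the first, middle or last third.
Averaging over the plateau matters: a plateau whose leading edge sits
below one third of the interval (possible for the trapezoid on narrow
high intervals) is still a middle-regime function.

## Metrics, groups, scales and names

The original numeric metric catalogue is not published in full; the
package ships eight pairwise metrics and four triple multi-metrics with
stable string ids, plus an alias table mapping numeric `M`-tokens onto
them so published-style names parse. The bond-angle multi-metric measures
the angle at the middle index in radians; the area and perimeter
multi-metrics are fully permutation-symmetric.

The beta-sheet-favouring group `FBS = {VAL, ILE, TYR, CYS, TRP, PHE,
THR}` is shipped; `PBS` and `PAH` are deliberately left undefined (their
original compositions are unpublished) and error until the user supplies
codes. Four property scales are bundled from their primary sources —
Collantes–Dunn electronic charge index (`ECI`), Zamyatnin residue volumes
(`GVO`), Hopp–Woods hydrophilicity (`HWH`), Kyte–Doolittle hydropathy
(`KDH`, alias `KDS`) — and any user-supplied named 20-vector is accepted.

Descriptor names are underscore-joined tokens in fixed order
(representation, aggregation, form `Q`/`T`, metric, `normalization-k`,
optional flags, optional group, optional `LGP[..]`/`LGL[..]`, optional
`LGST(function)[r_on-r_off]`, property). Interval tokens print as
fractions of `R`. Tokens that are not grammar elements (such as the
opaque `o` seen in published names) are preserved through parsing and
ignored in computation. `parseDescriptorName(descriptorName(spec))`
round-trips; two specs differing in any numeric field produce distinct
names.

## Numerical choices

* Diagonal (two-tuple) and repeated-index (three-tuple) entries hold the
  metric of identical points — zero for every shipped metric — and
  three-tuple repeated indices are explicitly zeroed.
* Negative Hadamard powers map 0 to 0 instead of infinity, so filtered
  entries and diagonals stay finite under gravitational/Coulombic
  weightings.
* `SS` normalization leaves all-zero rows/slices at zero; a fully zero
  tensor cannot be `SS`/`MP` normalized and errors.
* Undefined aggregation moments (skewness/kurtosis of a constant LAI
  vector, harmonic mean with zeros) return 0 with a warning rather than
  NaN, keeping descriptor tables dense; `computeDescriptors` suppresses
  the warning but a failure of a whole protein yields NA cells and a
  warning naming the protein.
* Membership statistics use the sample (n-1) standard deviation.
* Shannon entropy uses equal-width bins over each column's own observed
  range, with the bin count conventionally equal to the number of
  proteins; empty bins contribute nothing, constant columns have zero
  entropy. The upper bound `log2(B)` is attained by a uniform occupation
  (152 bins give 7.25 bits).
* The function dendrogram uses Euclidean distances between membership
  columns with Ward linkage (`ward.D2`); the flat-cluster cutoff is
  expressed as a fraction of the maximum linkage height (default 0.2)
  because absolute heights scale with the pooled residue count.
* PCA loadings are component–variable correlations of the standardized
  table; "varimax normalized" is `stats::varimax(normalize = TRUE)`
  (Kaiser row-normalization by communality square roots). Strong loading
  means `|loading| >= 0.7`. Constant columns error by name rather than
  being silently dropped.

## The synthetic-peptide generator

`makeSyntheticPeptide()` emulates the only structural feature the
truncation machinery sees: the radial distribution of residues around the
geometric centre. Placement rules pin distances-to-centre into bands of
`R` — near-centre `[0, 0.1]`, middle shell `[0.4, 0.6]`, surface
`[0.95, 1]`, or the `r^2` density of a uniform ball — so each membership
regime is exercised. Because the centre is itself the point-cloud mean,
band membership is enforced with an alternating projection (re-centre,
re-project to target shells, repeat), and interior placements pin one or
two anchor residues at the shell so that `R` stays defined and the
centroid can balance. Default size in the test suite is 6–25 residues
(10^4 for the distribution law check), radius 10 Angstrom.

What the generator does *not* emulate: peptide-bond connectivity,
excluded volume, secondary structure, side-chain geometry, or realistic
sequence composition (codes cycle the 20 standard residues by default).
Passing tests therefore demonstrate the algebraic and geometric
correctness of the pipeline on controlled point clouds, not biological
realism of any particular descriptor value. Structures rendered to PDB
carry one CA pseudo-atom per residue, so only the `CA` and `AVG`
representations are meaningful on synthetic input; `AB` and `CB` require
real backbones and are tested on hand-built backbone fixtures.

## Problem sizes and determinism

The shipped tests run on peptides of 2–25 residues (plus one 10^4-point
distribution check), 5 random intervals and 10^4-point sweeps for the
membership properties, 20 random rigid motions for the invariance check,
and 60-observation synthetic tables for the PCA structure check — a few
seconds in total. All randomness is seeded; `computeDescriptors` itself
is fully deterministic (fixed configuration and input give bit-identical
tables), and the generator restores the caller's RNG state.

## Known limitations

* The `AB` (amide-bond) representation has no published formal
  definition; the midpoint of backbone `C(i)` and `N(i+1)` (terminal
  residue: `C`–`O` midpoint) is this package's convention and may differ
  from other software.
* The per-residue equal-share tensor split guarantees additivity but is
  an approximation of the (unpublished) original aa-level construction;
  non-additive aggregations of the resulting LAI vectors can differ from
  other implementations.
* Only four of the sixteen property scales referenced in the descriptor
  literature ship with the package; the rest must be user-supplied.
* Multi-chain structures are concatenated chain by chain with a single
  global centre; no biological-assembly expansion or structure repair is
  attempted, and hydrogens are ignored throughout.
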