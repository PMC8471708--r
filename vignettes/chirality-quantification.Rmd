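---
title: "Quantifying the handedness of helical and helix-like structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the handedness of helical and helix-like structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helichir)
```

## The measure

A helix is chiral: it cannot be superimposed on its mirror image, and its
sense (right- or left-handed) is a sign, not a magnitude. helichir quantifies
that sign — and a size for it — with sums of scalar triple products of
consecutive vectors along the structure.

For a polypeptide chain of $n$ residues, the $n-1$ difference vectors
$\mathbf{v}_i$ between consecutive C$\alpha$ atoms define

$$\chi_{total} = \sum_{i=1}^{n-3} ([\mathbf{v}_i, \mathbf{v}_{i+1}],
\mathbf{v}_{i+2}),$$

where $([\mathbf{a},\mathbf{b}],\mathbf{c}) = \det(\mathbf{a};\mathbf{b};
\mathbf{c})$ is the scalar triple product. The triple product is a
pseudoscalar: invariant under proper rotations, negated by any reflection.
A right-handed helix gives $\chi_{total} > 0$, a left-handed one
$\chi_{total} < 0$.

Supramolecular helix-like assemblies — the motivating case is the peptide
nanotube self-assembled from diphenylalanine (FF), whose helical turn
("coil") contains six FF molecules — have no covalent backbone to trace.
There the same construction is applied to the *dipole-moment vectors*
$\mathbf{D}_i$ of the successive molecules in a turn, each anchored at its
molecule's center of mass:

$$c_{total} = \sum_{i=1}^{n-2} ([\mathbf{D}_i, \mathbf{D}_{i+1}],
\mathbf{D}_{i+2}) \quad (\text{Debye}^3),$$

with $n$ the number of molecules (the index numbers molecules, not bonds,
hence $n-2$ terms rather than $n-3$). Dividing by the cube of the mean
dipole magnitude $D_{av} = \tfrac1n \sum_i |\mathbf{D}_i|$ yields a
dimensionless measure,

$$c_{norm} = \frac{c_{total}}{D_{av}^3},$$

comparable across systems and across the method used to obtain the dipoles.
The sign convention carries over: $c > 0$ is right-handed (symbol D),
$c < 0$ left-handed (symbol L). An exact zero is classified as
indeterminate, with no symbol: the convention is undefined there, and
assigning either hand would be arbitrary.

## What the package computes, and from what

The dipole vectors themselves are inputs. They come from quantum-chemical or
force-field calculations (the bundled tables hold published PM3-RHF and
Amber dipoles for one coil of the L-FF and the D-FF nanotube), from any TSV
in the package's dialect, or — as a rough classical estimate only — from
per-atom partial charges via `point_charge_dipole()`, which computes
$\mathbf{D} = \sum_j q_j(\mathbf{r}_j - \mathbf{r}_{ref})$ and converts
e·Å to Debye with the factor 4.80320. That estimator is tagged
`"point-charge"` in its output and is *not* expected to reproduce
quantum-chemical dipoles; charges are never guessed from elements and must
be supplied (PQR file or TSV).

Magnitudes in a dipole table are always recomputed from the components.
This matters in practice: one bundled published table contains two rows
whose printed magnitude disagrees with the norm of its own printed
components (by 0.030 and 0.376 Debye). The reader attaches a warning and a
`magnitude_mismatch` record rather than silently preferring either number,
and all downstream computation uses the recomputed norms — which is also
the only choice that reproduces the published normalized chirality of that
system at its printed precision.

## Ordering is a semantic input

Reversing the traversal order of a coil negates every chirality sum (each
3×3 determinant suffers one row swap after reindexing), so the order of
molecules is part of the definition, not a presentation detail. The core
functions never re-sort. When dipoles are derived from a structure,
`structure_dipoles()` offers a deterministic traversal rule: fit a helix
axis to the molecular centers of mass, start at the molecule with the
lowest axial coordinate, and ascend by azimuth. Published tables are used
row order as printed.

The synthetic rosette generator emits its dipoles in *descending* helix
order (azimuth decreasing for a right-handed rosette, viewed from $+z$).
This matches the ordering evident in the published right-handed L-FF table,
whose in-plane dipole azimuths step by about $-60^\circ$ per molecule, and
it makes the generator's sign convention line up: a right-handed rosette
with the nanotube's downward axial dipole component ($D_z < 0$) has
$c_{total} > 0$. The convention is asserted by tests, including a
closed-form oracle: for in-plane magnitude $p$, azimuthal step $s$ and
constant axial component $z$, every term equals $p^2 z\,(2\sin s - \sin
2s)$, so the ideal 6-molecule rosette has $c_{total} = 4\,p^2|z|\sqrt3/2$.

## Parameters that matter

* `n` (molecules per turn, default 6) and `step_angle` (default $360/n$
  degrees): the published FF coil geometry. Any $n \ge 3$ is accepted; the
  $1/6$ of the published normalization generalizes to $1/n$.
* Rosette defaults `in_plane_magnitude = 19` Debye, `z_component = -12`
  Debye, `radius = 8.15` Å, `rise_per_turn = 5.456` Å: the magnitudes and
  helix geometry of the published L-FF coil, so synthetic tests run at
  realistic scale.
* α-helix generator defaults (radius 2.3 Å, rise 1.5 Å, 3.6
  residues/turn): canonical α-helix geometry.
* `noise_sigma`: isotropic per-component Gaussian noise, seeded;
  the simplest perturbation adequate for stability checks. The same spec
  and seed reproduce output bit for bit.
* Partitioning `cutoff = 1.9` Å for connectivity-based molecule
  partitioning: just above the longest common covalent bonds.

## Numerical choices

* Triple products are evaluated as 3×3 determinants (`det()`); a
  cofactor-expansion oracle written independently of that path checks them
  to 1e-12 relative tolerance in the tests.
* Published-table reproduction is asserted at 0.1% relative tolerance for
  $c_{total}$ (the inputs are printed to three decimals, and recomputation
  from printed components lands within ~0.01% of the printed totals) and at
  printed precision (two decimals) for $c_{norm}$. Internal identities use
  1e-9 to 1e-12.
* The helix fit first screens the three principal directions of the
  centered point cloud for the one about which radial distances vary least,
  then refines axis direction and in-plane offset by Nelder–Mead
  minimization of the radial-distance variance, which vanishes for an exact
  helix. Radius is the mean distance from the fitted axis; pitch is the
  mean per-point rise times the points-per-turn inferred from the mean
  azimuthal step. Points on a flat circle are reported with pitch ≈ 0 and
  `degenerate = TRUE`; collinear points are an error (no radius exists).
  The axis sign is fixed along the dominant traversal direction so results
  are deterministic.
* Units are carried as container metadata (Debye for dipole sets, Å for
  traces) rather than per-vector objects; the chirality sums refuse
  non-finite input and the two modes never mix containers.

## What the synthetic generators do and do not emulate

The rosette generator reproduces the *geometry* of a nanotube coil's dipole
arrangement — the ~60° azimuthal stepping that makes in-plane components
cancel around a full turn (exactly, in the ideal case), the constant axial
component, centers of mass on a helix. It does not attempt physically
realistic FF conformers, hydrogen-bond networks, or dipole fluctuations, so
passing tests demonstrate correctness of the *measure* on helix-like vector
arrangements, not the accuracy of any dipole model for real peptide
assemblies. Likewise the pseudo-molecules of `make_supramolecular_coil()`
are bonded random walks, adequate for exercising partitioning, centers of
mass and point-charge dipoles, not chemistry.

## Problem sizes

Everything here is small by construction: coils of 3–12 dipoles, traces of
4–10 residues, assemblies of ≤ 258 atoms, 1000-triple property sweeps. The
full test suite and the acceptance script each run in well under a minute.

## Known limitations

* The measure is defined per supplied vector sequence. Whether a long
  nanotube should be scored per coil or averaged over coils is left to the
  caller; no aggregation is imposed.
* Crystallographic symmetry expansion is out of scope: structures are used
  as-is and must already contain the full assembly.
* The point-charge dipole estimator is origin-independent only for
  net-neutral groups; for charged groups the reference-point choice
  (center of mass vs center of charge) changes the result, which is why
  both are explicit options.
* `fit_helix_params()` assumes the points are supplied in traversal order
  (its rise and azimuthal steps are consecutive differences); an unordered
  cloud will fit a sensible axis but a meaningless pitch.
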