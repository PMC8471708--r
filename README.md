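# helichir

Signed, normalized chirality measures for helical and helix-like molecular
structures, built from scalar triple products of consecutive vectors.

## The problem

Handedness — whether a helix twists right or left — is a sign, and most
structural descriptors throw it away. helichir computes a pseudoscalar that
keeps it. For a polypeptide chain, the vectors are the differences between
consecutive Cα positions and the measure is

    chi_total = sum_{i=1..n-3} ([v_i, v_{i+1}], v_{i+2})      (Å³)

where ([a,b],c) is the scalar triple product (the 3×3 determinant).
For helix-like supramolecular assemblies with no covalent backbone — the
motivating case is the peptide nanotube self-assembled from diphenylalanine
(FF), whose helical turn contains six FF molecules — the same sum runs over
the per-molecule dipole-moment vectors D_i, anchored at each molecule's
center of mass:

    c_total = sum_{i=1..n-2} ([D_i, D_{i+1}], D_{i+2})        (Debye³)
    c_norm  = c_total / D_av³,   D_av = (1/n) sum_i |D_i|     (dimensionless)

Positive values mean right-handed (symbol D), negative left-handed
(symbol L). c_norm is comparable across systems and across the method used
to compute the dipoles.

The package is for structural bioinformaticians and molecular modellers who
have dipole tables (from quantum-chemical or force-field calculations) or
atomic structures (PDB/mmCIF) and want a reproducible, signed handedness
number. It ships the published dipole tables for one coil of the L-FF and
D-FF nanotubes as fixtures, readers/writers for a plain TSV dipole dialect,
structure handling (Cα traces, molecule partitioning, centers of mass,
point-charge dipole estimates, helix-geometry fitting), seeded synthetic
generators for property testing, and a small CLI.

## Worked example

```r
library(helichir)

coil <- read_dipole_table(helichir_fixture("lff_pm3.tsv"))
res  <- full_dipole_analysis(coil)
res
#> Chirality analysis (dipole coil)
#>   label:      L-FF
#>   method:     PM3-RHF
#>   c_total:    16,035.28 Debye^3 over 4 triples
#>   D_av:       22.728 Debye
#>   c_norm:     1.37
#>   handedness: right (symbol D)
```

The six L-FF dipoles, taken in helix traversal order, give a positive total
chirality of about 1.6 × 10⁴ Debye³ over the four consecutive triples; the
mean dipole magnitude is 22.728 Debye, so the dimensionless normalized
chirality is 1.37 — a right-handed nanotube, symbol D. The D-FF enantiomer's
tables give the mirror result (c_norm = −1.23 for PM3 dipoles, symbol L).
`glance(res)` returns the same numbers as a one-row tibble, `tidy(res)` the
per-triple terms, and `autoplot(coil)` draws the rotating in-plane dipole
components.

Backbone mode works the same way from a structure:

```r
trace <- extract_calpha_trace(read_structure(helichir_fixture("helix4.pdb")), "A")
chi_total_backbone(trace)$handedness
#> [1] "right"
```

The CLI exposes the pipeline (`helichir dipoles table.tsv`,
`helichir backbone file.pdb --chain A`, `helichir structure-dipoles`,
`helichir synth`, `helichir fixtures`); it is installed under
`system.file("exec", "helichir", package = "helichir")`.

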