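# ledkit

Tooling for **local energy decomposition (LED)** analyses of molecular
interactions in multifragment systems — the workflow used to dissect, e.g.,
interstrand stabilisation in nucleic-acid duplexes, solute–solvent binding,
or cohesion in molecular crystals, from high-level local coupled-cluster
(DLPNO-CCSD(T) / HFLD) calculations.

LED splits the supersystem interaction energy

```
ΔE_int = E_super − Σ_K E_K
       = Σ_X ΔE_el-prep^X + Σ_{X>Y} ε(X,Y)
ε(X,Y) = ε_elstat + ε_exch + ε_no-disp + ε_disp (+ ε_solv)
```

into per-fragment electronic-preparation energies and pairwise
electrostatic, exchange, non-dispersive-correlation, dispersion (and
solvation) components; the fragment-pairwise (fp) layout further
redistributes the cumulative `ΔE_el-prep^X` diagonal over pairs so every
matrix cell is a pair interaction `ΔE_int^XY`. The package covers the whole
workflow around that model:

* **Fragment detection** from XYZ geometries via covalent radii (tunable
  distance cutoff, coordination-number caps, custom bond/break list).
* **Input enumeration and rendering** for N-body and two-body LED campaigns,
  with and without counterpoise (BSSE) ghost-atom correction, across
  computational settings — per setting `1+S+P+F` uncorrected or `1+S+3P`
  corrected calculations for `S` subsystems, `F` fragments and `P`
  subsystem-spanning fragment pairs.
* **Output parsing** of a documented LED text grammar, fragment-label
  alignment across files, salvage-merging of partial outputs, and HFLD
  redundant-term filtering.
* **Matrix assembly**: standard and fp layouts, two-body matrices from
  isolated-pair runs, and cooperativity (many-body) analysis by N-body minus
  two-body subtraction.
* **Two-point CBS and CPS extrapolation** of scalars and whole matrix sets
  (exponential reference / inverse-power correlation forms; affine PNO-space
  rule), with coefficient defaults shipped as replaceable table data.
* **Reporting**: CSV-workbook export (one sheet per component, absent cells
  empty) and zero-centred diverging heat maps with subsystem overlay boxes.
* **Mock-output generation**: seeded ground truths with exactly closing
  planted energies, so the entire pipeline is testable without a
  quantum-chemistry engine.

## Worked example

A synthetic 2-subsystem × 3-fragment campaign (the layout of a
three-base-pair duplex: 18 calculations uncorrected per setting), analysed
end to end:

```r
library(ledkit)

gt  <- generate_ground_truth(S = 2, f = c(3, 3), seed = 1)
man <- write_mock_outputs(gt, "mock", bsse = FALSE)   # 18 output files

super <- parse_led_output(man$output[man$role == "supersystem"])
parts <- lapply(man$output[man$role == "subsystem"], parse_led_output)

std <- assemble_standard_nbody(super, parts, gt$subsystems)
fp  <- assemble_fp_nbody(std, scheme = "prop_eps")

interaction_energy(super, parts)   # -111.66 kcal/mol
matrix_grand_total(std)            # -111.66  (conservation: equals ΔE_int)
matrix_grand_total(fp)             # -111.66  (fp redistribution conserves)

round(fp$components$total, 2)
#        1     2      3     4      5      6
# 1   0.00 -0.80  -0.46 -5.63 -17.31 -22.98
# 2  -0.80  0.00  -0.09 -3.75  -9.81  -3.89
# 3  -0.46 -0.09   0.00 -5.77 -20.93 -18.13
# 4  -5.63 -3.75  -5.77  0.00  -0.47  -0.72
# 5 -17.31 -9.81 -20.93 -0.47   0.00  -0.90
# 6 -22.98 -3.89 -18.13 -0.72  -0.90   0.00
```

Fragments 1–3 form subsystem A, 4–6 subsystem B; the off-diagonal 3×3 block
(rows 1–3 × columns 4–6) holds the genuine intersubsystem pair interactions
— here dominated by the 1–6, 3–5 and 1–5 contacts — while the small
same-subsystem cells are differential perturbations upon complex formation.
Adding the two-body analysis isolates many-body (cooperative) effects:

```r
pairs <- lapply(man$output[man$role == "pair"], parse_led_output)
monos <- lapply(man$output[man$role == "monomer"], parse_led_output)
tb <- assemble_twobody(pairs, monos, gt$subsystems, layout = "fp",
                       reference = super)
co <- cooperativity(fp, tb)
co$components$total[1, 4]          # -3.98 kcal/mol of environment-mediated
                                   # stabilisation for the 1-4 pair

export_matrices(fp, "fp_matrices")           # CSV workbook
render_heatmap(fp, "total", path = "fp.png") # red = attraction, blue = repulsion
```

`run_pipeline("config.yaml")` chains all of the above (plus optional
CBS/CPS extrapolation) from a single YAML config; see `?run_pipeline`.

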