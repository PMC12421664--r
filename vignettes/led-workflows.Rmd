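---
title: "LED workflows with ledkit: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LED workflows with ledkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledkit)
```

## The model

Local energy decomposition (LED) interprets the interaction energy of a
*supersystem* — a multifragment complex such as a nucleic-acid duplex, a
molecular cluster, or a solvated solute — by splitting it into chemically
meaningful terms. The hierarchy has three levels: the supersystem (the whole
complex), *subsystems* (chemical entities inside it, e.g. one strand), and
*fragments* (the smallest analysis units, e.g. one nucleobase). The
interaction energy is

$$\Delta E_{\mathrm{int}} \;=\; E_{\mathrm{super}} - \sum_{K} E_{K},$$

the supersystem energy minus the sum of subsystem energies, all evaluated at
the supersystem geometry (geometric deformation is out of scope here). The
standard LED writes this as

$$\Delta E_{\mathrm{int}} \;=\; \sum_{X}\Delta E^{X}_{\mathrm{el\text{-}prep}}
  \;+\; \sum_{X>Y}\varepsilon^{(X,Y)},$$

where $\Delta E^{X}_{\mathrm{el\text{-}prep}}$ is the *electronic
preparation* of fragment $X$ — the cumulative change of its internal energy
caused by all other fragments — and $\varepsilon^{(X,Y)}$ collects the
interfragment terms. For fragments in different subsystems
$\varepsilon^{(X,Y)}$ is a genuine intersubsystem interaction; for fragments
in the *same* subsystem it is a differential quantity, the perturbation of
that pair's internal interaction upon complex formation. Each
$\varepsilon^{(X,Y)}$ decomposes further into

$$\varepsilon = \varepsilon_{\mathrm{elstat}} + \varepsilon_{\mathrm{exch}}
 + \varepsilon_{\mathrm{no\text{-}disp}} + \varepsilon_{\mathrm{disp}}
 \;(+\;\varepsilon_{\mathrm{solv}}),$$

electrostatics and exchange at the reference (mean-field) level, a
non-dispersive correlation correction, London dispersion, and — with
implicit solvation — a solute–solvent term.

The *fragment-pairwise* (fp) layout redistributes the cumulative diagonal
$\Delta E^{X}_{\mathrm{el\text{-}prep}}$ over fragment pairs so that every
matrix element is a pair quantity
$\Delta E^{XY}_{\mathrm{int}} = \Delta E^{XY}_{\mathrm{el\text{-}prep}} +
\varepsilon^{(X,Y)}$ and the grand sum is unchanged. In the HFLD
(Hartree–Fock plus London dispersion) scheme the non-dispersive correlation
and the correlation part of the electronic preparation are discarded;
`exclude_redundant_hfld()` implements exactly that filter.

`ledkit` keeps all energies in Hartree internally and converts once, at
matrix assembly, using 1 Eh = 627.5094740631 kcal/mol.

## Matrix layouts and assembly

`assemble_standard_nbody()` places $\Delta E^{X}_{\mathrm{el\text{-}prep}}$
(supersystem intra minus part-record intra, reference and correlation parts
tracked separately) on the diagonal; spanning-pair cells take the
supersystem $\varepsilon$ components directly and same-subsystem cells take
supersystem-minus-part differentials. Conservation —
grand total $=\Delta E_{\mathrm{int}}$ — then holds identically whenever the
records themselves decompose their totals, and is enforced by tests at
1e-6 kcal/mol on mock campaigns.

`assemble_fp_nbody()` needs a partitioning rule for the diagonal. The exact
mutual-perturbation formula of the original fp scheme requires engine-side
quantities that an output file does not carry, so the partitioner is
pluggable behind a single contract — *the pairwise elprep cells must sum
exactly to the diagonal they replace* — with two built-ins:

* `"equal"`: each fragment's elprep is split evenly over its $F-1$ partners;
* `"prop_eps"`: shares proportional to $|\varepsilon^{(X,Y)}|$, falling back
  to the even split for a fragment whose $\varepsilon$ magnitudes all vanish.

The scheme id is stamped into the matrix-set metadata, and both schemes
necessarily agree for two-fragment systems (conservation forces the single
off-diagonal cell).

Two-body LED (`assemble_twobody()`) rebuilds the same matrices from LED runs
on each *isolated* pair of fragments spanning different subsystems, with
elprep taken as pair-record intra minus monomer intra. Cells with no
isolated-pair calculation are flagged *absent* — empty, never zero — so
sums are unaffected. `cooperativity()` subtracts two-body from N-body
cellwise; where the two-body cell is absent the N-body value passes through
and is flagged fully cooperative.

## Counterpoise conventions

In the BSSE-corrected setup every part is computed in the full supersystem
basis: subsystem records carry all other subsystems' atoms as ghosts, and
each spanning pair contributes two monomer calculations with real and ghost
fragments exchanged. Per setting this gives $1+S+3P$ calculations against
$1+S+P+F$ uncorrected ($S$ subsystems, $F$ fragments, $P$ spanning pairs);
for a 2-subsystem, 3+3-fragment system that is 30 vs 18, and a four-setting
CBS+CPS campaign multiplies both by four (120 / 72). The supersystem file is
shared between corrected and uncorrected analyses of one setting; the
campaign bookkeeping counts it in each setup, matching the per-setup totals
above. Uncorrected two-body monomers are emitted once per fragment, not once
per pair.

## Extrapolation

Reference energies converge as
$E(n) = E_{\mathrm{CBS}} + A\,e^{-\alpha\sqrt{n}}$ in the basis cardinal
number $n$, correlation energies as
$E(n) = E_{\mathrm{CBS}} + B\,n^{-\beta}$; two points determine each limit.
The default $\alpha/\beta$ pairs (4.420/2.460 for cardinals 2/3, 5.460/3.050
for 3/4, tuned for the (aug)-cc-pV$n$Z family) ship as a user-replaceable CSV
table, not as hard-coded constants, because they are calibration data.
PNO-space (CPS) extrapolation uses the affine two-point rule
$E = E_X + F\,(E_Y - E_X)$ over two successive $T_{\mathrm{CutPNO}}$
exponents, default $F = 1.5$, also overridable. Under CPS only
correlation-level components are extrapolated; reference-level components
pass through from the tighter-threshold record, since PNO truncation does
not touch the reference energy.

All three formulas are affine in $(E_X, E_Y)$, so extrapolating a matrix
cellwise commutes with any linear bookkeeping (totals, grand sums) — a
property the test suite exercises directly. Individual LED terms are
extrapolated exactly like the parent energies: elstat/exch (and solvation)
via the reference formula, no-disp/disp via the correlation formula, and the
electronic preparation split into its reference and correlation parts, which
is why matrix sets carry `elprep_ref` and `elprep_corr` alongside `elprep`.

## Fragment detection

`detect_fragments()` takes connected components of a bond graph in which
atoms $i,j$ bond when $d_{ij} \le s\,(r_i + r_j)$ with covalent radii from
the bundled Cordero (2008) consensus table and default scale $s = 1.15$, a
common covalent-bond heuristic; an absolute distance cutoff can replace the
radius criterion. Three knobs cover difficult cases: the cutoff itself,
per-element maximum coordination numbers (excess bonds pruned
farthest-first, ties resolved toward the lower-indexed partner — a
deterministic, physically sensible rule), and a custom bond list applied
last as the final word (`bond` adds, `break` removes, e.g. to split
covalently linked units into separate fragments). Fragment ids are assigned
1..F by each component's lowest atom index, so numbering is reproducible and
permutation-invariant up to relabeling. The labeled-XYZ dialect appends the
fragment id as a trailing integer column — the simplest annotation that
survives round trips through standard XYZ tooling.

## Output grammar, alignment, and salvage

The parser reads a documented block grammar (annotated example in
`inst/extdata/example_led_output.txt`) modelled on the LED blocks printed by
DLPNO-CCSD(T)/HFLD engines: a final-energy line, a fragment table with
explicit real/ghost markers, per-fragment `INTRA` REF/CORR terms, and
per-pair component blocks. Parsing is whitespace-tolerant and ignores
unrecognised content; ghost identity comes from the fragment table only.

Fragment labels in subsystem, pair, and monomer files rarely match the
supersystem's numbering, so `align_labels()` maps fragments by exact element
sequence plus coordinate agreement within 1e-4 Å per atom (configurable;
greedy nearest-neighbour with conflict detection, which cannot tie under a
bijective match). Two-body analyses inherit the N-body labels through the
supersystem reference record; without one, monomer file order defines the
labels.

`merge_alternative()` addresses runs that crash after the reference-level
LED: fields absent in the main output are filled from an alternative output,
main always wins, every filled field is logged, and a disagreement on a
field both files contain (beyond 1e-9 Eh) is a logged warning, not an error.

## The mock-data generator

`generate_ground_truth()` makes the whole pipeline testable without a
quantum-chemistry engine. It builds rigid water units (O–H 0.96 Å) on a
jittered grid with ≥ 2.5 Å separation — so fragment detection resolves them
— and plants every energy additively: isolated monomer intra energies near
−76 Eh, interfragment components on the −30…+10 kcal/mol scale of strong
noncovalent contacts, positive electronic-preparation energies of a few
kcal/mol, ghost-basis stabilisations of 0.1–0.6 kcal/mol (so counterpoise
monomer energies sit below uncorrected ones), and ~1 kcal/mol-scale
same-subsystem differentials and cooperativity offsets. Because supersystem
terms are isolated terms plus planted perturbations, the standard-LED
differences recover the planted numbers exactly and conservation closes by
construction; `expected_matrix_set()` exposes those planted expectations
analytically so tests compare two independent routes. For extrapolation
tests, `ground_truth_series()` perturbs every planted field on the exact
CBS/CPS model forms; since all derived energies are linear in the fields,
every record energy and matrix cell lies exactly on the model form and the
limit is recovered to numerical precision.

What the mock data does *not* emulate: realistic electronic-structure
magnitudes beyond the scales above, geometry-dependent energy correlations,
basis-set or PNO errors that deviate from the ideal convergence forms, or
engine-specific output quirks beyond the documented grammar. Green tests
therefore certify the bookkeeping — enumeration, parsing, alignment,
assembly arithmetic, conservation, extrapolation algebra — not the physics
of any particular engine's numbers.

## Reporting

`export_matrices()` writes a matrix set as a CSV workbook: one
full-precision CSV per component plus a metadata sheet (layout, body order,
BSSE mode, partitioner scheme, extrapolation provenance). Absent cells are
written as empty cells, never zeros. Heat maps use a diverging scale fixed
at zero — red for attraction, blue for repulsion, grey for absent cells —
with overlay boxes derived from the subsystem assignment: turquoise around
the diagonal elprep cells (standard layout), green around same-subsystem
differential blocks, black around each intersubsystem submatrix. Display
default is 2 decimal places in kcal/mol; CSV retains full precision.
`run_pipeline()` drives parse → align → assemble → two-body →
cooperativity → extrapolate → export from one YAML config and runs the
cooperativity stage automatically whenever both N-body and two-body inputs
are configured — for a two-fragment system, feeding corrected outputs as
"N-body" and uncorrected ones as "two-body" turns that stage into a direct
readout of the counterpoise correction.

## Numerical choices and test scales

* Pair-component closure is validated at 1e-9 Eh on every record; matrix
  conservation at 1e-6 kcal/mol; fp partition conservation exactly
  (1e-12 kcal/mol).
* Mock outputs print energies at 12 decimals in Hartree, so file round trips
  are exact to ~1e-12 Eh absolute; tests compare absolutely, not relatively.
* Coordinate matching: 1e-4 Å (alignment), 1e-7 Å (file round trips,
  8 printed decimals).
* Test and acceptance problem sizes: campaigns up to 3 subsystems × 4
  fragments per subsystem, 100 seeded conservation campaigns, 50–100 round
  trips, 50 random fragmentation geometries — small enough to run in tens of
  seconds while covering every enumeration branch.

## Known limitations

Open-shell LED, covalent fragment definitions that cut bonds, atomic-level
dispersion partitioning, triples-dispersion estimation, and distributing
implicit-solvation terms across fragments (beyond carrying a parsed
solvation component) are out of scope. The fp partitioners are conservative
stand-ins for the engine-side mutual-perturbation formula; a third scheme
implementing that formula can be added behind the same conservation
contract. Spreadsheet output is plain-text CSV by design — it round-trips
exactly and diffs cleanly under version control.
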