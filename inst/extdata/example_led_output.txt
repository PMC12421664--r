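Annotated example of the LED-output grammar read by parse_led_output() and
written by write_led_output(). Everything outside the recognised blocks is
ignored by the parser, which is how this commentary can live inside the file.
The example is a synthetic water-dimer supersystem record; a counterpoise
monomer record differs only in that the partner fragment is tagged "(ghost)"
and then carries no INTRA block and no interaction block.

All energies are Hartree, coordinates Angstrom. Numbers are parsed at full
printed precision; blocks may appear in any order; whitespace is free.

--- the Method/Setting header identifies the record ---

Method   : DLPNO-CCSD(T)
Setting  : TZ

--- fragment table: label, real/ghost identity, then one atom per line.
--- ghost identity is read from this marker only, never inferred.

------------------------------------------------------------
FRAGMENT INFORMATION
------------------------------------------------------------
FRAGMENT 1 (real)
   O         -0.15755887       0.03666317       0.22191967
   H          0.80244113       0.03666317       0.22191967
   H         -0.39755887       0.96666317       0.22191967
FRAGMENT 2 (real)
   O          3.30118702      -0.16597404       0.22173748
   H          4.26118702      -0.16597404       0.22173748
   H          3.06118702       0.76402596       0.22173748

--- total and reference energies; the final-energy line is mandatory and its
--- absence is a parse error naming the block

FINAL SINGLE POINT ENERGY   -152.586197664611
Reference energy            -152.090385151911

--- per-fragment intrafragment energies, reference and correlation level.
--- Real fragments only; the CORR. line may be absent in partial outputs.

------------------------------------------------------------
LED: INTRA-FRAGMENT CONTRIBUTIONS
------------------------------------------------------------
INTRA Fragment 1
   REF.   -76.045589507707
   CORR.  -0.247568970046

INTRA Fragment 2
   REF.   -76.000740111204
   CORR.  -0.241362633259

--- one block per unordered fragment pair. Electrostatics and exchange are
--- reference-level, non-dispersion and dispersion correlation-level; the
--- solvation line appears only with implicit solvation; Total must equal the
--- component sum to 1e-9 Eh. Any unreadable line inside a pair block is a
--- parse error carrying the line number.

------------------------------------------------------------
LED: INTER-FRAGMENT CONTRIBUTIONS
------------------------------------------------------------
Interaction of Fragments 1 and 2:
   Electrostatics (REF.)   -0.032704835485
   Exchange (REF.)         -0.008196687846
   Non dispersion (CORR.)  0.001415009942
   Dispersion (CORR.)      -0.008295919337
   Solvation               -0.003154009670
   Total                   -0.050936442396
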