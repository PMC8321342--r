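# mol2narupa

Narupa Builder is a virtual-reality molecule editor; NarupaXR is the
companion VR molecular-dynamics viewer. The builder exports TRIPOS mol2
files — in a locale-specific dialect that uses commas as decimal
separators — while the viewer loads simulation XML with coordinates,
bonds, a temperature, and one `MM3AtomMapping` / `LennardJonesAtomMapping`
entry per atom. Filling that XML in by hand is slow and error-prone for
anything larger than a few atoms. `mol2narupa` automates the conversion
and, along the way, re-implements the builder's chemistry operations as
ordinary, testable R functions:

- **mol2 I/O** for both the standard dot-decimal dialect and the builder's
  comma-decimal dialect, with strict parsing (any malformed record raises)
  or lenient parsing (documented, logged repairs — e.g. re-splitting a
  bond record whose last two tokens were fused into one);
- **valence-based validation**: each element has a maximum bond-order
  budget (H 1, C 4, N 3, O 2, ...); an atom over budget is a violation,
  and `bond_feasible()` answers the builder's green/red "can this bond be
  made?" question;
- **hydrogen balancing**: every heavy atom is brought to exactly its
  maximum valence by adding or removing hydrogens only;
- **harmonic bond-length minimization**: gradient descent on
  E = Σ k (d − r₀)² over bonds, with r₀ from a shipped covalent-radii
  table — angles and torsions are left free, as in the builder's own
  "minimize" action;
- **force-field typing** from a small, documented glossary XML, filling
  the `Type` / `MM3Type` attributes that are otherwise completed by hand
  from the engine's `mm3.xml`; atoms with no matching rule keep the blank
  `" "` placeholder.

## Worked example

The package ships the builder's ethane export verbatim
(`inst/extdata/ethane_narupa.mol2`), comma decimals and all — including a
defective final bond record `7 3 11` whose last two tokens were fused:

```r
library(mol2narupa)

doc <- read_mol2(system.file("extdata", "ethane_narupa.mol2",
                             package = "mol2narupa"))
doc
#> <mol2_document> narupa builder molecule: 8 atoms, 7 bonds, dialect=comma, 1 repair(s)
doc$repairs
#> [1] "line 22: re-split trailing bond token '11' into '1 1'"
molecular_formula(doc$molecule)
#> [1] "C2H6"
```

The lenient parser recognized the fused token, split it into bond
endpoint `1` and order `1`, and logged the repair (strict mode would have
raised instead). The printed coordinates put the C–C bond at 1.115 Å —
too short for ethane; the minimizer relaxes it onto the table length:

```r
res <- minimize_bonds(doc$molecule)
res$converged
#> [1] TRUE
m <- res$molecule
sqrt(sum((as.numeric(m$atoms[1, c("x","y","z")]) -
          as.numeric(m$atoms[2, c("x","y","z")]))^2))
#> [1] 1.539961
```

Conversion to simulation XML (untyped, so every mapping entry carries the
manual-fill blank):

```r
spec <- build_spec(doc, temperature = 300)
cat(write_simulation_xml(spec))
```

prints a document whose mapping block contains, for each of the eight
atoms,

```xml
<MM3AtomMapping AtomPath="0" Type=" "/>
...
<LennardJonesAtomMapping AtomPath="7" MM3Type=" "/>
```

With the shipped demo glossary the carbons get MM3 type code `1` and the
hydrogens `5`:

```r
spec <- build_spec(doc, glossary = demo_glossary())
spec$mm3_types
#>   0   1   2   3   4   5   6   7
#> "1" "1" "5" "5" "5" "5" "5" "5"
```

Batch conversion from a shell:

```sh
Rscript inst/scripts/mol2narupa.R convert molecules/*.mol2 --out-dir out/ \
    --glossary my_glossary.xml --balance-hydrogens --minimize
```

Exit codes: 0 all converted, 1 some file failed, 2 usage error.

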