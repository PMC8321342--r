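---
title: "Converting Narupa Builder mol2 exports to simulation XML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting Narupa Builder mol2 exports to simulation XML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mol2narupa)
```

## The problem

Narupa Builder, the VR molecule editor that accompanies the NarupaXR
molecular-dynamics viewer, exports molecules as TRIPOS mol2. The viewer,
however, loads a simulation XML that carries the coordinates, the bonds,
a temperature, and two per-atom force-field mapping entries
(`MM3AtomMapping` and `LennardJonesAtomMapping`, addressed by a
zero-based `AtomPath`). Translating between the two by hand means
re-typing every coordinate and mapping entry, which is slow and invites
transcription errors. This package does the translation mechanically and
exposes the builder's own chemistry operations — bond feasibility,
bond-order editing, hydrogen balancing, bond-length minimization — as
library functions so they can be tested and reused outside VR.

## The mol2 dialects and lenient repair

Builder exports differ from standard mol2 in one important way: on
systems with a comma decimal locale the coordinates are written as
`-6,165` rather than `-6.165`. The parser auto-detects this (any
coordinate token containing a comma switches the file to the comma
dialect), records the dialect in the returned document, and reproduces
it on write. A token containing both separators is rejected as malformed
rather than guessed at.

Real exports also contain mechanical defects. The package's reference
example — an ethane export — ends with the bond record `7 3 11`: three
tokens where every other record has four, referencing atom 11 in an
8-atom molecule. The only reading consistent with the declared count of
7 bonds is that the trailing `1 1` (endpoint and order) lost its
separator. Lenient mode therefore attempts exactly one repair on a
3-token bond record: re-split the trailing token at every position and
accept the first split whose left part is an in-range atom index and
whose right part is a valid order token. The repair is logged in the
document's `repairs`; strict mode raises instead. Unrepairable bond
records are dropped (lenient) with a log entry, never silently.

Two smaller conventions: any run of blanks or tabs separates tokens and
blank lines are ignored (printed exports contain them), and a ninth ATOM
token that parses as a number is stored as the partial charge — the
builder dialect stops after the substructure name, so its atoms carry no
charge. Coordinates are taken as Angstrom and passed through to the XML
unchanged; the formats themselves are unitless and pass-through is the
only faithful choice.

## The XML schema

Only the two mapping elements of the target format are publicly
documented, and the package reproduces their spelling exactly:

```
<MM3AtomMapping AtomPath="0" Type=" "/>
<LennardJonesAtomMapping AtomPath="0" MM3Type=" "/>
```

An untyped atom carries a single-space placeholder, not an empty string —
that is the state a user fills in by hand from their force-field
glossary, and downstream tooling keys on it. Everything else in the
document is package-defined and documented here: a root `Simulation`
element holding `Temperature`, `Atoms`, `Bonds` and `Mappings` blocks,
with atoms addressed by the same zero-based `AtomPath` (mol2 atom *i*
becomes path *i − 1*) and bond endpoints using those paths. Matching the
engine's full internal schema bit-for-bit is explicitly out of scope; the
package's `parse_simulation_xml()` is the inverse of its own writer so
conversions can be verified by round trip. Serialization uses fixed
attribute order and fixed numeric formatting (up to nine decimals,
trailing zeros trimmed), so writing is deterministic and
write → parse → write is byte-stable. The default temperature is 300 K,
always emitted explicitly; the target format requires a temperature but
no canonical value exists, so a room-temperature default is used.

## The valence model

The builder colours a proposed bond green or red according to chemical
feasibility, but its exact rules are not published. The package's
stand-in is a maximum-valence budget: each element has a maximum
bond-order sum (defaults H 1, C 4, N 3, O 2, S 6, P 5, halogens 1,
shipped as an editable config file), and a bond is feasible iff it does
not already exist and both endpoints stay within budget. Aromatic bonds
count 1.5 toward the sum (Kekulé-free accounting), amide bonds 1, and
unknown orders (`du`/`un`/`nc` in mol2) conservatively 1 — these weights
are fixed so tests are deterministic. The element itself is derived from
the SYBYL type (the text before the first dot, first letter uppercased,
a second lowercase letter kept), never from the atom name: an atom named
`C1` but typed `H` is hydrogen. Stereochemistry, formal charges,
resonance and aromaticity perception are out of scope.

## Hydrogen balancing

`balance_hydrogens()` brings every non-hydrogen atom to exactly its
maximum valence by editing hydrogens only. Excess hydrogens are removed
highest-index first (a deterministic tie-break); missing ones are added
with fresh indices, names `Hk`, single bonds, and positions on a sphere
of the element-to-hydrogen table length around the heavy atom.
Placement directions come from a small self-contained linear
congruential generator seeded by the `seed` argument (default 0), so
results are reproducible and R's global random state is never touched.
Geometry quality is a non-goal: the added hydrogens are at the right
distance but not at tetrahedral angles — the minimizer only adjusts
lengths, and users who care about angles should relax the structure in a
real force field. The operation is idempotent by construction: after one
pass every heavy atom sits exactly at its budget.

## Bond-length minimization

`minimize_bonds()` descends the bond-term energy

$$E = \sum_{(a,b) \in \text{bonds}} k \,(d_{ab} - r^0_{ab})^2$$

with equilibrium lengths $r^0$ from a shipped covalent-radii table
(C–C 1.54 Å, C–H 1.09 Å, O–H 0.96 Å, ...) and a single global force
constant $k$ (default 1; its scale only multiplies gradients and does
not move the minimum). Only bond terms appear — the builder's own
"minimize" action adjusts bond lengths, and angle/torsion/non-bonded
terms are out of scope — so for acyclic molecules the global minimum has
every bond exactly at $r^0$ and zero energy.

The descent takes a fixed nominal step (`step_size`, default 0.02)
along the negative gradient, and halves the step within an iteration
whenever the proposed move would increase the energy. A truly constant
step can overshoot near the minimum and raise the energy; the
backtracking variant preserves the simplicity of fixed-step descent
while guaranteeing the property the rest of the package relies on — the
energy trace is monotonically non-increasing on every run. Iteration
stops when the largest per-atom gradient norm falls below `tol`
(default 1e-4) or after `max_steps` (default 2000) iterations. Two
coincident atoms have no defined bond direction; such a bond contributes
energy but no gradient until another term separates the pair. A bond
between elements missing from the table is an error naming the pair
rather than a silent skip. Whether this reproduces the builder's own
minimization algorithm is unknown and no equivalence is claimed.

On the reference ethane export, whose printed C–C distance is 1.115 Å,
the minimizer converges to the table length:

```{r minimize}
doc <- make_fixture("ethane_paper")
res <- minimize_bonds(doc$molecule)
res$converged
m <- res$molecule
sqrt(sum((as.numeric(m$atoms[1, c("x","y","z")]) -
          as.numeric(m$atoms[2, c("x","y","z")]))^2))
```

## Force-field typing

The engine's real `mm3.xml` glossary ships with NarupaXR and its schema
is not public, so the package defines its own documented rule format
(`<Rule element=... degree=... sybyl=... type=.../>` inside a
`<ForceFieldGlossary>`) and ships a small demo glossary for common
organic atoms; users transcribe their own glossary entries into it. A
rule may constrain the SYBYL type, the element plus bonding degree, or
the element alone; per atom, an explicit SYBYL match beats
element+degree, which beats element-only, and within a tier the first
rule in document order wins. Atoms with no matching rule keep the blank
placeholder and are listed as warnings — exactly the manual-fill state
of an unassisted conversion. The MM3 mapping (`Type`) and the
Lennard-Jones mapping (`MM3Type`) take the same code by default but are
separately overridable in `simulation_spec()`, since whether they ever
differ in real engine files is not documented. Only type *codes* are
mapped; force-field parameters are out of scope.

## Fixtures and what the tests show

`make_fixture()` provides the reference ethane export verbatim
(including its defective bond record), methane, water, and seeded random
alkanes: straight carbon chains at 1.54 Å spacing, hydrogens added by
`balance_hydrogens()`, every coordinate jittered by up to 0.05 Å from a
seeded generator and rounded to four decimals, like a real export. The
jitter gives the minimizer nontrivial work while keeping the graph
valid; determinism per `(n, seed)` makes every test reproducible.

The test suite runs round trips (mol2 parse↔write, XML write↔parse) on
all fixtures including 100 seeded alkanes, compares `bond_feasible()`
and `balance_hydrogens()` against a brute-force valence-sum oracle
written independently in the test helpers, and asserts minimizer
monotonicity and convergence; problem sizes (chains up to 8 carbons,
hundreds of oracle comparisons) keep the whole suite under a minute.
These fixtures emulate the *structure* of builder exports — dialect,
token layout, small organic graphs — not their chemical diversity:
passing tests say nothing about rings, charged species, aromatic
systems, or exports from builder versions with a different defect
profile than the one documented here.

## Known limitations

Multi-molecule mol2 files and SUBSTRUCTURE/SET/CRYSIN sections are
skipped with a log entry. The XML schema beyond the two mapping elements
is package-defined, so files produced here may need adjustment for
engine versions with a different internal layout (including a possible
Angstrom-to-nanometre conversion, which the engine's documentation does
not settle). The valence budget is a deliberate simplification of
chemical feasibility: it cannot represent hypervalent exceptions,
charge-dependent valence, or delocalized systems beyond the fixed
aromatic weight.
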