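---
title: "Parametrizing metal complexes: methods and design notes"
author: "metalff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametrizing metal complexes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalff)
```

## The problem

Classical force fields describe organic molecules well, but transition-metal
centers defeat transferable parameter databases: no generic library entry
captures the stiffness of a particular Ru–N bond in a particular complex, and
a single shared type for all six nitrogen donors of an octahedral center
forces all N–M–N angles onto one equilibrium value, distorting the
coordination sphere. `metalff` builds a *bonded model* for the metal center —
explicit harmonic bond and angle terms plus point charges, with metal
dihedral barriers set to zero and metal Lennard-Jones terms taken from a
generic source — and parametrizes it directly from a quantum-chemical
Hessian of the specific complex.

Three ideas carry the package:

1. **Seminario force constants.** Harmonic bond/angle stiffnesses are read
   out of the Cartesian Hessian through eigendecompositions of 3×3
   interatomic sub-blocks, so no energy scans or refits are needed.
2. **Unique labeling strategy (ULS).** Every atom that coordinates a metal
   receives its own atom type, so every chemically distinct metal-involving
   bond and angle gets its own parameter entry — no shortage, no accidental
   averaging.
3. **Hybrid assembly.** Only metal-involving terms come from the Hessian;
   the organic scaffold keeps transferable database parameters, with the
   Seminario value as a flagged fallback for database misses.

## The Seminario method as implemented

For atoms A and B the interaction sub-Hessian is the sign-flipped,
symmetrized off-diagonal block

$$ H^{AB} = -\tfrac12\,(H_{[3A,3B]} + H_{[3B,3A]}^{\mathsf T}), $$

with eigenpairs $(\lambda_i, \hat v_i)$. The bond force constant projects the
eigenpairs onto the bond unit vector $\hat u_{AB}$:

$$ k_{AB} = \sum_{i=1}^{3} (\hat v_i \cdot \hat u_{AB})^2\, \lambda_i
\quad [\mathrm{Hartree/Bohr^2}]. $$

For an angle A–B–C (vertex B) the unit normal of the angle plane is
$\hat u_N = \hat u_{CB} \times \hat u_{AB}$, the in-plane perpendiculars are
$\hat u_{PA} = \hat u_N \times \hat u_{AB}$ and
$\hat u_{PC} = \hat u_{CB} \times \hat u_N$, and the reciprocal stiffness
combines the two bonds in series:

$$ \frac{1}{k_\theta} =
\frac{1}{R_{AB}^2 \sum_i \lambda_i^{AB} \lvert \hat u_{PA}\cdot\hat v_i^{AB}\rvert}
+ \frac{1}{R_{CB}^2 \sum_i \lambda_i^{CB} \lvert \hat u_{PC}\cdot\hat v_i^{CB}\rvert}, $$

with $R$ in Bohr so that $k_\theta$ comes out in Hartree/rad². Note the
deliberate asymmetry inherited from the method as printed: the bond formula
uses *squared* projections, the angle formula *absolute* ones. Both are
implemented exactly as stated rather than "fixed".

**Units and doubling.** Outputs are converted with 627.509474 kcal/mol per
Hartree and 0.529177211 Å per Bohr and then **doubled**, because the Amber
energy form is $K(r-r_0)^2$ rather than $\tfrac12 k (r-r_0)^2$. The bond
conversion factor is therefore $2 \times 627.509474/0.529177211^2 \approx
2\times2240.88$ per Hartree/Bohr². Equilibrium lengths and angles are
measured from the input optimized geometry; no re-minimization is attempted.

**Numerical choices.**

* Eigenvalue terms with $\lambda_i < 10^{-8}$ Hartree/Bohr² are skipped in
  the angle sums, and an angle whose both sums vanish is an error (no
  bending stiffness resolvable).
* Collinear triads (cross-product norm below $10^{-8}$) have no angle
  plane. `angle_force_constant()` refuses them by default; the
  whole-molecule driver `all_metal_parameters()` instead substitutes a
  deterministic perpendicular axis (the coordinate axis least aligned with
  the bond, Gram–Schmidt-orthogonalized) and flags the parameter
  `degenerate`. This is what makes the trans angles of an octahedron
  representable at all; the flag is preserved into the assembled set so a
  user can audit those terms.
* A Hessian asymmetry above $10^{-6}$ (beyond QM printing noise) triggers a
  warning; the matrix is always symmetrized as $(H+H^{\mathsf T})/2$.
* Hessians are assumed to be in Hartree/Bohr² for the Gaussian
  formatted-checkpoint and ORCA dialects (both programs' native
  convention); the plain dialect carries an explicit unit header line.

## The unique labeling strategy

Base types are a deliberately simple element + coordination-number
heuristic (`c3`, `c4`, `n2`, ...), with a user override hook for labels
produced by an external typing tool — full GAFF/SYBYL perception is an
external tool's job in the original workflow and is not re-implemented
here. Metals keep their element symbol.

ULS then relabels every coordinating atom: donors of the first metal get
element+digit labels (`N1`…`N6`), donors of the second metal element+letter
labels (`OA`…`OE`), the third lower-case letters, and later metals
letter+digit pairs — a deterministic generalization of the digit/letter
scheme beyond two metals, which is the only case the scheme was originally
spelled out for. Labels are globally unique, capped at 4 characters for
Amber compatibility, collisions advance the alphabet, and an atom bridging
two metals keeps its first label. With ULS on, the number of distinct
metal-vertex angle keys equals the number of topological metal-vertex
angles (15 for an octahedron); with ULS off they all collapse onto one key
— the degeneracy the strategy exists to remove.

## Topology, metals and limits

Bonds are perceived by the covalent-radius criterion
$d_{ij} \le t\,(r_i + r_j)$ with Cordero-style radii and a default
tolerance $t = 1.25$ (user-overridable; the radius table uses high-spin
values for Mn/Fe/Co). Pairs closer than 0.4 Å are rejected as overlapping.
Angles/dihedrals are enumerated purely from the bond graph with canonical
ordering so outputs are byte-stable. A metal is any element in the embedded
metal set; its coordination sphere is its bonded neighbor list (no
second-sphere distance shells). Two metals are *linked* if directly bonded
or sharing a bridging donor; linked groups larger than **four** metals are
rejected, matching the tool's stated multimetal limit. η-bonded rings are
handled as plain per-atom bonds to every ring atom within the distance
criterion (no centroid dummy atoms).

## Hybrid assembly and provenance

Per term: metal-involving bonds/angles always take the Seminario value;
otherwise a database hit wins; a miss falls back to the Seminario value and
is logged under `missing`. Metal-involving dihedrals are emitted as single
zero-barrier terms (PK = 0, PN = 1, phase = 0) rather than omitted, so MD
engines see a complete term list; organic dihedrals missing from the
database are likewise zeroed and flagged rather than aborting the run —
the only unresolvable situation (and hence an error) is a Lennard-Jones
type with no database entry and no element fallback. Metal LJ terms come
from an embedded UFF subset with the vdW distance halved (which lands
directly on Amber's $R_{\min}/2$ convention) and the well depth unchanged;
LJ parameters are never fitted. Every entry carries one provenance tag from
{`seminario`, `database`, `uff`, `zeroed`}, the tag sets are disjoint by
construction, and assembled keys exactly cover the topology term set.
Masses come from an embedded standard-atomic-weight table unless the
database provides MASS records. Dihedral records are written with the Amber
default 1–4 scalings (SCEE 1.2, SCNB 2.0), which the method leaves
unspecified.

The database reader accepts frcmod-style sectioned files
(MASS/BOND/ANGLE/DIHE/IMPROPER/NONBON). Wildcard dihedral keys are stored
verbatim but matched only exactly; improper records are accepted and
ignored (none are generated for metal centers).

## Restrained ESP charges

`fit_charges()` minimizes
$\sum_m \bigl(V_m - \sum_i q_i/r_{mi}\bigr)^2 + a\sum_i(\sqrt{q_i^2+b^2}-b)$
over a supplied ESP grid (potentials in atomic units, distances converted
to Bohr), subject to *exact* linear equality constraints: total charge,
per-atom fixed charges (e.g. pinning a metal at a desired formal-like
value such as +1.45 e), and intra-class equality for chemically equivalent
atoms found by iterated neighborhood refinement. The hyperbolic restraint
follows the standard RESP convention — strength $a = 0.0005$ a.u., width
$b = 0.1$ e, hydrogens unrestrained — handled by iterative reweighting of
a KKT system until $\max|\Delta q| < 10^{-6}$ e (cap 200 iterations). The
method's literature leaves one- vs two-stage fitting and the restraint
strength open; the default here is single-stage with both exposed as
options (`two_stage = TRUE` refits multi-member equivalence classes at
$a = 0.001$ with everything else frozen, a desk-scale rendition of the
two-stage convention). After convergence, fixed atoms are snapped exactly
to their targets and the solver's residual total-charge defect (~1e−12 e)
is spread uniformly over the free atoms, so conservation is exact; a fix
inside an equivalence class propagates to the whole class, and conflicting
fixes are rejected as infeasible. No quantum-mechanical ESP is ever
computed — grids are supplied or synthesized.

## What the synthetic generators emulate — and what they do not

The package's test bed is built entirely in code:

* `make_ideal_complex()` returns exact textbook coordination geometries
  (octahedral, square-planar, linear, a 3+5-donor bimetallic with a direct
  metal–metal bond, and a tris-bidentate octahedron whose chelate link is
  encoded as a direct donor–donor topology edge, since the idealized model
  omits the carbon backbone).
* `spring_model()` / `make_spring_hessian()` build the exact analytic
  Hessian of a harmonic network (per-bond stretching constant plus
  perpendicular stiffnesses), symmetric and translation-invariant by
  construction, with the interaction block of each bond equal to the
  spring block itself. On such Hessians the bond formula recovers every
  spring constant identically. The angle closed form
  $1/k_\theta = \sum 1/(R^2 k_\perp)$ holds exactly only when the
  perpendicular stiffness axes coincide with the angle plane: with an
  isotropic perpendicular constant the two perpendicular eigenvalues are
  degenerate and the absolute-projection sum depends on the arbitrary
  eigenbasis. The generator therefore supports anisotropic perpendicular
  constants (in-plane vs out-of-plane, drawn from disjoint ranges so
  eigenpairs are unambiguous), and the randomized oracle networks
  (`random_planar_star()`) are planar stars.
* `make_esp_grid()` samples shells at 1.4–2.0× an effective atomic radius
  and evaluates the exact Coulomb potential of known generating charges,
  giving an inverse problem with a known answer.

Passing these oracles demonstrates that the formulas, constraints and file
formats are implemented correctly. It does **not** demonstrate chemical
accuracy on real complexes: DFT Hessians are not spring networks (their
sub-blocks couple stretching and bending, and shared-atom effects bias
angle constants — the known Seminario limitation that motivated
modified-Seminario corrections, which this package does not implement),
real ESP grids carry basis-set and fit-region artifacts absent from a
Coulomb grid, and idealized geometries sidestep the conformational strain
of real ligands. Validation against ab initio dynamics is the task the
upstream QM/MD toolchain addresses and is out of scope here.

## Problem sizes and determinism

The shipped tests run idealized complexes of 3–10 atoms, 100 randomized
planar stars of 2–6 ligands for the force-constant oracles, and ESP grids
of 60–160 points — sizes chosen so every oracle is exact and the whole
suite re-derives its expectations from first principles in seconds.
Every generator takes an explicit seed; identical inputs produce
byte-identical outputs everywhere (canonical term ordering, fixed-width
writers, metal-first key ordering in frcmod files).

## Known limitations

* No modified-Seminario shared-atom correction; angle constants on real
  Hessians inherit the original method's bias.
* Dihedral force constants are never derived from the Hessian (the bonded
  model zeroes metal dihedrals by design).
* Base typing is a heuristic with an override hook, not a GAFF perception
  engine; database dihedral lookup is exact-key only (no wildcards).
* The Gaussian *log-file* Hessian layout is not parsed — only the
  formatted-checkpoint block, the ORCA `$hessian` section and the plain
  dense format.
* The `.lib` writer emits a minimal atoms+connectivity entry, not the full
  leap-internal table set.
* The embedded UFF table covers common metals only; absent elements
  require a manual Lennard-Jones entry.
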