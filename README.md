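# metalff

Automated Amber force-field parametrization for metal-containing molecules.

Transferable force fields (GAFF, Amber) have no parameters for metal
centers, and giving all donors of a coordination sphere one shared atom
type collapses chemically distinct metal terms onto a single entry,
distorting the geometry in MD. `metalff` builds a **bonded model** of the
metal center from quantum-chemical input:

* **Seminario force constants** — harmonic bond/angle stiffnesses from
  eigendecompositions of 3×3 interatomic sub-blocks of the Cartesian
  Hessian:
  `k_AB = Σᵢ (v̂ᵢ·û_AB)² λᵢ` for bonds, and for angles the series form
  `1/kθ = 1/(R²_AB Σᵢ λᵢ|û_PA·v̂ᵢ|) + 1/(R²_CB Σᵢ λᵢ|û_PC·v̂ᵢ|)`,
  converted to kcal/mol/Å² and kcal/(mol·rad²) and doubled for the Amber
  `K(x−x₀)²` energy form.
* **Unique labeling strategy (ULS)** — every metal-coordinating atom gets
  its own atom type (`N1…N6` for the first metal's donors, `OA…OE` for the
  second's), so every distinct metal bond/angle has its own parameter
  entry.
* **Hybrid assembly** — only metal-involving terms come from the Hessian;
  the organic scaffold keeps transferable database parameters (Seminario
  as a flagged fallback on misses); metal Lennard-Jones terms come from an
  embedded UFF table with the vdW distance halved; metal dihedrals are
  written as zero-barrier terms.
* **Constrained restrained-ESP charges** — least-squares fit to an ESP
  grid with a hyperbolic restraint and *exact* equality constraints: total
  charge, pinned per-atom charges (e.g. a metal at +1.45 e), and shared
  charges across chemically equivalent atoms.

Inputs: XYZ geometry; Hessian in Gaussian formatted-checkpoint, ORCA
`.hess` or plain dense-matrix form; charges as element/charge lists or
mol2. Outputs: `frcmod`, Tripos `mol2`, PDB (and optionally a minimal leap
`.lib`). Everything is deterministic: identical inputs give byte-identical
files.

## Worked example

An idealized octahedral Ru complex with six nitrogen donors at 2.10 Å and
an analytic spring-network Hessian (bond springs 0.25 Hartree/Bohr²,
perpendicular stiffness 0.05), so every expected number is known in closed
form:

```r
library(metalff)

cx  <- make_ideal_complex("octahedral")          # Ru + 6 N, metal at origin
m   <- spring_model(cx$geometry, cx$topology, k_bond = 0.25, k_perp = 0.05)
h   <- make_spring_hessian(m)

asg <- apply_uls(assign_base_types(cx$geometry, cx$topology), cx$topology)
asg$types
#> [1] "Ru" "N1" "N2" "N3" "N4" "N5" "N6"

sem <- all_metal_parameters(h, cx$geometry, cx$topology)
ps  <- assemble_parameters(cx$topology, asg, sem, cx$geometry)
ps
#> ff_parameter_set: 6 bond, 15 angle, 0 dihedral keys; 7 LJ types
#>   bonds     seminario:6
#>   angles    seminario:15
```

Each donor got its own type, so the 6 bonds and all 15 N–Ru–N angles have
their own entries (12 cis at 90°, 3 trans at 180°) — with a single shared
nitrogen type there would be exactly one bond key and one angle key. The
frcmod output starts:

```
BOND
N1-Ru         1120.439    2.1000
...
ANGLE
N1-Ru-N2          494.113    180.000
N1-Ru-N3          494.113     90.000
...
NONBON
  Ru       1.4815     0.0560
```

The bond constant is the spring constant put in: 2 × 2240.877 × 0.25 =
1120.44 kcal/mol/Å² (unit conversion and harmonic doubling), at the 2.10 Å
equilibrium distance. The Ru Lennard-Jones line is the UFF value with the
vdW distance halved (2.963/2 = 1.4815 Å, well depth 0.056 kcal/mol
unchanged).

Constrained charge fitting on a synthetic ESP grid generated from known
charges (total +2):

```r
grid <- make_esp_grid(cx$geometry, c(0.8, rep(0.2, 6)), 120, seed = 1)
fit  <- fit_charges(cx$geometry, grid,
                    restraint_spec(2L, fixed = c("1" = 1.45),
                                   classes = equivalence_classes(cx$topology,
                                                                 cx$geometry)))
round(fit$charges, 6)
#> [1] 1.450000 0.091667 0.091667 0.091667 0.091667 0.091667 0.091667
sum(fit$charges)
#> [1] 2
```

The metal sits exactly at its imposed +1.45 e, the six equivalent donors
share one fitted charge, and the total is conserved exactly.

A shell front end wraps the same pipeline
(`inst/scripts/metalff.R`):

```sh
Rscript inst/scripts/metalff.R parametrize \
    --xyz complex.xyz --hessian complex.hess --hessian-dialect orca \
    --out out --residue LIG --total-charge 2
Rscript inst/scripts/metalff.R charges \
    --xyz complex.xyz --grid grid.esp --constraints metal.cons --out out
```

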