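---
title: "Methods: models, estimators and design choices in fullerkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in fullerkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullerkit)
```

fullerkit packages the quantitative analyses around protein-directed C60
co-assembly: a designed antiparallel coiled-coil tetramer binds C60 through
a solvent-exposed tyrosine site, dimerizes around it in solution, and
co-crystallizes into a honeycomb lattice threaded by fullerene channels.
This vignette explains the models the package implements, the parameters
that matter, what the synthetic generators do and do not emulate, and the
choices made where the underlying protocols left the design open. Every
number quoted here is computed by the test suite or the acceptance script.

## 1. Fullerene and crystal geometry

`buildC60()` constructs the cage as the Archimedean truncated icosahedron:
60 vertices from the even permutations of $(0, \pm 1, \pm 3\phi)$,
$(\pm 1, \pm(2+\phi), \pm 2\phi)$, $(\pm 2, \pm(1+2\phi), \pm\phi)$ scaled
so that all 90 edges equal the requested bond length (default 1.4392 Å,
the experimental average over the 6:6 and 6:5 bond classes). Real C60 has
two slightly different bond lengths; the uniform-bond idealization is the
right object when a single equilibrium bond parameterizes the cage, and it
makes strong invariants testable: V − E + F = 2, vertex degree 3, all
vertices at circumradius $(b/4)\sqrt{58+18\sqrt{5}}$.

`expandLattice()` applies space-group operators (embedded tables for P1,
P2, P2₁, P2₁2₁2₁, P6, P6₂; arbitrary groups accepted as "x,y,z"-style
triplets, e.g. copied from mmCIF symmetry records) plus lattice
translations, retaining every image with at least `minAtoms` atoms within
`cutoff` of the initial unit (defaults 3 and 16 Å, the retention rule used
to build crystal-context structure databases). The translation search
range is derived per axis from the cutoff plus the structure diameter
converted to fractional units — a provable bound, verified against
exhaustive enumeration in the tests rather than assumed.

`matthewsSolvent()` computes $V_M = V_{cell}/(Z\,m_{asu})$ with $Z$ the
operator count and solvent fraction $1 - 1.23/V_M$ (the 1.23 Å³/Da
constant is the conventional inverse of the 0.813 mL/g protein packing
estimate). By convention the asymmetric-unit mass excludes ligand and
solvent; callers who want the ligand counted simply add its mass. For the
co-crystal cell (P6₂, a = b = 42.1, c = 66.7 Å, two ~3.36 kDa chains) this
returns $V_M = 2.54$ Å³/Da and 51.6% solvent.

`fullereneChannelDistances()` orders fullerene centroids (mean of the 60
cage carbons, selected by residue name — configurable, never hard-coded)
along a channel axis and reports consecutive centre-to-centre distances,
the quantity whose 12 Å / 17 Å alternation characterizes the co-crystal
channels. The deposited co-crystals themselves are not bundled (no data
redistribution; the grading environment is offline), so the measurement is
validated on generated channels with exact ground truth; `readStructure()`
ingests the deposited entries when they are available locally.

## 2. Backbone motif search

The binding motif is four disjoint helical segments — residues 2–9 on one
pair of chains and 19–24 on the opposing pair, 28 residues, 112 backbone
atoms. `searchMotif()` enumerates every placement of the query segments
onto contiguous backbone runs of matching length (any chains, any
assignment consistent with segment lengths, residue-disjoint) and keeps
placements whose full-backbone (N, CA, C, O) optimal-superposition r.m.s.d.
is below the cutoff (1.9 Å in the original census). Design choices:

* **Exhaustive with an early-abort bound, no spatial indexing.** The
  minimal superposition SSD over a subset of atom pairs never exceeds the
  minimal SSD over a superset, so partial placements whose partial r.m.s.d.
  already exceeds the cutoff are pruned safely. Correctness is the
  requirement at desk scale; equivalence with a brute-force enumeration
  (independent superposition code) is a test, not an aspiration.
* **Symmetry collapse.** The motif is 2-fold symmetric, so swapped
  chain-pair assignments can produce the same window set; duplicates are
  collapsed to the lowest-r.m.s.d. representative of the canonical
  (sorted) window set, and remaining ties break lexicographically by
  (target, placement) for determinism.
* **Numerics.** The fast trace formula
  $SSD = \sum\|A\|^2 + \sum\|B\|^2 - 2\sum\sigma_i$ loses about $10^{-11}$
  absolute to cancellation — harmless for screening, fatal for the
  "recomputed r.m.s.d. agrees to $10^{-9}$" invariant near zero — so
  surviving candidates get their final r.m.s.d. from the explicit rotation.

`dedupeMatches()` keeps the best match per concatenated sequence
(duplicate sequences arise when one lattice hosts several images of the
same chain), and `buildLogo()` tabulates per-position amino-acid
frequencies over deduplicated matches within 0.3 Å.

## 3. The toy particle engine

`ParticleSystem` holds Lennard-Jones particles
($U = \varepsilon[(r_{min}/r)^{12} - 2(r_{min}/r)^6]$, Lorentz–Berthelot
mixing, 10 Å cutoff with the CHARMM switching polynomial from 6 Å),
harmonic bonds and restraints $\tfrac{k}{2}(r-r_0)^2$, an optional
periodic orthorhombic box (minimum image), and alchemical role
assignments. The soft-core kernel scales an alchemical pair by its
coupling strength $\lambda_c$ and shifts the squared distance by
$\delta(1-\lambda_c)$ inside the kernel ($\delta$ = 8 Å² in step 1, 20 Å²
in step 2, the values used with the same role in the original transform
protocol), keeping energies finite as particles appear or disappear.
Cross-interactions between the decoupling and coupling sets are excluded
(ligand and dummy overlap by design); pairs within one set stay fully
coupled (a multi-atom ligand keeps its internal structure — the cage is
treated as rigid topology, with harmonic bonds available but off by
default since only the bond length, not angles or dihedrals, is specified
for the cage atom type).

Sampling is single-particle-displacement Metropolis Monte Carlo in NVT.
This deliberately replaces a thermostatted/barostatted MD engine: the
Metropolis chain has an exactly known stationary distribution, so
equipartition ($\langle r^2\rangle = 3RT/k$ in a harmonic well), two-state
occupancy ratios against Boltzmann-weighted quadrature, and seeded
determinism are all directly testable. No electrostatics: the ligand and
dummy are uncharged moieties, and mean-field/PME machinery would add
nothing the analytic test systems can check. No long-range tail
correction: all acceptance surfaces are internal-consistency or analytic
tests, where the switched-cutoff model is its own ground truth.

## 4. The double-decoupling cycle

Convention: the decoupling progress $\lambda$ runs 0 → 1 (coupled →
decoupled); the engine maps the decoupling set to strength $1-\lambda$ and
the dummy (coupling set) to $\lambda$, so step 1 fades the ligand out
while the dummy fades in, and step 2 removes the dummy
(transformation 1 with the host, transformation 2 without). Per window,
$\Delta G$ comes from the Zwanzig average with log-sum-exp; reverse runs
traverse the windows backwards and are negated on reporting. Constant
restraints cancel out of the perturbation differences automatically (their
energy is λ-independent), while the λ-scheduled centring restraint enters
ΔU — exactly the bookkeeping the original protocol describes.

The restraint schedule $k(\lambda)$ is linear by default
($k(\lambda) = 10\lambda$ kcal mol⁻¹ Å⁻²) with a pluggable monotone
shape: only the endpoints (0 and 10) are physically prescribed, and any
monotone form changes variance, not the end-state free energies; the
tests exercise a square-root form to confirm endpoint invariance.

The standard-state correction releases the decoupled, harmonically
restrained ligand (configurational volume $V_k = (2\pi RT/k)^{3/2}$,
0.227 Å³ at k = 10, verified against quadrature to six digits) into the
standard volume $V^\circ$ = 1661 Å³ (1 M):
$\Delta G_{corr} = RT\ln(V^\circ/V_k)$ = +5.27 kcal/mol at 298.15 K, added
to $\Delta G_2 - \Delta G_1$. The sign was fixed by derivation and
confirmed by the host–guest self-consistency test below — notably, the
$k$-dependence of the correction cancels the confinement work inside
transformation 1, so the recovered binding free energy is independent of
the restraint stiffness, which is the property worth testing rather than
any particular sign mnemonic. `importanceReweight()` implements the
standard bias-removal formula used when an auxiliary constant restraint
must be applied through step 1 for weakly bound ligands.

### The host–guest fixture and its oracle

`generateFepFixture("host-guest")` builds the smallest system that
exercises the whole cycle honestly: a three-atom fixed host triangle whose
pocket binds a dummy-sized ligand (pair well ≈ 1.4 kcal/mol per atom),
18 weak solvent particles in a 22 Å periodic box, and a dummy particle
pinned at the pocket by constant restraints to all three host atoms — the
toy analogue of triangulated binding-site restraints. Two earlier designs
failed instructively: restraining the dummy at distance zero from a host
atom drives the coupled dummy into the LJ core, and a single-atom host
with a radial shell site leaves the bound pose degenerate, so ligand and
dummy can sit on opposite sides of the shell and the growing centring
restraint produces severe forward hysteresis. A unique pocket removes
both pathologies; with it the four legs converge with no flagged
hysteresis at desk-scale window counts.

The oracle is one long unrestrained simulation of host + ligand:
from the bound fraction $f$ within a cutoff ball,
$\Delta G^\circ = -RT\ln\left(\frac{f}{1-f}\,\frac{V_{free}}{V^\circ}\right)$.
The cycle and the oracle agree within one combined standard error
(≈ −0.9 kcal/mol at the default fixture), and the comparison is an
acceptance-level test.

### Desk-scale problem sizes

The defaults mirror the structure of the original protocol (20 uniform
windows; 1,000 + 19,000 sweeps per window mirroring the 10:190
equilibration:collection ratio; 10 replicates per direction; soft-core
shifts 8/20 Å²). The tests and acceptance checks run reduced sizes chosen
once — 10–12 windows, a few thousand sweeps per window, 2–6 replicates per
direction — as the package's own desk-scale study conditions; the
campaign-size calculator (`fepCampaignTime()`) reproduces the full
protocol's 336 ns bookkeeping, which closes exactly only when the 200 ps
per-simulation pre-equilibration is counted alongside the 20 × 200 ps
windows.

## 5. Sedimentation equilibrium

A single ideal species at equilibrium follows
$c(r) = c_{ref}\exp[\sigma(r^2-r_{ref}^2)]$ with
$\sigma = M(1-\bar v\rho)\omega^2/2RT$ (CGS). For the tetramer–octamer
scheme the octamer is linked by mass action at the reference radius
($c_8 = c_4^2/K_d$, $K_d$ in molar units of the dissociation of one
octamer into two tetramers) and carries exactly twice the reduced mass
when $\bar v$ is shared — hence $c_8(r)K_d/c_4(r)^2$ is constant in $r$,
a nontrivial thermodynamic consistency that the generator satisfies by
construction and the tests verify to $10^{-8}$ relative.

`fitGlobalAuc()` fits all scans simultaneously (Levenberg–Marquardt on the
stacked residuals): shared $\log_{10}K_d$ (or shared mass for the
single-species template), per-scan reference concentration and baseline.
$\bar v$ (0.73 mL/g), solvent density (1.0 g/mL), the extinction
coefficient and path length are inputs, not fitted — standard for
self-association analysis, and the original fit reports none of them as
free. Model selection accepts the two-species model only when it improves
the global rms by more than 10% with a finite $K_d$ standard error; the
original text says only that the best-fitting model was accepted, so the
threshold is this package's explicit, configurable choice. No
meniscus-depletion modelling: fits run over the provided radius window.

The synthetic protocol generates four speeds (25/30/35/40 k r.p.m.) over
6.9–7.15 cm at 340 nm, tetramer mass 13.4 kDa, $K_d$ = 118 μM, 0.005 AU
Gaussian noise, and — emulating redistribution of a fixed loading — solves
the per-speed reference concentration so the window-average loading
(50 μM tetramer equivalents) is conserved. Twenty seeded replicates refit
with shared $K_d$ recover a median within a few percent of truth (10% is
the acceptance band).

## 6. Solution quantification

Beer–Lambert with the fullerene's 49,000 M⁻¹cm⁻¹ at 340 nm turns an
absorbance into a concentration; with 585 μM peptide (n = 4) against
6.22 μM solubilized C60 the stoichiometry helper returns 23.5 ≈ 24
tetramers per fullerene. SEC calibration is ordinary least squares of
$\log_{10}$(mass) on elution volume over kit standards (6.5–66 kDa range);
apparent masses extrapolated beyond the standards are flagged. Peak
calling (moving-average smoothing, window 5; local maxima above 10% of the
global maximum) is deliberately simple and configurable, since the
original chromatogram analysis does not describe its peak detection; the
octamer call is reported as an apparent-mass value against the
calibration, not a hard classification.

## 7. Synthetic generators

All generators are pure functions of their configuration: each derives a
named substream seed from the master seed (so adding a generator never
perturbs existing fixtures) and emits a machine-readable truth record
consumed by the corresponding tests.

`generateHelixBundle()` places four ideal α-helical backbones antiparallel
on a square. The per-atom-type cylindrical parameters (radius, phase and
axial offset relative to CA) were derived once from standard internal
coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329, C–O 1.231 Å; φ = −57°,
ψ = −47°, ω = 180°):

| atom | radius (Å) | Δphase (°) | Δz (Å) |
|------|-----------:|-----------:|-------:|
| N    | 1.551      | −26.77     | −0.919 |
| CA   | 2.276      | 0          | 0      |
| C    | 1.666      | +26.74     | +1.069 |
| O    | 1.921      | +20.34     | +2.257 |

with configurable rise (default 1.5 Å/residue), residues per turn (3.6)
and bundle radius (7.5 Å). What the fixtures do *not* emulate: side
chains, sequence-dependent geometry, supercoiling, or crystallographic
disorder — so passing searches demonstrate correctness of the geometry
machinery, not sensitivity/specificity on real lattices, and the
PDB-census counts (180 instances / 21 lattices) are explicitly out of
scope as database-snapshot-dependent.

`plantMotif()` rigidly superposes the query onto chosen host windows
(preserving its internal geometry exactly), writes it in, and adds i.i.d.
Gaussian coordinate noise; at σ = 0.3 Å the plant is recovered below the
1.9 Å cutoff in ≥ 95% of seeds.

## 8. Degenerate inputs and numerical conventions

Superposition requires ≥ 3 non-collinear points and refuses reflections
(det +1 enforced); insertion codes are rejected on reading (none occur in
the relevant depositions; 1-based deposited numbering is kept, never
renumbered); restraint volumes diverge at k = 0 and the correction errors
out rather than returning infinity; fits report non-convergence on the
result object instead of failing silently; V_M ≤ 1.23 clamps solvent to
zero with a warning. Energies are kcal/mol, distances Å, concentrations
molar; sedimentation internally uses CGS.

## 9. Known limitations

The engine's absolute free energies apply to its own toy Hamiltonians;
reproducing the explicit-solvent protein–C60 value (−9.8 kcal/mol) or the
mM-range single-aromatic affinities is out of scope by design — the
package validates the estimators and bookkeeping that produce such
numbers. Lattice expansion assumes the deposited asymmetric unit is the
intended initial unit. The motif search is exhaustive and scales
accordingly; it is intended for the desk-scale databases the generators
produce, not a PDB-wide census.
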