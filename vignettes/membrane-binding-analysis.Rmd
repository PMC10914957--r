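---
title: "Characterizing amyloid-beta(1-40) binding to a mixed bilayer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing amyloid-beta(1-40) binding to a mixed bilayer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membind)
```

## The problem

Amyloid-beta peptides damage neuronal membranes, and the 40-residue form
(Aβ40) is the most abundant species in vivo. Molecular-dynamics ensembles of
one Aβ40 monomer near a POPC/POPS/cholesterol (3:1:1) bilayer can resolve
*how* the peptide binds: which residues anchor it, how deeply they insert,
what secondary structure the bound peptide adopts, and how many distinct
binding modes coexist. `membind` implements the full analysis chain for such
ensembles — trajectories in, tables of contacts, depths, hydrogen bonds,
secondary structure, free-energy basins and binding-model labels out — plus
a synthetic-data generator that plants known ground truth so every stage can
be validated without any simulation.

The peptide sequence is divided into four functional regions used
throughout: the hydrophilic N-terminus NT (residues 1–16), the central
hydrophobic core CHC (17–21), the central loop CL (22–29) and the
hydrophobic C-terminus CT (30–40).

## The procedure and its assumptions

**Geometry.** All coordinates are nm; the membrane normal is the z axis
(the standard convention of membrane builders). Distances respect the
orthorhombic minimum-image convention; triclinic boxes are rejected.
Molecules are assumed whole (not wrapped across the boundary) — centers of
mass are computed directly, without re-wrapping heuristics, because
re-wrapping is error-prone and the supported inputs are generated whole.

**Contacts.** A peptide–bilayer contact is a pair of *heavy* atoms, one in
the peptide and one in any of the three lipid species, within 0.5 nm
(closed cutoff: a pair exactly at the cutoff counts; this is documented so
oracle tests are unambiguous). Water and ions are not part of the
"bilayer" selection. The production path uses a cell list; an O(N²) brute
force is retained as an independent second route and the two must agree
exactly — this dual-route check is one of the acceptance criteria.

**Distances and depths.** The peptide–bilayer distance is the absolute
z-separation of the two centers of mass. A residue's insertion depth is its
perpendicular COM distance from the bilayer COM minus a fixed half
thickness of 2.0 nm; negative depths are below the surface. The half
thickness is deliberately a constant, not an instantaneous phosphate plane:
the analysis protocol states a fixed 2 nm and a fluctuating definition
would change the meaning of "buried" between frames.

**Hydrogen bonds.** Geometric criterion: donor–acceptor heavy-atom
minimum-image distance ≤ 0.3 nm *and* the angle between the D→H and D→A
vectors ≤ 20° (the common VMD-style convention; the alternative D–H···A ≥
160° convention is switchable via `hbond_angle_convention = "dha"`).
Donors/acceptors are assigned by residue-type rules (backbone N–H and C=O,
side-chain N/O by chemistry, water O–H, lipid oxygens, the POPS amine and
the cholesterol hydroxyl). Methionine sulfur is excluded as an acceptor by
default (a weak acceptor; switchable). Both donation directions
(peptide→lipid and lipid→peptide) count and are summed. Both cutoffs are
closed with a 1e-9 guard so exactly-at-boundary geometry is kept despite
floating-point representation.

**Secondary structure.** A DSSP-style assignment from Kabsch–Sander
backbone hydrogen-bond energies (bond when E < −0.5 kcal/mol): two
consecutive n→n+4 turns give H, n→n+3 G, n→n+5 I; bridge patterns give E
(extended ladders) or B (isolated bridges); hydrogen-bonded turn interiors
give T; everything else C. Missing amide hydrogens are rebuilt 0.101 nm
from N opposite the bisector of the C(i−1)→N and CA→N bonds. DSSP was
chosen over STRIDE because its algorithm is fully specified in the
literature and therefore reproducible bit-for-bit; divergence from STRIDE
on edge residues is accepted. Consequently the validation targets are
*recovery of planted ideal geometry*, not agreement with any particular
STRIDE build. The seven classes group into unstructured (C+T+B), beta (E)
and helix (G+H+I); beta content is #E/40.

**Free-energy landscapes.** G = −kT ln P over binned collective variables,
shifted so the occupied-grid minimum is 0. kT is the native unit
(dimension-safe for unlabeled plots); kcal/mol uses k = 0.0019872
kcal/(mol·K) at the configured temperature (default 343 K, giving
1 kT = 0.6816 kcal/mol). Empty bins are masked and written as `NA`, never
±Inf. Basins are 8-neighbourhood local minima of the occupied grid,
filtered by depth (retain G ≤ min + `basin_min_depth_kT`) and pairwise grid
separation; every occupied bin joins a basin by steepest descent, and
descents ending in a discarded minimum join the nearest retained one.
Labels a, b, c, … follow descending distance coordinate, then ascending G.
Per-basin landscapes over (heavy-atom RMSD to a reference, beta content)
yield microstates, split into a high-beta group "x1" and a low-beta group
"x2" at a mean beta of 0.20 — the midpoint between the moderately beta-rich
(10–30 %) and beta-rich (30–50 %) binding modes.

**Bound/unbound and the four binding models.** A frame is bound iff it has
at least one peptide–bilayer contact. Bound frames pass a deterministic
first-match rule cascade:

| label   | rule |
|---------|------|
| model4  | ≥50 % of CHC and of CT buried, beta < 10 %, helix < 10 % |
| model3  | ≥50 % of CT buried, beta in [10 %, 30 %) |
| model1  | beta in [30 %, 50 %], buried residues only in CT, 2–15 contacting residues |
| model2  | NT helix fraction ≥ 20 %, no residue deeper than −0.2 nm, 2–15 contacting residues |
| otherwise | unclassified |

The beta and burial windows are stated quantitatively in the source
protocol; the model-2 "surface-lying" thresholds (20 % NT helix, −0.2 nm)
are this package's quantification of a qualitative description and live in
the configuration, not in stage code, so they are auditable and sweepable.

**REST2 diagnostics.** The effective-temperature ladder is geometric,
T_i = T_min · exp(i · ln(T_max/T_min)/(N−1)) with i = 0…N−1, so the
endpoints are exact (e.g. 18 rungs spanning 343–500 K). Exchange logs are a
package-defined plain-text dialect (`time_ps i j accepted`); diagnostics
report per-pair acceptance (both the over-pairs and the over-replicas
average, since the field uses both conventions), rung visitation and round
trips. No simulation or Hamiltonian scaling is performed.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `contact_cutoff` | 0.5 | nm | stated heavy-atom contact criterion |
| `hbond_da_cutoff` / `hbond_angle_cutoff` | 0.3 / 20 | nm / deg | stated H-bond criterion |
| `half_thickness` | 2.0 | nm | stated membrane half thickness |
| `temperature` / `kB` | 343 / 0.0019872 | K / kcal mol⁻¹ K⁻¹ | analysis replica temperature |
| `fel_bins_distance` × `fel_bins_contacts` | 0.05 × 10 | nm × count | resolves minima ~0.7 nm apart; the protocol states no widths |
| `fel_bins_rmsd` × `fel_bins_beta` | 0.05 × 0.025 | nm × fraction | per-basin grids |
| `basin_min_depth_kT` / `basin_min_separation_bins` | 1.0 / 2 | kT / bins | basins were identified visually in the source; exposed here |
| `equilibration_discard` | 200 | ns | stated transient discard |
| `longrange_min_separation` | 3 | residues | stated long-range pair rule |
| `microstate_beta_threshold` | 0.20 | fraction | midpoint of the 10–30 % / 30–50 % windows |
| `frame_spacing` | 1 | ns | PDB models carry no time stamps |

## What the synthetic generator emulates — and what it does not

`generate_binding_ensemble()` builds a coarse two-leaflet bilayer
(54 POPC / 18 POPS / 18 CHOL per leaflet on a jittered 0.65 nm lattice,
head-group oxygen clusters at ±2 nm from the center, ~6–10 heavy atoms per
pseudo-lipid) and poses an ideal-geometry peptide template in every frame
with a random rotation about z and truncated Gaussian rigid-body noise
(σ = 0.05 nm, hard cut ±0.1 nm). Templates plant, per binding model, the
region depths, sheet/helix content and contacting-residue counts that the
classifier rules require, with margins larger than the noise truncation, so
label recovery is a deterministic property of the stated world rather than
a statistical accident. Planted hydrogen bonds relocate one lipid headgroup
oxygen to the exact detection geometry (0.28 nm, 0° — inside both closed
cutoffs with margin).

Three idealizations matter when interpreting green tests. First, sheet
templates are *rigid assemblies*: strands are ideal-dihedral segments
stacked at offsets calibrated once (by grid search over the inter-strand
translation, maximising Kabsch–Sander E recovery) and connected by
geometrically inert linkers; linker backbone geometry is not physically
relaxed. Second, the truth labels for secondary structure mark only
strand/helix *interiors* — the first and last residue of an ideal fragment
is a turn/bridge edge by the DSSP definitions, so counting it as planted
helix/strand would be over-claiming. Third, there is no water box, no lipid
internal flexibility and no force field: a green classifier-recovery test
establishes that the analysis chain measures planted geometry correctly,
*not* that the four binding modes are thermodynamically correct for real
Aβ40 — the source ensembles required microseconds of replica-exchange
sampling that desk-scale synthesis cannot and does not emulate.

## Numerical choices

* Closed cutoffs everywhere, with a 1e-9 guard on the H-bond criteria
  (boundary geometry is representable only approximately in binary).
* Kabsch superposition handles the reflection case by flipping the
  smallest singular direction; collinear inputs are rejected rather than
  silently returning a reflection.
* Ranking ties (long-range pairs, H-bond types) break lexicographically,
  so every ranking is deterministic across runs and platforms.
* Basin assignment memoises steepest-descent paths; discarded shallow
  minima re-attach by grid distance, then depth.
* Degenerate inputs: a single occupied FEL bin is a valid landscape
  (G = 0); zero-population basins get `NA`, never Inf; an empty
  time-window result is a warning for library callers and a hard abort in
  the pipeline.
* One RNG stream per generator call, seeded explicitly; identical seeds
  give bit-identical ensembles, logs and reports (the end-to-end
  byte-identity is an acceptance criterion).

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* The bilayer surface is a fixed plane at ±2 nm; curvature, thickness
  fluctuations and per-leaflet analyses are out of scope.
* DSSP edge behaviour differs from STRIDE on fragment termini; chain
  termini are never assigned interior helix.
* No reweighting across REST2 replicas (MBAR/WHAM) and no kinetic models;
  analyses assume the lowest-temperature continuous trajectory.
* The exchange-log dialect is package-defined; converting
  GROMACS/PLUMED-native logs is a documented non-goal.
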