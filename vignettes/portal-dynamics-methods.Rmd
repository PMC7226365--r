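---
title: "Methods: portal occupancy, rotamer and protonation analytics"
author: "portaldyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: portal occupancy, rotamer and protonation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portaldyn)
```

`portaldyn` post-processes molecular-dynamics trajectories of proteins
whose antigen-binding groove opens through a portal between two
α-helices, the CD1d α1/α2 architecture being the motivating case. This
vignette is the package's own account of the methods: the conventions
each computation commits to, the parameters that matter, what the
synthetic generators do and do not emulate, and where design decisions
were genuinely open.

## Trajectories, selections and conventions

A trajectory is a topology (atom table with PDB-style names and per-atom
van der Waals radii) plus an `n_atoms x 3 x n_frames` coordinate array in
Å. Residue numbers are taken verbatim from the input file and never
renumbered, so selections such as `resid 60-88` mean the same thing in
the package as in the source structure; all residue ranges are inclusive
on both ends. The default time step is 0.04 ns per stored frame — the
2500-frames-per-100-ns convention of the production runs this package
targets — and is configurable everywhere.

Radii default to the Bondi set, shipped as a CSV
(`inst/extdata/radii_bondi.csv`) so any force-field-specific radius table
can be substituted; the upstream scripts this workflow descends from do
not document their radii, so the choice is deliberately explicit and
user-replaceable. Hydrogens are kept when present. Geometric analyses
that the field computes over heavy atoms (side-chain RMSD) select
non-hydrogen atoms by default; occupancy and SASA use whatever the
selection resolves to, because whether hydrogens were included upstream
is unknowable — both behaviours are flags, not assumptions.

PDB I/O goes through `bio3d`; DCD files are read by `bio3d` and written
by a minimal single-precision CORD writer (no unit cell, no fixed
atoms). PDB coordinates carry three decimals and DCD is float32, so
round-trip agreement is asserted at 10⁻³ Å, the format precision.

## Fractional occupancy maps

Grid points are lattice points: point (i, j, k) sits at
`origin + spacing·(i, j, k)`. Per frame, a point is occupied iff it lies
within the van der Waals sphere of at least one selected atom, with the
sphere boundary counting as inside (closed inequality, plus a 10⁻¹²
guard so exact lattice/radius coincidences are stable under roundoff).
The published description does not fix the boundary convention; fixing
it closed makes brute-force oracle tests exact, and the test suite
verifies bit-equality against a plain triple-loop oracle on instances up
to 15³ points × 10 atoms.

Averaging binary fields over frames gives per-point fractions whose
product with the frame count is an integer by construction. Iso-volumes
at a threshold θ are the point sets with value ≥ θ; the reported volume
is `n_points × spacing³`, a point-counting estimator, documented as such
(no marching-cubes surface is attempted — rendering is the viewer's
job). Defaults: spacing 0.5 Å, matching the common electrostatics-grid
convention (a 64 Å cube then has 129 points per axis), padding 2 Å
beyond the largest radius when auto-gridding over all frames. Atoms
whose spheres leave the grid contribute nothing and raise one counted
warning rather than an error, since auto-gridding normally prevents the
situation. Maps serialise to OpenDX scalar grids
(`object 1 class gridpositions`, z-fastest data order), the dialect
molecular viewers read.

## SASA, hydrogen bonds, smoothing

SASA is Shrake–Rupley: `n_points` test points per atom on the sphere of
radius r + 1.4 Å, exposed iff strictly outside every other context
atom's expanded sphere, area = exposed fraction × 4π(r + probe)². Two
deliberate choices: the point set is a deterministic golden-spiral
(Fibonacci) lattice, so results are bit-reproducible at fixed
`n_points`; and the exposure test is strictly exterior, so the
degenerate duplicate-atom case buries both copies — documented behaviour
instead of sampling-order luck. At the default n = 960 an isolated
sphere is within 1% of 4πr²; tests also check 2% agreement against an
independent 10⁵-point recomputation, additivity over well-separated
clusters, and monotonicity under added context atoms. Whether a bound
ligand should occlude the protein selection is a scientific choice, so
the context selection is an explicit argument (default: all atoms).

Hydrogen bonds use D···A ≤ 3.5 Å and D–H···A ≥ 140° when an explicit H
is attached to the donor (attachment = same residue, ≤ 1.25 Å in frame
1); donors without hydrogens fall back to the distance criterion alone
and the series is flagged. The criteria are the common
visualisation-tool defaults and fully configurable — the upstream
workflow does not state its cutoffs.

Savitzky–Golay smoothing defaults to a 3rd-degree polynomial on 51-frame
windows, the published smoothing of 2500-frame series. Interior points
use the exact central least-squares coefficients
(`signal::sgolay`); edges are handled by mirror padding, which keeps the
series length fixed and endpoint bias low — the edge policy is unstated
upstream, so it is ours and is recorded in the smoothed series'
metadata. A degree-3 filter reproduces any cubic signal at interior
points to ≤ 10⁻⁸ relative error, which the tests assert.

## χ1 rotamers

χ1 is the IUPAC-signed torsion N–CA–CB–CG, mapped to (−180°, 180°];
CG1/OG/OG1/SG are accepted as γ atoms for the branched/oxygen/sulfur
side chains. Statistics are circular, not arithmetic: mean = argument of
the mean resultant vector, deviation = √(−2 ln R̄). For a tight unimodal
trace the circular values agree with arithmetic ones to well under 0.1°,
so tabulated means are directly comparable, while traces that cross the
±180° wrap (trans rotamers do constantly) remain correct — whether the
published tables used arithmetic or circular averaging is unstated, so
the choice is flagged in output metadata.

Classification assigns the nearest of +60° (g+), 180° (trans), −60°
(g−) by circular distance, partitioning the circle into three 120°
arcs; exact ties (0°, ±120°) break toward trans, a documented
convention. Change detection labels every frame and records a change
when a *new* label persists for ≥ `dwell` frames; the default dwell of
50 frames (2 ns) separates rotamer jumps from librational spikes.
Side-chain RMSD superposes each frame onto frame 1 over a fit selection
(default: all CA atoms; the upstream superposition protocol is unstated)
and measures heavy side-chain atoms beyond the backbone, CB included.

## Consensus pKa and protonation

Predictor outputs (Propka/H++/Rosetta-class tools are upstream; their
tables are inputs here) are merged per residue by the rule: find the
largest subset of methods whose values all pairwise agree within ±0.1
pKa units; if it has ≥ 2 members the residue is resolved to the subset
mean, else unresolved. The agreement test is published; the combination
rule is not, so "largest pairwise-agreeing subset, ties to the smaller
spread" is this package's documented resolution of three-way near-ties
(exhaustive subset enumeration is exact at 3–5 methods). Unresolved
residues fall back to flagged model values (Asp 3.65, Glu 4.25, His 6.3,
Tyr 9.8, Lys 10.4, Arg 12.0) rather than disappearing, because a library
needs defined behaviour where a paper can silently restrict itself to
resolvable cases.

Protonation at pH is the closed test pKa ≥ pH for every titratable
type; the per-type charges are Asp/Glu/Tyr 0 (protonated) / −1, His +1
(protonated) / 0, Lys/Arg +1 throughout [0, 14]. One source-text wrinkle
deserves a note: the prose description of the His rule in the upstream
text inverts the inequality, but its own worked net-charge arithmetic
(+1 at pH 7 with neutral histidines of pKa ≈ 6; +8 at pH 4.5 with those
histidines protonated) requires pKa ≥ pH, which is also the chemically
meaningful direction; the arithmetic wins. Every rule is monotone in pH,
so net charge is non-increasing in pH — asserted as a property test.
Net charges count side chains only (termini excluded by default, by
flag otherwise). PQR export places each residue's integer formal charge
on a documented representative atom (OD2/OE2/NE2/OH/NZ/NH1), all other
atoms 0, so the file's charge sum equals the assignment's net charge
exactly; this module prepares charge *states*, not force-field partial
charges.

## Helix assignment and segmentation

Backbone hydrogen bonds are scored with the Kabsch–Sander electrostatic
model, E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol,
accepted below −0.5 kcal/mol; distances under 0.5 Å short-circuit to +∞
(clash guard). Missing amide hydrogens are placed 1.0 Å from N, anti to
the preceding carbonyl; chain breaks (C–N > 2.5 Å), prolines and chain
starts get no H and are flagged. Two consecutive (i, i+4) bonds make
residues i..i+3 helical — only the α pattern is implemented, since the
target tables report helix spans, not 3₁₀/π distinctions. Segmentation
inside a region returns maximal helical runs plus the interior
non-helical residues as hinges, and renders/parses the
"139‒150 + 153‒177" text notation. Externally computed per-residue
assignments can be ingested in place of the internal criterion, which
keeps the segmentation logic testable against reference tools.

## Structure comparison

Superposition is Kabsch via SVD with the reflection correction
(det = +1 always). Pairing across structures is by (residue number,
atom name) only — no sequence-independent alignment is attempted — with
unmatched atoms dropped and counted. The pairwise-RMSD matrix plus a
classical (Torgerson) MDS embedding is a deliberate surrogate for
elastic similarity scores of structure-comparison servers: those
heuristics are out of proportion to their role here, and the qualitative
clustering claim the embedding supports is reproducible with RMSD + MDS
on rigid or near-rigid families. The MDS double-centres −D²/2,
eigendecomposes, keeps the top-2 non-negative eigenpairs (eigenvalues at
numerical-noise scale are zeroed so flat axes come out exactly flat),
and fixes each axis' sign by the first non-zero coordinate, making the
embedding deterministic. Exactly-2D-embeddable matrices are reproduced
to 10⁻⁹, and a test cross-checks the implementation against
`stats::cmdscale`. Both backbone {N, CA, C, O} and CA-only modes exist
because "backbone RMSD" is ambiguous about O in the source material.

## Synthetic systems: what they emulate, what they do not

The generators are kinematic, not dynamical: no force field, thermostat
or solvent. They prescribe exactly the observable the analysis stage is
supposed to recover, which is what makes them usable as oracles, and
they are pure functions of (parameters, seed) — the session RNG state is
saved and restored, and identical inputs give bit-identical outputs.

- `build_ideal_helix` places a polyalanine N/CA/C/O/CB backbone by
  sequential internal-coordinate (NeRF) construction with bonds
  1.46/1.52/1.33 Å (N–CA/CA–C/C–N), angles 111°/117°/121°, ω = 180°, all
  recorded in one constants table. At φ = −57°, ψ = −47° it yields
  CA–CA ≈ 3.8 Å, rise ≈ 1.5 Å and O(i)···N(i+4) ≈ 3.1 Å; the built
  torsions invert to the inputs within 10⁻³°. The geometry is
  self-consistent textbook geometry, not CHARMM-exact.
- `build_portal_trajectory` sets two such helices parallel to z at
  separation d(t) per the aperture schedule plus per-atom Gaussian noise
  of the scheduled σ. It emulates the *geometry* of a breathing portal —
  separation, SASA growth, occupancy dwell — not its energetics or the
  side-chain packing of a real portal.
- `build_rotamer_trajectory` re-places a single CG atom each frame so
  the measured χ1 equals the scheduled target plus von Mises noise.
  Angular noise is von Mises (wrapped), not Gaussian, to stay on the
  circle. The default test scenario — g+ for 1499 frames, g− for 1001,
  κ = 40 (≈ 9° dispersion) over 2500 frames at 0.04 ns/frame — mirrors
  the switch-at-60-ns phenomenology that motivates the change detector.
- `build_pka_tables` adds per-method Gaussian noise to true values and,
  with a set probability, displaces a prediction by ≥ 1 pKa unit; the
  consensus rule must reject these outliers.

Passing tests on these systems demonstrates that each computation
recovers a known ground truth under controlled noise. It does not
demonstrate anything about force-field accuracy, sampling convergence,
or the biology of any real trajectory — those questions live upstream of
this package.

## Numerical choices and problem sizes

Tolerances are stated where the convention is ours: occupancy boundary
ties closed with a 10⁻¹² guard; SASA asserted at 1% (analytic sphere)
and 2% (independent dense oracle); Savitzky–Golay cubic invariance at
10⁻⁸ relative; MDS exact-embedding recovery at 10⁻⁹; PDB/DCD round
trips at the 10⁻³ Å format precision. Degenerate inputs are errors with
named culprits (collinear dihedrals, < 3 or collinear fit atoms,
duplicate atom keys, atom-count mismatches with the frame index) or
flagged fallbacks (missing amide H, donors without H, unresolved pKa,
missing PQR representative atoms).

The test suite runs entirely on generated systems sized for exactness
rather than scale: occupancy oracles at ≤ 15³ points × 10 atoms, SASA
oracles at 6 atoms × 10⁵ points, rotamer schedules at 2500 frames,
portals at 6–8 residues per helix and ≤ 30 frames, the rotation-grid
Kabsch oracle at 4 points. These sizes are the package's choice: small
enough to brute-force, large enough that every code path (streaming
accumulation, windowed smoothing, dwell filtering) is exercised.

## Known limitations

- Occupancy volumes are point counts, not meshed surfaces; at coarse
  spacing the estimator is blocky near curved boundaries.
- The helix module implements only the α (i, i+4) pattern; kinked
  helices containing genuine 3₁₀ turns will show as hinges.
- H-bond detection without explicit hydrogens is distance-only and
  correspondingly permissive.
- Structure pairing is by residue number; renumbered or mutated
  structures must be reconciled upstream.
- The MDS surrogate preserves metric structure of RMSDs, not the
  alignment-based similarity of elastic scores; embeddings of flexible
  families should be read as qualitative.
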