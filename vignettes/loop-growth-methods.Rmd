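---
title: "Distance-guided chain growth for protein loops: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-guided chain growth for protein loops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, and what passing the
package's tests does and does not demonstrate about real data.

## The problem

A loop is an irregular backbone segment between two fixed anchors — the C
atom of the residue before it and the N atom of the residue after it. Loop
modeling asks for an ensemble of conformations that (i) close exactly onto
the anchors with ideal covalent geometry, (ii) avoid steric clashes with
the protein body and themselves, and (iii) can be ranked so that low-energy
members are close to the (unknown) native conformation. Accuracy is
measured as fixed-frame backbone RMSD over N, CA, C, O — no superposition,
because the protein body is held fixed and displacement relative to it is
an error.

## Sequential chain growth with distance guidance

The loop grows N-to-C one residue at a time. With rigid bond lengths and
angles, the next backbone atom is confined to a circle around the previous
bond axis; what remains free is a dihedral. Rather than sampling the
dihedral directly, the growth samples the atom's *distance to the
C-terminal anchor* from an empirical conditional density and intersects the
circle with the anchor-centered sphere — at most two points, chosen with
equal probability. This bends growth toward closure: the empirical
distances encode how native loops approach their anchors.

The conditional density is a 2D Gaussian KDE over pairs (d_prev, d_new)
collected per residue separation g (the count of loop residues from the one
being placed through the last one). Two models are fitted per g: placing C
given the current CA distance, and placing the next CA given the C
distance. The N between them carries a trans peptide omega drawn from
N(180°, sigma). Fitting details:

* distances are Winsorized at the 99th percentile per axis before fitting
  (configurable; tames the long tail without deleting observations);
* the bandwidth matrix is diagonal with Scott's rule for two dimensions,
  h_i = sigma_i n^(-1/6) (variance-based, matching the diagonal structure
  of the bandwidth; a scale factor is exposed);
* the density is evaluated on a 32 x 32 grid spanning the Winsorized data
  range padded by two bandwidths per axis, and interpolated bilinearly;
  outside the grid the density is zero;
* the conditional slice at d_prev is the bilinear interpolation between the
  two nearest grid columns, sampled *exactly* as a piecewise-linear density
  (inverse CDF with a quadratic within-cell solve) — the test suite holds
  the sampler to a Kolmogorov–Smirnov check against the analytic slice CDF;
* a slice with no mass (d_prev far outside the fitted domain) falls back to
  the d_new marginal;
* separations longer than the largest fitted g reuse the largest-g model;
  separations whose pair sets are degenerate (g of 1–2 is geometry-bound in
  ideal chains) are simply not fitted — they are the closure's job anyway.

A sampled distance can be geometrically unreachable from the current
placement circle; the sampler redraws a few times (8) before discarding the
trial. On the final growth step the new CA is the closure pivot, so trials
whose anchor distance exceeds the tripeptide reach bound
(2 x 3.81 Å + 2.43 Å, minus a margin) are discarded immediately — a
necessary condition for closure, checked before any expensive work.

Per step, m = 32 trials are generated, k = 8 survive a filter that draws
without replacement proportional to a residue-typed (phi, psi) frequency
table (10° bins, pseudocount 10^-6 of the total mass), and one of the k is
selected with probability proportional to exp(-E/T) where E is the fragment
energy of the four new backbone atoms. Trials whose atoms leave the loop
ellipsoid, or whose backbone atoms clash with the environment or the
already-grown chain, are discarded outright — a backbone clash cannot be
repaired by any later stage, so allowing such trials only wastes restarts.
m, k, T and the omega sigma are configuration keys recorded in run
metadata; defaults m = 32, k = 8, T = 1, sigma = 5°.

## Analytic tripeptide closure

When three residues remain, closure solves for the six torsions (phi, psi
of three residues) that reconnect the chain to the anchor with ideal
geometry. With the anchor frame taken as the N, CA, C of the post-anchor
residue, the junction constraints number five, so one continuous degree of
freedom survives; the package pins it with the post-anchor residue's phi
dihedral (C3–Npost–CApost–Cpost). This mirrors the N-side, where the
anchor's psi (read from its carbonyl O) fixes the first loop N. The solver:

1. reverse-builds the targets C3 and CA3 from the anchor frame, the pinned
   phi, and the trans omega;
2. reduces the remaining system to one dimension: the middle CA lies on the
   circle where the spheres of the two rigid peptide-unit virtual bonds
   (|CA–CA| ≈ 3.81 Å with fixed omega) intersect;
3. for each circle position, the four remaining torsions follow in closed
   form — two cone intersections with two branches each — leaving a single
   angular residual at the third CA;
4. scans the circle (default 1024 points, vectorized across all four
   branches), brackets sign changes *and* feasibility edges (cone-tangency
   boundaries, where solutions are born; a plain sign-change scan misses
   roots hiding in narrow feasible slivers), and polishes by bisection.

Every solution is re-verified by forward rebuilding; acceptance requires
the junction bond within 1e-4 Å and the junction angles within 1e-3°. At
most 16 solutions are returned, matching the count of the classical
16-degree-polynomial treatment of the fully pinned problem. The
1D-scan-with-closed-form-branches route was chosen over the polynomial
because its failure modes are transparent and the residual tolerance is the
contract either way.

Closure near full extension has few or no solutions. The sampler therefore
conditions the pinned phi on reach: candidate values are screened by
whether their implied CA3 target lies strictly inside the virtual-bond
reach interval (margin 0.3 Å), weighted by the residue-typed phi marginal
and by the interior margin, and several candidates are tried per attempt
with a coarser scan (128 points). Failed attempts jitter the bond lengths
(sigma 0.01 Å), bond angles (1°) and omegas (2°) — small geometric
fluctuations that move the solution variety without leaving the ideal-
geometry regime. Solutions outside the ellipsoid or clashing with the
environment are rejected inside the search loop; one survivor is selected
by the Boltzmann rule on its fragment energy.

## The pair potential

Heavy atoms map to 20 classes: backbone N, CA, C, O plus 16 side-chain
classes (6 carbon, 6 nitrogen, 3 oxygen, 1 sulfur; proline's backbone N
takes the dedicated ring-N class). Distances bin into one sub-contact bin
[0, 2 Å) and 30 uniform bins of 0.2 Å up to 8 Å; beyond 8 Å there is no
interaction. For every unordered atom pair with at least one atom in a
loop region, observed counts n_obs come from native loops and expected
counts n_exp from geometry-only decoys (the sampler run with a
zero-energy potential), averaged per loop over its decoys (5 by default)
and summed over loops. The energy is

E(i, j, bin) = -ln[ (n_obs/N_obs) / (n_exp/N_exp) ],

with +3 for cells lacking observed or expected counts (repulsive but
finite, so Boltzmann weights stay defined) and a constant +10 in the
sub-contact bin (clashes must be strongly penalized but finite for the
same reason). Pairs within one residue and 1-2/1-3 pairs across the
peptide bond (C–N, C–CA, CA–N, O–N) are excluded everywhere — they are
covalent-geometry constants that would otherwise dominate every energy.
Loop–loop pairs count once (unordered), and the same convention defines
the N_obs/N_exp normalizers. Fragment energies telescope: summing them
over growth steps and closure reproduces the full loop score exactly,
because each unordered pair is counted exactly once, when its later atom
appears.

## Redcell: bounded energy evaluation

All loop backbone atoms satisfy |P - f1| + |P - f2| <= L by the triangle
inequality along the chain, where f1, f2 are the anchors and L is the sum
of the loop's backbone bond lengths. Side-chain atoms add at most 2 s_max
to that sum (s_max = 7.32 Å, the arginine extension computed from the
shipped topology) and interaction partners at most 2 d_cut more (d_cut =
8 Å, the potential range). Enlarging the semi-axes by s_max + d_cut —
i.e., membership threshold L + 2(s_max + d_cut) — therefore captures
*every* atom that can interact with *any* loop conformation: filtered and
unfiltered energies are identical, which the tests assert to the last bit.
A residue-radius cutoff against the anchors (r_i + r_j + c, c = 8 Å,
radii measured from the database as the largest center-to-atom distance
per residue type) can only add atoms on top of the ellipsoid set. The
environment is precomputed once per target; its size depends on loop
geometry, not protein size. The same ellipsoid prunes growth: an atom
placed outside can never belong to a closed loop.

## Side chains and clashes

Side chains are built after the backbone, residue by residue in growth
order: 16 trial chi vectors drawn from the residue-typed chi table (joint
over the chi vector, 10° bins, only observed bins can be drawn, uniform
within a bin; unseen residue types fall back to a canonical rotamer
library), atoms placed by ideal internal-coordinate topology, one trial
kept by exp(-E/T). Two atoms clash when their distance is below 0.7 times
the sum of their van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å).
Remaining clashes are resolved by rotating the side chain about chi1
(proline: chi2) in 15° steps, then by trying the canonical rotamers
outright; backbone atoms never move. A conformation with unresolved
clashes triggers a restart of the whole growth (up to 100 per requested
conformation); if the budget is exhausted the conformation is returned
flagged rather than silently dropped.

## The synthetic study conditions

The fixture generator emulates what the method needs from real data:
polypeptides with ideal covalent geometry, helix/strand/coil plans (coil
phi/psi from a mixture of broad Gaussians over the three classic
Ramachandran basins), full side chains from canonical rotamers, and —
importantly — *self-avoidance*: folds are redrawn and rotamers repacked
until the structure passes the same 0.7 vdW-ratio clash criterion the
sampler enforces, so natives are valid answers under the package's own
rules. The corpus default is 40 structures, each with two coil regions of
4–12 residues between regular elements (about 80 loops), fitted with 5
decoys per loop. Held-out targets are helix–coil–helix fixtures with a
4-residue and an 8-residue loop; their anchor spans sit near the median of
the corpus span distribution for their lengths, i.e., they are typical,
not cherry-picked, loops.

What passing on these conditions shows: the machinery is internally
consistent (exact closure, exact energy bounding, exact telescoping,
distributionally correct samplers) and can recover excised loops it has
never seen from database statistics alone. What it does not show: accuracy
on real crystal structures, whose geometry deviates from ideal values,
whose loops see crystal contacts and waters, and whose database is three
orders of magnitude larger. The database builder and the CLI accept real
PDB files with secondary-structure assignments for that use, with
expectations of the same order of magnitude, not equality.

## Numerical and design choices

* Angles are degrees at every interface, radians internally; dihedrals in
  [-180, 180) with +180 mapped down. The backbone geometry table uses
  Engh–Huber-style idealized values (residue-typed overrides for GLY, PRO
  and the beta-branched residues); the exact values are a versioned
  stand-in, and every tolerance in the package references this table, not
  external dictionaries.
* Circle/sphere tangency within 1e-9 returns one point; an anchor on the
  circle axis at the compatible distance is an explicit error (the growth
  construction cannot produce it for physical distances).
* Altloc handling keeps the highest occupancy (ties to 'A'); hydrogens are
  ignored throughout (the models are heavy-atom only).
* The KDE mass check (trapezoid integral in [0.95, 1.05]) tolerates the
  kernel mass that leaks past the two-bandwidth grid padding.
* Ensemble members draw per-member seeds from the master seed stream, so
  ensembles are bit-reproducible and nested (the first n members of a
  longer run are identical).
* Problem sizes in the tests and the acceptance script — 40-structure
  corpus, 1,000-conformation ensembles, 20-run tuning comparison with
  25-member ensembles — were chosen as the smallest sizes at which the
  ensemble statistics are stable enough to assert; the vignette's numbers
  and the README example come from those same runs.

## Known limitations

* Bond lengths and angles are rigid during growth; only closure jitters
  them, slightly. Real loops relax these.
* The closure's residual degree of freedom is pinned by the post-anchor
  phi; the feasibility-weighted sampling of that phi is a proposal choice,
  and importance weights are deliberately not tracked — the outputs are
  ensembles and min/ranked statistics, not reweighted expectations.
* The potential's reference state is geometry-only decoys from the same
  sampler; with few decoys per loop the sparse-cell cap dominates rare
  type pairs.
* Growth is N-to-C only.
* The chi tables are joint histograms over observed bins; residue types
  absent from the database fall back to canonical rotamers rather than
  borrowing statistics from similar types.
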