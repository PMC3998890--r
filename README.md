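# loopgrow

Distance-guided sequential chain-growth Monte Carlo for protein loop
modeling, in R.

Loops are the irregular segments connecting regular secondary-structure
elements. Given a protein structure with a loop removed, `loopgrow` samples
ensembles of closed, clash-free loop conformations between the fixed
anchors, and ranks them with a loop-specific atom-pair distance-dependent
statistical potential. It is aimed at structural bioinformaticians who want
a transparent, fully scriptable implementation of distance-guided chain
growth — every stage (empirical model fitting, growth, closure, scoring) is
an exported, testable function.

## The method

A loop of length L grows residue by residue from the N-side anchor toward
the C-side anchor. At growth step i:

1. **Distance guidance.** The distance d of the next backbone atom to the
   anchor atom (the N of the residue after the loop) is drawn from an
   empirical conditional density f(d_new | d_prev), a two-dimensional
   Gaussian kernel density estimate over (d_prev, d_new) pairs collected
   from a loop database at the same residue separation g, evaluated on a
   32x32 grid and interpolated bilinearly. Fixed bond lengths and angles
   confine the atom to a circle; the sampled distance picks one of the (at
   most) two circle/sphere intersection points. C and the next CA are
   placed this way in turn; the intervening N rides on a trans peptide
   omega drawn from N(180, sigma).
2. **Dihedral filtering.** Of m such trials, k are kept with probability
   proportional to a residue-typed (phi, psi) frequency table fitted from
   the same database.
3. **Boltzmann selection.** One of the k is drawn with probability
   proportional to exp(-E/T), where E is the interaction energy of the four
   new backbone atoms with the protein and the already-grown loop, under
   the pair potential E(i,j,r) = -ln[(n_obs/N_obs)/(n_exp/N_exp)] with a
   geometry-only decoy reference state.
4. **Closure.** Three residues before the anchor, an analytic tripeptide
   closure solves for the six backbone torsions that reconnect the chain
   exactly (at most 16 solutions), with small jitter on bond geometry to
   raise the success rate; one solution is chosen by the same Boltzmann
   rule. Side chains are then built from empirical chi tables and steric
   clashes resolved by chi-axis rotation.

Energy evaluation is bounded by **Redcell**: a residue-radius distance
cutoff plus an enlarged ellipsoid around the two anchors (semi-axes grown
by the maximum side-chain length plus the interaction cutoff) that provably
contains every atom able to interact with any loop conformation — filtered
and unfiltered energies are identical, and the cost is independent of
protein size.

## Worked example

Everything below runs self-contained on synthetic fixtures:

```r
library(loopgrow)

## 1. synthetic corpus + fitted parameter bundle (distance KDEs, dihedral
##    and chi tables, decoy-referenced pair potential)
corpus <- make_corpus(n_structures = 40, seed = 42, n_decoys = 5)

## 2. a held-out target: excise a 4-residue loop, keep the native as truth
fx <- make_protein("HHHHHHCCCCHHHHHH", seed = 424)
tg <- make_loop_target(fx$structure, "A", 7, 10)

## 3. sample an ensemble and rank it
ens <- sample_ensemble(tg$structure, tg$loop, corpus$bundle, n = 200,
                       seed = 1, native = tg$native)
rank_and_report(ens)[c("min_rmsd", "mean_rmsd", "rmsd_lowest_energy")]
```

Output (stochastic, but reproducible for a fixed seed):

```
$min_rmsd
[1] 0.2815112

$mean_rmsd
[1] 2.078199

$rmsd_lowest_energy
[1] 1.139095
```

`min_rmsd` is the best fixed-frame backbone RMSD (N, CA, C, O; no
superposition) to the excised native over the ensemble — a bound on
sampling quality. `rmsd_lowest_energy` is the RMSD of the conformation the
potential would pick blind; the gap between the two measures how well the
potential ranks.

For real PDB input the same pipeline runs from the command line (see
`inst/scripts/loopgrow.R`): `build-db` over a directory of PDB files with
secondary-structure assignment files, `fit`, `sample`, `score`.

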