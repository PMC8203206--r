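---
title: "Consensus scoring of docked protein-complex models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring of docked protein-complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockjury)
```

## The problem and the model

Rigid-body docking of two protein chains produces pools of candidate
complex models of very uneven quality, and without a native structure
there is no direct error to measure. `dockjury` implements a consensus
(jury) protocol built on one assumption: *correct binding modes are
rediscovered by independent docking attempts, incorrect ones are not*.
Under that assumption, a model's mean structural similarity to the rest
of the pool is a proxy for its similarity to the truth. The assumption
fails when the pool is systematically biased — if most models share the
same wrong interface, the jury will reward it. The method is therefore
intended for pools combining several docking engines, where such
correlated failure is less likely.

Three internal components are computed per model, plus optional external
single-model scores, and their unweighted mean is the global score used
to rank.

### Interface geometry: Dmin and the interface set

A residue's `Dmin` is its minimum heavy-atom distance to residues of any
*different* chain (hydrogens and deuterium are excluded by element; all
remaining ATOM-record atoms count, side chain and backbone alike).
Residues with `Dmin` at or below the cutoff — 5 Å, inclusive — form the
interface set. With more than two chains the minimum over all foreign
chains is used. `Dmin` is retained, uncapped, for *every* residue, not
only interface residues, because the cross-model average below needs the
distance of a residue even in models where it has drifted out of the
interface.

### ModFOLDIA: per-residue interface accuracy

For each interface residue of the scored model, the equivalent residue —
identified by (chain, author residue number, insertion code) — is looked
up in every other model and `MeanDmin` is the arithmetic mean of its
`Dmin` there. Distances pass through a sigmoid with a 20 Å half-point,

$$S_i = \frac{1}{1 + (D_{min}/20)^2}, \qquad
  \overline{S_i} = \frac{1}{1 + (\overline{D}_{min}/20)^2}, \qquad
  IA = 1 - \left|S_i - \overline{S_i}\right|,$$

so a residue scores 1 when its contact geometry matches the pool
consensus and decays linearly with the discrepancy of the squashed
distances. The global ModFOLDIA score is the sum of IA over the model's
interface divided by the larger of the model's own interface size and
the pool-mean interface size — the normaliser penalises models that
claim either far too small or far too large an interface relative to the
consensus.

Averaging includes the raw minimum distance from models where the
residue is not an interface residue at all; no cap is applied. Residues
absent from every other model cannot be averaged: their IA is recorded
as missing (with a warning) and contributes 0 to the global numerator
rather than shrinking the normaliser — the conservative choice, since an
unverifiable residue should not raise a model's score.

### The jury scores

`QSscoreJury` and `DockQJury` are the mean pairwise QS-score and DockQ of
a model against every other model in the pool, self-comparison excluded.
The QS-score is symmetric; DockQ is not (its fnat term counts the
*reference's* contacts), so in the jury each counterpart model acts in
turn as the DockQ reference and the row mean is taken.

The original method names these two pairwise metrics only by reference,
so the published constants of each are adopted and recorded here:

* **DockQ** = (fnat + 1/(1+(iRMS/1.5)²) + 1/(1+(LRMS/8.5)²)) / 3, with
  native contacts at a 5 Å heavy-atom cutoff, the interface for the iRMS
  term defined at 10 Å, backbone atoms N, CA, C, O, the receptor being
  the larger chain by residue count (ties broken by chain-id order), and
  superpositions by least squares.
* **QS-score**: inter-chain residue contacts on Cβ positions (Cα for
  glycine) within 12 Å, contact weight 1 up to 5 Å then a Gaussian decay
  `exp(−(d−5)²/(2·4.28²))`; score = Σ min(w_a, w_b) over shared contacts
  divided by Σ max-side weight over the union.

One situation arises in a jury that the published DockQ definition never
meets: the model acting as reference can be a blown-apart decoy with *no*
inter-chain contacts, leaving fnat (and possibly the 10 Å interface)
undefined. In jury mode the package scores those terms 0 — the natural
limit of each term as the reference interface empties — instead of
failing; when DockQ is used against a trusted reference
(`allow_empty_reference = FALSE`, the default of `dockq()`), a contactless
reference is an error, as it should be.

### Aggregation

The global score is the unweighted arithmetic mean of the available
components: the three internal ones always, plus any external per-model
scores supplied as TSV (per-chain-pair values are first averaged over
chain pairs into one assembly score). With both external slots present
this is a five-method mean; without them the documented three-component
mode is used and logged. Ranking is by global score descending, ties
broken by model id for determinism.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 5 Å | inclusive heavy-atom interface definition; also the fnat contact cutoff |
| sigmoid half-point | 20 Å | distance at which `Si` = 0.5; fixed by the scoring formula |
| DockQ scalings | 1.5 Å, 8.5 Å | iRMS and LRMS scale constants of the published composite |
| QS horizon / decay | 12 Å, 4.28 Å | Cβ contact horizon and Gaussian decay width |

Only `cutoff` is exposed as an analysis knob; the others define the
metrics themselves and changing them would change what "DockQ" or
"QS-score" means.

## What the decoy generator emulates — and what it does not

`make_reference_dimer()` builds two ideal α-helical poly-alanine chains
(rise 1.5 Å, twist 100°/residue; N, CA, C, O, CB each on a coaxial helix
with fixed radius/phase/axial offsets), antiparallel, axes 9 Å apart —
the shape of a two-helix coiled-coil interface, guaranteed to have 5 Å
contacts. `generate_pool()` perturbs chain B rigidly: near-native decoys
(≤ 5°, ≤ 1 Å) are striped evenly through the pool at the requested
fraction, the remainder draw rotations on [max/3, max] (default max 30°)
and translations on [max/3, max] (default max 15 Å) in random directions,
plus 0.1 Å per-atom Gaussian jitter. Each decoy derives its seed from the
pool seed and its own counter, so pools are bit-reproducible and grow
without reshuffling.

This emulates the *geometry* of a docking pool: a cluster of mutually
consistent near-native poses against scattered wrong poses with known
ground-truth DockQ. It does **not** emulate side-chain packing, sequence
diversity, flexible backbones, clashes, or the correlated errors real
docking engines make. Passing the ranking-recovery test therefore shows
the consensus machinery is correct, not that consensus scoring succeeds
on any real target — on real pools its power depends on the
rediscovery assumption above.

## Numerical choices

* Distances are computed as `sqrt(dx² + dy² + dz²)` term by term in the
  vectorised paths, deliberately matching the arithmetic of a scalar
  loop, so the accelerated interface profiles are bit-identical to the
  brute-force oracle used in the tests. Because every residue's uncapped
  `Dmin` is needed anyway, full cross-chain distance evaluation is used
  rather than a cutoff-limited spatial grid; at the pool sizes this
  package targets (hundreds of residues per model) that is both simpler
  and fast.
* Superposition uses the SVD solution of the orthogonal Procrustes
  problem with the determinant-sign correction, so reflections are never
  returned; the tests cross-check the minimised RMSD against an
  independent least-squares fit.
* Equivalent residues are matched by author numbering only; no sequence
  alignment fallback is attempted (see limitations).
* Alternate locations keep the highest-occupancy conformer, ties going
  to the first encountered; only the first MODEL block of a multi-model
  file is read (docking outputs are single-model).
* Residue numbers above 9999 cannot be written in fixed-width PDB and
  raise an error rather than silently switching numbering schemes.
* Two models that both have *no* inter-chain contacts at all are
  vacuously identical under the QS-score and score 1; disjoint non-empty
  contact sets score 0.
* Ranking ties are broken by model id sort order.

The test suite exercises pools of 5–30 models of 10–20 residues per
chain and random two-chain models of ~200 atoms; these sizes were chosen
so the full brute-force oracles remain practical while still covering
every code path, including the 30-model ranking-recovery run.

## Known limitations

* Residue correspondence trusts author numbering; renumbered or
  insertion-code-shifted pools must be harmonised upstream.
* DockQ is implemented for two-chain comparisons (receptor/ligand
  assignment by size); pools of higher-order assemblies are supported by
  the interface and QS machinery but not by DockQJury.
* External scorers are ingested, never recomputed: the package trusts
  the supplied TSV values to be in [0, 1].
* mmCIF input, nucleic-acid chains and biological-assembly expansion are
  out of scope; input is wwPDB fixed-width ATOM records (optionally
  gzipped).

## A complete run

```{r example, eval = FALSE}
dp  <- generate_pool(decoy_spec(n_decoys = 30, seed = 7,
                                fraction_near_native = 0.4))
res <- score_pool(dp$pool)
head(res$scores)
cor(res$scores$global, dp$ground_truth[res$scores$model_id],
    method = "spearman")
write_caspqa(res, "scores.caspqa")
```
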