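# dockjury

Consensus (jury) quality assessment for pools of docked protein-complex
models.

Rigid-body docking engines produce large pools of alternative models
("decoys") of the same protein–protein complex, and in the absence of an
experimental structure the central problem is picking the best one.
`dockjury` ranks a pool without any native reference by measuring how well
each model agrees with the rest of the pool, on the premise that
near-native poses recur across independent docking runs while wrong poses
scatter. It is aimed at structural bioinformaticians evaluating dimeric
(e.g. coiled-coil) complex models from engines such as MEGADOCK, FRODOCK,
PatchDock or ZDOCK.

## The method

For a pool of n ≥ 2 models sharing chain labels and residue numbering,
four ingredients are computed:

**Interface residues and Dmin.** A residue is an interface residue if any
of its heavy atoms lies ≤ 5 Å from a heavy atom in a different chain. For
every residue, Dmin is its minimum inter-chain heavy-atom distance.

**ModFOLDIA per-residue interface accuracy.** For each interface residue
of the model being scored, the equivalent residue (same chain, author
number, insertion code) is located in every other model and MeanDmin is
the mean of its Dmin there. Each distance is squashed through a sigmoid,

    Si     = 1 / (1 + (Dmin / 20)^2)
    MeanSi = 1 / (1 + (MeanDmin / 20)^2)
    IA     = 1 − |Si − MeanSi|

so IA is 1 when the residue's contact geometry agrees exactly with the
pool consensus. The global ModFOLDIA score is Σ IA over the model's
interface, normalised by max(model's interface size, mean interface size
across the pool).

**QSscoreJury and DockQJury.** Every model is compared pairwise with every
other model using the QS-score (weighted overlap of Cβ inter-chain
contacts, 12 Å horizon) and DockQ (fnat + interface RMSD + ligand RMSD,
each mapped to [0, 1]); a model's jury score is its mean similarity to
all other models, self-comparison excluded.

**Aggregate and rank.** The global score of a model is the unweighted mean
of its available components — the three internal ones above, plus
external per-chain-pair scores (ProQDock-style, VoroMQA-style) ingested
from TSV when supplied, giving a five-method mean. Models are ranked by
global score, descending.

A seeded decoy generator builds idealised two-helix dimers and rigid-body
perturbed pools with known ground-truth DockQ, so the whole protocol can
be exercised synthetically.

## Worked example

```r
library(dockjury)

dp  <- generate_pool(decoy_spec(n_decoys = 8, seed = 42, n_res_per_chain = 20))
res <- score_pool(dp$pool)
res
#> <pool_scores> target ref_dimer_n20_s42: 8 models ranked (cutoff 5.0 A)
#>    model_id qs_jury dockq_jury modfoldia n_components  global rank
#> 1 decoy_003 0.45143     0.4732    0.9527            3 0.62577    1
#> 2 decoy_008 0.45236     0.4740    0.9503            3 0.62554    2
#> 3 decoy_004 0.30409     0.4007    0.8728            3 0.52586    3
#> 4 decoy_001 0.31524     0.2948    0.9009            3 0.50363    4
#> 5 decoy_005 0.43339     0.3965    0.5385            3 0.45612    5
#> 6 decoy_002 0.16541     0.2243    0.0000            3 0.12990    6
#> 7 decoy_006 0.09777     0.1799    0.0000            3 0.09255    7
#> 8 decoy_007 0.01427     0.1321    0.0000            3 0.04880    8

round(dp$ground_truth[res$scores$model_id], 3)
#> decoy_003 decoy_008 decoy_004 decoy_001 decoy_005 decoy_002 decoy_006 decoy_007
#>     0.928     0.928     0.624     0.479     0.721     0.281     0.226     0.135
```

The two near-native decoys (ground-truth DockQ 0.93) rank first and
second: they agree with each other and partially with the mid-quality
decoys, while the scattered far decoys agree with nothing and collect
jury scores near 0. `modfoldia` is the interface-accuracy component
(0 when a decoy's interface is nowhere near the pool consensus),
`global` the 3-component mean used for the ranking; supplying
`external =` score tables extends it to a 5-component mean.

Per-residue IA scores live in `res$residue_ia`, pairwise QS/DockQ tables
in `res$pairwise$table`, and `write_caspqa()` / `write_scores_tsv()`
export CASP-QA-style text and TSV.

## Command line

```sh
Rscript inst/cli/dockjury.R simulate --out pool/ --n 30 --seed 7
Rscript inst/cli/dockjury.R score --out ranked/ pool/decoy_*.pdb
Rscript inst/cli/dockjury.R pairwise pool/decoy_001.pdb pool/reference.pdb
```

Exit codes: 0 success, 2 input error (unreadable files, fewer than two
models, chain mismatch), 3 computation error.

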