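# iredpanel

Structure-based prioritization of imine reductase (IRED) screening
panels for reductive amination.

## The problem

IREDs are NADPH-dependent enzymes that reduce imines and iminium ions to
chiral amines. Discovering one that accepts a new substrate normally
means expressing and screening a large enzyme panel. `iredpanel` ranks
candidate IRED sequences for a target imine so that a small panel
(20 sequences by default) can be screened instead: candidates are
matched to characterized IRED template structures and filtered,
structure models are qualified on the Ramachandran plot (≥ 90% of
residues in the favorable/core region), models are superposed onto the
dimer template and the NADPH cofactor is transferred in, docked poses
are screened on the distance between the cofactor's hydride-donating C4
atom and the imine nitrogen (kept iff 3.5 Å ≤ d ≤ 6.0 Å, closest
surviving pose selected), and the survivors are rescored with

```
refined score = 4.0 · Vina score + 1.0 · N_acidic − 9.0 · N_His + 9.0 · N_basic
```

where the counts are taken over residues within 8 Å (minimum heavy-atom
distance) of the substrate. Lower is better; the top candidates form the
screening panel. Evaluation utilities compute hit rates at 2% and 50%
conversion cutoffs, best-hit retrieval, the analytic hypergeometric
random-selection baseline `1 − C(N−m, k)/C(N, k)`, a resampled baseline
with SEM, and exhaustive grid-search tuning of the score weights over
[−10, 10].

Homology modeling and the docking search sit behind backend contracts
(`build_model()`, `dock()`); in-memory and directory-backed fixture
backends are included, along with deterministic generators
(`make_receptor()`, `make_pose_set()`, `make_rama_chain()`,
`make_panel()`) that create geometrically verified toy inputs for every
stage.

The package is aimed at biocatalysis groups triaging IRED candidate
lists, and at method developers who need a transparent, fully testable
reference implementation of the funnel's scoring and evaluation logic.

## Worked example

Rank four candidate sequences against a toy template with fixture
backends (a 60-residue template sequence, a receptor whose active site
holds an ASP at 5 Å, a HIS at 6 Å and a LYS at 8.5 Å, and stored pose
sets for a substrate `amine_26`):

```r
library(iredpanel)
res <- run_ranking(queries, templates, template_structure,
                   default_substrate(), n_index = 2,
                   modeling_backend, docking_backend,
                   pipeline_config(reference_ligand_resname = "LIG"),
                   substrate_id = "amine_26")
res$table
```

```
 rank sequence_id vina_score c4_n_distance n_acidic n_basic n_his refined_score        status
    1      cand_a       -9.0           3.9        1       0     1           -44        scored
    2      cand_b       -8.5           4.4        1       0     1           -42        scored
   NA      cand_c         NA            NA       NA      NA    NA            NA no_valid_pose
   NA      cand_d         NA            NA       NA      NA    NA            NA   not_homolog
```

Reading the output: `cand_a`'s best pose survives the 3.5–6.0 Å C4···N
filter at 3.9 Å with binding score −9.0; its shell holds one acidic
residue and a histidine (the LYS at 8.5 Å is outside the 8 Å shell), so
its refined score is 4·(−9) + 1 − 9 = −44, ranking it first. `cand_c`'s
poses fall at 3.4 Å (clash) and 6.1 Å (beyond hydride-transfer range),
so it is reported — not silently dropped — as `no_valid_pose`; `cand_d`'s
closest template is not a characterized IRED. `res$panel` holds the top
`panel_size` scored candidates for screening, and
`write_ranking(res$ranking, "ranking.csv")` exports the table.

The same pipeline is available from a shell via `exec/iredpanel`
(`rank`, `evaluate`, `tune`, `simulate` subcommands).

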