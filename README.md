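# rgcore — reduced-graph cores for lead-optimisation series

`rgcore` organises a lead-optimisation (LO) dataset into compound series at
the **reduced graph** (RG) level and summarises each series as a
Markush-style SAR table. Each molecule is collapsed into a small typed graph
— SSSR rings (aromatic/aliphatic), acyclic hydrogen-bond donor/acceptor
groups, complex atoms (heteroatoms, halogens, branched carbons) and inert
linkers — so that functionally equivalent substructures reduce to the same
node and many molecules share one RG. Series are then detected as **RG
cores**: connected RG subgraphs common to sets of molecules, found by an
iterative maximum-common-subgraph (MCS) procedure over graph-Tanimoto
near-neighbour lists,

        T = MCS / (A + B − MCS)

with `A`, `B` the node counts of two RGs and `MCS` the node count of their
maximum common connected subgraph (exact label and edge-multiplicity
matching). Every molecule is mapped onto every core it contains; ambiguous
mappings are resolved with node and substituent **topological distance
maps** aggregated over the uniquely mapped molecules. Each core node is
finally annotated with the substructures it represents, their frequencies,
and median/mean/sd pIC50 — the RG analogue of a Markush structure with its
R-group table. It is aimed at medicinal/computational chemists reviewing
what an LO programme explored at each position and where activity sits.

Chemistry perception (SMILES, SMARTS, rings, aromaticity, salt stripping,
neutralisation) is delegated to RDKit through a bundled Python helper; the
package needs a `python` with RDKit on the PATH (override via the
`RGCORE_PYTHON` environment variable). All method logic is R.

## Worked example

Six chloro-phenyl acetamides varied at the amide nitrogen (the bundled
demonstration series):

```r
library(rgcore)

fx  <- make_series_demo(seed = 1)
res <- rg_run(fx$records, rg_config(similarity_threshold = 0.5, min_core_size = 4))
res
#> <rg_result> 6 molecules, 5 unique RGs, 1 cores
#> <rg_core 1> [Ge][Li][No][Hg] (6 members)
```

One core is found: `[Ge][Li][No][Hg]` — an acyclic HBA-HBD node (the amide),
an inert linker (the CH2), an aromatic ring and a complex node (the
chlorine), i.e. the shared scaffold. All six molecules are members. The
per-node SAR table:

```r
print(as.data.frame(res$annotations[[1]]), digits = 4)
#>   core_id node_index label substructure_smarts count pic50_median pic50_mean pic50_std
#> 1       1          1    Ge            *NC(*)=O     5        7.150      7.072    0.8042
#> 2       1          1    Ge             *C(N)=O     1        6.500      6.500        NA
#> 3       1          2    Li                 *C*     6        6.825      6.977    0.7563
#> 4       1          3    Hg                 *Cl     6        6.825      6.977    0.7563
#> 5       1          4    No        *c1ccc(*)cc1     6        6.825      6.977    0.7563
```

Reading it: the amide node (`Ge`) appears in two forms — substituted
(`*NC(*)=O`, five molecules, median pIC50 7.150) and primary (`*C(N)=O`, one
molecule) — while the linker, chlorine and para-substituted phenyl are
invariant across the series (one substructure each, count 6). Wildcards
(`*`) mark where members extend beyond the node. `export_results(res, "out/")`
writes the same content as per-core JSON (with pie-chart segment fractions),
per-core combined-substructure CSVs, a core-overlap matrix and a dataset
summary.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rgcore.R",package="rgcore"))')" \
    run --input data.csv --smiles-col smiles --id-col id --activity-col pic50 \
    --threshold 0.5 --min-core-size 5 --out results/
```

(`demo` and `sweep` subcommands run the bundled series and the
threshold/min-size sensitivity grid.)

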