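# EnsembleContacts

Contact profiling of structural ensembles of protein dimers, built around
the STAT5A phosphotyrosine–SH2 dimer interface.

Activated STAT5A dimerizes through reciprocal phosphotyrosine (pY694)–SH2
domain binding, and the quality of such a dimer model is judged by which
residue–residue contacts persist across a conformational ensemble.
`EnsembleContacts` takes a multi-model PDB ensemble of a two-chain
SH2+C-terminal-tail fragment and computes, per frame:

* **hydrogen bonds** — donor–acceptor distance `d(D,A) < 0.35` nm **and**
  hydrogen–donor–acceptor angle `θ(H–D–A) < 30°` (explicit hydrogens
  required, strict inequalities);
* **salt bridges** — minimum N⁺···O⁻ heavy-atom distance `< 0.4` nm between
  a positive charge group (Arg, Lys) and a negative one (Asp, Glu, PTR
  phosphate);
* **hydrophobic contacts** — side-chain centre-of-mass distance `< 0.5` nm,
  for every residue type with a non-empty side chain;
* **aromatic contacts** — the hydrophobic-criterion subset with two
  aromatic rings (F/Y/W/H/PTR), additionally requiring ring-centroid
  distance `< 0.5` nm.

Per-frame events are aggregated into residue-pair **occupancies**
(`100·n_present/n_frames`), each contact is assigned to one of the three
dimer interfaces — (1) intermolecular PTM–SH2, (2) intermolecular PTM–PTM,
(3) intramolecular PTM–SH2, with the linker class kept apart — and a mean
|Δoccupancy| **asymmetry score** compares the two reciprocal orientations.
The package also provides GROMOS neighbour-counting clustering with
representative-structure selection, Kabsch superposition / backbone-RMSD
series, covariance ("essential dynamics") analysis with the Hess
cosine-content convergence criterion, and annotation of leukemia/lymphoma
STAT5 point mutations onto the computed interfaces with cohort frequencies
recomputed from carrier counts. A synthetic-ensemble generator with exact
per-frame ground truth makes every stage testable without any deposited
trajectory.

Intended users: structural bioinformaticians analysing MD or other
conformational ensembles of (SH2-mediated) protein dimers, and anyone who
needs a deterministic, fully testable contact-occupancy pipeline.

## Worked example

A 200-frame synthetic dimer with mirrored pY694–R618 salt bridges at 75%
designed occupancy, one PTM–PTM hydrogen bond and one intramolecular
F706–F633 aromatic contact:

```r
library(EnsembleContacts)

sched <- rep(c(TRUE, TRUE, TRUE, FALSE), length.out = 200)   # 75%
spec <- contactScheduleSpec(200L, 42L, list(
  designedPair("salt_bridge", "A", 694, "B", 618, schedule = sched),
  designedPair("salt_bridge", "B", 694, "A", 618, schedule = sched),
  designedPair("hbond",       "A", 699, "B", 705, p = 0.55),
  designedPair("aromatic",    "A", 706, "A", 633, p = 0.60)))
gen  <- generateContactEnsemble(spec)
prof <- interfaceProfile(gen$ensemble)
prof[, c("interface", "orientation", "kind", "res_a", "res_b",
         "occupancy_pct", "label")]
#>   interface orientation        kind res_a res_b occupancy_pct      label
#> 1         1           B hydrophobic   618   694          75.0 persistent
#> 2         1           A hydrophobic   694   618          75.0 persistent
#> 3         1           B salt_bridge   618   694          75.0 persistent
#> 4         1           A salt_bridge   694   618          75.0 persistent
#> 5         2        <NA>       hbond   699   705          51.5 persistent
#> 6         3           A    aromatic   633   706          60.0 persistent
#> 7         3           A hydrophobic   633   706          60.0 persistent
asymmetryScore(prof, "1")
#> [1] 0
```

The salt bridges are recovered at exactly the designed 75% in both
orientations (a charged pair below 0.4 nm necessarily also satisfies the
0.5 nm side-chain COM criterion, hence the paired hydrophobic records), the
Bernoulli hydrogen-bond schedule realizes 51.5%, and the mirrored design
gives an interface-1 asymmetry of 0.

Clustering and convergence on designed fixtures:

```r
cl <- gromosCluster(generateClusterFixture(30, 20, 1.0, 0.02, seed = 1),
                    cutoff = 0.2)
cl
#> ClusterResult: 2 cluster(s) at cutoff 0.2 nm; sizes 30,20 ; coverage 0.600
representativeStructure(cl)$coverage   # 0.6 (> 0.5: "most representative")
cosineContent(generateProjectionSeries("cosine", 1000, 1), 1)
#> [1] 1
variantFrequency(7, 21)   # N642H in NK/γδ T-cell lymphoma
#> [1] 33.3
```

A command-line wrapper over the same functions ships in
`inst/scripts/ensemble-contacts.R`
(`Rscript ensemble-contacts.R profile --pdb model.pdb --chains A,B --out out/`,
plus `cluster`, `converge`, `annotate`, `simulate`).

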