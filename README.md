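# karyoband

Comparative cytogenetics of polytene chromosome banding sequences, in the
style of classical *Chironomus* karyosystematics.

Chironomids carry giant polytene chromosomes whose reproducible transverse
bands can be read like a barcode: each species/arm has a *banding sequence*,
written in Keyl interval notation (`"1-7 15-12 8-11 16-19"`, a descending
token marking an inverted segment). Species diverge by paracentric
inversions within arms and by whole-arm translocations that reshuffle the
seven arms A–G into chromosomes. `karyoband` turns those observations into
computable objects:

* **Band model** — parse/format Keyl formulas, validate karyotype records
  (JSON dialect + TSV export).
* **Block refinement** — reduce two sequences over the same band set to a
  signed permutation of maximal common oriented blocks.
* **Inversion distance** — exact minimal reversal counts via the
  breakpoint-graph formula `d = (n + 1) − c + h + f` (cycles, hurdles,
  fortress), with optimal reversal scenarios and an independent
  brute-force BFS oracle for `n ≤ 8`.
* **Cytocomplexes** — classify whole-arm combinations (pseudothummi
  `AE CD BF G`, thummi `AB CD EF G`, parathummi `AC BF DE G`, fused
  "modified" variants) and compute whole-arm translocation distances by
  exhaustive search over the partition lattice.
* **Pool statistics** — per-species sequence-pool sizes, polymorphic arms,
  cosmopolitan-basic vs endemic classification against a reference registry.
* **Phylogeny export** — per-arm inversion-step matrices, minimum-spanning
  networks (DOT), neighbor-joining trees (Newick), PHYLIP matrices.
* **Synthetic evolution** — seeded generators for arms, species and whole
  studies with a ground-truth ledger, so the full pipeline is testable
  without figure-locked photomaps.

The shipped species records are transcriptions of a published six-species
African *Chironomus* study; since the published band formulas exist only as
photomap figures, all fixture formulas are synthetic placeholders
(`*_synthetic.json`) constructed to satisfy the stated relations
(identities with basic sequences, simple-inversion polymorphisms).

## Worked example

```r
library(karyoband)
k   <- read_karyotype(system.file("extdata", "alluaudi_synthetic.json",
                                  package = "karyoband"))
reg <- read_basic_registry()   # shipped synthetic basic-sequence registry

classify_cytocomplex(k$arm_combination)
#> <cytocomplex_call> pseudothummi (n=4, reference AE BF CD G)

pool_summary(k, reg)
#> <pool_summary> Chironomus alluaudi: 9 sequences (3 basic, 6 endemic)
#>   polymorphic arms: C, G
#>   basic: allA1, allE1, allF1

arm_distance(k$pool$C[[1]], k$pool$C[[2]], scenario = TRUE)
#> <distance_result> distance=1 (breakpoints=2 cycles=3 hurdles=0 fortress=0)
#>   scenario: (2,2)
```

The karyotype groups seven arms into `n = 4` chromosomes as `AE CD BF G`,
the pseudothummi arm combination. The species pool holds 9 banding
sequences; three of them are identical (inversion distance 0) to
cosmopolitan basic sequences in the registry, the other six are endemic.
The two arm-C sequences differ by one inversion step — the scenario names
the block interval to reverse.

A fully synthetic study with known ground truth:

```r
study <- generate_study(seed = 42)   # 6 species, 3 cytocomplexes
study_summary(study$records, study$registry)$complex_counts
#> pseudothummi       thummi   parathummi
#>            3            2            1
```

There is also a command-line front end (see `?karyo_main`):

```sh
karyo=$(Rscript -e 'cat(system.file("exec", "karyo", package = "karyoband"))')
Rscript "$karyo" classify inst/extdata/*_synthetic.json
Rscript "$karyo" net inst/extdata/{alluaudi,transvaalensis,nakuru}_synthetic.json \
    --arm E --registry inst/extdata/basic_registry_synthetic.json --format dot
Rscript "$karyo" simulate --species 6 --seed 42 --out study_dir/
```

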