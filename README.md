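# srsmut

Substrate-recognition-site mapping and variant-screening analytics for
cytochrome P450 engineering.

Plant P450s share six substrate recognition sites (SRS1–SRS6) that line
the catalytic pocket and set substrate- and regio-specificity.
Semi-rational engineering of these enzymes — as practised on the
CYP76AH subfamily that oxidises 13R-manoyl oxide en route to forskolin —
follows a recurring loop: map the SRS regions onto the enzyme of
interest by alignment to reference-annotated P450s, pick candidate
residues (K-helix ExxR-offset hotspots in SRS5, reciprocal differences
against a homologue, positions transferred from other engineered CYPs),
build the variants, and quantify the in vivo screen by internal-standard
GC–MS. `srsmut` implements every computational step of that loop as a
tested R package, for enzyme engineers and metabolic engineers who want
the arithmetic reproducible instead of living in spreadsheets.

The core quantities:

* per-SRS percent identity between homologues, from one global
  alignment (Needleman–Wunsch, BLOSUM62, affine gaps), with
  gap-containing columns counted as mismatches;
* SRS interval projection through alignment columns, boundaries on gaps
  moved inward, multi-reference consensus by intersection;
* variant notation `A99I` / `473DDP::EL` (substitution / length-changing
  segment swap), parsed, canonically rendered and applied;
* relative yield = mean over replicates of analyte area / internal
  standard area; titer = (response − intercept)/slope from an OLS
  standard curve, floored at 0;
* specificity metrics per strain: oxygenated % = 100·(total −
  substrate)/total and content of target % = 100·target/total over a
  quantified compound set (default {1, 2, 3, 7});
* fold change = ratio of mean responses (or titers) between strains.

Ground-truthed simulators (`simulate_family()`, `simulate_screen()`)
generate homologous families with planted SRS divergence, a planted
ExxR motif and optional SRS6 indels, and replicate GC–MS peak tables
with known titers — so the whole pipeline is testable offline.

## Worked example

Reproduce the derived columns of the published shake-flask screen of
CYP76AH15 variants from their per-compound titers:

```r
library(srsmut)

# native enzyme: 15.9 mg/L substrate (1), 23.4 mg/L target ketone (2),
# 0.2 mg/L hydroxy product (3), 4.3 mg/L oxo-hydroxy derivative (7)
wt <- strain_metrics(c("1" = 15.9, "2" = 23.4, "3" = 0.2, "7" = 4.3))
wt
#> <strain_metrics> total 43.8 mg/L, oxygenated 64%, content of target 53%

a99i <- strain_metrics(c("1" = 0.9, "2" = 86.4, "3" = 0.4, "7" = 0),
                       reference_titers = wt$titers)
a99i
#> <strain_metrics> total 87.7 mg/L, oxygenated 99%, content of target 99%
round(a99i$fold_change[["2"]], 1)   # target product up vs native
#> [1] 3.7
round(1 / a99i$fold_change[["1"]])  # substrate depletion fold
#> [1] 18
```

The A99I variant converts nearly all substrate: 99% of its diterpenoids
are oxygenated and 99% is the target ketone, a 3.7-fold product increase
and an 18-fold substrate depletion relative to the native enzyme.

Mapping SRS regions onto a simulated subfamily (one member carries a
planted single-residue SRS6 deletion):

```r
fam <- simulate_family(family_sim_config(seed = 5, n_sequences = 1,
                                         indel_prob = 1))
proj <- project_srs(fam$annotation,
                    global_align(fam$ancestor, fam$descendants$desc1),
                    fam$descendants$desc1)
proj$total_residues   # ancestor carries 78 SRS residues; the deletion
#> [1] 77              # brings the descendant to 77
```

The numbered scripts under `analysis/` run the full workflow on
simulated inputs (`01` simulate → `02` map SRS → `03` propose
candidates → `04` quantify screen → `05` recompute the published
screening metrics → `06` optional identity-table reproduction when the
subfamily sequences are supplied); each writes its tables under
`results/`.

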