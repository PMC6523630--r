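# lipidrules

Rule-based prediction of lipid ESI-MS/MS spectra, and spectral-library
compound identification that weights spectral similarity with citation and
chemical-class metadata.

## What it is for

In untargeted lipidomics, acquired tandem mass spectra are identified by
matching against reference libraries, but measured reference spectra cover
only a fraction of lipid space. Lipids are modular — a class-specific polar
backbone plus fatty chains — and fragment in stereotyped ways (head-group
loss, chain loss as free acid or ketene, a few constant head-group ions),
so class- and adduct-specific fragmentation rules predict their spectra
quickly and accurately. `lipidrules` provides:

* **Formula and mass arithmetic** — Hill-style formula parsing, IUPAC
  monoisotopic masses, electron-corrected adduct m/z for the covered ESI
  adduct set ([M+H]+, [M+Na]+, [M+Li]+, [M+NH4]+, [M−H]−, [M+Cl]−,
  [M−2H]2−), and a lipid shorthand parser (`PC(16:0/16:0)`,
  `PS(16:0/18:1(9Z))`, `PC(O-16:0/16:0)`, `SM(d18:1/16:0)`, ...).
* **A fragmentation rule registry** — a manifest of the curated coverage
  (21 lipid classes, 344 rules, 50 class/adduct combinations, verified at
  load) plus a concrete encoded subset for seven classes, producing
  annotated spectra at 10, 20 and 40 eV with categorical intensities
  (low/medium/high/maximum mapped to 8/37.5/75/100).
* **Spectrum handling** — peak-list and MSP-dialect I/O, base-peak
  normalization, tolerance-based greedy peak alignment, and the standard
  dot-product (cosine) similarity.
* **Identification** — precursor-window candidate retrieval and the
  combined score `S_TOTAL = 0.6·S_CFM_ORIG + 0.1·S_CLASS + 0.3·S_REF`
  (each term normalized by its column maximum; raw similarity ≥ 0.95
  bypasses the metadata terms; citations capped at 156), competition
  ranking, top-k / medal-score evaluation, chemical-class prediction, and
  grid-search weight optimization with cross-validation.
* **Synthetic data** — deterministic generators for libraries, perturbed
  query spectra and identification challenges, so the whole pipeline is
  testable without any external download.
* **A CLI** — `predict`, `identify`, `classify`, `simulate`, `evaluate`
  subcommands (`inst/cli/lipidrules`).

## Worked example

Predict the 40 eV [M+H]+ spectrum of dipalmitoyl phosphatidylcholine:

```r
library(lipidrules)
registry <- load_registry()
pc <- parse_lipid_name("PC(16:0/16:0)")
predict_spectrum(pc, "[M+H]+", 40, registry)$peaks
#>          mz intensity                                               annotation
#> 1   86.0964       8.0                          choline fragment cation C5H12N+
#> 2  104.1070       8.0                                       protonated choline
#> 3  124.9998       8.0             cyclic 1,2-phosphate diester cation C2H6O4P+
#> 4  166.0628       8.0                     dehydrated phosphocholine head group
#> 5  184.0733     100.0                                phosphocholine head group
#> 6  478.3292      37.5                    loss of sn-1 chain as free fatty acid
#> 7  496.3398      37.5                             loss of sn-2 chain as ketene
#> 8  551.5034      37.5 neutral loss of phosphocholine (diacylglycerol-like ion)
#> 9  675.4959       8.0                           neutral loss of trimethylamine
#> 10 716.5589       8.0                                               water loss
#> 11 734.5694      37.5                                         precursor [M+H]+
```

Ten fragment peaks beside the precursor; the phosphocholine head-group ion
at m/z 184.0733 is the base peak. At 10 eV only the precursor (m/z
734.5694) is emitted, and at 20 eV the precursor plus the 184.0733 ion.

Identification on a synthetic library:

```r
lib  <- generate_library(synth_config(n_compounds = 50, seed = 7), registry)
cfg0 <- synth_config(50, seed = 7, mz_jitter_sd = 0,
                     intensity_noise_sd = 0, dropout_prob = 0)
ch  <- generate_challenges(lib, 50, cfg0, seed = 7)
res <- run_challenges(ch$challenges, ch$library)
evaluate_ranking(res$hit_rank)
#> $n            50
#> $top1         50
#> $top3         50
#> $top10        50
#> $average_rank 1
#> $median_rank  1
#> $medal_score  250
```

With perturbation off every query recovers its own compound at rank 1
(medal score 5 per challenge); raising the peak-dropout probability
degrades the identification rate.

From a shell:

```sh
inst/cli/lipidrules predict --name "PC(16:0/16:0)" --adduct "[M+H]+" \
    --energy 40 -o pc.msp
inst/cli/lipidrules simulate --n 100 --seed 7 --out bench --challenges 20
inst/cli/lipidrules evaluate --challenges bench -o ranks.tsv
```

## Scope

The package covers the rule-based lipid layer and the scoring/ranking
layer only: it does not implement a trained probabilistic fragmenter for
arbitrary small molecules (non-lipids are flagged for external handling),
a structure-based chemical classifier (classification assignments are
consumed as tabular input), raw-data formats (mzML), or numeric intensity
prediction for lipids.
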