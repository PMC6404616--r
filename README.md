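# phenolscreen

Chemical-genomic fitness screening of yeast deletion libraries, from
scanned spot-assay plates to calls, overlaps, clusters and enrichments.

Genome-wide deletion libraries (~2,800 strains in *S. pombe*, ~5,000 in
*S. cerevisiae*) are screened by growing every strain on agar plates with
and without a compound, scanning the plates, and asking which deletions
change fitness. `phenolscreen` implements the full quantitative analysis
chain for such screens, aimed at labs running plate-based chemical
genomics:

- **Plate densitometry** — grid detection by marginal-projection peak
  calling (with a small-rotation search) and per-spot integrated density
  with local annulus-median background subtraction and quality flags
  (`detect_grid()`, `quantify_spots()`, `collapse_dilution_series()`).
- **Growth score values (GSV)** — the wild-type-normalized fitness ratio

  `GSV = (d_treated / d_untreated) / (wt_treated / wt_untreated)`

  with replicate averaging, inclusive-threshold calling (GSV ≤ 0.5
  sensitive, GSV ≥ 2.0 resistant) and m-of-t consensus rules
  (`compute_gsv()`, `score_screen()`, `classify_sensitivity()`,
  `consensus_call()`).
- **Cross-compound overlap accounting** by exact set arithmetic with
  inclusion–exclusion checking, also from published marginal counts alone
  (`overlap_analysis()`, `overlap_from_counts()`).
- **Profile clustering** — average-linkage clustering of log2 GSV
  profiles, heatmap and Newick export (`build_profile_matrix()`,
  `hierarchical_cluster()`).
- **Gene-set enrichment** — upper-tail hypergeometric probability
  `P(X ≥ k)` for a query of n genes against a term of K genes in a
  universe of N, computed in log space, with Bonferroni/BH correction and
  a radial bubble display (`hypergeom_upper_tail()`, `enrich_gene_sets()`,
  `bubble_layout()`).
- **Dose-response** — two-parameter logistic curves, percent inhibition,
  IC50–IC80 estimation by log-interpolation or Levenberg–Marquardt fit,
  and screening-dose selection by the "about 10% of mutants grow like
  wild type, more than 10% grow at all" rule (`estimate_ic()`,
  `select_screening_concentration()`).
- **Synthetic data with ground truth** — screens with planted fitness
  effects, rendered 16-bit plate scans, annotation universes with planted
  enrichment folds, and dose-response curves, so the entire pipeline is
  testable end to end (`simulate_screen()`, `render_plate_image()`,
  `simulate_annotation_universe()`, `simulate_dose_response()`).

## Worked example

Simulate a 500-strain screen against three compounds (10% planted
sensitive strains, 15% multiplicative noise, 3 replicates), score it, and
summarize:

```r
library(phenolscreen)

sim    <- simulate_screen(n_strains = 500, frac_sensitive = 0.1,
                          noise_cv = 0.15, n_replicates = 3, seed = 42)
scores <- score_screen(sim$densities)
head(scores[order(scores$gsv), c("strain", "compound", "gsv", "call")], 3)
#>          strain compound        gsv      call
#> 421 strain00420      BHA 0.08372215 SENSITIVE
#> 1258 strain00255     BPA 0.09019962 SENSITIVE
#> 357 strain00356      BHA 0.09100798 SENSITIVE

table(scores$call, scores$compound)
#>             BHA BHT BPA
#>   NORMAL    442 443 441
#>   RESISTANT   9  10  10
#>   SENSITIVE  50  48  50
```

Each strain's GSV is its treated/control density ratio divided by the
wild type's; the ~50 strains called SENSITIVE per compound are the 10%
planted hits (GSV well below the 0.5 cutoff, like the 0.084 above), the
~10 RESISTANT the 2% planted resistant. Overlaps between the per-compound
sensitive sets:

```r
sens <- lapply(split(scores, scores$compound),
               function(d) d$strain[d$call == "SENSITIVE"])
overlap_analysis(sens)
#> overlap_summary
#>  sizes: BHA=50, BHT=48, BPA=50
#>  union: 135 (triple = 1)
#>  unique: BHA=41, BHT=41, BPA=41
```

and an IC estimate from a noiseless logistic dose-response curve
(IC50 planted at 0.4 mM, Hill slope 2):

```r
curve <- simulate_dose_response(ic50 = 0.4, hill_slope = 2,
          concentrations = c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2))
estimate_ic(curve, 50, "logistic")   # 0.4 mM
estimate_ic(curve, 80, "logistic")   # 0.8 mM
```

`run_full(pipeline_config(), "out/")` chains every stage — simulation (or
image rendering and re-digitization with `use_images = TRUE`), scoring,
overlap, clustering, enrichment, IC estimation — into a run directory with
TSVs, figures, a report and a checksummed manifest.

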