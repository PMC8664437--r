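# bulkscan

Fast genome-wide eQTL scans for two-genotype-class populations
(recombinant inbred panels such as the mouse BXD family, backcrosses),
computing every trait-by-marker LOD score through one dense matrix product
instead of millions of separate regressions.

## The method

For trait *i* and marker *j*, the one-degree-of-freedom Haley-Knott LOD
score of the single-marker linear model
*y*ᵢ = *X*ⱼβⱼ + εᵢ is

    LODᵢⱼ = (n/2) log₁₀(RSS0ᵢ / RSS1ᵢⱼ) = −(n/2) log₁₀(1 − r²ᵢⱼ),

where *r*ᵢⱼ is the Pearson correlation between trait *i* and marker *j*
over the *n* strains. With trait and genotype matrices column-standardized
to mean 0, variance 1 (Y\*, G\*), the whole correlation matrix is a single
cross-product, R = (1/n) Y\*′G\*, and the LOD matrix is an element-wise
transform of R. Covariates Z (intercept included) are projected out of both
Y and G as least-squares residuals before standardization, giving the
covariate-adjusted scan by the same multiplication.

The package provides:

* `scan_eqtl()` — the three-step engine (standardize → multiply →
  transform) with MAF filtering, covariate projection, trait chunking, a
  per-trait max-LOD output mode that never materializes the full matrix,
  and a single-precision (32-bit) compute path via RcppArmadillo;
* `brute_scan()` / `lod_ols()` — a transparent one-fit-per-pair
  regression oracle the fast path is verified against;
* `read_geno()` and friends — a GeneNetwork-style `.geno` dialect reader,
  trait/covariate readers, strain alignment, strict missing-data dropping,
  peak and matrix writers;
* `simulate_panel()` — a recombinant-inbred panel simulator (Haldane
  linkage Markov chains, planted eQTL at a chosen heritability) with
  recorded ground truth;
* `plot_eqtl_map()` — the trans-eQTL map (peak position vs cognate-gene
  position);
* a command-line interface (`inst/cli/bulkscan.R`) with `simulate`, `scan`
  and `plot` subcommands and per-stage timing logs.

## Worked example

```r
library(bulkscan)

panel <- simulate_panel(sim_config(n_strains = 80, n_traits = 200, seed = 42))
res <- scan_eqtl(panel$geno, panel$traits)   # max mode, MAF 0.05, double
res
#> <lod_result> peaks for 200 traits (n = 80); max LOD = 14.43

head(res$peaks[order(-res$peaks$lod), ], 5)
#>  trait_id marker_index marker_id chromosome position_cM      lod
#>    T00045          144     c3m42          3          82 14.42595
#>    T00024          818     c17m2         17           2 14.40042
#>    T00008          469    c10m10         10          18 13.01481
#>    T00006          961    c19m43         19          84 12.45931
#>    T00048          995    c20m26         20          50 12.32500
```

Each row is one trait's best marker: at 80 strains a LOD of 14.4
corresponds to r² ≈ 0.56 at that marker. Against the simulator's recorded
truth, 59/60 planted eQTL (98.3%) peak within 10 cM of their causal marker,
and 60 of the 200 traits (the 30% that carry a planted eQTL at
heritability 0.4) exceed the conventional reporting threshold LOD > 5.

The same run from a shell:

```sh
Rscript inst/cli/bulkscan.R simulate --n-strains 80 --n-traits 200 --seed 42 --out panel/
Rscript inst/cli/bulkscan.R scan --geno panel/panel.geno --traits panel/traits.csv --out scan/
Rscript inst/cli/bulkscan.R plot --peaks scan/peaks.tsv --annotation panel/annotation.tsv --out map.png
```

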