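---
title: "Bulk eQTL genome scans by matrix multiplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk eQTL genome scans by matrix multiplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The problem

An expression QTL (eQTL) study in a recombinant inbred (RI) panel such as
the mouse BXD family asks, for every one of tens of thousands to millions of
transcripts, whether its abundance co-segregates with the genotype at any of
thousands of markers. Population-scale eQTL mappers fit one regression per
trait-marker pair; at a million traits by ten thousand markers that is
10^10 model fits. In a two-genotype-class population the test is a
one-degree-of-freedom comparison, and in that special case the entire scan
collapses to one dense matrix product plus an element-wise transform, which
is what this package implements.

## The model

For trait $i$ and marker $j$ the single-marker model is

$$y_i = X_j \beta_j + \epsilon_i, \qquad \epsilon_i \sim N(0, \sigma_i^2 I),$$

with $X_j$ holding an intercept and the marker dosage (plus covariates when
given). Writing $\mathrm{RSS0}_i$ for the residual sum of squares of the
null model and $\mathrm{RSS1}_{ij}$ for the full model, the LOD score of the
one-df test is

$$\mathrm{LOD}_{ij} = \frac{n}{2}\log_{10}\frac{\mathrm{RSS0}_i}{\mathrm{RSS1}_{ij}}
                    = -\frac{n}{2}\log_{10}\!\left(1 - r_{ij}^2\right),$$

where $r_{ij}$ is the Pearson correlation between trait $i$ and marker $j$.
If $Y^{*}$ and $G^{*}$ are the trait and genotype matrices with columns
centered and scaled to variance one, the whole correlation matrix is a
single product,

$$R = \tfrac{1}{n} Y^{*\prime} G^{*},$$

and the LOD matrix is an element-wise function of $R$. Covariates $Z$
(intercept included) are handled by projecting both $Y$ and $G$ onto the
orthogonal complement of the covariate space — computationally, taking
least-squares residuals against $Z$ via a QR decomposition; the projector
$I - Z(Z'Z)^{-1}Z'$ is never formed — and then standardizing and
multiplying exactly as before.

The engine therefore has three steps (`scan_eqtl()`): standardize, multiply,
transform. The brute-force path (`brute_scan()`, one QR fit per pair) exists
purely as the correctness oracle; the identity between the two forms of the
LOD above is the package's core regression test.

## Conventions and numerical choices

* **Sign of the LOD.** The score is $-\frac{n}{2}\log_{10}(1-r^2)$; the
  minus sign is forced by $\mathrm{RSS1} \le \mathrm{RSS0}$ and
  $\mathrm{LOD} \ge 0$.
* **Standardization scale.** `standardize_columns()` scales to population
  variance one ($\frac{1}{n}\sum z^2 = 1$) and `correlation_scan()` divides
  the cross-product by $n$, so $R$ is exactly the Pearson correlation.
* **Degrees of freedom.** The $n$ in the formula is the aligned sample size
  and is *not* reduced by the number of covariates, consistent with the
  correlation identity; this differs from an F-test convention and is
  documented on `scan_eqtl()`.
* **Perfect fits.** $r^2$ is clamped at $1 - 10^{-12}$ (configurable) before
  the log, so a trait duplicating a marker gives a large finite LOD rather
  than an infinity that would poison the max reduction. The brute-force
  oracle applies the same clamp so both paths agree at the edge.
* **Constant columns.** Zero-variance traits or markers get correlation 0
  and LOD 0, and are flagged; the MAF filter normally removes monomorphic
  markers first. Silent `NaN`s would corrupt the per-trait argmax.
* **Ties.** Equal maximum LOD at several markers resolves to the lowest
  marker index, for deterministic output.
* **MAF filter.** A marker with mean dosage $f$ is kept iff
  $\min(f, 1-f) \ge$ `maf_threshold` (default 0.05), applied to raw dosages
  *before* covariate projection.
* **Missing data.** Strictly a pre-processing concern: `drop_incomplete()`
  removes traits (or markers) with any missing entry; nothing is imputed.

## Precision

Double precision is the default. The single-precision path exists because
32-bit arithmetic doubles the throughput of the dense product on most
hardware and most trait-marker associations are null, where the last digits
of a LOD score carry no information. R has no native 32-bit float type, so
the single path is a C++ kernel (RcppArmadillo `fmat`) that narrows the
standardized matrices to float and runs the cross-product and the
$\log_{10}$ transform in float. One genuine float limitation: $1 - 10^{-12}$
is not representable in 32-bit, so the clamp saturates at $1 - 10^{-7}$
there, bounding single-precision LOD at roughly $3.5\,n$. Across the
standard simulated panel the two paths agree to better than $10^{-3}$
wherever the double-precision LOD is below 25 (`test-acceptance.R` checks
exactly this), so peak *locations* are essentially always identical; only
the magnitudes of extreme peaks (far beyond any significance threshold)
compress slightly.

## Memory and chunking

The output is the scan's dominant cost: the LOD matrix is traits x markers,
far larger than the inputs. In `"max"` mode (the default) the engine
processes traits in chunks (`trait_chunk`, default 10,000), reduces each
block to its per-trait maximum and argmax, and discards it — the full
matrix never exists in memory. The peak table is invariant to the chunk
size up to last-bit floating-point wiggle (optimized BLAS kernels differ by
block shape), which the tests assert at $10^{-10}$. The dense
double-precision cross-product is routed through a single replaceable
`backend` function in `scan_config()`, the seam where an accelerator (GPU)
backend would plug in; only the CPU backend ships and is tested.

## What the simulator emulates — and what it does not

`simulate_panel()` generates the study conditions every test runs under:

* **Map**: evenly spaced markers (default 2 cM) on independent chromosomes
  (default 20 x 100 cM, a mouse-sized genome).
* **Genotypes**: each strain is an independent two-state \{0, 1\} Markov
  chain along each chromosome — first marker Bernoulli(0.5), adjacent
  markers flipping with the Haldane recombination fraction
  $r = (1 - e^{-2d/100})/2$ for spacing $d$ cM, optionally expanded to
  $4r/(1+6r)$ for RI lines by sib mating. Dosages are hard 0/1: fully
  inbred strains, no heterozygotes.
* **Traits**: a fraction `prop_with_qtl` (default 0.3) of traits get one
  causal marker drawn uniformly; the trait is
  $y = \beta\, z(g) + \epsilon$ with standardized dosage $z(g)$, unit
  Gaussian noise, and $\beta = \sqrt{h^2/(1-h^2)}$ so the population $r^2$
  at the causal marker equals the heritability $h^2$ (default 0.4 — a
  moderate, detectable eQTL at $n \approx 80$–100). Expected LOD at the
  causal marker is then $-\frac{n}{2}\log_{10}(1-h^2)$.

Defaults (80 strains, 1000 traits) mirror a BXD-scale expression study.
Deliberately absent: polygenic background and relatedness (the linear model
here has no mixed-model term), genotyping error, missing data patterns,
epistasis, multi-founder alleles, and non-Gaussian expression noise. Passing
tests on this panel therefore demonstrate numerical and algorithmic
correctness of the scan — not that a single-marker linear scan is the right
model for any particular real population; for strongly structured
populations a mixed model is the appropriate extension and is out of scope
here.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` verify, among other properties:
the nested-RSS/correlation identity over 120 random draws at
$n \in \{10, 80, 200\}$ (agreement $< 10^{-9}$, observed $\sim 10^{-14}$);
element-wise agreement of `scan_eqtl()` with `brute_scan()` on an 80-strain,
500-marker, 200-trait panel with and without covariates ($< 10^{-8}$);
chunking invariance over `trait_chunk` $\in \{1, 7, 10000\}$; recovery of
planted eQTL within 10 cM for $\ge 90\%$ of 500 traits at $n = 100$,
$h^2 = 0.4$; uniformity of null peak positions over chromosomes
(chi-square goodness of fit); and $E[n r^2] \approx 1$ for null traits.
These sizes keep each check well-powered while completing in seconds to
tens of seconds; they are stated here so results are reproducible, and can
be scaled up freely.

## Worked example

```{r example}
panel <- simulate_panel(sim_config(n_strains = 80, n_traits = 200, seed = 42))
res <- scan_eqtl(panel$geno, panel$traits)
head(res$peaks[order(-res$peaks$lod), ])
# how many planted eQTL were recovered within 10 cM?
tr <- panel$truth[panel$truth$has_qtl, ]
idx <- match(tr$trait, res$peaks$trait_id)
mean(res$peaks$chromosome[idx] == tr$chr &
     abs(res$peaks$position_cM[idx] - tr$cM) <= 10)
```

The same pipeline is available from a shell through
`inst/cli/bulkscan.R` (`simulate`, `scan`, `plot` subcommands); the `plot`
subcommand draws the trans-eQTL map — peak-marker position against
cognate-gene position, cis effects on the diagonal — for peaks above a LOD
threshold (default 5). When only cM positions are available the plot uses
cM; with physical (Mb) annotations it uses Mb.

## Known limitations

* One-df tests only: two genotype classes (or a single dosage column per
  marker); no multi-allelic or >2-founder encodings.
* No permutation-based significance thresholds; the LOD > 5 convention is a
  reporting filter, not a calibrated genome-wide error rate.
* No linear mixed model: relatedness and polygenic background are not
  absorbed, so the scan is best suited to balanced RI panels.
* Missing data must be resolved upstream (`drop_incomplete()`); traits with
  sporadic missingness are dropped, not imputed, which can discard signal.
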