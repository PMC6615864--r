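---
title: "Statistical methods for pooled shRNA dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for pooled shRNA dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

# The screening problem

A pooled shRNA dropout screen infects a cell population with a library of
hairpins (here ~5 per gene), passages it for a fixed number of population
doublings under a treatment, and sequences the integrated barcodes before
(t0) and after (tF). If knocking a gene down impairs growth under a
G-quadruplex-stabilising ligand (PDS or PhenDC3) but not under vehicle
(DMSO), its hairpins become depleted specifically in the ligand arm. The
statistical task is to turn barcode counts into calibrated per-hairpin
tests and then into gene-level *sensitiser* calls, separating
ligand-specific losses from generic essentiality.

`dropscreen` implements that pipeline end to end — counting, filtering,
normalization, negative-binomial testing, gene calling, set logic,
enrichment — plus the pharmacology used around such screens (dose-response
GI values, Bliss synergy, saturation binding), and a generative simulator
with known ground truth so every stage can be validated without any
sequencing data.

# The count model and test

Counts for hairpin $g$ in sample $k$ are modelled as negative binomial
with mean $\mu_{gk}$ and dispersion $\phi_g$
($\mathrm{var} = \mu + \phi\mu^2$), with a log link and per-sample offsets
$\log(N_k f_k)$, where $N_k$ is the library size and $f_k$ the TMM
normalization factor. Designs are one-way layouts (group means for t0 and
each treatment arm). For each contrast (PDS−t0, PhenDC3−t0, DMSO−t0) the
likelihood-ratio statistic compares the two-group fit to a pooled fit and
is referred to $\chi^2_1$; BH adjustment is applied within each
pool × contrast.

Numerical choices:

* The GLM is fitted by IRLS. The exported single-hairpin fitter
  (`fit_nb_glm()`) takes arbitrary full-rank designs and uses
  step-halving; the internal whole-matrix fitter exploits the diagonal
  Fisher information of group-indicator designs to update every hairpin
  and group simultaneously, which is what makes genome-scale simulation
  studies run in seconds. The two paths are tested for agreement against
  a brute-force likelihood grid.
* Convergence is declared at a relative deviance change below $10^{-8}$
  (50 iterations maximum for the general fitter). All-zero responses are
  flagged degenerate, with fitted means 0 and coefficients at a $-\infty$
  guard rather than an error, so a complete dropout never aborts a run.
* Reported log2 fold changes come from a separate fit with a prior count
  (0.5, scaled by relative effective library size) added to the counts.
  The *test* always uses the raw counts; the prior only prevents infinite
  fold changes when an arm bottoms out at zero.

# Dispersion estimation

Both a common and a tagwise (per-hairpin) dispersion are estimated from
the Cox–Reid adjusted profile likelihood (APL): the NB log-likelihood at
the $\phi$-specific fitted means minus half the log-determinant of the
coefficient information. The common value maximizes the summed APL over a
log-spaced grid on $[10^{-4}, 10]$ refined by golden-section search.
Tagwise values maximize the weighted likelihood
$\mathrm{APL}_g(\phi) + (d_0/d_r)\,\overline{\mathrm{APL}}(\phi)$, an
empirical-Bayes shrinkage toward the common curve with prior df $d_0$
(default 10) against residual df $d_r$. $\overline{\mathrm{APL}}$ is
precomputed on the grid and spline-interpolated; the per-hairpin term is
evaluated exactly during a vectorized, per-hairpin golden-section
refinement. The limits behave as expected and are tested: $d_0 = 0$
reproduces per-hairpin ML, $d_0 \to \infty$ returns the common value
everywhere.

On null simulations at the screen's design (5000 hairpins, four groups of
three, $\phi = 0.1$) the estimator recovers the generating dispersion and
per-contrast p-values are uniform, with type-I error at the nominal 5%
level falling in [0.03, 0.08].

# Filtering and normalization

Hairpins must reach CPM ≥ 0.5 in **every** t0 replicate (5 counts in a
10M-read library); endpoint samples are never consulted, so complete
dropouts cannot disqualify themselves. The boundary is inclusive.

TMM factors follow the published weighted-trimmed-mean-of-M-values
procedure: reference = sample whose upper quartile of library-scaled
counts is closest to the mean upper quartile; hairpins zero in either
sample dropped; double trimming at 30% per tail of M and 5% per tail of A;
inverse-delta-method-variance weights; factors rescaled to geometric mean
1. The implementation matches an independently written straight-line
transcription of the formula to $10^{-10}$ and `edgeR::calcNormFactors`
to $10^{-8}$. Depth-scaling a sample changes the factors only through the
(asymptotically invariant) precision weights.

# From hairpins to genes

A gene is *significantly depleted* in a contrast when at least
`ceiling(0.5 · n_hairpins)` **or** at least 3 of its hairpins are
significant (FDR ≤ 0.05 and log2FC < 0) and the median log2FC is
negative; it is a *sensitiser* when that median is ≤ −1. Both halves of
the disjunction suffice on their own, including the two-hairpin /
one-significant edge case. The median is computed over the significantly
depleted hairpins by default (an "all hairpins" mode is provided); the
figures that pair "number of depleted hairpins" with a median fold change
motivate the default. Ligand-specific sets subtract the DMSO
depleted-gene set; cross-screen logic (Venn regions, per-screen
both-ligand sets, key genes present for both ligands in all screens) is
plain set algebra and is property-tested against inclusion–exclusion.

# Enrichment statistics

Three related tests are provided. `fisher_enrichment()` computes the
one-sided Fisher exact p (hypergeometric tail) and the fold enrichment
$(a/n)/(K/N)$; when only a background *proportion* is known (as with the
"3.3% of protein-coding genes" cancer-census background), the fold uses
the proportion and the p-value falls back to a binomial tail, labelled as
such — the two modes are never mixed silently.
`hypergeom_rightsided_batch()` applies the same test across a GMT
collection with Bonferroni (or BH) correction. `ease_score()` is the
jackknifed Fisher p (overlap reduced by one), so EASE ≥ Fisher always,
and a single-gene overlap is never significant. All tails are verified
against exhaustive binomial-coefficient sums for every table with
N ≤ 60.

# Pharmacology

**4PL dose-response.** $y = b + (t - b)/(1 + 10^{(\log_{10} x - L)h})$,
with $h > 0$ meaning inhibition (viability falls with dose) — the sign
convention is chosen so that GI values come out on the inhibition side of
the IC50, e.g. GI$_{20}$ = IC50/4 at $h = 1$ on a normalized curve.
Fitting is deterministic Levenberg–Marquardt with asymptotes started at
the data extremes, $L$ at the dose bracketing the half-range, and a
two-point multi-start $h_0 \in \{+1, -1\}$ (best RSS wins, first on
ties); free fits canonicalize to bottom ≤ top. `gi_value()` inverts the
fitted curve analytically and refuses targets outside the asymptotes.

**Bliss independence.** Fractional inhibitions are clamped to [0, 1];
the expectation from the single-agent margins is $I_a + I_b - I_a I_b$,
and synergy is reported in percentage points,
$S = 100(I_{obs} - I_{bliss})$, positive for synergy. Replicate matrices
are averaged *before* the surface is computed, and the peak is the
maximum of that mean surface (the alternative — averaging per-replicate
peaks — is upward biased). The untreated cell must sit within 5% of 100%.

**One-site binding.** $y = B_{max} x/(K_d + x)$ by least squares, with
one deterministic restart if $K_d$ comes out non-positive. The
half-saturation identity $y(K_d) = B_{max}/2$ holds on every returned
fit.

# The simulator and what it does (not) show

`make_library()` + `simulate_screen()` generate screens with known truth:

* log-normal baseline hairpin abundance (σ = 1);
* an initial multinomial bottleneck to `coverage × H` cells
  (default 1000×, the representation floor the screen design maintains);
* deterministic exponential growth within a passage,
  $2^{\Delta d (1 + e_h s_{g,c})}$, with a multinomial re-plating
  bottleneck every 3 doublings until 15;
* gamma-Poisson sequencing with mean depth 300 reads/hairpin and
  dispersion $\phi_{seq} = 0.05$, t0 sampled before any
  treatment-specific selection.

Per-hairpin knockdown efficacy is Beta(5, 2) (mean ≈ 0.71): a
vendor-optimised library where most hairpins work but some are weak.
Sensitisers carry $s = -0.2$ per doubling under their ligand, so a fully
efficacious hairpin is expected at $d \cdot s = -3$ log2 units — clearly
past the −1 calling threshold; essentials carry the same coefficient in
every arm. The closed form ignores the composition shift (dropouts free
up library share for everyone else); TMM removes that shift downstream,
and the calibration test centres on neutral hairpins for the same reason.

Deliberately **not** modelled: multiple integrations per cell (the screen
design used MOI 0.3 precisely to avoid them), PCR amplification bias,
index hopping, and wall-clock passage timing (everything is indexed by
population doublings). Passing recovery tests therefore demonstrates the
statistics under the stated generative model, not robustness to these
real-data artefacts.

At the default study conditions (1000 genes × 5 hairpins, 10% planted
ligand sensitisers, 3 replicates, 20 seeds) the full
simulate → test → call pipeline achieves gene-level sensitivity ≥ 0.9
with empirical false discovery ≤ 0.1 — the package's acceptance test
recomputes exactly this. Problem sizes in the test-suite (2000–5000
hairpins for calibration runs, 200 seeds for pharmacology recovery) were
chosen as the smallest designs at which the asymptotic checks are stable.

# Read counting

Reads are trimmed to the 22-nt guide length, 3'-quality-trimmed
(Phred+33, default minimum Q20 — the screen's stated "quality threshold
of 33" is read as the encoding offset, since Q33 is not a meaningful
base-call cutoff), and matched against the library by hash lookup: exact,
or one-mismatch mode in which a read is assigned only if exactly one
hairpin's guide sits at the minimal Hamming distance (≤ 1); ties are
discarded as ambiguous, as are exact hits on guides shared by several
hairpins. Matching a fixed set of 22-mers needs no positional aligner,
and the dictionary approach is bit-reproducible. No reverse-complement
search is performed (the protocol sequences the sense strand).

# Known limitations

* Dispersion estimation offers no abundance-trended prior, and no
  quasi-likelihood F-test is provided; at three replicates per arm the
  χ² reference is mildly liberal (visible as the upper half of the
  [0.03, 0.08] calibration band).
* The one-mismatch matcher enumerates read neighbourhoods in R; it is
  meant for desk-scale validation, not for production counting of
  100M-read lanes.
* Gene calls assume each gene's hairpins live in a single pool (true of
  the library designs modelled here); genes split across pools would be
  called per pool and unioned.
* The binding model assumes saturation kinetics; fitted $K_d$ values from
  curves that never approach saturation are indicative only, and their
  standard errors say so.
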