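---
title: "Stage-specific miR-gene co-expression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific miR-gene co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirstagenet` builds stage-specific bipartite micro-RNA-to-gene regulatory
co-expression networks across ordered tumor phenotypes — non-tumor adjacent
tissue (NT) plus progression stages I-IV, modeled on clear cell renal
carcinoma cohorts. The core idea is a three-step sieve applied per stage:

1. **Co-expression**: estimate mutual information (MI) between every miR and
   every gene over the samples of one phenotype, and keep the K
   strongest pairs.
2. **Differential expression**: call genes and miRs differentially expressed
   between *contiguous* phenotypes (NT-I, I-II, II-III, III-IV), so each
   stage is contrasted against the stage it evolved from rather than only
   against normal tissue.
3. **Canonical regulation**: within stage *s*'s top-K network, keep only
   edges whose miR and gene moved in opposite directions in the contrast
   leading into *s* (over-expressed miR with under-expressed target or vice
   versa) — the expression signature of canonical miR-mediated repression.

Downstream analyses compare the five networks as edge sets (UpSet-style
exclusive intersections, uniqueness fractions, the edges shared by all tumor
stages but absent from NT), annotate edges with chromosome/cytoband
co-location, and track *persistent* miRs — those differentially expressed in
every contiguous contrast — together with their stage-specific targets.

## Differential expression model

Counts are modeled as negative binomial with per-feature dispersion
$\phi$: $\mathrm{Var}(Y) = \mu + \phi\mu^2$. For a two-group contrast the
package:

* estimates size factors jointly over both groups by median-of-ratios
  (the reference set is features with strictly positive counts everywhere,
  so the geometric mean is defined);
* estimates $\phi$ per feature by method of moments on the normalized
  scale, pooled across the two groups with degree-of-freedom weights,
  floored at $10^{-8}$; with `dispersion_mode = "trend"` the raw estimate
  is shrunk 50/50 toward a fitted $a_0 + a_1/\mu$ mean-dispersion trend;
* computes $\log_2\mathrm{FC} = \log_2\frac{\bar\mu_B + c}{\bar\mu_A + c}$
  with pseudocount $c = 0.5$ on normalized means (avoids $\log 0$;
  configurable), and a delta-method standard error
  $\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left(
  \frac{\widehat{\mathrm{Var}}(\bar\mu_A)}{(\bar\mu_A + c)^2} +
  \frac{\widehat{\mathrm{Var}}(\bar\mu_B)}{(\bar\mu_B + c)^2}\right)$ with
  $\widehat{\mathrm{Var}}(\bar\mu_g)$ carrying both the Poisson part
  (scaled by the group's size factors) and the $\phi\mu^2$ part;
* takes a two-sided p-value from the standard normal reference for the
  Wald statistic, with Benjamini-Hochberg adjustment across all features
  of the matrix. All-zero features are defined (not errors):
  $\log_2\mathrm{FC} = 0$, $p = 1$.

Thresholds follow the field's convention for this design and are strict
inequalities: genes are `over`/`under` at $|\log_2\mathrm{FC}| > 1$ and
BH-adjusted $p < 10^{-5}$; miRs at $|\log_2\mathrm{FC}| > 0.5$ and **raw**
$p < 10^{-5}$. The miR rule uses the raw p-value by default because miR
panels are small (hundreds of features, so FDR adjustment is both less
necessary and less stable) and because the two RNA classes have different
dynamic ranges; both rules expose `use_adjusted` so either convention can
be selected.

Under a global null (identical NB groups, $n = 30$ per group) the raw
$p < 0.05$ call rate of this test sits near 0.055 — slightly above nominal,
as expected for a plug-in Wald test that ignores dispersion-estimation
noise — and calls at the strict thresholds above are essentially absent
(none in $10^4$ null features in the shipped checks).

## Mutual-information estimator

The paper-scale estimator must be deterministic and cheap at ~4.5 million
pairs, and invariant to monotone distortions of expression scale. The
package uses: average-tie rank transform, equal-frequency binning into
$B = \max(2, \lfloor n^{1/3}\rfloor)$ bins (`"auto"`; $n$ = samples in the
phenotype), and the plugin estimate
$\widehat{I} = \sum_{ij} \hat p_{ij}\ln\frac{\hat p_{ij}}{\hat p_{i\cdot}\hat p_{\cdot j}}$
over occupied cells, optionally adding the Miller-Madow small-sample
correction $(m_{occ} - r_{occ} - c_{occ} + 1)/(2n)$, with the result floored
at 0. Binning is `bin(i) = ceiling(rank_i * B / n)`, which makes
$\widehat I(x, x) = \ln B$ exactly whenever $B$ divides $n$ and all values
are distinct, and which assigns boundary ties deterministically.

Two numerical notes. Rank binning yields invariance under strictly
*increasing* transforms always; under decreasing transforms only when $B$
divides $n$ (otherwise the remainder samples sit in different bins after
rank reversal). Constant vectors occupy a single bin and give MI = 0.
Top-K retention sorts by MI descending with ties broken lexicographically
by (miR id, gene id) in C-locale radix order, so networks are reproducible
across platforms and invariant to input edge order.

## Retention parameter K

The study design keeps the 100,000 strongest of
$275 \times 16{,}227 = 4{,}462{,}425$ candidate pairs — a retention
fraction of 2.24%. At the desk-scale default of $50 \times 300 = 15{,}000$
pairs the package scales K proportionally to **K = 336**. Retention
fraction, not absolute K, is the quantity that controls the null
false-inclusion rate: a pair with no real dependence lands in one top-K
list with probability ≈ K/N, and in all four stage lists with probability
≈ (K/N)^4. At 2.24% retention the expected number of chance edges in the
"shared by all tumor stages, absent in NT" set is ~0.004 across 15,000
pairs, so that set is essentially pure signal; a much larger K fraction
would fill it with coincidences and likewise dilute the precision of the
canonical networks. K is a plain argument everywhere.

## Synthetic study design

`default_study()` fixes the conditions every check runs under: 300 genes,
50 miRs, sample sizes NT = 40, I = 60, II = III = IV = 40 (stage I largest,
echoing the imbalance typical of tumor-stage cohorts), NB dispersion 0.1,
log-normal library-size factors with $\sigma = 0.15$, and baseline means
drawn log-uniformly from $2^4$–$2^{10}$ counts.

Planted structure:

* **One persistent miR** (`mir01`) with transition effects
  $(-2.5, -2.0, +2.0, -2.0)$ log2 units — under, under, over, under, a sign
  flip mid-progression like the motivating exemplar — coupled to a
  different target gene in each stage.
* **16 stage-specific negative couplings** (4 per stage) whose endpoints
  are planted DE with opposite signs (miR ±1.5, gene ∓2) in the matching
  contiguous contrast.
* **Free DE features** per contrast (2 miRs, 4 genes) that are *not*
  coupled, so the canonical filter has same-sign and uncorrelated bait.
* **5 tumor-only persistent couplings** active in stages I-IV but not NT
  (endpoints not DE) — the ground truth for the tumor-shared-not-control
  set — and **5 positive couplings** active everywhere.

Coupling uses a shared per-sample latent $z \sim N(0,1)$: the gene mean is
scaled by $e^{\lambda z - \lambda^2/2}$ and the miR mean by
$e^{\pm\lambda z - \lambda^2/2}$, with $\lambda = 0.85\rho$. The
$-\lambda^2/2$ term keeps planted fold changes unbiased
($E\,e^{\lambda z} = e^{\lambda^2/2}$), and the 0.85 calibration makes the
induced rank-correlation magnitude ≈ $\rho$ given the ~0.11 residual
log-scale variance of NB counts at dispersion 0.1 and the planted mean
scale. Latent-factor coupling was chosen over copula sampling because it
approximately preserves NB marginals while giving sign-controlled
dependence that is transparent to test.

Two second-order design constraints matter and are worth recording:

* A coupled feature carries extra variance $e^{\lambda^2} - 1$ ≈ 0.6 on
  top of its NB dispersion, which roughly doubles the Wald SE of its fold
  change. Planted effects on coupled endpoints are therefore sized (miR
  1.5, gene 2, persistent miR 2-2.5) so the strict $p < 10^{-5}$ rules are
  still cleared with high probability.
* Transition effects are cumulative, so a repeatedly down-regulated
  feature can drift toward the count floor where Poisson noise swamps the
  latent coupling. Planted features' baselines are therefore lifted by
  their worst-case cumulative depletion, keeping every per-phenotype mean
  in the $2^6$–$2^9$ range.

Coupled pairs are placed on the same cytoband for the configured fraction
(default 50%) — honored exactly to rounding within each coupling class
rather than by independent coin flips, so small classes (the 5 tumor-only
pairs) realize the intended fraction. The persistent-miR targets use
nearby start positions when co-located.

What the generator does **not** emulate: batch structure, GC-content and
length bias curves, isoform-level miR quantification, compositional
library effects, or correlated gene modules beyond the planted pairs.
Passing checks on this generator demonstrate that the pipeline's logic
(filtering, testing, ranking, set algebra, tracking) is correct under the
model it assumes — not that the model captures every property of real
tumor cohorts.

## Filtering and preprocessing

Features are removed, in order, when (1) absent from the annotation,
(2) zero in more than 50% of samples (strict inequality), or (3) below a
mean of 10 counts (strict). A removed feature is attributed to the first
filter that caught it, and the filter report satisfies the accounting
identity `n_input = n_kept + sum(removals)` by construction. The same
filters apply to the miR matrix; the annotation filter can be skipped
there (`annot = NULL`) for pre-harmonized miR matrices. An optional
covariate-correction stage stratifies features into equal-frequency bins
of a covariate (GC, length) and rescales each bin to the global median —
a deterministic surrogate for loess-type bias removal; zero-median bins
are left untouched and reported. Batch correction is intentionally not a
pipeline stage (the generator has no batch variable); the stage order
leaves room to add one upstream of DE.

## Degenerate inputs and tie-breaking

* Sample tables: records with empty or "not reported" stages are dropped
  and counted; any other unmappable label is a hard error.
* Phenotypes with fewer than 4 samples stop `build_stage_series` by name;
  DE groups need at least 2 samples each.
* The NT network is never canonically filtered — it has no preceding
  contrast; it participates in comparisons at top-K level (also when the
  comparison level is `canonical`).
* Edges whose endpoints lack DE records are treated as `ns`, not errors:
  DE tables and networks may legitimately cover different feature sets
  after filtering.
* Empty canonical networks, empty edge files, and 0/0 uniqueness or
  co-location fractions are all defined (0 with a warning), never errors.
* Persistence does not require a constant sign across the four contrasts.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full pipeline on the
default 300 × 50 study (five MI networks of 15,000 candidate pairs each),
10 simulated studies for the recovery medians, 20 null datasets of 500
features for test calibration, 1,000 random pairs for MI-oracle
equivalence, and 200 random network collections for the set-algebra
oracle. These sizes were chosen so the whole battery completes in about a
minute on one core while every estimator still operates in its intended
regime; all of them are plain arguments if larger runs are wanted.

## Known limitations

* The NB Wald test is a plug-in test: dispersion uncertainty is not
  propagated, so raw p-values are mildly anti-conservative near the
  nominal 5% level (≈ 0.055 under the null at $n = 30$). The pipeline's
  decisions all happen at $p < 10^{-5}$, where this bias is immaterial at
  the tested sample sizes.
* MI at $B = 3$ bins (the auto rule for 27-63 samples) is coarse;
  moderately coupled pairs near the top-K boundary can drop in or out
  between replicates. The recovery guarantees are therefore stated as
  medians over seeds.
* Co-location analysis uses start positions and string-equality of
  cytobands only; no band-hierarchy logic, no overlap semantics.
* Edge identity is the ordered (miR, gene) pair; the bipartite design has
  no miR-miR or gene-gene edges and no triplet-pruning step (data-processing
  inequality pruning does not apply to a bipartite all-pairs top-K design).
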