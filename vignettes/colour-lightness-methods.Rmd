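---
title: "Methods: colour lightness, phylogenetic decomposition and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour lightness, phylogenetic decomposition and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette defines the statistical models implemented by `froglight`,
the design of the synthetic-world generator used to validate them, the
numerical choices made along the way, and the known limitations. It makes
no empirical claims beyond what the package's tests and the acceptance
script compute.

## 1. Colour lightness

An individual's dorsal colouration is recorded as a set of colour patches,
each a wheel colour (or explicit RGB triple) with a coverage fraction in
5% steps summing to 1. Its **colour lightness** is

$$ L \;=\; \sum_i c_i \,\frac{R_i + G_i + B_i}{3}, $$

ranging from 0 (black) to 255 (white). Species values are unweighted means
over individuals, pooling sexes and morphs (`species_lightness()`). The
default scoring wheel (`build_default_wheel()`) has 18 equally spaced hues
at saturations 10/40/70/100%, converted from HSV at a common value
channel; any printed wheel's actual catalog can be supplied as CSV
instead. Nearest-colour quantisation errs by at most half the wheel's
largest lightness gap (`wheel_max_gap()`); two-colour bracketing with 5%
coverage rounding (`lightness_to_patches()`) errs by at most `gap × 0.025`.
Systematic differences between observers are measured (and can be removed)
by ordinary regression of one observer's estimates on another's
(`observer_calibration()`).

## 2. Phylogenetic comparative methods

**Covariance.** Under Brownian motion on a rooted tree, trait covariance
between species is the shared root-to-MRCA path length
(`vcv_from_tree()`). **Pagel's lambda** rescales the off-diagonal of that
matrix; `fit_pagel_lambda()` profiles the mean and scale analytically from
the Cholesky-whitened data and maximises over λ ∈ [0, 1], comparing
interior and boundary optima. On a star tree the likelihood is flat in λ
and the fit is flagged unidentifiable.

**Decomposition.** The phylogenetic mixed model
$y = \mu + a + e$, $a \sim N(0, \sigma_a^2 C)$, $e \sim N(0, \sigma_e^2 I)$
is fitted by EM in the eigenbasis of $C$ (`lynch_decompose()`): with
$C = U D U^\top$, the rotated data decouple into independent scalar
problems with variances $\sigma_a^2 d_i + \sigma_e^2$, making each EM
iteration O(n) after one eigendecomposition. The reported components are
the BLUPs $P = \hat a$ and $S = \hat e$; because
$\hat a + \hat e = y - \hat\mu$ identically, the additive identity
$\mu + P_i + S_i = y_i$ holds to machine precision for every species (the
package tests assert 1e-8). The EM log-likelihood trace is returned and is
non-decreasing. Near the pure-Brownian boundary ($\sigma_e^2 \to 0$) EM
converges slowly; iterations are cheap, so the default cap is 10,000.

**PGLS.** `pgls_fit()` whitens response and design with the Cholesky
factor of the λ-transformed covariance and solves the least-squares
problem; λ is profiled by ML when requested. At λ = 0 it reproduces OLS
and at λ = 1 the closed-form GLS estimator, both to 1e-10 (tested). R² is
reported on the whitened scale and labelled as such.

**Grafting.** Species with colour data but absent from the tree are
attached inside their genus: a seeded random congeneric tip is chosen and
the new tip bound to its terminal branch at 10% of its length
(`graft_missing_species()`), preserving ultrametricity; pruning the grafts
recovers the original covariance.

## 3. Assemblages, filters and diversity

Species occupancy on the equal-area grid is summarised per cell as the
unweighted mean of raw lightness and of its P and S components
(`assemblage_trait_means()`); species without colour data count towards
richness but not the means. Cells with water fraction strictly above 0.5
are excluded, as are assemblages whose colour coverage is strictly below
33% (`filter_cells()`, `filter_assemblages()`); group-level models exclude
families with fewer than 10 species, realms with at most 50 assemblages,
and (for disease-severity models) families with fewer than 9 species.

Colour-lightness **diversity** is the standardised effect size of mean
pairwise distance: `ses = (observed − null mean) / null sd` against
`n_draws` same-richness draws without replacement from the assemblage's
realm pool (`ses_mpd()`). Mean pairwise distance uses the sorted-weights
identity $\sum_i (2i - k - 1)\, x_{(i)}$, so a draw costs O(k log k). When
$\binom{|pool|}{k}$ is at most `enum_cap` the null is enumerated
exhaustively. Each cell's draw seed is derived from the global seed and
the cell id, so results do not depend on evaluation order.

## 4. Environmental regression

Assemblage lightness is regressed on z-scaled mean annual temperature,
elevation, productivity (EVI) and UVB. The spatial model adds a
tensor-product smooth of the coordinates, `te(x, y, bs = "cr")`, fitted
with `mgcv` under GCV (`trend_surface_fit()`); since the smooth's penalty
null space nests the plain linear model, the trend-surface R² can never
fall below the linear one. **Basis dimension:** the default is k = 13 per
margin, chosen so that on the default 50×50 study grid the knot spacing
(≈3.8 cells) resolves latent structure down to the generator's
environmental-field autocorrelation range (4 cells); a coarser surface
demonstrably leaves lag-1 residual autocorrelation behind. Residual
spatial structure is diagnosed with Moran's I in equal-width distance
classes (`morans_correlogram()`, binary weights, `ape::Moran.I`) and
judged against a seeded permutation band (`moran_permutation_band()`).

Predictor importance uses **hierarchical partitioning**
(`hierarchical_partitioning()`): each predictor's independent contribution
is its average incremental R² over all orderings, computed from all
2^k subset R² with level weights; contributions sum exactly to the
full-model R² (tested against explicit enumeration of all 4! orderings to
1e-10). Realm- and family-level slopes come from a single full-interaction
model (`grouped_interaction_fit()`), equivalent to separate per-group
regressions on the common z-scale. Disease-severity models
(`severity_models()`) regress an ordinal severity score (unaffected
co-occurring species coded 0) on the colour × productivity interaction per
family and overall by PGLS.

## 5. The synthetic world

The generator (`world_config()`, `simulate_world()`) plants every signal
the analysis is supposed to recover, under one master seed with
independent per-stage streams (`stage_seed()`), so changing an
observation-stage knob never perturbs the environment or the tree.

- **Environment** (stage 1): a 50×50 planar grid; MAT follows a quartic
  latitudinal profile (flat warm tropics, steep temperate decline) plus a
  smooth Gaussian random field (range 4 cells); EVI couples to MAT at a
  configured correlation of 0.5, made exact by orthogonalising its
  independent component against MAT before mixing, with extra tropical
  variance; UVB peaks at the equator and rises with elevation; four
  latitudinal realm bands; a 3-cell water border (~1,936 land cells).
- **Tree and trait** (stage 2): a 300-tip pure-birth tree rescaled to unit
  height; genus and family labels from slicing the tree at heights 0.15
  and 0.45. Thermal, productivity and UVB niche centres evolve as
  (transformed) Brownian motion; true lightness is
  `165 + 20·z(thermal) − 10·z(productivity) − 8·z(UVB) + a + e` with `a` a
  λ-damped Brownian deviation (λ = 0.5, σ² = 100) and `e` iid (σ² = 64),
  clipped to the wheel's lightness span (clip fraction is reported and
  tested to stay below 5%). Because the niche terms are themselves
  phylogenetically conserved, the trait-level signal exceeds the
  configured deviation λ; the variance-implied composite value is stored
  in the manifest for recovery tests.
- **Ranges and observations** (stage 3): each species occupies the
  flood-filled contiguous block of land cells matching all three niche
  centres within configured breadths (breadths widen ×1.5 on empty
  matches, up to 3 retries, then the species is dropped with a log entry).
  Observations: 1 + Poisson(0.4) individuals per species with observer
  noise (sd 5), expressed as two bracketing wheel colours with 5%
  coverages; 10% of species lack observations entirely; calibration pairs
  are generated with a planted slope/intercept/noise; 5% of ranged species
  are withheld from the distributed tree (never a genus's last tip) to
  exercise grafting; an ordinal severity table is generated from a
  colour × productivity latent interaction.

Multi-axis niches are essential: if ranges tracked temperature alone, the
productivity and UVB assemblage signals would exist only through latitude
collinearity and their planted signs would not be identifiable.

## 6. Numerical choices

- All likelihood computations use Cholesky whitening (`backsolve` against
  the transposed factor), never explicit inverses.
- λ optimisation uses `optimize()` on [0, 1] with explicit endpoint
  comparison, since boundary optima are common.
- The EM decomposition stops on a relative log-likelihood change of 1e-8;
  additivity of the returned components is exact by construction.
- SES null draws are seeded per cell by hashing (global seed, cell id), so
  parallel or reordered evaluation cannot change results.
- Every pipeline stage writes plain-text outputs and records MD5 hashes in
  a run manifest; a repeated run with unchanged inputs is skipped
  (hash-checked idempotence) and a fixed master seed reproduces all
  outputs byte-identically (tested).

## 7. Limitations

- The generator is a stylised world: rectangular geometry, four realm
  bands, one observer, no spatial error in the environmental layers. It
  validates the machinery, not any empirical claim about real amphibians.
- The composite trait's phylogenetic signal is only approximately Pagel-λ
  distributed (it is a mixture of niche-driven and λ-damped components);
  recovery tests therefore compare against the variance-implied value.
- The trend-surface basis default is tied to the default grid's field
  scale; other grids should scale `k` accordingly.
- `ses_mpd()` assumes the realm pool contains the assemblage and that all
  pool species carry trait values; both are enforced, not repaired.
- PGLS R² is on the whitened scale and not comparable to OLS R².
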