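---
title: "Model-based geostatistics for childhood stunting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistics for childhood stunting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Childhood stunting — a height-for-age z-score (HAZ) more than two standard
deviations below the WHO growth-standard median — is the canonical marker of
chronic undernutrition. National household surveys such as the Demographic and
Health Surveys (DHS) measure it on a few hundred to a couple of thousand
sampled clusters, yet nutrition programmes need estimates for *second-level*
administrative units (districts / local government areas), most of which
contain no sampled cluster at all. Model-based geostatistics bridges that gap:
a latent, spatially continuous risk surface is estimated from the sampled
clusters and child-level covariates, then integrated over administrative
polygons to give small-area prevalence estimates with honest credible
intervals.

`stuntmap` implements that pipeline end to end — survey descriptives, raster
covariate linkage, a finite-element SPDE representation of the spatial field,
Bayesian spatial logistic regression, DIC/WAIC model comparison, gridded
prediction with admin aggregation, and cluster-level hold-out validation —
together with a synthetic DHS-like survey generator so that every stage is
testable without restricted microdata.

## The model

For child $i$ in cluster $c(i)$ at location $s_{c(i)}$:

$$y_i \mid p_i \sim \mathrm{Bernoulli}(p_i), \qquad
\operatorname{logit} p_i = x_i^\top \beta + S(s_{c(i)}),$$

where $x_i$ collects categorical determinants (illness, maternal, household,
health-service, climatic factors; reference-level coding) and $S$ is a
zero-mean stationary, isotropic Gaussian random field with Matérn covariance
of smoothness $\nu = 1$. The non-spatial model drops $S$.

### SPDE representation

$S$ is represented as the weak solution of
$(\kappa^2 - \Delta)(\tau S) = \mathcal{W}$ on a triangulated mesh: with
linear finite elements, lumped mass matrix $C$ (diagonal) and stiffness
matrix $G$, the mesh-vertex weights have sparse precision

$$Q(\kappa, \tau) \;=\; \tau^2\!\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),$$

the $\alpha = 2$ (i.e. $\nu = 1$ in two dimensions) member of the Matérn
family. The smoothness is a fixed, documented constant — the conventional
choice for prevalence mapping — not a tuning knob. Derived quantities used
throughout reporting:

* spatial range $\rho = \sqrt{8}/\kappa$ (correlation $\approx 0.1$ at
  distance $\rho$);
* marginal variance $\sigma^2 = 1/(4\pi\kappa^2\tau^2)$.

A sparse projector matrix $A$ of barycentric weights maps vertex values to
observation or prediction locations; rows for locations inside the mesh have
at most three non-zeros summing to one.

The mesh works in raw lon/lat degrees ("point-coordinate units"), so
$\kappa$ is per degree and the range is in degrees; `degrees_to_km()` converts
at a stated reference latitude for reporting. The two are reported side by
side and no agreement between unit systems is forced.

### Priors and computation

Fixed effects get independent $N(0, 10^2)$ priors on the log-odds scale —
effectively flat over the plausible range of odds ratios. The spatial
hyperparameters get penalised-complexity-style priors expressed on the
interpretable scale: $P(\rho < \rho_0) = 0.5$ with $\rho_0$ defaulting to a
fifth of the domain diameter, and $P(\sigma > 1) = 0.1$. Both are documented
defaults, configurable in `model_spec()`.

Inference is exact-conditional MCMC rather than an integrated nested Laplace
approximation: the inferential target (posterior odds ratios, credible
intervals, prevalence surfaces) is the contract, not any particular
approximation algorithm, and agreement with a brute-force quadrature
posterior is part of the test suite. The sampler is:

1. **Pólya-Gamma augmentation.** $\omega_i \sim \mathrm{PG}(1, \eta_i)$ makes
   the conditional of all Gaussian unknowns exactly Gaussian. The PG(1, z)
   draws use the exact alternating-series rejection sampler (compiled code,
   no truncation or tuning).
2. **One Gaussian block.** $(\beta, S)$ is updated jointly from its exact
   conditional with sparse precision
   $\left[\begin{smallmatrix} X^\top\Omega X + B_0^{-1} & X^\top \Omega A\\
   A^\top \Omega X & Q + A^\top\Omega A\end{smallmatrix}\right]$,
   via a sparse Cholesky factorisation whose symbolic pattern is cached
   across iterations.
3. **Collapsed Metropolis for $(\kappa, \tau)$.** Random-walk proposals on
   $(\log\kappa, \log\tau)$ are accepted with $(\beta, S)$ *integrated out*
   (the Gaussian evidence is available from the same factorisation). The
   proposal is correlated along the variance-preserving direction
   $\delta\log\tau \approx -\delta\log\kappa$, because $\sigma^2$ is far
   better identified than $\kappa$ alone; the step size adapts towards
   20–40% acceptance during burn-in. Collapsing removes the strong
   $S \leftrightarrow (\kappa,\tau)$ coupling that otherwise makes the
   hyperparameters mix an order of magnitude slower.

Convergence is reported per fit as split-$\widehat R$ (threshold 1.05) and
effective sample size. Default controls (`mcmc_control()`) are sized for
desk-scale synthetic analyses; production analyses should raise iterations
and chains.

### Model comparison

`compute_dic()` uses the classic $p_D = \bar D - D(\bar\theta)$ variant, and
`compute_waic()` the variance-based penalty (pWAIC2), with a max-shifted
log-mean-exp so extreme log-likelihoods cannot overflow. For spatial fits the
pointwise likelihood conditions on the sampled latent field (the conditional,
INLA-comparable choice; the alternative of marginalising the field over its
posterior is deliberately not used). Observations whose log-likelihood draw
variance exceeds 0.4 trigger the customary reliability warning.

### Prediction and aggregation

`predict_grid()` evaluates, per retained posterior draw and grid pixel,
$p = \operatorname{logit}^{-1}(x_g^\top\beta_d + (A_{\mathrm{grid}}S_d)_g)$.
Only raster-backed covariates (the climate/urbanisation bands) vary across
pixels; survey-only covariates are held at their reference levels, so the
surface is a *reference-child* risk surface — the conventional choice when
child-level covariates have no raster counterpart. Admin-level and national
estimates average pixels *within each draw* (equal weights by default, an
optional population raster hook otherwise), so credible intervals at every
aggregation level are coherent functionals of one posterior rather than
aggregates of pixel-wise intervals.

### Hold-out validation

`split_clusters()` partitions whole clusters 75/25 (test size
`floor(0.25 n)`), stratified by admin-1 so the held-out set preserves
geographic spread (a plain random split is a flag away). `evaluate_holdout()`
scores posterior-predicted against observed cluster prevalence: Pearson and
Spearman correlations (both reported, since correlation type is a reporting
choice), mean error, MAE, and 95% predictive-interval coverage with the
binomial sampling noise of the finite cluster size folded in.

## The synthetic survey generator

`simulate_survey()` emulates the design of a national DHS:

* **Two-stage stratified cluster sampling.** Voronoi admin maps (level 1
  subdivided into level 2), strata = admin-1 x urban/rural with sizes
  proportional to polygon area and the urban fraction, clusters allocated by
  largest remainder — mimicking PPS selection of enumeration areas — with 30
  households per cluster and a Poisson number of analysed children
  (mean 9.2 per cluster at national scale, matching a 12,627-children /
  1,377-cluster survey; the eligible-child distribution is not published, so
  Poisson is the modelling choice).
* **Geo-masking.** Cluster GPS coordinates are displaced along a uniform
  bearing by a distance uniform on [0, 2 km] (urban) or [0, 10 km] (rural),
  redrawn until inside the country polygon; true coordinates are retained
  for validation only. The real DHS scheme additionally sends 1% of rural
  points up to 10 km — the uniform cap is the documented simplification,
  configurable.
* **Covariate structure.** Child-level categories are drawn from the
  published marginal distributions and cluster-level climate categories come
  from smooth synthetic rasters through the same circular-buffer extraction
  used for real data; the true conditional log-odds default to the published
  adjusted odds ratios (`covariate_catalog()`), the latent field to
  $\kappa = 7.33$, $\sigma^2 = 0.24$, and the intercept to $-0.6$.
* **HAZ back-fill.** Continuous z-scores are drawn from a
  $N(-1.3, 1.1^2)$ truncated consistently with stunting status, so
  `classify_stunting()` round-trips exactly.

What the generator does **not** emulate: household non-response (the study
survey's response rate was 99.3%), informative sampling within strata,
measurement error in anthropometry, and non-stationarity or anisotropy of the
latent field. Passing recovery tests therefore demonstrate the pipeline's
internal consistency under its own assumptions, not robustness to their
violation on real data.

## Numerical choices

* **Delaunay triangulation** is computed by Bowyer–Watson insertion with a
  deterministic $10^{-9}$ relative jitter to break cocircular ties (regular
  grids); the jittered coordinates are the mesh coordinates, so the
  triangulation is exactly Delaunay for the coordinates used (property-tested
  against the empty-circumcircle definition).
* **Boundary effect.** The Neumann boundary of the FEM domain inflates the
  field variance near the hull, so `build_mesh()` surrounds the data with
  three concentric convex rings (default offset 15% of the cloud diameter).
  Lumped-mass discretisation adds a relative variance bias of roughly
  $(h\kappa)^2/2$ at mesh spacing $h$; meshes should keep
  $h \lesssim 0.3/\kappa$ where that bias matters.
* **Climate band edges.** Published band labels disagree slightly between
  sources (141 vs 142 mm; 34.9 vs 35.0 °C): the bands are implemented as
  half-open intervals — DLST $[30, 35)$, rainfall $[142, 1200)$ — and the
  aridity bands as $<17.5$ / $[17.5, 32.5]$ / $>32.5$, so every covariate
  domain is partitioned without gaps; the choice is documented here and
  enforced by tests.
* **Buffer extraction** uses the cell-centre-in-buffer rule (the common
  zonal-statistics default) on the sphere, with nodata cells excluded and a
  sub-cell buffer falling back to the containing cell.
* **Stunting boundary** is strict (`HAZ < -2.0` exactly); implausible
  scores ($|HAZ| > 6$) are flagged out per WHO convention (configurable,
  since survey reports are silent on flagging).
* **Report rounding** is half-up to one decimal, matching published tables;
  all computation carries full precision.
* **Survey variance** uses the Horvitz–Thompson ratio estimator with
  stratified between-PSU Taylor linearisation; a stratum contributing a
  single PSU is treated as a certainty unit (zero variance contribution)
  with a warning.
* **Degenerate inputs** error early and descriptively: zero-area bounding
  boxes, collinear meshes, empty strata, duplicate cluster ids, non-positive
  weights, locations outside the mesh.

## Problem sizes used in the checks

The recovery and comparison studies shipped with the package are scaled-down
designs chosen so the spatial signal is actually identifiable: 300 clusters
of 20 children on a 4°x4° domain (cluster spacing ≈ 0.23°, comfortably below
the true range of 0.386°) for hyperparameter and odds-ratio recovery; 150
clusters x 15 children for the spatial-vs-non-spatial information-criterion
comparison; 400 clusters x 8 children for the null-data validation check
(enough held-out clusters that a null correlation concentrates near zero).
Meshes use cutoffs of 0.12–0.25° with graded extension rings, giving a few
hundred vertices. These sizes are the package's own desk-scale choices; the
same functions run unchanged at full national scale.

## Known limitations

* The latent field is stationary and isotropic; no spatio-temporal or
  non-stationary extensions.
* Marginal-likelihood estimation is out of scope (no bridge/path sampling);
  model choice relies on DIC/WAIC.
* Prediction holds survey-only covariates at reference levels rather than
  integrating over their population distribution; admin estimates are
  therefore reference-child surfaces unless a population raster and
  covariate rasters for all terms are supplied.
* Replicate-weight (jackknife/BRR) survey variance is not implemented; the
  Taylor-linearised estimator is.
* The degree-based FEM treats lon/lat as planar coordinates, appropriate at
  the scale of a single low-latitude country; spherical FEM is out of scope.
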