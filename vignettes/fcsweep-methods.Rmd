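---
title: "Methods: simulating and evaluating resting-state connectivity pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating resting-state connectivity pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsweep)
```

# What the package is for

Estimates of resting-state functional connectivity from fMRI are confounded
by vascular physiology, head motion, temporal autocorrelation, and
misalignment between template regions of interest (ROIs) and a person's true
functional regions. Which preprocessing choices mitigate which confound --
and at what cost to reliability -- is an empirical question that in real
cohorts can only be answered observationally, because the ground truth is
unknown. `fcsweep` turns that question into a controlled experiment: it
simulates two-session, multi-subject ROI-voxel datasets in which those
confounds are planted with known structure, runs the standard grid of
preprocessing choices over them, and scores every pipeline with the same
battery of reliability and confound-association indices one would use on
real data.

# The generative model

Each cohort is defined by a `cohort_spec()`. For subject $s$ with age $a_s$,
session $k$ of length $T_k$:

**Traits.** A Gaussian copula couples age (uniform on 18--88 years), a
standardized session-specific *vascular health* score $v_{sk}$, and a
lognormal session-specific *trait motion* score $m_{sk}$ (mm RMS
displacement, median 0.15). Latent correlations are analytically inflated to
undo the attenuation of the margin transforms, so the observed Pearson
targets hold: $\mathrm{cor}(a, v) = -0.50$, $\mathrm{cor}(a, m) = +0.50$,
and across-session reliabilities of $0.77$ for both traits. Jointly
infeasible targets (non-positive-semidefinite latent matrix) raise an error
naming the offending pair.

**True connectivity.** ROI latent signals follow a stationary AR(1) process
whose cross-sectional correlation is the subject's true connectivity
$C_s = C_0 + (a_s - \bar a)\,E$, where $C_0$ has block structure over 16
networks (within-network correlation 0.45, between 0.10) and $E$ is the
planted age-effect map (default: within-network slope $-0.002$/yr,
between-network $+0.0004$/yr; eigenvalues are clamped and the diagonal
restored if an extreme age pushes $C_s$ off the correlation manifold). Both
sessions share $C_s$; only noise is regenerated, which is what gives
test-retest reliability its planted ceiling.

**Voxels.** A voxel in ROI $r$ carries
$\sqrt{h}\,\ell_r(t) + \sqrt{1-h}\,\varepsilon(t)$ with homogeneity share
$h = 0.5$ and per-voxel AR(1) noise. The AR(1) coefficient is
$\rho(a) = 0.45 - 0.0037\,(a - 18)$, i.e. $0.32$ at the mid age of the
default range, declining with age.

**Global physiological signal.** One AR(1) signal $g(t)$ per session is
added to *every* ROI voxel and every WM/CSF nuisance voxel with amplitude
$\alpha_{sk} = g_0 \exp(0.35\, v_{sk})$ ($g_0 = 0.7$ by default), so better
vascular health means a stronger shared signal and higher raw connectivity.
The nuisance pools contain this signal plus independent noise and no network
signal, which makes WM/CSF regression an effective but not perfect antidote.

**Motion spikes.** Motion channels are random walks with occasional large
innovations; timepoints where the displacement trace exceeds the
$(1-f_s)$-quantile of its own trace receive additive heavy-tailed ($t_3$)
offsets with a subject-stable spatial pattern. Spike rate and amplitude
scale with trait motion, so artefact burden is age-correlated and reliable
across sessions. `exclude_high_spike()` implements the mean + 2 SD exclusion
rule on the recorded spike percentages (strict inequality; a zero-spread
distribution excludes nobody).

**Boundary misalignment.** Each subject gets a smooth random displacement
field over the ROI grid with magnitude `misalignment_scale_per_year`
$\times\,(a - 18)$ mm. A boundary voxel mixes the latent of its
best-aligned foreign neighbor in proportion to the displacement (capped at
a half mixture per lattice spacing), normalized to unit variance. This
reproduces increasing idiosyncrasy in the location of functional regions
with age without any image registration. The spatial scale of the real
phenomenon is not quantified in the literature we emulate, so the default
(0.02 mm/yr, i.e. up to 1.4 mm at age 88 on a 3 mm lattice) is an exposed
free parameter chosen once to be physiologically modest.

# Preprocessing

**Confound designs** (`confound_design()`): 24 motion regressors (each
channel, its backward difference with first element zero, and both squared)
plus, depending on the option, expanded mean CSF (option C, 28), expanded
mean CSF and WM (CW, 32), or five CompCor components of the jointly pooled,
variance-normalized CSF+WM voxels (CC, 29). Filtering is simultaneous with
regression: DCT-II columns at frequencies $k/(2T\,\mathrm{tr})$ up to the
high-pass cutoff (so $K = \lfloor 2T\,\mathrm{tr}\,f \rfloor$ columns; 8 at
$T=261$, tr $=1.97$ s, $f=0.008$ Hz), plus, for band-pass, all columns above
the upper cutoff. Joint estimation matters because sequential projection
equals the joint fit only when the blocks are orthogonal (tested).

**Autocorrelation and pre-whitening** (`estimate_autocorr()`,
`prewhiten()`): the residual temporal covariance of each ROI is modelled as
$V = \sigma^2 I + \sum_{i=1}^{8} \lambda_i Q_i$, with
$Q_i[t,u] = \exp(-|t-u|\ln 2 / h_i)$ on the doubling half-life grid
$h_i \in \{0.5, 1, \ldots, 64\}$ TRs (the grid spacing is our choice; only
the range and count are given in the literature). A separate white-noise
hyperparameter is included, as is standard. Hyperparameters are estimated
from the voxel-pooled covariance by Fisher scoring on the restricted
likelihood: gradients are exact, the expected information is approximated in
the frequency domain (the Toeplitz components are nearly diagonalized by the
DFT), positivity is enforced by optimizing $\log\lambda$, steps are halved
until the objective does not decrease, and iteration stops at a relative
log-likelihood change below $10^{-6}$ (at most 64 iterations). A
`"whittle"` method maximizes the Whittle frequency-domain approximation of
the same likelihood directly from the pooled periodogram; it agrees with the
covariance-domain fit on simulated AR data (tested) at a small fraction of
the cost, and is therefore the default inside cohort-scale pipeline sweeps,
where tens of thousands of ROI fits are needed. Should a fit fail to
produce finite values, a moment-matched AR(1)+white model is substituted and
flagged. The whitener is $V^{-1/2}$ by eigendecomposition (`"chol"` uses
the inverse Cholesky factor, which satisfies the same identity
$W V W^\top = I$ and is cheaper inside sweeps).

# Connectivity

**Pearson (Pcor)** correlates ROI-mean timecourses; matrices are Fisher
z-transformed before group statistics by default (the z scale stabilizes
the sampling variance entering ICCs; the flag is exposed because the
choice is not settled). **Unbiased distance correlation (Dcor)** uses all
voxel timeseries: with timepoints as samples and z-scored voxels as
variables, U-centered Euclidean distance matrices $\tilde A, \tilde B$ give
$\mathrm{dCov}^2_u = \sum_{i\ne j}\tilde A_{ij}\tilde B_{ij} / (T(T-3))$
and $\mathrm{dCor}^2_u = \mathrm{dCov}^2_u / \sqrt{\mathrm{dVar}_u X\,
\mathrm{dVar}_u Y}$. The estimator's expectation is zero under
independence, so the signed square can be negative; we truncate at zero
before the square root but keep the signed value as a diagnostic attribute.
The diagonal of Dcor matrices is set to 1 by convention for comparability
with Pcor; only off-diagonals enter statistics, and the off-diagonal mean
is the unweighted upper-triangle mean throughout.

**Mean regression (MR)** regresses, per session and connection, the
across-participant values on participant mean connectivity (with
intercept), keeping residual plus the group mean of that connection.
Because the connection-mean of the fitted slopes is exactly 1, every
participant's mean connectivity afterwards equals the group mean exactly;
the operation is a projection (idempotent), and a second application sees a
zero-variance predictor and returns its input with a warning.
`harmonize_session_means()` then shifts both sessions' grand means to their
common average, leaving within-session differences intact.

# Evaluation battery

Reliability uses the single-measure, two-way random-effects,
absolute-agreement ICC(2,1) from the ANOVA decomposition. The literature we
emulate says only "ICC"; we fix ICC(2,1) as the default because
absolute agreement is the property actually claimed (values, not just
ranks, stable across sessions), and provide `"consistency"` (ICC(3,1)) as
an option. Whether effect maps should be Fisher-transformed before their
ICC is likewise unstated; we compute the ICC on the correlation scale.

The indices are: **RP** (per-participant ICC of vectorized matrices across
sessions), **RS** (per-connection across-participant ICC, averaged into
within-network RSW and between-network RSB), **RA** (ICC between
session-wise age-effect maps), **SP** (correlation with the mean matrix of
the 30 nearest-age peers, ties in age distance broken by participant
index), and **VH/HM** (mean absolute partial correlation of connectivity
with vascular health / motion after residualizing both sides on age).
Percentages of significant connections use uncorrected two-sided
$\alpha = 0.05$ by default with a Benjamini-Hochberg option, since the
emulated analyses never state a correction.

Pipelines are compared with a per-connection label-swap permutation test
(statistic: difference of map means; p-value smoothed as $(b+1)/(B+1)$ so
it can never be zero), a variant that swaps option labels identically in
both sessions and recomputes RA, the tie-corrected normal-approximation
Wilcoxon signed-rank test, and Steiger's z for dependent overlapping
correlations. Mediation uses standardized variables, so $c = c' + ab$
holds exactly, with Sobel normal-theory inference for the indirect effect
and an optional percentile bootstrap.

# Parcellation

Voxel graphs connect 26-neighborhood lattice pairs with correlation
strictly above 0.5. Normalized-cut clustering embeds each connected
component with the top eigenvectors of $D^{-1/2} W D^{-1/2}$ and
discretizes with seeded k-means (20 restarts) -- the reference NCUT
implementation's exact discretization and its handling of disconnected
graphs are unspecified, so k-means discretization with proportional
cluster allocation across components is our documented default. NMI is
normalized by the geometric mean of the label entropies (the normalization
is also unspecified in the source material). In synthetic use the cluster
count is scaled to the ROI count (k = 40) rather than the 750 used on
whole-brain data. Homogeneity is the mean off-diagonal voxel correlation
per ROI, averaged across ROIs on the Fisher-z scale.

# Problem sizes and numerical choices

The package's own evaluation runs on cohorts of 60 subjects, 40 ROIs of 12
voxels, and sessions of 150 and 100 volumes at TR 1.97 s -- large enough
for every directional phenomenon to be detectable, small enough that a
20-cohort replicate battery completes in minutes. The full-length default
sessions (261 and 152 volumes) are used where single fits are examined
(e.g. whitening contracts at $T = 261$). Degenerate inputs are defined,
not crashed on: zero-variance ROI means give NaN rows with a warning, zero
distance variance gives Dcor 0 with a warning, an empty DCT basis warns
and returns zero columns, rank-deficient designs drop collinear columns
with their names logged, and exact threshold ties (spike exclusion,
neighbor-graph edges) resolve by strict inequality.

# What the synthetic cohorts do and do not show

The generator reproduces the *statistical couplings* the evaluation is
about -- amplitude-coded vascular confounding, trait-like age-correlated
motion artefacts, age-declining autocorrelation, age-increasing regional
idiosyncrasy, session structure with unequal lengths -- but not scanner
physics: no k-space artefacts, slice timing, susceptibility distortion,
registration error, or realistic cardiac/respiratory waveforms, and its
noise is Gaussian-mixture rather than physiologic. Passing the battery
therefore certifies that the estimators and pipeline comparisons behave as
designed under known ground truth (directions of effects, calibration of
tests, exactness of algebraic contracts); it does not certify effect
magnitudes on real data, and absolute index values here (e.g. the very low
band-pass reliability at 100 volumes with 32 confounds, which leaves few
residual degrees of freedom) should be read as properties of the simulated
regime. The optional NIfTI adapter exists so the identical pipeline code
can be pointed at real volumes when those questions arise.
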