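---
title: "Precision-weighted modelling of cued pain perception: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-weighted modelling of cued pain perception: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model the package implements, the conventions and
numerical choices behind each stage, and what validation on synthetic
cohorts does and does not establish.

## The generative model of a pain rating

A participant's rating $Y$ on trial $i$ (0–100 scale) is treated as the
inversion of a generative model with three independent Gaussian factors:

$$p(Y \mid X, \beta^2, q, \rho^2, SD, \eta, \mu, \nu^2) \;\propto\;
  \mathcal{N}(X;\, Y, \beta^2)\;
  \mathcal{N}(q;\, Y + \eta\,SD, \rho^2)\;
  \mathcal{N}(Y;\, \mu, \nu^2)$$

The stimulation factor says the delivered intensity $X$ scatters around the
"true" pain $Y$ with variance $\beta^2$; the cue factor says the observed
average cue $q$ scatters around $Y$ shifted by $\eta \cdot SD$, where $SD$
is the spread of the two cue cards — so a positive $\eta$ means wider
(more uncertain) cues raise the pain expectation; the bias factor is a
participant-specific prior on ratings with mean $\mu$ and variance
$\nu^2$. Reciprocal variances are reported as *precision weights*
(`w_stim`, `w_cue`, `w_bias`): the relative influence of stimulation, cue
and bias on perception.

Completing the square over $Y$, the product normalises to a Gaussian with

$$\frac{1}{s^2} = \frac{1}{\beta^2} + \frac{1}{\rho^2} + \frac{1}{\nu^2},
\qquad
m = s^2\left(\frac{X}{\beta^2} + \frac{q - \eta\,SD}{\rho^2} +
\frac{\mu}{\nu^2}\right),$$

a convex (precision-weighted) combination of the three factor "opinions".
`collapse_posterior()` returns these moments; the test suite verifies them
against grid quadrature of the unnormalised product to relative error
below $10^{-6}$ over a thousand random configurations.

**Likelihood of the reported rating.** The model itself does not dictate
how the internally inferred rating maps onto the number the participant
reports. The package treats the report as a draw from the collapsed
Gaussian $(m, s^2)$, which makes the three-factor product, read as a
density in $Y$, the exact per-trial likelihood — the unique reading under
which Bayesian inversion of the model by MCMC is well-posed. Forward
simulation clips draws to $[0, 100]$ and records the pre-clip value;
fitting uses the untruncated Gaussian. The two stay consistent as long as
clipping is rare, so `simulate_rating()` warns when the clip rate exceeds
5%, and the cohort manifest records the realised rate (about 3–4% under
the default population).

## The cued task

`task_config()` encodes the paradigm: 60 trials; integer stimulation
levels between the psychophysics anchors 3 (pain threshold) and 7 (highest
tolerable); target-card pairs at least 2 levels apart, sampled uniformly
over the admissible set; a lure pair that repeats one target card while
its other card strictly exceeds the remaining target card (uniform over
admissible choices — only the constraint is specified by the paradigm, so
the sampling distribution is our choice); delivery of either chosen card
with probability ½; and rescaling of levels to the 0–100 rating scale by
the affine map sending the anchors to 0 and 100.

Conventions worth stating:

* **Cue SD.** For a two-card cue the "standard deviation" is ambiguous;
  we adopt the population SD, $|r(a) - r(b)|/2$ on the rescaled scale
  (`sd_convention = "sample"` gives $|r(a)-r(b)|/\sqrt 2$). The scale of
  $\eta$ is arbitrary up to this constant, so the point is to fix one
  convention and document it.
* **Stimulation levels are integers** before rescaling, as on the cards.
* **Choices.** Real data carry observed choices; synthetic participants
  pick the target with probability 0.95 (configurable). The delivered
  level and the observed cue statistics come from the *chosen* pair;
  lure-choice trials are flagged (`chosen_is_target`) and retained —
  only the attention rule removes data, by excluding participants whose
  lure-pick fraction strictly exceeds 25%.

## Bayesian inversion

`fit_participant()` samples the posterior of
$(\beta^2, \eta, \rho^2, \mu, \nu^2)$ with JAGS under weakly-informative
priors: half-Normal(0, 50) on each factor SD (rating units — wide relative
to the 0–100 scale), Normal(0, 5) on $\eta$, Normal(50, 30) on $\mu$, all
overridable through `prior_spec()`. With 60 trials the likelihood
dominates these priors in recovery experiments. Each factor SD carries a
floor of 0.01 rating units (variance $10^{-4}$, negligible on this scale):
degenerate data such as perfectly constant ratings make the likelihood
unbounded as a variance shrinks to zero, and the floor keeps the sampler
inside a numerically valid region while the fit is flagged as degenerate.

Defaults: 3 chains, 1000 adaptation + 1000 burn-in iterations, 5000
retained draws per chain, fixed mid-prior starting points with chain-wise
jitter, and chain RNGs seeded deterministically so identical seeds give
bitwise-identical fits. Convergence is gated, not assumed: split-$\hat R$
above 1.01 or effective sample size below 400 on any parameter flags the
fit. These thresholds are package policy (reporting conventions vary);
flagged fits are returned with their flags so a cohort run can report
them.

Precisions are computed by transforming *draws*, not summaries: by
Jensen's inequality the mean of $1/\beta^2$ is not the reciprocal of the
mean of $\beta^2$, so `transform_draws()` reciprocates per draw and
summaries are taken afterwards. Point estimates for downstream correlation
are posterior means by default (medians available) — the conventional
summary where none is dictated.

Identifiability deserves a note: the collapsed likelihood is a regression
of ratings on $X$, $q$, $SD$ and an intercept plus a residual variance —
five observables for five parameters, so the model is just-identified.
$\nu^2$ is the slow parameter: its precision is the small difference
between the total precision and the other two, so its posterior stays wide
at 60 trials. This is visible in the recovery suite (wide but calibrated
intervals), and is why the posterior-contraction test uses a regime where
the bias factor carries appreciable weight.

## EEG features

Epochs are stimulation-locked (−4500 to +500 ms, 500 samples/s by
default) with per-trial event markers: `pair_onset` (card pairs appear),
`choice`, `cue_onset` (chosen cue on screen for 3 s), `stim_onset`.
Anchoring windows on markers rather than fixed offsets makes the code
indifferent to the variable choice duration of real data; the synthetic
timing fixes choice at 500 ms.

The four canonical windows: baseline = [−500, 0) ms from `pair_onset`
(fixation); early anticipation = [0, 500) ms from `cue_onset`; late
anticipation = [2500, 3000) ms from `cue_onset`, which under the 3 s cue
display equals the 500 ms before stimulation; post-stimulation = each
participant's P2 peak ± 100 ms. Windows are half-open at sample
resolution, with ms offsets rounded toward the earlier sample — one fixed
convention rather than per-call choices, to prevent off-by-one drift.
Baseline correction subtracts the per-trial, per-channel baseline *mean*
(the median would be an alternative; the mean is the standard choice).

The P2 electrode is selected from the grand-average ERP across
participants (largest post-stimulus maximum; ties go to the first channel
in order, with a warning), and the peak is the maximum of the *signed*
amplitude in (0, 500] ms — P2 is by definition a positive deflection —
with `mode = "absolute"` available. Peak windows that would extend past
+500 ms are clipped and flagged. On noiseless synthetic bumps the detector
recovers the planted latency to the exact sample and the amplitude to
float precision; the electrode is derived from the data, never hard-coded.

## Correlation analyses

Model parameters (the three precision weights, $\eta$, and $\mu$) are
correlated with ROI activities, P2 amplitude, questionnaire covariates and
mean ratings using Spearman rank correlation — parameter distributions are
heavy-tailed, especially the precisions, so ranks are the safe choice.
$\eta$ enters as $|\eta|$: its sign encodes the *direction* of the
uncertainty effect, while the hypotheses concern its strength.

For production sample sizes the p-value uses the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. For $n \le 8$ the package
enumerates the full permutation distribution instead (tie-safe): at such
sizes the approximation is visibly off (for example 0.104 vs the exact
0.133 at $n = 5$, $\rho = 0.8$), and exactness is cheap.

**Families and correction.** Hypothesised tests are declared in a
`hypothesis_map()` — by default the somatosensory weight against
structures previously associated with somatic processing, the cue weight
and $|\eta|$ against cue-processing structures, and the trio
$\{w_{stim}, \eta, \mu\}$ against P2 amplitude. Benjamini–Hochberg
correction is applied within one family per time window (ROI tests), with
the P2 trio as its own family — correction "at each time window" scoped
exactly to each analysis's table. Everything outside the map is
exploratory and deliberately uncorrected (tentative by construction);
exploratory and hypothesised sets partition the parameter × target space.
Default tests are two-sided; the design power claim is one-tailed, and
`alternative = "greater"` is available where a directional hypothesis
warrants it.

**ROI redundancy.** ROIs of the same structure and window with Spearman
correlation strictly above 0.7 are redundant; within such a pair the ROI
farther (Euclidean) from the structure's centre of mass is dropped. With
more than two ROIs the highest-correlation pair is resolved first —
greedy, deterministic and order-stable; distance ties drop the
later-listed ROI, with a message. Centroids ship as an editable table
(`structure_centroids_synthetic.csv`, approximate MNI points); the package
embeds no atlas, and real analyses should substitute atlas-derived
centroids.

**Power.** `power_corr()` implements the Fisher-z closed form
$\Phi(\operatorname{atanh}\rho\,\sqrt{n-3} - z_{1-\alpha/\text{tails}})$;
`simulate_power()` draws bivariate-normal samples and counts rejections.
The two agree within Monte-Carlo error, and both put the one-tailed
$\rho = 0.33$, $\alpha = 0.05$ design above 0.8 power at $n = 70$ and
$n = 63$.

## The synthetic cohort

`generate_cohort()` builds everything the pipeline consumes, with known
ground truth: parameters drawn from the population, trials from the task
generator, ratings from the forward model, EEG-like epochs, ROI
activities, and null questionnaire covariates plus per-participant mean
ratings. One root seed expands into per-participant sub-streams
(`substream_seed()`), so bundles regenerate bit-exactly and any
participant's data is independent of cohort size.

Default population (all overridable): $\beta^2 \sim$ logNormal(log 200,
0.5²), $\rho^2 \sim$ logNormal(log 400, 0.5²), $\nu^2 \sim$ logNormal(log
900, 0.5²), $\eta \sim$ N(0, 0.5²), $\mu \sim$ N(50, 15²), 63
participants. These were chosen once to produce ratings spanning the 0–100
scale at a low clip rate with a realistic mix of stimulation-, cue- and
bias-dominated participants; they are testing conditions, not claims about
the human population, whose true parameter distributions are unknown.

Planted effects use the Gaussian copula: the target variable is built from
the parameter's normal scores with Pearson correlation
$r = 2\sin(\pi\rho_s/6)$, the bivariate-normal relation that makes the
expected sample Spearman correlation converge to the target $\rho_s$. ROI
margins are standard normal — only rank structure matters downstream.
Synthetic ERPs are a Gaussian bump (SD 40 ms) at a per-participant latency
(250 ± 30 ms) on a designated channel over 1/f-shaped noise, with the bump
amplitude optionally rank-linked to a parameter; no waveform model is
inherited from anywhere, so this is the simplest shape with the right
qualitative features.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: volume conduction and channel
covariance, artefacts and their rejection, non-Gaussian rating noise,
trial-to-trial learning (the model is static per participant, as in the
paradigm), systematic lure-choice behaviour, and any real link between
questionnaire scores and model parameters (covariates are generated null).
Validation on this cohort establishes *software correctness and
statistical calibration* of the pipeline, not neuroscientific claims.

## Validation problem sizes

The test suite validates at sizes chosen to balance Monte-Carlo resolution
against a test run of a couple of minutes: quadrature equivalence over
1000 random configurations; parameter recovery on one cohort of 50
participants × 60 trials (95% intervals cover each parameter's truth at
≥ 85%, $\eta$'s posterior-median sign correct in ≥ 90% of participants
with $|\eta| \ge 0.5$); planted-effect detection (rank correlation 0.6,
$n = 63$) over 20 cohorts with null calibration over 100; power
simulations at 20,000 replicates. Exhaustive oracles (BH step-up,
permutation Spearman) run at the vector lengths where exhaustion is
feasible ($m \le 8$, $n \le 7$).

## Known limitations

* The sampler is JAGS (slice-within-Gibbs), not Hamiltonian Monte Carlo;
  any sampler targeting the correct posterior is acceptable here, and
  correctness is established by the recovery suite rather than by
  matching a specific sampler's draws.
* Priors are this package's defaults, stated above; posterior numbers are
  reproducible under these priors but not interchangeable with fits under
  other prior choices.
* The untruncated likelihood ignores boundary censoring; heavy clipping
  (bias means near 0 or 100 with small variances) would bias fits, which
  is why the clip rate is surfaced rather than hidden.
* $\nu^2$ (and hence `w_bias`) is weakly identified at 60 trials; its
  intervals are honest but wide, and downstream correlations against
  fitted `w_bias` are attenuated relative to truth.
* Exploratory results are uncorrected by design and should be treated as
  hypothesis-generating.
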