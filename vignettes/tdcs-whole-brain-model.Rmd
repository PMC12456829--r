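---
title: "Simulating tDCS effects on whole-brain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tDCS effects on whole-brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tdcsim` couples three stages: a structural-connectivity-coupled dynamic
mean-field model of regional neural activity, a linear mapping from the
tDCS-induced cortical electric field to a stimulation term in the neural
equations, and a hemodynamic forward model producing BOLD signals that are
then analyzed exactly as an empirical fMRI acquisition would be.

### Neural dynamics

Each cortical parcel is a reduced Wong–Wang neural mass. Its state is the
mean NMDA synaptic gating fraction $S_i \in [0,1]$:

$$\dot S_i = -\frac{S_i}{\tau_S} + \gamma (1 - S_i)\, H(x_i) + \sigma v_i(t) + \theta_i(t)$$
$$x_i = w J S_i + G J \sum_j C_{ij} S_j + I$$
$$H(x) = \frac{a x - b}{1 - e^{-d (a x - b)}}$$

$C$ is the structural connectome scaled so its maximum element is 0.2,
$H$ the population firing rate (Hz), $x_i$ the total input current (nA),
and $v_i$ unit white noise. Defaults are the canonical parameterization of
this reduction: $a = 270$, $b = 108$ Hz, $d = 0.154$ s, $\tau_S = 0.1$ s,
$\gamma = 0.641$, $w = 0.9$, $J = 0.2609$ nA, $I = 0.3$ nA,
$\sigma = 0.01$.

A note on units: we keep time in seconds and rates in Hz, under which the
kinetic prefactor is $\gamma = 0.641$ with no extra factor. The
often-quoted $0.641/1000$ belongs to implementations that integrate in
milliseconds while keeping $H$ in Hz; applying the $1/1000$ with time in
seconds would collapse the gating fixed point to $S^* \sim 10^{-4}$ and
destroy the model's dynamic range, so we deliberately do not.

The global coupling $G$ is, in empirical applications, fitted per subject
or group to maximize the similarity of simulated and measured functional
connectivity. No fitted value can be reproduced without that data, so the
package default is $G = 2$, a typical magnitude for connectomes scaled to
a maximum element of 0.2. All experiments in the package run at this
single homogeneous operating point; the consequences are discussed under
*Limitations*.

### Stimulation term

tDCS polarizes cortical neurons through the field component normal to the
cortical surface (inward-normal depolarizes, outward hyperpolarizes;
tangential components have no net effect at the population level). The
package ingests per-region samples of $E_{normal}$ (mV/mm, numerically
V/m) and applies the linear polarization law

$$V_{tDCS}(i) = \lambda\, \bar E_{normal}(i), \qquad \theta(i) = k\, V_{tDCS}(i),$$

with $\lambda = 0.13$ mV/(mV/mm) — so that a 30 mV/mm field polarizes by
3.9 mV, inside the empirical $|4\,\mathrm{mV}|$ bound — and $k = 1$.
Only *crucial* regions receive $\theta$: a region qualifies when the
maximum $|E_{normal}|$ over its samples strictly exceeds the 99th
percentile of $|E_{normal}|$ pooled over all samples (linear-interpolation
percentile, so tests are exact; a constant field selects nothing). The
percentile is pooled across the whole cortex rather than per region
because the selection rule describes a whole-cortex peak. Aggregation is
deliberately split: the **maximum** per region decides selection, the
**mean** per region sets $\theta$ — the first matches "peak field"
selection, the second is the region-wise averaged field entering the
polarization law.

$\theta$ is a boxcar: constant on $[\mathrm{onset}, \mathrm{onset} +
\mathrm{duration})$ and exactly zero afterwards. It adds directly to
$\dot S_i$; the dimensional bridge from millivolts of polarization to a
gating rate is not derivable from first principles, which is why $k$ is
exposed as an explicit gain users can calibrate to keep responses
physiological.

### Hemodynamics and sampling

Gating activity drives a standard four-state Balloon–Windkessel model per
region (vasodilatory signal, inflow, venous volume, deoxyhemoglobin;
Friston-2003 constants, all overridable), integrated by Euler at the
trajectory recording rate (1 ms by default; at most 10 ms). BOLD is the
usual nonlinear observation, in percent signal units. The synaptic gating
variable is the drive by default (`drive = "rate"` switches to firing
rate); this is the common choice for this model family.

The high-rate BOLD is then treated like an acquisition: the first 60 s are
discarded (initial transient), and the series is decimated to TR = 0.72 s
by nearest-sample decimation — no anti-alias filter, since BOLD is already
slow and exact sample indices keep tests sharp. The full-scale protocol
retains exactly 1200 TRs (hence 924 s of simulation); the stimulus starts
at the first retained TR and lasts 60 s.

TR index $i$ (0-based) covers $[i \cdot TR, (i+1) \cdot TR)$. The During
period is the set of TRs whose full interval lies inside the stimulation
epoch — 83 TRs (indices 0–82) for 60 s at TR 0.72 — and Post is everything
after. The matching window of an unstimulated run is marked `Without` so
paired comparisons are aligned. Static analyses use the first 130 TRs.

## Analysis battery

* **Static FC**: Pearson correlation over a TR slice; zero-variance
  regions are flagged and recorded as 0.
* **Graph topology**: negative correlations are zeroed (keeps distances
  positive), edge length is $1/w$ (preserves weight ordering), global
  efficiency is the mean of $1/d_{ij}$ over distinct pairs with
  disconnected pairs contributing 0, characteristic path length averages
  over connected pairs only, and clustering is the mean Onnela weighted
  coefficient. The default scheme is fully weighted; proportional
  thresholding exists for sensitivity analyses, since thresholds in the
  protocol apply only to the SC-seed analyses.
* **RSN aggregation**: mean FC within and between the seven canonical
  resting-state networks, self-pairs excluded.
* **Dynamic FC**: 40-TR windows, step 1 (1161 windows from 1200 TRs).
  Windows are half-open index ranges; Phase 1 windows sit fully inside the
  During period, Phase 2 windows straddle the During→Post boundary,
  Phase 3 windows sit fully in Post.
* **Kuramoto synchrony/metastability**: regional series are demeaned,
  band-passed (2nd-order Butterworth, 0.04–0.07 Hz, the customary slow
  BOLD band; configurable), phases extracted from the FFT analytic
  signal, and $R(t) = |n^{-1}\sum_j e^{i\phi_j(t)}|$ summarized after
  trimming 5% of samples at each end. Per-period values summarize the
  full-series $R(t)$ inside each period's TRs: the During period alone
  (60 s) is shorter than three cycles of the 0.04 Hz band edge, so
  filtering within a period would be meaningless.
* **Complexity**: per region and period — Hurst exponent by first-order
  DFA over log-spaced scales 4..N/4 (rescaled-range alternative via
  `method = "rs"`); Lempel–Ziv complexity of the median-binarized series,
  LZ76 phrase count normalized as $c(n)\log_2 n / n$; permutation fuzzy
  entropy with embedding $m = 3$, delay 1, fuzzy width $r = 0.15 \cdot SD$
  and power 2, where each ordinal pattern occurrence is down-weighted by
  $\prod_g (1 - e^{-(\Delta_g/r)^2})$ over its sorted consecutive gaps so
  near-ties count less; the entropy is normalized by $\log m!$. Because
  $r$ scales with the SD, all three metrics are affine-invariant. Periods
  shorter than 64 TRs raise an error rather than silently degrading.
* **Statistics**: paired t-tests across matched run ensembles (run $r$ of
  each condition shares the seed offset, which is what makes pairing
  meaningful in silico), Fisher z-transform before edgewise FC tests,
  Benjamini–Hochberg FDR at $q = 0.05$ over all static edges jointly and
  per window for dFC (each window's map is its own family), Spearman rank
  correlation with a t-approximation p-value. Zero-variance differences
  are flagged rather than silently dropped.

## Synthetic generators and study conditions

The package is exercised on synthetic inputs that emulate the empirical
ones:

* **Connectome**: Erdős–Rényi mask (density 0.3) with log-normal weights
  (meanlog 0, sdlog 1), connectivity enforced by redrawing, scaled to max
  0.2 — the sparse, heavy-tailed character of tract-count matrices.
* **Bipolar field**: one anodal focus at $+0.5$ mV/mm and one cathodal
  focus at $-0.5$ mV/mm (2% jitter), background $\mathcal N(0, 0.05)$
  mV/mm, 100 samples per region. The focal magnitude is the scale of the
  strongest regional normal fields a 2 mA bipolar montage induces in
  cortex; the resulting $|\theta| \approx 0.065$ stays far inside the 4 mV
  polarization bound and produces no gating saturation (clamp activations
  are counted and are zero at these settings).
* **Smoke study**: 16 regions, 5 runs per condition, 300 retained TRs
  (hence 276 s of simulation per run at dt = 0.1 ms), one stimulation
  condition against the `Without` baseline. These sizes keep a complete
  two-condition study, with every analysis stage, in the minutes range on
  a single core while preserving all structural constants that matter
  (TR, discard, window length, stimulus timing). The full-scale
  1200-TR/30-run protocol is the package default for real use.

What the generators do *not* emulate: hemispheric and geometric structure
of real connectomes (modularity, distance-dependence), the spatial
smoothness of real field maps, regional heterogeneity of hemodynamics,
and measurement noise in BOLD. Passing directional tests on synthetic
inputs therefore demonstrates mechanism plumbing, not empirical validity.

## Numerical choices

* Euler–Maruyama at dt = 0.1 ms, states recorded every 1 ms; the gating
  state is clamped to $[0,1]$ and clamp activations are reported.
  First-order convergence is tested by step-halving.
* $H$ is evaluated as written, with the removable singularity at
  $ax = b$ computed as $1/d$ via `expm1`, accurate through $\pm 10^{-9}$.
  $H$ is positive for every real argument and is not clipped.
* Initialization is $S(0) = 0.1$ uniformly; a deterministic fixed point
  (damped iteration on $\dot S = 0$) is available for equilibrium tests.
* Per-run seeding: run $r$ of condition $c$ uses
  $\mathrm{base} + 1000c + r$, recorded in the manifest, so every number
  in the outputs is reconstructible from configuration plus seeds.
* SC read tolerance: relative Frobenius asymmetry $\le 10^{-8}$ is
  averaged away; anything larger errors, because tractography outputs are
  nominally symmetric and silent large repairs hide bugs. "Presence" in
  the consensus operator means strictly nonzero weight; retained edges
  carry the mean over all subjects.
* Ranking ties (seed splits) break by region id and are logged.

## Limitations

The single most important caveat: the empirical pipeline this package
mirrors fits its neural parameters ($G$, $w$, $I$, $\sigma$) to measured
FC, which places the model near the edge of instability where stimulation
can trigger qualitative dynamical changes (state switching, increased
signal irregularity). Those fitted values are not publicly printed, and
the package runs at a canonical, stable operating point instead. At this
operating point a weak bipolar stimulus produces the expected focal BOLD
signatures (anodal increase, cathodal decrease), the Phase-1 whole-brain
FC dip with the Phase-2 recovery/rise, SC-guided propagation of BOLD
changes, higher Hurst exponents and lower synchrony during stimulation —
but it does *not* reliably reproduce the empirically reported *increase*
of Lempel–Ziv complexity, permutation fuzzy entropy, metastability, or of
the whole-brain mean firing rate during stimulation: at smoke scale the
LZC and metastability contrasts are at noise level (their sign varies
with the base seed), while PFEN and the whole-brain mean rate lean weakly
negative. Two mechanisms explain the reversals at a stable operating
point: an equal-magnitude hyperpolarizing focus is slightly more
effective than the depolarizing one (the restoring rate
$1/\tau_S + \gamma H$ weakens as $S$ falls), and the stimulus-locked
drift makes the During-period BOLD smoother, not more irregular. These
directions are reported as computed; flipping them would require the
near-critical fitted regime.

Also out of scope by design: finite-element field modelling (fields are
ingested or synthesized), excitatory–inhibitory two-population variants
with feedback-inhibition tuning, heterogeneous per-region parameters,
subcortical nodes, empirical preprocessing, and dFC state clustering.

## A worked smoke run

```{r, eval = FALSE}
library(tdcsim)
bundle <- smoke_study(base_seed = 1)
ct <- bundle$contrasts[["F3a-Fp2c"]]
ct$bold_t[ct$anodal + 1]     # paired t, anodal BOLD During vs Without: > 0
ct$bold_t[ct$cathodal + 1]   # cathodal: < 0
ct$sc_bold$rho               # SC-to-seed vs BOLD-change rank correlation
glance(ct$edgewise)          # edgewise FDR summary
autoplot(bold_fc(...))       # FC heatmap of any bold_series
```

The README shows the numbers this prints on the fixed seed.
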