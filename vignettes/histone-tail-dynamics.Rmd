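---
title: "Methods: linking histone-tail MD ensembles to NMR and thermal-shift observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking histone-tail MD ensembles to NMR and thermal-shift observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taildyn)
```

Histone N-terminal tails are intrinsically disordered arms that remain
associated with nucleosomal DNA as a "fuzzy complex": globally bound, locally
exchanging rapidly among many nonspecific DNA sites. Characterising how a
mutation reshapes that ensemble requires connecting two very different kinds
of measurement — solution NMR (chemical shift perturbations, ¹⁵N relaxation,
residue-wise correlation times) and microsecond molecular-dynamics ensembles
(contact statistics, binding kinetics, intra-tail interaction networks) —
through a shared quantitative layer. `taildyn` implements that layer. This
vignette describes the models, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## 1. Spin relaxation from bond-vector trajectories

### The model

For a backbone amide, ¹⁵N relaxation is driven by the reorientation of the
N–H bond vector. Its memory is the P2 orientational autocorrelation
function

$$C(\tau) = \langle P_2(\hat u(t)\cdot\hat u(t+\tau)) \rangle, \qquad
P_2(x) = \tfrac{3x^2-1}{2},$$

whose frequency content is the spectral density $J(\omega)$. The pipeline is:

1. **`p2_autocorrelation()`** — the vector series is split into `n_chunks`
   equal segments (default 20), $C(\tau)$ is computed per chunk over all
   time origins and averaged, and the scatter across chunks gives a per-lag
   standard error. Lags are limited to `max_lag_fraction` (default 0.5) of
   the chunk length, where the all-origin average is still well conditioned.
   The per-chunk computation is exact: $P_2(\hat u\cdot\hat u')$ expands
   into the six quadratic components $u_a u_b$, each of whose lagged
   product-sums is evaluated by FFT, so the cost is $O(n\log n)$ rather than
   $O(n^2)$ with results identical to the brute-force double loop.
2. **`fit_triexponential()`** — $C(\tau)$ is fitted with up to three
   exponentials $\sum_i A_i e^{-\tau/\tau_i}$ under $A_i \ge 0$,
   $\sum_i A_i \le 1$, $\tau_i > 0$. The fit is weighted by the per-lag
   standard errors, started from several log-spaced time-constant triplets,
   and the best start wins (lowest weighted residual; ties broken by the
   smallest $\sum_i |\log\tau_i|$ so results are reproducible). The
   component count (1–3) is selected by BIC, and components with amplitude
   below $10^{-4}$ are pruned. One further guard matters in practice:
   because $J(0) = \tfrac25\sum_i A_i\tau_{eff,i}$, a component slower than
   the lag window whose amplitude sits inside the chunk-sampling noise of
   the correlation tail can inject an essentially arbitrary $A\tau$ product
   into $J(0)$ while barely changing the fit. Such statistically
   unresolvable components (beyond-window $\tau$, amplitude below twice the
   tail standard error) are pruned as well. A genuine plateau (restricted
   motion with $S^2$ well above the noise) is unaffected and is
   representable as a component with $\tau_i$ at the upper bound,
   $10^4\times$ the lag window. We allow $\sum A_i \le 1$ rather than
   $=1$: any deficit is reported as `fast_deficit`, an unresolved
   sub-frame-interval component, rather than forced into the slowest term.
3. **`apply_tumbling()`** — internal motion was computed in the frame of the
   superposed core, so overall tumbling must be reintroduced. Multiplying
   $C(\tau)$ by $e^{-\tau/\tau_{rot}}$ is, for an exponential mixture,
   exactly the harmonic combination
   $1/\tau_{eff,i} = 1/\tau_i + 1/\tau_{rot}$ with unchanged amplitudes.
   The default $\tau_{rot} = 163.4$ ns is the accepted overall rotational
   correlation time of the nucleosome core particle; it is a plain argument
   and should be overridden for other assemblies. The analytic transform of
   the fitted exponentials is the primary route to
   $J(\omega) = \tfrac{2}{5}\sum_i A_i \tau_{eff,i}/(1+(\omega\tau_{eff,i})^2)$
   — noise-free and closed-form — rather than an FFT of the raw, noisy
   $C(\tau)$.
4. **`relaxation_rates()`** — standard dipolar + CSA expressions with
   $d = (\mu_0/4\pi)\hbar\gamma_H\gamma_N/r_{NH}^3$ and
   $c = \omega_N\,\Delta\sigma/\sqrt3$ give $R_1$, $R_2$ and the
   heteronuclear NOE from $J$ evaluated at $0$, $\omega_N$,
   $\omega_H\pm\omega_N$ and $\omega_H$.
5. **`residue_tau_c()` / `tau_c_from_rates()`** — the effective rotational
   correlation time from the rate ratio,
   $\tau_c = \sqrt{6R_2/R_1 - 7}\,/\,(4\pi\nu_N)$, with first-order error
   propagation through the ratio. Ratios at or below $7/6$ are flagged
   undefined (at exactly $7/6$, $\tau_c = 0$ is reported but still flagged,
   since the inversion has no sensitivity there). The normalization
   convention is locked by tests: with high-frequency terms zeroed, the
   identity $(d^2/8 + c^2/6) = \tfrac16(3d^2/4 + c^2)$ makes this inversion
   exact for a rigid rotor at any $\tau$ and any CSA — a useful internal
   consistency check that would fail immediately if the $J$ or rate
   conventions were ever mixed.

### Constants

The spin-system defaults (`spin_constants()`) are field-standard values for
backbone amides: $r_{NH} = 1.02$ Å, $\Delta\sigma = -172$ ppm,
$\gamma_H = 2.6752\times10^8$ and $\gamma_N = -2.7126\times10^7$
rad s⁻¹ T⁻¹, ¹H frequency 600.13 MHz, with $\nu_N$ derived from the ¹H
frequency by the gyromagnetic-ratio quotient (≈ 60.85 MHz) unless supplied.
All are overridable and are carried in every output record, because CSA and
bond-length conventions differ across the literature and silently mixing
them is the classic failure mode of relaxation back-calculation.

Burn-in before relaxometry is configurable and defaults to 0: equilibration
exclusion is a property of the trajectory preparation (where a burn-in is
the `residue_dna_contacts()` default), not of the correlation-function
machinery itself.

## 2. Experimental NMR tables

Chemical shift perturbations combine the ¹H and ¹⁵N shift differences as
$\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (0.154\,\Delta\delta_N)^2}$.
The nitrogen weight is a named argument with default exactly 0.154; other
conventions (0.14, 0.2) exist, which is why it is a parameter and not a
constant buried in code. Matching is by residue id only — peak tables from
different constructs rarely align row-by-row — and residues absent from
either table are emitted with a missing flag rather than dropped, so
prolines and exchange-broadened peaks stay visible in the output.

Relaxation decays are fitted as $I(t) = I_0 e^{-Rt}$, two parameters, no
offset, by nonlinear least squares started from the log-linear solution.
Duplicate delays (the "×2" points of typical relaxation schedules) enter as
independent observations, so their scatter feeds the residual variance that
scales the covariance-based $\sigma_R$. How duplicate-derived uncertainties
should enter is not standardised; this covariance-with-replicate-scatter
choice is ours and is validated against a Monte-Carlo replicate oracle in
the tests (σ consistent within 30% at 5% noise). Non-decaying data pin
$R = 0$ with a boundary flag instead of failing.

## 3. Tail–DNA contact kinetics

Contacts are strict: two heavy (non-hydrogen) atoms, one from the tail
selection and one from the DNA selection, at distance $< 4.0$ Å. Analysis
frames drop a configurable burn-in (default 200 ns) and are strided
(default 1 ns). The distance search is an exact all-pairs evaluation;
any acceleration must reproduce the brute-force result bit for bit.

The whole-tail state uses the 10% rule: a frame is **unbound** when no more
than 10% of tail residues maintain DNA contact. Because "no more than 10%"
of, say, 36 residues is not an integer count, we use
$\lfloor 0.10\,n \rfloor$: a 36-residue tail is unbound at ≤ 3 contacting
residues and bound at 4. The rounding direction is a documented choice.

`extract_events()` run-length encodes the state series. Bound episodes
shorter than the residence filter (default 50 ns — the time taken to
establish stable DNA interactions) are excluded from residence statistics
and, by default, merged into the flanking unbound time before events are
counted, so a single consistent state sequence underlies both numbers;
`count_short_events = TRUE` retains them for the event count. The episode
reaching the final frame is censored: flagged, excluded from residence
statistics, but its frames still count toward state populations. The
episode at the start of the analysis window is treated as observed from its
first frame.

Ensemble thermodynamics use frame counts over **all** analyzed frames
(before any residence filtering): $K_d$ = unbound frames / bound frames and
$\Delta G^0 = RT\ln K_d$ in kcal/mol at the simulation temperature
(default 310 K), negative when binding dominates. Degenerate cases (no
frames in one state) return a flagged undefined result with the counts, not
infinities.

Per-base-pair maps aggregate atom-pair contact counts to the base-pair index
of the DNA atom, with the default duplex pairing $i \leftrightarrow 2N+1-i$
for consecutively numbered strands, so both nucleotides of a pair pool into
one bin. The sum of the per-bp means equals the mean total atomic contact
count per frame — a conservation property the tests enforce.

## 4. Intra-tail ensemble descriptors

The dynamic cross-correlation matrix uses one representative atom per
residue (Cα for proteins, the bead itself for coarse systems):
$C_{ij} = \langle \Delta r_i\cdot\Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$.
It presumes the trajectory was superposed first; otherwise rigid-body
motion leaks into every entry. Our implementation is cross-checked in the
tests against the independent Bio3D implementation.

The residue–residue contact-probability map supports a heavy-atom distance
criterion (default < 4 Å) and a geometric hydrogen-bond proxy
(donor-heavy–acceptor distance < 3.5 Å, donor–H–acceptor angle > 120°, N/O
donors identified by an attached H within 1.3 Å). The proxy is exactly
that — a proxy: full interaction typing (π-stacking, ionic, etc.) is the
domain of dedicated interaction-network servers, whose exported edge tables
`read_edge_table()` ingests directly; that import path is the faithful one
for reproducing published network degrees. Adjacent-residue pairs
(|i−j| ≤ 1) are masked as uninformative. `node_degree()` sums incident edge
probabilities, errors on duplicated edges rather than double-counting, and
is additive over any partition of edges into classes.

## 5. Thermal-shift melting analysis

Raw dye-fluorescence curves are min–max normalized per replicate
(`normalize_curve()`), differentiated by forward difference with the value
assigned to the $T_{i+1}$ grid point (`derivative_curve()`), and melting
temperatures are read off the derivative peaks (`find_tm()`). The
$T_{i+1}$ assignment biases a symmetric transition about half a grid step
high; we keep the convention as stated and document the bias rather than
centre the difference. A transition sampled symmetrically produces two
*equal* maximal derivative values; peak detection therefore treats a run of
equal values flanked by lower ones as one peak at its first point.

Peaks are ranked by topographic prominence. The default threshold
(`min_prominence = 0.05` on the normalized-derivative scale) is our
operational reading of "too small to measure" for attenuated secondary
transitions; it is qualitative in origin and exposed as a parameter.
Replicate Tm values are matched by nearest-temperature clustering with a
3 °C window — comfortably separating transitions ~9 °C apart while
absorbing replicate scatter — and summarised as mean ± sample SD.

Because normalization removes affine transformations of the raw signal,
the derivative curve and every Tm are invariant to instrument gain and
offset; this holds exactly and is asserted in the tests.

## 6. What the synthetic generators emulate — and what they do not

Every pipeline input can be generated with known ground truth:

- **`gen_rotdiff_vectors()`** — isotropic rotational diffusion as a
  small-step random walk: each step rotates the vector about a uniformly
  random perpendicular axis by an angle drawn from
  $N(0,\,\sigma^2 = 4D\,dt)$, $D = 1/(6\tau_c)$, then renormalizes. This
  has the correct diffusion limit, so $C(\tau) \to e^{-\tau/\tau_c}$; steps
  with variance > 0.1 rad² are refused with guidance, since the small-step
  approximation would silently degrade.
- **`gen_cone_vectors()`** — the same walk confined to a spherical cap
  (moves leaving the cap are rejected, leaving the stationary distribution
  uniform on the cap), giving the diffusion-in-a-cone plateau
  $S^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2$. `tau_internal` is defined as
  the *effective* internal correlation time — the area under
  $(C(t)-S^2)/(1-S^2)$ — and the wobble diffusion coefficient is derived
  from it through the closed-form diffusion-in-a-cone relation, so
  model-free comparisons with $\tau'^{-1} = \tau_{int}^{-1} +
  \tau_{rot}^{-1}$ are well-posed.
- **`gen_two_state_timeline()`** — the two-state Markov chain with per-step
  leave probabilities $1-e^{-k\,dt}$, drawn as alternating geometric
  sojourns (distributionally identical to stepping frame by frame, and fast
  at $10^6$ frames). Ground-truth rates ride along in metadata.
- **`gen_toy_nucleosome_traj()`** — a bead "DNA" lattice plus a tail chain
  whose beads sit 3 Å from DNA beads when scripted bound and ≥ 10 Å when
  unbound. The margins around the 4 Å cutoff guarantee that the contact
  pipeline recovers the scripted state series *exactly*, which is what
  makes end-to-end kinetics tests meaningful.
- **`gen_melt_curve()`** — sums of logistic transitions with additive
  Gaussian noise on the normalized-fluorescence scale (heteroscedastic
  instrument noise is out of scope) and per-replicate sub-seeds. For the
  biphasic test condition we use transitions at 72 and 81 °C, width 1.5 °C,
  with equal amplitudes — at low salt the two disassembly steps (dimer
  release, tetramer dissociation) produce dye responses of comparable size.
- **`gen_peak_tables()`** — a base peak table plus a copy shifted by stated
  per-residue perturbations, with the exact combined CSP stored.

All generators are deterministic given their explicit seed and touch no
global random state.

What passing these tests shows is that the *computational chain* is
faithful: correct formulas, correct conventions, correct bookkeeping. What
it cannot show is fidelity to real nucleosomes: the generators contain no
force-field physics, no anisotropic tumbling, no chemical exchange, no
correlated multi-residue motion, and the toy contact geometry is a lattice,
not DNA. Conclusions about real systems still require real trajectories
and real spectra.

## 7. Problem sizes and numerical tolerances

The test and acceptance workloads are sized so the statistical targets are
comfortably met while remaining quick: rotational-diffusion recovery uses
$2\times10^5$ frames at 10 ps (2 µs of synthetic time, 20 chunks — matching
the chunking used for production trajectories), Markov kinetics use $10^6$
frames at 1 ns, and DCCM independence bounds use $10^4$ frames. At these
sizes the relaxometry chain reproduces closed-form rates within a few
percent (10% asserted), ensemble $K_d$ lands within ~5% of truth (10%
asserted), and mean residence times within ~5% (15% asserted). $J(0)$
recovery is the statistically hardest quantity — its estimator inherits the
correlated noise of the correlation-function tail — so, as with production
MD data, correlation functions from independent runs should be averaged
before fitting (the reproduction script does exactly that).

Numerical edge cases are handled explicitly rather than by exception:
undefined $\tau_c$ (ratio ≤ 7/6), non-decaying intensity series, flat melt
curves, zero-variance DCCM residues, empty selections (warning, not error)
and degenerate Kd counts all return flagged results with diagnostics.

## 8. Known limitations

- Tumbling is isotropic; rotational diffusion tensors and chemical-exchange
  ($R_{ex}$) contributions are out of scope.
- The H-bond criterion is geometric; no energetic or orbital terms.
- Trajectory reading covers PDB (single and multi-model), DCD and a
  plain-text fixture format; XTC is not supported. Binary timestamps are
  ignored in favour of an explicit frame interval so fixtures and real data
  behave identically. No periodic-boundary handling: trajectories should be
  imaged before import.
- Superposition targets "the rigid core" by selection expression; which
  residues constitute the histone core is system-specific and deliberately
  left to the caller rather than hard-coded.
- Thermal-shift analysis extracts transition temperatures only; two-state
  ΔH/ΔG unfolding thermodynamics are not fitted.

## A worked micro-example

```{r}
vs <- gen_cone_vectors(cone_spec(half_angle = 30, tau_internal = 2e-9,
                                 dt = 1e-11, n_frames = 5e4, seed = 1))
rec <- relaxation_from_vectors(vs, tau_rot = 163.4e-9, n_chunks = 10)
rec[, c("R1", "R2", "tau_c")]
```

For this restricted internal motion ($S^2 \approx 0.65$) with nucleosome
tumbling reintroduced, the effective `tau_c` lands a few tens of ns —
between the fast internal time and the 163.4 ns overall tumbling, exactly
the intermediate regime partially DNA-restricted tail residues occupy. An
unrestricted vector (plateau ≈ 0) instead returns its own internal
correlation time, which is how residue-wise `tau_c` profiles separate
rigidified from mobile tail segments.
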