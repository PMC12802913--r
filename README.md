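# taildyn

Histone N-terminal tails are disordered, highly basic arms that stay
associated with nucleosomal DNA while exchanging rapidly among nonspecific
binding sites — a "fuzzy complex". Understanding how mutations or
modifications reshape this ensemble means reconciling two data streams:
solution NMR on reconstituted nucleosomes (chemical shift perturbations,
¹⁵N relaxation) and all-atom molecular-dynamics ensembles (contacts,
binding kinetics, intra-tail networks). `taildyn` is an R package for the
quantitative layer that connects them. It is aimed at structural biologists
and simulators who have tail trajectories and/or peak tables and want
comparable, residue-resolved observables out of both.

## What it computes

**Spin relaxation from trajectories.** From per-residue N–H bond-vector
series: the chunk-averaged P2 autocorrelation
C(τ) = ⟨P₂(û(t)·û(t+τ))⟩, a constrained multi-exponential fit
C(τ) ≈ Σᵢ Aᵢ e^(−τ/τᵢ) (Aᵢ ≥ 0, ΣAᵢ ≤ 1), reintroduction of overall
tumbling via 1/τ_eff = 1/τᵢ + 1/τ_rot (default τ_rot = 163.4 ns for a
nucleosome core particle), the spectral density
J(ω) = (2/5) Σᵢ Aᵢ τ_eff,i/(1+(ωτ_eff,i)²), and the standard dipolar+CSA
expressions for R₁, R₂ and NOE. Residue-wise effective correlation times
come from the rate ratio,

    tau_c = sqrt(6 R2/R1 − 7) / (4 pi nu_N),

with first-order error propagation, plus Pearson comparison of computed
and measured profiles.

**Experimental tables.** CSP Δδ = √(Δδ_H² + (0.154 Δδ_N)²) between peak
tables matched by residue; single-exponential intensity-decay fits
I(t) = I₀e^(−Rt) with covariance-based σ_R; τ_c from fitted R₂/R₁.

**Contact kinetics.** Heavy-atom tail–DNA contacts (< 4 Å, 1 ns stride,
200 ns burn-in defaults), whole-tail bound/unbound classification (unbound
when ≤ floor(0.10·n) residues touch DNA), binding/unbinding events with a
50 ns residence filter, and ensemble thermodynamics
K_d = N_unbound/N_bound, ΔG⁰ = RT ln K_d. Per-base-pair contact maps
aggregate both strands of the duplex.

**Ensemble descriptors.** Dynamic cross-correlation matrices, radius of
gyration, residue–residue contact-probability maps (distance or geometric
H-bond proxy), and node degrees over interaction-network edge tables.

**Thermal shift.** Min–max normalization of dye-fluorescence melt curves,
forward-difference derivative (value assigned to T_{i+1}), prominence-ranked
Tm peaks for mono- and biphasic disassembly, replicate aggregation.

**Synthetic data.** Seeded generators for every input with ground truth
embedded: rotational-diffusion and cone-restricted unit vectors, two-state
Markov binding timelines, toy bead nucleosomes with scripted binding,
logistic melt curves, perturbed peak-table pairs. They make the whole
pipeline testable without external data.

## A worked example

Generate a 2 µs synthetic bond-vector trajectory for restricted internal
motion, push it through the relaxometry chain, and look at the kinetics of
a synthetic binding timeline:

```r
library(taildyn)

vs  <- gen_cone_vectors(cone_spec(half_angle = 30, tau_internal = 2e-9,
                                  dt = 1e-11, n_frames = 5e4, seed = 1))
rec <- relaxation_from_vectors(vs, tau_rot = 163.4e-9, n_chunks = 10)
rec$R1; rec$R2; rec$tau_c * 1e9
#> [1] 0.9955433
#> [1] 146.4304
#> [1] 38.69432
```

R₂ is large because overall tumbling dominates the J(0) term through the
motional restriction (S² ≈ 0.65); the effective τ_c of 38.7 ns sits between
the 2 ns internal time and the 163.4 ns tumbling time, which is the
signature of a partially DNA-restricted residue.

```r
ts <- gen_two_state_timeline(two_state_spec(k_on = 4e6, k_off = 1e6,
                                            dt = 1e-9, n_frames = 1e6, seed = 2))
th <- binding_thermodynamics(ts)           # truth: Kd = k_off/k_on = 0.25
ev <- extract_events(ts, min_residence_ns = 50)
c(th$Kd, th$deltaG0_kcal_mol, mean(ev$residence_ns))
#> [1]  0.2339327 -0.8949252 1046.9570000
```

K_d ≈ 0.234 against a ground truth of 0.25 (sampling scatter at 10⁶
frames), ΔG⁰ ≈ −0.89 kcal/mol (bound state favoured), and a mean residence
time of ≈ 1047 ns against the 1/k_off = 1000 ns truth.

```r
mc <- gen_melt_curve(melt_spec(data.frame(tm = c(72, 81), width = 1.5,
                                          amplitude = c(0.5, 0.5)),
                               noise_sd = 0.02, seed = 19, n_replicates = 3))
melt_analysis(mc, smooth = TRUE)$summary
#>   transition mean_tm_C  sd_tm_C n_replicates
#> 1          1  72.00000 1.000000            3
#> 2          2  81.66667 1.154701            3
```

Both disassembly transitions of the biphasic melt are recovered within a
grid step of the 72/81 °C ground truth.

The methods vignette (`vignettes/histone-tail-dynamics.Rmd`) documents the
models, parameter defaults, numerical conventions and limitations.

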