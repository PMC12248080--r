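# taildyn

Histone tails are intrinsically disordered and live on nucleosomal DNA as a
*fuzzy complex* — a bound state of many rapidly interconverting, non-specific
configurations. Whether a sequence change (say, an arginine substitution in
the flexible hinge of the H3.3 tail) rigidifies the tail, repositions it on
the DNA, or changes nucleosome stability is a quantitative question that
spans three kinds of data: molecular dynamics trajectories, ¹⁵N NMR spin
relaxation, and thermal shift assays. `taildyn` is an R package for
structural biologists and biophysicists that implements the complete
analysis chain connecting them, together with ground-truth synthetic-data
generators that make every stage testable end to end.

## What it computes

**Trajectory → NMR observables.** From core-aligned NH bond vectors, the
rank-2 orientational autocorrelation
C(t) = ⟨P₂(μ̂(s)·μ̂(s+t))⟩ is computed per residue (all time origins,
chunk-averaged for convergence: 20 chunks of 100 ns for a 2 µs run), the
overall tumbling of the nucleosome core particle is reintroduced as
C(t)·exp(−t/τ_rot) with τ_rot = 163.4 ns, and a constrained
(aᵢ ≥ 0, Σaᵢ ≤ 1) multi-exponential fit yields the spectral density

    J(ω) = (2/5) Σᵢ aᵢ τᵢ / (1 + (ω τᵢ)²)

from which R₁, R₂ and the heteronuclear NOE follow via the standard
dipolar + CSA expressions (r_NH = 1.02 Å, Δσ = −170 ppm), and the
per-residue effective correlation time via

    τ_c = (1 / 4πν_N) · sqrt(6 R₂/R₁ − 7)       (ν_N in Hz).

**Experimental NMR analysis.** Chemical shift perturbations
Δδ = √(Δδ_H² + 0.154 Δδ_N²), single-exponential intensity-decay fits
without offset (duplicate delays retained, two uncertainty estimates),
τ_c from R₂/R₁ with first-order error propagation, and Pearson comparison
of predicted vs measured profiles.

**Tail–DNA binding kinetics.** Heavy-atom contacts at strictly < 4 Å every
1 ns; the full tail is unbound iff ≤ 10% of residues keep contacts; maximal
constant-state runs give residence times (50 ns filter for distributions,
none for transition counts) and the frame-count statistics
K_d = frames_unbound/frames_bound, ΔG⁰ = RT ln K_d at 310 K.

**Interaction networks.** Hydrogen-bond and van der Waals residue–residue
edges over an ensemble extracted every 10 ns with tail copies pooled; edge
probability = fraction of frames; node degree = summed incident
probabilities; adjacent residues masked in contact maps.

**Thermal shift.** Per-replicate min/max normalization, forward-difference
derivative assigned to the upper temperature, prominence-based melting-point
detection, replicate aggregation.

**Synthetic data.** Rotational diffusion on the sphere (exact rigid-rotor
law), diffusion-in-a-cone internal motion (plateau = S²), two-state Markov
binding timelines, exponential intensity decays on the experimental delay
schedules, sigmoidal melt curves, and a scripted toy nucleosome — all
deterministic under a seed, all carrying their ground truth.

## Worked example

Recover a 5 ns tumbling time from a simulated 400 ns vector trajectory,
then characterize binding kinetics and a melt curve:

```r
library(taildyn)

field <- field_parameters(h_freq_mhz = 600)   # nu_N = 60.8 MHz
vecs  <- gen_rotational_diffusion(tau_rot_ns = 5, dt_ns = 0.02,
                                  n_frames = 2e4, n_vectors = 1, seed = 7)
fit   <- fit_exponentials(chunk_average(vecs, residue = 1, n_chunks = 10))
fit
#> <sdens_model> C(t) = sum a_i exp(-t/tau_i):
#>   a = 1.0000  tau = 5.029 ns
#>   rms residual 2.49e-02
relaxation_from_J(fit, field)
#> <relax_pred> R1 = 2.319 /s, R2 = 8.299 /s, NOE = 0.885, tau_c = 4.976 ns
```

The fitted decay time (5.03 ns) and the τ_c recovered from the forward
R₂/R₁ ratio (4.98 ns) both land within 1% of the generating 5 ns.

```r
tl     <- gen_two_state_timeline(k_bind_per_ns = 0.02, k_unbind_per_ns = 0.01,
                                 n_residues = 36, n_frames = 1e5, seed = 7)
states <- call_states(tl)                     # <= 10% rule, inclusive
detect_events(states, min_duration_ns = 50)
#> <binding_events> 1332 events (646 kept at >= 50 ns), 666 unbound->bound transitions
binding_stats(states)
#> <binding_stats> Kd = 0.4957 (33141 unbound / 66859 bound), dG0 = -1.809 kJ/mol @ 310 K
```

The recovered K_d (0.496) matches the generating stationary odds
k_unbind/k_bind = 0.5, and the bound fraction 66859/1e5 matches
k_bind/(k_bind+k_unbind) = 2/3.

```r
mc <- analyze_melt_curve(gen_melt_curve(noise_sd = 0.02, seed = 7))
mc$tm
#> [1] 73 81
```

Two melting transitions are detected within one 1 °C grid step of the
generating midpoints (72, 81 °C; the forward-difference convention can
shift a peak one step up).

See the vignette (`vignettes/histone-tail-dynamics.Rmd`) for the models,
conventions, numerical safeguards and their rationale.

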