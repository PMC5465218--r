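# warburgsim

Overflow metabolism — incomplete oxidation of a nutrient at high intake,
with secretion of partially metabolized carbon such as lactate — is a
hallmark of fast-growing cells, most famously tumor cells (the Warburg
effect). `warburgsim` is an R package for studying how a single cell with
this phenotype can spread through a healthy tissue, for modelers in
systems biology and quantitative cancer research who want a minimal,
fully reproducible sandbox for microenvironmental feedback: competition
for the primary nutrient, toxicity of the accumulating waste, its
clearance by the blood, and its *recycling* by nutrient-starved healthy
neighbors (the lactate-shuttle scenario).

## The model in brief

A tissue is an N×N lattice of cells, each healthy or aberrant, coupled to
nutrient and waste fields s and w. Every cell imports nutrient at rate
*u* (Michaelis–Menten in s), oxidizes a precursor at a capped rate
*r* = *u* + *v* ≤ r_max, and outputs energy *e* = Y_u·u + Y_r·r with
Y_r > Y_u. Healthy cells target a fixed maintenance output e_m, topping
up with imported waste (*v* ≥ 0) when nutrient is short; aberrant cells
maximize energy with uptake inflated by α_ab and secrete the overflow
(*v* ≤ 0). Aberrant cells replicate at rate

λ = λ_max · max{e − e_m, 0}/(e − e_m + K_E) · K_inh/(K_inh + w)

and die at σ = σ_max · w/(K_tox + w); fields obey lattice
reaction–diffusion with blood exchange k(c − s) and −k·w. The simulator
alternates fast metabolite equilibration (quasi-steady state) with
Gillespie birth/death events. A spatially homogeneous mean-field tier
(φ, s, w) with dφ/dt = (λ − σ)φ(1 − φ) admits closed-form substrate
thresholds

s_m = K_s·u_m/(u_max − u_m),  s_sec = K_s·r_max/(α_ab·u_max − r_max),
s_gr = K_s·u_m/(α_ab·u_max − u_m),  u_m = e_m/(Y_u + Y_r),

their aberrant-fraction duals φ_m, φ_sec, φ_gr, and a phase
classification (W−: waste never secreted; Sh.: secreted and recycled;
W+: secreted, never recycled). See the methods vignette
(`vignettes/overflow-tissue-model.Rmd`) for the full account.

## Worked example

Fast blood turn-over with scarce nutrient (non-dimensional k = 1000,
c = 0.1): the aberrant clone secretes waste, nearby starved healthy cells
recycle it, and the tissue is taken over.

```r
library(warburgsim)

p <- default_nondim_params(k = 1000, c_blood = 0.1)
tr <- run_simulation(p, N = 20, seed = 1)
tr
#> tissue_trajectory: 20x20 lattice, seed 1, k = 1000, c = 0.1
#> 399 events, outcome: takeover (phi_f = 1); waste secreted; waste recycled

classify_region(p, phi_f = tr$phi_f)
#> Region IIIa (Sh.), phi_f = 1
#> thresholds: phi_m = -0.0303, phi_sec = 0.4143, phi_gr = 6.01
```

399 events are the 399 net replications that convert the remaining
lattice; `phi_f = 1` is full takeover. The negative φ_m says healthy
cells need waste recycling from the very start (c < s_m), and
φ_sec = 0.41 marks the aberrant fraction beyond which secretion stops —
the shuttle phase (`Sh.`). In dimensional units the thresholds evaluate
to s_m = 2 mM, s_sec ≈ 0.139 mM, s_gr ≈ 0.0101 mM
(`substrate_thresholds(default_dimensional_params())`).

The mean-field tier reproduces the same takeover
(`asymptotic_fraction(p)$phi_f` is 1) and, scanned in c at moderate k,
shows a discontinuous drop of φ_f at the takeover edge that shifts to
lower c when the shuttle is knocked out (`shuttle_knockout()`, forcing
v_he = 0). Near that edge the lattice model is bistable: identical
parameters, different seeds, opposite outcomes
(`bistability_scan(50, 0.875, p, replicates = 10, seed0 = 1)`).

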