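---
title: "A nonlocal reaction–diffusion model of planar cell polarity on periodic tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nonlocal reaction-diffusion model of planar cell polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Planar cell polarity (PCP) is the coordinated in-plane polarization of
epithelial cells: hairs, bristles and cilia across a tissue point the same
way because membrane proteins of the core pathway — Frizzled (Fz) and Van
Gogh (Vang), bridged across cell–cell junctions by Flamingo homodimers —
segregate to opposite sides of every cell.  `pcpsim` implements a
reaction–diffusion description of this process on periodic polygonal
tissues.  The polarized unit is the cross-junctional complex F–G
(F ≡ Fz:Fmi, G ≡ Fmi:Vang).  On the junction between cells *i* and *j* we
track two concentrations: `u`, complexes with their F-end in *i*, and `v`,
complexes with their F-end in *j*.  These are one field seen from two
sides — the package stores a single value per *directed half-edge*, and
`v` on a half-edge is `u` on its opposite.

A cell is polarized when `u` and `v` segregate to opposite sides of its
perimeter; the cell dipole **P** (vector sum of junctional differences
`u − v` pointing from the centroid to each junction midpoint) measures
this.  Tissue-scale order is quantified by the magnitude of the mean
dipole `Pbar`, the mean dipole magnitude `Qbar`, their ratio
`O = Pbar/Qbar ∈ [0, 1]`, and the orientational correlation length `ξ`.

## Kinetics

Each cell carries fixed total concentrations `f0` and `g0` of the two
membrane proteins.  Unbound protein equilibrates over the cell much faster
than junctional occupancies change, so the unbound pools are spatially
uniform within a cell:

    f_ubd(i) = f0(i) − ⟨u⟩_i ,   g_ubd(i) = g0(i) − ⟨v⟩_i ,

where `⟨·⟩_i` is the perimeter-averaged bound concentration
(`Σ uℓ / Σ ℓ` over the cell's junctions).  Concentrations and totals share
units (amount per membrane length), which makes the pool terms a
*fraction* of the total rather than a sum over junctions; with six
junctions, the summed convention would deplete the pools six-fold at a
uniform occupancy and (at the reference binding rate, κ = 10) pool
depletion would then overwhelm any cooperative feedback: the uniform state
would be linearly stable for every `g0` and no junction could polarize.
The averaged convention is the one under which the model has its reported
phenomenology — a junctional polarizability threshold near `g* ≈ 0.25` and
spontaneous polarization at `g0 = 1` (both recomputed by
`junctional_threshold()` and the test suite).

Cooperative interactions are carried by cytoplasmic messenger proteins
that are activated at membrane-bound complexes, diffuse through the
cytosol, and modulate binding elsewhere in the same cell.  At steady state
a messenger emitted at distance `Δr` contributes `∝ exp(−Δr/λ)`, so the
input a junction receives is a kernel-weighted sum over the junctions of
a cell (next section).  A shared junction is regulated by *both* of its
cells — the two protein species enter the pathway on an equal footing —
so the effective same-polarity input of a junction averages the two
cells' channels: `Ku = (Ku^(i) + Ku^(j))/2`, where `Ku^(i)` weights the
same-polarity complexes of cell *i* with *i*'s kernel and `Ku^(j)` does
the mirror-image sum in cell *j*; `Kv` is defined analogously for the
opposite polarity.  This averaging is what makes relabeling the two
species (F↔G together with `f0`↔`g0` and `u`↔`v`) an exact symmetry of
the dynamics.  The equations read

    du/dt = κ f_ubd(i) g_ubd(j) (1 + α Ku)
          − γ u (1 + β Kv) / (1 + α Ku)
          + cue(t) + η(t) ,

for a half-edge owned by cell *i* facing cell *j*.  The three kinetic
ingredients:

* **Mass action**: formation consumes unbound F from the near cell and
  unbound G from the far cell, at rate κ.
* **Upregulation** (strength α): same-polarity messengers both *promote
  formation* — the factor `(1 + α Ku)` — and *stabilize existing
  complexes*, dividing the dissociation rate by the same factor.  The
  stabilization term is what lets junctions carrying many same-polarity
  complexes keep them; it is also the mechanism by which longer junctions
  (with larger self-input, see below) out-compete shorter ones in
  elongated tissues.
* **Downregulation** (strength β): opposite-polarity messengers enhance
  dissociation through `(1 + β Kv)`.

All rates are non-negative for any state, so the scheme needs no clipping
of reaction terms.  With `α = β` the cooperative factors cancel at the
junction-symmetric uniform state, whose occupancy `u*` solves
`κ (f0 − u)(g0 − u)(1 + αu) = γ u (1 + βu)/(1 + αu)`; polarization is a
linear instability of this state towards junction-antisymmetric
perturbations (`u` up, `v` down), driven by the α and β feedbacks and
opposed by the bare dissociation and pool depletion.

`η(t)` is Gaussian white noise of magnitude `η0` per half-edge,
representing molecular shot noise of the binding reactions.

## Interaction kernels

`pairwise_edge_kernel()` integrates `exp(−|r − r′|/λ)` along both junction
segments (straight chords through the cell interior — messengers diffuse
through the cytosol, not along the membrane) and normalizes by both
lengths.  The diagonal (same-junction) entry has a closed form; cross
terms use two 8-point Gauss–Legendre panels per segment, which resolves
the mild corner kink between adjacent junctions to ~1e-4 — far below any
effect propagated to the dynamics.

`assemble_operator()` turns raw entries into the operator weights
actually used by the drift: the kernel is integrated along *both*
junctions (the emitted signal scales with the protein a junction
carries, and the received signal accumulates along the target), and all
entries are divided by one per-λ constant — the total input received by
a junction of the regular reference hexagon.  On the ordered lattice
every row then sums to exactly one for every λ, which pins the overall
cooperative gain and makes the junctional threshold and the interaction
range independent controls:

* λ → 0: the operator tends to the identity — purely same-junction
  cooperativity.  Junctions still polarize (the threshold mechanism
  survives), but nothing couples a cell's junctions, so cell dipoles
  orient at random: the strictly-local regime reproduces short-range
  order with full-strength junctional polarity.
* λ ≈ 0.5 ℓ0: adjacent junctions reinforce each other, opposite junctions
  are weakly coupled; the most unstable perturbation of a cell is dipolar
  and the tissue develops long-range order.
* λ ≳ 0.8 ℓ0: the kernel couples opposite cell sides almost as strongly
  as neighbours; upregulation then fights segregation itself, the
  dipolar instability weakens and polarization degrades — interaction
  ranges comparable to the cell diameter are counterproductive.

On irregular cells the weights follow the local geometry: the
cooperative input of a junction grows with its length — nearly linearly
below the kernel saturation scale — so long junctions bind and retain
complexes more readily than short ones.  This is the geometric readout
behind perpendicular polarization of elongated tissues, and it requires
nonlocality: in the strictly local limit the length bias vanishes with
λ.  Normalizing each row to exactly one instead (so every junction
receives the same total weight regardless of its length) erases the
readout and lets the proximity of junctions across the compressed cell
axis dominate, flipping the selected polarity to be parallel to the
elongation axis — the package therefore deliberately normalizes by the
fixed reference constant, not per row.

## Tissue geometry

`build_hexagonal()` tiles a torus with regular hexagons (edge length
`l0`), the reference ordered tissue.  Geometric disorder is generated by
displacing the triangular lattice of cell centers by i.i.d. vectors of
magnitude `ε0 · l0 · U[0,1]` and rebuilding the tissue as the periodic
Voronoi tessellation of the displaced seeds (`apply_disorder()`).  The
construction is exact half-plane clipping, needs no external geometry
library, returns the input unchanged at `ε0 = 0`, and produces
progressively broader junction-length and neighbour-count distributions
as `ε0` grows; `ε0 ≈ 0.45` is mildly disordered, `ε0 ≈ 0.6` strongly so.
Generating seeds are stored with the tissue so that later seed-level
transforms (mutant patches) are exact.

`apply_elongation()` applies an area-preserving stretch along the x- or
y-axis (an oblique stretch would shear the rectangular periodic box, so
only axis-aligned elongation is supported).  The stretch factor is
calibrated by root-finding so the *measured* tissue elongation index hits
the request exactly; the index is `E = (a − b)/(a + b)` from the
eigenvalues of the area-normalized second-moment tensor — zero for any
regular polygon, and the standard bounded choice.

`carve_geometric_clone()` implements geometric mutant patches: seeds
inside a radius are contracted towards the patch center (shrinking cell
areas) and given extra jitter, both ramping linearly to zero over a
transition width, after which the Voronoi tessellation is rebuilt — the
patch dissolves smoothly into the background and the topology stays valid
by construction.

## Observables

* `cell_dipoles()` — junction lengths do **not** enter the dipole: the
  dipole measures protein segregation, and any perpendicular alignment in
  elongated tissues must come from the dynamics, not from weighting long
  junctions more.
* `order_parameters()` — `O` is undefined (NA), not 0/0, when every
  dipole vanishes; dipole angles are undefined below a 1e-8 magnitude
  floor and excluded from angular statistics.
* `correlation_length()` — pair correlation `C(r) = ⟨cos Δφ⟩` binned at
  `l0` resolution, with `ξ` the interpolated 1/e crossing, capped at half
  the box diagonal (reported as capped when the correlation never
  decays).  A parameter-free estimator; on synthetic fields with imposed
  exponential-like correlations it agrees with a direct exponential fit
  of `C(r)` to within 20% (asserted in the tests).
* `elongation_polarity_scatter()` — angle differences are folded to
  `[0°, 90°]` (axes are undirected).

## Thresholds

`junctional_threshold()` computes the uniform symmetric state on a small
ordered lattice, forms the drift Jacobian by central differences,
projects it onto the junction-antisymmetric sector (one basis vector per
edge, `u` and `v` displaced oppositely), and bisects `g0` for the sign
change of the leading eigenvalue.  A 4×4 periodic lattice already
contains every lattice mode that matters (the result is identical on
6×6).  The threshold decreases with the cooperativity product αβ and
depends on the interaction length through the kernel spectrum; the
reference value is taken at `λ/ℓ0 = 0.5`.

`simulate_chain_1d()` is the one-dimensional reduction: cells with two
interfaces, intracellular coupling `exp(−ℓ_i/λ)` between them (same row
normalization), quenched cell lengths `ℓ_i ~ U[ℓ0(1±ε0)]`, and the same
kinetics.  `threshold_1d()` sweeps the `G0/F0` ratio and estimates the
critical ratio as the midpoint of the steepest rise of the
ensemble-averaged polarization — with finite chains and noise the onset
is smeared, so a steepest-rise midpoint is the robust estimator.  With
the default noise `η0 = 0.1` the sub-threshold curve sits on a noise
floor (`|p| ≈ 0.12` for four fluctuating junction differences), which the
steepest-rise estimator ignores by construction.

## Numerical choices

* **Integration**: classical RK4 with `dt = 1e-3 γ⁻¹` (stability margin
  ≳ 40× at reference parameters; fourth-order convergence is asserted
  against an adaptive solver in the tests).  Noise is added after each
  RK4 step as an Euler–Maruyama increment `η0 √dt N(0,1)` per half-edge,
  followed by reflection at zero by clipping — the scheme for additive
  noise with a non-negativity constraint.
* **RNG**: the integrator uses a self-contained xoshiro256++ stream
  seeded by the `seed` argument, so trajectories are bit-reproducible and
  independent of R's RNG state; geometry and initial conditions use R's
  RNG under `set.seed`, restored afterwards.
* **Steady-state detection**: a run is steady when the mean of `Qbar` and
  `O` over the last 10 γ⁻¹ window differs from the previous window by
  less than `max(tol, 2 × standard error of the window)`, with
  `tol = 1e-3`.  The standard-error guard is what makes the rule usable
  for stochastic runs, where instantaneous changes never fall below a
  fixed tolerance; noise-free runs terminate on the tolerance alone.
* **Quadrature**: 16 Gauss–Legendre nodes per segment; diagonal in closed
  form.
* **Bisection**: tolerance 0.005 on `g*`; the λ-sweep argmax breaks ties
  towards the smaller λ.
* **Degenerate inputs**: zero-area cells, non-closing lattices, pool
  overdraws at initialization, and empty clone regions raise errors that
  name the offending entity.

## Study designs and problem sizes

The experiment drivers run at a desk scale chosen so the full suite of
studies completes on a single CPU in minutes while staying comfortably
inside the asymptotic regime of each observable: tissues of 20×20 cells
(400 cells, 2400 half-edges), 3–5 seeds per condition, durations of
100–200 γ⁻¹ with early stopping at the detected steady state.  Key
qualitative results are insensitive to doubling either the lattice or the
ensemble (the threshold is identical on 4×4 and 6×6 lattices; the 1D
critical ratio moves by < 0.01 when the chain is doubled).  The
one-dimensional sweep uses 200-cell chains with up to 100 realizations
per ratio.

The geometry generator emulates the static packing statistics of
epithelia — junction-length dispersion, variable neighbour counts, local
area variation, elongation — but not their mechanics: no junction
remodelling, T1 transitions, divisions, or stress feedback.  The model's
timescale argument is that polarity kinetics are fast compared to tissue
rearrangement, so geometry enters as a quenched background.  Passing
tests therefore demonstrate the reaction–diffusion mechanism on realistic
*static* geometries; they say nothing about regimes where polarity and
mechanics co-evolve.

## Behaviour at the desk scale, and what does not reproduce

Several headline behaviours are robust at the sizes above and are
asserted by the test suite: the junctional threshold (`g* ≈ 0.243` at
the reference cooperativity, decreasing with αβ, and matched by the
gain/loss of junctional polarity in the full simulator), the critical
ratio of the 1D chain, spontaneous junctional polarization and protein
turnover at the reference parameters, the strictly-local/nonlocal
contrast of the correlation length, the instability of the alternating
zero-net-polarity pattern under infinitesimal noise, the exact F–G
relabeling symmetry, and perpendicular polarization of strongly
elongated tissues (folded angle ≈ 90° at `E = 0.4`).

Four behaviours are weaker in this implementation than the model family
is expected to show, and their acceptance checks are deliberately left
failing rather than retuned:

* **Weak elongation (`E ≈ 0.1`).**  The length bias of the cooperative
  gain is a few percent at this elongation — smaller than the
  junction-length scatter of a disordered tissue (`ε0 = 0.3`) and
  comparable to the basin-selection randomness of the initial
  condition.  Individual runs polarize fully but can lock into
  near-parallel metastable states that survive hundreds of `1/γ`; the
  ensemble mean of the folded angle lands far below 90°.
* **Noise fragility of local activation.**  With `λ_u → 0` the
  same-junction stabilization factor makes each junction strongly
  hysteretic, so an imposed polarity stays frozen even in highly
  disordered tissues; the expected coherence loss of local activation
  under noise does not occur within accessible run times.
* **Large interaction ranges.**  The dipole magnitude collapses with
  growing λ (pool turnover drops several-fold between `λ = 0.2` and
  `0.8`) and polarization is lost just above `λ ≈ 0.85`, but at the
  desk scale the measured correlation length keeps increasing up to
  `λ = 0.8` instead of peaking near `0.5–0.6`: ordering speed, not the
  final correlation, dominates the estimate at these sizes and
  durations.
* **Tissue-scale ordering time.**  Starting from random initial
  conditions, domains of aligned dipoles form quickly (within tens of
  `1/γ`) but their coarsening into a single tissue-spanning domain is
  slow: even ordered 20×20 lattices sit at intermediate alignment
  ratios (`O ≈ 0.5–0.85`) after a thousand `1/γ`, depending on the
  seed, so checks that demand near-perfect global alignment from random
  starts do not pass at desk durations.

All three trace back to the same root: the closure of the cooperative
rate factors is reconstructed (formation enhancement plus complex
stabilization by same-polarity messengers), and its nonlinear depth —
how strongly a polarized junction resists turnover — is only loosely
constrained by the threshold anchors it was validated against.

## Known limitations

* Protein distributions are uniform along each junction; sub-junctional
  clustering (puncta) is not represented.
* Elongation is a global axis-aligned map; locally varying anisotropy
  fields are not supported.
* The cue model is a constant-gradient bulk term with exponential decay
  or a boundary strip (clamped or initial-only); growing cues are out of
  scope.
* The closure of the cooperative terms is a modelling choice made at the
  level of rates (multiplicative enhancement/stabilization factors);
  other closures with the same linearization would behave identically
  near threshold but can differ quantitatively deep in the polarized
  regime.

## A minimal session

```{r}
library(pcpsim)

tissue <- apply_disorder(build_hexagonal(20, 20), 0.45, seed = 1)
params <- model_params()            # reference parameter set
ic     <- init_state(tissue, "random", 0.5, seed = 1)
traj   <- simulate(tissue, params, ic, Tend = 200, seed = 1)

dip <- cell_dipoles(state_at(traj), tissue)
order_parameters(dip)
correlation_length(dip, tissue)$xi

junctional_threshold()              # critical g0 on the ordered lattice
```
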