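---
title: "Modeling renal arterial networks and coupled nephron dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling renal arterial networks and coupled nephron dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nephronet)
```

This vignette is the package's account of the science it implements: the
stochastic generator of renal arterial trees, the three physical layers
coupled on top of them (pressure, electrotonic conduction, nephron dynamics),
the choices made where the underlying description left the design open, and
the known limits of the standard parameter set.

## 1. The vascular tree generator

### Sampling laws

Four laws, bundled in a `morphometry_profile`, drive the generator:

* **Daughter diameter** given parent diameter: Gaussian, with a cubic
  polynomial mean and a linear SD in the parent diameter (µm). The second
  daughter is not sampled; it is the Murray complement
  `Dd2 = (Dp^3 - Dd1^3)^(1/3)`, so the cube of diameter is conserved exactly
  at every branch point.
* **Vessel length** given diameter: Gaussian, linear mean and SD (µm).
* **Inter-arteriole spacing**: exponential with rate `lambda` (1/µm). The
  exponential is the minimal law consistent with two observations in cleared
  renal tissue: arterioles often originate in doublets or triplets (high
  probability of near-zero spacings) and vessel segments without arteriole
  origins are rare. The spacing is taken to be independent of the feeding
  vessel's diameter.
* **Afferent arteriole diameter**: Gaussian, truncated below the feeding
  diameter.

Gaussian draws are truncated to their physical ranges by rejection with a
100-retry cap, after which the draw is clamped 1% inside the violated
boundary; a cap hit is a sign of a pathological profile, not of normal
operation. Draws outside the profile's `valid_diameter_range` extrapolate the
fits; the builder counts them (`meta$n_extrapolated`) rather than warning per
draw, because the recursion necessarily queries a little below the smallest
fitted diameter near the stop criterion.

### The two algorithms

`build_abt()` starts from a root of diameter `D_initial` and recursively
bifurcates depth-first (first daughter first, the first daughter being the
sampled one); any daughter at or below `D_stop` becomes an afferent
arteriole. Arterioles therefore sit only at the terminal branch points.

`build_ksabt()` first *segments* every non-root vessel: a walk along the
vessel places arteriole origins at exponentially spaced positions, each
attachment reducing the continuing diameter by Murray's law, and the
bifurcation at the vessel's end then uses the reduced diameter. The residual
spacing when the walk overshoots a vessel carries into the first arterial
daughter (a single scalar shift path); the second daughter starts a fresh
draw. Whether the shift should propagate to one or both daughters is not
fixed by the algorithm's description; the single-path carry was chosen
because it matches the notion of "distance to the arteriole on the parent
vessel" and keeps realized spacings exactly exponential along each chain,
which `summary()` exploits when it reports inter-arteriole walk distances.

Two boundary rules needed decisions:

* **Diameter exhaustion.** When an attachment would push the continuing
  diameter to `D_stop` or below, the vessel stops branching and the remaining
  piece becomes a terminal arteriole *stub* (it is below the arteriole
  threshold diameter). Stubs are flagged (`stub = TRUE`) and excluded from
  the reported walk spacings, which are meant to be the realized draws of the
  exponential law.
* **Depth cap.** A configurable recursion cap (default 60) guards against
  profiles whose daughter/parent ratio approaches 1; branches hitting it are
  terminated as arterioles with a warning. The default profile stays far
  from the cap.

### The default morphometry profile and what it can and cannot match

The packaged defaults (`inst/extdata/default_morphometry.yaml`) are smooth
approximations to published micro-CT morphometry of the rat kidney, with the
small-diameter end adjusted so that whole-kidney ABT trees
(`D_initial = 530`, `D_stop = 22` µm) reproduce the published
afferent-arteriole statistics: across seeds the generator yields ~19.9k
arterioles of mean diameter 19.4 µm (published: 20188 and 19.37 µm). This
agreement is not a coincidence of fitting: Murray's law conserves the sum of
diameter cubes down the tree, so the arteriole count of *any*
cube-conserving tree is pinned at `D_initial^3 / E[D_AA^3]`, and the
published ABT row satisfies that identity to 0.02%.

The same identity is the generator's hard limit: the published KSABT
arteriole count (32127 at the same `D_initial` and arteriole diameters) would
require the cube sum to grow by ~58% and is unreachable by any parameter
choice while Murray's law is enforced at segmentation events, as this
implementation (and the algorithm it follows) requires. The package
therefore reproduces the *orderings* — KSABT produces more arterioles than
the matched ABT for every seed, from wider feeding vessels and with a smaller
pressure drop — but not that absolute count, and the corresponding acceptance
test records the discrepancy rather than hiding it.

The spacing rate default `lambda = 1/30` µm⁻¹ was chosen from the scale of
cleared-tissue spacing measurements (tens of µm); the KSABT count is
insensitive to it, again because of cube conservation.

The generator emulates topology and calibres only. It does **not** produce a
3D embedding (plots are schematic), arteriole doublets/triplets at single
sites beyond what near-zero spacings produce, a juxtamedullary subpopulation,
or a venous tree; passing tests therefore say nothing about spatial
collision, perfusion territories, or medullary physiology.

## 2. Hemodynamics

Each vessel is a Poiseuille resistance `R = 128 eta(D) L / (pi D^4)` with the
in-vivo viscosity law at hematocrit 0.45 (asymptote 3.2 cP; the printed form
is used with its published constants). Units are chosen so no prefactor
appears: diameters and lengths in µm and viscosity in cP give `R` directly in
kPa·s/nL. Junction nodes carry one pressure state each with a lumped
compliance `C_hdr` (default 3.0 nL/kPa; the dynamics are insensitive over
0.3–5): `C_hdr dP_j/dt = sum(in) - sum(out) - F_neph`. Afferent arterioles
are not resistors in this network — their resistance is the nephron model's
dynamic `R_a` — and enter only as nephron sinks
`F_neph = (P_node - P_g)/R_a` at their origin nodes. The root inlet pressure
is a boundary condition, not a state.

`steady_pressures()` solves the equivalent linear resistor network directly
(dense, the relevant trees are small); the ODE steady state is tested to
coincide with it, and flow is conserved at every node to below 1e-8 nL/s.

## 3. Electrotonic coupling

A vessel of diameter `D` has `N = round(pi D / W_c)` endothelial cells per
cross-section (`W_c = 5` µm) and is a chain of `M = round(L / L_c)` units
(`L_c = 50` µm, the effective overlapped cell length); counts round half away
from zero and floor at 1. A unit leaks with `G_u = N G_c` to the resting
potential (−40 mV) and couples to chain neighbors with `G_g = N G_gj`
(`G_c = 1/8`, `G_gj = 1/3` MΩ⁻¹). At a branch point the cells of each vessel
split toward the other two in proportion to their diameters
(largest-remainder apportionment, so the split is exact); the junction
conductance between two vessels is the arithmetic mean of the two facing
counts times `G_gj` — symmetric by construction, though an odd cell count
cannot split evenly, so "equal daughters couple equally" holds exactly only
for even counts. The tree is cut from a larger bed: the root's upstream end
sees two rest-held boundary conductances of `2 N_root G_gj` each.

Because endothelial dynamics are much faster than TGF, membrane potentials
are treated as instantaneous and the network reduces to one symmetric
positive-definite sparse solve. One published equation writes the
interior-unit coupling coefficient as the leak conductance `G_u`; this is
interpreted as a misprint for the gap conductance `G_g` (consistent with the
nephron-site equation and the circuit diagram), and the literal form remains
available as `eq6_literal = TRUE`.

`coupling_matrix()` injects a unit test current at the distal (macula-densa)
end of each arteriole — "end of the vessel" was ambiguous; the distal unit
was chosen — and records the voltage-deflection ratios at all other
arterioles' distal ends: `K[m, n] ∈ (0, 1]`, diagonal 1, not symmetric in
general (asymmetric branchings conduct anisotropically). Unit lengths
quantize to `L_c`, so the transfer coefficient is a step function of
arteriole length; on the minimal Y geometry the published coupling regimes
(~0.05 and ~0.1) fall inside the swept range but not exactly on grid values.

### Feedback composition and the gain `g_md`

The depolarization sent by a nephron's macula densa is proportional to its
TGF activation. The composition rule adopted is

`Psi_eff_m = Psi_m + g_md * sum_{n != m} K[m, n] (Psi_n - Psi_eq)`,

which makes the transfer coefficient `K` directly the "strength of electrical
interaction". The proportionality constant is not published; `g_md = 1`
(direct unit proportionality) was fixed by requiring that the two-nephron
fixture reproduce the published dichotomy within the standard measurement
window: the short-second-arteriole geometry (K ≈ 0.13) locks in phase from a
0.38-period initial offset within 300 s, the long one (K ≈ 0.04) does not.
Two caveats are documented deliberately. First, locking is operational
("within the measurement window"): at these faithful Poiseuille resistances
the competing hemodynamic interaction is weak, so arbitrarily long
integrations eventually align even weakly coupled pairs. Second, gains
`g_md >= 2` *destabilize* the synchronous state — the transferred activation
inflates the loop gain of the symmetric mode and pushes it out of its stable
window — so more coupling is not monotonically more synchrony in this model.

## 4. The nephron model

Six ODEs per nephron: proximal tubular pressure `P_t` (kPa), normalized
arteriolar radius `r` and its velocity `v_r`, and a three-stage linear chain
`X1..X3` approximating the TGF transport delay `T = 13.5` s (a gamma-kernel
approximation, exactly as specified — no true delay-differential solver).
The algebraic closure per evaluation: Henle flow `(P_t - P_d)/R_Hen`;
afferent resistance `R_a = R_a0 (beta + (1 - beta)/r^4)`; a cubic
`A Ce^3 + B Ce^2 + C Ce + D = 0` for the efferent protein concentration
(unique positive root in the operating regime); glomerular pressure
`P_g = b Ce^2 + a Ce + P_t`; filtration
`F_filt = (1 - H_a)(1 - C_a/Ce)(P_a - P_g)/R_a`; the TGF sigmoid `Psi(X3)`
(exactly `Psi_eq = 0.38` at `3 X3/(T F_Hen0) = 1`); and the arteriolar
equilibrium pressure `P_eq = P_el + Psi P_act`.

Numerical choices: the cubic is solved analytically (Cardano/trigonometric,
vectorized across nephrons) with a three-step Newton polish; relative
residuals stay below 1e-10 and the root is verified in tests against a
10^6-point bracketing scan. If several positive roots exist the largest
(continuation of the physiological branch) is returned; if none exists the
state is outside the model's working regime and a classed error
(`nephronet_ce_error`) carries the state so sweeps can mark the nephron
inactive. `b = 0` degenerates to the quadratic closed form. Integration uses
adaptive stiff solvers (`lsoda` for a single nephron, `lsodes` for networks,
where millisecond nodal-pressure relaxation coexists with ~30 s TGF periods;
the sparse Jacobian structure gives a ~6x speedup), with `rtol = 1e-6`,
`atol = 1e-8` by default.

`F_eff` is defined as `(P_g - P_v)/R_e` with the printed `R_e = 1.9`. The
closure cubic itself, re-derived from the glomerular mass balance, implies an
efferent outflow resistance equal to `R_a0 = 2.4` — an internal inconsistency
of the printed constant set. The definition above is used for reported
flows; the alternative `F_neph - F_filt` is available from the auxiliaries
(`f_neph`, `f_filt`) for cross-checking.

### The oscillatory window

With the standard constants the single nephron at *fixed* feed pressure has
its Hopf window at approximately `P_a ∈ [11.6, 13.1]` kPa: at `P_a = 13.3`
the printed equations give a weakly stable focus (the right-hand side was
verified term-by-term against an independent transcription, and every printed
worked value reproduces). Oscillations at a 13.3 kPa *root* pressure appear
once the nephron is embedded in a network, where the feed pressure sits
slightly below the root and is dynamically loaded. The window's location is
also why, on the 40-µm test branches, the all-nephron activation threshold
lies near 12.5 kPa root pressure, with the kidney-specific structure
activating at every grid pressure at least as readily as the matched ABT —
the published comparison's ordering — while an 8 kPa threshold is not
attainable with the printed constants, whose faithful behavior the package
deliberately preserves. Robustness was checked across `beta ∈ {0.4, 0.67}` and
`alpha ∈ {12, 20}`: every corner keeps a nonempty oscillation window
containing `P_a = 12` kPa.

"Inactive" classification everywhere: oscillation amplitude below 0.01 kPa
peak-to-peak (well below the ~0.5 kPa physiological oscillations, above
solver noise), a negative mean tubular pressure (the signature of
insufficient feed pressure), or a closure failure.

## 5. Network experiments and their problem sizes

`assemble_network()` binds tree, pressures, coupling matrix and nephrons;
`simulate_network()` integrates the full coupled system. Experiments follow
the package's standard windows: 300 s transient discard plus 300 s
measurement (≥10 TGF cycles). Phase extraction is by quadratic peak
interpolation (the traces are strongly periodic; no analytic-signal machinery
is needed), with phases linear between peaks; a pair is in-phase locked when
the circular variance of the phase difference is < 0.1 and the circular mean
is within π/4 of zero.

Dynamics are exercised on branches of `D_initial = 40` µm (8–10 nephrons) —
the same scale the published network experiments use — and tree statistics on
whole-kidney trees (`D_initial = 530` µm, ~20k arterioles, ~0.6 s to generate)
over 10 seeds. Full-kidney *dynamics* (~30k nephrons) are out of scope for
the test suite.

## 6. Known limitations

* The KSABT arteriole count is bounded by cube conservation (Section 1);
  matching the published absolute count would require abandoning Murray's law
  at attachment sites.
* The printed nephron constants place the operating pressure 13.3 kPa just
  outside the fixed-pressure Hopf window; all network-level oscillation
  results inherit that shift (Section 4).
* Electrical discretization quantizes lengths to 50 µm units, so coupling
  strengths move in steps with geometry.
* All nephrons share one parameter set; inter-nephron heterogeneity,
  myogenic-mechanism biochemistry, pulsatile flow and hematocrit
  heterogeneity are not modeled.
* Trees are topological; plots are schematic layouts, not anatomy.
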