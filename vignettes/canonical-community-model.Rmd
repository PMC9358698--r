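---
title: "A minimal closed-mass-balance ecosystem built from DEB V1-morphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal closed-mass-balance ecosystem built from DEB V1-morphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canocom)
```

## The model

`canocom` simulates the smallest ecosystem that still deserves the name:
two nutrients (carbon dioxide `M_C` and ammonia `M_N`), a producer with a
carbohydrate reserve and a nitrogenous reserve, a consumer, a decomposer,
and four detritus pools fed by consumer faeces and dead consumer biomass —
thirteen state variables in all, in µmol C L⁻¹ (µmol N L⁻¹ for ammonia),
with time in days.  The system is closed for matter: every carbon atom and
every nitrogen atom is somewhere in those thirteen pools at all times.

All three living groups are Dynamic Energy Budget (DEB) V1-morphs.  A
V1-morph's uptake area is proportional to its structural volume, so every
mass-specific rate is independent of individual size and a population is
fully described by its total structural mass `M_V` and reserve density
`m_E = M_E / M_V`.  Reserve density follows first-order dynamics
(`reserve_density_rate()`),

$$\frac{dm_E}{dt} = j_{EAm} f - \dot k_E m_E,$$

and the specific growth rate (`specific_growth_rate()`) is

$$\dot r = \frac{\dot k_E m_E - j_{EM}}{m_E + y_{EV}},$$

negative when mobilized reserve cannot cover maintenance — shrinkage is a
legitimate state of affairs here, not an error.  The κ allocation rule is
fixed at κ = 1: organisms divide rather than mature, so there is no
maturity compartment anywhere in the package.

## Synthesizing units

Every uptake, maintenance and growth process is the stationary throughput
of a *synthesizing unit* (SU): a server that binds Poisson-arriving
substrate particles and releases product.  The package ships the closed
forms —

* `su_single()` / `su_substitutable()`: the (multi-prey) Holling type II
  response, used for predation and detritus uptake;
* `su_parallel_complementary()`: non-substitutable substrates bound in
  parallel; for arrivals $J_i$ and capacity $k_{max}$ the reciprocal rate
  is the inclusion–exclusion sum
  $1/k_{max} + \sum_i 1/J_i - \sum_{i<j} 1/(J_i + J_j) + \dots$, used for
  photosynthesis (light × CO₂, and light × CO₂ × NH₃) and for the
  producer's growth SU;
* `su_sequential()` and `su_minimum_operator()` for comparison;
* `preference_su_demand()`: a two-substrate SU run at a *fixed* product
  rate (demand kinetics), which is how every organism splits its
  maintenance bill between mobilized reserve (preferred) and structure
  (tolerated, at preference ρ = 0.01).

Because each closed form is a pseudo-steady-state solution of a small
continuous-time Markov chain, the package also ships the chain itself:
`su_markov_oracle()` solves the stationary linear system of any of the
chain builders (`markov_su_*()`), and the test suite requires closed form
and chain to agree to 10⁻¹⁰ relative on hundreds of random draws.  The
n-substrate inclusion–exclusion form is *validated* this way rather than
asserted: only the 2- and 3-substrate cases are textbook results.

Two numerical notes on the demand-driven preference SU, whose dissociation
rate solves a quadratic $A\dot k^2 + B\dot k + C = 0$:

* the admissible root is computed cancellation-free (both roots via the
  stable pairing, then verified against the delivery balance), because the
  naive $(-B+\sqrt{B^2-4AC})/2A$ branch loses all precision when the
  mobilized flux is epsilon-scale;
* when $|A| \approx 0$ the finite root $-C/B$ can be negative while the
  true root diverges — supply then barely meets demand and the unit must
  cycle infinitely fast.  That limit is taken explicitly
  (`k_diss = Inf`, preferred flux `min(y1*J1, kP)`), keeping the fluxes
  continuous.  Both cases arise in practice during ecosystem runs.

## From an isomorph database entry to ecosystem rates

Consumers are parameterized from a standard isomorph (energy–length) DEB
record for the water flea *Daphnia magna*
(`daphnia_isomorph_params()`).  Fixing a reference structural length
$L_d = 0.07$ cm turns area-specific into volume-specific rates
(`isomorph_to_v1_energy_length()`), dividing by the energy density of
structure $\mu_E[M_V] = 3556$ J cm⁻³ makes them dimensionless mass–mass
rates (`energy_length_to_mass_mass()`), and dividing the assimilation
maximum by the digestion efficiency κ_X = 0.9 yields the consumption
maximum (`max_consumption_from_assimilation()`):

```{r}
iso <- daphnia_isomorph_params()
el <- isomorph_to_v1_energy_length(iso)
mm <- energy_length_to_mass_mass(iso)
c(pAm_vol = el$pAm_vol, k_E = el$k_E,
  j_cons = max_consumption_from_assimilation(mm$j_EAm, iso$kappa_X),
  j_EM = mm$j_EM, y_EV = mm$y_EV)
```

The assimilation-basis and consumption-basis maxima are deliberately two
distinct quantities in the code; conflating them is the easiest way to be
silently wrong by a factor κ_X.  `default_ecosystem_params()` wires the
consumption maximum in as the consumer's producer-uptake maximum and half
of it as the decomposer-uptake maximum, and carries every half-saturation
constant, maintenance rate, conductance, yield and nitrogen content of the
default parameterization.  Nitrogen contents follow a molar C:N of 6.6
(Redfield, $n_N = 0.15$) everywhere except the producer's carbohydrate
reserve (0) and nitrogenous reserve (0.8).

## Fluxes and closure

`assemble_flux_matrix()` evaluates all fifteen processes (five consumer,
four producer, six decomposer rows) against the eleven organic pools; the
signed matrix is sparse exactly where no process touches a pool.
`ecosystem_derivatives()` sums the columns and then *defines* the nutrient
rates as

$$\frac{dM_C}{dt} = -\sum_* \dot J_*, \qquad
  \frac{dM_N}{dt} = -\sum_* n_{N,*} \dot J_*,$$

so total carbon and total nitrogen are conserved identically — the
conservation tests check the arithmetic, not the model.

The producer is the subtle part.  Its specific growth rate $\dot r$
appears inside its own mobilization fluxes, so
`producer_growth_solve()` finds the root of
$g(\dot r) = (J_{growth}(\dot r) - J_{struct.maint}(\dot r))/M_{VP} -
\dot r$ by Brent's method on a bracket that provably encloses a sign
change: at $\dot r = \max \dot k_{E_iP}$ mobilization is clamped to zero
so $g < 0$, and at
$\dot r = -(j_{E_1P,MP}/y_{E_1P,VP} + j_{E_2P,MP}/y_{E_2P,VP}) -
\max \dot k_{E_iP}$ the implied rate cannot be that negative, so $g > 0$.
The residual at the accepted root is polished below 10⁻¹²·max(1, k̇) —
the test suite checks 10⁻¹⁰ and cross-checks the root against a damped
fixed-point iteration that never touches the bracketing code.  Of the
reserve flux offered to the growth SU but not consumed by it, a fraction
κ_E returns to the reserve and the rest dissipates; the rejected amount is
defined as the non-negative difference between offer and consumption,
which is the only reading under which every magnitude is non-negative and
mass balances.

## Forcing

Temperature and irradiance follow 365-day cosine cycles between their
annual extremes (`seasonal_temperature()`, `seasonal_irradiance()`;
defaults: 2.85–19.6 °C peaking on day 225, 0.98–20.88 MJ m⁻² d⁻¹ peaking
on day 170).  Light is attenuated by producer self-shading as
$\exp(-K_S M_{VP})$ with $K_S = 0.1$ L µmol⁻¹ — the sign is the one under
which self-shading *shades*.  Every parameter with dimension per-time
(uptake and synthesis maxima, maintenance rates, conductances, the death
rate) is multiplied by the Van 't Hoff–Arrhenius factor
$\exp(T_A/T_1 - T_A/T)$ ($T_A = 8000$ K, $T_1 = 293$ K); half-saturations,
yields and stoichiometric coefficients are not rates and are never
corrected.  Whether the death rate should be corrected is not a settled
question; it is corrected by default and any rate can be exempted through
`arrhenius_exclusions` in the configuration.

## Integration and the ammonia floor

`run_simulation()` integrates the system with deSolve's `lsoda` at
rtol 10⁻⁸ / atol 10⁻¹⁰ — stiff-capable because the decomposer conductance
(14.5 d⁻¹) coexists with detritus pools turning over a hundred times
slower.  Fluxes are evaluated on the state floored at zero, and a material
pool sinking below −10⁻⁹ times the initial carbon stock aborts the run.

Ammonia is deliberately exempt from that abort.  The nitrogen closure
makes consumer assimilation of the producer's nitrogen-free carbohydrate
reserve into nitrogen-bearing consumer reserve an implicit ammonia sink,
and nothing in the model's rate laws saturates that sink as `M_N`
approaches zero.  In the default run the demand genuinely crosses zero
around day 162: ammonia then runs a transient bookkeeping deficit (about
−0.19 µmol N L⁻¹ at its deepest, each summer), during which the producer's
nitrogen-reserve synthesis sees zero ammonia.  Total nitrogen remains
conserved to machine precision throughout; a hard floor on `M_N` would
simply make the five-year reference run impossible.  Interpreting the
deficit physically — as nitrogen the consumers would have needed but could
not get — and adding a saturating uptake term would change the model, so
the package reports it honestly instead.

## The seasonal attractor

The default configuration (reference initial state, 1825 days, daily
output) settles into a yearly repeating pattern with two producer blooms
per year — an early-summer bloom and a slightly lower late-summer bloom —
each followed by a consumer peak, with decomposers clearing the detritus
afterwards.  `detect_annual_peaks()` counts local maxima with topographic
prominence of at least 5 % of the window's range; the threshold has no
counterpart in the underlying model description and was chosen once so
that genuine blooms are separated from solver-scale ripple (it is a
function argument, not a constant).  The peak count is invariant to
halving the solver tolerances, which is the robustness check the test
suite runs.

```r
traj <- run_simulation(simulation_config())
detect_annual_peaks(traj, "M_VP", window = c(1460, 1825))
```

## What the tests do and do not show

The oracle tests (Markov chains, scalar root-finds, fixed-point
iteration, term-wise re-assembly of the full flux matrix) establish that
the code computes the stated equations; the conservation and attractor
tests establish that the assembled system behaves as a closed seasonal
ecosystem.  None of this validates the model against field data: the
producer here is "the phytoplankton", the consumer "the zooplankton", the
decomposer "the bacteria", each a single homogeneous V1-morph population.
Known limitations worth keeping in mind: no producer background
mortality (consumers alone terminate blooms), a single consumer cohort
with no size structure, no phosphorus, no spatial transport, and the
ammonia-deficit bookkeeping described above.

## Problem sizes used in checking

The shipped checks use the five-year (1825-day) reference run at daily
output plus one repeat at halved tolerances, a few hundred random draws
per SU oracle comparison, and a dozen random states for the implicit
growth solve — sizes at which every check is exact or property-based
rather than statistical.
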