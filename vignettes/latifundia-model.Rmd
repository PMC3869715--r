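---
title: "The latifundia model: land use, pre-capitalist trade and disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The latifundia model: land use, pre-capitalist trade and disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latifundia)
library(dplyr)
```

## The model

`latifundia` simulates how land ownership concentrates — or fails to —
in a population of `n` landowners who each start with `m` parcels of a
landscape. The model couples three processes, each stepped once per
simulated year.

**Land use.** Every parcel is in one of three states: forest (`x`),
agriculture (`y`) or post-agricultural land in recovery (`z`, "empty"
land). Parcels are continuous and divisible, and the yearly transitions
act as deterministic proportions of each owner's holdings:

$$
\begin{aligned}
x' &= (1-r)\,x + \mu\,z \\
y' &= r\,x + (1-\eta)\,y \\
z' &= \eta\,y + (1-\mu)\,z
\end{aligned}
$$

with deforestation rate $r$, degradation rate $\eta$ and recovery rate
$\mu$, all probabilities per year. By default recovering land returns
to forest, which preserves a forested state at equilibrium; the strict
one-way cascade in which $\mu$ sends empty land back to agriculture
(so forest only drains) is available as
`recovery_target = "agriculture"`. For rates in $(0,1]$ the chain's
stationary distribution is proportional to $(1/r,\,1/\eta,\,1/\mu)$
under the default; `landuse_stationary()` computes it for either
variant. Land use never moves land between owners: each owner's total
is conserved exactly.

**Trade.** Trade is pre-capitalist: no capital accumulation, no credit,
no prices — land is exchanged at its instantaneous value, and only
empty-state land is on the market. Owner $i$'s utility is the value of
their holdings,

$$U_i = a\,x_i + b\,y_i + c\,z_i,$$

with per-parcel utilities $a$ (forest, ecosystem services), $b$
(agriculture, crop revenue net of management) and $c$ (empty land).
Purchasing power is the owner's share of the population's utility,
$P_i = U_i / \sum_j U_j$, and sale pressure is its complement,
$V_i = 1 - P_i$: the richer an owner, the less inclined to sell. (Two
harder alternatives, selling everything when below the population mean
or median utility, are available through `sale_rule`.) Each year all
empty land under sale pressure is pooled, $T = \sum_j V_j z_j$, and
redistributed in proportion to purchasing power:

$$z_i' = (1 - V_i)\,z_i + P_i\,T .$$

Because the $P_i$ sum to one, trade conserves total land and total
empty land exactly. Trade happens before the year's land-use
transition. If every utility is zero (possible only when all owners are
simultaneously infected under full discount) purchasing power falls
back to the uniform $1/n$.

**Disease.** A frequency-dependent susceptible–infected–susceptible
process runs on the owners. With $\kappa$ owners infected in the
previous year, the force of infection is

$$\lambda = \min\!\left(1,\; R_0\,\kappa / n\right),$$

and each exposable owner is infected independently with probability
$\lambda$ (rejection sampling on uniform draws). Infection lasts one
year; an owner infected in year $t$ recovers during year $t+1$ and can
be infected again from year $t+2$. This one-year refractory period
matters: with immediate re-exposure and $R_0 > 1$, the saturated force
$\lambda = 1$ would lock the entire unprotected population permanently
in the infected state, which both erases the between-owner variation
the trade dynamics feed on and drives every utility to zero under full
discount. A `protected_frac` fraction of owners, sampled once per run,
is immune for the whole run — modelling heterogeneity in
susceptibility. In an infected year an owner's utility is multiplied by
the discount $h \in [0,1]$ ($h = 0$: a sick owner's land yields
nothing; $h = 1$: disease is economically neutral), which shrinks both
their purchasing power and their ability to hold on to land.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `n`, `m` | owners, parcels per owner | 64, 64 | the reference community size of the sweep and disease experiments |
| `r`, `eta`, `mu` | yearly land-use rates | 0.5 each | the reference uniform-turnover regime |
| `a`, `b`, `c` | utilities F/A/E | 1, 2, 3 | the ordering least prone to spontaneous concentration, used as the null model for the disease experiments |
| `sale_rule` | how V is formed | complement | richer owners hold land (richer-conquers assumption) |
| `r0` | basic reproductive number | 2 | endemic regime; 1 for the epidemic regime |
| `h` | discount while infected | 1 | disease economically neutral unless asked otherwise |
| `kappa0` | initial infected | endemic level | see below |
| `eq_tol`, `eq_window` | steady-state rule | 1e-9·m over 10 years | see below |
| `landless_eps` | extinction threshold | 1e-3 | proportional trade never reaches exactly zero |
| `equity_fraction` | equity label threshold | 0.9 | "a large proportion of the original landowners" is not a sharp number; exposed in the configuration |

**Disease seeding.** The disease is introduced either epidemically or
as an endemically established infection. The default initial infected
count is the deterministic SIS endemic level floored at one case,
$\kappa_0 = \max\{1, \mathrm{round}(n(1 - 1/R_0))\}$: a single
introduced case when $R_0 \le 1$, the established prevalence when
$R_0 > 1$. Seeding an endemic scenario at one case instead would make
roughly a third of replicates lose the infection to stochastic
fade-out before it can touch the land dynamics, turning a statement
about endemic disease into a mixture over extinction; `kappa0`
overrides the rule when that mixture is wanted.

**Steady-state detection.** The paper-level notion of equilibrium is
that holdings stop changing. Losing owners decay geometrically, so
exact constancy never occurs in finite time; we declare a steady state
when every owner's total changes by less than `eq_tol` = 1e-9·m
*relative to two years earlier* for `eq_window` = 10 consecutive
years. The two-year lag makes detection period-aware: under sustained
transmission the SIS process alternates cohorts between infected and
susceptible years, so the attractor is generically a period-two orbit
(of which a fixed point is the special case), and a one-year test
would never terminate. Runs that hit `max_steps` (1e5) are flagged
`converged = FALSE` but still classified from their final state.

**Outcome classification.** An owner survives while holding more than
`landless_eps`·m land. The run is labelled *equity* if at least
`equity_fraction`·n owners survive, otherwise *latifundia* — the
published dichotomy shows a single owner "or a few" absorbing the
land, so the boundary is configurable rather than hard-coded at one
survivor.

## The two-owner analysis

With purchasing powers frozen (`two_owner_steady_state()`), the
trade-plus-land-use system is linear and its long-run shares are the
dominant eigenvector of a 6×6 map (the unit tests verify the iterative
result against exactly that eigenvector). Equal shares occur only at
$P_i = 0.5$; the share is monotone in $P_i$; and $P_i = 1$ hands all
land to owner $i$. The pooled mechanism coincides with the pairwise
trade rates $t_{ij} = (1-P_i)P_j$ when $P_i + P_j = 1$, so a single
implementation serves both.

With *dynamic* purchasing power the initial advantage matters — but
what kind of advantage is decisive. An advantage in utilities held *at
the stationary land-use mix* (i.e. a wealth advantage) is
self-reinforcing: the richer owner's share is non-decreasing every
year and tends to one (checked for 100 random unequal endowments, and
for several utility orderings). An advantage that comes purely from
land-use *composition* at equal totals need not persist: with
$c > b > a$ the utility-richer owner is empty-land-heavy and is
therefore a net seller in the very first year, and in simulations the
initially utility-richer owner frequently ends up the loser. We
regard the persistent-takeover statement as a statement about wealth
advantages and test it as such.

## What the simulations show, and their limits

Two stability facts organise everything the simulator does (both are
reproducible from `landuse_matrix()` plus a few lines of linear
algebra; the package's tests exercise their consequences rather than
the Jacobians themselves):

* The perfect-equity state is *weakly unstable* under the complement
  rule: at `n = 64` the leading growth factor is about 1.005 per year
  for every rate combination and utility ordering we examined. A
  perfectly symmetric population therefore stays symmetric forever
  (the dynamics are deterministic between infection draws), but any
  asymmetry — from a random initial landscape or from stochastic
  infection histories — is amplified until one or two owners hold
  everything. Random-start runs at the reference scale accordingly end
  in latifundia, and the equity outcomes of this model are the
  symmetric and near-symmetric ones: the disease-free control from an
  equitable start, protected sub-populations that start equal and stay
  so, and seed-paired comparisons of how *fast* concentration runs.
* Disease converts symmetry into asymmetry. Infected owners with
  discounted utility dump their empty land and cannot buy; protected
  owners purchase every year. From a perfectly equitable start with
  $R_0 = 2$ and $h = 0$, the unprotected fraction is dispossessed
  within decades while the protected owners — identical among
  themselves, hence un-concentratable — all survive: the final
  proportion of landowners equals the protected proportion
  (13/64 = 20.3% with 20% protected). With no protection and a random
  start, the same disease invariably accelerates full concentration.

The synthetic landscapes are the model's own study conditions, not an
emulation of mapped data: equal per-owner totals with uniformly random
composition (two uses drawn from Uniform(0, 2m/3), the third the
remainder, the remainder state rotated randomly). Real tenure systems
start unequal, have indivisible parcels, spatial adjacency,
inheritance and prices; none of that is represented, so passing tests
say nothing about such mechanisms — they validate the internal logic
of this null model only.

## Numerical choices

* Expected flows, not per-parcel coin flips: parcels are continuous
  and rates act as proportions, which makes equilibrium detection
  well-defined and conservation exact to floating precision
  (tolerances 1e-9 on E-land in trade, 1e-6·n·m along trajectories).
* Degenerate inputs: all-zero utilities fall back to uniform
  purchasing power; negative holdings raise a state error rather than
  propagating.
* Reproducibility: one root seed; replicate `k` derives a 32-bit child
  seed arithmetically (no global RNG involved), the initial landscape
  and protected set are drawn from it, and the infection process uses
  a second stream derived from the child seed — so disease-free and
  `h = 1` runs see bitwise-identical landscapes.
* Problem sizes: the shipped tests and the acceptance script run the
  reference 64×64 system with 20 replicates per scenario and reduced
  sweep grids (the sweep drivers take `reps = 100` and full grids for
  publication-scale runs); a 64×64 replicate converges in a few
  hundred simulated years and a few hundredths of a second.

## Known limitations

* The equity/latifundia probability surfaces over size, utility
  ordering and rates are degenerate at the reference scale under this
  implementation (equity probability ≈ 0 from random starts), because
  equity is weakly unstable everywhere; the sweep drivers faithfully
  report what the dynamics do rather than reproducing published
  contour shapes.
* The mean/median sale rules are implemented as hard
  below-threshold indicators (sell all empty land when below), the
  simplest reading of decision-by-average-assets; they are switches on
  `land_params()`, not separately calibrated mechanisms.
* `h` values for the intermediate discount regime are a free list
  (defaults 0.1 and 0.5 in `disease_experiment()`); no canonical set
  exists.
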