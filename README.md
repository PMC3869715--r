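# latifundia

Land tenure inequality has recurred across history as *latifundia*:
landscapes in which ownership ends up concentrated in one or a few
hands. `latifundia` implements a null model of how that happens, for
quantitative social-ecological modellers and epidemiologists: a fixed
landscape of `n × m` continuous parcels, divided equally among `n`
owners, in which parcels cycle through land uses, owners trade the land
that is between uses, and an infectious disease can sap the
productivity of whoever is sick.

## The model

Each owner's holdings sit in three states — forest `x`, agriculture
`y`, and post-agricultural "empty" land `z` — moved by a yearly Markov
chain with deforestation rate `r` (F→A), degradation rate `η` (A→E)
and recovery rate `μ` (E→F by default):

    x' = (1−r)x + μz,   y' = rx + (1−η)y,   z' = ηy + (1−μ)z.

Trade is pre-capitalist (no capital, credit or prices) and restricted
to empty land. With per-parcel utilities `a`, `b`, `c` for the three
states, owner *i*'s utility is `U_i = a·x_i + b·y_i + c·z_i`,
purchasing power is the utility share `P_i = U_i / ΣU_j`, and sale
pressure its complement `V_i = 1 − P_i` (mean- and median-threshold
rules are also available). All empty land under sale pressure is
pooled, `T = Σ V_j z_j`, and redistributed by purchasing power:

    z_i' = (1 − V_i) z_i + P_i T.

Disease is a frequency-dependent SIS process: with `κ` owners infected
last year, each exposable owner is infected this year with probability
`λ = min(1, R₀ κ / n)`; infection lasts one year (with a one-year
refractory period after recovery) and multiplies the sick owner's
utility by a discount `h ∈ [0, 1]`. Runs iterate to a steady state and
are classified as **equity** (most owners keep land) or **latifundia**
(ownership collapses onto one or a few owners).

## Worked example

Endemic disease (`R₀ = 2`) with full discount of sick owners' utility
(`h = 0`) introduced into a perfectly equitable 64 × 64 landscape in
which a fifth of owners are protected from infection:

```r
library(latifundia)

cfg <- sim_config(n = 64, m = 64, seed = 1, reps = 5, init = "equal",
                  disease = disease_params(r0 = 2, h = 0, protected_frac = 0.2))
reps <- run_replicates(cfg)
reps
#> # A tibble: 5 × 7
#>   replicate converged steps owners_initial owners_final ratio outcome
#>       <int> <lgl>     <int>          <int>        <int> <dbl> <chr>
#> 1         1 TRUE        155             64           13 0.203 latifundia
#> 2         2 TRUE        145             64           13 0.203 latifundia
#> 3         3 TRUE        157             64           13 0.203 latifundia
#> 4         4 TRUE        149             64           13 0.203 latifundia
#> 5         5 TRUE        150             64           13 0.203 latifundia
100 * mean(reps$ratio)
#> [1] 20.3125
```

Every replicate reaches a steady state within ~150 simulated years in
which exactly the 13 protected owners (`⌈0.2 · 64⌉`) still hold land:
the surviving fraction equals the protected fraction, 20.3%. The
unprotected owners, whose utility vanishes in every infected year, sell
their empty land under full pressure and cannot buy it back, so their
holdings decay below the landless threshold.

The two-owner analysis with frozen purchasing power shows why equity is
knife-edged — equal steady-state land shares occur only at
`P_i = 0.5`, and any fixed imbalance tilts the landscape:

```r
two_owner_steady_state(0.75)
#> # A tibble: 2 × 2
#>   owner share
#>   <chr> <dbl>
#> 1 i     0.900
#> 2 j     0.100
```

Sweep drivers (`sweep_size_utilities()`, `sweep_transition_rates()`,
`disease_experiment()`) run seed-paired Monte-Carlo grids over system
size, utility orderings, transition rates and disease scenarios, and
return tidy tables with `autoplot()` methods. A thin command-line
front end with the same capabilities ships in `inst/cli/latifundia.R`.
See the vignette (`vignettes/latifundia-model.Rmd`) for the model's
assumptions, numerical choices and limitations.

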