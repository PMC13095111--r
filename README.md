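# cxsteer

Rule-based construction, fitting and simulation of insect central-complex
steering circuits.

## The science

Insects keep course by comparing an internal compass (head-direction cells
whose firing peaks at a preferred azimuth) against an internal goal
direction. In the central complex these two population codes converge on
left and right steering populations; the difference between the summed left
and right steering activity is the turn command. `cxsteer` implements a
firing-rate model of this motif and a small set of geometric construction
rules that predict whether a given wiring diagram can steer:

1. **Compass directions must form a positive basis** — the preferred
   directions, taken as unit vectors, must surround the origin (every
   adjacent gap strictly below 180°). Otherwise some headings are
   indistinguishable and steering acquires spurious stable points.
2. Each steering neuron inherits a direction: the weighted circular sum of
   the compass directions it samples (descriptive).
3. Each goal neuron acts through the left and right steering neurons it
   innervates (descriptive).
4. **Declared goal directions must agree with the wiring-implied ones** —
   the direction a goal neuron claims to represent must match the direction
   its downstream steering pair actually pushes the animal toward.
5. **The inferred goal directions must themselves form a positive basis**,
   so every goal azimuth is reachable.

The package builds circuits that follow the rules (uniform `N`-column
circuits; a fly model with 12 FC2 goal neurons on a 30° lattice and 2×12
PFL3 steering neurons on a 45° lattice with a measured softplus
activation), circuits that deliberately break single rules, and an
"unintuitive" sparse 4-compass/5-steering/3-goal circuit whose 19 free
parameters are found by differential evolution so that its steering surface
matches the fly model's. Closed-loop simulation protocols (von Mises
random-walk goal, smooth 0→360→0 turn, step changes) expose the behavioural
signature of each broken rule.

## Quick start

```r
library(cxsteer)

u <- build_uniform(3)
u
#> <circuit_spec> sigmoid-rate  (builder: uniform )
#>   3 compass, 3 goal, 3 left + 3 right steering neurons
#>   compass PFDs: 0, 120, 240
#>   goal dirs ( inferred ): 60, 180, 300
#>   gain k = 1 , balance = 0.5
```

Goal directions are not free labels: they are inferred from the wiring by
the directed-midpoint construction (rule 4 checks declared labels against
these):

```r
infer_goal_directions(u)
#> # A tibble: 3 × 7
#>   goal_neuron gl_deg gr_deg      u     v signed_angle_deg eta_deg
#>         <int>  <dbl>  <dbl>  <dbl> <dbl>            <dbl>   <dbl>
#> 1           1      0    120 -0.5   0.866              120      60
#> 2           2    120    240 -0.5   0.866              120     180
#> 3           3    240      0 -0.500 0.866              120     300
```

Rule conformance is a single call; here for a circuit whose goal wiring was
rerouted so all inferred directions crowd into one half-plane:

```r
rule_check(build_rule_breaker("rule5"))
#> Rule-check report (circuit: rule_breaker_rule5 )
#>   rule 1 (compass positive basis):     PASS (max gap 120 deg)
#>   rule 2 (steering directions):        described, 6 steering neurons
#>   rule 3 (goal-steering innervation):  described, 3 goal neurons
#>   rule 4 (declared vs inferred dirs):  PASS (max |diff| 0 deg, tol 20)
#>   rule 5 (goal-dir positive basis):    FAIL (max gap 315 deg)
#>   inferred goal directions: 60, 90, 105
```

Closed-loop simulation, with the gain tuned so every circuit steers at a
comparable 50–60 °/s peak rate:

```r
u <- tune_gain(u)
traj <- run_closed_loop(u, step_change_goal(step_deg = 90, hold = 5, n_cycles = 1))
glance(traj)
#> # A tibble: 1 × 5
#>       n duration_s angular_rmse_deg final_abs_err_deg peak_rate_deg_per_s
#>   <int>      <dbl>            <dbl>             <dbl>               <dbl>
#> 1  1000       9.99             23.4              3.11                55.0
```

The fly circuit passes all prescriptive rules; note the real 15° offset
between its anatomical goal-neuron labels and the wiring-implied directions
(duplicated steering tunings serve neighbouring goal columns):

```r
tidy(rule_check(build_fly()))
#> # A tibble: 5 × 4
#>   rule  prescriptive pass  detail
#>   <chr> <lgl>        <lgl> <chr>
#> 1 rule1 TRUE         TRUE  compass max gap 45 deg
#> 2 rule2 FALSE        NA    24 steering-neuron directions
#> 3 rule3 FALSE        NA    12 goal-neuron innervation sets
#> 4 rule4 TRUE         TRUE  max declared-inferred |diff| 15 deg (tol 20)
#> 5 rule5 TRUE         TRUE  goal-dir max gap 45 deg
```

Fitting the sparse unintuitive circuit against the fly steering surface
(seeded, deterministic; ~20 s):

```r
fit <- fit_unintuitive(config = fit_config(seed = 42))
glance(fit)          # rmse, convergence, optimiser settings
rule_check(fit$spec) # fitted circuit passes rules 1, 4 and 5
```

Surfaces and trajectories plot via `ggplot2::autoplot()`:

```r
autoplot(steering_surface(build_fly()))
autoplot(traj)
```

## Command line

A thin `steer` CLI wraps the same functions:

```sh
STEER=$(Rscript -e 'cat(system.file("cli", "steer.R", package = "cxsteer"))')
Rscript "$STEER" build --type uniform --n 5 --out circuit.json
Rscript "$STEER" check --circuit circuit.json
Rscript "$STEER" surface --circuit circuit.json --grid 72 --out surface.csv
Rscript "$STEER" fit --seed 1 --out fitted.json
Rscript "$STEER" simulate --circuit circuit.json --protocol random-walk --seed 1 --out traj.csv
```

`check` exits non-zero naming the failing prescriptive rule(s); every
file-producing subcommand echoes its parameters to `<out>.log`; all runs are
deterministic given `--seed`.

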