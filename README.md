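# assemblytime

Stochastic kinetics and time complexity of heterogeneous self-assembly.

How long does it take `N` copies of each of `S` distinct building blocks to
self-assemble into `N` complete target structures — and how does that time
scale with the structure size? `assemblytime` is for researchers in
biological and artificial self-assembly (DNA bricks, capsids,
macromolecular complexes) who want to compare *control strategies* for
avoiding kinetic traps: the dead-end state in which too many partial
structures nucleate and starve each other of parts.

The model is nucleation-and-growth chemistry in a well-mixed volume. The
target is a 1D ring, 2D sheet or 3D cube of `S = L^d` sites, one dedicated
species per site, with binding only between lattice neighbours:

* dimerization of two compatible monomers at rate `mu` (nucleation),
* growth by single-monomer attachment at rate `nu` per bond formed,
* detachment of an `n`-bond member at `delta_n = A e^{-n E_B}`,
  `A = 1e18 C nu` (irreversible when `E_B = Inf`),
* optional supply control: constant influx at rate `N alpha` per species,
  or scheduled batches.

Four canonical scenarios control the assembly — reversible binding (`E_B`),
a dimerization barrier (`mu/nu`), activation/influx (`alpha`), and
just-in-sequence supply (batch spacing `delta_T` with an onion-shell
supply order and an optional nonstoichiometric `0.9N -> 1.1N` ramp). For
each, the package measures `T90` (the time to 90% yield), finds the
optimal control value, and fits the power laws

```
T90min ~ S^theta        (time complexity exponent theta)
control_opt ~ S^-phi    (control parameter exponent phi)
```

The exact stochastic simulation runs in compiled code (Gillespie direct
method with integer propensity bookkeeping); a species-symmetric
Becker–Döring-type mean-field integrator provides an independent 1D
cross-check, including the closed form `T90 = 9/(mu C)` at `S = 2`.

## Worked example

```r
library(assemblytime)

ring <- build_geometry(1, 64)                 # 64-species ring
cfg  <- make_dimerization(ring, mu_over_nu = 64^-2, N = 1000)
run  <- run_simulation(cfg, seed = 1)
run
#> assembly trajectory: dimerization scenario, S = 64, N = 1000
#>   final yield 1.000 at t = 8.313e+04 (63000 events)
#>   T90 = 591.617
nucleation_growth_ratio(run)                  # ~1/S: slow-nucleation regime
#> [1] 0.01612903

sr <- scaling_experiment("dimerization", d = 1, sizes = c(16L, 32L, 64L, 128L),
                         N = 1000, n_replicates = 10L, seed = 101)
sr
#> scaling experiment: dimerization scenario, d = 1, S in {16, 32, 64, 128}
#>   theta = 1.028 +/- 0.007 (T90min ~ S^theta)
#>   phi   = 2.023 +/- 0.034 (optimal control ~ S^-phi)
```

Reading: with the dimerization rate tuned per size, the minimal assembly
time grows linearly with `S` (`theta ~ 1`) and the optimal nucleation rate
falls as `S^-2` (`phi ~ 2`) — dimerization control is the fastest of the
four scenarios in 1D, while reversible binding is the slowest
(`theta ~ 4`, diffusive cluster growth). A trajectory's
nucleation-to-attachment event ratio near `1/S` is the signature of
time-optimal assembly.

A thin command line sits over the same functions:

```sh
exec/assemblytime simulate --config run.yaml --seed 1 --out results/
exec/assemblytime scaling --scenario dimerization --d 1 --sizes 16,32,64,128
exec/assemblytime jis-plan --d 2 --L 5 --delta-T 3 --N 1000 --ramp linear
```

See the vignette `vignettes/time-complexity.Rmd` for the model, the
scenario definitions, numerical choices and the finite-size caveats of the
exponent estimates.

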