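# presas

Integrative deconvolution of conformational equilibria from paramagnetic
relaxation enhancement (PRE) and small-angle scattering (SAXS/SANS) data.

## The problem

Modular enzymes such as RNA-guided methyltransferases exchange in solution
between an active conformation, with the catalytic module docked on its
substrate, and inactive detached conformations. Neither crystallography nor
any single solution structure captures this: PRE data over-weight conformers
that bring a nitroxide spin label close to observed methyl groups, while
scattering curves report the population-weighted average shape. `presas` is
for structural biologists who want to turn that tension into numbers — the
fractional population of each state and the free-energy difference between
them — using ensembles of coarse or atomic conformers fitted jointly to PRE
and multi-contrast scattering data.

## The method

- **PRE quantification.** Methyl intensity ratios follow
  I_para/I_dia = exp(−Γ₂ t_HMQC) · R₂ᴴR₂ᴴᶜ / ((R₂ᴴ+Γ₂)(R₂ᴴᶜ+Γ₂));
  the map is inverted numerically (bisection, 1e-8) and Γ₂ converts to a
  distance via r = [K/Γ₂ · (4τ_C + 3τ_C/(1+ω²τ_C²))]^(1/6) with
  K = 1.23e-32 cm⁶ s⁻², errors propagated with a 10 % ratio-error floor and
  a 2 Å distance floor. τ_C is calibrated from PREs of known distance.
- **Scattering.** Debye-formula curves with per-subunit contrast weights
  (contrast-matched subunits drop out), Guinier fits iterated to the
  s·R_g ≤ 1.3 window, P(r) histograms, and χ² fitting with the analytically
  optimal scale c = Σ I_exp I_calc/σ² ÷ Σ I_calc²/σ².
- **Restraint partitioning.** Restraints violated by more than 10 Å in one
  state's structure set are removed from that state's list and kept in the
  other, iterated to a fixed point.
- **Ensemble selection.** A pseudo-genetic algorithm: 4 parent ensembles of
  2–10 conformers, 20 children of 3–10 conformers per iteration with a 30 %
  duplicate-or-replace mutation, scored by a consensus of min–max-normalized
  χ² over five scattering curves plus the PRE χ², with ⟨r⁻⁶⟩ fast-exchange
  averaging, two-tag summation and two-copy ratio averaging in the PRE
  back-calculation. Populations come from the top 3 ensembles of 3
  independent runs; member multiplicity is the population weight.
- **Thermodynamics.** ΔΔG = RT[ln(f_a/(1−f_a)) − ln(f_b/(1−f_b))] with
  first-order error propagation.

A synthetic two-site complex generator (`makeToyComplex()`) emulates the
full experimental design — five contrast schemes, three spin labels, 24
methyl reporters, a mobile module exchanging between a duplex-bound and
detached poses at a known on-state fraction — so the entire pipeline is
testable without downloads.

## Worked example

```r
library(presas)
toy <- makeToyComplex(toySpec(seed = 7, fOn = 0.66))   # truth: 66 % on
conf <- c(poolMembers(toy$onPool), poolMembers(toy$offPool))
sim <- simulateDatasets(conf, trueMixtureWeights(toy), toy$schemes, seed = 101)
res <- runSelection(list(on = toy$onPool, off = toy$offPool),
                    sim$sasData, schemes = toy$schemes, preData = sim$preData,
                    cfg = scoringConfig(nIterations = 120, seed = 101))
res$population
#> PopulationEstimate: f_on = 0.696 +/- 0.018 (n = 9)
```

The recovered on-state fraction (69.6 ± 1.8 % over the top-3 ensembles of 3
runs, truth 66 %) is the quantity of interest: the fraction of conformers
with the catalytic module docked. Converting two such populations into an
activation free-energy difference:

```r
ddgFromPopulations(0.66, 0.34, sdA = 0.08, sdB = 0.10, temperature = 328.15)$ddG
#> [1] 0.8650679
```

i.e. a 66 %/34 % population pair corresponds to a 0.87 kcal/mol difference
in the off→on transition free energy at 55 °C — small enough that modest
sequence changes can retune enzyme activity. A Guinier fit of the simulated
SAXS curve (`guinierFit(sim$sasData[[5]], sRgMax = 1.0)`) gives
R_g = 24.1 Å, matching the population-weighted model R_g.

There is also a thin CLI over the same functions:

```sh
Rscript exec/presas ddg --fa 0.66 --fb 0.34 --T 328.15
# ddG = 0.87 kcal/mol (quadrature +/- 0.00, linear +/- 0.00) at T = 328.15 K
Rscript exec/presas synth --out demo --seed 3 --n-on 3 --n-off 5
Rscript exec/presas guinier --curve demo/curves/SAXS.dat
```

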