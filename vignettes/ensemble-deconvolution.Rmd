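---
title: "Deconvolving conformational equilibria from PRE and small-angle scattering data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving conformational equilibria from PRE and small-angle scattering data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presas)
```

## The problem

Modular enzymes often exchange between conformations in solution — for
instance an RNA-guided methyltransferase whose catalytic module is either
docked on its substrate–guide duplex ("on") or detached ("off"). No single
structure reproduces all solution data for such a system: paramagnetic
relaxation enhancement (PRE) reports strongly on conformers that bring a
spin label close to observed methyl groups, while small-angle X-ray and
neutron scattering (SAXS/SANS) report on the population-weighted average
shape. `presas` implements an integrative workflow that (i) turns PRE
intensity ratios into distance restraints, (ii) partitions restraints
between candidate states, (iii) selects mixed conformational ensembles
against PRE and scattering data simultaneously with a pseudo-genetic
consensus-scoring algorithm, and (iv) converts the resulting state
populations into free-energy differences.

## The PRE model

For methyl-detected HMQC spectra, the paramagnetic-to-diamagnetic
peak-height ratio of a methyl resonance follows

$$\frac{I_{para}}{I_{dia}} =
  e^{-\Gamma_2 t_{HMQC}}\,
  \frac{R_2^{diaH} R_2^{diaHC}}
       {(R_2^{diaH}+\Gamma_2)(R_2^{diaHC}+\Gamma_2)},$$

with $t_{HMQC}$ the transfer time (7.6 ms by default) and $R_2^{diaH}$,
$R_2^{diaHC}$ the diamagnetic single- and multiple-quantum relaxation
rates of that peak. The map is strictly decreasing in $\Gamma_2$ but not
analytically invertible; `gamma2FromRatio()` inverts it by bisection
(relative tolerance 1e-8) and propagates errors by re-inverting at the
corners of the error box, with a 10 % floor on the ratio error. The PRE
rate relates to the electron–proton distance through

$$r = \left[\frac{K}{\Gamma_2}
  \left(4\tau_C + \frac{3\tau_C}{1+\omega^2\tau_C^2}\right)\right]^{1/6},$$

evaluated in cgs units and reported in ångström. We use the standard
nitroxide–proton interaction constant $K = 1.23\times10^{-32}$
cm^6^ s^-2^. Note that this constant is sometimes quoted with a corrupted
exponent ($10^{-23}$) in the literature; that value is dimensionally
implausible (it would place typical PRE-active methyls at hundreds of
ångström), so the package defaults to $10^{-32}$ and leaves $K$
configurable.

The correlation time $\tau_C$ is calibrated from intra-domain PREs of
known distance (`calibrateTauC()`): the ratios are inverted to observed
$\Gamma_2$ (this step does not involve $\tau_C$) and $\tau_C$ is fitted
by weighted least squares, with a bootstrap spread over resampled
calibration pairs. This is a deliberate simplification of joint
tag-ensemble/$\tau_C$ optimizers: tag positions are held fixed during
calibration, and tag-conformation refinement is done separately
(`refineTags()`), after ensemble selection, where it cannot perturb the
scattering fit. The weighting scheme of the full joint optimizer is not
reproduced; the package's least-squares choice is documented here as its
own.

### Restraints

Measurements with a ratio below the observability threshold (0.8 by
default) become bounded restraints through the inversion chain; slacks
carry a 2 Å floor to absorb tag flexibility. A ratio near 1 places the
methyl beyond a detection-limit distance (default 25 Å, configurable —
the literature states no value; 25 Å corresponds to a PRE of a few
s^-1^ under the default parameters, i.e. at the edge of detectability).
Stereo-unassigned methyl pairs are grouped under an OR contract, and
satisfaction is evaluated on the PRE-physical effective distance
$(\sum_i r_i^{-6})^{-1/6}$. In calculations that allow one of two protein
copies to approach the tag ("on_off" mode) the lower slack is extended
by 4 Å, because the observed peak sums two copies of which only one may
be attenuated; this additive rule keeps the on_off lower bound at 4 Å or
more in every case.

### State partitioning

`partitionRestraints()` iterates the published rule: a restraint violated
by more than 10 Å in one state's structure set is removed from that
state's list but kept in the other. "Violated in a set of calculations"
is ambiguous; the default interpretation is conservative — violated in
*every* structure of that state (minimum violation over structures) — and
a `rule = "mean"` switch provides the laxer reading. With static pools the
procedure reaches a fixed point quickly and is idempotent; lists can only
shrink.

## The scattering model

Bead-model curves are computed with the Debye formula
$I(s) = \sum_{ij} w_i w_j \sin(s r_{ij})/(s r_{ij})$ with per-subunit
contrast weights, $s = 4\pi\sin\theta/\lambda$ in Å^-1^. Contrast-matched
subunits carry weight 0, mirroring SANS contrast matching at the solvent
match point. This forward model deliberately omits the hydration shell
and excluded-volume corrections of atomic-detail predictors; per-conformer
curves computed externally can be imported anywhere a curve library is
accepted, so real-data runs can use those programs' outputs unchanged.
Guinier fits (`guinierFit()`) iterate the $s\,R_g \le 1.3$ admissible
range to self-consistency (initial window $s \le 0.05$ Å^-1^, at most 20
rounds), weighting points by the inverse variance of $\ln I$. The 1.3
limit is the convention for globular particles; for strongly anisotropic
shapes (a dumbbell, or the elongated toy particle below) the systematic
underestimate at 1.3 reaches a few percent, and the exposed `sRgMax`
argument should be lowered to ~1.0 as is standard for such particles. $\chi^2$
fitting uses the analytically optimal scale factor
$c = \sum I_{exp}I_{calc}/\sigma^2 \big/ \sum I_{calc}^2/\sigma^2$,
so curve comparisons are invariant to the arbitrary units of the
calculated intensities; PRE ratios, being absolute, are compared with the
scale fixed to 1.

## Ensemble selection

Candidate ensembles are multisets of 2–10 conformers drawn from pools;
member multiplicity *is* the population weight (an optional non-negative
least-squares mixture mode exists, but multiplicity weighting is the
default because the algorithm's duplication move is only meaningful if
multiplicity encodes weight). Each iteration draws 20 child ensembles of
3–10 members from the merged four parents, each sub-sampling event
mutating with 30 % probability (duplicating a member or replacing one
with a pool conformer, with equal probability); all children are scored
and the best four seed the next generation. The parent-update rule is
not fully specified in the published description of this class of
algorithm; elitism (best children become parents) is the package's
choice, consistent with standard genetic-algorithm practice, and it
makes the archive-best consensus non-increasing by construction.

Scoring sums min–max-normalized $\chi^2$ terms: each of the five
scattering datasets is normalized over the ensembles seen so far in the
run, summed and renormalized into a single SAS fitness in [0, 1], and
added to the normalized PRE $\chi^2$ to give the consensus score.
Normalization is maintained with running minima/maxima across all
ensembles seen in a run, so scores remain comparable across iterations;
final rankings apply the final normalization to the whole archive. Ties
break deterministically by (score, smaller ensemble, lexicographic
member ids), and each run consumes a single seeded RNG stream, so fixed
seeds give bit-identical rankings.

PRE back-calculation for mixed ensembles assumes fast exchange:
$\langle r^{-6}\rangle$ is averaged over ensemble members
(population-weighted) and spin-label conformations (weighted), summed
over the tags contributing to a dataset; per-copy ratios from the
intensity-ratio model are averaged across symmetry-equivalent copies
before comparison. Whether each parent should draw from one pool or all
pools is also ambiguous in the published description; the default draws
from all pools (a flagged alternative restricts parents per pool), which
lets the population split emerge purely from the data.

The on-state population is reported as the mean fraction of on-tagged
members over the top three ensembles of three independent runs, with
their SD as the spread. Populations convert to free energies via
$\Delta\Delta G = RT[\ln(f_a/(1-f_a)) - \ln(f_b/(1-f_b))]$
(`ddgFromPopulations()`). The measurement temperature default is
328.15 K (55 °C); uncertainty is propagated to first order and reported
both in quadrature and as the linear sum, because neither rule is
canonical for SDs estimated from top-ensemble spreads — the two bracket
the plausible range, and the package asserts neither.

## The synthetic study system

`makeToyComplex()` builds a ~160-bead mono-RNP-like particle: a rigid
elongated scaffold (45 beads), a small partner subunit (20), a
substrate–guide duplex (30), a statically detached second catalytic copy
(30 — the half-loaded complex always has one copy off), and one mobile
catalytic module (36 beads) that either sits on the duplex site or
samples clash-free tethered poses (uniform rotation, uniform translation
in a 40 Å tether sphere, 3 Å clash threshold, centroid excluded from a
15 Å neighbourhood of the on pose so the states are geometrically
distinct). Three spin labels sit on the rigid body; the duplex-adjacent
one reports specifically on the on state, emulating the tag whose PREs
discriminate the states in the real system. Five contrast schemes mimic
a SANS campaign plus SAXS; the scaffold schemes carry fractional
contrast on the catalytic copies because, in the system emulated, the
deuterated scaffold protein includes the lobe that rides with the
catalytic module — a bead model without a separate lobe approximates
that with a partial module weight.

Simulated data use the package's own forward models plus Gaussian noise
(2 % relative on SAS, 0.05 absolute on PRE ratios, with the 10 % error
floor applied to the reported errors). The ground truth is a small
discrete mixture (by default the on fraction spread over 3 on poses and
the remainder over 4 off poses). What passing tests show, therefore, is
that the selection machinery recovers populations when the forward
models are exact and the truth is representable in the pools; real data
add model error (hydration shells, flexible loops re-sampled during
structure calculation, imperfect tag models) that the toy does not
emulate, and the mobile module here moves as a rigid body, so loop
entropy is not represented.

## Problem sizes and numerical choices

The packaged study conditions are scaled so a full analysis runs on a
single CPU in minutes: pools of 10 on + 40 off poses, 48-point curves,
72 PRE measurements (24 methyls × 3 tags), 120 selection iterations ×
3 runs. The same engine accepts the published-scale setup (pools of
thousands, 250 iterations) unchanged. Degenerate inputs are handled
explicitly: all-equal score sets normalize to 0; ratios above 1 (noise)
give a zero PRE rate with an error-model upper bound; a zero total
scattering weight, an empty pool, an unresolvable site or a missing
member curve raise errors naming the offender. The consensus-score
comparison between mixed-pool and single-state-pool runs uses raw summed
$\chi^2$, because normalized consensus values are only comparable within
one scoring population.

## A worked example

```{r example, eval = FALSE}
toy <- makeToyComplex(toySpec(seed = 7, fOn = 0.66))
conf <- c(poolMembers(toy$onPool), poolMembers(toy$offPool))
sim <- simulateDatasets(conf, trueMixtureWeights(toy), toy$schemes,
                        seed = 101)
res <- runSelection(list(on = toy$onPool, off = toy$offPool),
                    sim$sasData, schemes = toy$schemes,
                    preData = sim$preData,
                    cfg = scoringConfig(nIterations = 120, seed = 101))
res$population      # recovered on-state fraction +/- SD
```

## Known limitations

- The Debye forward model has no hydration shell or excluded volume;
  absolute intensities are arbitrary (the optimal scale absorbs this).
- Mobile modules move rigidly; internal flexibility must be represented
  by pool diversity.
- Restraint partitioning assumes the caller supplies per-state structure
  pools; re-calculating structures between iterations is outside the
  package's scope.
- Population spreads from top-ensemble SDs are heuristic, which is why
  both error-propagation rules are reported for the free-energy
  difference.
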