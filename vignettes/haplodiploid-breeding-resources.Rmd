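---
title: "Models and methods behind hapbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hapbreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapbreed)
```

`hapbreed` supports the quantitative design of three laboratory breeding
resources in haplodiploids — inbred-line panels, controlled-cross outbred
populations, and serial-transfer experimental-evolution regimes. This
vignette documents the models, their assumptions, the tunable parameters and
the numerical choices, in enough detail that a user can judge what the
package's guarantees do and do not cover.

## The sib-mating cross-type chain

In a haplodiploid, a line founded by a single mated female can carry at most
three distinct alleles per locus: two from the female, one from her (haploid)
mate. Classifying a mated pair by the female's zygosity and allele sharing
with her mate gives four cross types — A (\[xy\]×\[z\]), B (\[xy\]×\[x\]),
C (\[xx\]×\[y\]) and D (\[xx\]×\[x\]) — and random sib-mating maps their
frequencies forward as

$$A' = \tfrac{A}{2},\qquad B' = \tfrac{A}{2} + \tfrac{B}{2} + C,\qquad
  C' = \tfrac{B}{4},\qquad D' = \tfrac{B}{4} + D.$$

Each coefficient follows from enumerating the brood of the corresponding
cross and the sib-pairs it can form; type D is absorbing, so the chain
converges to full inbreeding. The inbreeding coefficient is $f = C + D$ (the
female's two alleles are identical by descent exactly when she stems from a
homozygous mother's cross) and $D$ itself is the probability the line is
already fully inbred at the locus.

Assumptions worth stating explicitly:

* **Single locus, no selection.** The chain tracks one neutral locus;
  genotypes do not affect survival or fecundity. Inbreeding depression —
  conspicuous in real line creation — is deliberately outside the model; its
  demographic effect is handled separately by the attrition model below.
* **Single father.** All of a female's offspring share one sire (first-male
  sperm precedence). Species with mixed paternity need a different founding
  scheme (isolating virgins) and are not modelled.
* **Random sib-mating.** The next generation's pair is a uniform draw over
  the brood's daughter × son combinations.

The default initial state is the most-heterozygotic founding cross
($A_0 = 1$). When the founder's genotype is unknown this is the conservative
choice: any other initial distribution only accelerates inbreeding.
Arbitrary valid initial distributions are accepted for users who know their
founders' genotypes.

### Two computations of *f*, and their index alignment

`direct_f_recurrence()` implements the alternative recursion
$f_t = \tfrac14 + \tfrac14 f_{t-2} + \tfrac12 f_{t-1}$ with
$f_1 = f_2 = 0$: with probability 1/2 both of a female's alleles descend
from her grandmother (then IBD with probability $\tfrac12 + \tfrac12
f_{t-2}$), and with probability 1/2 one allele comes from the grandfather
(IBD with probability $f_{t-1}$). The two methods give the same sequence,
but their natural indexings differ by one: the recurrence value at index
$t+1$ equals the chain value at generation $t$. The package treats the chain
indexing — generation $t$ = $t$ completed sib-mating generations since the
founding cross — as canonical, because only that convention yields
$f = 95.1\%$ *after 15 generations*; the recurrence output is reported with
its own indices and the shift is documented here and in the function help.

### Exact arithmetic

Every chain update is a halving or quartering, so from any dyadic starting
point all frequencies remain dyadic rationals. Exact mode stores integer
numerators over a common power-of-two denominator, reduces after each step,
and verifies numerators stay below $2^{53}$ (the exact-integer range of a
double), failing loudly rather than silently rounding. Initial frequencies
must have denominator at most $2^{32}$ to enter exact mode — a deliberate
cap, since every floating-point number is technically dyadic and admitting,
say, `1/3`'s 54-bit approximation would exhaust the headroom immediately.
From $A_0 = 1$ this supports ~50 generations, far beyond any practical
sib-mating horizon; floating mode (plain doubles) is available past that.
Display convention: percentages are rounded to one decimal; stored values
keep full precision.

## Gene dropping

`estimate_inbreeding_mc()` is the stochastic counterpart of the chain and
exists chiefly as its independent verification: it simulates allele
transmission (one uniformly chosen maternal allele per offspring, plus the
paternal allele for daughters) through many replicate lines and reports
per-generation cross-type frequencies, $\hat f$ and the type-D proportion
with binomial standard errors. Design choices:

* **Line-major random streams.** All uniforms are drawn up front in
  line-major order from the single seed, so the simulation is vectorised
  across lines yet enlarging `n_lines` under the same seed leaves existing
  lines' trajectories bit-for-bit unchanged. This makes spot-checks and
  incremental runs reproducible.
* **Loci are unlinked** and segregate independently; the focal locus (the
  first) feeds the headline estimates, and per-locus summaries let
  exchangeability be checked. A genome-wide "fully inbred at all simulated
  loci" proportion is reported as a clearly separate quantity: the analytic
  $D_t$ is per-locus, and the genome-wide figure assumes independence across
  the simulated loci, which real linkage would violate.
* The individual-based functions (`found_line()`, `produce_offspring()`,
  `advance_line()`, `simulate_pedigree()`) implement the identical
  transmission model at pedigree scale, with explicit arrhenotoky
  constraints (sons reject a father; ploidy is validated), and write a
  TSV pedigree dialect in which females carry `x/z`-style diploid genotypes
  and males a single allele — standard two-parent pedigree formats cannot
  encode fatherless haploid males unambiguously.

What the simulator does *not* emulate: brood-size demography, viability
differences among genotypes, linkage, or mutation. Agreement between the
simulator and the chain therefore validates the transmission algebra, not
any claim about real mite colonies.

## Line-panel attrition

Real line creation loses lines — female death, null fecundity, failed
hatching, single-sex broods. The protocol buffers this by keeping 3
replicate patches per line per generation while continuing each line from a
single patch (so replication is survival insurance, not genetic branching —
the model keeps these separate on purpose). `simulate_line_panel()` draws
independent replicate failures with a constant marginal probability $q$ per
replicate per generation; a line dies only when all replicates fail, i.e.
with probability $q^r$. The per-cause decomposition is cosmetic (causes are
attributed to failed replicates in proportion to supplied rates) because
per-cause rates are rarely known; only their sum matters dynamically.

Since per-generation loss counts are generally not recorded, the model is
calibrated from endpoints: `calibrate_failure_prob()` inverts
$(1 - q^r)^g = S/N$ by bounded root-finding (the left side is strictly
decreasing in $q$, so the root is unique; tolerance $10^{-10}$). The default
panel configuration — 450 founded lines, 15 generations, 3 replicates — is
the inbred-line protocol itself; with the endpoint 59 surviving lines this
gives $q \approx 0.502$. A constant, independent failure rate is the
simplest model consistent with endpoint data; real attrition is likely
front-loaded (maladapted genotypes purge early), so the simulated trajectory
shape should not be over-interpreted between its calibrated endpoints.

## Crossing designs for outbred populations

Because hybrid males must be bred from virgin hybrid females (unfertilized
eggs), building a *fully* hybrid population is a scheduling problem. Two
designs are supported — exactly the two with a defined protocol; other
population counts are refused at validation rather than extrapolated:

* **Matched pairs, 4 populations**: reciprocal parental crosses within two
  fixed pairs, then reciprocal hybrid × hybrid crosses across pairs; 8
  fully hybrid combinations.
* **Round robin, 3 populations**: reciprocal parental crosses among all
  pairs; each F1 hybrid female is mated to males from the population absent
  from her parental cross; 6 combinations. This is the enumeration
  consistent with six distinct combinations and balanced representation.

Combination labels record maternal lineage first: the female offspring of an
AB mother and a CD-derived father is ABCD, so a combination's first letter
is its mitochondrial origin. (The letter-order semantics are a package
convention, documented because label strings alone do not define them.)
Both designs give each founder exactly two combinations as mitochondrial
root, which `mito_representation()` verifies.

`build_schedule()` expands a design into generation blocks and
`validate_schedule()` checks realizability: every hybrid male used at block
$g$ must descend from a virgin female isolated at block $g-1$, every hybrid
female used must come from a cross at block $g-1$, and synchrony is achieved
by repeating each set of matings one generation later (hybrid females of the
repeat meet hybrid males bred from the first round). Founder-population
individuals come from stock and are always available. The terminal block
pools every combination; `founding_census()` then applies the
equal-representation rule — found with the *minimum* count available across
combinations, so no population is overrepresented — or passes counts through
unchanged (`"as-available"`, the pragmatic choice when one sex is too scarce
to equalize). Hybrid incompatibilities (e.g. hybrid breakdown of one
population) are handled by the user excluding that population up front;
the package does not model incompatibility outcomes.

## Effective generations of selection

Serial-transfer experimental evolution keeps census size constant (220
females per transfer by default — enough that >200 survive transfer
mortality) by topping up from, in priority order, the current box, the
previous generation's backup box, and the unselected base population
(`plan_transfer()`, greedy, base treated as inexhaustible). Because migrants
have experienced fewer generations of selection, replicates accumulate
selection at different effective rates, summarised by the transfer-weighted
mean

$$\mathrm{Gen}_{t+1} = 1 + \frac{N_t\,\mathrm{Gen}_t +
  N_{t-1}\,\mathrm{Gen}_{t-1} + N_0 \cdot 0}{N_\mathrm{total}}.$$

Values are kept fractional. Conventions: the backup box's value is the
regime's value one transfer before the current box's (it *is* the previous
generation's box, left until the next transfer); the base population is
unlimited and pinned at 0 generations (it is not adapting to the new
environment); only a one-step backup is supported; and transfer mortality is
not modelled — the user supplies realized availabilities.

One bound deserves care. Under uninterrupted operation the value gains at
most one per transfer ($\mathrm{Gen}_{t+1} \le \mathrm{Gen}_t + 1$, with
equality exactly under full continuation). But the formula is a weighted
mean over *sources*, so the universally valid bound is
$\mathrm{Gen}_{t+1} \le 1 + \max(\mathrm{Gen}_t, \mathrm{Gen}_{t-1})$: if a
current box crashes (its value resetting towards 1 via base sourcing) while
the older backup survives with a higher value, the next transfer can raise
the value by more than one. The property tests assert the sharp bound; the
familiar one is asserted where its premise (backup never ahead of current)
holds.

## Run configurations and reproducibility

The five pipelines share a YAML run-configuration layer (`load_config()`,
`dispatch_run()`) and a thin command-line script (`exec/hapbreed.R`).
Defaults are the protocol's own values: 15-generation horizon, 450-line
panel with 3 replicates, 220-female transfers, 200 crosses per type.
Unknown keys are rejected so typos fail loudly. Every stochastic run records
its seed, and identical configuration plus seed yields byte-identical data
artifacts; the run report is the single exception, as it carries a
timestamp, which is why the timestamp lives there and not in any artifact.

## Problem sizes used in the tests

The suite verifies the chain against an independent matrix-power oracle over
40 generations, method equivalence over 35, and the Monte-Carlo components
at sizes chosen so the binomial 3-standard-error bands are well behaved:
20,000 lines over generations 1–10 for the per-generation frequency-vector
check (all expected cell counts ≥ ~20), 200,000 lines for the generation-15
endpoint check, and 10,000 replicate panels for the calibrated-attrition
endpoint. Monte-Carlo assertions use fixed seeds and 3-SE bands throughout;
with those bands a fully correct implementation still fails a given
assertion with probability ≈ 0.3% per comparison, which is the accepted
trade-off of seeded stochastic testing.

## Known limitations

* The chain and simulator are neutral single-line models: no selection,
  inbreeding depression, linkage or mutation.
* Attrition assumes a constant independent failure rate; only endpoint
  calibration is supported.
* Crossing designs generalize to exactly the two supported layouts;
  incompatibility screening is the user's responsibility.
* Effective-generation bookkeeping assumes a one-step backup at the regime's
  previous value and an unevolving base population.
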