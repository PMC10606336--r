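---
title: "Queueing, pooling and entropy: the models behind carenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queueing, pooling and entropy: the models behind carenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
```

carenet asks a hospital-design question quantitatively: given a set of care
units with uncertain demand, which units should be pooled, and how should
the reallocation of nurses between them be coordinated? The package answers
it with three instruments — a queueing-network model of the units, a daily
Monte-Carlo occupancy simulation, and information entropy applied to demand
and to the coordination structure itself. This vignette explains each model,
its assumptions, the parameters that matter, and the design decisions taken
where the methodology leaves choices open.

## The care system as a queueing network

Each unit *i* is an M/M/c station: Poisson external arrivals at rate
$\lambda_{0i}$ patients/day, exponential length of stay with mean
$1/\mu_i$ days, and $c_i$ staffed beds. Units are coupled by a routing
matrix $r_{ij}$, the probability that a patient leaving unit *i* continues
in unit *j*; row shortfalls $1-\sum_j r_{ij}$ are discharges home. The
effective arrival rate solves the traffic equations

$$\mathrm{Eff}\,\lambda_i \;=\; \lambda_{0i} + \sum_j \mathrm{Eff}\,\lambda_j\, r_{ji},$$

implemented as the linear system $(I-R^\top)\lambda = \lambda_0$, which has
a unique non-negative solution whenever the routing matrix's spectral
radius is below 1. Networks violating that (patients cycling forever) are
rejected with an error naming the offending cycle. Utilization is the
traffic formula $\rho_i = \mathrm{Eff}\,\lambda_i / (c_i \mu_i)$; values
above 1 are reported as-is, because overload is exactly what the redesign
analysis needs to see. We deliberately stop at $\rho$: closed-form M/M/c
waiting-time quantities (Erlang-C) are outside the package's scope because
the design comparison only uses utilization and expected occupancy.

## Pooling plans

A pooling plan partitions the unit ids into groups; `apply_pooling()`
builds the redesigned network with one unit per group. Beds, external
demand and nurses add up — pooling combines the capacity and the demand
associated with the members. Two quantities are not determined by that
principle alone, and here the package makes its own choices:

* **Pooled routing.** Transfer fractions out of a pooled group are the
  arrival-weighted average of the members' fractions,
  $r_{GH} = \sum_{i\in G} w_i \sum_{j \in H} r_{ij}$ with
  $w_i = \mathrm{Eff}\lambda_i / \sum_{G}\mathrm{Eff}\lambda_i$, and
  transfers inside a group are dropped (a move within a pooled unit is no
  longer a transfer). This is the unique merge that preserves every
  downstream unit's expected inflow. Users with re-measured post-merge
  fractions can pass a replacement matrix via the `routing` argument.
* **Pooled service rate.** The arrival-weighted harmonic mean of the
  members' rates, i.e. $\mu_G = \sum_G \mathrm{Eff}\lambda_g \big/
  \sum_G (\mathrm{Eff}\lambda_g/\mu_g)$, chosen so that the pooled
  expected occupancy $\sum_g \lambda_g/\mu_g$ is conserved: pooling
  redistributes workload, it does not create or destroy it.

Staffed beds are integers before pooling and integer sums after — never
averages. All computation runs at full precision; only the reporting layer
(`utilization_table(rounded = TRUE)`) rounds rates to one decimal and
utilization to whole percents.

## The daily occupancy simulation

`simulate_days()` runs the operational side of the comparison. For each of
`horizon_days` days (default 365, one planning year):

1. external arrivals per unit are drawn Poisson at the unit's external
   rate;
2. the day's draws propagate through the routing matrix to give effective
   arrivals $\mathrm{Eff}\lambda_{iS}$;
3. the day's expected occupancy is $U_{iS} = \rho_{iS} c_i =
   \mathrm{Eff}\lambda_{iS} / \mu_i$, and the unit is overutilized by
   $\max(U_{iS}-c_i, 0)$ beds or underutilized by the complement.

System-level over- and underutilization sum the positive parts across
units; a day with any overutilization is a day on which nurses must be
reallocated, and the count of such days is the headline mismatch statistic.
Over/under amounts stay fractional — no rounding to whole beds.

This is a rate-level Monte Carlo with analytic occupancy, not a
patient-level discrete-event simulation: lengths of stay, blocking and
transfer queues are not simulated, which keeps a year's run in
milliseconds and is faithful to the day-granular reallocation question.
Patient-level DES is a deliberate non-goal.

Two propagation modes exist for step 2. `"expected"` applies the traffic
equations to the day's draws, so each transfer stream is a deterministic
fraction of its upstream flow. `"sampled"` (the default) draws the day's
transfers as multinomial counts, so each transferred patient is a discrete
event. The default matters: under expected-value routing, a unit fed
purely by transfers (the post-intensive-care unit in the built-in fixture)
has a daily demand that is an exact scalar multiple of its upstream unit's
demand. Its overload days then coincide with the upstream unit's and the
pooling designs become nearly indistinguishable — the degeneracy defeats
the purpose of counting reallocation days. Sampled routing keeps the
transfer stream's own (binomial) variability, at identical expected flows.
Sampled mode requires a feed-forward network; cyclic routing falls back to
`"expected"` explicitly.

One further reproducibility device: a pooled unit remembers its members'
external rates as separate demand components, and the simulation draws each
component separately before summing. The sum of independent Poisson draws
is distributionally identical to one pooled draw, but component-wise
drawing means that under the same seed every pooling design faces the *same
realized demand stream* — comparisons between designs ("given the simulated
input data, how does the partition perform?") are then paired rather than
confounded by Monte-Carlo noise. `run_full_comparison()` relies on this by
simulating every model with the scenario's single seed. Identical seeds
give bit-identical results.

### The portfolio view

`census_correlation()` computes the Pearson correlation of units' daily
occupancy series, and `pooling_variance_gain()` the variance bookkeeping of
a plan: by
$\mathrm{Var}(\sum X_i) = \sum \mathrm{Var}X_i + 2\sum_{i<j}\mathrm{Cov}(X_i,X_j)$,
pooling negatively correlated demands yields a pooled variance below the
sum of the parts — the Markowitz-portfolio argument for combining wards
whose workloads do not peak together. Zero-variance series have no defined
correlation; these pairs are returned as `NA` with an `"undefined"` flag
instead of letting `NaN` propagate.

## Entropy measures

All entropies are Shannon entropies in bits (base-2 logarithm), with
$0\log_2 0 := 0$ by continuity. Distributions are validated to sum to 1
within $10^{-6}$. Three uncertainties are measured:

**Arrival entropy.** The relative demand $d_i =
\mathrm{Eff}\lambda_i/\sum_j \mathrm{Eff}\lambda_j$ is a distribution over
units; its entropy $H_{as}$ measures uncertainty about *where* demand
lands. The maximum, $\log_2 N$ at uniform demand, falls whenever units are
pooled — variety reduction is entropy reduction.

**Positional entropy.** Each patient class *k* has a distribution $P_{ki}$
over positions; its entropy $H_k$ sums over classes to $H_{ps}$, the
uncertainty about where patients are headed in the system.
`derive_position_matrix()` offers a canonical construction for
feed-forward networks — one class per external entry stream, with the
class's placement distribution equal to the entry unit's one-step routing,
plus a `"home"` pseudo-position for discharge mass. This construction is
the package's own: position-probability data are usually not published,
and users with real patient-class data should supply a `position_matrix()`
directly. The maximum variant uses the uniform distribution over each
class's declared support (its nonzero positions) rather than over all $N$
units, so a class that can only ever occupy two positions contributes at
most 1 bit.

**Decision-structure entropy.** A coordination design is a bipartite
structure: decision makers reading information sources with probabilities
$P_{ab}$. Its entropy $H_{ds} = \sum_a H_a$ proxies the information-
processing burden of running the design. Following the maximum-entropy
principle, the builders use uniform source distributions throughout — with
no empirical reading frequencies, assuming anything else would smuggle in
information. Three strategies are constructed from a network, its pooling
plan and its staffing:

* *hierarchy* — nurses → unit planners → one team manager per team → one
  manager. With aggregated information, nurse detail collapses to one
  workload signal per unit, read by the team managers (planners then
  contribute zero bits).
* *network* — one planner per unit, each reading all other units (their
  aggregate signals, or their individual nurses). With $A$ units and
  aggregation this is exactly $A\log_2(A-1)$ bits.
* *hub* — planners reading a centralized information system. Aggregated,
  each planner has a single source and the structure carries 0 bits;
  non-aggregated, each planner still chooses among its own unit's
  nurse-level records.

Nurse-level sources default to the day shift's counts (the shift is
selectable); a unit with zero nurses on the chosen shift contributes a
degenerate zero-bit planner with a warning. Pooled groups report to the
team manager named in the plan's `team_assignment`, defaulting to
neonatology — with the built-in fixture, that default is the only
assignment consistent with the reported hierarchy entropies across all
four candidate designs.

**Total entropy.** `total_entropy()` is the exact sum of the three
components. The summary convention used by `run_full_comparison()` adds
the *maximum* arrival and positional entropies to each strategy's decision
entropy, ranking designs by the uncertainty they would face with nothing
assumed about the demand distribution; the minimal-total row is flagged as
the recommended design. Because the arrival and positional components are
constant across strategies within a model, hub ≤ hierarchy ≤ network holds
within every model and aggregation level.

## The perinatology fixture

The built-in scenario is a five-unit newborn-flow system: delivery room
(O3, 6 beds, $\mu=1.0$), NICU (N1, 14 beds, $\mu=0.10$), post-IC (N2, 4
beds, $\mu=0.06$), high/medium care (N3, 11 beds, $\mu=0.19$) and nursery
ward (O1, 7 beds, $\mu=0.91$), with day/evening/night nurse rosters and
four candidate designs: the current partition and three poolings of the
downstream units (N3+O1, N2+N3, N2+O1).

Two rate variants are stored, and reports say which one they use.
The `"printed"` variant carries the reported per-unit effective rates
(4.0, 1.2, 0.2, 0.9, 2.7 patients/day) directly; it reproduces the
reported utilizations and the current configuration's arrival entropy of
1.9 bits (max $\log_2 5 = 2.32$). The `"derived"` variant carries the
observed entry streams (4.0 births/day; 0.6/day and 0.4/day external
admissions to NICU and HC/MC) and the transfer fractions (68.5% of births
to the nursery ward, 15.8% to the NICU, 15.7% to HC/MC; the NICU→post-IC
fraction $0.2/1.232 \approx 0.162$ implied by the post-IC inflow). The two
variants cannot be fully reconciled: the entry streams alone give the
HC/MC unit $0.4 + 0.157\times4 = 1.028$/day against the reported 0.9, and
the post-IC utilization computes to 83% from the reported inputs against a
reported 96% — the published figures were evidently produced from
unrounded source data that are not available. Both discrepancies are
documented and left as-is; "fixing" either would silently change the
model. For the same reason the reported positional entropies and the
non-aggregated decision entropies of the original study are not
reproduction targets: their class definitions and source enumerations are
not derivable from the published description, and the package's own
constructions (documented above) are used instead.

```{r fixture}
utilization_table(perinatology_network("printed"), rounded = TRUE)
```

## The synthetic-scenario generator

`generate_synthetic()` exists to exercise the portfolio claims without
historical census data. Unit parameters are drawn uniformly from the
spec's ranges (defaults: external rates 2–8/day, service rates 0.1–1/day,
4–20 beds — magnitudes matching mid-size ward practice). The daily demand
series per unit is independent Poisson noise plus a signed, mean-centred
common-mode component $s_i(C_t - \nu)$, $C_t \sim \mathrm{Poisson}(\nu)$,
whose intensity $\nu$ is calibrated by root-finding so the mean pairwise
correlation equals the target — exact in expectation, and empirically
within sampling error ($\pm 0.01$ at the default 10,000-day horizon).
Limitations to keep in mind: with more than two units and a negative
target, the $\pm$ loadings alternate, so only opposite-sign pairs are
negatively correlated; strongly negative targets can push individual days
below zero (the series is a mean-centred fluctuation, not a count); and
real hospital censuses carry weekday and seasonal structure that a
common-mode Poisson model does not emulate. Passing tests on synthetic
scenarios therefore validates the estimators' algebra and calibration, not
the realism of any particular hospital's demand process.

## Numerical choices and test scale

* Distribution validation tolerance $10^{-6}$; stability margin on the
  spectral radius $10^{-12}$; probability clipping only to absorb
  floating-point overshoot in sequential binomial thinning.
* Degenerate inputs have defined behaviour: single-unit networks give zero
  entropies, empty source lists contribute zero bits, all-zero arrival
  vectors are an error (no distribution to take entropy of).
* The test suite runs year-length (365-day) simulations for design
  comparisons, a 10,000-day run for the law-of-large-numbers check
  (sample mean occupancy within three standard errors of
  $\mathrm{Eff}\lambda_i/\mu_i$), and 20 seeds for the paired ordering of
  reallocation days across designs; entropy invariants (bounds, uniform
  maximum, permutation invariance, the grouping identity) are checked on
  100 random distributions.

## Known limitations

The occupancy model treats each day's sampled arrival rate as if sustained
in steady state ($U = \lambda/\mu$), so a single extra admission at a
long-stay unit swings the day's occupancy by a full $1/\mu$ beds; this
makes small-rate, long-stay units look spikier than a patient-level
simulation would. Nurse reallocation itself is not modelled — the package
counts the days coordination is needed and the information burden of the
coordination structure, not the reallocation policies. And the entropy
ranking is ordinal machinery: half a bit of decision entropy has no
clinical unit, it is a comparative measure between candidate designs
evaluated under identical conventions.
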