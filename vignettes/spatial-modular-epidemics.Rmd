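---
title: "SIR epidemics on spatial modular networks: model, theory and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIR epidemics on spatial modular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialsir)
```

## The model

`spatialsir` studies epidemic spreading in a country modelled as a
two-dimensional arrangement of cities. Nodes sit on a periodic
\(L \times L\) lattice partitioned into \(\zeta \times \zeta\) communities
(cities). Infection channels inside a city are dense and unstructured:
each community is wired internally as an Erdős–Rényi graph with mean
intra-degree \(K\), i.e. every node pair inside a community is linked
independently with probability \(K/(N_c-1)\), \(N_c = \zeta^2\).
Channels between cities are sparse and spatial: links exist only between
the four lattice-adjacent communities (periodic wrap, a torus). With mean
per-node inter-degree \(k_{inter}\), each community carries
\(Q = k_{inter}\zeta^2\) inter-links on average.

The number of links joining a given pair of adjacent communities follows
the binomial \(P_k(Q) = \binom{Q}{k} (1/4)^k (3/4)^{Q-k}\): each of a
community's \(Q\) inter-links picks one of its four neighbours uniformly.
The generator draws exactly this distribution per community-lattice edge
(its same-mean Poisson analogue when \(Q\) is not a whole number), with
uniformly chosen endpoint nodes; duplicate node pairs are discarded
(collision probability \(O(k_{inter}^2)\)). Two consequences worth
stating, because they fix conventions that are easy to get wrong by a
factor of two: a node's total inter-degree is then Poisson with mean
\(k_{inter}\) (not \(2k_{inter}\)), and a community's total incident
inter-link count averages to \(Q\) (not \(2Q\)). Both are checked by
tests against their binomial/Poisson bands.

Limits: \(\zeta \to L\) collapses the model to a single ER network (no
inter-links); \(\zeta \to 0\) approaches a regular lattice.

Dynamics are discrete-time SIR: one initially infected node; at each step
every infected node attempts to infect each susceptible neighbour
independently with probability \(\beta\), then recovers (recovery
probability 1). Newly infected nodes become infectious the next step.
This is the standard choice because the final recovered set is then
distributed exactly as the origin's reachable set under bond percolation
with bond probability \(\beta\) — the package verifies this equivalence
exhaustively on small graphs (`sir_reach_distribution_exhaustive()`
against Monte-Carlo runs of the same compiled kernel `run_sir()` uses).

## Two epidemic thresholds

The model has two transitions rather than one:

* a **local** threshold \(\beta_c^{ER} = 1/K\), above which an outbreak
  fills a finite fraction \(S\) of its origin city, with
  \(S = 1 - e^{-K\beta S}\) (`er_outbreak_size()` returns the epidemic
  root of this self-consistency equation, by bracketed root-finding on
  \([tol, 1]\); the trivial root \(S=0\) is returned when
  \(K\beta \le 1\));
* a **global** threshold \(\beta_c^{2D}\), above which infected cities
  percolate through the community lattice and the epidemic spans the
  country.

The global threshold comes from mapping city-to-city spread onto bond
percolation on the square lattice (bond threshold \(p_c = 1/2\)). A local
outbreak fails to cross one inter-link with probability \(1 - S\beta\);
averaging over the binomial link count gives the non-spread probability
\(\beta_b = [1 - S\beta/4]^Q\) (`no_spread_prob()`, analytic in real
\(Q\)). Setting \(\beta_b = p_c\) and eliminating \(S\) yields

\[
\beta_c^{2D} \;=\; \frac{4\,(1 - 2^{-1/Q})}{1 - \exp(-4K(1 - 2^{-1/Q}))},
\qquad
S(\beta_c^{2D}) \;=\; 1 - \exp(-4K(1 - 2^{-1/Q})),
\]

implemented in `critical_beta_2d()` and `outbreak_size_at_threshold()`.
At \(K = 4\), \(Q = 10\): \(\beta_c^{2D} = 0.4074\), \(S = 0.6575\).
The outbreak size at the global threshold is *finite* — every infected
city is already above its local threshold — and shrinks like
\(4K\ln 2/Q\) for large \(Q\) (`outbreak_size_limit()`; note the limit
formula exceeds 1 at small \(Q/K\), outside its validity). As
\(Q \to \infty\) the two thresholds coalesce at \(1/K\).

Control strategies invert these formulas: `critical_K()` is the closed
form for the intra-degree below which a given \(\beta\) no longer
percolates (infeasible, with an explicit error, when
\(4(1-2^{-1/Q}) \ge \beta\)); `critical_Q()` solves the monotone equation
numerically. Other community tilings substitute their bond threshold and
coordination number through `lattice_spec()`; the hexagonal constant is
deliberately user-supplied rather than hardcoded, since printed values
for it differ across sources.

All of these identities — threshold/size consistency, \(\beta_b = 1/2\)
at criticality, inversion roundtrips, monotonicity in \(K\) and \(Q\),
\(\beta_c^{2D} \ge 1/K\) — are asserted to \(10^{-6}\) over a
\(20\times20\) parameter grid in the test suite.

## Percolation machinery

`bond_percolation_trial()` opens each of the \(2L^2\) bonds of the torus
independently and clusters sites by union-find with path compression,
tracking each site's lattice offset to its parent so that a bond closing
a cycle with nonzero net displacement certifies a cluster *wrapping* the
torus. Wrapping (not open-boundary spanning) matches the model's periodic
boundaries and has sharper finite-size behaviour near \(p_c\).

`estimate_pc_square()` bisects the wrapping frequency against 1/2. The
indicator bisected is wrapping around one *fixed* axis: at criticality
the infinite-lattice wrapping probabilities are ≈ 0.69 for
"either axis" but ≈ 0.52 for a fixed axis, so the fixed-axis
1/2-crossing estimates \(p_c\) nearly without bias, while the either-axis
crossing sits visibly below \(p_c\) at moderate sizes. At
`size = 128, replicates = 200` the estimate lands within 0.01 of 1/2 in
roughly two seconds.

## Simulation experiments and their estimators

**Two-threshold sweep.** `beta_sweep()` averages the final recovered
fraction \(R\) over replicates per \(\beta\) (by default one network per
replicate, reused across the grid with paired seeds).
`log_derivative_thresholds()` implements the inset procedure: smooth
\(\log \bar R\) (3-point moving average; \(\bar R\) floored at \(1/N\)),
differentiate by central differences, and report the two largest
well-separated maxima. The scaled experiment (L = 500, ζ = 50, K = 4,
k_inter = 4·10⁻³, 21 β values over [0.17, 0.49], 100 replicates) uses a
separation of 5 grid steps — half the predicted distance between the two
thresholds — because at this system size the first transition's shoulder
would otherwise masquerade as the second maximum. At \(N \sim 10^8\) the
two maxima are crisp; at desk scale \(N = 2.5\cdot10^5\) the second
transition is smeared by the small (10×10) community lattice, which is
why its detected position is accepted within ±0.05.

**Spatial propagation.** `propagation_curve()` tracks
\(\langle r_{max}\rangle(t)\), the mean over runs of the maximal distance
from the origin among recovered nodes. Two measurement choices matter and
are worth spelling out:

* *Extent metric.* The minimal-image distance saturates near \(L/2\); on
  the scaled geometries used here that destroys the late-time window. The
  default extent metric is therefore the **unwrapped displacement**
  accumulated along the infection tree (each newly infected node's
  displacement is its infector's plus the minimal-image step between
  them), which keeps growing when the front winds around the torus. The
  two metrics coincide exactly until the first winding.
  `recovery_events` always report the minimal-image distance.
* *Averaging.* The default conditions on survival: the curve averages
  runs still infectious at a reference time \(t_{ref}\) (the last time at
  least 10% of replicates remain active). Runs approaching extinction
  stall before dying; mixing them in ("active" mode) or freezing their
  final extents into the average ("carry" mode, the only mode that is
  monotone by construction) biases the apparent front velocity downward.
  All three modes are available.

Early on the epidemic dwells in concentric circles of cities:
`circle_timescales()` assigns circle index
\(\lfloor r/\zeta + 1/2\rfloor\) and reports the plateau durations
\(\tau_0 > \tau_1 > \tau_2\) and the mean plateau-to-plateau transition
time \(\tau_x\) (the transition duration is not operationally defined in
the underlying theory; this package reports last-time-at-plateau to
first-time-at-next and labels plateaus occupied under 2 steps as
unidentifiable). At late times the circle structure dissolves into clean
critical spreading, \(\langle r_{max}\rangle \sim t^{1/d_{min}}\) with
the 2D chemical-distance exponent \(d_{min} \approx 1.13\).

`fit_dmin()` returns the inverse least-squares slope of
\(\log\langle r_{max}\rangle\) vs \(\log t\). Its default window excludes
the circle regime (\(r < 3\zeta\)), the finite-size regime (\(r > L/2\)
for the unwrapped metric — beyond that the front meets the burned wake of
its own periodic images — or \(r > 0.45L\) for the minimal metric),
times with fewer than 5 active runs, and keeps the last decade of what
remains.

**A stated limitation.** On the scaled criticality geometry used by the
acceptance experiments (L = 400, ζ = 40, so a 10×10 community grid), the
admissible window \(3\zeta < r < L/2\) spans barely half a decade, and
the transient additive extent of order \(\zeta/2\) contributed by the
origin city biases the naive inverse slope upward. With 150–300 replicates
the estimator converges to ≈ 1.35–1.5 rather than 1.13 (local slopes
within the window do touch \(1/1.15\)). This is a finite-size property of
the estimator at this scale, not of the dynamics; recovering 1.13 to
±0.1 with this plain log–log fit requires a larger \(L/\zeta\) and a
longer window than these experiment sizes provide. The acceptance
pipeline reports the honestly fitted value and the test suite records
this check as failing at the strict ±0.1 band.

**Interventions.** `run_sir()` takes a schedule of `intervention()`s:
social (\(\beta \to \beta'\)), intra-community quarantine
(\(K \to K'\): a uniform subset of intra-links is removed so the expected
mean degree hits \(K'\)), inter-community quarantine
(\(k_{inter} \to k_{inter}'\), equivalently \(Q \to Q'\) at fixed
\(\zeta\)). Each takes effect at the start of step \(t_x\); a finite
window \(t_q\) restores the removed links bit-exactly (and reverts
\(\beta'\)) at \(t_x + t_q\). Quarantine edge subsets are drawn from
independently derived seed streams, so trajectories before \(t_x\) are
unaffected by whether an intervention is scheduled — paired-seed
comparisons across schedules are exact up to \(t_x\).
`intervention_outcome()` compares the mean extent at \(t_x\) with the
terminal extent over runs still active at \(t_x\), calling the epidemic
stopped when the mean additional spread stays below \(2\zeta\), and also
reports the per-run stopped fraction (the more informative quantity at
criticality, where part of the runs die regardless).

At the study conditions (K = 4, Q = 10, β = β_c = 0.4074, intervention in
the first-circle regime), each of β → 0.3, K → 3, Q → 1 puts the system
below its (new) global threshold — β_c rises to 0.485 under K' = 3 and
far higher under Q' = 1 — and the spatial spread halts within the
\(2\zeta\) band while uncontrolled runs roughly double their extent. For
the temporal quarantine the stopped fraction increases with \(t_q\):
a one-step window leaves a substantial fraction of runs propagating
after restoration, while a 300-step window lets the sub-threshold
epidemic burn out entirely.

## Strategy optimization in the (K, Q) plane

For a country at \((K_0, Q_0)\) facing \(\beta > \beta_c^{2D}(K_0,Q_0)\),
`critical_line()` discretizes the target line
\(\beta_c^{2D}(K, Q) = \beta(1+\epsilon)\) (margin \(\epsilon\), default
\(10^{-3}\), because the bare line is an open boundary), and
`optimize_strategy()` minimizes a weight function over it, restricted to
\(K \le K_0, Q \le Q_0\) — quarantines can only remove links; this
restriction is a deliberate design choice. The default weight is the raw
Euclidean distance \(\sqrt{(K_0-K)^2 + (Q_0-Q)^2}\) (minimal total link
reduction); arbitrary user weights are accepted since realistic cost
structures are far more complex. Ties break toward the smaller total
relative reduction. Results are labelled local / global / mixed according
to which coordinates moved by more than 0.1%. The optimizer is checked
against a brute-force grid scan, and `k_inter_from_Q()` translates
\(Q_{opt}\) back to an implementable per-node rate.

## Reproducibility and numerical choices

* Every stochastic operation draws from a stream seeded by
  `derive_seed(master, tag, index)` (a polynomial hash below \(2^{31}\)),
  so adding replicates or interventions never shifts existing streams,
  and every result is bit-reproducible from its master seed.
* Root-finding uses bracketed Brent iterations (`uniroot`) at absolute
  tolerance \(10^{-10}\) (thresholds) and \(10^{-8}\) (\(Q_c\)).
* `er_outbreak_size()` treats roots below its tolerance as 0 — the
  epidemic and trivial roots are numerically indistinguishable there.
* Degenerate grids are wired consistently: a \(1\times1\) community grid
  has no inter-links (the ER limit); a \(2\times2\) grid allows doubled
  adjacency through the wrap while still forbidding duplicate node pairs.
* The SIR kernel, the Monte-Carlo reach tally and the union-find
  percolation trials are compiled (Rcpp) and consume R's own RNG stream,
  so `set.seed()` semantics carry through compiled code.

## What the synthetic experiments do and do not show

All data in this package are generated by the model itself; there is no
observational input. The experiments demonstrate the internal consistency
of theory and simulation — thresholds where the closed forms put them,
percolation equivalence, intervention phenomenology — at sizes a desk
machine can run (\(N \le 2.5\cdot10^5\) here versus \(\sim10^8\) in
full-scale studies of this model). They do not establish anything about
real epidemics: cities of equal size, absence of long-range links,
recovery after exactly one step and a single scalar \(\beta\) are all
idealizations, and finite-size effects visibly shift or smear the
transitions at these scales (quantified above for \(d_{min}\) and the
second-threshold detection).
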