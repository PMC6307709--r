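---
title: "Methods: the generalized threshold q-voter model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the generalized threshold q-voter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvoter)
```

## The model and its assumptions

The package studies a population of `N` agents with binary opinions
`S_i = ±1` on a **complete graph**: any agent can influence any other, which
makes the up count `n = N↑` a sufficient description of the state and the
model exactly solvable. Updating is random sequential: one elementary step
(duration `1/N` Monte Carlo steps) updates one uniformly chosen target.

The target's response is drawn from the Willis–Nail repertoire:
conformity with probability `1 − p`, anticonformity with `p(1 − z)`,
independence with `pz`. Conformity and anticonformity act through a panel of
`q` distinct agents sampled uniformly **without replacement** from the other
`N − 1` agents (the falling-factorial structure of the finite-`N` rates
forces this interpretation; sampling with repetition only matters on sparse
graphs, which are out of scope). Conformity requires at least `r` panelists
to hold the opinion *opposite* to the target's; anticonformity requires at
least `w` panelists to *share* the target's opinion. Independence redraws
the opinion with flip probability `f = 1/2`; `f` is stored but frozen, since
the aggregate independence rates take their symmetric form only at `1/2` and
other values merely rescale the phase diagram.

Two micro-level choices deserve note, because the verbal description of
threshold rules is ambiguous where the aggregate equations are not:

* only the opinion **opposite to the target** is tested for conformity, and
  only the target's **own** opinion for anticonformity. This keeps the rule
  single-valued even when `r ≤ q/2` lets both opinions clear the threshold,
  and it is the event decomposition that reproduces the binomial-tail rates
  exactly;
* in the tie case `r = q/2` with a half–half panel, the target flips: the
  threshold is "at least `r`", and the `i = q/2` term belongs to the sum.

## Transition rates

With up fraction `x = (1+m)/2` and down fraction `v = (1−m)/2`, the
infinite-population flip rates are binomial tails,

```
α⁺ = v·P(Bin(q,x) ≥ r)    α⁻ = x·P(Bin(q,v) ≥ r)
β⁺ = v·P(Bin(q,v) ≥ w)    β⁻ = x·P(Bin(q,x) ≥ w)
γ⁺ = v/2                  γ⁻ = x/2
```

and the finite-`N` rates are the same expressions with hypergeometric tails
(panel drawn from the `N − 1` non-target agents). The aggregate one-step
rates are `λ± = (1−p)α± + p(1−z)β± + pz·γ±`, with `λ⁰ = 1 − λ⁺ − λ⁻`.
Tails are computed by `pbinom`/`phyper`, never by asymptotic approximation,
and the finite-`N` rates are validated in the test suite against brute-force
enumeration of every (target, panel) draw for all systems with `N ≤ 8`.

## Stationary analysis and the transition classifier

Setting `λ⁺ = λ⁻` is linear in `p` and yields the stationary relation
`p(m) = A/(A − C)` with `A = α⁺ − α⁻` and `C = (1−z)(β⁺−β⁻) − z·m/2`. Its
`m → 0⁺` limit is the critical nonconformity `p*` (the lower spinodal), and
the sign of `p₂` in `p(m) = p* + p₂m² + p₄m⁴ + …` classifies the
transition: `p₂ < 0` (maximum of `p(m)` at `m = 0`) means the ordered branch
exists only below `p*` — a continuous transition; `p₂ > 0` means `p(m)`
rises to an interior maximum (the upper spinodal) and a coexistence window
opens — a discontinuous transition.

A word on the sign convention: a hand-reduced continuous case
(`q = 3, r = w = 3, z = 1`, where `p(m) = (1−m²)/(3−m²)`) has a *maximum*
of `p(m)` at `m = 0`, which fixes "continuous ⇔ `p₂ < 0`" unambiguously.

### Numerical strategy

`m(p)` is singular at the transition, so nothing is differentiated
numerically. Both `A` and `C` are odd polynomials in `m`; their series
coefficients through order `m⁵` are computed in closed form from derivatives
of the binomial tail `T(x) = P(Bin(q,x) ≥ r)` at `x = 1/2`, using
`T′(x) = r·C(q,r)·x^(r−1)(1−x)^(q−r)` and exact falling-factorial
expressions for the higher derivatives. Every quantity involved
(`r·C(q,r) ≤ 50·C(50,25) < 2^53`, dyadic powers of `1/2`) is exactly
representable in double precision up to `q = 50` and well beyond, which
delivers the accuracy that exact rational arithmetic would, without the
machinery. A cache keyed on `(q, r)` makes the large scans cheap.

### The tricritical boundary needs the quartic term

At `q = 5, r = w = 5, z = 1` the quadratic coefficient `p₂` is *exactly*
zero: the conformity-plus-independence model sits precisely at its
tricritical point at `q = 5`. The classifier therefore falls back to the
quartic coefficient `p₄` when `|p₂|` is below tolerance (`10⁻¹⁰`): here
`p₄ < 0`, so `q = 5` is classified continuous, in agreement with the known
result that discontinuity starts at `q = 6`. Only when `p₂` and `p₄` both
vanish does the classifier report `"tricritical"`. Parameters with
`p* ∉ (0,1)` (e.g. very small `r`, where conformity does not order the
system at all) are reported as type `"none"` rather than force-classified.

### Upper spinodal

The maximum of `p(m)` over `(0, 1]` is located on a 2001-point grid and
refined with `optimize()` to `10⁻¹⁰`; for continuous transitions the
supremum is the `m → 0` limit `p*` itself and no search is run.

## Critical maps: `z*`, `r*`, `q*`

`critical_z(q, r, w)` scans `z` at step `0.02`, refuses (with an error) to
bisect when the classification changes sign more than once, and otherwise
bisects the single boundary to `10⁻⁶`. It returns 1 when every `z` is
continuous and 0 when every `z` is discontinuous; a `direction` attribute
distinguishes the usual orientation (discontinuous above `z*`) from
inverted pockets.

`critical_r(q)` returns the smallest conformity threshold in the **majority
domain** `r > q/2` for which a discontinuous transition exists at some
interior `z`. Two deliberate choices here, both auditable from the returned
`per_w` matrix:

* **Majority domain.** For large panels the classifier also finds
  discontinuity pockets at sub-majority thresholds (e.g. `q = 15, r = 6`,
  driven by low-`z` anticonformity); these are genuine features of the
  equations — direct evaluation of `p(m)` shows the interior maximum — but
  they lie outside the majority regime that the critical-majority question
  is about, where `r/q ∈ [0.5, 1]` and `r*/q → 0.5` as `q → ∞`. They remain
  reachable through `classify_transition()`.
* **`w` aggregation.** The default policy requires the discontinuity at
  **every** anticonformity threshold `w` (`w_policy = "every_w"`);
  `"any_w"` is also provided. The policies agree at moderate `q` (the
  anticonformity threshold is nearly irrelevant there: at `q = 10` whole
  `r`-rows of the `per_w` matrix flag uniformly), but at `q = 50` a weak
  pocket at `r = 29, w ≈ q/2` makes `"any_w"` return 29 where the
  critical-majority sequence `r*(10) = 8`, `r*(15) = 11`, `r*(50) = 30`
  (ratios 0.8, 0.73, 0.6) requires `"every_w"`. We treat the every-`w`
  reading as the operative definition of the critical majority — "below
  `r*` the transition is continuous regardless of `w` and `z`" is then
  violated only by thresholds where *all* anticonformity levels admit a
  discontinuity — and keep the pocket visible in `per_w` rather than hiding
  the discrepancy.

`tricritical_q(a_r, a_w, z)` resolves fractional thresholds through the
ceiling convention `r = ⌈a·q⌉` (the source of the saw-tooth features in
phase diagrams swept at fixed fractions) and returns the smallest
discontinuous `q`.

## Master equation

The up count performs a reversible birth–death chain with the tabulated
`λ±(n)`. Its stationary law is the exact product form
`π(n+1)/π(n) = λ⁺(n)/λ⁻(n+1)`, accumulated in log space — `O(N)` and
numerically safe — and is cross-checked in the tests against a dense
eigenvector solve to total variation `< 10⁻¹⁰`. Reducible chains (pure
conformity absorbs at both consensus states; unanimity thresholds also close
the up-channel of low-`n` interior states) are refused by name;
`absorption_probabilities()` instead solves the first-step-analysis
tridiagonal system, which remains valid when one-sided channels close.
Time evolution multiplies the one-elementary-step stochastic matrix, with a
renormalization guard against accumulated rounding.

## Monte Carlo engine

The compiled simulator holds the opinion vector explicitly, samples panels
by partial Fisher–Yates with an id/position pair of arrays (O(`q`) per
step), and draws randomness from four substreams (target, kind, panel,
independence coin) derived from one integer seed via splitmix64-seeded
xorshift128+ generators. Substreams mean that two runs differing only in
the initial configuration consume randomness in lockstep, which turns the
global-flip symmetry of the dynamics into an exactly testable property:
negating the initial opinions and mirroring the independence coin
(`u → 1 − u`) negates the trajectory bit-for-bit. Defaults: burn-in 20% of
the duration, one sample per MCS. `⟨|m|⟩` (not `⟨m⟩`) is reported, because
finite systems restore symmetry by rare whole-branch flips.

## What the synthetic data does and does not establish

The Monte Carlo engine *is* the package's data generator: it emulates finite
populations of homogeneous agents on a complete graph under exactly the
stated response rules. Green tests establish the internal consistency of the
three engines (enumerated rates, exact chain, simulation) and the mean-field
limits — they do not establish anything about heterogeneous agents,
zealots, sparse or modular social networks, with-repetition panel sampling,
or real opinion data, all of which are out of scope.

## Numerical choices

* classification tolerance on `p₂`, `p₄`: `10⁻¹⁰` (the coefficients are
  exact to machine precision, so this only catches true boundary cases);
* `critical_z`: coarse scan `Δz = 0.02` before bisection to `10⁻⁶`;
  `critical_r`: existence scan on a `Δz = 0.005` interior grid;
* upper-spinodal search: 2001-point grid plus local refinement, `10⁻¹⁰`;
* mean-field trajectories: RK4 with `dt = 0.01` MCS, clamped to `[−1, 1]`;
* master-equation evolution: exact elementary-step products (no operator
  splitting), renormalized each step;
* degenerate inputs: `stationary_p` errors when `A = C`; roots outside
  `[0, 1]` are reported as `NA` ("no physical stationary p at this m").

## Known limitations

* Discontinuous transitions in this family are weak: coexistence windows
  are narrow (e.g. `[0.135, 0.151]` at `q = 6, r = w = 6, z = 1`) and the
  disordered well of the effective potential is shallow (`~10⁻⁴` at
  mid-window), so observable metastability at these parameters requires
  populations in the tens of thousands. At `N` of a few hundred both the
  simulator and the exact chain show frequent spontaneous branch changes
  within hundreds of MCS — a physical feature of the model at that size,
  confirmed by the master equation, not simulation noise.
* Binodals (equal-depth lines) are not computed; the spinodal pair is.
* `critical_r` scans integer thresholds; its resolution in the ratio
  `r*/q` is `1/q` by construction.
* The infinite-`q` limit is outside the numerical scan range; the ratio
  `r*/q` approaches `1/2` from above as `q` grows.
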