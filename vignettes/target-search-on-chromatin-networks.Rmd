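---
title: "Target search on chromatin contact networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target search on chromatin contact networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadwalk)
```

## The model

A chromatin domain of genomic length $L$ kb is coarse-grained into $L + 1$
beads of 1 kb, indexed $0 \dots L$. Its 3D folding is summarised in *contact
space*: a symmetric binary matrix $C_{ij}$ with the backbone always bonded
($C_{i,i+1} = 1$) and long-range bonds between beads that touch in space.
Rather than tracking one specific structure, bonds are drawn independently
from a contact-probability law

$$P_c(s) \;=\; \begin{cases} p_u & \text{uniform model} \\
c\, s^{-\gamma} & \text{power-law model,} \end{cases} \qquad s = |i - j| \ge 2,$$

capped at 1. The exponent $\gamma$ measures compaction: a self-avoiding coil
has $\gamma \approx 2.2$, an ideal chain $1.5$, whole chromosomes
$\approx 1.08$, and folded TADs (topologically associating domains)
substantially less than 1. The prefactor default $c = 0.0214$ is the
genome-wide average fitted to normalised GM12878-style Hi-C maps at 1 kb
resolution; it is also the value the package uses whenever a "TAD-average"
network is requested.

A searching protein is an unbiased random walker absorbed at the boundary
beads 0 and $L$ (where promoters concentrate in real domains). Per step at
bead $i$ it either

* unbinds with probability $p_\mathrm{off}$, pays the residence time $\tau$
  plus a bulk excursion $\tau_f$ (default $100\,\tau$), and rebinds uniformly
  over all $L + 1$ beads — landing on a target counts as arrival; or
* moves to a uniformly chosen bonded neighbour, paying $\tau$ for a backbone
  slide and $t_\mathrm{jump}$ (default $\tau$) for an intersegmental hop.

The pure-sliding reference time from the midpoint is
$T_d = L^2 \tau / 4$; all scaled results divide by it.

### Boundary insulation

By default the targets are insulated: non-backbone bonds form only among
interior beads (`boundary_factor = 0`), so a hop can never land on a target
directly. `boundary_factor` in $(0, 1]$ admits leakier insulation. Networks
derived from 3D conformations or Hi-C maps have no such constraint built in;
`insulate_boundary()` applies the same convention to them. This matters:
without insulation, search on polymer-derived networks becomes monotone in
compaction, because ever-denser folding keeps adding direct bonds into the
absorbing beads. All polymer-network search results in the tests therefore
use insulated networks, while conversion itself (`conformation_to_network()`)
reports the raw geometric contacts.

## Three routes to the mean search time

**Monte-Carlo walks** (`simulate_walks()`, `ensemble_search_time()`) run the
process literally, averaging over walker noise and over network
realisations. The loops are compiled; $10^4$ walks on a static $L = 500$
chain (mean $62{,}500$ steps each) take a few seconds.

**Quenched solves** (`solve_quenched()`, `mean_quenched()`). On a fixed
configuration the mean first-passage times solve a linear system: for
interior beads

$$T_i = (1 - p_\mathrm{off}) \sum_j \frac{C_{ij}}{N_i}\,(c_{ij} + T_j)
      + p_\mathrm{off}\,(\tau + T_f), \qquad
  T_f = \tau_f + \frac{1}{L + 1} \sum_{j = 0}^{L} T_j,$$

with $T_0 = T_L = 0$, $N_i$ the degree of bead $i$, and $c_{ij}$ the per-move
cost ($\tau$ or $t_\mathrm{jump}$). The system is solved sparsely (dense when
fill exceeds 5%); the relative residual is reported and checked below
$10^{-10}$. Configuration averages sample fresh networks per solve.

**Annealed solves** (`solve_annealed()`). When bonds are redrawn every step
(`t_config_switch = 1`), the walk is a Markov chain with transition
probabilities $\mathbb{E}[C_{ij} / N_i]$ under a fresh draw. The package
computes these exactly: conditioning on $C_{ij} = 1$, the remaining degree is
a Poisson-binomial variable whose pmf is built by dynamic programming, and
$\mathbb{E}[(3 + K)^{-1}]$ follows by removing bond $j$ from the pool
(a one-Bernoulli deconvolution, run forward for $p \le 1/2$ and backward
otherwise for stability; the pmf support is truncated at tail mass
$10^{-16}$). Each interior row of the resulting kernel sums to 1 to
$10^{-12}$, and the kernel matches brute-force enumeration over all bond
configurations at small $L$ to $10^{-12}$. A mean-field variant
($P_{ij} / \mathbb{E}[N_i]$) is provided for comparison with closed-form
treatments; it is labelled approximate and is *not* the default.

### The printed asymptotics and their status

`low_pu_approx()` implements the first-order expansion
$T / T_d \approx 1 - (L^3 - 5L^2 - 20L + 48)\,p_u / 48$, valid for
$p_u \ll 1/L^2$ (a warning fires beyond $p_u L^2 > 0.1$). `high_pu_approx()`
implements the closed form
$[2 + (L - 3)p_u + (2 + (L - 4)p_u)^2] / (2 p_u)$, derived from a simplified
system that treats all interior beads as equivalent. Both are asymptotic
approximations, not exact values: at $p_u = 1$ the network is deterministic
(complete interior graph) and the exact midpoint time, obtainable by hand
from the two-level edge/interior system, is $(L^2 - 2L + 2)/2$, while the
closed form gives $(L^2 - 3L + 3)/2$ — a relative gap of order $1/L$
($2 \times 10^{-3}$ at $L = 500$). The solver is held to the exact values;
agreement with the printed forms is asserted in the limits where they are
valid approximations ($p_u \to 0$ inside the expansion's regime, and
$O(1/L)$ convergence at $p_u = 1$).

## What the model predicts

```{r nonmono, eval = FALSE}
sc <- run_scan("gamma", c(0.1, 0.3, 0.5, 0.71, 1.0, 1.5, 2.2),
               model = contact_model("powerlaw", c = 0.0214, gamma = 1),
               L = 500, mode = "quenched", n_configs = 50, rng_seed = 1)
sc[, c("value", "scaled")]
```

* **Non-monotonicity in compaction.** $\langle T \rangle$ versus $p_u$
  (uniform) or $\gamma$ (power law) has a strict interior minimum: sparse
  networks search diffusively ($T \to T_d$), over-connected ones divert the
  walker into excess hops. The $\gamma$-minimum falls below 1, in the
  compaction range observed for real TADs.
* **Bulk excursions help only open chains.** At $p_u \lesssim 10^{-5}$
  ($L = 500$) there is a classical facilitated-diffusion optimum near
  $p_\mathrm{off} \approx 10^{-2}$; by $p_u = 10^{-3}$ the optimum is gone
  and unbinding only slows the search.
* **Near-ballistic scaling.** On TAD-average networks
  ($c = 0.0214$, $\gamma = 0.71$) the annealed solver gives
  $\langle T \rangle \sim L^{0.90}$ over $L = 100$–$1600$ — far from the
  diffusive $L^2$ — and the fitted exponent $\nu(\gamma)$ has its minimum in
  the TAD range $\gamma \in (0.3, 1.2)$.

## Polymer models

`generate_frc()` builds freely rotating chains: unit bonds, fixed angle
$\theta$ between successive bond vectors (the rod limit is $\theta = 0$;
large $\theta$ folds the chain), uniform azimuth — the paper's cone wording
does not fix the azimuthal law, and the uniform choice is the standard FRC.
The sampled ensemble reproduces the fixed-angle end-to-end closed form
$\langle R^2 \rangle / n b^2 \to (1 + \cos\theta)/(1 - \cos\theta)$.

`langevin_evolve()` integrates the bead-spring chain
($E_\mathrm{spring} = k (r - \sigma)^2 / 2$, truncated LJ or soft-core LJ
pairs) with velocity Verlet at $dt = 0.01$, friction and thermal kicks in
the force. The spring constant is not fixed by theory; the default
$k = 100$ keeps bond fluctuations near 5% of $\sigma$ at $k_BT = 1$ while
leaving the spring period ($2\pi/\sqrt{k} \approx 0.63$) well above $dt$.
The soft pair potential
$V_0 [1 - (r / r_m)^{\eta_1}]^{\eta_2} - \epsilon$ (for $r < r_m$, with
$V_0 = 10^7$, $\eta_2 = 3.16$, $r_m = 1.12$) allows overlap at finite cost
$V_0 - \epsilon$ and crosses over to LJ at $r_m$, where the two branches
agree to better than $10^{-3}\,\epsilon$. The integrator targets chains of
up to a few hundred beads; production-scale equilibration belongs in a
dedicated MD engine, with trajectories imported through `read_xyz()`.

Conformations become networks through a distance cutoff $r_c$. No cutoff
value is dictated by the theory; the package default is
$r_c = 1.5\,\sigma$ — beyond nearest-image contact ($\sigma$) but well
inside the interaction cutoff ($2.5\,\sigma$) — and it is an explicit
argument everywhere so results can state it.

Reduced-scale study sizes used in the test suite, chosen to finish in
seconds while leaving the physics visible: FRC search scans use 300-bead
chains with 10 network realisations per angle; the soft-vs-hard comparison
equilibrates 80-bead chains for $10^4$ steps, 6 replicates per
($\epsilon$, $\eta_1$) point. At this scale the open-chain branch of the
$\epsilon$ scan is dominated by equilibration noise, so the strength of
non-monotonicity is quantified by the post-minimum rise
$T(\epsilon_{\max}) / \min_\epsilon T$, which is systematically larger for
the softer potential ($\eta_1 = 0.02$ vs $0.05$).

## Hi-C analysis and the synthetic generator

Normalised contact maps are scaled to probabilities by dividing by the
maximum off-diagonal entry, per chromosome (`probability_scale()`, an
idempotent operation). For each TAD, `intra_tad_contact_curve()` averages
$P_{ij}$ at fixed separation and `fit_power_law()` fits
$\log P = \log c - \gamma \log s$ over $s \in [10, L - 100]$ kb — the
conventional fitting window. TADs of 110 kb or less cannot host that window
with the minimum four points; `tad_fit_all()` skips them and reports the
skipped set, rather than inventing a narrower window. Non-positive
probabilities are dropped from the log fit, not imputed.

`build_hic_network()` draws Bernoulli networks directly from $P_{ij}$
(backbone enforced); `tad_search_time()` averages walks over such draws.
These map-derived networks carry boundary contacts, so their solver
counterpart is the quenched average over model networks with
`boundary_factor = 1`; matched this way the two routes agree within
Monte-Carlo error, while mixing conventions (annealed vs quenched, insulated
vs not) produces genuine 30–60% differences. Walks on Hi-C networks use
$p_\mathrm{off} = 0$ by default, consistent with the intersegmental-transfer
regime the model addresses.

The synthetic generator (`generate_map()`) emulates exactly what the
pipeline consumes: block-wise power laws $c\,s^{-\gamma}$ inside
non-overlapping TADs, a weaker background law elsewhere (defaults
$c = 0.005$, $\gamma = 1.08$, the genome-scale decay), multiplicative
lognormal noise on probabilities, capping at 1, symmetry. It does *not*
emulate read-count sampling, distance-dependent coverage bias, unmappable
bins, nested sub-TAD structure, or compartment checkerboards — so passing
round trips demonstrate that the fitting machinery is unbiased under the
model's own noise assumptions, not that real Hi-C artefacts are handled.
With $\sigma_{\log} = 0.2$ the fitted $\hat\gamma$ is unbiased to well
within $0.05$ across $\gamma \in \{0.3, 0.71, 1.5\}$.

## Numerical conventions

* Times are in units of $\tau$ throughout; scaled columns divide by
  $T_d = L^2 \tau / 4$.
* Randomness always flows through R's global generator; every sampling
  function takes an `rng_seed`, and network sampling consumes exactly one
  uniform per eligible pair in row-major $(i < j)$ order, so realisations
  are reproducible from the seed alone.
* Linear solves are sparse LU (dense beyond 5% fill); residuals are checked
  against $10^{-10}$.
* For odd $L$ the walker starts at $\lfloor L/2 \rfloor$.
* Unbinding is decided before the move, and the residence cost $\tau$ is
  charged on the unbinding step, so one unbind–rebind cycle costs
  $\tau + \tau_f$.
* Reshuffle intervals count walker moves, not elapsed time.

## Known limitations

The contact-space picture draws bonds independently, ignoring the
correlations that loops impose on real conformations; this is harmless for
fast-rewiring (annealed) domains but is an approximation for frozen ones.
The bulk phase is a single mean exploration time with uniform rebinding —
no spatial 3D diffusion, no distance-dependent rebinding. One walker
searches at a time; cooperative or crowding effects are out of scope, as is
loop-extrusion dynamics. The Langevin integrator is deliberately minimal
(single chain, $O(L^2)$ pair loop) and is meant for reduced-scale checks,
not phase-diagram production.
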