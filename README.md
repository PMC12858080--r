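# tadwalk

How fast can a DNA-binding protein find a target inside a folded chromatin
domain? `tadwalk` models a 1-kb-resolution chromatin domain as a network in
*contact space* — beads `0..L` joined by the backbone plus stochastic
long-range bonds drawn from a contact-probability law — and computes the
mean first-passage time of a searching protein to the domain boundaries.
The walker slides along the backbone (cost τ per step), hops across
intersegmental bonds, and may unbind into the bulk (probability
`p_off` per step, excursion time `τ_f`) before rebinding at a random bead.

The package is for quantitative chromatin biologists and biophysicists who
want to connect Hi-C-derived contact statistics to protein search kinetics:

* contact models `P_c(s) = p_u` (uniform) or `P_c(s) = c·s^(−γ)`
  (power law), with the TAD-average defaults `c = 0.0214`, `γ = 0.71`;
* Monte-Carlo search simulation on static or dynamically rewired networks
  (compiled core);
* exact mean first-passage-time theory: quenched (fixed network) linear
  solves, and an exact *annealed* solution for fully dynamic networks via
  the Poisson-binomial expectation `E[C_ij/N_i]`, plus the printed low- and
  high-connectivity asymptotics;
* polymer conformation generators (freely rotating chain; Lennard-Jones and
  soft-core bead-spring chains under Langevin dynamics) with
  conformation-to-network conversion;
* Hi-C/TAD analysis: probability scaling, intra-TAD contact curves,
  power-law fits over `s ∈ [10, L−100]` kb, Bernoulli networks drawn from
  measured `P_ij`, and search-time scaling exponents `⟨T⟩ ~ L^ν`;
* a synthetic contact-map generator with known ground truth, so the whole
  pipeline is testable offline.

The central results the package reproduces: search time is *non-monotonic*
in domain compaction with an optimum at `γ < 1` (where real TADs sit); bulk
excursions only help weakly connected domains; and search on TAD-like
networks scales near-ballistically, `⟨T⟩ ~ L^0.9`, instead of the diffusive
`L²`.

## Worked example

```r
library(tadwalk)

## a TAD-average power-law domain of 501 beads (L = 500)
model <- contact_model("powerlaw", c = 0.0214, gamma = 0.71)
C <- build_connectivity(model, L = 500, rng_seed = 1)
C
#> <connectivity_matrix> beads 0..500, 500 backbone bonds, 130 non-backbone bonds

## exact mean search time on this one network, walker started mid-domain
solve_quenched(C)
#> <fpt_solution> L = 500, T_mid = 5646.69 tau (residual 3.6e-14)

## ensemble over networks and trajectories
ensemble_search_time(model, L = 500, walker_params(),
                     n_configs = 20, n_walks = 500, rng_seed = 2)
#> <search_estimate> <T> = 2463 +/- 26.4 tau (T/T_d = 0.03941; 500 walks x 20 configs)

## compaction scan: the minimum sits below gamma = 1
sc <- run_scan("gamma", c(0.2, 0.5, 0.71, 1.1, 1.6, 2.2), model = model,
               L = 500, mode = "quenched", n_configs = 20, rng_seed = 3)
sc[, c("value", "mean", "sem", "scaled")]
#>   value  mean     sem  scaled
#> 1  0.20  2017   36.48 0.03227
#> 2  0.50  1807  113.33 0.02891
#> 3  0.71  2757  295.45 0.04411
#> 4  1.10 11821 1549.73 0.18914
#> 5  1.60 48575 1695.37 0.77720
#> 6  2.20 59422 1142.59 0.95075

## near-ballistic scaling of search time with domain length
Ls <- c(100, 200, 400, 800, 1600)
Ts <- sapply(Ls, function(L) solve_annealed(model, L)$T_mid)
fit_scaling_exponent(Ls, Ts)
#> <scaling_fit> <T> ~ 5.648 * L^0.903 (R^2 = 0.9998, 5 lengths)
```

Reading the numbers: a single 500-kb domain realisation at TAD-average
compaction is searched in ~5,600 τ from the midpoint, against the
pure-sliding reference `T_d = L²τ/4 = 62,500 τ` — a ten-fold speed-up from
intersegmental hops alone (the ensemble mean over many realisations,
~2,500 τ, is 25-fold). The scan shows search time falling and then rising
again as the domain compacts (γ decreasing from 2.2 to 0.2), with the
optimum below γ = 1, and the length scan shows `⟨T⟩ ~ L^0.90`: search on
TAD-like topologies is close to ballistic even though every move is
diffusive.

## Command line

A thin CLI over the same functions ships in `inst/cli/tadwalk`
(after installation: `system.file("cli", "tadwalk", package = "tadwalk")`):

```sh
tadwalk net --kind powerlaw --L 500 --c 0.0214 --gamma 0.71 --seed 1 --out net.tsv
tadwalk sim --net net.tsv --nwalks 10000 --seed 2 --out sim.json
tadwalk scan --var gamma --grid 0.2,0.5,0.71,1.1,1.6,2.2 \
             --kind powerlaw --c 0.0214 --gamma 1 --L 500 \
             --mode quenched --nconfigs 50 --seed 3 --out scan.tsv
tadwalk synth-hic --nbins 320 --tad 10:310:0.0214:0.71 --sigma-log 0.2 \
                  --seed 4 --out-map map.tsv --out-tads tads.bed
tadwalk tad-fit --map map.tsv --coo --tads tads.bed --out fits.tsv
```

## Scientific scope and caveats

Bonds are drawn independently pair by pair, so loop-induced correlations in
real conformations are neglected; the bulk phase is a mean excursion time
with uniform rebinding, not spatial 3D diffusion. The Langevin integrator
is a minimal single-chain implementation intended for reduced-scale
validation; large-scale equilibration should come from a dedicated MD
engine via the xyz reader. See the methods vignette
(`vignettes/target-search-on-chromatin-networks.Rmd`) for the model
assumptions, parameter conventions, and numerical choices in full.
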