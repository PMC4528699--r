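# mitofate

Hybrid multi-scale simulation of the competition between Bnip3-mediated
mitophagy and Bax/MOMP-driven apoptosis across a mitochondrial
population.

Mitochondria integrate death signaling: BH3-only proteins activate Bax,
mitochondrial outer membrane permeabilization (MOMP) releases cytochrome
*c* and fires the caspase cascade, while the autophagy receptor Bnip3
can instead hand the organelle to an autophagosome for degradation
(mitophagy). Bnip3 does both at once — its BH3 domain inhibits
pro-survival Bcl2/Bcl-x<sub>L</sub>, its phosphorylation-controlled LIR
domain binds LC3 on autophagosomes — so each mitochondrion runs an
internal race whose outcome depends on local ROS, autophagosome access
and its own Bax/Bcl2 complement. `mitofate` is for systems biologists
who want to ask how that single-organelle race, repeated over a
heterogeneous population in space, shapes the cell-level apoptosis
decision.

## Model core

Per mitochondrion, a mass-action ODE network over 11 species:

- ROS-driven Bnip3 activation: `d[Bnip3_a]/dt ⊃ r_f·[Bnip3_i]·[ROS] − r_r·[Bnip3_a]`
- LIR–autophagosome binding (the mitophagy potential):
  `d[Bnip3·AV]/dt = r_lir·(1 + α·[Bcl2·Bnip3])·[Bnip3_a]·[AV] − r_r·[Bnip3·AV]`
- BH3 sequestration of Bcl2, Bcl2 neutralization of Bax, tBid-catalyzed
  Bax activation (`r_f·[tBid]·[Bax_i]`), MOMP
  (`k_momp·[Bax_a]·[cytc_m]`), caspase-3 activation tracking cumulative
  release (`r_f·(1 − [cytc_m])·[casp3_i]`), caspase-mediated AV
  inactivation, and ROS-induced ROS release (`k_ros_bax·[Bax_a]`).

Rates follow the qualitative parameterization `r_f = 0.1`,
`r_r = 0.01`, with LIR variant binding rates `r_lir` = 0.05 (WT),
3 (2SE, constitutively active) and 0.001 (2SA, inactive).

One hundred such agents live on a closed 20 × 20 lattice with diffusing
ROS/tBid/cytochrome-*c* fields and a consumable autophagosome layer
(random, homogeneous or radial-ring placement), move by an
exclusion-respecting random walk, and commit irreversibly to a
phenotype after holding it for 15 consecutive steps — mitophagy ends in
degradation, apoptosis in a single MOMP burst fed back into the
environment. Ensembles of runs quantify cell-to-cell variability.

## Worked example

The standard stressed-cell scenario: autophagosomes at 20 % coverage
(AV = 75, random), 20 % Bnip3 pre-activation, tBid switched on at step 5.

```r
library(mitofate)

cfg <- sim_config(steps = 100L, tbid_start = 5, seed = 1L)
res <- run(cfg)
res
#> <mito_run> 71 steps, census: mitophagy=21 apoptosis=79 uncommitted=0,
#> total cytc released=98.19
annotate_phases(res)
#> $activation_end   16
#> $competition_end  68
```

Of 100 mitochondria, 21 escaped into mitophagy and 79 underwent MOMP,
releasing essentially their full cytochrome-*c* complement (98.2 of
100) — the roughly 4:1 apoptosis:mitophagy split of a wild-type
population under this dose. The population activated within 16 steps and
the last agent locked in at step 68. Across cells:

```r
run_ensemble(cfg, n_runs = 10)$summary
#>                statistic mean    sd      cv
#> 1    max_total_mitophagy 33.0 1.806 0.05474
#> 3       census_mitophagy 22.6 2.675 0.11836
#> 4       census_apoptosis 77.4 2.675 0.03456
#> 6             cytc_total 98.0 0.296 0.00302
```

The census CV of ~0.12 is the model's cell-to-cell variability: cells
with identical parameters diverge through AV placement and movement
alone. A single-mitochondrion dose–response locates the Bax level below
which mitophagy wins despite tBid (the apoptosis-resistant
subpopulation):

```r
dr <- dose_response("WT", sweep = seq(0, 2, 0.5), param = "bax")
attr(dr, "crossover")
#> 0.1357
```

Named presets (`preset("fig3_tbid")`, `"fig4_av_sweep"`,
`"fig6_radial"`, `"fig7_bax_het"`, `"s7_ros"`, `"s12_mobility"`, ...)
bundle the scenario sweeps; `run_scenario()` returns per-condition
means, dispersions and fold changes. A thin command-line runner is
installed at `inst/cli/simulate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/simulate.R", package="mitofate"))')" \
  scenario --name fig3_tbid --runs 50 --out out/
```

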