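# biomedyn

Multi-clade analysis of how a biome is assembled over evolutionary time,
from dated, range-coded phylogenies.

A regional biota is built by two processes: **dispersal into the region**
and **in situ diversification** once there. Given a set of dated
ultrametric trees (newick, or BEAST-style NEXUS with node-age 95% HPD
annotations) whose tips are coded for geographic range, `biomedyn`:

1. fits the **dispersal–extinction–cladogenesis (DEC)** model of range
   evolution per clade — anagenetic expansion at rate
   *d*·Σ<sub>i∈G</sub> m<sub>ij</sub> (with per-time-slice dispersal
   multipliers m and a maximum range size), per-area extirpation at rate
   *e*, and equal-weight subset-sympatry/vicariance cladogenesis — and
   estimates marginal ancestral ranges by maximum likelihood;
2. classifies species-level **biogeographic events**: a dispersal-in event
   on every edge whose child range gains the focal area, and an in situ
   diversification event at every node where ancestor and both daughters
   occupy it, each dated by the node-age credibility intervals, with
   source regions taken from a finer regionalization;
3. pools events across clades into **MDisE / MDivE curves** (events
   counted in every 0.1-Ma slice their interval overlaps, smoothed with a
   0.5-Ma sliding window), extracts **origination** and **peak** with 1000
   bootstrap pseudoreplicate CIs, and locates **change points** by
   segmented (piecewise-linear) regression with 1–4 breakpoints selected
   by BIC, `BIC = n log(RSS/n) + (2 + 2k) log(n)`;
4. reconstructs **ancestral habitat states** (open vs closed) under a
   two-state Markov model to test whether immigrants descend from
   open-habitat ("pre-adapted") ancestors;
5. ships a **synthetic-data generator** — birth–death trees, forward DEC
   histories with logged true events, habitat histories, and event
   ensembles from piecewise intensities with known change points — so
   every stage is validated against known truth.

It is aimed at historical biogeographers and macroevolution researchers
who have per-clade dated trees and range codings and want reproducible,
scriptable assembly-dynamics summaries.

## Worked example

Simulate a study-scale event ensemble (about 130 events from a
piecewise-linear intensity originating at 10.24 Ma with kinks at 7.2, 2.6
and 0.6 Ma), tally it, and extract curve features:

```r
library(biomedyn)

events <- simulate_event_ensemble(sim_scenario(seed = 1))
tally_report <- tally(events)
cat(format_tally(tally_report))
#> Biogeographic events: 129 total (103 dispersal into the focal region, 26 in situ diversification)
#> Dispersal : in situ ratio = 3.96
#> Source regions assigned for 25 dispersal events:
#>   G: 9 (36.0%)
#>   B: 6 (24.0%)
#>   ...

disp <- events[events$event_type == "dispersal_in", ]
bootstrap_features(disp, n_boot = 1000, seed = 1)
#> Origination: 9.85 Ma (95% CI 10.35-9.40)
#> Peak:        1.10 Ma (95% CI 1.25-0.95)
#> (1000 bootstrap pseudoreplicates, mode 'interval', seed 1)
```

The origination is the oldest dispersal's point age with a CI from drawing
ages inside each event's credibility interval; the peak is the midpoint of
the maximal run of the smoothed 0.1-Ma curve — here the simulated
intensity truly peaks at 0.6–1 Ma, and the ~10 Ma origination reflects the
intensity's 10.24 Ma origin minus the sparseness of early events.

The full tree-based pipeline runs from a config file (see
`?run_config`); a complete synthetic study directory to try it on is one
call away:

```r
cfg <- simulate_study("study-dir", sim_scenario(n_clades = 3, n_tips = 15, seed = 5))
run_pipeline("study-dir/config.yaml")
```

which writes `events.tsv`, per-type curve tables, `features.json` and a
`summary.txt` with the tally, feature, change-point, and habitat-ancestry
blocks. A thin command-line wrapper with the same two entry points lives
at `inst/scripts/biomedyn.R`:

```sh
Rscript inst/scripts/biomedyn.R simulate study-dir --seed 1
Rscript inst/scripts/biomedyn.R pipeline study-dir/config.yaml
```

## Package layout

| Area | Functions |
| --- | --- |
| Tree / table I/O | `read_dated_tree`, `write_dated_tree`, `read_coding`, `read_event_table`, `write_event_table` |
| DEC model | `area_scheme`, `build_state_space`, `anagenetic_rate_matrix`, `cladogenesis_distribution`, `dec_loglik`, `fit_dec`, `ancestral_ranges` |
| Events | `classify_events`, `attach_timing`, `assign_sources`, `tally` |
| Curves | `mde_curve`, `origination`, `peak`, `bootstrap_features`, `per_source_curves` |
| Change points | `fit_segmented`, `select_changepoints` |
| Habitat | `ancestral_habitat`, `preadaptation_report` |
| Synthetic data | `sim_scenario`, `simulate_tree`, `simulate_ranges`, `simulate_event_ensemble`, `simulate_habitats`, `simulate_study` |
| Orchestration | `run_config`, `run_pipeline` |

The methods vignette (`vignettes/biome-assembly-dynamics.Rmd`) documents
the models, conventions, numerical choices, and the limits of what the
synthetic validation shows.
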