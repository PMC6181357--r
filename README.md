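# nestdyn

Stock-and-flow simulation of nest-site availability and occupancy for a
Mediterranean forest raptor community (booted eagle *Hieraaetus pennatus*,
common buzzard *Buteo buteo*, northern goshawk *Accipiter gentilis*), and of
how clearcut forestry rotations and nest-protection measures reshape it.

Tree-nesting raptors in these systems reuse long-lived stick nests across
years and species, so the number of standing platforms is a slow resource
stock of its own. `nestdyn` integrates two coupled stocks — total nests `tn`
and occupied nests `on` (breeding pairs) — under a carrying capacity set by
mature forest area:

```
moc  = mfa / mfap                     carrying capacity (pairs)
onir = anr * or * (tn - on) * cr      settlement: anr = (moc-on)/moc, or = on/moc
onar = (on - moc) * cr                abandonment when capacity shrinks
nb   = on * nbr                       platform building by pairs
ndr  = tn / nlf                       platform decay
nlfc = tn * mfcr                      platform loss at a clearcut event
```

Settlement requires empty platforms and is facilitated by pairs already
present (conspecific attraction), which makes extinction absorbing. An
age-cohort forest submodel supplies the mature area `mfa(t)` and the cut
fraction `mfcr` of each clearcut event; nest protection (buffers around all
platforms) reduces event losses by 90%. Defaults are the field-derived
parameterisation of a 10,000-ha Aleppo pine study area in SE Spain
(`nbr = 0.14`/yr, `nlf = 20.68` yr, `mfap = 300` ha/pair, maturity at 34 yr).

The package is aimed at modellers and conservation planners who want to
re-run, probe or extend the published scenario experiments from
configuration alone: colonisation history, a reforestation validation run,
and 2010–2050 rotations of 40/50/60/70-year cutting ages with and without
nest protection.

## Worked example

```r
library(nestdyn)

# decadal clearcutting of 40-year-old trees, with nest protection
traj <- simulate_scenario(build_managed(40, protection = TRUE))
traj
#> Nest-occupancy trajectory 'cut40_prot': 41 annual samples (2010-2050)
#>   4 clearcut event(s), 16.5 nests lost in total
#>   final state 2050: on = 8.33 pairs, tn = 19.89 nests, moc = 0.00

runs <- lapply(c("unmanaged_2010", "cut70_noprot",
                 "cut40_noprot", "cut40_prot"), simulate_scenario)
summarize_scenarios(runs, window = c(2010, 2050))
#>               id mean_moc sd_moc mean_on sd_on gap_percent final_on extinct
#> 1 unmanaged_2010    33.33   0.00   33.33  0.00        0.00 3.33e+01   FALSE
#> 2   cut70_noprot    17.07   2.38   17.85  3.17       -4.57 1.90e+01   FALSE
#> 3   cut40_noprot     4.88   4.16    2.65  5.97       45.76 8.48e-05    TRUE
#> 4     cut40_prot     4.88   4.16    6.11  5.61      -25.21 8.33e+00   FALSE
```

Reading the table: the unmanaged forest holds a constant 33.3 pairs.
Cutting 70-year-old trees halves the average capacity (`mean_moc` 17.1
pairs) and occupancy tracks it. Cutting 40-year-old trees is fatal without
protection — the decadal pulses destroy the whole platform stock and the
community goes extinct (`final_on` ≈ 0) — while protecting nests during the
same cuts keeps 8.3 pairs breeding in 2050. (`moc = 0.00` in the final
state above is the sawtooth trough of the 40-year rotation: in 2050, right
after a cut, no stand is over the 34-year maturity age; the 2010–2050 mean
capacity is 4.9 pairs.) A negative capacity gap means occupancy spent part
of the window above the reduced capacity while surplus pairs abandoned.

Each trajectory is a tidy data frame (year, stocks, capacity, all flows,
pulse losses) with the clearcut event log and the full configuration
attached; `write_run()` exports CSVs plus a JSON snapshot that reproduces
the run bit-for-bit, and `compare_to_observed()` scores a trajectory
against a count series. A command-line wrapper is installed under
`inst/cli/nestdyn`:

```sh
Rscript inst/cli/nestdyn simulate --scenario cut50_noprot --out runs/
Rscript inst/cli/nestdyn sweep --rotation-ages 40,50,60,70 --protection both --out runs/
Rscript inst/cli/nestdyn list-scenarios
```

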