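# termeff

Quantification and modeling of Rho-independent (intrinsic) terminator
efficiency under transcription–translation coupling in bacteria.

In bacteria the pioneer ribosome translates the nascent mRNA right behind
RNA polymerase (RNAP). When an intrinsic terminator sits only a few
nucleotides downstream of a gene's stop codon, that ribosome can sterically
occlude folding of the terminator hairpin, letting RNAP read through. As the
stop-codon-to-hairpin spacer grows, termination efficiency (TE) rises
smoothly to the terminator's intrinsic maximum. `termeff` implements the
complete analysis of this phenomenon for dual-fluorescence reporter
experiments:

- **Quantification** — converts plate-reader time series (OD600 + RFP/GFP
  fluorescence) into per-cell protein synthesis rates
  *P* = *μf*(1 + *μτ*/ln 2), where *μ* is the growth rate, *f* = ∂F/∂OD and
  *τ* the fluorophore maturation half-time, and into termination
  efficiencies

  TE = 1 − (P<sub>GFP</sub>/P<sub>GFP,ref</sub>) / (P<sub>RFP</sub>/P<sub>RFP,ref</sub>),

  normalized against a terminator-free reference construct (with a GFP-only
  variant for constructs whose upstream gene was modified).

- **Coupling model** — the stochastic ribosome–RNAP coupling model

  TE(*d*) = TE₀ [1 − CDF(*α*, *λ*(*d*))],  *λ*(*d*) = *d* + *c*,

  where the distance between the pioneer ribosome and the hairpin at the
  moment RNAP reaches the terminator is Poisson with mean *d* + *c*, and the
  ribosome occludes hairpin folding whenever that distance is at most
  *α* nt. Includes exact prediction, exhaustive-grid least-squares fitting
  (integer grids over *α* and per-series *c*, closed-form TE₀), and
  case-resampling bootstrap intervals. Fitted defaults for the phage λ tR2
  terminator: TE₀ = 0.9, *α* = 27 nt, *c* = 15 nt (natural upstream
  sequence) / 7 nt (designed random spacer).

- **Mechanistic simulator** — a Gillespie simulation (Rcpp) of one RNAP and
  the pioneer ribosome on a nascent transcript, with steric exclusion,
  translation-initiation delay, and configurable RNAP/ribosome pause sites.
  It produces the ribosome–hairpin distance distribution that the Poisson
  model approximates, plus head-start and catch-up statistics.

- **Synthetic data** — generators for construct panels, plate-reader growth
  curves with known ground-truth TE, and noisy TE–distance tables, so the
  whole pipeline is testable end to end without any external data.

- **Spacer design** — rejection sampling of low-GC spacer sequences screened
  against complementarity with the terminator hairpin arms (forward design
  of TE by distance).

## Worked example

Simulate a two-series reporter panel, quantify it, and refit the coupling
model:

```r
library(termeff)
library(dplyr)

params <- coupling_params()                      # TE0 = 0.9, alpha = 27, c_W = 15, c_R = 7
panel  <- make_construct_panel(params)
meas   <- make_growth_series(panel, noise = noise_model(0.02, 0.01,
                                                        replicates = 3, seed = 11))
te_tab <- quantify_te(meas, panel)
te_tab
#> # A tibble: 22 × 8
#>   construct_id series distance_nt    te   te_se method n_replicates ...
#> 1 W8           W                8 0.167 0.00522 dual              3
#> 2 W13          W               13 0.474 0.00896 dual              3
#> 3 W18          W               18 0.752 0.00358 dual              3
#> 4 W23          W               23 0.868 0.00232 dual              3
#> 5 W28          W               28 0.895 0.00144 dual              3
```

The measured TEs rise from ~0.17 at an 8-nt spacer to the ~0.9 plateau by
~28 nt. Uncoupled constructs (RBS deleted, so no pioneer ribosome) sit at
TE₀ at any distance; exclude them before fitting:

```r
fit <- te_tab |> filter(translation_coupled) |> fit_coupling()
fit
#> Coupling-model fit (exhaustive integer grid, least squares)
#> Ribosome-RNAP coupling model parameters
#>   TE0   : 0.901
#>   alpha : 27 nt (inclusive convention)
#>   lambda(d) = d + c with c: W = 15, R = 7
#>   rss = 0.000309585 on 20 points (none weights)

autoplot(fit)       # measured points + fitted TE-distance curves
```

The fit recovers the generating parameters: an occlusion threshold of 27 nt
and per-series offsets of 15 and 7 nt. The mechanistic simulator gives the
same phenomenology from kinetics alone:

```r
te_from_simulation(sim_config(distance_nt = 12), n_traj = 10000, seed = 7)
#> # A tibble: 1 × 3
#>       te       se n_traj
#> 1 0.0034 0.000582  10000
```

At a 12-nt spacer the simulated ribosome almost always sits within 27 nt of
the hairpin when RNAP arrives, so termination is nearly abolished — the
mechanistic curve is steeper than the Poisson-smoothed analytic model, which
absorbs kinetic heterogeneity into the distance distribution (see the
methods vignette).

## Input formats

- Measurements CSV: `construct_id, replicate, time_min, od600, f_rfp, f_gfp`
  (long format; `#` lines are metadata). Read with `read_measurements()`.
- Construct table CSV: `construct_id, series, distance_nt, rfp_modified,
  translation_coupled, is_reference`. Read with `read_construct_table()`.
- Fits are serialized to JSON (`write_fit()`/`read_fit()`), TE tables and
  simulator samples to CSV with `#` metadata headers.

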