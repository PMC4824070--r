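---
title: "Termination efficiency under transcription–translation coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Termination efficiency under transcription–translation coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termeff)
```

# The problem

Intrinsic (Rho-independent) terminators end bacterial transcription through
a GC-rich RNA hairpin followed by a U-tract. Because transcription and
translation are coupled in bacteria, the pioneer ribosome trails RNAP on the
nascent transcript; if the terminator hairpin begins only a few nucleotides
downstream of the upstream gene's stop codon, the ribosome parked at the
stop codon can sequester part of the hairpin sequence and prevent folding,
so RNAP reads through. With a longer spacer the ribosome can no longer
reach, and termination efficiency (TE) recovers to the terminator's
intrinsic maximum. `termeff` implements the three layers of this analysis —
reporter quantification, an analytic coupling model, and a mechanistic
simulator — plus the synthetic-data generators that make the whole pipeline
testable end to end.

# Reporter quantification

The measurement design places a terminator between two fluorescent reporter
genes (upstream RFP, downstream GFP) behind one promoter, with an insulator
before the downstream RBS so the spacer under study cannot affect downstream
translation. TE is the fraction of RNAPs that terminate, read out as the
deficit of downstream synthesis:

$$\mathrm{TE} = 1 - \frac{P_\mathrm{GFP}/P_\mathrm{GFP,ref}}
                        {P_\mathrm{RFP}/P_\mathrm{RFP,ref}},$$

with a terminator-free reference construct defining TE = 0. Normalizing each
channel by the reference cancels differences in translation efficiency and
fluorophore brightness between the two proteins; normalizing GFP by RFP
cancels promoter activity and copy-number variation. For constructs whose
RFP gene was modified (different 3′ end, different fluorescence), the
GFP-only form $\mathrm{TE} = 1 - P_\mathrm{GFP}/P_\mathrm{GFP,ref}$ is used
instead; it coincides with the dual form exactly when RFP expression matches
the reference.

Per-cell synthesis rates come from exponential-phase balanced growth:

$$P = \mu f \left(1 + \frac{\mu\tau}{\ln 2}\right), \qquad
  f = \frac{\partial F}{\partial OD},$$

where $\mu$ (min⁻¹) is the growth rate from a log-linear OD fit, $f$ is the
OLS slope of background-subtracted fluorescence against OD, and $\tau$ (min)
is the fluorophore maturation half-time. Under balanced growth a two-pool
(immature → mature) maturation model gives mature fluorescence proportional
to OD with slope $P/(\mu(1+\mu\tau/\ln 2))$; the correction factor exactly
inverts the maturation lag.

Choices a user should know about:

- **Exponential window.** `select_exponential_window()` takes the longest
  contiguous run with OD600 in [0.02, 0.3], then trims end points until the
  ln(OD) regression reaches R² ≥ 0.99. All bounds are arguments.
- **Maturation half-times.** Defaults are $\tau_\mathrm{GFP}$ = 15 min and
  $\tau_\mathrm{RFP}$ = 40 min, applied per channel — typical magnitudes for
  fast-maturing GFPs and slower red fluorophores. Because both TE formulas
  are ratios against a reference measured with the same $\tau$, the TE
  estimate is insensitive to the absolute values as long as construct and
  reference share them; $\tau$ matters only for absolute synthesis rates.
- **One $\mu$ per culture.** The growth rate is estimated once from OD and
  shared by both channels; it is a property of the culture, not the channel.
- **Background.** A constant per-channel background is subtracted before the
  $f$ regression; default 0 (the generator emits background-free signal).
- **Replicates.** TE is computed per replicate against the mean reference
  rates, then aggregated as mean ± SE.
- **Negative TEs** are reported, not clipped: under noise a construct can
  read out slightly below the reference, and clipping would bias the
  downstream fit.

# The analytic coupling model

At the moment RNAP reaches the terminator, let $X$ be the distance (nt)
between the pioneer ribosome and the first base of the hairpin stem. The
model assumes the ribosome occludes hairpin folding iff $X \le \alpha$, and
that $X$ is Poisson with mean $\lambda(d) = d + c$, where $d$ is the spacer
length and $c$ a series-specific offset absorbing sequence-dependent
elongation dynamics:

$$\mathrm{TE}(d) = \mathrm{TE}_0\,[1 - \mathrm{CDF}(\alpha, d + c)].$$

- $\mathrm{TE}_0$ — the terminator's maximal efficiency (0.9 for phage λ
  tR2), reached when the ribosome cannot interfere.
- $\alpha$ — the occlusion threshold, 27 nt for this system: roughly the
  ribosome's downstream footprint plus the free mRNA the hairpin needs to
  fold.
- $c$ — per-series offset: 15 nt for the natural upstream sequence series
  (W), 7 nt for the designed random-spacer series (R). A larger $c$ shifts
  the ribosome distribution away from the hairpin and raises TE at equal
  $d$; this is the direction in which the two measured series differ.

**Equality convention.** The verbal model is ambiguous about repression at
exactly $X = \alpha$. The default (`"inclusive"`) represses iff
$X \le \alpha$; `"strict"` represses iff $X \le \alpha - 1$. The two differ
by one Poisson mass point and both are exposed; every headline conclusion
holds under either.

**Fitting.** `fit_coupling()` does exhaustive integer grid search,
$\alpha \in [0, 60]$ and $c \in [-10, 40]$ by default (wide enough to
bracket any footprint-plausible geometry), because the objective is ragged
in the integer parameters and a grid keeps the optimum global and
deterministic. At each grid point TE₀ has the closed-form conditional
least-squares solution
$\hat{\mathrm{TE}}_0 = \sum w_i t_i m_i / \sum w_i m_i^2$ with
$m_i = 1 - \mathrm{CDF}(K, d_i + c_{s(i)})$, clamped to [0, 1]. Ties are
broken toward the smallest $\alpha$, then the smallest offsets in series
order, so the fit is reproducible. Weights are optional ($1/\mathrm{SE}^2$);
the default is unweighted, since replicate SEs from small $n$ are noisy.
Grid points where some $d + c < 0$ are invalid (a Poisson mean cannot be
negative) and are skipped rather than clamped; a grid on which every
predicted mass $m_i$ is zero is reported as unidentifiable. TE₀ is shared
across series (the two measured series plateau at the same maximum). The
Poisson is used untruncated: the stop codon in reality bounds $X$ from
below, but the analytic model deliberately stays with the plain Poisson and
leaves the bounded distribution to the mechanistic simulator.

**Uncertainty.** `bootstrap_ci()` case-resamples constructs (within series,
preserving series sizes) and refits; percentile 95% intervals. Degenerate
resamples are skipped and counted.

# The mechanistic simulator

`simulate_coupling()` grounds the Poisson approximation in kinetics: a
continuous-time Markov (Gillespie) simulation of one RNAP and the pioneer
ribosome with exponential waiting times. Since only event order matters for
the recorded outputs, the embedded jump chain is simulated (no clock). The
trajectory loop is C++ (Rcpp) drawing from R's RNG, so `set.seed()` gives
bit-identical trajectory sets; a single sequential stream is used (no
parallel substreams).

Moves and constraints:

- RNAP advances 1 nt at rate `k_rnap` (30 nt/s default), overridable per
  position via `pause_sites` (the rate of stepping *out of* a position).
- The ribosome advances one codon (3 nt) at rate `k_ribosome` (15 codons/s
  default — 45 nt/s, intrinsically faster than RNAP, which is what makes
  coupling tight in coding regions), with per-A-site overrides
  (`ribosome_pause_sites`), and halts when the stop codon enters the A site.
- **Steric exclusion**: the A site plus ~10 nt of downstream protection may
  never enter the ~12 nt of mRNA sequestered by RNAP (4–5 nt protected plus
  7–8 nt in the DNA:RNA hybrid).
- **Initiation**: once RNAP has cleared both the RBS and the exclusion zone
  of a freshly placed ribosome, initiation fires at `k_init` (1/1.5 s). The
  gate consistent with exclusion is
  `max(rbs_end, A_init + down_protect) + rnap_protect`; with the default
  geometry RNAP is 30 nt past the RBS when initiation first becomes
  possible, and the mean head start is that offset plus
  `k_rnap/k_init` ≈ 45 nt of transcription during the initiation wait —
  75 nt in total. A gate at `rbs_end + rnap_protect` alone would place the
  new ribosome inside the RNAP zone and violate exclusion.
- When RNAP reaches the decision point (hairpin start + hairpin length
  24 nt + U-tract 8 nt by default), $X$ = hairpin start − A-site position is
  recorded ($+\infty$ if no ribosome initiated) and termination is drawn:
  Bernoulli(TE₀) if $X$ exceeds the threshold, Bernoulli(`readthrough_floor`,
  default 0) otherwise. Hairpin-folding kinetics are deliberately abstracted
  into TE₀ and $\alpha$.

Conventions surfaced as knobs rather than guessed: the ribosome reference
point for $X$ (`"a_site"` default, `"leading_edge"` = A site + downstream
protection — the $\alpha$ threshold absorbs the offset, so the two are
jointly calibrated), and the repression equality convention shared with the
analytic model. At initiation the A site sits on the second codon
(start + 3), and the ribosome halts with the stop codon in the A site, so
the minimal recorded distance is $d + 3$. `catch_up_pos` records the first
A-site position at which the ribosome — having advanced past initiation —
is sterically blocked; contact at the initiation instant itself is the gate,
not a catch-up, which is why a slow ribosome reports catch-up as essentially
absent rather than a burst of spurious contacts at the start codon.

At default rates the simulated ribosome catches RNAP within roughly
100–200 nt and then tracks it to the stop codon, so the distance
distribution at RNAP arrival piles up at the stop-codon bound with a lagging
tail — visibly non-Poisson (the mean/variance ratio reported by
`poisson_adequacy()` departs from 1) — and the mechanistic TE–distance curve
is steeper than the analytic one. This is the
expected relationship: the analytic model's Poisson distribution absorbs
cell-to-cell kinetic heterogeneity (initiation timing, sequence-dependent
pausing) that the single-rate simulator deliberately omits.
`poisson_adequacy()` (method-of-moments fit, χ² with bins pooled to expected
counts ≥ 5) is diagnostic output, not an assertion.

# Synthetic data

The generators define the study conditions for every test:

- `make_construct_panel()` — a W-like series spanning 8–48 nt, an R-like
  series spanning 9–59 nt (the measured panels' ranges), one terminator-free
  reference, and uncoupled variants (RBS deleted; ground truth TE₀ at any
  distance, since uncoupling abolishes ribosomal repression). Coupled ground
  truths lie on the model curve.
- `make_growth_series()` — OD600 every 30 min through exponential growth
  (μ = 0.01 min⁻¹, a ~70-min doubling typical of minimal-medium growth; OD
  0.005 → 0.4 so the 0.02–0.3 analysis window is well populated), with
  fluorescence from the two-pool maturation model so that the quantifier
  recovers the generating TE exactly at zero noise. Noise is multiplicative
  lognormal on OD and fluorescence (scale-proportional instrument noise;
  defaults 1% OD, 2% fluorescence, 3 replicates — chosen to match typical
  plate-reader replicate scatter).
- `make_te_table()` — model curve plus additive Gaussian noise (σ = 0.02
  per replicate), matching replicate-level TE scatter.

What the generator deliberately does **not** emulate: lag and stationary
phase, evaporation and plate-position effects, plasmid copy-number
variation, mRNA-stability differences between constructs, and autofluorescence
drift. Passing round-trip tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to those real-world
artifacts.

# Spacer design

`design_spacer()` rejection-samples uniform random DNA against three fatal
screens — GC fraction ≤ 0.5, no G/C run > 3, and no k-mer (k = 6) whose
reverse complement occurs in a supplied hairpin arm or downstream in the
spacer itself with a foldable ≥ 3-nt loop — plus a non-fatal warning for
Shine–Dalgarno-like motifs (AGGAGG with an ATG 4–12 nt downstream, a
heuristic for accidental internal initiation sites). Complementary-k-mer
screening is a deliberate proxy for thermodynamic folding: the design rules
are qualitative (low GC, short GC runs, nothing that base-pairs with the
hairpin), and a full MFE folder can be swapped in behind the same report
interface. The loop requirement keeps palindromic k-mers overlapping
themselves (e.g. poly-AT) from being miscounted as structure.

# Problem sizes and numerics

Default analysis sizes keep the full suite fast: grid fits evaluate
61 × 51 × 51 parameter combinations over ~300 data points in well under a
second (per-series sufficient statistics are precomputed per α as matrix
products); simulator checks use 10⁴ trajectories per condition (binomial SE
≈ 0.003 near the plateau, ~1 s per condition in C++); bootstrap examples use
B in the low hundreds on reduced grids. The Poisson CDF is evaluated through
the regularized incomplete gamma function (`stats::ppois`), which matches
direct pmf summation to 10⁻¹² over the whole relevant range (λ ≤ 100,
k ≤ 200).

# Known limitations

- The analytic model is phenomenological: $c$ is fitted per series, not
  derived from sequence; hairpin thermodynamics, Rho-dependent termination
  and RNAP backtracking are out of scope.
- Only the pioneer ribosome is simulated; trailing ribosomes and
  polysome-scale exclusion effects are not.
- α and c are strongly anti-correlated along the fitted curve (shifting both
  by one nearly preserves predictions), so single-parameter bootstrap
  intervals should be read jointly.
- The GFP-only TE assumes the modified construct's upstream mRNA level
  matches the reference; validating that (e.g. by qPCR) is outside the
  package.
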