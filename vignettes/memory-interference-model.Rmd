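---
title: "A two-pathway control-theory model of memory and interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-pathway control-theory model of memory and interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memflex)
```

## The model and its assumptions

`memflex` implements a deliberately coarse ("toy") control-theory model of
how the hippocampus balances memory consolidation against active
forgetting, and of why strengthening one memory can impair the next. Its
ingredients:

1. **Experience as a step input.** A learning experience is a brief
   stimulus; hippocampal activity integrates it into an output that is
   long-lasting on the timescale of the experiments (days). We therefore
   model the drive as an ideal step of magnitude $u$ switched on at the
   training time and persisting thereafter. The pulse width never appears:
   only the resulting step magnitude matters, and $u$ is a free parameter
   varied over a stated range rather than estimated from data.

2. **Two parallel first-order pathways.** The step drives a fast
   *memory-strengthening* process $x_1$ (transcriptional activators such as
   CREB and EGR1) and a slow *memory-weakening* process $x_2$ (repressors
   such as WT1), each governed by
   $\tau_i \, \dot x_i = -x_i + K_i\,u(t)$. Both start at zero — the animal
   is naive, with no residual signalling from earlier experiences.

3. **A single saturation.** Net drive is the difference passed through the
   model's only nonlinearity: pathway activity
   $\mathrm{PA} = \mathrm{sat}(x_1 - x_2,\,0,\,1)$. Negative transients are
   clipped here and only here; the linear states themselves are never
   clipped, so superposition still holds upstream of the saturation.

4. **Finite effectors.** A fixed pool of downstream effectors reads out
   pathway activity: $\mathrm{Effectors\ Available} = 1 - \mathrm{PA}$.
   For several events, each event $i$ drives its own $(x_1, x_2)$ pair; the
   aggregate activity that consumes effectors is the *sum* of the per-event
   differences passed through one saturation (sum-then-saturate — consistent
   with the single stated nonlinearity), while each event's own PA is
   saturated separately where it enters the memory formula.

5. **Memory via have/need.** The peak PA an event would reach in isolation
   is the capacity it *needs* to be fully learned; the effectors free at
   its stimulus onset — computed from prior events only — are what the
   circuit *has*. Memory attributable to event $i$ is
   $$\mathrm{Memory}_i(t) = \frac{\mathrm{PA}_i(t)}{\max \mathrm{PA}_i}
     \cdot \min\!\left(\frac{have}{need_i},\,1\right).$$
   The ratio is capped at 1: surplus effectors never amplify a memory, they
   only fail to penalise it. In the alternative `"excess"` effector mode the
   weight is identically 1, which is the model's statement of what behaviour
   looks like when capacity is *not* limiting.

Two design points were genuinely open and are fixed as follows. *have* is a
scalar evaluated at the event's onset, not a time-varying signal: the weight
multiplies the whole normalised trajectory, and a time-varying have would
leave the scalar ratio in the memory formula undefined at test time. And the
2.4-fold effect of losing WT1 function is applied to the gains
($K = 7.2$ vs $3$) rather than to $u$; in this linear structure the two are
indistinguishable, so the input sweep explores both readings at once.

## Parameters

| parameter | meaning | default (control / wt1d) | units |
|---|---|---|---|
| `tau1` | strengthening time constant; fast, WT1-independent | 0.5 / 0.5 | h |
| `tau2` | weakening time constant; slow, prolonged by WT1 loss | 36 / 144 | h |
| `K1`, `K2` | steady-state gains (signal amplification) | 3 / 7.2 | — |
| `u` | step-input magnitude, shared by all memory tests | 0.125, swept 0.025–0.15 | — |

With these values a single event's $x_1 - x_2$ peaks at
$t^\* = \ln(\tau_2/\tau_1) / (1/\tau_1 - 1/\tau_2)$ — about 2.17 h (control)
and 2.84 h (wt1d) after training — giving `need` 0.348 and 0.879. At the
nominal $u$, the knockdown sits close to the saturation ceiling
($K u = 0.9$), which is why its first memory is both strong and expensive.

```{r headline}
ctrl <- default_parameters("control"); wt1d <- default_parameters("wt1d")
run_protocol(built_in_protocol("sequential-short"), wt1d)$tests
run_protocol(built_in_protocol("sequential-short"), ctrl)$tests
```

The built-in protocols mirror the behavioural designs the model was built
to probe: novel object location followed by contextual fear conditioning
either 48 h later (train day 0, test day 1, second training the next day)
or 240 h later, with memory always read 24 h after each training. The
interference penalty $1 - \min(have/need, 1)$ for the second task decays
with the interval, vanishing by ten days.

## Numerical choices

- **Closed form first.** Step inputs admit the exact solution
  $K u (1 - e^{-(t-t_{on})/\tau})$, which the engine uses everywhere;
  `integrate_first_order()` (fixed-step RK4 via `deSolve`) exists for
  arbitrary inputs and as the numerical cross-check — the two agree to
  better than $10^{-6}$ over 0–300 h at a 0.01 h step (the test suite's
  independent oracle is a separate hand-written RK4 loop).
- **Grids.** The default trajectory grid step is 0.01 h, resolving
  $\tau_1 = 0.5$ h; the horizon is the last test time + 24 h. Test-time
  memories are computed in closed form, so grid resolution affects only the
  exported trajectories.
- **Degenerate inputs.** An event with $u = 0$ has `need = 0` and its
  memory is explicitly undefined (an error from `memory_trajectory()`, an
  `NA` with `defined = FALSE` in sweep tables) rather than a silent 0/0.
  Sweeps warn when $u > 1/K$, where the saturation ceiling begins to bind.
- **Ranking ties** in enrichment are broken alphabetically by TF name, and
  the DEG fold-change and FDR boundaries are inclusive
  ($q \le 0.05$, $|\log_2 \mathrm{FC}| \ge \log_2 1.3$, checked with a
  $10^{-12}$ guard against floating-point representation of the boundary).
- **Determinism.** Every stochastic routine takes a seed and uses an
  isolated RNG stream (`withr::with_seed`), leaving the global RNG
  untouched; pipeline CSVs round numerics to 12 significant digits so
  identical runs are byte-identical.

## What the synthetic data emulate — and what they do not

The package ships no behavioural or sequencing data; its test surface is
synthetic by construction.

**Cohorts.** `generate_cohort()` maps model memory onto behavioural scales
through an affine link — freezing 0–100 %, place preference 50–100 % with
50 % as chance — plus truncated Gaussian noise (default sd 5 %). The link is
declared plumbing: the underlying studies never state a mapping from a
latent memory variable to percent freezing, and the simplest monotone link
suffices for ordering and recovery checks. The synthetic cohorts therefore
reproduce group means, orderings and noise levels, but none of the
structure of real behavioural data (per-animal baselines, floor effects at
low freezing, session-to-session correlation), so passing tests validate
the model arithmetic and the estimation machinery — not the biology.

**Parameter recovery.** `recovery_study()` simulates cohorts at the
WT1-deficient truth and re-estimates $(K, \tau_2)$ by exhaustive grid
search on the squared error of group means. The design matters: a single
sub-saturation memory trajectory is *uninformative about* $K$ — the
normalisation by peak activity cancels it — so the default design observes
the sequential-short schedule at +6, +24, +72 and +168 h, where the
interference penalty depends on $K u$ directly and late readouts pin down
$\tau_2$. Degenerate designs (one time point, one genotype) are flagged
`non_identifiable` via a ridge test on the loss surface: a near-optimal set
spanning most of a parameter's grid range. Defaults: $n = 30$ animals,
noise 5 %, grids $K \in [3, 12]$ step 0.3 and $\tau_2 \in [48, 288]$ h step
6, truth on-grid.

**Enrichment.** `simulate_enrichment_data()` builds a universe of 2000
symbols, 20 TF target sets of 100, and 150 DEGs drawn with 4× weight on one
spiked TF's targets. This plants a clean, single-source signal; real TF
libraries have heavily overlapping, size-skewed sets and real DEG lists
carry correlated co-regulation, so the planted-signal detection rate speaks
to the scoring arithmetic, not to the recall of any particular database
version. Reproducing an actual published TF ranking additionally depends on
the TRANSFAC/JASPAR snapshot and the homology tables used, which is why it
is out of scope here.

## Problem sizes

Simulations evaluate closed forms on grids of $\sim 3\times 10^4$ points;
the Monte-Carlo studies use 100 replicates each (cohorts of 30 animals;
enrichment problems of 2000 genes), with the grid-search predictions
vectorised over all $41 \times 31$ candidates at once. A full test run and
the acceptance script each complete in well under a minute of compute per
stage on one core.

## Known limitations

- The model is linear up to one saturation; it cannot express extinction,
  reversal learning, or any interaction between events beyond competition
  for effectors.
- `have` is frozen at stimulus onset; effectors freed *during* an event's
  consolidation window do not rescue it.
- No fitting of $\tau$ or $K$ to electrophysiology is attempted — the
  2.4-fold gain factor is taken as given — and the input magnitude $u$ has
  no empirical anchor, hence the sweep.
- The enrichment stage scores raw right-tailed p-values, matching the
  $-\log_{10} p$ ranking convention it reimplements; a Benjamini–Hochberg
  column is available (`adjust = TRUE`) but never alters the ranking.
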