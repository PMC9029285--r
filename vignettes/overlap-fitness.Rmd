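---
title: "Overlap fitness metrics for ssDNA ecosystems: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap fitness metrics for ssDNA ecosystems: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandfit)
```

## The model

`strandfit` treats short single-stranded DNA oligomers as individuals of a
minimal ecosystem: long "predator" strands compete to hybridize with a
shorter "resource" strand, and a predator's fitness is the strength of the
best duplex it can form with the target. The fitness metric is purely
combinatorial — no thermodynamics, no nearest-neighbour free energies, no
melting temperatures. That is a deliberate modelling choice: the metric is
meant to be a transparent, discrete proxy for binding strength that can be
computed exactly from sequence alone and compared directly against
per-frame hydrogen-bond records from coarse-grained simulations.

Two strands of lengths $L$ and $l$ are laid antiparallel: strand 1 is
written 5′→3′ left-to-right, strand 2 is written 3′→5′ left-to-right, and
an integer register $r \in [-l+1,\, L-1]$ shifts strand 2's left end
relative to strand 1's. This gives exactly $L + l - 1$ admissible
registers. At each register, with only canonical pairings (A/T, C/G)
counted:

* $\mathrm{MCO}|_r$ — the longest run of consecutive complementary
  opposing bases;
* $\mathrm{TMO}|_r$ — the total number of complementary opposing bases,
  so $\mathrm{TMO}|_r \ge \mathrm{MCO}|_r$ always;
* $\omega = \max_r \mathrm{MCO}|_r$ — the fitness statistic.

Only the antiparallel register is scored. Physical DNA duplexes are
antiparallel, and it is also the convention under which $\omega$ equals
the longest common substring between strand 1 and the reverse complement
of strand 2 — an identity the package uses for independent verification:
`omega_oracle()` computes that substring length by exhaustive
substring-set comparison, sharing no code with the register scan in
`overlap_profile()`, and the two are required to agree on every input
(property-tested on thousands of random pairs). Parallel-register
complementarity, if a bond list ever contains it, contributes to TMO but
never to MCO.

### Degenerate windows

The maximum $\omega$ frequently occurs at several registers or positions.
Rather than picking one arbitrarily, `overlap_profile()` enumerates every
maximal run of length $\omega$ and reports them in a deterministic
$(r, \mathrm{start1})$ order. Window coordinates are 0-based 5′→3′ indices
on *both* strands (base `start1 + k` of strand 1 pairs base
`start2 + length - 1 - k` of strand 2), because a single-strand coordinate
plus a register is ambiguous the moment the reader forgets which strand
was reversed. For the bundled strands this matters: the weak predator p4
has two distinct $\omega = 4$ windows on the resource, and only one of
them overlaps the strong predator p10's unique $\omega = 10$ window — the
three shared resource bases (positions 9–11, `ACC`) are what make the
two predators compete for the same niche.

Self-affinity $\omega(s, s)$ is computed between two independent copies of
the sequence (an inter-strand duplex of a homodimer), not as intra-strand
folding; self-folding is a separate per-frame observable (`self_fold()`).

### Sequence design

`design_sequence()` produces a strand of length $L$ with a prescribed
$\omega$ against a resource by rejection sampling: embed the reverse
complement of a random resource window of the target length in a random
background, then verify the full profile and reject on any accidental
longer (or extended) window. Verification is unconditional because the
random background creates unintended windows with non-negligible
probability, especially for small target $\omega$. The search is seeded
and deterministic; the achievable range is $1 \le \omega_\text{target}
\le \min(L, l)$.

## Trajectory statistics

The analysis consumes the text formats of coarse-grained DNA MD engines:
a topology file (strand membership and backbone connectivity), an optional
configuration file (only headers and positions are read; orientations and
velocities are parsed and discarded), and per-frame hydrogen-bond pair
lists. Frames carry MD step stamps; with the default recording interval of
$10^3$ steps and the 15 fs/step conversion, $10^8$ steps ≈ 1.5 µs
(`steps_to_time()`).

Parameters that matter, with defaults:

* **Binding-event threshold** (`binding_events()`, default MCO ≥ 4
  consecutive paired bases): below four consecutive pairs two strands do
  not form an effective attachment — the bonds break too easily — so an
  event is a maximal run of frames at or above the threshold. Lifetimes
  are reported in MD steps with an exclusive end step, so
  `lifetime = end_step - start_step` equals frames × recording interval.
  Events touching either end of the trace are flagged censored: their
  lifetime is a lower bound, which keeps "at least $N$ steps" statements
  representable.
* **Complex edge rule** (`detect_complexes()`, default TMO ≥ 1): an edge
  in the strand-contact graph requires only one bond, because weakly
  attached "parasite" strands — a predator riding on a competitor that is
  itself bound to the resource — are exactly the structures worth
  detecting. A stricter MCO ≥ k rule is available. Components are labelled
  by species multiset (e.g. `p10+p4+2xres` for a bridged tetramer), with
  an optional `species` vector so replicate strands share a label.
* **Self-fold loop minimum** (`self_fold()`, default `min_loop = 3`):
  intra-strand pairs separated by three or fewer backbone positions cannot
  close a physical hairpin loop and are excluded from counts.
* **Histogram zero bin**: "not bonded" is encoded as MCO = TMO = 0 and is
  always present as a bin, so the unbound fraction is read directly off
  the histogram. Frames are pooled across runs with equal weight.
* **Smoothing** (`ensemble_timeseries()`): off by default; a centred
  moving average is opt-in, so the default output is the raw pointwise
  mean over runs.

Per-frame MCO requires strict antiparallel register among the recorded
bonds (local positions $(i+k, j-k)$), which guarantees the invariant
that a frame's MCO never exceeds the pair's sequence-level $\omega$.
Bonds a strand forms with third parties never enter a pair's statistics;
whether that is the right treatment of indirectly mediated contact is a
genuinely open choice, and the package resolves it in favour of direct
bonds only, leaving indirect association to the complex report.

## The synthetic generator

Validating the pipeline needs trajectories with known ground truth, which
an MD engine cannot provide. `generate_trajectory()` therefore emulates
the *statistical* structure of bond trajectories, not their physics:

* each strand pair alternates between unbound and bound sojourns with
  geometric dwell times (chosen for analytic tractability — the mean is
  the single parameter, and thresholded event lengths are geometric too);
* at each bound sojourn a run length is drawn from the configured
  stationary distribution, one of the pair's degenerate $\omega$-windows
  is chosen, and the run is placed uniformly inside it; the unbound-dwell
  mean is derived from the bound-dwell mean and the stationary unbound
  probability, so empirical state frequencies converge to the configured
  ones;
* isolated extra complementary pairs (never adjacent to the run or to
  each other) are added per frame at a configurable rate, so TMO > MCO
  occurs without perturbing MCO;
* pairs evolve independently, except that (i) explicit exclusion rules
  forbid two pairs' runs from occupying the same bases of a shared
  strand — the winner is the pair listed first, determinism over realism —
  and (ii) residual one-bond-per-base conflicts are resolved in
  configuration order with every dropped bond logged.

Every sojourn, exclusion and conflict is recorded in a ground-truth log,
and fixture files in the simulation text dialects are byte-stable under a
fixed seed (`make_fixture_files()`).

What the generator does *not* emulate: 3D geometry, excluded volume and
crowding, sequence-dependent kinetics, the relaxation phase of an MD
protocol, and any coupling between TMO and binding stability. Passing
recovery tests therefore shows that the *analysis* is correct — that
histograms, event lifetimes and occupancies faithfully measure what is in
a bond trajectory — not that real MD output has the presets' statistics.

### Preset parameter choices

The shipped presets encode the qualitative binding behaviour of the
bundled strand set as stationary probabilities: `p4res` (unbound 25% of
frames, full $\omega$-run 60%, remainder on shorter runs), `p10res`
(run $\omega$ 55%, run $\omega-1$ 30%), `p4p10` (run 7 at 55%), and
`competition3`, where the p10–res pair (unbound 25%) excludes p4–res from
the shared resource bases — since every p4 window lies inside p10's
window span, p4 can only bind while p10 is detached, which is what makes
its recovered bound fraction collapse relative to the two-strand preset
while p10's barely moves.

Bound-dwell means are 10 frames for p4–res, 50 for p10–res and 30 for
p4–p10 (at the default recording interval, $10^4$, $5 \times 10^4$ and
$3 \times 10^4$ MD steps). The ordering mirrors the physical picture — a
4-bp duplex is short-lived, a 10-bp duplex persists — while keeping
sojourns short enough that a $10^4$-frame trajectory contains hundreds of
independent binding cycles, the sample size the package's statistical
validation uses: stationary probabilities are checked to ±0.02 and mean
event lifetimes to ±10% at $10^4$ frames. Substantially longer dwells
would be *more* realistic for the strong binder but would leave too few
cycles to validate against.

## Numerical and degenerate-input conventions

* Tie-breaks: windows sort by $(r, \mathrm{start1})$; components are
  ordered by their first strand's topology index; conflicting bonds are
  resolved by configured pair priority.
* A base listed in two bonds of one frame keeps its first bond; the
  duplicate is dropped with a warning (bond lists from upstream tools
  occasionally contain them).
* Empty frames, empty pair lists and all-unbound configurations are valid
  inputs everywhere and yield zeros, not errors; an empty trace is an
  error only where a probability would be 0/0 (`overlap_histogram()`).
* Uppercase coercion on input; RNA letters and IUPAC ambiguity codes are
  rejected with the offending symbol named, never silently mapped.
* Strand global indices are 0-based and strand ids 1-based, matching the
  topology dialect; all public reports use strand names and 0-based 5′→3′
  local coordinates.

## Known limitations

* The fitness metric ignores stacking, mismatch context, bulges and
  loops; two windows with equal $\omega$ can differ thermodynamically.
* Gapped or bulged alignments are out of scope; the metric is strictly
  ungapped.
* The contact-graph edge rule treats one bond and nineteen bonds alike
  unless the MCO rule is chosen; occupancy fractions are per-component
  tallies, not free energies.
* The generator's independence and exclusion assumptions are stylized;
  recovered statistics validate the measurement pipeline, not MD physics.
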