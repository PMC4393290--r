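---
title: "Profiling DNA twist flexibility and calling flexibility peaks"
author: "twistflexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling DNA twist flexibility and calling flexibility peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistflexr)
```

## The model and its assumptions

Double-stranded DNA is not uniformly stiff: the ease with which the helix
twists about its axis depends on the identity of each dinucleotide step.
`twistflexr` models this with a 16-entry step table assigning each step XY
a twist-fluctuation magnitude $f(XY)$ in degrees. Physics imposes one hard
constraint, which the loader enforces: because both strands describe the
same helix, $f(XY) = f(\mathrm{revcomp}(XY))$, leaving ten free
parameters. The model is deliberately local — no coupling between
neighbouring steps, no dependence on flanking context — which is what
makes genome-scale profiling linear in sequence length and is the standard
assumption behind dinucleotide flexibility/bendability scales.

A window of length $L$ starting at 0-based position $p$ gets the
unweighted mean of its $L-1$ step values,

$$F(p) = \frac{1}{L-1}\sum_{i=p}^{p+L-2} f(s_i s_{i+1}),$$

assigned to the window's midpoint dinucleotide step. Windows advance by a
shift $s$. Only fully contained windows are evaluated, so a chromosome of
length $n$ yields exactly $\lfloor (n-L)/s \rfloor + 1$ values. Two
consequences worth knowing: every defined profile value is bounded by the
step-table extremes, and the profile of the reverse complement is exactly
the reversal of the profile (a direct corollary of table symmetry that the
test suite asserts on random sequences).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_len` ($L$) | 100 | bp | averaging window; sets the spatial resolution (values quantize at ~$L$ bp) |
| `shift` ($s$) | 1 | bp | window step; 1 gives the dense profile the peak caller expects |
| `preselect_sd_mult` ($k$) | 2 | — | preselection threshold $\mathcal{S} = \mu + k\sigma$ over all pooled windows |
| `peak_theta` ($\theta$) | 13.8 | deg | fixed peak threshold, the flexibility-island cutoff established in the fragile-site literature |
| `min_len`, `min_purity` | 20 bp, 0.8 | | AT tandem-repeat detector: minimal tract length and phase-match fraction |
| `score_min` | 945 | reads | poly(A) site intensity cutoff ("intense" cleavage sites) |
| `max_dist` | 500 | nt | maximal site-to-repeat-midpoint distance retained |

$\mu$ and $\sigma$ are computed once from **all** defined windows of all
chromosomes, with the population ($n$) denominator — the threshold is a
property of the genome-wide value distribution, not of any one
chromosome, and per-chromosome statistics would make peak calls depend on
how the assembly happens to be split. $\mathcal{S}$ is where the pooled
distribution's upper tail departs from a Gaussian of matched mean and
standard deviation (`value_distribution()` quantifies this as the excess
tail mass), which is why preselection is data-driven while $\theta$ is
fixed.

Boundary conventions are resolved as: preselection keeps windows with
$F \ge \mathcal{S}$ (the threshold is itself "not lower than" language),
and a region is a peak when its maximum reaches $\theta$
($\max \ge \theta$). Ties sit on a measure-zero set for real data, but
tests need the determinism.

## The step table is an input

The packaged default table is a **synthetic reconstruction**, and its file
name says so. The historical laboratory-derived twist-fluctuation values
behind this kind of profiler are not redistributable in this package, so
the shipped table was built once to satisfy every structural constraint
the method needs — reverse-complement symmetry, strict positivity, TA the
softest step by a wide margin, G+C-only steps the stiffest, extremes
bracketing the [7, 16] degree range in which genome window values live —
and is not tuned further. Every number the pipeline produces on a real
genome is conditional on the table loaded; anyone reproducing published
genome-wide figures must load the original parameter set via
`load_step_table()` (a 10-line text file). All package tests and the
acceptance script use the shipped table against the synthetic generator,
where ground truth comes from the manifest, not from literature values.

## Peak calling and its conventions

Maximal runs of consecutive evaluated windows at/above $\mathcal{S}$
become regions; a missing (N-containing) window breaks a run, and no gap
merging is performed — "consecutive" means consecutive. The region
footprint is the union of member-window footprints,
$[\text{first start}, \text{last start} + L)$, so the minimal region
length is $L$ even for a single qualifying window; this is why called
peaks are always longer than the tracts that generate them (a 120 bp pure
(TA) tract under the default table typically yields a ~270 bp peak).
Peaks are named `peak<ROMAN>-<k>` with $k$ ascending along each
chromosome; the roman numeral comes from a user-supplied map, from a
`chr<ROMAN>` name, or from input order as a last resort.

## Annotation analytics

**InterORF classes.** Gaps between consecutive non-overlapping ORFs are
classed by flanking strands: `+ −` convergent (two 3' ends, terminator
territory), `− +` divergent (two promoters), equal strands unidirectional.
Terminal gaps are not classifiable (one flank missing) and overlapping ORF
pairs yield no gap; both are logged, not errors.

**Placement.** Priority telomere > rRNA > inside-ORF > interORF. A peak
is "inside" an ORF when at least half its length overlaps a single ORF —
the cutoff is configurable (`inside_frac`) because no principled value
exists; 50% makes the call unambiguous for the common case of a peak
mostly embedded in one gene. Wide interORF peaks can straddle a region
border, so the orientation class is inherited from the region containing
the peak **midpoint**: deterministic, one class per peak, which is what
class tallies need.

**UTR co-localization.** 3'UTR intervals extend `utr3_len` nt downstream
of each ORF's 3' end on its strand (5'UTRs mirrored upstream); lengths
come from a measured table, and ORFs absent from the table fall back to
the table's mean lengths — the same convention used when a few genes lack
measurements. A hit is $\ge 1$ bp of half-open overlap, so a peak between
convergent genes can legitimately score both flanking ORFs.

**AT tandem repeats.** The built-in detector scores every phasing of the
period-2 unit TA and the period-3 unit TTA (rotations of TTA and of its
reverse complement TAA are one family). Positions matching the phased
unit weigh $+(1-p)$ and mismatches $-p$ with $p$ = `min_purity`; the
detector reports all maximal scoring subsequences of that weight profile
(the Ruzzo–Tompa decomposition, computed in C++ with exact integer
weights so tie handling is deterministic and scan-direction invariant).
Every reported segment therefore starts and ends on matching positions
and has match fraction $\ge p$. Segments shorter than `min_len` are
dropped; overlapping candidates across phasings are resolved greedily by
match count; a winning segment with purity below 0.9 is labelled
`AT-rich` rather than a clean `(TA)n`/`(TTA)n`. Two accuracy notes: a
substitution within a few bp of a tract end necessarily pulls the
score-optimal boundary inward, and a coincidentally phased background
base extends it outward — on 50 bp tracts with 10% substitutions the
median boundary error is ~1 bp with >90% of boundaries within 5 bp, while
detection itself is 100%. When a RepeatMasker annotation is available it
takes precedence; the detector exists so the pipeline has no external
tool dependency.

**Poly(A) distances.** Sites with score $\ge$ `score_min` are measured to
the nearest in-peak repeat midpoint on the same chromosome (unsigned bp;
distances are unstranded because the underlying biology — cleavage sites
clustering around the repeat — is read out on both strands), retained up
to `max_dist`, and summarized as a 25 nt-binned histogram plus the
fractions within 25 and 100 nt.

## Statistics

`fisher_exact()` computes the two-sided p-value from first principles:
hypergeometric probabilities of all tables with the observed margins,
summing those at most as probable as the observed table (with the common
$1+10^{-7}$ relative tie tolerance). A zero margin means one
classification is degenerate: p = 1 by convention, logged.
`welch_t_test()` is the unequal-variance t with Welch–Satterthwaite
degrees of freedom — gene-group variances (e.g. half-lives) are not
plausibly equal, so the pooled-variance t is never used. Both are
cross-checked in the test suite against the independent base-R
implementations. Enrichment constructions (peak class counts vs genomic
background counts) are emitted alongside their p-values so the exact 2×2
tables can be audited; no multiple-testing correction is applied to match
the single-test reporting style of this analysis type. The half-life
comparison groups ORFs by whether a peak overlaps their 3'UTR and tests
overall and poly(A) half-lives separately.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` builds: i.i.d. background sequence at a configurable
GC fraction (0.38, yeast-like); stranded gene arrays whose internal gaps
realize a requested divergent:unidirectional:convergent mix (default
4:8:4 per chromosome, the canonical 1:2:1); (TA)$_{60}$ tracts planted at
a fixed offset inside the 3'UTR side of every second eligible
(non-divergent) gap; poly(A) sites at mixture offsets from tract midpoints
(75% uniform on [5, 25] nt, 25% on [26, 500] nt) with an 80/20
intense/weak score split; and lognormal half-lives with lower mean for
tract-hosting ORFs. Three generator choices deserve their rationale:

* **Tract length 120 bp**: with $L = 100$ at least one window lies fully
  inside the tract, so its value equals the pure-tract step mean — under
  the shipped table 15.0°, comfortably above $\theta$ — making planted
  peak recovery deterministic rather than statistical.
* **Every second eligible gap** (`plant_stride = 2`): planting in all
  eligible gaps would make repeat-carrying ORFs the majority of genes,
  inverting the situation the group statistics are meant for (peak ORFs
  are a small minority of a real genome); the stride keeps the flagged
  group a minority while preserving per-class coverage.
* **Default sizes** (3 × 100 kb, ~50 ORFs, 18 tracts): large enough that
  the pooled window statistics are stable and every analytic stage has
  non-trivial input, small enough that the full pipeline runs in a couple
  of seconds — these are the problem sizes the test suite and the
  acceptance script use.

What it does **not** emulate: higher-order sequence composition (isochores,
codon structure), nucleosome positioning, transcription, replication
timing, or repeat-length variability. Passing tests on this generator
demonstrate algorithmic correctness — thresholds derived as specified,
runs extracted exactly, classes and overlaps computed right, planted
signal recovered — not that any biological conclusion transfers to a real
genome, where the step table, annotation quality and genuine sequence
heterogeneity dominate.

## Numerical choices

* Window sums use a convolution filter (each window summed afresh in C),
  not a running cumulative difference: no cancellation error accumulates
  along a chromosome, and the profile matches a naive per-window oracle
  to $10^{-9}$.
* Midpoint of an even-length window is resolved by flooring:
  the assigned step index is $\lfloor (L-1)/2 \rfloor$, i.e. offset 49
  for $L = 100$. Deterministic and documented rather than ambiguous.
* Windows containing N are missing, break preselection runs, and are
  excluded from the pooled mean/σ — the step model defines no N
  parameters, and silent imputation would bias the genome statistics.
* The repeat scan uses integer weights (purity quantized at $10^{-6}$) so
  segment boundaries never depend on floating-point tie behaviour; the
  compiled scan is cross-checked against an independently written plain-R
  reference implementation in the tests.
* Degenerate inputs have defined behaviour: sequences shorter than $L$
  give an empty profile with a warning; a profile with no defined values
  is an error for `genome_stats()`; zero-variance samples give the
  documented p = 1 / p = 0 conventions; zero-margin tables give p = 1.

## Known limitations

* The shipped step table is a reconstruction (see above); genome-wide
  numbers on real assemblies are conditional on loading the original
  parameter set.
* Region footprints assume the union-of-windows convention; other
  implementations may report trimmed footprints, shifting lengths by up
  to $L$ and occasionally splitting/merging border-line peaks.
* The midpoint rule assigns exactly one interORF class per peak; a peak
  overlapping an ORF boundary by just under `inside_frac` is counted as
  interORF even though much of it lies in coding sequence.
* The repeat detector is purity-based, not alignment-based: it does not
  model insertions/deletions within a tract, and interleaved or composite
  repeats are resolved greedily.
* Fisher backgrounds must be supplied (or derivable from the annotation);
  when they are not, the corresponding test is skipped with a message
  rather than silently inventing a universe.
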