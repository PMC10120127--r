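---
title: "Models and methods behind crisprkas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprkas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the scientific model behind each stage of the
package, the tunable parameters and their defaults, the generative model of
the simulator, and the numerical and design choices made where the
underlying biology or common practice leaves the details open.

## The assay model

A Cas9 or dCas9 ribonucleoprotein engaged with its target forms an R-loop:
the sgRNA spacer pairs with the *target strand* while the *non-target
strand* — whose sequence equals the protospacer as written 5′→3′ — is
displaced as ssDNA. Kethoxal reacts with unpaired guanines only, so a site
is capturable only if the displaced strand exposes at least one G
(`count_exposed_guanines()`); an all-A/T/C protospacer strand is invisible
to the assay regardless of occupancy. After shearing to roughly 150–400 bp
and streptavidin capture, sequenced fragments cluster around occupied
sites with a characteristic strand asymmetry: fragment (plus-strand) 5′
ends accumulate to the left of the site and minus-strand 5′ ends to the
right, because every captured fragment must overlap the labeled base.
Active Cas9 additionally cleaves: the HNH domain cuts the target strand
bluntly 3 bp from the PAM, and the RuvC domain cuts the non-target strand
at two to three staggered positions, which phases read 5′ ends sharply at
the cut on both strands.

## Off-target search

`find_sites()` scans both strands of every contig for exact PAM matches
(IUPAC codes expand; no PAM mismatches, matching the common search-tool
default) and evaluates the adjacent protospacer:

- **Mismatch-only** (`max_bulge = 0`): every site within `max_mismatches`
  substitutions is reported. Genomic `N` never matches a spacer base and
  never satisfies a PAM position (conservative).
- **Single-bulge** (`max_bulge > 0`): per PAM locus, the search enumerates
  all alignments with at most one contiguous bulge — a run of extra
  genomic bases (DNA bulge) or skipped spacer bases (RNA bulge) — of at
  most `max_bulge` bases, anchored at the PAM-proximal end, and reports
  the minimal-cost alignment. Cost is lexicographic in (bulged bases,
  mismatches), so a bulge is never preferred when a substitution-only
  reading stays within budget; remaining ties prefer a DNA bulge over an
  RNA bulge and the bulge placement closest to the PAM. This tie-break is
  a package convention (no community standard exists); it is deterministic
  and is exactly mirrored by the test oracles.

Coordinates are 0-based half-open everywhere, including BED emission.
Mismatch and bulge offsets are distances from the PAM-proximal end
(1 = adjacent to the PAM). The predicted blunt cut sits 3 bp PAM-proximal
of the PAM (`pam_start − 3` on plus-strand sites, `pam_end + 3` on minus),
anchored to the PAM so it remains defined for bulged sites.

For specificity summaries (`mismatch_position_matrix()`), the seed region
is defined as the PAM-proximal half of the spacer (offsets 1–10 for a
20-nt spacer) and the distal region as the rest. The halves are a
convention chosen for symmetry; the seed/distal contrast is robust to the
exact boundary.

For genome-wide off-target *prediction* lists the default budget is
`max_mismatches = 4, max_bulge = 0`, a typical search-tool setting;
both are exposed as parameters.

## The simulator

`make_genome()` draws i.i.d. bases at a configurable GC content (default
0.41, mammalian-like) and plants protospacer+PAM cassettes with requested
mismatch offsets, bulges, strands, occupancies and cut fractions, spaced by
a margin (default 1000 bp) so fragments from neighbouring sites never mix.
Every planted site is verified by re-scanning with `find_sites()` at its
stated budget; a failure to recover it is a construction error, not a
warning.

`simulate_fragments()` implements the simplest generative model that
reproduces the assay's signatures:

- Fragment attempts split between sites (proportionally to occupancy,
  largest-remainder rounding) and background (`background_rate`).
- A site molecule is captured iff a per-exposed-G Bernoulli
  (`labeling_per_G`, default 0.5) succeeds for at least one bubble
  guanine; the captured fragment has uniform length in
  `fragment_length = c(150, 400)` and a uniform breakpoint constrained to
  overlap one labeled G. This is a modelling choice, not a measured
  labeling efficiency: it is the minimal mechanism that yields (a) zero
  signal for zero-G bubbles, (b) signal monotone in exposed-G count, and
  (c) the left/right strand asymmetry of 5′ ends.
- With `nuclease = "cas9"`, each captured molecule is cleaved with its
  site's `cut_fraction`. Cleaved molecules yield a left piece truncated at
  the blunt target-strand cut and a right piece starting at the non-target
  cut, whose offset is drawn from `cut_offsets = c(3, 4, 5)` bp from the
  PAM with weights `c(0.5, 0.3, 0.2)`. The offsets and weights are
  configuration (the biology fixes only "two to three positions"); pieces
  shorter than 20 bp are dropped as unsequenceable.
- Background is uniform; in `in_vivo` mode, intervals in
  `active_intervals` receive an additional `(active_fold − 1)×` rate so
  the total rate inside is exactly `active_fold×` the outside rate,
  emulating endogenous ssDNA over transcribed regions on both strands.
  The no-guide control is the identical generative process with all
  occupancies set to zero — note its library is smaller than the
  treatment when `background_rate < 1`; RPM normalization absorbs this.
- Duplicates are simulated by resampling emitted fragments with
  probability `duplicate_rate`, to exercise deduplication.

Randomness is organized into per-component streams derived from one master
seed (site *k*, background, duplicates each get their own derived seed),
so adding or removing a planted site never perturbs the background draws
and all outputs are byte-stable under a fixed seed.

What the simulator does *not* emulate: sequence-dependent shearing and
capture biases, chromatin accessibility, mapping artifacts and
mappability gaps, PCR stochasticity beyond exact duplication, and any
kinetics of binding or cleavage. Passing tests therefore demonstrate that
the *analysis* recovers the planted truth under the stated biochemical
model, not that the model captures every property of real libraries.

## Profiles and peaks

`read_set()` deduplicates at fragment level (identical contig, start, end,
strand), mirroring picard-style duplicate marking on pairs, and defines the
RPM denominator `|R|` as the post-deduplication mate count (a fragment
record contributes two mates). The minus-strand 5′ end of a record
`[start, end)` is `end − 1`; this convention is used everywhere.

`call_peaks()` scores sliding windows (default 300 bp, step 100 bp) by the
Poisson upper-tail probability of their record-start count against
`λ = max(global rate, local rates in 1/5/10-kb centred flanks)` scaled to
the window, applies Benjamini–Hochberg across all windows, merges
significant windows, and places the summit at the maximum of combined
fragment coverage (first position on ties). Taking the maximum over
several λ estimates makes the caller conservative by construction; on pure
background the fraction of windows with `p < α` stays below `2α` in the
test suite. The caller takes the read set rather than a finished RPM
track because the Poisson model needs integer counts, which an
RPM-normalized track no longer carries; the summit is still computed from
coverage.

The **asymmetry score** formalizes the manual curation shape: for an
anchor `p`, with `L⁺/R⁺` the plus-strand 5′ mass in
`[p − w, p)` / `[p, p + w)` and `L⁻/R⁻` the minus-strand analogues,
`score(p) = (L⁺ + R⁻ − R⁺ − L⁻) / (L⁺ + R⁺ + L⁻ + R⁻)`, maximized over
anchors in the peak. It is 1 for perfectly separated strands, 0 for
symmetric pileups, negated under strand swap, and undefined (flagged, not
scored) when every anchor window is empty. The curation threshold 0.5 and
half-window 100 bp are tunables, presented as this package's
formalization rather than anyone's published rule.

## Quantification

- `rpm_ot()` counts mates overlapping `[cut − 500, cut + 501)` (any
  overlap; both overlap-vs-containment and the window width are
  parameters) and divides by `|R| / 10⁶`.
- `rpm_diff()` is treatment minus control `rpm_ot` and may be negative.
- `c_score_track()` computes, at each position, the product of the
  plus- and minus-strand 5′-end RPM masses summed over the running 3-bp
  window `[i − 1, i + 1]`, truncating the window at contig edges.
- `classify_cut_vs_bind()` compares the maximal C-score within ±50 bp of
  the predicted cut against an empirical null built by permuting the
  per-base 5′ masses of both strands within that same window. The
  permutation preserves each strand's total windowed mass — i.e. the null
  is occupancy-matched by construction — while destroying phasing, which
  is cleaner than hunting for occupancy-matched windows elsewhere in the
  genome. A site is called `cut` above the 0.999 null quantile (2000
  permutations by default), `bind_only` otherwise, and `undetermined`
  below an occupancy floor (`min_rpm`, default 1 RPM) where the C-score
  carries no information. The calibrated call is this package's addition;
  the C-score itself is descriptive.
- `saturation_analysis()` subsamples records binomially (10 seeded sets
  per fraction by default), recomputes `rpm_ot`, and reports the mean ± SD
  proportion of sites within 20% (relative) of their full-depth value.
  Sites with zero full-depth occupancy are excluded (relative tolerance
  undefined) and counted. At fraction 1 the subsample is the identity, so
  the proportion is exactly 1 with SD 0.
- `indel_frequency()` walks CIGAR strings: a read contains an indel over
  position *p* iff a deletion spans *p* or an insertion occurs between *p*
  and *p + 1*; insertions are assigned to the reference base 5′ of the
  insertion point. The denominator at *p* counts reads whose alignment
  spans *p*.

## Numerical and testing choices

Dense per-contig double vectors back all tracks (desk-scale genomes of a
few Mb at most; sparse export via run-length-encoded bedGraph, printed at
full precision so round trips are exact). The test suite verifies the two
protospacer searches against independent oracles (an all-windows character
matrix comparison, and a string-surgery enumeration of bulged alignments
under the same documented tie-break), and the RPM/C-score formulas
bit-for-bit against brute-force evaluators. Stochastic properties
(asymmetry recovery, cleavage phasing, cut-vs-bind separation, peak
calibration and recovery, saturation monotonicity, occupancy-rank
recovery) run on seeded simulations with 2 × 10⁴ – 10⁶ fragments on
100–200-kb genomes — sizes chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick on one
core. The acceptance script uses the same machinery at slightly reduced
seed counts and reports every quantity it computes.

## Limitations

- The bulge model allows one contiguous bulge per site; sites with
  multiple separated bulges are out of scope.
- The peak caller is a deliberately simple local-lambda Poisson scheme —
  statistically the same idea as common ChIP-seq callers, but not a
  bit-for-bit reproduction of any of them.
- RPM quantification does not model copy-number or mappability variation;
  on real genomes a user-supplied blacklist (`filter_blacklist()`) is the
  only artifact control.
- In vivo signal is modelled as site signal plus elevated background over
  user-declared active intervals; real endogenous ssDNA landscapes are
  richer, so `rpm_diff` against a matched control remains essential.
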