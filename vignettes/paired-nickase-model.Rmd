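---
title: "Paired nickase geometry, TREX2 viability rules, and junction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired nickase geometry, TREX2 viability rules, and junction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairnick)
```

# The model

## Cut-site geometry

A SpCas9 target is a 20-nt protospacer followed by an NGG PAM on the
protospacer-bearing (nontarget) strand — a 23-bp footprint. Both nuclease
domains cut 3 bp 5′ of the PAM, between spacer positions 17 and 18. The
two nickase variants differ only in which strand they cut: D10A (RuvC
inactivated) nicks the target strand, the one base-paired with the sgRNA;
H840A (HNH inactivated) nicks the nontarget strand. All coordinates in
pairnick are 0-based and half-open; a nick junction `j` lies between
reference positions `j − 1` and `j`.

Two nicks on opposite strands define a double-strand break. With the
plus-strand junction `p` and minus-strand junction `m`:

* `p < m` → protruding 5′ ends, length `m − p`;
* `p > m` → protruding 3′ ends, length `p − m`;
* `p == m` → blunt;
* both nicks on one strand → no break at all (`same_strand`).

For two footprints on opposite strands whose starts differ by an offset
`d` (minus-strand footprint to the right for positive `d`), the inter-nick
distance is `|d − 11|` and the target overlap is `23 − |d|` when positive.
Consequences the package exposes through `overlap_series()`:

* D10A on overlapping PAM-in targets cuts blunt exactly at a 12-bp
  overlap and produces 3′ overhangs of `12 − overlap` nt as the overlap
  shrinks from 12 to 1 (0–11 nt).
* H840A produces 3′ overhangs along the complementary branch: overhang
  `overlap − 12` for overlaps 12–23 and `34 − overlap` beyond the
  23-bp coincidence point, i.e. 0–33 nt.
* Swapping D10A for H840A on the same site pair preserves overhang length
  and flips polarity; blunt maps to blunt.

One geometric fact the schematic sliding series glosses over: the most
deeply overlapping D10A placements (overlap 1–3 bp, overhangs 9–11 nt,
minus-strand offset 20–22) cannot exist in real DNA, because one target's
GG PAM bases would have to be the other target's CC. `overlap_series()`
tabulates them anyway — it is pure coordinate arithmetic — while
`make_reference()` refuses to plant them and raises an explicit
infeasible-layout error.

## Sequential nicking and the TREX2 rules

Overlapping targets cannot be occupied by both Cas9n–sgRNA complexes at
once, so the nicks must be laid down one after the other. Whether the
second nick can still be induced is decided by `second_nick_viability()`
from the position of the first nick relative to the second target,
applying four rules in order (distances in nt along the relevant strand,
from the first-nick junction to the PAM-proximal spacer edge of the
second site):

1. **Nick at or inside the second PAM** — the second ternary complex
   cannot be stabilised; never viable.
2. **D10A pairs**: a first nick on the second site's nontarget strand at
   ≤ 17 nt (`d10a_block_max_dist_nt`) from its PAM terminates target
   unwinding prematurely; nonviable.
3. **H840A pairs**: a first nick on the second site's target strand
   within 17 nt PAM-distal of the PAM leaves < 18 nt of PAM-proximal
   pairing; nonviable. The 18-nt floor (`min_pairing_nt`) is the pairing
   length generally required to activate the nuclease.
4. **TREX2 gap extension** (H840A first nicks only): an H840A nick frees
   the PAM-distal 17 nt of the nontarget strand inside the R-loop with a
   fresh 3′ terminus at the nick. TREX2, a non-processive 3′→5′
   exonuclease, chews this segment back — by at most 8 nt when supplied
   free (`free_trex2_max_degrade_nt`) and by at least 9 nt when fused to
   the nickase (`fused_trex2_min_degrade_nt`) — extending the nick into a
   gap. If the intact PAM-proximal pairing stretch of the second target,
   `distance − depth` clamped to [0, 20], drops below 18 nt, the second
   nick fails. D10A first nicks release no such segment, so the rule does
   not apply to them.

The arithmetic reproduces the two worked configurations that anchor the
parameter values: a first nick 22 nt from the second PAM fails under free
TREX2 (22 − 5 = 17 < 18 already at the minimal depth), while 26 nt
passes (26 − 8 = 18) — and the same 26-nt pair fails when TREX2 is fused
(26 − 9 = 17). Enumerating distances gives a free-mode viability
threshold of 18 + 8 = 26 nt.

Because the model does not know which sgRNA binds first,
`pair_viability()` evaluates both orderings and calls the pair workable
if either order succeeds. Fused-mode degradation is modelled at exactly
9 nt — the least-assumption worst case consistent with its lower bound.
An optional `degrade_depth` override supports sensitivity sweeps over
depths 0–17 nt.

`stimulation_prediction()` adds the empirical constraint that TREX2
stimulates mutagenic end joining only of 3′-overhanging ends and only
within a window of inter-nick distances, default 13–96 bp. The
variant-specific sub-windows observed at individual loci (14–81,
29–86, 13–43, 34–96 bp) travel along as annotations, not filters.

# Amplicon indel calling

`align_and_call()` performs an end-anchored global (Needleman–Wunsch)
alignment of each read to its reference amplicon via
`Biostrings::pairwiseAlignment`, with conventional amplicon scoring:
match +2, mismatch −3, gap open −6, gap extend −1, where a length-`L`
gap costs `open + (L − 1) · extend`. Gaps are mapped to
reference-coordinate deletion intervals and insertion events, and every
event is normalised VCF-style to its lowest reference coordinate, so all
shift-equivalent placements inside repeats collapse to one canonical
representative; canonicalization is idempotent. Substitution-only reads
are classed `unedited` — with these scores a substitution (−5 relative)
is always preferred to an indel pair (−12), so sequencing errors never
masquerade as edits. Reads shorter than 30 nt or with mean Phred quality
below 20 (Phred+33) are `low_quality`. The class taxonomy
(`deletion`, `insertion`, `deletion_plus_insertion`, `complex`) is ours;
the original junction caller's handling of compound reads is not
described anywhere we could follow.

`call_edits()` scores a read as edited when it carries an indel of at
least `min_indel_nt` (default 1) intersecting the window around the
nicks (default nicks ± 20 nt), and reports the indel frequency as the
edited fraction divided by the transfection efficiency, capped at 1.
Identical sequences are aligned once and the calls fanned back out, which
keeps 10,000-read sets in seconds without changing any result.

# Junction analysis

`assign_first_nick()` implements the nick-anchored deletion-length
definition: the deletion boundary nearest a nick junction (within
`boundary_tol_nt`, default 1 nt) names the first nick, and the signed
length records how far the other boundary extends toward (+) or away
from (−) the second nick. When both boundaries sit on nicks — the full
nick-to-nick deletion — the left nick wins the tie, so each read gets
exactly one anchoring; reads whose boundaries are all beyond tolerance
are kept as an `unassigned` bin so edited-denominator frequencies still
account for every edited read.

`summarize_junctions()` reports the percentage of edited reads whose
deletions remove the entire inter-nick interval (full overhang removal),
a near-full variant allowing `near_full_tolerance_nt` uncovered nt
(default 3 — the source data say "full or near-full" without a number),
the median total deleted length (by default over deletion-bearing reads;
whether insertion-only edited reads belong in that median is genuinely
underdetermined, so it is switchable), and the precise nick-to-nick
deletion fraction.

One numerical choice deserves emphasis. After left-normalisation, a read
that is sequence-identical to a full-span deletion product can carry a
canonical interval shifted off the span by microhomology — judging
coverage from the canonical interval alone undercounted full removals by
about ten percentage points in TREX2-like simulations. Coverage and
precision are therefore assessed over the whole shift-equivalence class
of each deletion whenever the reference is supplied: full removal is a
property of the read, not of one alignment representative.

`fold_change()` is the plain condition-over-control ratio with no
pseudocount (zero control → `NA`), and
`overhang_stimulation_regression()` is ordinary least squares with the
Pearson correlation and its two-sided p value from the exact t transform
on n − 2 degrees of freedom.

# The synthetic read generator

`simulate_reads()` emulates the contrast the junction analysis is built
to detect. Each read is independently unedited with probability
`1 − edit_rate`, otherwise one of three components:

* `nick_local` — a deletion starting at a uniformly chosen nick,
  geometric length (1 + Geom(`nick_local_p`)), extending toward or away
  from the other nick with equal probability;
* `full_span` — a deletion covering the whole inter-nick interval with
  independent geometric overshoot (Geom(`extra_resection_p`)) on each
  side;
* `insertion` — a uniform-random 1..`insertion_length_max` nt sequence
  at a nick.

Per-base substitution errors are applied last; qualities are constant
Q30; a single RNG stream with a documented per-read draw order makes the
same seed byte-identical. Geometric length laws are the
minimal-assumption choice — no empirical resection-length distribution
is available to fit — and the presets are qualitative emulations, not
fits:

| preset | edit rate | nick_local / full_span / insertion | resection p |
|---|---|---|---|
| `EV_like` | 0.02 | 0.75 / 0.10 / 0.15 | 0.5 |
| `TREX2_like` | 0.30 | 0.20 / 0.70 / 0.10 | 0.4 |
| `fused_like` | 0.25 | 0.15 / 0.75 / 0.10 | 0.3 |

`EV_like` encodes rare editing dominated by small nick-local loss;
`TREX2_like` and `fused_like` encode frequent editing dominated by full
or near-full overhang removal, the fusion with slightly deeper resection
tails. Edit rates are desk-scale stand-ins of the right order for
negligible-versus-stimulated editing; none of the cell-biology outcomes
(absolute efficiencies, fold stimulations) are simulation targets.

What the simulator deliberately does not model: PCR duplicates and
chimeras, position- or motif-dependent error, quality-score variation,
paired-end structure, translocations, and any kinetics of nick repair
between the two nicking events. Passing end-to-end tests therefore shows
that the analysis recovers the statistical structure it assumes — not
that real amplicon libraries satisfy those assumptions.

# Verification set-up and problem sizes

The test suite pins every worked example above, checks
`find_protospacers()` and `enumerate_pairs()` against brute-force scans
on 100 random 500-bp references, and checks the caller against an
independently written affine-gap dynamic programme on 1,000 randomized
planted-indel cases (reference length 80–120 bp): the call's implied
alignment score must equal the DP optimum and the canonical call must
equal the canonical planted edit. End-to-end recovery runs the
`TREX2_like` preset at 10,000 reads across 20 seeds and requires the
called edit rate, full-removal fraction and median deletion length to
fall inside their 99% confidence intervals (exact binomial for rates,
order-statistic for the median; 99% rather than 95% to control the
family-wise error of 60 interval checks) in at least 19 of 20 runs, with
the theoretical median computed from the exact mixture pmf. With the
substitution error set to zero, calls must equal the generator's ground
truth read for read. These sizes keep the full suite within a few
minutes on one CPU while leaving the binomial standard errors well below
the effect sizes being checked.

# Known limitations

* The viability rules are categorical; binding order, nick religation and
  R-loop interference with TREX2 access are not modelled
  quantitatively.
* Mixed-variant pairs (one D10A + one H840A site) are rejected, and only
  NGG PAMs are scanned.
* The stimulation window is an empirical annotation, not a mechanism;
  overlapping D10A pairs with sub-13-bp overhangs fall outside it even
  though some such pairs respond in cells.
* The caller is single-amplicon and single-end: no genome-scale mapping,
  paired-end merging, UMI handling, or quality recalibration.
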