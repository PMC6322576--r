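---
title: "Methods: wound-responsive miRNA analysis with mirwound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wound-responsive miRNA analysis with mirwound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwound)
```

mirwound implements the computational chain of a plant-wounding small-RNA
study around sweet potato miR408: quantify mature miRNAs in two sequencing
libraries and classify their wound response, decide whether a transcriptome
contig is a credible precursor hairpin, predict target transcripts by
penalty-score complementarity, and convert RACE clone endpoints into
cleavage positions on the miRNA axis. This vignette explains each model,
its assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Quantification and wound-response classes

Reads are collapsed to unique sequences and assigned to a catalog of mature
miRNAs by **perfect, full-length identity** — no offsets, no mismatches, and
length variants count as different reads. Abundance is reads per million
(RPM), `count / depth x 1e6`, and the wound response is the wounded/unwounded
RPM ratio with strict thresholds: ratios above 1.2 are *induced*, below 0.8
*repressed*, anything in between (boundaries included) *unchanged*. A ratio
with zero control RPM is undefined, not infinite, and classifies as
*undetermined*, as does any miRNA below the detection floor (`min_rpm`,
default 1 RPM) in both conditions. The floor is a stand-in for whatever
minimum-evidence rule the original analysis used; 1 RPM keeps a star strand
at 2.7 RPM classifiable while suppressing one-read artifacts. Ratios are
kept at full precision internally and rendered at two decimals only in
reports, which is why a stored 0.6772 prints as the published-style 0.68.

## Precursor hairpins

A contig is a precursor candidate when it contains the mature sequence
exactly (either strand). A window of `flank_nt` (150 nt) on each side is
folded and the structure is accepted as a precursor when the mature sits in
one arm of a stem-loop and pairs the opposite arm — the miRNA:miRNA\*
duplex.

Two folding backends satisfy the same `fold_result` contract:

* **thermo** (default when the `RNAfold` binary is available): ViennaRNA
  minimum-free-energy folding. Stacking energetics keep genuine helices
  intact, which matters: the acceptance rules read the pairing partners of
  the mature directly off the structure.
* **maxpair**: a weighted maximum base-pairing fold (Nussinov-style dynamic
  programming, C++): Watson–Crick pairs weigh 1.0, G:U wobbles 0.8, hairpin
  loops span at least `min_loop = 3` unpaired bases. The G:U discount keeps
  wobble-saturated spurious stems below genuine ones. Ties are resolved
  deterministically by zipping stems from the outside in. This backend has
  no free-energy parameters, is fully self-contained, and is the one whose
  optimality is verified against an exhaustive recursion in the test suite.
  Its known limitation is promiscuity: on long windows with arbitrary
  flanks, many co-optimal structures exist and the returned one may
  scatter pairs, so the interpretive layer below matters more for it.

The acceptance rules operate on the mature's **duplex positions 1..L-2**
(the last two bases are the mature's own 2-nt 3' overhang under DCL duplex
geometry): at least `pairing_fraction = 0.60` of them paired, at most
`max_bulged = 5` unpaired, all partners on a single arm, and at most
`loop_overhang = 2` positions hanging past the innermost stem pair into
the terminal loop. A mature that pairs *within itself* puts the hairpin
apex inside the mature and is rejected as overlapping the terminal loop.
Two interpretive filters make the rules robust to imperfect structures:
partners within `star_gap = 6` nt of the mature span are counted as
terminal-loop pairs, not duplex pairs; and partners whose antiparallel
register (position + partner) strays more than `register_tol = 2` from the
median register are stray pairs and count as unpaired. The tolerance of 2
admits small bulge-induced register shifts while rejecting the
register-inconsistent pairings that random flanks produce; with it, mature
sequences embedded in random 150-nt flanks without a planted arm are
rejected in 97 of 100 draws in the test suite, while planted hairpins with
up to 4 stem mismatches are accepted.

The star strand is predicted from the helix register rather than from
extreme partner positions: with median register \(R\), the star spans the
partners of duplex positions, `[R - mature_end + 2, R - mature_start + 2]`
in window coordinates — the segment pairing mature positions 1..L-2 plus
the star's own 2-nt 3' overhang. Using the median makes the prediction
insensitive to a slipped or stray boundary pair. For precursors whose
duplex contains asymmetric bulges the register is not constant and the
predicted boundaries can be off by the bulge asymmetry; the synthetic
generator plants substitution-only duplexes, so passing tests demonstrate
substitution robustness, not indel robustness.

## Target prediction

Complementarity is scored on the duplex of the miRNA (5'→3') against the
reverse-oriented site: 1 point per mismatch, 0.5 per G:U wobble, 2 per gap,
0 for Watson–Crick pairs, with no positional weighting. Sites are
candidates when the total penalty is at most 3 **and** the central region —
miRNA positions 9–11 from the 5' end, where AGO slices — contains no
mismatch. A central G:U wobble does not exclude (only mismatches are
exclusionary) but still costs its 0.5; published patterns never exercise
this case, so it is a documented interpretation. With the 3-point cutoff
and 2-point gaps, two gaps can never survive, so alignments allow at most
one gap (`max_gaps = 1`); the optimum is found exactly by enumerating the
gapless register and every single-gap placement. Ties prefer fewer gaps,
then penalized columns closest to the miRNA 3' end (mirroring the
biological tolerance for 3' imperfections). Gap columns are attributed to
the region of the miRNA position 5' of the gap; no published site carries
a gap, so this convention is unconstrained by data.

Scanning slides windows of the miRNA length (±1 nt) along the sense strand
of every contig — contigs are oriented mRNA transcripts, so reverse-strand
scanning is off by default — computes each window's minimum penalty with
vectorized prefix/suffix sums, and keeps candidate verdicts, collapsing
overlapping windows to the minimum-penalty site (ties: longest, then
leftmost). A brute-force re-scorer with no shared code verifies every
per-window penalty in the tests.

## Cleavage mapping

"Cleaved at the kth nucleotide" means the scission between the target
bases pairing miRNA positions k and k+1, reported as k. A 5'-RLM-RACE
clone endpoint is the first base of the 3' fragment and pairs k; a
3'-PPM-RACE endpoint is the last base of the 5' fragment, pairs k+1, and
is normalized down by one. The two chemistries therefore report the same
scission identically, which the tests verify exactly. Clone counts
accumulate per position; the modal call breaks ties toward the canonical
slicer position 10 (configurable), then toward the smaller position.

A statistical caveat worth stating precisely: with clone scissions drawn
as `round(rnorm(true, sd = 1))`, positions mode/±1 receive probabilities
about 0.38/0.24/0.24. The probability that the empirical argmax over 50
clones equals the true mode is then about 0.83, and reaches 95% only
around n ≈ 120 (or sd ≲ 0.7 at n = 50). The modal caller is exact in the
noise-free case; under that noise model its replicate-level recovery is a
property of the sampling distribution, not of the implementation.

## Synthetic data

The generator emulates the study's inputs: two-condition libraries whose
per-miRNA counts realize planned RPM values by half-even rounding at a
chosen depth (default 1e6 reads, a realistic small-RNA library scale;
published RPM values become exact integer counts at a depth of 1e8, which
the bundled miR408 example uses); precursor contigs built as flank +
mature + loop + arm with the arm the full reverse complement of the mature
and mismatches planted at interior, non-central stem positions chosen so
they cannot be absorbed by a one-step register slip; target contigs with
exact per-region GU/mismatch/gap patterns; and RACE clone sets with a
planted modal scission and Gaussian positional noise. For gap-free
patterns the planted site's score is provably the aligner's optimum and
the generator's expected score always matches; a planted gap adjacent to
planted mismatches can be re-explained more cheaply by the optimal
alignment, so for gap-bearing patterns only penalty optimality is
guaranteed. What the generator does not emulate: sequencing errors,
adapter artifacts, isomiR variation, expression dynamics, and
bulged/asymmetric precursor duplexes — conclusions about those require
real libraries.

## Problem sizes and reproducibility

The bundled checks run at desk scale: fold optimality is verified
exhaustively on windows up to 60 nt over 50 seeds, scanner equivalence on
30 seeded contig sets up to 200 nt, recovery experiments on a 20-miRNA
catalog at depth 2e7, 100 shuffled-flank controls, and 200 Monte-Carlo
clone replicates. Every generator is a pure function of its seed and the
pipeline writes an md5 manifest so a rerun on the same config and inputs
is verifiably byte-identical.
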