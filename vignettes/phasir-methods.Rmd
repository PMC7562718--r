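---
title: "Detecting phased siRNA loci and validating their sliced targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phased siRNA loci and validating their sliced targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biology being modelled

Reproductive phasiRNAs are 21- or 24-nt small RNAs produced in precise
head-to-tail increments from long non-coding precursor transcripts. A trigger
miRNA (miR2118 for 21-nt loci, miR2275 for 24-nt loci) guides AGO-mediated
cleavage of the precursor between the target bases paired with trigger
nucleotides 10 and 11; RDR6 then converts the downstream fragment to double-
stranded RNA, and a Dicer-like enzyme processes it processively into duplexes
of one fixed length. The cleavage site therefore sets a *phase register*:
phasiRNA 5' ends recur at a fixed residue class modulo the period. 21-nt
phasiRNAs additionally show a strong 5'-cytosine bias, and a subset of them
act like miRNAs, slicing complementary mRNA targets — which leaves a
diagnostic degradome (PARE) tag whose 5' end sits exactly at the target base
paired with sRNA position 10 (the "+1" position).

phasir implements the full computational chain around this model: exact
read mapping and profiling, phase-score locus detection, mispair-score
target prediction, degradome category classification and target calling,
and a wild-type/mutant dependence classifier, plus a generator of synthetic
data with planted ground truth for every stage.

## The phase score

For a window of nine cycles (9 × period nt), only reads whose length equals
the period are considered. Each (effective 5' position, strand) cell with at
least one read is *occupied*. Given a register $r \in [0, p)$:

$$\mathrm{score} = (k - 2)\,\ln\!\left(1 + \frac{10\,P}{1 + U}\right),
\qquad k \ge 3 \text{ (else 0)}$$

where $k$ is the number of occupied in-register cells, $P$ the summed
in-register read count, and $U$ the summed off-register count in the window.
The statistic is strictly increasing in $P$ and $k$ and strictly decreasing
in $U$. The scan slides the window 1 nt at a time over read-supported
regions, takes the best register per window, keeps windows with score at or
above the threshold and $k$ at or above the occupancy minimum, and merges
overlapping passing windows that share a register into loci spanning their
first to last in-register read.

**Minus-strand register.** DCL duplexes carry 2-nt 3' overhangs: the duplex
partner of a plus-strand read starting at $x$ occupies $[x-2, x+p-2)$, so its
*biological 5' end* lies at forward coordinate $x+p-3$. We therefore compare
minus-strand reads at their leftmost coordinate + 2 — the convention of
bowtie-based phasing pipelines — which places both strands of a duplex in
the same register. (Note that adding 2 to the biological 5' end instead
would *not* restore the register; the two conventions differ by 1 mod $p$.)
The generator uses the same duplex geometry, and the trigger-consistency
check verifies that the locus register equals the annotated trigger cleavage
position mod $p$.

**Thresholds.** The default locus call requires score ≥ 15 (natural-log
units) and k ≥ 4, both configurable; the pipeline reports a sensitivity
table over a grid of score thresholds so this choice is auditable. A merged
call shorter than three full cycles is discarded as degenerate. The original
consensus-of-two-tools rule that these thresholds replace is not
reproducible from a single scan; the threshold pair was chosen so that
planted loci of ten cycles at moderate coverage are recovered while 100
random-background simulations yield essentially no calls (the specificity
test in the suite).

## The mispair score

sRNA:target complementarity is scored antiparallel with sRNA positions
numbered 1–21 from the 5' end: Watson–Crick pairs cost 0, G:U wobbles 0.5,
mismatches and each bulged nucleotide 1, and every penalty is halved outside
the core region, positions 2–17. Sites scoring ≤ 3.5 (inclusive) form the
candidate target pool. The optimal alignment is found by banded dynamic
programming with at most 2 bulged nucleotides in total (two bulges already
consume ≥ 2 of the 3.5 budget, and with three the budget is nearly
unreachable); a target-strand bulge takes the position index of the
5'-adjacent consumed sRNA nucleotide, and target bulges are only allowed
between sRNA positions 1 and m (a terminal target overhang is a different
window, not a bulge). Ambiguity codes score as mismatches. Ties during
traceback prefer pair over sRNA-bulge over target-bulge; among equal-score
windows at one end, the length closest to the sRNA length (then the shorter)
is kept; overlapping sites resolve to the lower score, leftmost on ties.

Scanning a transcriptome is accelerated by an exact semi-global pass that
computes, in one sweep with cells clamped above 3.5, the minimum score over
all alignments ending at every position; the rare candidate regions it
reports are then re-scored and enumerated by the per-end banded DP. The test
suite verifies both that the DP equals exhaustive alignment enumeration and
that the accelerated scan equals the direct one.

The predicted cleavage coordinate of a candidate is the target position
paired with sRNA nucleotide 10; it is undefined (and the candidate cannot
validate) if position 10 is bulged.

## Degradome categories and target calling

Degradome tags are ~20-nt sense fragments whose 5' ends mark cleavage
products. Tags are placed by exact forward-strand match; each transcript's
profile keys tag counts by 1-based 5' position. A queried site with $t \ge 1$
tags is classified against its transcript profile:

* **4** — a single tag ($t = 1$);
* **3** — $t > 1$ but at most the average;
* **2** — above the average, below the maximum;
* **1** — equal to a maximum shared by more than one site;
* **0** — the unique maximum with $t > 1$.

The "average" is computed over occupied positions (the convention of the
tools that introduced the scheme); averaging over all transcript positions
is selectable and flagged in output. A candidate is a **validated target**
iff its category is 0 or 1, the site carries ≥ 4 tags, and those tags are
≥ 10% of the transcript's total — all bounds inclusive, checked
mechanically on every output row by the test suite. Per-library abundances
are reported as RP10M (reads per ten million mapped tags).

## Dependence classification

For wild-type versus mutant comparisons, counts are RPM-normalized by
library size and the fold change is the ratio of condition means. The
per-feature p-value comes from a deliberately simple stand-in: a two-sided
exact binomial test of the pooled wild-type count against the library-size
expectation, with Benjamini–Hochberg correction; a negative-binomial count
model is out of scope here, and externally computed p-values can be
supplied instead. A phasiRNA is *dependent* iff fold ≥ 2 and FDR ≤ 0.05.

Relative normalization can only see depletion against an unaffected
majority: if phased reads dominated the library, dividing by the shrunken
mutant library size would absorb the biological signal (in real libraries
the anchor is provided by miRNAs, hc-siRNAs and other unaffected classes).
The generator's default reference is sized accordingly (below).

## The synthetic generator

`generate_reference()` plants, per locus, an exact reverse-complement
trigger site in a random precursor, derives the cleavage position from
trigger nucleotide 10, and lays phased duplexes (both strands, 2-nt
3'-overhang geometry) downstream. The 5'-C bias of 21-nt phasiRNAs is
realized *in the reference*: with probability `five_prime_c_bias` the
precursor base under a phasiRNA 5' end is set to C (G on the minus strand),
so simulated reads remain exact matches — the only mechanism consistent
with exact mapping. The default triggers are synthetic stand-ins named for
the roles they emulate and carry G at position 10, so the planted site's +1
base is already a C and the site stays a perfect duplex. Counts are Poisson
per position and replicate; the mutant divides phased means by
`mutant_depletion_factor`. Unphased background reads (18–30 nt, uniform
positions and strands) arrive at `background_read_rate` per reference nt.
Degradome background decays geometrically from the transcript 5' end
(mean `degradome_background_mean` × `degradome_decay_rate`^(pos−1)),
emulating exonucleolytic background, with Poisson spikes of mean
`degradome_spike_mean` at every planted cleavage coordinate — both
phasiRNA target sites and the trigger sites on precursors.

Defaults define the benchmark conditions used throughout the tests: 20
21-nt and five 24-nt loci of 10 cycles, phased mean 20, background 0.05/nt,
50 planted targets, spike mean 50, three replicates, 4-fold mutant
depletion. The free design choices were fixed once: 250 transcripts of
1.5–2.5 kb (≈ 0.5 Mb), so that background reads form the normalization
anchor discussed above, as in real libraries; 5'-C bias 0.9, matching the
strong (not absolute) bias reported for 21-nt phasiRNAs; degradome
background 0.5 tags/position at the 5' end with decay 0.998/nt, giving
transcript totals of a few hundred tags against which a spike of ~50 is a
clear but not overwhelming category-0 signal. The pipeline's negative controls are dinucleotide-preserving shuffles of
detected 21-nt phasiRNAs (random Eulerian walks on the dinucleotide
multigraph). A rare walk nearly reproduces its source and would still pair
with the source's own planted site, so shuffles retaining a duplex score
within 1 of the candidate ceiling against that site are redrawn — the
standard composition-matched negative-control design, which leaves decoys
free to hit anything except through a genuine targeting relationship.

One emergent property of the planted design is worth knowing: the first
phasiRNA of every 21-nt locus begins at the trigger cleavage position and
therefore shares its first ten nucleotides (the trigger-complement overlap)
with its counterparts from all other 21-nt loci, exactly as in real
miR2118-triggered families. These cycle-0 phasiRNAs can cross-hit each
other's planted target sites within the 3.5 ceiling at the same cleavage
coordinate, so a planted site may validate for several related phasiRNAs —
a faithful reproduction of family-level target sharing, not an artifact.

The generator does **not**
simulate sequencing error, adapters, quality scores, multimapping gene
families, or any biogenesis difference between the 21- and 24-nt classes
beyond the period itself — so passing recovery tests demonstrate the
correctness of the analysis chain under its own model assumptions, not
robustness to every artifact of real libraries.

## Numerical and interface conventions

Coordinates are 0-based half-open internally and 1-based inclusive in every
written table; the 5' position of a minus-strand read is its rightmost
base's forward coordinate. Sequences are normalized to DNA (U→T) on input
and phasiRNA 5' composition is reported over A/C/G/U. The RPM denominator
is the total mapped 18–30-nt count (overridable, since "total clean reads"
is an equally defensible choice). Multi-mapping reads and tags default to
count-all with weight 1 per placement; fractional 1/n weighting is
available for sensitivity checks. Locus ids are `<period>PHAS<number>` in
reference order; member phasiRNAs are `<locus>_<offset><strand>` with
offset the nt distance of the biological 5' end from the locus start on the
forward strand.

Problem sizes in the shipped tests were chosen to exercise the default
benchmark honestly on a single CPU: ten seeded full-pipeline runs for
recovery, 1000 fuzzed pairs for the duplex oracle, the complete ≤ 5-site ×
counts ≤ 6 enumeration for the category classifier, and two-seed controls
for the null dependence rate.

## Known limitations

* The binomial dependence test ignores overdispersion; with few replicates
  and biological noise beyond Poisson it is anti-conservative. It is a
  documented stand-in, and external p-values are accepted.
* Phase-score scanning assumes both strands contribute to one register via
  the overhang correction; loci with strand-asymmetric degradation are
  still detected but with lower k.
* Trigger annotation reports the best site per trigger; tandem duplicated
  trigger sites in one precursor are reported as secondary, not modelled.
* The duplex scorer has no thermodynamic term; scores are the penalty
  scheme only.
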