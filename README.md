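# phasir

Detection of phased siRNA (*PHAS*) loci from small-RNA sequencing data and
degradome-based validation of phasiRNA-directed target cleavage.

## The problem

Plant reproductive phasiRNAs are 21- or 24-nt small RNAs processed in
head-to-tail register from long non-coding precursors after a trigger miRNA
(miR2118 / miR2275) cleaves the precursor between the bases paired with its
nucleotides 10 and 11. Finding the loci that produce them, and showing that
particular 21-nt phasiRNAs actually slice mRNA targets, requires a chain of
specialised steps that are usually scattered across ad-hoc scripts. phasir
packages that chain for R users working on plant small-RNA biology:

* **exact read mapping and profiling** — collapsed reads placed with no
  mismatches, 5'-end position profiles, size and 5'-nucleotide summaries,
  RPM/RP10M normalization;
* **phase-score locus detection** — a nine-cycle sliding window scoring
  `(k − 2) · ln(1 + 10 P / (1 + U))` over occupied phase cells (k), phased
  (P) and unphased (U) counts, with the canonical 2-nt duplex-overhang
  correction for minus-strand reads; loci named `21PHAS0001`, members
  `21PHAS0001_165-`;
* **target prediction** — the mispair score (mismatch/bulge 1, G:U wobble
  0.5, halved outside sRNA positions 2–17; candidates ≤ 3.5) by banded
  dynamic programming, with the predicted cleavage site at the target base
  paired with sRNA position 10;
* **degradome validation** — PARE tags mapped sense-to-transcript,
  cleavage-site categories 0–4, and the target filter: category 0/1 with
  ≥ 4 tags holding ≥ 10% of the transcript's degradome signal;
* **dependence classification** — replicated wild-type vs mutant counts,
  fold ≥ 2 and BH-FDR ≤ 0.05;
* **a synthetic-data generator** with planted ground truth (registers,
  trigger sites, target cleavage spikes, replicate count matrices) so every
  claim above is testable by recovery.

## Worked example

A small synthetic study: three 21-nt and one 24-nt locus planted among 15
random transcripts, three planted targets, three replicates per condition,
4-fold mutant depletion.

```r
library(phasir)

cfg <- synthetic_config(seed = 7, n_transcripts = 15,
                        transcript_len_range = c(400, 600),
                        n_phas21 = 3, n_phas24 = 1, n_planted_targets = 3)
bundle <- run_pipeline(cfg, n_decoys = 5)

bundle$loci[, c("locus_id", "ref", "start1", "end1", "register", "score",
                "trigger", "trigger_register_consistent")]
#>     locus_id       ref start1 end1 register    score trigger trigger_register_consistent
#> 1 21PHAS0001 PRE21_001     53  262       10 123.1224 miR2118                        TRUE
#> 2 21PHAS0002 PRE21_002     53  262       10 126.0989 miR2118                        TRUE
#> 3 21PHAS0003 PRE21_003     53  262       10 134.6756 miR2118                        TRUE
#> 4 24PHAS0001 PRE24_001     53  292        4 131.1562 miR2275                        TRUE
```

All four planted loci are recovered at their exact registers, each
annotated with its trigger at mispair score 0 and a cleavage position
consistent with the phase register. The validated targets:

```r
calls <- bundle$target_calls
calls[calls$validated & !calls$is_decoy,
      c("srna_id", "transcript", "site_1based", "tags_at_site", "category",
        "site_fraction")]
#>            srna_id transcript site_1based tags_at_site category site_fraction
#> 44 21PHAS0002_126+     TX0008         331           50        0     0.2604167
#> 45 21PHAS0002_105+     TX0011         396           50        0     0.2252252
#> 46 21PHAS0001_123-     TX0013          95           56        0     0.2616822
```

Exactly the three planted cleavage sites validate (category 0, the
diagnostic tag is the transcript's unique maximum and holds 22–26% of its
degradome signal); none of the five dinucleotide-shuffled decoy sRNAs
validates anywhere. The recovery report summarises this against the truth:

```r
unlist(bundle$recovery$loci)
#>        tp        fp        fn precision    recall n_planted  n_called
#>         4         0         0         1         1         4         4
```

## Further reading

The methods vignette (`vignettes/phasir-methods.Rmd`) documents the model
assumptions, the scoring conventions (tie-breaks, bulge attribution,
averaging conventions), what the synthetic generator does and does not
emulate, and the package's known limitations.
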