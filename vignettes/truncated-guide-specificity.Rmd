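---
title: "Assessing activity and specificity of truncated CRISPR/Cas9 guides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing activity and specificity of truncated CRISPR/Cas9 guides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truguide)
```

## The problem

SpCas9 is directed by an sgRNA whose spacer is conventionally 20 nt.
Truncating the spacer at its 5' (PAM-distal) end to 19, 18 or 17 nt can
retain — sometimes improve — on-target activity, but it also relaxes the
specificity constraint: a shorter spacer can only lose mismatches against
any fixed genomic locus, so the set of candidate off-target sites within a
fixed mismatch budget grows monotonically as the spacer shortens. Deciding
whether those extra candidates are *actually* edited requires sequencing
them, and deep sequencing of candidate panels has its own failure mode:
microsatellite (SSR) loci mutate by replication/PCR slippage, producing
indel signal in unedited control samples that is indistinguishable from
editing unless the loci are flagged.

`truguide` implements that assessment loop end to end on synthetic data
with known truth:

1. **Guide design and off-target enumeration** — exhaustive, both-strand
   scan for loci matching the spacer within ≤ 5 mismatches next to an NRG
   PAM (R = A/G); NGG for on-target design.
2. **Microsatellite scanning** — perfect and compound tandem repeats
   (unit 1-6 nt), MISA-style thresholds, per-site flags over ~200-bp
   windows.
3. **Amplicon indel quantification** — read QC, semi-global affine-gap
   alignment, indel calling restricted to a window around the cut site.
4. **Site classification** — paired control/edited decision rules:
   coverage floor, control-background ceiling, SSR attribution.
5. **T7 endonuclease I densitometry** — the heteroduplex band-intensity
   estimate used for wet-lab cross-validation.
6. **A seeded simulator** producing genomes, planted sites and read sets
   whose truth every stage can be scored against.

## Conventions

All internal coordinates and BED output are 0-based half-open; the
human-readable site TSV is 1-based inclusive and says so in a header
comment. Spacer positions are numbered 1..*k* **from the PAM-proximal
base**; the seed region is positions 1-12. The cut site is the blunt
boundary 3 bp 5' of the PAM (between spacer positions 3 and 4), standard
SpCas9 geometry; the cut coordinate is invariant under 5' truncation,
which is what makes cross-length panels comparable by cut-site key.

## Off-target enumeration

`find_offtargets()` counts Hamming mismatches over the spacer (no bulges:
the search is mismatch-only) and matches the PAM against an IUPAC pattern.
An ambiguous genome base (N) counts as a spacer mismatch; in the PAM
pattern, `N` matches anything and `R` matches A/G only. Both strands of a
locus are counted as separate sites. The on-target locus itself appears
with `n_mismatch = 0`, which gives a built-in positive control.

Two properties anchor the tests: equality with an independent
`matchPattern`-based oracle on random genomes, and truncation
monotonicity — for every locus the truncated spacer's mismatch count is
bounded by the full-length count, so hit counts are non-decreasing as the
spacer shortens. `overlap_across_lengths()` keys sites by (contig,
cut-site, strand) so loci found at several lengths collapse onto one key;
the full intersection is the shared candidate panel a capture experiment
would target.

## Microsatellite model

`find_perfect_ssrs()` reports maximal tandem runs of a *primitive* unit
(a unit that is not itself a shorter repeat), trimmed to whole units and
reported leftmost. Default minimum repeat counts are the canonical MISA
settings — 10/6/5/5/5/5 for unit lengths 1-6 — and are configurable;
where threshold-passing runs of different unit lengths overlap, the longer
run wins with ties broken leftmost, so reported perfect SSRs never
overlap.

`merge_compound()` merges qualifying runs separated by at most 100 bases
(interruption bases are carried literally in the composition so that
re-expanding any composition string reproduces the genomic substring
exactly). **Extension mode** additionally absorbs a tandem run of a
different unit immediately adjacent to a qualifying SSR, with at least 2
repeats — this is how `(CA)8(GA)2`-type motifs are representable even
though `(GA)2` is far below the dinucleotide threshold on its own. Two
deliberate restrictions keep extension from degenerating: only **one**
absorbed run per side, and the absorbed unit must be at least 2 nt.
Without them, incidental doublets in random flanking sequence (`TT`,
`GCGC`, ...) chain indefinitely and compounds swallow arbitrary flanks;
with them, the scanner still represents every compound motif the
classification stage needs while agreeing with brute-force enumeration on
perfect repeats.

## Alignment and indel calling

Reads are aligned to the reference amplicon semi-globally (read global,
free end gaps on the reference) with affine gap penalties: match +2,
mismatch −3, gap open −8, gap extend −1 (a gap of length *l* costs
8 + *l*). Both the read and its reverse complement are tried and the
better score kept. Reads whose best alignment matches fewer than 60% of
their bases are `discarded_unaligned` rather than erroring. A fast path
skips dynamic programming for reads of reference length with at most 5
mismatches: under these scores a gapped alignment of such a read can
never beat the substitution-only one (two compensating gaps cost at least
18 + the lost matches, more than five mismatches at −5 each), so the
shortcut is exact, not an approximation.

Indels are **left-aligned** within repeat context before window testing,
so a slipped repeat unit is always called at the repeat's left edge —
deterministic placement at SSR loci. A read is an editing event iff at
least one insertion or deletion intersects the window
`cut_pos ± quant_window`; substitutions never count, which is why the
simulator's per-base error rate does not inflate efficiency.
`quant_window` defaults to ±10 bases: wide enough for the 1-9-base
NHEJ indels the simulator plants at the cut, narrow enough to exclude
indels unrelated to the cut. A window ≥ 50 would start counting slippage
at an SSR 50 bases away — the window-sensitivity test documents exactly
this trade-off, which is the mechanism by which microsatellites inflate
apparent editing in wide-window or enzyme-based assays.

QC follows the standard contract: adapter suffixes trimmed by
exact-prefix match with ≥ 8 bases overlap, reads containing N discarded,
reads shorter than 35 bases after trimming discarded. Efficiency uses
aligned ("qualified") reads as its denominator, not raw reads.

## Classification rules

For each site with paired control (wild-type) and edited quantifications,
`classify_site()` applies, in order:

1. control aligned reads < 10 → `low_coverage`;
2. control efficiency ≥ 1% → `background_unstable` (if the site's SSR
   flag is set, the flag is recorded as the suspected cause);
3. edited efficiency ≥ 1% → `validated_offtarget`;
4. otherwise `clean`.

The precedence is a design choice: coverage is tested first so that an
under-sequenced site can never masquerade as `clean`, and background is
tested before validation so an unstable locus can never be promoted to a
validated off-target no matter how strong its "signal" in the edited
sample. Sites failing the background rule are retained and labelled, not
dropped, so the noise budget stays reportable. The edited-sample
validation threshold defaults to the same 1% as the control ceiling but
is separately configurable. Statuses are mutually exclusive and
exhaustive — the per-status counts always sum to the panel size.

## T7 endonuclease I estimate

For band intensities *a* (uncut) and *b*, *c* (cut products):

$$\text{indel%} = 100 \left(1 - \sqrt{1 - \frac{b+c}{a+b+c}}\right)$$

The square root accounts for heteroduplex formation from random
re-annealing of mutant and wild-type strands. The implementation uses the
conventional `1 − fraction` form. The estimate is strictly increasing in
the cut fraction and bounded in [0, 100], but saturates below the true
modified fraction at high editing — one reason sequencing-based
quantification supersedes it.

## What the simulator emulates — and what it does not

`simulate_reads()` draws, per read: an editing flag (probability
`edit_rate`), one signed indel size from `indel_size_dist` placed with
its left edge at the cut site, independent per-base substitutions
(`subst_error_rate`, default 0.001), and — at SSR loci — a slippage event
(`stutter_rate`) that inserts or deletes one whole repeat unit of the
span's dominant run, equiprobably in either direction. One indel per
edited read, left-anchored, makes truth labels unambiguous for
parameter-recovery tests. Reads are full amplicon copies with constant
Q30 qualities.

Defaults the package treats as its study conditions: 300 reads per site
(capture-style depth), an NHEJ-flavoured indel spectrum dominated by
small deletions (40% −1, 15% +1, 15% −2, 10% −3, 5% −4, 5% −5, 4% −6,
3% −9, 3% +2 — the real spectrum is locus-dependent and not specified by
any single reference, so this is a package choice), 5% stutter at SSR
loci, and planted editing rates of 67.4% (on-target) and 51.4/31.7/10.5%
(the three true off-targets) in the edited sample only. SSR-noise sites
are planted on the plus strand with the microsatellite immediately 3' of
the PAM: left-aligned slippage calls land at the repeat's left edge,
6 bases from the cut and therefore inside the default ±10 window. (On a
minus-strand site the repeat's left edge would sit 26 bp from the cut and
the planted noise would be invisible at the default window — a real
survey would widen the window or test overlap with the repeat span
instead.)

Not modelled: sequencing-machine error profiles and quality variation,
paired-end reads and merging, PCR duplicates, fragmentation, HDR or
base-editing outcomes, chromatin effects on cleavage, and bulge
(gapped-protospacer) off-targets. Passing tests therefore demonstrate
algorithmic correctness against a clean generative model, not performance
on real libraries, where adapter chemistry, quality trimming and
alignment ambiguity contribute additional noise.

## Problem sizes and numerical choices in the test suite

The suite checks oracle equality on twenty 50-kb genomes (all at the
hardest mismatch budget, two of them over the full 0-3 budget sweep, the
lower budgets being hit-subsets of the hardest), SSR-scanner equality on
one hundred 5-kb sequences, editing-rate recovery at rates
{0, 5, 15, 50}% with 2,000 reads × 20 seeds per rate (estimates within 3
binomial standard errors in ≥ 95% of replicates), and exact truth
recovery — sensitivity and specificity 1.0 for `validated_offtarget`,
all five SSR-stutter sites in `background_unstable` — on the default
28-site panel at 300× coverage. These sizes were chosen so every
distributional claim has enough replicates to be meaningful while the
whole suite stays comfortably re-runnable on a laptop. All randomness
flows through explicit integer seeds; identical configuration yields
byte-identical FASTA/FASTQ output.

## Known limitations

* The off-target search is exhaustive-scan, O(genome × spacer length);
  fine up to tens of megabases, not engineered for mammalian genomes
  (index-based search would be the next step).
* Strands are counted as separate sites; a palindromic locus appears
  twice.
* The compound-SSR extension rule is intentionally conservative (one
  ≥ 2 nt-unit run per side); interrupted or imperfect repeats beyond that
  are not scored.
* Classification is rule-based, not statistical: no confidence intervals
  on efficiencies and no test of control-vs-edited difference; at 300×
  the 1% threshold sits near three expected background reads, so
  shallower panels need a higher ceiling.
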