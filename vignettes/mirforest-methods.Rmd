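---
title: "mirforest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirforest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model the package implements, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
method leaves room for interpretation.

## The stacked model

MicroRNA precursors leave a distinctive footprint in small RNA-seq data:
one or two sharply 5′-defined read stacks (the mature miR and, less
abundantly, the miR\*) on the two arms of a ~70-nt stem-loop, sometimes
with minor moR (offset) and loop products. `mirforest` detects this
footprint in two classifier layers rather than with hard abundance
thresholds.

**Layer 1 — mature products (MPRF).** Reads are grouped into *read
regions*: maximal connected components of the interval-overlap graph per
chromosome and strand (half-open intervals; abutting reads do not
overlap). Each region is scored by a probability random forest on 36
features. The discriminative core is (i) 5′ precision — Drosha/Dicer cuts
are precise, so the fraction of reads off the modal 5′ position
(`fivePrimeHet`, and the full −7..+7 offset profile) separates miRs from
degradation products — and (ii) `duplexEnergy`, the minimum RNAduplex
energy of the region's most frequent read against the 70-bp windows on
either side: a genuine miR has a near-complement (the miR\*) nearby even
when the star arm has no reads at all. Because classification replaces an
abundance cutoff, single-read regions are scored like any other; this is
what lets the pipeline call microRNAs supported by one read.

**Span finding.** Folding is notoriously sensitive to the window chosen,
so candidate precursor spans are derived from the *duplex*, not the fold:
the optimal duplex between the major product and its flanking windows
defines a duplex-focused span (product + duplexed subsequence), and every
pair of MPRF-passing products separated by ≥ 5 nt defines a
product-focused span. All candidates are folded and compete; nothing is
decided by the fold of one fixed window.

**Layer 2 — hairpin precursors (HPRF).** Read stacks inside a candidate
are named as the products expected from Drosha/Dicer processing: the most
abundant stack is the miR of its arm; a stack on the opposite arm
overlapping the duplex register (±2 nt) is the miR\*; stacks 5′ of
miR-5p / 3′ of miR-3p are moRs; stacks over the main loop are loop
products; the rest are out/other. A 71-feature vector summarizes the fold
(MFE, pairing densities of miR and duplexed region, bulge/interior-loop
geometry, loop size, offshoot hairpins), the sequence (GC, dinucleotides),
expression (sense/antisense ARPM, unique-read fraction, average hit
count), product geometry (11 labelled pairwise overlaps, same-arm and
cross-arm shifts, sense-antisense displacement), read-count and
start-position variances, a 1000-nt neighbour count, and the mean MPRF
decision value of the candidate's products. Overlapping scored candidates
are resolved greedily best-score-first; final predictions require both a
decision value and an ARPM threshold.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `mprf_threshold` | 0.5 | vote fraction | entry into span finding; the method text requires "a minimum threshold" without fixing it |
| `y_threshold` | 0.28 | vote fraction | tuned optimum shipped as default |
| `expression_threshold` | 0.11 | ARPM | tuned optimum; applied to locus sense ARPM |
| `hprf_ratio` (X) | 25 | — | tuned 1:25 positive:negative stratified sampling |
| `mprf_ratio` | 1 | — | 1:1 for the product layer, so as many products as possible reach the hairpin phase |
| `window` | 70 | nt | flank width for the product duplex; applied to each flank, min() over the two |
| `min_gap` | 5 | nt | product-focused span separation (the method's Results phrase "4 nt or more away" is read as the same >4 rule) |
| `pad` | 5 | nt | extension beyond product/duplex edges before folding; spans that end exactly at cut positions fold poorly at the margins |
| `max_span` | 250 | nt | cap against pathological folds; precursors are ~70 nt |
| `register_tol` | 2 | nt | miR\* matching tolerance around the duplex register (the 2-nt 3′ overhang scale) |
| neighbour window | 1000 | nt | clustering tendency of miRNA loci |
| cluster distance | 10000 | nt | inclusive edge-to-edge chaining |
| pseudocount | 0.015 | ARPM | knockdown log2 fold changes |
| `num_trees` | 500 | — | conventional forest size; `mtry = floor(sqrt(p))`, unlimited depth, vote-fraction decision values |

Forests are grown with a fixed seed on one thread, so fits and predictions
are bit-reproducible.

## Design decisions where the method is open

* **5′ heterogeneity** is `1 − (weighted reads at the modal 5′)/(total)`,
  the simplest statistic matching the name and the [0,1] range; the
  offset profile is stored as fractions (scale-invariant across library
  depths), not raw counts.
* **Duplex window sidedness**: the 70-bp window is taken on *each* flank
  and the better (lower-energy) side wins, for both the MPRF feature and
  the duplex-focused span.
* **F-score variant**: the published comparison tables tabulate
  PR/(P+R) — half the harmonic mean — while the text says "harmonic
  mean". `f_scores()` returns both (`f1`, `f_paper`); the tuner's
  objective is configurable and defaults to `f1`. The discrepancy is
  surfaced rather than silently resolved.
* **Main-stem selection** in multibranch folds: the stem whose closing
  pair most tightly encloses the anchor (major product); if no pair
  encloses it, the stem with the largest span-overlap with the anchor,
  ties to the longer stacked helix. Descent through multiloops follows
  the child with the longest helix. This matters when merged stacks run
  past the last paired base.
* **`innerLoopGapCount`** counts maximal runs of ≥ 3 unpaired positions
  in the interior of the innermost main-stem pair *including* child
  hairpin loops — exactly the reading under which "more than one
  indicates a multibranched loop" is true.
* **`numOffshoots`** counts hairpin loops other than the main loop within
  the enclosing pair of the main stem; a single stem-loop therefore has 0
  offshoots.
* **Variance features** use population (not sample) variance; `wAPV` is
  weighted by product read fraction, `wARV` by product length.
* **HPRF training pool**: during training, every read region enters the
  candidate stage — annotated products regardless of their MPRF score (so
  each annotated precursor yields its best-overlap positive) and
  background regions as the negative pool. At prediction time only
  MPRF-passing products generate candidates. On clean data almost no
  background survives the MPRF, and restricting training to passing
  regions would leave the hairpin layer with no negative class.
* **Homology engine**: a dependency-free Smith–Waterman
  (`Biostrings::pairwiseAlignment`, match +1 / mismatch −2, gap 2/1) with
  an ungapped Karlin–Altschul E-value (λ = 1.28, K = 0.46); the seed is
  mature positions 2–8, 1-based. The engine identity is recorded in every
  call so a BLAST adapter can be swapped in without changing verdicts
  semantics.
* **Clusters** require ≥ 2 members (a singleton is not a cluster);
  annotated loci are chained first, then novels join or form novel-source
  clusters, so a cluster is "annotated" only if it exists without any
  novel prediction.
* **Evaluation**: overlap fraction is measured against the annotation's
  length (≥ 50%); "fold direction" is operationalized as every annotated
  mature of the matched precursor landing on the same arm in the
  prediction's fold; antisense overlaps are false positives outright.

## The synthetic-data generator

`sim_config()` / `simulate_mir_experiment()` emulate the read anatomy the
classifiers exploit: planted hairpins (miR + 8–20-nt loop + reverse
complement with a configurable mismatch rate, 2-nt 3′-overhang register),
guide-arm reads at 5–50× depth with 90% 5′ precision, miR\* reads at 20%
of guide depth, minor moR/loop stacks, and unstructured background stacks
(50% 5′ precision, depth 1–10) at ~10× the number of hairpins.
Multimapping is realized by physically duplicating a fraction of noise
loci, so NH counts are consistent by construction. Defaults describe a
clean, well-expressed library over a 250-kb genome; every draw comes from
the config seed, and fixtures are byte-identical across runs.

What the generator does **not** emulate: sequencing errors and adapter
artifacts, transcriptome-scale expression structure, isomiR biology beyond
±1–2-nt jitter, genuinely structured non-miRNA RNAs (tRNA/snoRNA
fragments fold, too), or chained moR stacks — moR/loop products are placed
with a few nucleotides of clearance so they form their own read regions.
Background noise carries no planted complement, which makes the duplex
features cleanly discriminative by design. Passing tests therefore
demonstrate correct mechanics and parameter recovery under the stated
conditions, not field performance on real libraries, where the
noise-versus-hairpin margin is narrower.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally; SAM/GFF3 1-based inputs are
converted at the boundary and converted back on export. T→U on input to
the folding engine; structures are reported in RNA alphabet, genomic
coordinates in DNA. A no-duplex result (engine energy ≥ 0) is the
sentinel 0 with an explicit `found = FALSE`; candidates without a duplex
get 0 for all dup\* features. Empty spans in the fold/duplex agreement
return 1 by convention. Ties: modal 5′ positions break to the smallest
genomic coordinate; overlap resolution breaks score ties to the lower
genomic start, then duplex-focused origin; the tuner breaks F ties to
smaller X, then larger thresholds (more conservative). Zero-denominator
precision/recall is flagged `NA`, never silently propagated.

## Problem sizes

The shipped tests train and evaluate on simulated fixtures of 10 planted
hairpins + 80 noise loci (unit level) and 50 hairpins + 500 noise loci
across three disjoint genomes for the train/tune/test recovery study, with
a 3×1×2 tuning grid around the shipped thresholds — sizes chosen so the
full suite exercises every stage, including two full model fits, in a few
minutes on one CPU. The structure-anatomy oracle runs on 100
engine-produced folds of ≤ 80 nt.

## Known limitations

* The product-naming concretization (register tolerance, moR/out
  boundaries) follows the documented conventions above; the upstream
  algorithm it abstracts is cited but not published in reproducible
  detail, so other implementations may label borderline stacks
  differently.
* tapd/aapd/sameShift/bothShift are documented conventions for the same
  reason.
* Folding is delegated to ViennaRNA at default parameters; results are
  deterministic only for a pinned engine version (recorded in model
  metadata and provenance files).
* The homology E-value uses ungapped Karlin–Altschul constants; absolute
  E-values differ from BLAST's, though verdicts at the stated thresholds
  agree for near-identical matures.
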