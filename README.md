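# mirforest

MicroRNA discovery from aligned small RNA-seq reads with a **stacked
two-layer random forest**: a *mature-product* layer that scores every read
stack as a plausible mature miRNA (no read-abundance floor — single-read
loci are evaluated), and a *hairpin-precursor* layer that scores candidate
precursor spans built around each passing product. It is aimed at
bioinformaticians annotating miRNAs in well- or poorly-annotated genomes
from bowtie-style alignments.

## The method

Aligned reads are grouped into **read regions** (maximal sets of
overlapping same-strand reads). Expression is quantified in **ARPM**
(adjusted reads per million): a read aligning to *n<sub>r</sub>* genomic
locations contributes 1/*n<sub>r</sub>* per location,

&nbsp;&nbsp;&nbsp;&nbsp;ARPM(L) = 10⁶ · Σ<sub>r∈L</sub> 1/n<sub>r</sub> / Σ<sub>r∈S</sub> 1/n<sub>r</sub>

for locus *L* in sample *S*. The **MPRF** (mature-product random forest)
scores each region from 36 features: 5′ heterogeneity, read-offset profile
around the modal 5′ end (−7..+7), GC/dinucleotide composition,
Wootton–Federhen complexity, median read length, and the minimum duplex
energy between the region's most frequent read and the surrounding 70 bp
windows (RNAduplex).

Each passing product seeds candidate precursor spans two ways:
**duplex-focused** (the region between the product and its optimal duplex
in the flanking genome — the miR:miR\* duplex, not the fold, defines the
span) and **product-focused** (between the product and any other product
≥ 5 nt away). Candidates are folded (RNAfold, 37 °C), read stacks are
named as the products Drosha/Dicer would produce (miR-5p/miR-3p at the
duplex register, moRs, loop, out), and the **HPRF** (hairpin-precursor
random forest) scores each candidate from 71 sequence, structure and
read-distribution features (fold MFE, pairing densities, bulge/interior
loop geometry, product overlaps and shifts, read-count variances, strand
ARPMs, a 1 kb neighbour count, and the mean MPRF decision value).
Overlapping candidates are resolved best-score-first; final calls require
HPRF decision value ≥ 0.28 and ≥ 0.11 ARPM (tuned defaults; the 1:25
positive:negative training ratio, decision value and ARPM threshold were
selected by F-score grid search).

Post-processing assigns homology for unannotated matures (identical seed,
positions 2–8, and E < 0.05 against a known-mature database), chains
precursors into genomic clusters (≤ 10 kbp, annotated loci first), and
finds novel families (perfect seed, same arm, E ≤ 0.5, with
antisense-to-self and identical-mature exclusions). Dicer-knockdown
support uses log₂ fold changes with a 0.015 ARPM pseudocount.

## Requirements and installation

R ≥ 4.0 with Bioconductor (Rsamtools, Biostrings, IRanges,
GenomicRanges), `ranger`, `jsonlite`, and the **ViennaRNA** command-line
tools (`RNAfold`, `RNAduplex`) on `PATH`.

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "mirforest", load_package = "installed")'
```

## Worked example

Everything below is fully synthetic — the package ships a generator that
plants hairpin loci with Dicer/Drosha-style read stacks plus background
noise, so the whole pipeline can be exercised without downloads:

```r
library(mirforest)

train <- simulate_mir_experiment(sim_config(seed = 11, genome_length = 60000,
                                            n_hairpins = 10, n_noise_loci = 80))
test  <- simulate_mir_experiment(sim_config(seed = 13, genome_length = 60000,
                                            n_hairpins = 10, n_noise_loci = 80))
train
#> mir_simulation: genome 60000 nt; 10 hairpins, 80 noise loci, 866 aligned reads (seed 11)

fit <- mir_forest(train$reads, train$genome, train$annotations, seed = 1)
fit
#> Stacked microRNA discovery model (mir_forest)
#>   MPRF: 20 pos / 20 neg, 500 trees
#>   HPRF: 10 pos / 88 neg, 500 trees
#>   thresholds: MPRF >= 0.5 | HPRF >= 0.28 | ARPM >= 0.11
#>   engine: RNAfold 2.7.2

pred <- predict(fit, test$reads, test$genome)
pred
#> mir_predictions: 10 predicted precursor(s), 10 scored locus/loci
#>   duplex-focused span fraction: 80.0%

head(pred$predictions[, c("chrom","strand","start","end","origin","hprf_score")], 3)
#>   chrom strand start   end          origin hprf_score
#> 1  chr1      -  1551  1624  duplex_focused      0.946
#> 2  chr1      + 14311 14386  duplex_focused      0.860
#> 3  chr1      - 18096 18166 product_focused      0.762

rrs <- group_read_regions(annotate_hit_counts(test$reads))
pr  <- precision_recall(pred, test$annotations, rrs = rrs)
f   <- f_scores(pr$precision, pr$recall)
sprintf("precision %.3f  recall %.3f  F1 %.3f", pr$precision, pr$recall, f$f1)
#> "precision 1.000  recall 1.000  F1 1.000"
```

All 10 planted hairpins are recovered with no false calls; 80% of the
final spans came from the duplex-focused method. `pred$locus_scores`
retains a score for every evaluated locus (also the rejected ones), which
is what `pr_curve_auprc()` consumes for precision–recall curves.

File-level wrappers (`run_train`, `run_discover`, `run_tune`,
`run_evaluate`, `run_simulate`) operate on SAM/FASTA/GFF3 paths and write
GFF3/TSV/JSON outputs; `inst/cli/mirforest.R` is a thin shell front end
over them.

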