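# hairpin_rf: product naming, distribution/overlap/variance features, the
# 71-feature vector, training-set construction and prediction thresholds

# a clean folded candidate with controllable read stacks, built from a
# planted hairpin on the plus strand
hairpin_scene <- function(seed = 23, loop = 14, star_reads = 2,
                          mor_reads = 0, loop_reads = 0) {
  set.seed(seed)
  mir <- random_seq(22)
  genome <- c(chr1 = paste0(random_seq(120), mir, random_seq(loop), rc(mir),
                            random_seq(120)))
  mir_span <- c(120, 142)
  star_span <- c(142 + loop, 164 + loop)
  reads <- make_reads(rep(mir_span[1], 5), rep(mir_span[2], 5), seq = mir,
                      id = sprintf("m%d", 1:5))
  if (star_reads > 0) {
    seg <- substr(genome, star_span[1] + 1, star_span[2])
    reads <- rbind(reads, make_reads(rep(star_span[1], star_reads),
                                     rep(star_span[2], star_reads),
                                     seq = seg,
                                     id = sprintf("s%d", 1:star_reads)))
  }
  if (mor_reads > 0) {
    seg <- substr(genome, 102 + 1, 120)
    reads <- rbind(reads, make_reads(rep(102, mor_reads),
                                     rep(120, mor_reads), seq = seg,
                                     id = sprintf("o%d", 1:mor_reads)))
  }
  if (loop_reads > 0) {
    seg <- substr(genome, 144 + 1, 154)
    reads <- rbind(reads, make_reads(rep(144, loop_reads),
                                     rep(154, loop_reads), seq = seg,
                                     id = sprintf("l%d", 1:loop_reads)))
  }
  rrs <- group_read_regions(reads)
  sdp <- stack_duplex_energies(rrs, genome)
  major <- rrs$regions$region_id[rrs$regions$start == mir_span[1]]
  cands <- generate_candidates(rrs, rrs$regions$region_id, genome, sdp)
  cands <- fold_candidates(cands, rrs, genome)
  cand <- cands[cands$origin == "duplex_focused" &
                cands$major_region_id == major, ][1, ]
  anatomy <- parse_hairpin(cand$structure, c(cand$mir_t1, cand$mir_t2))
  lib <- sample_library(annotate_hit_counts(reads))
  list(genome = genome, reads = reads, rrs = rrs, cand = cand,
       anatomy = anatomy, lib = lib, mir_span = mir_span,
       star_span = star_span, major = major)
}

test_that("products are named miR/miR*/moR/loop as Dicer/Drosha would cut", {
  sc <- hairpin_scene(star_reads = 2, mor_reads = 2, loop_reads = 1)
  p <- name_products(sc$cand, sc$anatomy, sc$rrs)
  expect_equal(sum(p$is_major), 1)
  expect_equal(p$label[p$is_major], "miR-5p")
  expect_true("miR-3p" %in% p$label)   # star at the duplex register
  expect_true("moR-5p" %in% p$label)   # abutting upstream stack
  expect_true("loop" %in% p$label)
  # labels partition the stacks
  expect_false(any(is.na(p$label)))
})

test_that("a stack centered on the loop is labeled loop; lone major gets miR", {
  sc <- hairpin_scene(star_reads = 0, loop_reads = 2, loop = 18)
  p <- name_products(sc$cand, sc$anatomy, sc$rrs)
  expect_equal(p$label[p$is_major], "miR-5p")
  expect_true("loop" %in% p$label)
  expect_false("miR-3p" %in% p$label)
})

test_that("distribution features: urf, ahc, afh, RPM and product fractions", {
  sc <- hairpin_scene(star_reads = 2)
  rrs <- sc$rrs
  rrs$reads <- annotate_hit_counts(rrs$reads)
  p <- name_products(sc$cand, sc$anatomy, rrs)
  d <- distribution_features(p, sc$cand, rrs, sc$lib)
  expect_equal(d$urf, 1)          # all reads unique (n_r = 1)
  expect_equal(d$ahc, 1)
  expect_equal(d$afh, 0)          # homogeneous 5' ends
  # locus holds every sense read of the library
  expect_equal(d$totalSenseRPM, 1e6)
  expect_equal(d$totalAntisenseRPM, 0)
  fr <- unlist(d[grep("prodFrac", names(d))])
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(unname(fr["prodFrac_miR5p"]), 5 / 7)
  # hit-count average over a multimapping major product
  rd <- make_reads(c(0, 0, 0), c(22, 22, 22), hit = c(1, 1, 3),
                   id = c("a", "b", "c"),
                   seq = c("A", "C", "G"))
  rr2 <- group_read_regions(rd)
  rr2$reads$hit_count <- c(1L, 1L, 3L)
  p2 <- data.frame(label = "miR-5p", region_id = rr2$regions$region_id[1],
                   t_start = 0L, t_end = 22L, arm = "5p", is_major = TRUE,
                   total_dup = 3L, modal_t5 = 0L, stringsAsFactors = FALSE)
  cand2 <- data.frame(chrom = "chr1", strand = "+", start = 0L, end = 22L,
                      dup_found = FALSE, stringsAsFactors = FALSE)
  d2 <- distribution_features(p2, cand2, rr2,
                              sample_library(rr2$reads))
  expect_equal(d2$ahc, 5 / 3)
})

test_that("overlap features measure the labelled pairs in nucleotides", {
  # hand-built products: miR-5p [10,32), moR-5p [0,12) -> 2 nt overlap
  p <- data.frame(label = c("miR-5p", "moR-5p"), region_id = 1:2,
                  t_start = c(10L, 0L), t_end = c(32L, 12L),
                  arm = "5p", is_major = c(TRUE, FALSE),
                  total_dup = c(10L, 2L), modal_t5 = c(10L, 0L),
                  stringsAsFactors = FALSE)
  cand <- data.frame(chrom = "chr1", strand = "+", start = 0L, end = 60L,
                     dup_found = FALSE, stringsAsFactors = FALSE)
  rrs <- group_read_regions(make_reads(c(10, 0), c(32, 12),
                                       id = c("a", "b"),
                                       seq = c("A", "C")))
  o <- overlap_shift_features(p, cand, rrs)
  expect_equal(o$miRmoR5pOverlap, 2)
  expect_equal(o$totalOverlap, 2)
  expect_equal(o$totalRelativeOverlapAmount, 2 * 2 / 10)
  expect_equal(o$averageOverlapAmount, 2 * 2 / 12)
  expect_equal(o$sameShift, 10)
  expect_equal(o$tapd, 0)  # no antisense products
  expect_equal(o$aapd, 0)
  # disjoint clean products: all overlaps zero
  p2 <- p; p2$t_start <- c(20L, 0L); p2$t_end <- c(42L, 18L)
  o2 <- overlap_shift_features(p2, cand, rrs)
  expect_equal(o2$totalOverlap, 0)
  expect_equal(o2$miRmoR5pOverlap, 0)
})

test_that("variance features use population variance with stated weights", {
  # one product, distinct dup counts {4,2}: population variance 1
  rd <- make_reads(c(0, 1), c(22, 23), dup = c(4, 2), id = c("a", "b"),
                   seq = c("A", "C"))
  rrs <- group_read_regions(rd)
  p <- data.frame(label = "miR-5p", region_id = rrs$regions$region_id[1],
                  t_start = 0L, t_end = 23L, arm = "5p", is_major = TRUE,
                  total_dup = 6L, modal_t5 = 0L, stringsAsFactors = FALSE)
  v <- variance_features(p, rrs)
  expect_equal(v$APV, 1)
  expect_equal(v$wAPV, 1)
  # start positions 0 (w 4) and 1 (w 2): weighted pop var = 2/9
  expect_equal(v$ARV, 2 / 9)
  # single-distinct-read products have zero variance
  rd2 <- make_reads(0, 22)
  rr2 <- group_read_regions(rd2)
  p2 <- p; p2$region_id <- rr2$regions$region_id[1]
  expect_equal(variance_features(p2, rr2)$APV, 0)
})

test_that("neighbor count applies the 1000 nt window, excluding the candidate", {
  mk <- function(starts) {
    group_read_regions(make_reads(starts, starts + 22,
                                  id = sprintf("n%d", seq_along(starts)),
                                  seq = as.character(seq_along(starts))))
  }
  cand <- data.frame(chrom = "chr1", start = 5000L, end = 5100L,
                     stringsAsFactors = FALSE)
  expect_equal(neighbor_count(cand, mk(5010)), 0)       # inside: excluded
  expect_equal(neighbor_count(cand, mk(c(4578, 6099))), 2)  # 400 & 999 away
  expect_equal(neighbor_count(cand, mk(6101)), 0)       # 1001 away
  expect_equal(neighbor_count(cand, mk(6100)), 1)       # exactly 1000
})

test_that("the hairpin feature vector has all 71 features, finite, in order", {
  sc <- hairpin_scene(star_reads = 2, mor_reads = 1)
  rrs <- sc$rrs
  rrs$reads <- annotate_hit_counts(rrs$reads)
  cands <- generate_candidates(rrs, rrs$regions$region_id, sc$genome,
                               stack_duplex_energies(rrs, sc$genome))
  cands <- fold_candidates(cands, rrs, sc$genome)
  scores <- data.frame(region_id = rrs$regions$region_id,
                       mprf_score = 0.8)
  h <- hairpin_feature_matrix(cands, rrs, sc$lib, scores)
  expect_equal(names(h)[-1], hprf_feature_names())
  expect_equal(ncol(h), 72)
  expect_true(all(is.finite(as.matrix(h))))
  expect_equal(h$RFProductAvg, rep(0.8, nrow(h)))
  # clean planted hairpin: strong duplex, high pairing of the miR
  # (select the duplex-focused candidate whose major product is the miR)
  dc <- h[cands$origin == "duplex_focused" &
          cands$major_region_id == sc$major, ][1, ]
  expect_lt(dc$duplexEnergy, -15)
  expect_gte(dc$pbp, 0.8)
})

test_that("HPRF training picks best-overlap positives and samples negatives", {
  sim <- small_sim(11)
  reads <- annotate_hit_counts(sim$reads)
  rrs <- group_read_regions(reads)
  lib <- sample_library(rrs$reads)
  sdp <- stack_duplex_energies(rrs, sim$genome)
  cands <- generate_candidates(rrs, rrs$regions$region_id, sim$genome, sdp)
  cands <- fold_candidates(cands, rrs, sim$genome)
  scores <- data.frame(region_id = rrs$regions$region_id, mprf_score = 0.5)
  h <- hairpin_feature_matrix(cands, rrs, lib, scores)
  tr <- build_hprf_training_set(cands, h, sim$annotations, ratio_x = 2,
                                seed = 3)
  n_pos <- sum(tr$y == "pos")
  expect_gte(n_pos, 5)
  expect_lte(sum(tr$y == "neg"), 2 * n_pos)
  # positives: among candidates over an annotation, the best reciprocal
  # overlap wins
  prec <- sim$annotations[sim$annotations$kind == "precursor", ][1, ]
  over <- cands[cands$chrom == prec$chrom & cands$strand == prec$strand &
                cands$start < prec$end & cands$end > prec$start, ]
  ov <- pmin(over$end, prec$end) - pmax(over$start, prec$start)
  recip <- pmin(ov / (over$end - over$start), ov / (prec$end - prec$start))
  expect_true(over$cand_id[which.max(recip)] %in% tr$cand_id[tr$y == "pos"])
  # negatives never overlap an annotation on either strand
  negs <- cands[match(tr$cand_id[tr$y == "neg"], cands$cand_id), ]
  ann <- sim$annotations
  for (i in seq_len(nrow(negs))) {
    expect_false(any(ann$chrom == negs$chrom[i] &
                     ann$start < negs$end[i] & ann$end > negs$start[i]))
  }
  # reproducible under the same seed
  tr2 <- build_hprf_training_set(cands, h, sim$annotations, 2, seed = 3)
  expect_identical(tr$cand_id, tr2$cand_id)
})

test_that("prediction applies score and expression thresholds, then resolves", {
  fit <- small_fit()
  sim <- small_sim(13)
  pred <- predict(fit, sim$reads, sim$genome)
  expect_s3_class(pred, "mir_predictions")
  expect_true(all(pred$predictions$hprf_score >= fit$y_threshold))
  expect_true(all(pred$predictions$totalSenseRPM >=
                  fit$expression_threshold))
  # the locus score table includes sub-threshold loci
  expect_gte(nrow(pred$locus_scores), nrow(pred$predictions))
  # raising the threshold shrinks predictions monotonically
  strict <- predict(fit, sim$reads, sim$genome, y_threshold = 0.95)
  expect_lte(nrow(strict$predictions), nrow(pred$predictions))
  expect_true(all(strict$predictions$hprf_score >= 0.95))
  # shipped tuned defaults
  expect_equal(fit$y_threshold, 0.28)
  expect_equal(fit$expression_threshold, 0.11)
  expect_equal(fit$meta$hprf_ratio, 25)
})
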