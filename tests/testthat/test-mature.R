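# mature_product_rf: per-region features, training set, scoring

test_that("Wootton-Federhen complexity matches the closed form", {
  expect_equal(wootton_federhen("AAAAAA"), 0)
  expect_equal(wootton_federhen("ACGT"), log(24) / (4 * log(4)),
               tolerance = 1e-12)
  # invariant under base relabeling
  expect_equal(wootton_federhen("AACGT"), wootton_federhen("CCATG"))
  # ambiguous symbols excluded from counts
  expect_equal(wootton_federhen("ACGTNN"), wootton_federhen("ACGT"))
})

test_that("5' heterogeneity is the non-modal weighted fraction", {
  expect_equal(five_prime_heterogeneity(make_reads(c(10, 10), c(32, 33))), 0)
  # two equal stacks at distinct 5' ends: tie broken to leftmost modal
  expect_equal(five_prime_heterogeneity(make_reads(c(10, 15), c(32, 37))), 0.5)
  r <- make_reads(c(10, 11), c(32, 33), dup = c(8, 2))
  expect_equal(five_prime_heterogeneity(r), 0.2)
  # minus strand: 5' end is the right edge
  rm <- make_reads(c(10, 9), c(32, 32), "-", dup = c(3, 1))
  expect_equal(five_prime_heterogeneity(rm), 0)
})

test_that("read offset profile is strand-aware and sums to 1 within the window", {
  single <- read_offset_profile(make_reads(10, 32))
  expect_equal(unname(single["s0"]), 1)
  expect_equal(sum(single), 1)
  r <- make_reads(c(10, 10, 10, 11), c(32, 32, 32, 33))
  p <- read_offset_profile(r)
  expect_equal(unname(p["s0"]), 0.75)
  expect_equal(unname(p["f1"]), 0.25)
  # on the minus strand +1 (f1) is genomically one base left of modal
  rm <- make_reads(c(10, 9), c(32, 31), "-", dup = c(3, 1))
  pm <- read_offset_profile(rm)
  expect_equal(unname(pm["s0"]), 0.75)
  expect_equal(unname(pm["f1"]), 0.25)
})

test_that("stack duplex energy finds the planted complement in the flank", {
  set.seed(9)
  mir <- random_seq(22)
  genome <- c(chr1 = paste0(random_seq(100), mir, random_seq(14), rc(mir),
                            random_seq(100)))
  reads <- make_reads(100, 122, seq = mir)
  rrs <- group_read_regions(reads)
  sd <- stack_duplex_energies(rrs, genome)
  expect_lt(sd$energy, -15)
  expect_equal(sd$side, "down")
  # the duplexed genomic span is the planted complement
  expect_lte(abs(sd$t_gstart - 136), 3)
  expect_lte(abs(sd$t_gend - 158), 3)
  # poly-A flanks give the sentinel
  genome2 <- c(chr1 = paste0(strrep("A", 100), mir, strrep("A", 100)))
  sd2 <- stack_duplex_energies(group_read_regions(reads), genome2)
  expect_equal(sd2$energy, 0)
})

test_that("feature vectors are complete and match a per-feature oracle", {
  set.seed(21)
  mir <- random_seq(22)
  genome <- c(chr1 = paste0(random_seq(80), mir, random_seq(12), rc(mir),
                            random_seq(80)))
  reads <- rbind(
    make_reads(rep(80, 3), rep(102, 3), seq = mir, id = c("a", "b", "c")),
    make_reads(81, 103, seq = paste0(substr(mir, 2, 22), "A"), id = "d"))
  rrs <- group_read_regions(reads)
  m <- mprf_feature_matrix(rrs, genome)
  expect_equal(ncol(m), 37)
  expect_false(anyNA(m))
  expect_equal(names(m)[-1], mprf_feature_names())
  # independent recomputation of each feature family
  expect_equal(m$fivePrimeHet, 0.25)
  expect_equal(m$medianLength, 22)
  s <- strsplit(mir, "")[[1]]
  expect_equal(m$gcContent, mean(s %in% c("G", "C")))
  di <- paste0(tolower(s[-22]), tolower(s[-1]))
  expect_equal(m[1, di[1]], sum(di == di[1]) / 21)
  expect_equal(m$s0, 0.75)
  expect_equal(m$f1, 0.25)
  cnt <- table(factor(s, levels = c("A", "C", "G", "T")))
  expect_equal(m$WFC, (lfactorial(22) - sum(lfactorial(cnt))) / (22 * log(4)))
  expect_lt(m$duplexEnergy, -10)
  # dinucleotide frequencies sum to 1
  expect_equal(sum(m[1, 5:20]), 1, tolerance = 1e-9)
  # offset profile sums to 1 when all 5' ends are within the window
  expect_equal(sum(m[1, 21:35]), 1, tolerance = 1e-9)
})

empty_ann <- function() {
  data.frame(name = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), kind = character(),
             parent = character(), arm = character(), stringsAsFactors = FALSE)
}

test_that("training set sampling respects the ratio and the seed", {
  sim <- small_sim(11)
  reads <- annotate_hit_counts(sim$reads)
  rrs <- group_read_regions(reads)
  feats <- mprf_feature_matrix(rrs, genome = NULL)
  tr1 <- build_mprf_training_set(feats, rrs, sim$annotations, 1, seed = 5)
  expect_equal(sum(tr1$y == "neg"), sum(tr1$y == "pos"))
  tr3 <- build_mprf_training_set(feats, rrs, sim$annotations, 3, seed = 5)
  expect_equal(sum(tr3$y == "neg"),
               min(3 * sum(tr3$y == "pos"),
                   nrow(rrs$regions) - length(unique(
                     c(which(mirforest:::regions_overlapping(
                       rrs$regions, sim$annotations, "mature", "either")),
                       which(mirforest:::regions_overlapping(
                         rrs$regions, sim$annotations, "precursor",
                         "either")))))))
  tr1b <- build_mprf_training_set(feats, rrs, sim$annotations, 1, seed = 5)
  expect_identical(tr1$region_id, tr1b$region_id)
  expect_error(build_mprf_training_set(feats, rrs, empty_ann(), 1, 1),
               "positive")
})

test_that("MPRF separates planted stacks from noise and never drops single reads", {
  sim <- small_sim(11)
  reads <- annotate_hit_counts(sim$reads)
  rrs <- group_read_regions(reads)
  feats <- mprf_feature_matrix(rrs, sim$genome)
  tr <- build_mprf_training_set(feats, rrs, sim$annotations, 1, seed = 1)
  model <- train_mprf(tr, seed = 1)
  sc <- score_read_regions(model, feats)
  pos <- mirforest:::regions_overlapping(rrs$regions, sim$annotations,
                                         "mature", "same")
  # AUROC via rank statistic
  r <- rank(sc$mprf_score)
  auroc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  expect_gte(auroc, 0.95)
  # scoring is deterministic and total: every region, even single-read ones
  expect_equal(nrow(sc), nrow(rrs$regions))
  single <- rrs$regions$n_reads == 1
  expect_true(any(single))
  expect_false(anyNA(sc$mprf_score[single]))
  expect_identical(sc, score_read_regions(model, feats))
  # feature order mismatch is a hard error
  bad <- feats[, c(1, ncol(feats):2)]
  expect_error(score_read_regions(model, bad), "order")
})
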