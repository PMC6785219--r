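# folding_geometry: engine contract, duplexes, dot-bracket anatomy

test_that("folding is deterministic, handles unstructured input, recovers planted stems", {
  f <- rna_fold("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$mfe, 0)
  stem <- "GCGCGCGCGCGC"
  hp <- paste0(stem, "AAAA", rc(stem))
  f2 <- rna_fold(hp)
  pt <- pair_table(f2$structure)
  expect_gte(sum(pt[1:12] > 0), 10)   # >= 10 of 12 stem pairs form
  expect_identical(rna_fold(hp), rna_fold(hp))
})

test_that("duplex finds full pairing with the reverse complement and none with poly-A", {
  set.seed(3)
  q <- random_seq(22)
  d <- rna_duplex(q, rc(q))
  expect_true(d$found)
  expect_lt(d$energy, -15)
  expect_gte(d$q_end - d$q_start, 18)
  d2 <- rna_duplex(strrep("A", 22), strrep("A", 22))
  expect_false(d2$found)
  expect_equal(d2$energy, 0)
})

test_that("duplex locates a complement planted at a known target offset", {
  set.seed(5)
  q <- random_seq(22)
  target <- paste0(random_seq(30), rc(q), random_seq(18))
  d <- rna_duplex(q, target)
  expect_true(d$found)
  expect_lte(abs(d$t_start - 30), 3)
  expect_lte(abs(d$t_end - 52), 3)
  expect_lt(d$energy, -15)
})

test_that("hairpin anatomy parses simple stems, interior loops and offshoots", {
  # plain stem-loop
  a <- parse_hairpin("((((....))))", c(0, 4))
  expect_equal(a$main_loop, c(4, 8))
  expect_false(a$no_hairpin)
  sf <- structural_features(a, c(0, 4))
  expect_equal(sf$loopSize, 4)
  expect_equal(sf$maxBulge, 0)
  expect_equal(sf$maxInteriorLoop, 0)
  # symmetric 1x1 interior loop
  b <- parse_hairpin("(((.((....)).)))", c(0, 3))
  sfb <- structural_features(b, c(0, 16))
  expect_equal(sfb$maxInteriorLoop, 2)
  expect_equal(sfb$intLoopSideDiff, 0)
  # anchor reaching into a stem adopts it even without an enclosing pair
  cta <- parse_hairpin("....((((....))))", c(0, 5))
  expect_false(cta$no_hairpin)
  expect_equal(cta$main_loop, c(8, 12))
  # fully unpaired anchor with no stem at all: flagged no-hairpin
  d <- parse_hairpin("....................", c(0, 5))
  expect_true(d$no_hairpin)
})

test_that("multibranch descent picks the longer stem and counts offshoots", {
  # outer stem enclosing a multiloop with a 6-pair and a 3-pair hairpin
  st <- "((.((((((....)))))).(((...))).))"
  a <- parse_hairpin(st, c(0, 2))
  # main loop belongs to the 6-pair stem; the 3-pair stem is an offshoot
  expect_equal(a$main_loop, c(9, 13))
  expect_equal(a$offshoots, 1)
  sf <- structural_features(a, c(0, 2))
  expect_equal(sf$numOffshoots, 1)
  # the loop region (interior of the multiloop-closing pair) holds two
  # unpaired runs of >= 3 nt (the two hairpin loops): > 1 flags multibranch
  expect_equal(sf$innerLoopGapCount, 2)
})

test_that("anatomy classification is a partition of the structure", {
  folds <- random_structures(60, 80)
  for (i in seq_len(nrow(folds))) {
    st <- folds$structure[i]
    d <- mirforest:::decompose_structure(st)
    expect_equal(length(d$class), nchar(st))
    expect_false(any(is.na(d$class)))
    counts <- table(factor(d$class, levels = c("paired", "loop", "bulge",
                                               "interior", "exterior")))
    expect_equal(sum(counts), nchar(st))
    expect_equal(unname(counts["paired"]), sum(pair_table(st) > 0))
  }
})

test_that("loop decomposition agrees with the brute-force pair-table oracle", {
  folds <- random_structures(100, 80)
  for (i in seq_len(nrow(folds))) {
    st <- folds$structure[i]
    d <- mirforest:::decompose_structure(st)
    o <- oracle_classify(st)
    expect_equal(unname(d$class), unname(o$class), label = st)
  }
})

test_that("structural features match the oracle on random structures", {
  folds <- random_structures(100, 80)
  n_checked <- 0
  for (i in seq_len(nrow(folds))) {
    st <- folds$structure[i]
    pt <- pair_table(st)
    pairs <- which(pt > seq_along(pt))
    # anchor at the stem enclosing the first hairpin loop, so the main loop
    # is unambiguous for the oracle
    o <- oracle_classify(st)
    hp_runs <- Filter(function(r) r$type == "hairpin", o$runs)
    if (length(hp_runs) == 0) next
    run <- hp_runs[[1]]$run
    ci <- run[1] - 1L; cj <- run[length(run)] + 1L
    expect_equal(pt[ci], cj)
    a <- parse_hairpin(st, c(ci - 1L, cj))
    sf <- structural_features(a, c(0L, nchar(st)))
    # oracle values computed directly from the classified runs
    expect_equal(sf$loopSize, length(run), label = st)
    bulges <- Filter(function(r) r$type == "bulge", o$runs)
    expect_equal(sf$maxBulge,
                 if (length(bulges)) max(vapply(bulges, `[[`, 0, "size"))
                 else 0, label = st)
    ints <- Filter(function(r) r$type == "interior", o$runs)
    expect_equal(sf$maxInteriorLoop,
                 if (length(ints)) max(vapply(ints, `[[`, 0, "size"))
                 else 0, label = st)
    # anchored at a hairpin-closing pair the inner region is that loop
    expect_equal(sf$innerLoopGapCount, as.integer(length(run) >= 3),
                 label = st)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("miR-anchored features read bulges, overhangs and loop distance", {
  # 3-nt bulge (positions 4-6) inside the mir span
  st <- "(((...((((....)))))))"
  a <- parse_hairpin(st, c(0, 10))
  sf <- structural_features(a, c(0, 10))
  expect_equal(sf$maxBulge, 3)
  # fully paired mir has pbp 1 and no overhang
  b <- parse_hairpin("((((((....))))))", c(0, 6))
  sfb <- structural_features(b, c(0, 6))
  expect_equal(sfb$pbp, 1)
  expect_equal(sfb$maxUnboundOverhang, 0)
  expect_equal(sfb$mpLoopDistance, 0)  # mir abuts the loop
  # mir covering unpaired tail: overhang counted
  cc <- parse_hairpin("..((((....))))", c(0, 6))
  sfc <- structural_features(cc, c(0, 6))
  expect_equal(sfc$maxUnboundOverhang, 2)
})

test_that("fold/duplex agreement is a fraction over the span", {
  st <- "((((....))))"
  full <- rep(TRUE, 12); full[5:8] <- FALSE
  expect_equal(fold_duplex_agreement(st, full, c(0, 12)), 1)
  expect_equal(fold_duplex_agreement(st, !full, c(0, 12)), 0)
  half <- c(rep(TRUE, 4), rep(TRUE, 4), rep(FALSE, 4))
  # positions 1-4 agree (paired), 5-8 disagree, 9-12 disagree
  expect_equal(fold_duplex_agreement(st, half, c(0, 12)), 4 / 12)
  expect_equal(fold_duplex_agreement(st, full, c(3, 3)), 1)  # empty span
})

test_that("duplex-derived pairing vector maps query and target spans", {
  dup <- data.frame(found = TRUE, structure = "(((&)))", q_start = 2L,
                    q_end = 5L, t_start = 10L, t_end = 13L,
                    stringsAsFactors = FALSE)
  v <- duplex_paired_vector(dup, 20, q_offset = 0L)
  expect_equal(which(v), c(3:5, 11:13))
  v2 <- duplex_paired_vector(data.frame(found = FALSE), 20)
  expect_false(any(v2))
})
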