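# The stacked model: mir_forest() fits both random-forest layers from an
# annotated training sample; predict() runs the full discovery pipeline
# (regions -> MPRF -> spans -> HPRF -> overlap resolution -> thresholds).

prepare_sample <- function(reads, sample_id = "sample", trust_nh = FALSE) {
  reads <- annotate_hit_counts(reads, trust_nh = trust_nh)
  rrs <- group_read_regions(reads)
  list(rrs = rrs,
       library = sample_library(rrs$reads, sample_id))
}

# MPRF scoring + candidate generation + HPRF features for one sample.
# extra_pass_ids forces regions into the candidate stage regardless of
# their MPRF score (used to guarantee annotated positives during training).
candidate_stage <- function(rrs, genome, library, mprf_model, mprf_threshold,
                            params, extra_pass_ids = integer(0)) {
  sd <- stack_duplex_energies(rrs, genome, params$window)
  feats <- mprf_feature_matrix(rrs, genome, params$window, stack_dup = sd)
  scores <- score_read_regions(mprf_model, feats)
  passing <- union(scores$region_id[scores$mprf_score >= mprf_threshold],
                   extra_pass_ids)
  cands <- generate_candidates(rrs, passing, genome, sd, params)
  cands <- fold_candidates(cands, rrs, genome)
  hfeats <- hairpin_feature_matrix(cands, rrs, library, scores, params)
  list(mprf_feats = feats, mprf_scores = scores, passing = passing,
       cands = cands, hfeats = hfeats)
}

#' Build the hairpin-precursor training set
#'
#' Positives: for each annotated precursor, the single same-strand candidate
#' with the greatest reciprocal overlap (minimum of the two mutual overlap
#' fractions). Negatives: candidates overlapping no annotation on either
#' strand, stratified-sampled (seeded) at \code{ratio_x} per positive.
#'
#' @param cands folded candidates.
#' @param hfeats hairpin feature matrix for \code{cands}.
#' @param annotations annotation data frame.
#' @param ratio_x negatives per positive (tuned default 25).
#' @param seed RNG seed for the negative sample.
#' @return list \code{x}, \code{y}, \code{cand_id}.
#' @export
build_hprf_training_set <- function(cands, hfeats, annotations, ratio_x = 25,
                                    seed = 1L) {
  prec <- annotations[annotations$kind == "precursor", , drop = FALSE]
  pos_ids <- integer(0)
  for (i in seq_len(nrow(prec))) {
    a <- prec[i, ]
    same <- cands$chrom == a$chrom & cands$strand == a$strand &
      cands$start < a$end & cands$end > a$start
    if (!any(same)) next
    sub <- cands[same, , drop = FALSE]
    ov <- pmin(sub$end, a$end) - pmax(sub$start, a$start)
    recip <- pmin(ov / (sub$end - sub$start), ov / (a$end - a$start))
    pos_ids <- c(pos_ids, sub$cand_id[which.max(recip)])
  }
  pos_ids <- unique(pos_ids)
  if (length(pos_ids) == 0) stop("no positive training candidates")
  ann_hit <- vapply(seq_len(nrow(cands)), function(i) {
    any(annotations$chrom == cands$chrom[i] &
        annotations$start < cands$end[i] &
        annotations$end > cands$start[i])
  }, logical(1))
  neg_pool <- cands$cand_id[!ann_hit]
  n_neg <- min(length(neg_pool), ratio_x * length(pos_ids))
  old <- .Random.seed_save()
  set.seed(seed)
  neg_ids <- sort(sample(neg_pool, n_neg))
  .Random.seed_restore(old)
  ids <- c(pos_ids, neg_ids)
  list(x = hfeats[match(ids, hfeats$cand_id), -1, drop = FALSE],
       y = factor(rep(c("pos", "neg"), c(length(pos_ids), length(neg_ids))),
                  levels = c("neg", "pos")),
       cand_id = ids)
}

#' Fit a stacked microRNA discovery model
#'
#' Trains both classifier layers on one annotated small RNA-seq sample: the
#' mature-product random forest (MPRF) on read regions labelled by overlap
#' with annotated mature microRNAs, then the hairpin-precursor random
#' forest (HPRF) on candidate precursor spans generated from MPRF-passing
#' products and labelled by reciprocal overlap with annotated precursors.
#'
#' @param reads aligned reads (\code{\link{load_alignments}}).
#' @param genome named character vector (\code{\link{load_genome}}).
#' @param annotations \code{\link{load_annotations}} data frame.
#' @param mprf_ratio negatives per positive for the MPRF (default 1, which
#'   lets as many products as possible into the hairpin phase).
#' @param hprf_ratio negatives per positive for the HPRF (tuned default 25).
#' @param mprf_threshold minimum MPRF decision value for a product to enter
#'   span finding (default 0.5).
#' @param y_threshold default HPRF decision-value threshold carried by the
#'   model (tuned default 0.28).
#' @param expression_threshold default ARPM threshold (tuned default 0.11).
#' @param num_trees trees per forest (default 500).
#' @param seed RNG seed (negative sampling and forest growth).
#' @param params \code{\link{span_params}}.
#' @return object of class \code{mir_forest}.
#' @export
mir_forest <- function(reads, genome, annotations, mprf_ratio = 1,
                       hprf_ratio = 25, mprf_threshold = 0.5,
                       y_threshold = 0.28, expression_threshold = 0.11,
                       num_trees = 500, seed = 1L, params = span_params()) {
  smp <- prepare_sample(reads)
  rrs <- smp$rrs
  feats <- mprf_feature_matrix(rrs, genome, params$window)
  mtr <- build_mprf_training_set(feats, rrs, annotations, mprf_ratio, seed)
  mprf <- train_mprf(mtr, num_trees = num_trees, seed = seed)
  # during training every region enters the candidate stage: annotated
  # products must yield positive candidates regardless of their MPRF score,
  # and sub-threshold background is the negative pool for the hairpin layer
  stage <- candidate_stage(rrs, genome, smp$library, mprf, mprf_threshold,
                           params, extra_pass_ids = rrs$regions$region_id)
  htr <- build_hprf_training_set(stage$cands, stage$hfeats, annotations,
                                 hprf_ratio, seed)
  hprf <- train_forest(htr$x, htr$y, num_trees, seed, hprf_feature_names())
  class(hprf) <- "hprf_model"
  obj <- list(mprf = mprf, hprf = hprf,
              mprf_threshold = mprf_threshold,
              y_threshold = y_threshold,
              expression_threshold = expression_threshold,
              params = params,
              meta = list(seed = seed, num_trees = num_trees,
                          mprf_ratio = mprf_ratio, hprf_ratio = hprf_ratio,
                          engine = vienna_version(),
                          n_regions = nrow(rrs$regions),
                          n_candidates = nrow(stage$cands)),
              call = match.call())
  class(obj) <- "mir_forest"
  obj
}

#' @export
print.mir_forest <- function(x, ...) {
  cat("Stacked microRNA discovery model (mir_forest)\n")
  cat("  MPRF:", x$mprf$meta$n_pos, "pos /", x$mprf$meta$n_neg, "neg,",
      x$mprf$meta$num_trees, "trees\n")
  cat("  HPRF:", x$hprf$meta$n_pos, "pos /", x$hprf$meta$n_neg, "neg,",
      x$hprf$meta$num_trees, "trees\n")
  cat("  thresholds: MPRF >=", x$mprf_threshold,
      "| HPRF >=", x$y_threshold,
      "| ARPM >=", x$expression_threshold, "\n")
  cat("  engine:", x$meta$engine, "\n")
  invisible(x)
}

#' @method summary mir_forest
#' @export
summary.mir_forest <- function(object, ...) {
  print(object)
  cat("\nTop MPRF features (impurity importance):\n")
  imp <- sort(object$mprf$forest$variable.importance, decreasing = TRUE)
  print(round(utils::head(imp, 8), 2))
  cat("\nTop HPRF features (impurity importance):\n")
  imp <- sort(object$hprf$forest$variable.importance, decreasing = TRUE)
  print(round(utils::head(imp, 8), 2))
  invisible(object)
}

#' Discover microRNA loci with a fitted model
#'
#' Runs the full pipeline on a new sample: reads are grouped into regions,
#' scored by the MPRF, passing products generate duplex- and
#' product-focused candidate spans, candidates are folded and scored by the
#' HPRF, overlapping hairpins are resolved (best score wins), and the
#' tuned decision-value and ARPM thresholds are applied. Every resolved
#' locus keeps its score regardless of verdict, enabling precision-recall
#' curves.
#'
#' @param object a fitted \code{mir_forest}.
#' @param reads aligned reads of the sample to scan.
#' @param genome named character vector.
#' @param y_threshold,expression_threshold override the model's tuned
#'   thresholds.
#' @param ... unused.
#' @return object of class \code{mir_predictions}: list with
#'   \code{$predictions} (final calls: span, score, ARPM, origin, mature
#'   5p/3p coordinates and sequences) and \code{$locus_scores} (every
#'   resolved locus with its HPRF score and ARPM).
#' @export
predict.mir_forest <- function(object, reads, genome,
                               y_threshold = object$y_threshold,
                               expression_threshold =
                                 object$expression_threshold, ...) {
  smp <- prepare_sample(reads)
  rrs <- smp$rrs
  if (nrow(rrs$regions) == 0) return(empty_predictions())
  stage <- candidate_stage(rrs, genome, smp$library, object$mprf,
                           object$mprf_threshold, object$params)
  cands <- stage$cands
  if (nrow(cands) == 0) {
    return(empty_predictions())
  }
  cands$hprf_score <- forest_scores(object$hprf,
                                    stage$hfeats[, -1, drop = FALSE])
  cands$totalSenseRPM <- stage$hfeats$totalSenseRPM
  prods <- attr(stage$hfeats, "products")
  resolved <- resolve_overlapping_hairpins(cands)
  locus_scores <- resolved[, c("cand_id", "chrom", "strand", "start", "end",
                               "origin", "hprf_score", "totalSenseRPM")]
  keep <- resolved[resolved$hprf_score >= y_threshold &
                   resolved$totalSenseRPM >= expression_threshold, ,
                   drop = FALSE]
  preds <- locus_scores[match(keep$cand_id, locus_scores$cand_id), ,
                        drop = FALSE]
  mat <- lapply(keep$cand_id, function(id) {
    i <- match(id, cands$cand_id)
    p <- prods[[i]]
    cand <- cands[i, ]
    one <- function(lab) {
      k <- which(p$label == lab)
      if (length(k) == 0) return(c(NA_integer_, NA_integer_, NA_character_))
      k <- k[which.max(p$total_dup[k])]
      t1 <- p$t_start[k]; t2 <- p$t_end[k]
      if (cand$strand == "+") {
        g <- c(cand$start + t1, cand$start + t2)
      } else {
        g <- c(cand$end - t2, cand$end - t1)
      }
      c(g[1], g[2], most_frequent_seq(region_reads(rrs, p$region_id[k])))
    }
    c(one("miR-5p"), one("miR-3p"))
  })
  mat <- do.call(rbind, mat)
  if (nrow(preds)) {
    preds$mature_5p_start <- as.integer(mat[, 1])
    preds$mature_5p_end <- as.integer(mat[, 2])
    preds$mature_5p_seq <- mat[, 3]
    preds$mature_3p_start <- as.integer(mat[, 4])
    preds$mature_3p_end <- as.integer(mat[, 5])
    preds$mature_3p_seq <- mat[, 6]
  } else {
    preds <- empty_predictions()$predictions
  }
  rownames(preds) <- NULL
  structure(list(predictions = preds, locus_scores = locus_scores,
                 y_threshold = y_threshold,
                 expression_threshold = expression_threshold),
            class = "mir_predictions")
}

empty_predictions <- function() {
  preds <- data.frame(cand_id = integer(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), origin = character(),
                      hprf_score = numeric(), totalSenseRPM = numeric(),
                      mature_5p_start = integer(), mature_5p_end = integer(),
                      mature_5p_seq = character(),
                      mature_3p_start = integer(), mature_3p_end = integer(),
                      mature_3p_seq = character(), stringsAsFactors = FALSE)
  structure(list(predictions = preds, locus_scores = preds[, 1:8],
                 y_threshold = NA_real_, expression_threshold = NA_real_),
            class = "mir_predictions")
}

#' @export
print.mir_predictions <- function(x, ...) {
  cat("mir_predictions:", nrow(x$predictions), "predicted precursor(s),",
      nrow(x$locus_scores), "scored locus/loci\n")
  if (nrow(x$predictions)) {
    frac <- mean(x$predictions$origin == "duplex_focused")
    cat(sprintf("  duplex-focused span fraction: %.1f%%\n", 100 * frac))
  }
  invisible(x)
}
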