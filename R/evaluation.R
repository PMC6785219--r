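# Annotation-based evaluation: stringent true-positive rules (>=50% overlap
# of the annotation, correct fold direction, antisense exclusion),
# precision/recall and both F-score variants, precision-recall curves with
# AUPRC, the three-parameter F-score grid search, and knockdown log fold
# changes.

#' Classify one prediction against annotations
#'
#' A prediction is a true positive only if it overlaps an annotated
#' precursor on the same strand by at least half of the annotation's length
#' AND its fold runs in the right direction (each annotated mature of the
#' precursor falls on the same arm of the prediction as its name/position
#' indicates). Same-strand predictions failing either rule are "overlap"
#' false positives; opposite-strand overlaps are antisense false positives;
#' everything else is a novel call (a false positive against the
#' annotation set, possibly a genuine discovery).
#'
#' @param pred one prediction row (needs chrom, strand, start, end, and for
#'   the fold-direction check mature_5p_start/.._end and
#'   mature_3p_start/.._end, NA allowed).
#' @param annotations annotation data frame.
#' @param min_frac minimum overlap as a fraction of the annotation (0.5).
#' @return one of "TP", "FP_overlap", "FP_antisense", "FP_novel", plus the
#'   matched annotation name as the \code{"annotation"} attribute for TPs.
#' @export
classify_prediction <- function(pred, annotations, min_frac = 0.5) {
  prec <- annotations[annotations$kind == "precursor", , drop = FALSE]
  hit <- prec$chrom == pred$chrom & prec$start < pred$end &
    prec$end > pred$start
  if (!any(hit)) return("FP_novel")
  same <- hit & prec$strand == pred$strand
  if (!any(same)) return("FP_antisense")
  sub <- prec[same, , drop = FALSE]
  ov <- pmin(sub$end, pred$end) - pmax(sub$start, pred$start)
  frac <- ov / (sub$end - sub$start)
  best <- which.max(frac)
  if (frac[best] < min_frac) return("FP_overlap")
  a <- sub[best, ]
  if (!fold_direction_ok(pred, a, annotations)) return("FP_overlap")
  structure("TP", annotation = a$name)
}

# each annotated mature of the precursor must fall on the same arm in the
# prediction's fold as its annotated arm
fold_direction_ok <- function(pred, prec_ann, annotations) {
  mats <- annotations[annotations$kind == "mature" &
                      !is.na(annotations$parent) &
                      annotations$parent == prec_ann$name, , drop = FALSE]
  if (nrow(mats) == 0) return(TRUE)
  has_call <- c(`5p` = !is.na(pred$mature_5p_start),
                `3p` = !is.na(pred$mature_3p_start))
  if (!any(has_call)) return(TRUE)   # no arm calls to contradict
  for (i in seq_len(nrow(mats))) {
    arm <- mats$arm[i]
    if (!(arm %in% c("5p", "3p")) || !has_call[[arm]]) next
    ps <- pred[[paste0("mature_", arm, "_start")]]
    pe <- pred[[paste0("mature_", arm, "_end")]]
    ov <- min(pe, mats$end[i]) - max(ps, mats$start[i])
    if (ov <= 0) return(FALSE)       # annotated mature lands on wrong arm
  }
  TRUE
}

#' Classify all predictions
#' @param preds prediction data frame (or \code{mir_predictions}).
#' @param annotations annotation data frame.
#' @return character vector of labels, one per prediction.
#' @export
classify_predictions <- function(preds, annotations) {
  if (inherits(preds, "mir_predictions")) preds <- preds$predictions
  if (nrow(preds) == 0) return(character(0))
  vapply(seq_len(nrow(preds)), function(i) {
    as.character(classify_prediction(preds[i, ], annotations))
  }, character(1))
}

#' Precision and recall against expressed annotations
#'
#' Precision counts every non-TP prediction as a false positive. Recall is
#' measured against annotated precursors, restricted (when
#' \code{expressed_only}) to those with at least one aligned read; an
#' annotation is recovered if some prediction classifies as TP against it.
#'
#' @param preds predictions (data frame or \code{mir_predictions}).
#' @param annotations annotation data frame.
#' @param rrs optional \code{read_region_set} used to determine which
#'   annotations are expressed.
#' @param expressed_only restrict the recall denominator to expressed
#'   annotations (default TRUE when \code{rrs} is supplied).
#' @return list \code{precision}, \code{recall}, \code{tp}, \code{fp},
#'   \code{n_annotated}, \code{labels}.
#' @export
precision_recall <- function(preds, annotations, rrs = NULL,
                             expressed_only = !is.null(rrs)) {
  if (inherits(preds, "mir_predictions")) preds <- preds$predictions
  prec_ann <- annotations[annotations$kind == "precursor", , drop = FALSE]
  if (expressed_only) {
    stopifnot(!is.null(rrs))
    expressed <- vapply(seq_len(nrow(prec_ann)), function(i) {
      a <- prec_ann[i, ]
      any(rrs$reads$chrom == a$chrom & rrs$reads$strand == a$strand &
          rrs$reads$start < a$end & rrs$reads$end > a$start)
    }, logical(1))
    prec_ann <- prec_ann[expressed, , drop = FALSE]
  }
  labels <- character(nrow(preds))
  matched <- character(0)
  for (i in seq_len(nrow(preds))) {
    lab <- classify_prediction(preds[i, ], annotations)
    labels[i] <- as.character(lab)
    if (labels[i] == "TP") matched <- c(matched, attr(lab, "annotation"))
  }
  tp_ann <- intersect(unique(matched), prec_ann$name)
  tp <- sum(labels == "TP")
  fp <- sum(labels != "TP")
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (nrow(prec_ann) > 0) length(tp_ann) / nrow(prec_ann) else NA_real_
  list(precision = p, recall = r, tp = tp, fp = fp,
       n_annotated = nrow(prec_ann), labels = labels)
}

#' F-scores from precision and recall
#'
#' Returns both the harmonic mean \code{f1 = 2PR/(P+R)} and the tabulated
#' benchmark variant \code{f_paper = PR/(P+R)} (half the harmonic mean),
#' which is the quantity printed by the published performance-comparison
#' tables this package reproduces.
#'
#' @param precision,recall values in [0, 1].
#' @return list \code{f1}, \code{f_paper}.
#' @export
f_scores <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    return(list(f1 = 0, f_paper = 0))
  }
  list(f1 = 2 * precision * recall / (precision + recall),
       f_paper = precision * recall / (precision + recall))
}

#' Precision-recall curve and AUPRC
#'
#' Sweeps every distinct score as a threshold, computes precision and
#' recall at each, and integrates precision over recall by the trapezoid
#' rule. Scores are per-locus decision values; labels are logical
#' (TRUE = locus is a real positive).
#'
#' @param scores numeric vector.
#' @param labels logical vector, same length.
#' @param n_positive optional recall denominator (defaults to
#'   \code{sum(labels)}; pass the number of expressed annotations when some
#'   positives receive no score).
#' @return list \code{curve} (data frame threshold/precision/recall) and
#'   \code{auprc}.
#' @export
pr_curve_auprc <- function(scores, labels, n_positive = sum(labels)) {
  stopifnot(length(scores) == length(labels))
  if (n_positive == 0 || (all(labels) && n_positive == length(labels))) {
    return(list(curve = NULL, auprc = NA_real_,
                note = "single-class input; AUPRC undefined"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct score
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_positive
  curve <- data.frame(threshold = s[keep], precision = precision,
                      recall = recall)
  r <- c(0, recall); p <- c(precision[1], precision)
  auprc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  list(curve = curve, auprc = auprc)
}

#' Grid search of the three tuned thresholds
#'
#' Exhaustively evaluates every (y, E, X) triple: for each stratified
#' sampling ratio X the supplied \code{score_fn} retrains the hairpin layer
#' and returns scored loci on the tuning sample; each (y, E) pair is then a
#' pure thresholding of those scores, evaluated by \code{eval_fn}. The
#' triple maximizing the objective F-score wins; ties break to smaller X,
#' then larger y (more conservative).
#'
#' @param score_fn function(X) returning a data frame of scored loci with
#'   columns \code{hprf_score} and \code{totalSenseRPM} (plus whatever
#'   \code{eval_fn} needs).
#' @param eval_fn function(kept_loci) returning list(precision, recall).
#' @param grid_y,grid_e,grid_x numeric grids.
#' @param objective "f1" (default) or "f_paper".
#' @return list \code{y}, \code{e}, \code{x}, \code{f}, \code{grid} (full
#'   table of the search).
#' @export
tune_grid <- function(score_fn, eval_fn, grid_y, grid_e, grid_x,
                      objective = c("f1", "f_paper")) {
  objective <- match.arg(objective)
  if (!length(grid_y) || !length(grid_e) || !length(grid_x)) {
    stop("empty tuning grid")
  }
  rows <- list()
  for (x in grid_x) {
    scored <- score_fn(x)
    for (y in grid_y) for (e in grid_e) {
      kept <- scored[scored$hprf_score >= y & scored$totalSenseRPM >= e, ,
                     drop = FALSE]
      pr <- eval_fn(kept)
      f <- f_scores(pr$precision, pr$recall)[[objective]]
      rows[[length(rows) + 1L]] <- data.frame(
        y = y, e = e, x = x, precision = pr$precision, recall = pr$recall,
        f = f)
    }
  }
  grid <- do.call(rbind, rows)
  grid$f[is.na(grid$f)] <- 0
  best <- grid[order(-grid$f, grid$x, -grid$y, -grid$e), ][1, ]
  list(y = best$y, e = best$e, x = best$x, f = best$f, grid = grid)
}

#' Knockdown log fold change with pseudocount
#'
#' \code{log2((kd + c) / (wt + c))} with c = 0.015 ARPM, the pseudocount
#' used to avoid taking the log of zero when comparing Dicer-knockdown to
#' wild-type expression. Real microRNAs are expected to show negative
#' values under Dicer depletion.
#'
#' @param kd_arpm,wt_arpm expression in ARPM.
#' @param pseudocount default 0.015 ARPM.
#' @return log2 fold change (vectorized).
#' @export
dicer_log_fold_change <- function(kd_arpm, wt_arpm, pseudocount = 0.015) {
  stopifnot(all(kd_arpm >= 0), all(wt_arpm >= 0))
  log2((kd_arpm + pseudocount) / (wt_arpm + pseudocount))
}
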