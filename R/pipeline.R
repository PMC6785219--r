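# File-level orchestration: train / discover / tune / evaluate / simulate
# over paths to standard-format inputs. These are thin wrappers over the
# package functions; each writes its resolved configuration next to its
# outputs for provenance.

write_provenance <- function(outdir, what, extra = list()) {
  info <- c(list(tool = "mirforest",
                 version = as.character(utils::packageVersion("mirforest")),
                 step = what, engine = vienna_version(),
                 time = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(info, file.path(outdir, paste0(what, "_config.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Train both model layers from files
#'
#' @param alignments SAM/BAM of the training sample.
#' @param genome_fa genome FASTA.
#' @param gff3 miRBase-style annotation GFF3.
#' @param outdir output directory; the fitted model is saved as
#'   \code{model.rds} with a JSON manifest of feature order and metadata.
#' @param ... passed to \code{\link{mir_forest}}.
#' @return the fitted model, invisibly.
#' @export
run_train <- function(alignments, genome_fa, gff3, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reads <- load_alignments(alignments)
  genome <- load_genome(genome_fa)
  ann <- load_annotations(gff3)
  fit <- mir_forest(reads, genome, ann, ...)
  saveRDS(fit, file.path(outdir, "model.rds"))
  jsonlite::write_json(
    list(mprf_features = mprf_feature_names(),
         hprf_features = hprf_feature_names(), meta = fit$meta),
    file.path(outdir, "model_manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  write_provenance(outdir, "train")
  invisible(fit)
}

#' Discover microRNAs in a sample with a trained model
#'
#' Writes predictions GFF3, a per-locus score TSV (every evaluated locus,
#' enabling PR curves), and a BED of read regions.
#'
#' @param model a \code{mir_forest} or path to a saved \code{model.rds}.
#' @param alignments SAM/BAM to scan.
#' @param genome_fa genome FASTA.
#' @param outdir output directory.
#' @param ... passed to \code{\link{predict.mir_forest}} (threshold
#'   overrides).
#' @return the \code{mir_predictions}, invisibly.
#' @export
run_discover <- function(model, alignments, genome_fa, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(model)) model <- readRDS(model)
  stopifnot(inherits(model, "mir_forest"))
  genome <- load_genome(genome_fa)
  reads <- load_alignments(alignments)
  pred <- predict(model, reads, genome, ...)
  write_predictions_gff3(pred$predictions, file.path(outdir,
                                                     "predictions.gff3"))
  utils::write.table(pred$locus_scores,
                     file.path(outdir, "locus_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rrs <- group_read_regions(annotate_hit_counts(reads))
  write_regions_bed(rrs, file.path(outdir, "read_regions.bed"))
  write_provenance(outdir, "discover",
                   list(y_threshold = pred$y_threshold,
                        expression_threshold = pred$expression_threshold))
  invisible(pred)
}

#' Evaluate predictions against annotations from files
#'
#' @param pred a \code{mir_predictions} (or its \code{$predictions} frame).
#' @param gff3 annotation GFF3.
#' @param alignments optional SAM/BAM used to restrict recall to expressed
#'   annotations.
#' @param outdir optional output directory for a metrics JSON.
#' @return metrics list: precision, recall, both F-score variants, label
#'   tallies.
#' @export
run_evaluate <- function(pred, gff3, alignments = NULL, outdir = NULL) {
  ann <- load_annotations(gff3)
  rrs <- NULL
  if (!is.null(alignments)) {
    rrs <- group_read_regions(annotate_hit_counts(
      load_alignments(alignments)))
  }
  pr <- precision_recall(pred, ann, rrs = rrs)
  f <- f_scores(pr$precision, pr$recall)
  metrics <- list(precision = pr$precision, recall = pr$recall,
                  f1 = f$f1, f_paper = f$f_paper, tp = pr$tp, fp = pr$fp,
                  n_annotated = pr$n_annotated,
                  labels = as.list(table(pr$labels)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_provenance(outdir, "evaluate")
  }
  metrics
}

#' Tune thresholds on a held-out sample
#'
#' Trains on one annotated sample at each stratified-sampling ratio X in the
#' grid, scores the tuning sample, and grid-searches the HPRF decision
#' value y and ARPM threshold E for the best F-score. Training and tuning
#' on the same sample is refused unless \code{allow_leakage}.
#'
#' @param train_reads,train_genome,train_ann training sample (objects).
#' @param tune_reads,tune_genome,tune_ann tuning sample (objects).
#' @param grid_y,grid_e,grid_x grids (defaults bracket the shipped tuned
#'   values 0.28 / 0.11 ARPM / 1:25).
#' @param seed RNG seed.
#' @param objective "f1" or "f_paper".
#' @param allow_leakage permit identical train/tune inputs.
#' @param ... passed to \code{\link{mir_forest}}.
#' @return \code{\link{tune_grid}} result plus the model fitted at the
#'   winning X.
#' @export
run_tune <- function(train_reads, train_genome, train_ann,
                     tune_reads, tune_genome, tune_ann,
                     grid_y = c(0.2, 0.28, 0.4),
                     grid_e = c(0.11), grid_x = c(10, 25),
                     seed = 1L, objective = "f1",
                     allow_leakage = FALSE, ...) {
  if (!allow_leakage && identical(train_reads, tune_reads)) {
    stop("training and tuning samples are identical; ",
         "use allow_leakage = TRUE to override")
  }
  tune_rrs <- group_read_regions(annotate_hit_counts(tune_reads))
  fits <- list()
  score_fn <- function(x) {
    fit <- mir_forest(train_reads, train_genome, train_ann,
                      hprf_ratio = x, seed = seed, ...)
    fits[[as.character(x)]] <<- fit
    pred <- predict(fit, tune_reads, tune_genome,
                    y_threshold = 0, expression_threshold = 0)
    scored <- pred$locus_scores
    scored
  }
  eval_fn <- function(kept) {
    pr <- precision_recall(kept, tune_ann, rrs = tune_rrs)
    list(precision = pr$precision, recall = pr$recall)
  }
  res <- tune_grid(score_fn, eval_fn, grid_y, grid_e, grid_x,
                   objective = objective)
  res$model <- fits[[as.character(res$x)]]
  res$model$y_threshold <- res$y
  res$model$expression_threshold <- res$e
  res
}

#' Simulate a fixture to disk
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory.
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  generate_fixture(config, outdir)
}
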