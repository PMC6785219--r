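# Mature-product layer: per-read-region features (sequence, 5' precision,
# read-offset profile, stack duplex energy) and the first random forest.

DINUC_NAMES <- as.vector(outer(c("a", "c", "g", "t"), c("a", "c", "g", "t"),
                               function(a, b) paste0(a, b)))
OFFSET_NAMES <- c(paste0("r", 7:1), "s0", paste0("f", 1:7))

#' MPRF feature order manifest
#' @return character vector of the 36 mature-product feature names.
#' @export
mprf_feature_names <- function() {
  c("fivePrimeHet", "medianLength", "gcContent", DINUC_NAMES,
    OFFSET_NAMES, "WFC", "duplexEnergy")
}

#' Wootton-Federhen sequence complexity
#'
#' \code{(1/N) * log4(N! / prod(n_i!))} over the base counts n_i of the
#' sequence; 0 for homopolymers, approaching 1 for maximally mixed
#' composition. Non-ACGT symbols are excluded from the counts.
#'
#' @param seq nucleotide string (DNA or RNA alphabet).
#' @return complexity in [0, 1].
#' @export
wootton_federhen <- function(seq) {
  s <- gsub("U", "T", toupper(seq))
  counts <- table(strsplit(s, "")[[1]])
  counts <- counts[names(counts) %in% c("A", "C", "G", "T")]
  n <- sum(counts)
  if (n == 0) return(0)
  (lfactorial(n) - sum(lfactorial(counts))) / (n * log(4))
}

gc_content <- function(seq) {
  s <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  s <- s[s %in% c("A", "C", "G", "T")]
  if (length(s) == 0) return(0)
  mean(s %in% c("G", "C"))
}

# overlapping dinucleotide frequencies; pairs containing ambiguous bases are
# dropped from numerator and denominator
dinucleotide_freqs <- function(seq) {
  s <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  out <- stats::setNames(rep(0, 16), DINUC_NAMES)
  if (length(s) < 2) return(out)
  di <- paste0(tolower(s[-length(s)]), tolower(s[-1]))
  di <- di[di %in% DINUC_NAMES]
  if (length(di) == 0) return(out)
  tab <- table(di) / length(di)
  out[names(tab)] <- as.numeric(tab)
  out
}

read_five_primes <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' 5' heterogeneity of a read stack
#'
#' One minus the dup-count-weighted fraction of reads whose 5' end sits at
#' the modal 5' position. 0 for a perfectly homogeneous stack.
#'
#' @param reads the reads of one region.
#' @return value in [0, 1].
#' @export
five_prime_heterogeneity <- function(reads) {
  stopifnot(nrow(reads) > 0)
  fp <- read_five_primes(reads)
  modal <- modal_five_prime(reads)
  1 - sum(reads$dup_count[fp == modal]) / sum(reads$dup_count)
}

#' Read-offset profile around the modal 5' end
#'
#' Dup-count-weighted fraction of reads whose 5' end lies at each offset
#' d = -7..+7 from the modal 5' position, measured 5'->3' along the read
#' strand (r7..r1 upstream, s0 modal, f1..f7 downstream).
#'
#' @param reads the reads of one region.
#' @return named numeric vector of 15 fractions (sums to <= 1).
#' @export
read_offset_profile <- function(reads) {
  stopifnot(nrow(reads) > 0)
  fp <- read_five_primes(reads)
  modal <- modal_five_prime(reads)
  d <- ifelse(reads$strand == "+", fp - modal, modal - fp)
  w <- sum(reads$dup_count)
  out <- stats::setNames(rep(0, 15), OFFSET_NAMES)
  for (k in -7:7) {
    nm <- if (k < 0) paste0("r", -k) else if (k == 0) "s0" else paste0("f", k)
    out[nm] <- sum(reads$dup_count[d == k]) / w
  }
  out
}

# most abundant distinct read sequence; ties to lexicographically smallest
most_frequent_seq <- function(reads) {
  w <- tapply(reads$dup_count, reads$seq, sum)
  names(w)[order(-w, names(w))][1]
}

#' Load a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector, one entry per contig.
#' @export
load_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

# flank sequences of a region in read-strand orientation; list(up, down)
# where "up" is 5' of the read along its strand. Flanks shorter than
# min_len are dropped (NA).
genome_flanks <- function(genome, chrom, start, end, strand,
                          window = 70L, min_len = 10L) {
  gseq <- genome[[chrom]]
  glen <- nchar(gseq)
  ls <- max(0L, start - window); le <- start      # genomic left flank
  rs <- end; re <- min(glen, end + window)        # genomic right flank
  left <- if (le - ls >= min_len) substr(gseq, ls + 1L, le) else NA_character_
  right <- if (re - rs >= min_len) substr(gseq, rs + 1L, re) else NA_character_
  if (strand == "+") {
    list(up = left, down = right, up_gstart = ls, down_gstart = rs)
  } else {
    list(up = if (is.na(right)) NA_character_ else revcomp(right),
         down = if (is.na(left)) NA_character_ else revcomp(left),
         up_gstart = rs, down_gstart = ls)
  }
}

#' Stack duplex energies for all read regions
#'
#' For every region, the minimum duplex energy between its most frequent
#' read sequence and the flanking genomic windows on either side (the flanks
#' exclude the region span itself). Flanks shorter than 10 nt are skipped;
#' if neither flank is usable, or no favourable duplex exists, the sentinel
#' 0 is returned for that region. All duplexes are computed in a single
#' engine invocation.
#'
#' @param rrs a \code{read_region_set}.
#' @param genome named character vector from \code{\link{load_genome}}.
#' @param window flank width in nt (default 70).
#' @return data frame with \code{region_id}, \code{energy}, and the winning
#'   flank's duplex geometry (\code{side}, \code{t_gstart}, \code{t_gend}:
#'   genomic coordinates of the duplexed target span, NA when sentinel).
#' @export
stack_duplex_energies <- function(rrs, genome, window = 70L) {
  regs <- rrs$regions
  if (nrow(regs) == 0) {
    return(data.frame(region_id = integer(), energy = numeric(),
                      side = character(), t_gstart = integer(),
                      t_gend = integer(), stringsAsFactors = FALSE))
  }
  jobs <- list()
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    q <- most_frequent_seq(region_reads(rrs, r$region_id))
    fl <- genome_flanks(genome, r$chrom, r$start, r$end, r$strand, window)
    for (side in c("up", "down")) {
      if (!is.na(fl[[side]])) {
        jobs[[length(jobs) + 1L]] <- list(
          region_id = r$region_id, side = side, query = q,
          target = fl[[side]], gstart = fl[[paste0(side, "_gstart")]],
          strand = r$strand, tlen = nchar(fl[[side]]))
      }
    }
  }
  out <- data.frame(region_id = regs$region_id, energy = 0,
                    side = NA_character_, t_gstart = NA_integer_,
                    t_gend = NA_integer_, stringsAsFactors = FALSE)
  if (length(jobs) == 0) return(out)
  dup <- rna_duplex(vapply(jobs, `[[`, "", "query"),
                    vapply(jobs, `[[`, "", "target"))
  for (k in seq_along(jobs)) {
    j <- jobs[[k]]; d <- dup[k, ]
    if (!d$found) next
    i <- match(j$region_id, out$region_id)
    if (d$energy < out$energy[i]) {
      # map target span (on the oriented flank) back to genomic coordinates
      if (j$strand == "+") {
        gs <- j$gstart + d$t_start; ge <- j$gstart + d$t_end
      } else {
        gs <- j$gstart + j$tlen - d$t_end; ge <- j$gstart + j$tlen - d$t_start
      }
      out$energy[i] <- d$energy
      out$side[i] <- j$side
      out$t_gstart[i] <- gs
      out$t_gend[i] <- ge
    }
  }
  out
}

#' Mature-product feature matrix
#'
#' Computes the full 36-feature vector of the mature-product classifier for
#' every read region: 5' heterogeneity, dup-weighted median read length, GC
#' content, dinucleotide frequencies, the -7..+7 read-offset profile,
#' Wootton-Federhen complexity, and the stack duplex energy against the
#' surrounding genomic windows. Sequence features are computed on the
#' region's most frequent read sequence.
#'
#' @param rrs a \code{read_region_set}.
#' @param genome named character vector (needed for duplex energies; pass
#'   NULL to set duplexEnergy to 0, e.g. in unit tests).
#' @param window duplex flank width (default 70 nt).
#' @param stack_dup optional precomputed \code{\link{stack_duplex_energies}}
#'   result, to avoid duplicate engine calls when the caller also needs the
#'   duplex geometry.
#' @return data frame: \code{region_id} followed by the 36 features in
#'   manifest order.
#' @export
mprf_feature_matrix <- function(rrs, genome = NULL, window = 70L,
                                stack_dup = NULL) {
  regs <- rrs$regions
  feat_names <- mprf_feature_names()
  if (nrow(regs) == 0) {
    m <- as.data.frame(matrix(numeric(0), ncol = length(feat_names) + 1))
    names(m) <- c("region_id", feat_names)
    return(m)
  }
  denergy <- if (!is.null(stack_dup)) {
    stack_dup
  } else if (is.null(genome)) {
    data.frame(region_id = regs$region_id, energy = 0)
  } else {
    stack_duplex_energies(rrs, genome, window)
  }
  rows <- lapply(seq_len(nrow(regs)), function(i) {
    r <- regs[i, ]
    rd <- region_reads(rrs, r$region_id)
    s <- most_frequent_seq(rd)
    lens <- rep(nchar(rd$seq), rd$dup_count)
    v <- c(fivePrimeHet = five_prime_heterogeneity(rd),
           medianLength = stats::median(lens),
           gcContent = gc_content(s),
           dinucleotide_freqs(s),
           read_offset_profile(rd),
           WFC = wootton_federhen(s),
           duplexEnergy = denergy$energy[match(r$region_id,
                                               denergy$region_id)])
    v
  })
  m <- as.data.frame(do.call(rbind, rows))
  names(m) <- feat_names
  cbind(region_id = regs$region_id, m)
}

# regions overlapping annotations of given kind; strand "same"/"either"
regions_overlapping <- function(regions, ann, kind, strand = c("same", "either")) {
  strand <- match.arg(strand)
  a <- ann[ann$kind == kind, , drop = FALSE]
  if (nrow(a) == 0 || nrow(regions) == 0) {
    return(logical(nrow(regions)))
  }
  vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- a$chrom == r$chrom & a$start < r$end & a$end > r$start
    if (strand == "same") hit <- hit & a$strand == r$strand
    any(hit)
  }, logical(1))
}

#' Build the mature-product training set
#'
#' Positives are read regions overlapping an annotated mature microRNA on
#' the same strand. Negatives are sampled (seeded) from regions overlapping
#' no microRNA annotation on either strand, at \code{ratio_x} negatives per
#' positive (all available if fewer exist).
#'
#' @param feats feature matrix from \code{\link{mprf_feature_matrix}}.
#' @param rrs the corresponding \code{read_region_set}.
#' @param annotations annotation data frame (\code{\link{load_annotations}}).
#' @param ratio_x negatives per positive (default 1).
#' @param seed RNG seed for the negative sample.
#' @return list: \code{x} (features), \code{y} (factor pos/neg),
#'   \code{region_id}.
#' @export
build_mprf_training_set <- function(feats, rrs, annotations, ratio_x = 1,
                                    seed = 1L) {
  regs <- rrs$regions
  pos <- regions_overlapping(regs, annotations, "mature", "same")
  any_ann <- regions_overlapping(regs, annotations, "mature", "either") |
    regions_overlapping(regs, annotations, "precursor", "either")
  neg_pool <- which(!any_ann)
  pos_idx <- which(pos)
  if (length(pos_idx) == 0) stop("no positive training regions")
  n_neg <- min(length(neg_pool), ratio_x * length(pos_idx))
  old <- .Random.seed_save()
  set.seed(seed)
  neg_idx <- sort(sample(neg_pool, n_neg))
  .Random.seed_restore(old)
  idx <- c(pos_idx, neg_idx)
  ids <- regs$region_id[idx]
  list(x = feats[match(ids, feats$region_id), -1, drop = FALSE],
       y = factor(rep(c("pos", "neg"), c(length(pos_idx), length(neg_idx))),
                  levels = c("neg", "pos")),
       region_id = ids)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

train_forest <- function(x, y, num_trees, seed, feature_names) {
  stopifnot(identical(names(x), feature_names))
  rf <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, probability = TRUE,
    mtry = floor(sqrt(ncol(x))), min.node.size = 1,
    seed = seed, num.threads = 1, importance = "impurity")
  list(forest = rf, feature_names = feature_names,
       meta = list(num_trees = num_trees, seed = seed,
                   n_pos = sum(y == "pos"), n_neg = sum(y == "neg")))
}

forest_scores <- function(model, x) {
  if (!identical(names(x), model$feature_names)) {
    stop("feature order mismatch between model and input")
  }
  p <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  as.numeric(p[, "pos"])
}

#' Train the mature-product random forest (MPRF)
#'
#' @param training list from \code{\link{build_mprf_training_set}}.
#' @param num_trees forest size (default 500).
#' @param seed forest RNG seed.
#' @return object of class \code{mprf_model}.
#' @export
train_mprf <- function(training, num_trees = 500, seed = 1L) {
  m <- train_forest(training$x, training$y, num_trees, seed,
                    mprf_feature_names())
  class(m) <- "mprf_model"
  m
}

#' Score read regions with a trained MPRF
#'
#' The decision value is the forest's positive-class vote fraction. Regions
#' are never pre-filtered by abundance: a single-read region is scored like
#' any other.
#'
#' @param model an \code{mprf_model}.
#' @param feats feature matrix (\code{\link{mprf_feature_matrix}}).
#' @return data frame \code{region_id}, \code{mprf_score}.
#' @export
score_read_regions <- function(model, feats) {
  data.frame(region_id = feats$region_id,
             mprf_score = forest_scores(model, feats[, -1, drop = FALSE]))
}
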