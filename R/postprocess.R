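# Post-processing of predictions: homology of novel matures to known
# microRNAs, genomic clustering of precursors, and novel-family discovery.

#' Smith-Waterman homology search with Karlin-Altschul E-values
#'
#' Local alignment of a mature query against a database of known mature
#' microRNAs (Biostrings pairwise alignment, match +1 / mismatch -2, gap
#' open 2 / extend 1) with an ungapped Karlin-Altschul E-value
#' \code{E = K * m * n * exp(-lambda * S)} (lambda = 1.28, K = 0.46 for
#' the +1/-2 scoring). The verdict is "homolog" only when the best hit
#' shares the exact seed (mature positions 2-8) and E < 0.05.
#'
#' @param mature_seq query mature sequence (18-26 nt, DNA or RNA alphabet).
#' @param known named character vector of known mature sequences (e.g. a
#'   miRBase mature FASTA loaded with \code{\link{load_genome}}).
#' @param e_threshold homology E-value cutoff (default 0.05).
#' @return list: \code{verdict} ("homolog"/"novel"), \code{best_hit},
#'   \code{e_value}, \code{seed_match}, \code{score}, \code{engine}.
#' @export
assign_homology <- function(mature_seq, known, e_threshold = 0.05) {
  engine <- "internal-sw/karlin-altschul(+1/-2,go2,ge1,l1.28,K0.46)"
  if (length(known) == 0) {
    warning("empty known-mature database; calling novel")
    return(list(verdict = "novel", best_hit = NA_character_,
                e_value = Inf, seed_match = FALSE, score = NA_real_,
                engine = engine))
  }
  q <- gsub("U", "T", toupper(mature_seq))
  db <- gsub("U", "T", toupper(known))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(db), Biostrings::DNAString(q),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  scores <- Biostrings::score(aln)
  best <- which.max(scores)
  s <- scores[best]
  lambda <- 1.28; k <- 0.46
  e <- k * nchar(q) * sum(nchar(db)) * exp(-lambda * s)
  seed_match <- seed_of(q) == seed_of(db[best])
  verdict <- if (seed_match && e < e_threshold) "homolog" else "novel"
  list(verdict = verdict, best_hit = names(db)[best], e_value = e,
       seed_match = seed_match, score = s, engine = engine)
}

seed_of <- function(seq) substr(gsub("U", "T", toupper(seq)), 2, 8)

#' Group precursor loci into genomic clusters
#'
#' Single-linkage chaining of precursors whose span edges lie within
#' \code{distance} (inclusive) of each other. Annotated loci are clustered
#' first; novel loci then join an existing cluster when within range of one
#' of its members, or chain into new clusters among themselves. A cluster
#' requires at least two members (singletons are not clusters). A cluster's
#' source is "annotated" if two or more annotated members cluster together
#' without needing any novel locus, "novel" otherwise.
#'
#' @param annotated,novel data frames with \code{name}, \code{chrom},
#'   \code{start}, \code{end} (strand ignored: clusters are positional).
#' @param distance inclusive chaining distance (default 10000 nt).
#' @return data frame: \code{cluster_id}, \code{source}, \code{member},
#'   \code{member_source}.
#' @export
identify_clusters <- function(annotated, novel = NULL, distance = 10000L) {
  if (is.null(novel)) novel <- annotated[0, , drop = FALSE]
  chain <- function(df) {
    # returns integer component id per row (single linkage on gap <= distance)
    if (nrow(df) == 0) return(integer(0))
    comp <- seq_len(nrow(df))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
        if (comp[i] != comp[j] && df$chrom[i] == df$chrom[j]) {
          gap <- max(df$start[j] - df$end[i], df$start[i] - df$end[j], 0)
          if (gap <= distance) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    match(comp, unique(comp))
  }
  ann_comp <- chain(annotated)
  rows <- list()
  next_id <- 0L
  ann_cluster_of <- rep(NA_integer_, nrow(annotated))
  for (cid in unique(ann_comp)) {
    members <- which(ann_comp == cid)
    if (length(members) < 2) next
    next_id <- next_id + 1L
    ann_cluster_of[members] <- next_id
    for (m in members) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = next_id, source = "annotated",
        member = annotated$name[m], member_source = "annotated",
        stringsAsFactors = FALSE)
    }
  }
  # novels join annotated clusters within range, else chain among leftovers
  leftover <- list()
  for (i in seq_len(nrow(novel))) {
    joined <- FALSE
    for (a in seq_len(nrow(annotated))) {
      if (!is.na(ann_cluster_of[a]) &&
          annotated$chrom[a] == novel$chrom[i]) {
        gap <- max(novel$start[i] - annotated$end[a],
                   annotated$start[a] - novel$end[i], 0)
        if (gap <= distance) {
          rows[[length(rows) + 1L]] <- data.frame(
            cluster_id = ann_cluster_of[a], source = "annotated",
            member = novel$name[i], member_source = "novel",
            stringsAsFactors = FALSE)
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) leftover[[length(leftover) + 1L]] <- novel[i, ]
  }
  # chain leftover novels together with unclustered annotated loci
  pool <- rbind(
    cbind(annotated[is.na(ann_cluster_of), , drop = FALSE],
          msrc = rep("annotated", sum(is.na(ann_cluster_of)))),
    if (length(leftover)) cbind(do.call(rbind, leftover),
                                msrc = "novel") else NULL)
  if (!is.null(pool) && nrow(pool) > 0) {
    comp <- chain(pool)
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) < 2 || !any(pool$msrc[members] == "novel")) next
      next_id <- next_id + 1L
      for (m in members) {
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = next_id, source = "novel",
          member = pool$name[m], member_source = pool$msrc[m],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster_id = integer(), source = character(),
                      member = character(), member_source = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$cluster_id), , drop = FALSE]
}

#' Identify novel microRNA families
#'
#' Searches each novel mature against the combined set of novel and known
#' matures. Family membership requires a perfect seed match (positions
#' 2-8), the same arm for query and hit, and E <= 0.5; hits antisense to
#' the query's own locus and hits with a mature sequence identical to the
#' query are excluded (both guard against repeat-derived loci).
#'
#' @param novel data frame: \code{name}, \code{seq}, \code{arm},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @param database data frame: \code{name}, \code{seq}, \code{arm}, and
#'   optionally \code{chrom}, \code{start}, \code{end}, \code{strand} for
#'   the antisense-to-self exclusion.
#' @param e_threshold family E-value cutoff (default 0.5).
#' @return data frame: \code{query}, \code{hit}, \code{e_value}.
#' @export
identify_novel_families <- function(novel, database, e_threshold = 0.5) {
  out <- list()
  for (i in seq_len(nrow(novel))) {
    q <- novel[i, ]
    for (j in seq_len(nrow(database))) {
      h <- database[j, ]
      if (identical(q$name, h$name)) next
      qs <- gsub("U", "T", toupper(q$seq))
      hs <- gsub("U", "T", toupper(h$seq))
      if (qs == hs) next                               # identical matures
      if (seed_of(qs) != seed_of(hs)) next
      if (!identical(q$arm, h$arm)) next
      if (!is.null(h$chrom) && !is.na(h$chrom) &&
          h$chrom == q$chrom && h$start < q$end && h$end > q$start &&
          !is.null(h$strand) && !identical(h$strand, q$strand)) {
        next                                           # antisense to itself
      }
      hom <- assign_homology(qs, stats::setNames(hs, h$name),
                             e_threshold = e_threshold)
      if (hom$e_value <= e_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          query = q$name, hit = h$name, e_value = hom$e_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query = character(), hit = character(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
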