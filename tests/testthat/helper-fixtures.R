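# Shared fixtures, built in code and memoised for the session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a small but complete simulated experiment (10 hairpins, 80 noise loci)
small_sim <- function(seed = 11) {
  memo(paste0("sim", seed), simulate_mir_experiment(
    sim_config(seed = seed, genome_length = 60000, n_hairpins = 10,
               n_noise_loci = 80)))
}

small_fit <- function() {
  memo("fit11", {
    sim <- small_sim(11)
    mir_forest(sim$reads, sim$genome, sim$annotations, seed = 1)
  })
}

# hand-built aligned reads
make_reads <- function(start, end, strand = "+", chrom = "chr1",
                       seq = NULL, dup = 1L, hit = 1L, id = NULL) {
  n <- length(start)
  if (is.null(seq)) seq <- strrep("A", end - start)
  if (is.null(id)) id <- sprintf("r%03d", seq_len(n))
  data.frame(read_id = id, chrom = rep_len(chrom, n), start = start,
             end = end, strand = rep_len(strand, n),
             seq = rep_len(seq, n), dup_count = rep_len(as.integer(dup), n),
             hit_count = rep_len(as.integer(hit), n),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  chartr("ACGTU", "TGCAA", paste(rev(strsplit(toupper(x), "")[[1]]),
                                 collapse = ""))
}

# brute-force pair-table classifier, independent of the package's loop
# decomposition: classifies every unpaired run via its innermost enclosing
# pair, found by exhaustive scanning
oracle_classify <- function(structure) {
  pt <- mirforest::pair_table(structure)
  n <- length(pt)
  cls <- ifelse(pt > 0, "paired", NA)
  pairs <- which(pt > seq_len(n))
  enclosing_of <- function(p) {
    cand <- pairs[pairs < p & pt[pairs] > p]
    if (length(cand) == 0) return(NULL)
    cand[which.max(cand)]            # innermost = largest opening index
  }
  # group unpaired runs
  up <- which(pt == 0)
  runs <- split(up, cumsum(c(1, diff(up) != 1)))
  out_runs <- list()
  for (r in runs) {
    i <- enclosing_of(r[1])
    if (is.null(i)) { cls[r] <- "exterior"; next }
    j <- pt[i]
    # top-level helices directly inside (i, j) by exhaustive scan
    inner_pairs <- pairs[pairs > i & pt[pairs] < j]
    top_level <- inner_pairs[vapply(inner_pairs, function(k) {
      !any(inner_pairs < k & pt[inner_pairs] > pt[k])
    }, logical(1))]
    k <- length(top_level)
    if (k == 0) {
      cls[r] <- "loop"
      out_runs[[length(out_runs) + 1L]] <- list(type = "hairpin", run = r)
    } else if (k == 1) {
      a <- top_level[1]; b <- pt[top_level[1]]
      left <- if (a - 1 >= i + 1) (i + 1):(a - 1) else integer(0)
      right <- if (b + 1 <= j - 1) (b + 1):(j - 1) else integer(0)
      if (length(left) && length(right)) {
        cls[r] <- "interior"
        out_runs[[length(out_runs) + 1L]] <-
          list(type = "interior", size = length(left) + length(right))
      } else {
        cls[r] <- "bulge"
        out_runs[[length(out_runs) + 1L]] <-
          list(type = "bulge", size = length(r))
      }
    } else {
      cls[r] <- "loop"
      out_runs[[length(out_runs) + 1L]] <- list(type = "multi", run = r)
    }
  }
  list(class = cls, runs = out_runs)
}

# random realistic dot-brackets: fold random sequences with the engine
random_structures <- function(n, max_len = 80, seed = 42) {
  memo(paste0("rs", n, "_", max_len, "_", seed), {
    set.seed(seed)
    seqs <- vapply(seq_len(n), function(i) {
      random_seq(sample(30:max_len, 1))
    }, character(1))
    rna_fold(seqs)
  })
}

write_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tmiRNA_primary_transcript\t101\t180\t.\t+\t.\tID=MI001;Name=toy-mir-1",
    "chr1\tx\tmiRNA\t106\t127\t.\t+\t.\tID=MIMAT1;Name=toy-miR-1;Derives_from=MI001",
    "chr1\tx\tmiRNA\t151\t172\t.\t+\t.\tID=MIMAT2;Name=toy-miR-1-3p;Derives_from=MI001",
    "chr2\tx\tmiRNA_primary_transcript\t501\t570\t.\t-\t.\tID=MI002;Name=toy-mir-2",
    "chr2\tx\tmiRNA\t545\t566\t.\t-\t.\tID=MIMAT3;Name=toy-miR-2;Derives_from=MI002"),
    path)
  path
}
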