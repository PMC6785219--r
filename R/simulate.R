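# Synthetic-data generator: a random genome with planted hairpin loci whose
# read stacks emulate Drosha/Dicer processing (miR, miR*, moR and loop
# products with tunable 5' precision), plus unstructured background noise
# stacks and optional decoy-duplicated multimapping loci. Every pipeline
# stage can be trained and tested against the returned ground truth with no
# external data.

#' Simulation configuration
#'
#' Defaults describe a clean, well-expressed small RNA library over a
#' compact genome: ~22 nt matures, 8-20 nt loops, 2 nt 3' overhang
#' register, 90% of read 5' ends at the modal cut position (planted stacks)
#' versus 50% for background noise, minor moR/loop products, and a small
#' multimapping fraction realized by physically duplicating noise loci.
#'
#' @param genome_length genome size in nt.
#' @param gc genome GC fraction.
#' @param n_hairpins number of planted hairpin loci.
#' @param mir_length inclusive range of mature lengths (nt).
#' @param loop_length inclusive range of loop lengths (nt).
#' @param star_mismatch_rate per-base mismatch rate of miR* vs the exact
#'   reverse complement of the miR.
#' @param overhang 3' overhang register of the miR:miR* duplex (nt).
#' @param depth inclusive range of miR read depth per hairpin.
#' @param five_prime_precision fraction of planted reads whose 5' end sits
#'   exactly at the planted cut.
#' @param star_ratio miR* depth as a fraction of miR depth.
#' @param moR_fraction,loop_fraction minor-product depths as fractions of
#'   miR depth.
#' @param n_noise_loci number of unstructured background stacks.
#' @param noise_depth inclusive range of noise stack depth.
#' @param noise_five_prime_precision 5' precision of noise stacks.
#' @param multimap_fraction fraction of noise loci duplicated at a decoy
#'   position (reads then align to both copies, NH = 2).
#' @param seed RNG seed (mandatory; the generator is fully deterministic).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 250000L, gc = 0.42,
                       n_hairpins = 50L, mir_length = c(21L, 23L),
                       loop_length = c(8L, 20L), star_mismatch_rate = 0.05,
                       overhang = 2L, depth = c(5L, 50L),
                       five_prime_precision = 0.9, star_ratio = 0.2,
                       moR_fraction = 0.1, loop_fraction = 0.05,
                       n_noise_loci = 500L, noise_depth = c(1L, 10L),
                       noise_five_prime_precision = 0.5,
                       multimap_fraction = 0.05, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  fracs <- c(gc = gc, star_mismatch_rate = star_mismatch_rate,
             five_prime_precision = five_prime_precision,
             star_ratio = star_ratio, moR_fraction = moR_fraction,
             loop_fraction = loop_fraction,
             noise_five_prime_precision = noise_five_prime_precision,
             multimap_fraction = multimap_fraction)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) stop("sim_config fractions out of [0,1]: ",
                        paste(bad, collapse = ", "))
  if (genome_length < 1000) stop("sim_config: genome_length too small")
  structure(cfg, class = "sim_config")
}

rand_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Plant one hairpin into a genome sequence
#'
#' Writes miR + loop + miR* (reverse complement of the miR, mutated at
#' \code{star_mismatch_rate}) into the genome at \code{position} (forward
#' strand for \code{strand == "+"}, reverse-complemented for "-") and
#' returns the truth record: precursor span and the genomic spans of both
#' matures in the configured overhang register.
#'
#' @param genome_seq single genome string.
#' @param position 0-based genomic start of the precursor.
#' @param strand "+" or "-".
#' @param config \code{\link{sim_config}} (draws lengths from the
#'   configured ranges; uses the current RNG stream).
#' @return list \code{genome_seq} (modified), \code{record} (one-row truth
#'   data frame).
#' @export
plant_hairpin <- function(genome_seq, position, strand, config) {
  L <- sample(config$mir_length[1]:config$mir_length[2], 1)
  K <- sample(config$loop_length[1]:config$loop_length[2], 1)
  o <- config$overhang
  mir <- paste(rand_bases(L, 0.5), collapse = "")
  loop <- paste(rand_bases(K, config$gc), collapse = "")
  star <- mutate_bases(revcomp(mir), config$star_mismatch_rate)
  transcript <- paste0(mir, loop, star)
  tlen <- nchar(transcript) + o          # precursor includes the overhang
  if (position + tlen > nchar(genome_seq)) stop("hairpin does not fit")
  insert <- if (strand == "+") transcript else revcomp(transcript)
  # on "-" the transcript occupies the same genomic window, reverse strand
  substr(genome_seq, position + 1L, position + nchar(transcript)) <- insert
  # transcript-coordinate spans
  mir_t <- c(0L, L)
  star_t <- c(L + K + o, L + K + o + L)  # overhang register
  t2g <- function(tt) {
    if (strand == "+") position + tt
    else c(position + nchar(transcript) - tt[2], position +
             nchar(transcript) - tt[1])
  }
  mg <- t2g(mir_t); sg <- t2g(star_t)
  prec <- if (strand == "+") c(position, position + tlen)
          else c(position - o, position + nchar(transcript))
  # the planted miR is the transcript 5' arm by construction; which arm
  # carries the abundant guide reads is drawn separately
  guide_arm <- sample(c("5p", "3p"), 1)
  rec <- data.frame(
    hairpin_start = prec[1], hairpin_end = prec[2], strand = strand,
    mir5p_start = mg[1], mir5p_end = mg[2],
    mir3p_start = sg[1], mir3p_end = sg[2],
    mir_seq = mir, star_seq = star,
    mir_arm = guide_arm,
    guide_seq = if (guide_arm == "5p") mir else star,
    is_noise = FALSE, stringsAsFactors = FALSE)
  list(genome_seq = genome_seq, record = rec)
}

# read stack around a modal 5' cut; returns data.frame(start,end) genomic
stack_spans <- function(modal5, len_range, n, precision, strand,
                        max_shift = 2L) {
  if (n <= 0) return(NULL)
  shift <- ifelse(stats::runif(n) < precision, 0L,
                  sample(c(-max_shift:-1, 1:max_shift), n, replace = TRUE))
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  if (strand == "+") {
    s <- modal5 + shift
    data.frame(start = s, end = s + len)
  } else {
    e <- modal5 + 1L - shift          # modal5 is the genomic 5' base
    data.frame(start = e - len, end = e)
  }
}

#' Simulate a small RNA-seq experiment
#'
#' Builds the genome, plants hairpins and noise loci, and simulates aligned
#' read stacks. Fully deterministic for a fixed config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{mir_simulation}: \code{genome} (named
#'   character vector), \code{reads} (aligned-read data frame, hit counts
#'   unset), \code{truth} (one row per planted locus), \code{annotations}
#'   (miRBase-style annotation data frame for the planted hairpins),
#'   \code{known_matures} (named character vector), \code{config}.
#' @export
simulate_mir_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  glen <- config$genome_length
  genome_seq <- paste(rand_bases(glen, config$gc), collapse = "")
  n_decoy <- ceiling(config$n_noise_loci * config$multimap_fraction)
  n_slots <- config$n_hairpins + config$n_noise_loci + n_decoy
  slot <- floor((glen - 200) / n_slots)
  if (slot < 320) stop("genome too small for requested loci")
  positions <- 100 + slot * (seq_len(n_slots) - 1L) +
    sample(0:(slot - 250L), n_slots, replace = TRUE)
  positions <- sample(positions)        # shuffle slot assignment
  truth <- list(); reads <- list(); ann <- list()
  mat_seqs <- character(0)
  rid <- 0L
  new_ids <- function(n) {
    out <- sprintf("r%07d", rid + seq_len(n)); rid <<- rid + n; out
  }
  emit <- function(spans, chrom, strand, ids = NULL) {
    if (is.null(spans) || nrow(spans) == 0) return(NULL)
    spans$start <- pmax(0L, as.integer(spans$start))
    spans$end <- pmin(glen, as.integer(spans$end))
    if (is.null(ids)) ids <- new_ids(nrow(spans))
    data.frame(read_id = ids, chrom = chrom, start = spans$start,
               end = spans$end, strand = strand,
               seq = NA_character_, dup_count = 1L,
               hit_count = NA_integer_, stringsAsFactors = FALSE)
  }
  for (h in seq_len(config$n_hairpins)) {
    pos <- positions[h]
    strand <- sample(c("+", "-"), 1)
    pl <- plant_hairpin(genome_seq, pos, strand, config)
    genome_seq <- pl$genome_seq
    rec <- pl$record
    rec$name <- sprintf("sim-mir-%d", h)
    depth <- sample(config$depth[1]:config$depth[2], 1)
    rec$depth <- depth
    truth[[h]] <- rec
    L <- nchar(rec$mir_seq)
    a5 <- c(rec$mir5p_start, rec$mir5p_end)
    a3 <- c(rec$mir3p_start, rec$mir3p_end)
    fp_of <- function(span) if (strand == "+") span[1] else span[2] - 1L
    guide_g <- if (rec$mir_arm == "5p") a5 else a3
    star_gg <- if (rec$mir_arm == "5p") a3 else a5
    reads[[length(reads) + 1L]] <- emit(
      stack_spans(fp_of(guide_g), c(L - 1L, L + 1L), depth,
                  config$five_prime_precision, strand), "chr1", strand)
    reads[[length(reads) + 1L]] <- emit(
      stack_spans(fp_of(star_gg), c(L - 1L, L + 1L),
                  round(depth * config$star_ratio),
                  config$five_prime_precision, strand), "chr1", strand)
    # moR flanking the guide product outside the hairpin: 5' of miR-5p on
    # the 5p arm, 3' of miR-3p on the 3p arm (transcript direction)
    n_mor <- round(depth * config$moR_fraction)
    if (n_mor > 0) {
      # a few nt of clearance so jittered moR reads cannot chain into the
      # mature stack and blur the major-product span
      dir <- if (strand == "+") 1L else -1L
      mor5 <- if (rec$mir_arm == "5p") fp_of(a5) - dir * 22L
              else {
                if (strand == "+") a3[2] + 6L else a3[1] - 7L
              }
      reads[[length(reads) + 1L]] <- emit(
        stack_spans(mor5, c(17L, 19L), n_mor,
                    config$five_prime_precision, strand), "chr1", strand)
    }
    # loop product between the two matures, only when the loop is large
    # enough that its reads cannot chain the miR and miR* stacks together
    n_loop <- round(depth * config$loop_fraction)
    loop_lo <- min(a5[2], a3[2]); loop_hi <- max(a5[1], a3[1])
    if (n_loop > 0 && loop_hi - loop_lo >= 16L) {
      llen <- loop_hi - loop_lo - 8L
      loop5 <- if (strand == "+") loop_lo + 4L else loop_hi - 5L
      reads[[length(reads) + 1L]] <- emit(
        stack_spans(loop5, c(llen - 1L, llen), n_loop,
                    config$five_prime_precision, strand, max_shift = 1L),
        "chr1", strand)
    }
    # annotations (miRBase dialect truth)
    ann[[length(ann) + 1L]] <- data.frame(
      name = rec$name, chrom = "chr1", start = rec$hairpin_start,
      end = rec$hairpin_end, strand = strand, kind = "precursor",
      parent = NA_character_, arm = "unknown", stringsAsFactors = FALSE)
    for (arm in c("5p", "3p")) {
      ann[[length(ann) + 1L]] <- data.frame(
        name = paste0(sub("mir", "miR", rec$name), "-", arm),
        chrom = "chr1",
        start = rec[[paste0("mir", arm, "_start")]],
        end = rec[[paste0("mir", arm, "_end")]],
        strand = strand, kind = "mature", parent = rec$name, arm = arm,
        stringsAsFactors = FALSE)
    }
    mat_seqs[paste0(sub("mir", "miR", rec$name), "-",
                    rec$mir_arm)] <- rec$guide_seq
  }
  # background noise stacks (and decoy-duplicated multimapping loci)
  n_multimap <- ceiling(config$n_noise_loci * config$multimap_fraction)
  for (k in seq_len(config$n_noise_loci)) {
    pos <- positions[config$n_hairpins + k]
    strand <- sample(c("+", "-"), 1)
    depth <- sample(config$noise_depth[1]:config$noise_depth[2], 1)
    modal5 <- if (strand == "+") pos else pos + 24L
    spans <- stack_spans(modal5, c(18L, 28L), depth,
                         config$noise_five_prime_precision, strand,
                         max_shift = 5L)
    nr <- emit(spans, "chr1", strand)
    reads[[length(reads) + 1L]] <- nr
    is_mm <- k <= n_multimap
    if (is_mm && !is.null(nr)) {
      # physically duplicate the locus sequence at a decoy slot so the same
      # read aligns at both copies (NH consistency by construction)
      dpos <- positions[config$n_hairpins + config$n_noise_loci + k]
      lo <- min(nr$start); hi <- max(nr$end)
      seg <- substr(genome_seq, lo + 1L, hi)
      substr(genome_seq, dpos + 1L, dpos + nchar(seg)) <- seg
      dup <- nr
      dup$start <- nr$start - lo + dpos
      dup$end <- nr$end - lo + dpos
      reads[[length(reads) + 1L]] <- dup   # same read_ids: NH = 2
    }
    truth[[length(truth) + 1L]] <- data.frame(
      hairpin_start = min(nr$start), hairpin_end = max(nr$end),
      strand = strand, mir5p_start = NA_integer_, mir5p_end = NA_integer_,
      mir3p_start = NA_integer_, mir3p_end = NA_integer_,
      mir_seq = NA_character_, star_seq = NA_character_,
      mir_arm = NA_character_, guide_seq = NA_character_, is_noise = TRUE,
      name = sprintf("noise-%d", k), depth = depth,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)
  # fill read sequences from the final genome (read orientation)
  seg <- substring(genome_seq, reads$start + 1L, reads$end)
  reads$seq <- ifelse(reads$strand == "+", seg, revcomp(seg))
  reads <- reads[order(reads$start, reads$end, reads$read_id), , drop = FALSE]
  rownames(reads) <- NULL
  structure(list(genome = c(chr1 = genome_seq), reads = reads,
                 truth = do.call(rbind, truth),
                 annotations = do.call(rbind, ann),
                 known_matures = mat_seqs, config = config),
            class = "mir_simulation")
}

#' @export
print.mir_simulation <- function(x, ...) {
  cat("mir_simulation: genome", nchar(x$genome[[1]]), "nt;",
      sum(!x$truth$is_noise), "hairpins,", sum(x$truth$is_noise),
      "noise loci,", nrow(x$reads), "aligned reads (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulation to disk as standard-format files
#'
#' Writes genome FASTA, aligned reads SAM, truth annotations GFF3 (miRBase
#' dialect), known matures FASTA, a truth TSV, and a manifest JSON with the
#' config and file checksums. Byte-identical across runs with the same
#' config.
#'
#' @param sim a \code{mir_simulation} (or a \code{sim_config}, which is
#'   simulated first).
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
generate_fixture <- function(sim, outdir) {
  if (inherits(sim, "sim_config")) sim <- simulate_mir_experiment(sim)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  writeLines(c(">chr1", chunk_seq(sim$genome[[1]])), fa)
  sam <- file.path(outdir, "reads.sam")
  write_sim_sam(sim, sam)
  gff <- file.path(outdir, "truth.gff3")
  write_truth_gff3(sim$annotations, gff)
  mat <- file.path(outdir, "matures.fa")
  writeLines(as.vector(rbind(paste0(">", names(sim$known_matures)),
                             unname(sim$known_matures))), mat)
  tsv <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(fa, sam, gff, mat, tsv)
  manifest <- list(config = unclass(sim$config),
                   md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

chunk_seq <- function(s, width = 70L) {
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

write_sim_sam <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:chr1\tLN:", nchar(sim$genome[[1]]))), con)
  r <- sim$reads
  nh <- table(r$read_id)
  flag <- ifelse(r$strand == "+", 0L, 16L)
  seq_fwd <- ifelse(r$strand == "+", r$seq, revcomp(r$seq))
  lines <- sprintf("%s\t%d\tchr1\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                   r$read_id, flag, r$start + 1L, r$end - r$start,
                   seq_fwd, as.integer(nh[r$read_id]))
  writeLines(lines, con)
}

write_truth_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  prec <- ann[ann$kind == "precursor", , drop = FALSE]
  for (i in seq_len(nrow(prec))) {
    p <- prec[i, ]
    writeLines(sprintf(
      "%s\tsim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      p$chrom, p$start + 1L, p$end, p$strand, p$name, p$name), con)
    kids <- ann[ann$kind == "mature" & !is.na(ann$parent) &
                ann$parent == p$name, , drop = FALSE]
    for (k in seq_len(nrow(kids))) {
      m <- kids[k, ]
      writeLines(sprintf(
        "%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
        m$chrom, m$start + 1L, m$end, m$strand, m$name, m$name, p$name), con)
    }
  }
  invisible(path)
}
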