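#' Load aligned small RNA-seq reads from SAM/BAM
#'
#' Reads mapped records from a SAM or BAM file into a data frame of aligned
#' reads. Coordinates are converted to 0-based half-open intervals; sequences
#' of minus-strand alignments are stored in read orientation (reverse
#' complement of the genome-forward SEQ field). Collapsed-read multiplicities
#' encoded in the read name as a trailing \code{x<N>} (collapsed-FASTA
#' practice, e.g. \code{read12_x53}) are honoured as \code{dup_count};
#' otherwise \code{dup_count} is 1.
#'
#' @param path path to a SAM or BAM file.
#' @param min_mapq minimum mapping quality; default 0 so that multi-mapping
#'   reads (which typically carry MAPQ 0) survive. Multiplicity is handled
#'   downstream by fractional 1/n_r weighting, not by filtering.
#' @return data frame with columns \code{read_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{seq}, \code{dup_count},
#'   \code{hit_count} (NA until \code{\link{annotate_hit_counts}} is run,
#'   unless the file carries NH tags), one row per alignment record.
#' @export
load_alignments <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$pos)
  if (n == 0) return(empty_reads())
  keep <- is.na(x$mapq) | x$mapq >= min_mapq
  ref_w <- cigar_ref_width(as.character(x$cigar))
  seqs <- as.character(x$seq)
  strand <- as.character(x$strand)
  minus <- strand == "-"
  # SAM stores SEQ on the genome-forward strand; flip back to read orientation
  seqs[minus] <- revcomp(seqs[minus])
  reads <- data.frame(
    read_id = as.character(x$qname),
    chrom = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L + ref_w,
    strand = strand,
    seq = seqs,
    dup_count = dup_from_id(as.character(x$qname)),
    hit_count = if (is.null(x$tag$NH)) NA_integer_ else as.integer(x$tag$NH),
    stringsAsFactors = FALSE)
  reads <- reads[keep, , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

empty_reads <- function() {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), seq = character(),
             dup_count = integer(), hit_count = integer(),
             stringsAsFactors = FALSE)
}

# reference-consuming cigar width (M, D, N, =, X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    lens <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

dup_from_id <- function(ids) {
  m <- regmatches(ids, regexpr("[_-][xX](\\d+)$", ids))
  out <- rep(1L, length(ids))
  has <- lengths(regmatches(ids, gregexpr("[_-][xX]\\d+$", ids))) > 0
  out[has] <- as.integer(sub("^[_-][xX]", "", m))
  out
}

#' Reconstruct genome hit counts (NH) per read
#'
#' Sets \code{hit_count} (the n_r of the ARPM definition) to the number of
#' alignment records sharing each \code{read_id}. When \code{trust_nh} is
#' TRUE and every record already carries an NH value, the existing tags are
#' kept instead.
#'
#' @param reads data frame from \code{\link{load_alignments}}.
#' @param trust_nh keep pre-existing NH tags when complete (default FALSE:
#'   recompute by read-id tally).
#' @return the reads with \code{hit_count} populated.
#' @export
annotate_hit_counts <- function(reads, trust_nh = FALSE) {
  if (nrow(reads) == 0) return(reads)
  if (trust_nh && !anyNA(reads$hit_count)) return(reads)
  tab <- table(reads$read_id)
  nseq <- tapply(reads$seq, reads$read_id, function(s) length(unique(s)))
  if (any(nseq > 1)) {
    warning("read_id collision across distinct sequences; counting per read_id")
  }
  reads$hit_count <- as.integer(tab[reads$read_id])
  reads
}

#' Merge identical collapsed reads
#'
#' Alignment records with identical chrom/start/end/strand/seq are merged and
#' their \code{dup_count}s summed. Run after
#' \code{\link{annotate_hit_counts}} so hit counts refer to distinct
#' alignment positions.
#'
#' @param reads aligned reads data frame.
#' @return merged reads data frame.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  key <- paste(reads$chrom, reads$start, reads$end, reads$strand, reads$seq,
               sep = "\r")
  dup <- tapply(reads$dup_count, key, sum)
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$dup_count <- as.integer(dup[key[first]])
  out <- out[order(out$chrom, out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group reads into read regions (read stacks)
#'
#' A read region is a maximal set of same-strand reads whose genomic
#' intervals form a connected component of the overlap graph. Abutting
#' half-open intervals (end of one equals start of the next) do not overlap
#' and are kept in separate regions. Regions are the unit scored by the
#' mature-product random forest.
#'
#' @param reads aligned reads (hit counts not required).
#' @return an object of class \code{read_region_set}: a list with
#'   \code{$regions} (one row per region: \code{region_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{n_reads},
#'   \code{total_dup}, \code{modal_start}) and \code{$reads} (the input with
#'   a \code{region_id} column).
#' @export
group_read_regions <- function(reads) {
  reads <- collapse_reads(reads)
  if (nrow(reads) == 0) {
    regs <- data.frame(region_id = integer(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer(), n_reads = integer(),
                       total_dup = integer(), modal_start = integer(),
                       stringsAsFactors = FALSE)
    return(structure(list(regions = regs,
                          reads = cbind(reads, region_id = integer())),
                     class = "read_region_set"))
  }
  reads$region_id <- NA_integer_
  next_id <- 1L
  for (grp in split(seq_len(nrow(reads)),
                    paste(reads$chrom, reads$strand, sep = "\r"))) {
    ir <- IRanges::IRanges(start = reads$start[grp] + 1L,
                           end = reads$end[grp])
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, merged, minoverlap = 1L)
    reads$region_id[grp] <- next_id - 1L + S4Vectors::subjectHits(hit)
    next_id <- next_id + length(merged)
  }
  by_reg <- split(seq_len(nrow(reads)), reads$region_id)
  regs <- do.call(rbind, lapply(names(by_reg), function(id) {
    i <- by_reg[[id]]
    data.frame(region_id = as.integer(id),
               chrom = reads$chrom[i[1]],
               strand = reads$strand[i[1]],
               start = min(reads$start[i]),
               end = max(reads$end[i]),
               n_reads = length(i),
               total_dup = sum(reads$dup_count[i]),
               modal_start = modal_five_prime(reads[i, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  # renumber by genomic order for stable, order-independent ids
  ord <- order(regs$chrom, regs$start, regs$end, regs$strand)
  regs <- regs[ord, , drop = FALSE]
  remap <- stats::setNames(seq_len(nrow(regs)), regs$region_id)
  regs$region_id <- seq_len(nrow(regs))
  reads$region_id <- as.integer(remap[as.character(reads$region_id)])
  reads <- reads[order(reads$region_id, reads$start, reads$end, reads$seq), ,
                 drop = FALSE]
  rownames(regs) <- rownames(reads) <- NULL
  structure(list(regions = regs, reads = reads), class = "read_region_set")
}

#' @export
print.read_region_set <- function(x, ...) {
  cat("read_region_set:", nrow(x$regions), "regions,",
      nrow(x$reads), "reads\n")
  invisible(x)
}

# strand-aware dup-count-weighted modal 5' position; ties -> smallest coord
modal_five_prime <- function(reads) {
  fp <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  w <- tapply(reads$dup_count, fp, sum)
  pos <- as.integer(names(w))
  pos[order(-w, pos)][1]
}

region_reads <- function(rrs, region_id) {
  rrs$reads[rrs$reads$region_id == region_id, , drop = FALSE]
}

#' Adjusted read count of a set of reads
#'
#' Each read contributes \code{dup_count / hit_count}: a read aligning to
#' n_r genomic locations contributes a fractional count of 1/n_r to each.
#'
#' @param reads aligned reads with hit counts populated.
#' @return non-negative numeric scalar.
#' @export
adjusted_count <- function(reads) {
  if (nrow(reads) == 0) return(0)
  if (anyNA(reads$hit_count)) {
    stop("hit_count missing; run annotate_hit_counts() first")
  }
  sum(reads$dup_count / reads$hit_count)
}

#' Sample library size for ARPM normalization
#'
#' @param reads every aligned read of the sample (hit counts populated).
#' @param sample_id optional label.
#' @return list with \code{sample_id} and \code{total_adjusted_reads}.
#' @export
sample_library <- function(reads, sample_id = "sample") {
  list(sample_id = sample_id, total_adjusted_reads = adjusted_count(reads))
}

#' Adjusted reads per million (ARPM)
#'
#' ARPM of a locus is \code{1e6 * sum_{r in locus} dup/n_r / sum_{r in
#' sample} dup/n_r}: multi-mapped reads are distributed uniformly over their
#' alignment positions, then normalized to parts per million of the sample.
#'
#' @param locus_adjusted adjusted count of the locus
#'   (\code{\link{adjusted_count}}).
#' @param library a \code{\link{sample_library}} or a positive total.
#' @return ARPM value.
#' @export
arpm <- function(locus_adjusted, library) {
  total <- if (is.list(library)) library$total_adjusted_reads else library
  if (!is.numeric(total) || total <= 0) {
    stop("library total_adjusted_reads must be positive")
  }
  1e6 * locus_adjusted / total
}

#' Load miRBase-style GFF3 annotations
#'
#' Parses \code{miRNA_primary_transcript} (precursor) and \code{miRNA}
#' (mature) records. Matures are linked to their precursor through the
#' \code{Derives_from} attribute. The arm of a mature is taken from a
#' \code{-5p}/\code{-3p} name suffix when present; otherwise it is inferred
#' from the position of the mature midpoint within the parent precursor
#' (5' half of the transcript, strand-aware, gives 5p). GFF 1-based closed
#' coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return data frame: \code{name}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{kind} (precursor/mature), \code{arm}
#'   (5p/3p/unknown), \code{parent} (precursor name, NA for precursors and
#'   orphans).
#' @export
load_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_annotations())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9)
  if (length(bad)) stop("malformed GFF3 record at line ", bad[1])
  typ <- vapply(f, `[[`, "", 3)
  keep <- typ %in% c("miRNA_primary_transcript", "miRNA")
  f <- f[keep]; typ <- typ[keep]
  attr_of <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^(;)?", key, "="), "", m)
  }
  ann <- do.call(rbind, lapply(seq_along(f), function(i) {
    x <- f[[i]]
    a <- x[9]
    nm <- attr_of(a, "Name")
    if (is.na(nm)) nm <- attr_of(a, "ID")
    data.frame(name = nm,
               id = attr_of(a, "ID"),
               chrom = x[1],
               start = as.integer(x[4]) - 1L,
               end = as.integer(x[5]),
               strand = x[7],
               kind = if (typ[i] == "miRNA") "mature" else "precursor",
               derives = attr_of(a, "Derives_from"),
               stringsAsFactors = FALSE)
  }))
  prec <- ann[ann$kind == "precursor", , drop = FALSE]
  id2name <- stats::setNames(prec$name, prec$id)
  ann$parent <- NA_character_
  mat <- ann$kind == "mature"
  ann$parent[mat] <- ifelse(ann$derives[mat] %in% names(id2name),
                            id2name[ann$derives[mat]], ann$derives[mat])
  orphan <- mat & (is.na(ann$parent) | !(ann$parent %in% prec$name))
  if (any(orphan)) {
    warning(sum(orphan), " mature record(s) without resolvable parent")
    ann$parent[orphan] <- NA_character_
  }
  ann$arm <- "unknown"
  ann$arm[mat & grepl("-5p", ann$name)] <- "5p"
  ann$arm[mat & grepl("-3p", ann$name)] <- "3p"
  infer <- which(mat & ann$arm == "unknown" & !is.na(ann$parent))
  for (i in infer) {
    p <- prec[match(ann$parent[i], prec$name), ]
    mid <- (ann$start[i] + ann$end[i]) / 2
    frac <- if (p$strand == "+") (mid - p$start) / (p$end - p$start)
            else (p$end - mid) / (p$end - p$start)
    ann$arm[i] <- if (frac < 0.5) "5p" else "3p"
  }
  ann$id <- ann$derives <- NULL
  rownames(ann) <- NULL
  ann
}

empty_annotations <- function() {
  data.frame(name = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), kind = character(),
             parent = character(), arm = character(), stringsAsFactors = FALSE)
}

#' Export read regions as BED6
#'
#' @param rrs a \code{read_region_set}.
#' @param path output file.
#' @export
write_regions_bed <- function(rrs, path) {
  r <- rrs$regions
  bed <- data.frame(r$chrom, r$start, r$end,
                    paste0("region_", r$region_id), r$total_dup, r$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export predictions as miRBase-dialect GFF3
#'
#' Writes one \code{miRNA_primary_transcript} per prediction with child
#' \code{miRNA} records for the called 5p/3p matures. Internal 0-based
#' half-open coordinates are converted back to GFF 1-based closed.
#'
#' @param preds predictions from \code{\link{predict.mir_forest}}.
#' @param path output file.
#' @export
write_predictions_gff3 <- function(preds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(preds) == 0) return(invisible(path))
  for (i in seq_len(nrow(preds))) {
    p <- preds[i, ]
    id <- sprintf("Novel-%d", i)
    writeLines(sprintf(
      "%s\tmirforest\tmiRNA_primary_transcript\t%d\t%d\t%.3f\t%s\t.\tID=%s;Name=%s",
      p$chrom, p$start + 1L, p$end, p$hprf_score, p$strand, id, id), con)
    for (arm in c("5p", "3p")) {
      s <- p[[paste0("mature_", arm, "_start")]]
      e <- p[[paste0("mature_", arm, "_end")]]
      if (!is.na(s)) {
        writeLines(sprintf(
          "%s\tmirforest\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s-%s;Name=%s-%s;Derives_from=%s",
          p$chrom, s + 1L, e, p$strand, id, arm, id, arm, id), con)
      }
    }
  }
  invisible(path)
}

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(gsub("U", "T", toupper(x)))))
}
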