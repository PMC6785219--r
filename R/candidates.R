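# Hairpin candidate generation (duplex-focused and product-focused spans),
# Dicer/Drosha product naming within candidates, and the 71-feature vector
# of the hairpin-precursor classifier.

#' Default span-finding parameters
#'
#' @param window duplex flank width in nt around a product (70).
#' @param min_gap minimum separation between two products for a
#'   product-focused span (5 nt).
#' @param pad extension beyond the product/duplex boundaries before folding
#'   (5 nt each side; stabilizes folding of spans that end exactly at
#'   Drosha/Dicer cut positions).
#' @param max_span cap on candidate span length (250 nt).
#' @param register_tol tolerance when matching a read stack to the miR:miR*
#'   duplex register (2 nt).
#' @return list of parameters.
#' @export
span_params <- function(window = 70L, min_gap = 5L, pad = 5L,
                        max_span = 250L, register_tol = 2L) {
  list(window = window, min_gap = min_gap, pad = pad, max_span = max_span,
       register_tol = register_tol)
}

# genomic -> transcript coordinates of an interval within a candidate span
g2t_interval <- function(gs, ge, cstart, cend, strand) {
  if (strand == "+") c(gs - cstart, ge - cstart)
  else c(cend - ge, cend - gs)
}

candidate_seq <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Generate hairpin precursor candidates for MPRF-passing products
#'
#' For each passing product, a duplex-focused span is built from the optimal
#' duplex between the product's most frequent read and the flanking genomic
#' windows (the region between the product and the duplexed subsequence),
#' and product-focused spans are built between the product and every other
#' passing product on the same chrom/strand separated by at least
#' \code{min_gap} nt. Spans are padded and capped; each candidate records
#' its major product and origin.
#'
#' @param rrs \code{read_region_set}.
#' @param passing_ids region ids that passed the MPRF threshold.
#' @param genome named character vector.
#' @param stack_dup result of \code{\link{stack_duplex_energies}} for these
#'   regions (provides the optimal flank duplex geometry).
#' @param params \code{\link{span_params}}.
#' @return data frame of candidates: \code{cand_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{origin},
#'   \code{major_region_id}.
#' @export
generate_candidates <- function(rrs, passing_ids, genome, stack_dup,
                                params = span_params()) {
  regs <- rrs$regions
  out <- list()
  pass <- regs[regs$region_id %in% passing_ids, , drop = FALSE]
  for (i in seq_len(nrow(pass))) {
    r <- pass[i, ]
    glen <- nchar(genome[[r$chrom]])
    clamp <- function(s, e) c(max(0L, s), min(glen, e))
    # duplex-focused span
    d <- stack_dup[match(r$region_id, stack_dup$region_id), ]
    if (!is.na(d$side) && d$energy < 0) {
      se <- clamp(min(r$start, d$t_gstart) - params$pad,
                  max(r$end, d$t_gend) + params$pad)
      if (se[2] - se[1] <= params$max_span) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = r$chrom, strand = r$strand, start = se[1], end = se[2],
          origin = "duplex_focused", major_region_id = r$region_id,
          stringsAsFactors = FALSE)
      }
    }
    # product-focused spans vs every other passing product
    others <- pass[pass$chrom == r$chrom & pass$strand == r$strand &
                   pass$region_id != r$region_id, , drop = FALSE]
    for (k in seq_len(nrow(others))) {
      o <- others[k, ]
      gap <- max(o$start - r$end, r$start - o$end)
      if (gap < params$min_gap) next
      se <- clamp(min(r$start, o$start) - params$pad,
                  max(r$end, o$end) + params$pad)
      if (se[2] - se[1] > params$max_span) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = r$chrom, strand = r$strand, start = se[1], end = se[2],
        origin = "product_focused", major_region_id = r$region_id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cand_id = integer(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), origin = character(),
                      major_region_id = integer(), stringsAsFactors = FALSE))
  }
  cands <- do.call(rbind, out)
  cands <- unique(cands)
  cands <- cands[order(cands$chrom, cands$start, cands$end, cands$strand,
                       cands$origin, cands$major_region_id), , drop = FALSE]
  rownames(cands) <- NULL
  cbind(cand_id = seq_len(nrow(cands)), cands)
}

#' Duplex-focused span for a single product
#'
#' Convenience wrapper returning only the duplex-focused candidate for one
#' region (NULL if no favourable flank duplex exists).
#'
#' @inheritParams generate_candidates
#' @param region_id the product's region id.
#' @export
duplex_focused_span <- function(rrs, region_id, genome,
                                params = span_params()) {
  sub <- rrs
  sub$regions <- rrs$regions[rrs$regions$region_id == region_id, ,
                             drop = FALSE]
  sd <- stack_duplex_energies(sub, genome, params$window)
  cands <- generate_candidates(rrs, region_id, genome, sd, params)
  cands <- cands[cands$origin == "duplex_focused", , drop = FALSE]
  if (nrow(cands) == 0) NULL else cands
}

#' Product-focused spans among a set of products
#'
#' @inheritParams generate_candidates
#' @export
product_focused_spans <- function(rrs, passing_ids, genome,
                                  params = span_params()) {
  sd <- data.frame(region_id = passing_ids, energy = 0, side = NA_character_,
                   t_gstart = NA_integer_, t_gend = NA_integer_)
  cands <- generate_candidates(rrs, passing_ids, genome, sd, params)
  cands[cands$origin == "product_focused", , drop = FALSE]
}

#' Fold candidates and locate the major-product duplex
#'
#' Folds every candidate span (strand-aware sequence) in one engine call and
#' computes the optimal duplex between each candidate's major product (most
#' frequent read) and the candidate sequence with the product span masked,
#' yielding the miR* register within the fold.
#'
#' @param cands candidate data frame from \code{\link{generate_candidates}}.
#' @param rrs \code{read_region_set}.
#' @param genome named character vector.
#' @return the candidates with added columns: \code{seq}, \code{structure},
#'   \code{mfe}, \code{mir_t1}, \code{mir_t2} (major product in transcript
#'   coordinates), \code{dup_energy}, \code{star_t1}, \code{star_t2},
#'   \code{dup_found}, \code{dup_structure}, \code{dup_q1}, \code{dup_q2}.
#' @export
fold_candidates <- function(cands, rrs, genome) {
  if (nrow(cands) == 0) {
    for (col in c("seq", "structure", "dup_structure")) cands[[col]] <- character(0)
    for (col in c("mfe", "dup_energy")) cands[[col]] <- numeric(0)
    for (col in c("mir_t1", "mir_t2", "star_t1", "star_t2", "dup_q1",
                  "dup_q2")) cands[[col]] <- integer(0)
    cands$dup_found <- logical(0)
    return(cands)
  }
  seqs <- vapply(seq_len(nrow(cands)), function(i) {
    candidate_seq(genome, cands$chrom[i], cands$start[i], cands$end[i],
                  cands$strand[i])
  }, character(1))
  fold <- rna_fold(seqs)
  cands$seq <- fold$seq
  cands$structure <- fold$structure
  cands$mfe <- fold$mfe
  mir_t <- t(vapply(seq_len(nrow(cands)), function(i) {
    r <- rrs$regions[match(cands$major_region_id[i], rrs$regions$region_id), ]
    tt <- g2t_interval(max(r$start, cands$start[i]), min(r$end, cands$end[i]),
                       cands$start[i], cands$end[i], cands$strand[i])
    as.integer(tt)
  }, integer(2)))
  cands$mir_t1 <- mir_t[, 1]; cands$mir_t2 <- mir_t[, 2]
  queries <- vapply(seq_len(nrow(cands)), function(i) {
    most_frequent_seq(region_reads(rrs, cands$major_region_id[i]))
  }, character(1))
  masked <- vapply(seq_len(nrow(cands)), function(i) {
    s <- cands$seq[i]
    n1 <- cands$mir_t1[i]; n2 <- cands$mir_t2[i]
    paste0(substr(s, 1, n1),
           strrep("N", n2 - n1),
           substr(s, n2 + 1, nchar(s)))
  }, character(1))
  dup <- rna_duplex(queries, masked)
  cands$dup_energy <- ifelse(dup$found, dup$energy, 0)
  cands$dup_found <- dup$found
  cands$star_t1 <- ifelse(dup$found, dup$t_start, NA_integer_)
  cands$star_t2 <- ifelse(dup$found, dup$t_end, NA_integer_)
  cands$dup_structure <- dup$structure
  cands$dup_q1 <- dup$q_start
  cands$dup_q2 <- dup$q_end
  cands
}

#' Name the products of a hairpin candidate
#'
#' Assigns each read stack inside the candidate span to the product expected
#' from Drosha/Dicer processing: the most abundant stack is the major
#' product (miR on its arm); a stack on the opposite arm overlapping the
#' miR:miR* duplex register (within the register tolerance) is the miR of
#' that arm; stacks 5' of miR-5p are moR-5p, stacks 3' of miR-3p are
#' moR-3p; stacks over the main loop are loop products; the remainder are
#' out-5p/out-3p/other.
#'
#' @param cand one row of a folded candidate data frame.
#' @param anatomy parsed \code{\link{parse_hairpin}} of the candidate fold
#'   anchored at the major product.
#' @param rrs \code{read_region_set}.
#' @param params \code{\link{span_params}}.
#' @return data frame of products: \code{label}, \code{region_id},
#'   \code{t_start}, \code{t_end}, \code{arm}, \code{is_major},
#'   \code{total_dup}, \code{modal_t5}.
#' @export
name_products <- function(cand, anatomy, rrs, params = span_params()) {
  regs <- rrs$regions
  inside <- regs$chrom == cand$chrom & regs$strand == cand$strand &
    regs$start < cand$end & regs$end > cand$start
  regs <- regs[inside, , drop = FALSE]
  if (nrow(regs) == 0) {
    return(data.frame(label = character(), region_id = integer(),
                      t_start = integer(), t_end = integer(),
                      arm = character(), is_major = logical(),
                      total_dup = integer(), modal_t5 = integer(),
                      stringsAsFactors = FALSE))
  }
  n <- nchar(cand$seq)
  loop <- anatomy$main_loop
  if (is.null(loop)) loop <- c(n %/% 2L, n %/% 2L)
  tt <- t(vapply(seq_len(nrow(regs)), function(i) {
    v <- g2t_interval(max(regs$start[i], cand$start),
                      min(regs$end[i], cand$end),
                      cand$start, cand$end, cand$strand)
    as.integer(v)
  }, integer(2)))
  modal_t5 <- vapply(seq_len(nrow(regs)), function(i) {
    m <- regs$modal_start[i]
    as.integer(if (cand$strand == "+") m - cand$start
               else cand$end - 1L - m)
  }, integer(1))
  center <- (tt[, 1] + tt[, 2]) / 2
  arm <- ifelse(center < loop[1], "5p",
                ifelse(center >= loop[2], "3p", "loop"))
  p <- data.frame(label = NA_character_, region_id = regs$region_id,
                  t_start = tt[, 1], t_end = tt[, 2], arm = arm,
                  is_major = regs$region_id == cand$major_region_id,
                  total_dup = regs$total_dup, modal_t5 = modal_t5,
                  stringsAsFactors = FALSE)
  maj <- which(p$is_major)
  stopifnot(length(maj) == 1)
  mir_arm <- p$arm[maj]
  p$label[maj] <- if (mir_arm == "loop") "loop" else paste0("miR-", mir_arm)
  # star: opposite-arm stack overlapping the duplex register
  if (mir_arm %in% c("5p", "3p") && isTRUE(cand$dup_found)) {
    opp <- if (mir_arm == "5p") "3p" else "5p"
    tol <- params$register_tol
    reg <- c(cand$star_t1 - tol, cand$star_t2 + tol)
    cand_star <- which(is.na(p$label) & p$arm == opp &
                       p$t_start < reg[2] & p$t_end > reg[1])
    if (length(cand_star)) {
      star <- cand_star[which.max(p$total_dup[cand_star])]
      p$label[star] <- paste0("miR-", opp)
    }
  }
  mir5 <- which(p$label %in% "miR-5p")
  mir3 <- which(p$label %in% "miR-3p")
  for (i in which(is.na(p$label))) {
    p$label[i] <- if (p$arm[i] == "loop") {
      "loop"
    } else if (p$arm[i] == "5p" && length(mir5) &&
               p$t_end[i] <= p$t_start[mir5] + params$register_tol) {
      "moR-5p"
    } else if (p$arm[i] == "3p" && length(mir3) &&
               p$t_start[i] >= p$t_end[mir3] - params$register_tol) {
      "moR-3p"
    } else if (p$arm[i] == "5p") {
      "out-5p"
    } else if (p$arm[i] == "3p") {
      "out-3p"
    } else "other"
  }
  p
}

PRODUCT_CLASSES <- c("miR-5p", "miR-3p", "moR-5p", "moR-3p", "loop",
                     "out-5p", "out-3p", "other")

OVERLAP_PAIRS <- list(
  miRmoR5pOverlap = c("miR-5p", "moR-5p"),
  miR5pLoopOverlap = c("miR-5p", "loop"),
  miR5pmiR3pOverlap = c("miR-5p", "miR-3p"),
  miRmoR3pOverlap = c("miR-3p", "moR-3p"),
  miR3pLoopOverlap = c("miR-3p", "loop"),
  moR5pLoopOverlap = c("moR-5p", "loop"),
  moR3pLoopOverlap = c("moR-3p", "loop"),
  miR5pOut5pOverlap = c("miR-5p", "out-5p"),
  miR3pOut3pOverlap = c("miR-3p", "out-3p"),
  moR5pOut5pOverlap = c("moR-5p", "out-5p"),
  moR3pOut3pOverlap = c("moR-3p", "out-3p"))

#' HPRF feature order manifest
#' @return character vector of the 71 hairpin-precursor feature names.
#' @export
hprf_feature_names <- function() {
  c("mfe", "pbp", "urf", "gcContent", "totalSenseRPM", "loopSize",
    "maxBulge", "tapd", "aapd", "ahc", "afh", "sameShift", "bothShift",
    DINUC_NAMES,
    "maxInteriorLoop", "intLoopSideDiff", "OPA", "duplexEnergy",
    "foldDupCmp", "dupPBP", "dupLoopLength", "APV", "wAPV", "ARV", "wARV",
    "mpLoopDistance", "dupLoopDistance", "totalOverlap",
    "totalRelativeOverlapAmount", "averageOverlapAmount",
    "innerLoopGapCount", "totalAntisenseRPM", "maxUnboundOverhang",
    "numOffshoots", "dupSize", "neighborCount", "RFProductAvg",
    paste0("prodFrac_", gsub("-", "", PRODUCT_CLASSES)),
    names(OVERLAP_PAIRS))
}

pop_var <- function(x, w = NULL) {
  # population (not sample) variance, optionally weighted
  if (length(x) <= 1) return(0)
  if (is.null(w)) w <- rep(1, length(x))
  m <- sum(w * x) / sum(w)
  sum(w * (x - m)^2) / sum(w)
}

#' Read-distribution features of a candidate
#'
#' @param products from \code{\link{name_products}}.
#' @param cand the candidate row.
#' @param rrs \code{read_region_set}.
#' @param library \code{\link{sample_library}} of the whole sample.
#' @return named list: urf, ahc, afh, OPA, totalSenseRPM,
#'   totalAntisenseRPM, and the 8 per-class product count fractions.
#' @export
distribution_features <- function(products, cand, rrs, library) {
  reads <- rrs$reads
  sense <- reads$chrom == cand$chrom & reads$strand == cand$strand &
    reads$start < cand$end & reads$end > cand$start
  anti <- reads$chrom == cand$chrom & reads$strand != cand$strand &
    reads$start < cand$end & reads$end > cand$start
  sr <- reads[sense, , drop = FALSE]
  adj <- adjusted_count(sr)
  urf <- if (adj > 0) sum(sr$dup_count[sr$hit_count == 1]) / adj else 0
  maj <- region_reads(rrs, products$region_id[products$is_major])
  ahc <- sum(maj$dup_count * maj$hit_count) / sum(maj$dup_count)
  afh <- five_prime_heterogeneity(maj)
  total_dup <- sum(products$total_dup)
  fracs <- stats::setNames(rep(0, length(PRODUCT_CLASSES)),
                           paste0("prodFrac_", gsub("-", "", PRODUCT_CLASSES)))
  for (cl in PRODUCT_CLASSES) {
    fracs[paste0("prodFrac_", gsub("-", "", cl))] <-
      sum(products$total_dup[products$label == cl]) / total_dup
  }
  mj <- which(products$is_major)
  ovl <- which(!products$is_major &
               products$t_start < products$t_end[mj] &
               products$t_end > products$t_start[mj])
  opa <- if (length(ovl)) max(products$total_dup[ovl]) / total_dup else 0
  c(list(urf = urf, ahc = ahc, afh = afh, OPA = opa,
         totalSenseRPM = arpm(adj, library),
         totalAntisenseRPM = arpm(adjusted_count(reads[anti, , drop = FALSE]),
                                  library)),
    as.list(fracs))
}

#' Product overlap and shift features
#'
#' Pairwise overlaps between named products (the 11 labelled pairs plus
#' aggregate sums), 5' offsets between overlapping same-arm products, the
#' deviation of opposite-arm product pairs from the miR:miR* duplex
#' register, and total/average displacement of sense vs antisense products.
#'
#' @param products from \code{\link{name_products}}.
#' @param cand the candidate row.
#' @param rrs \code{read_region_set} (for antisense stacks).
#' @return named list of 18 features.
#' @export
overlap_shift_features <- function(products, cand, rrs) {
  # one representative (most abundant) product per label
  rep_of <- function(lab) {
    i <- which(products$label == lab)
    if (length(i) == 0) return(NULL)
    products[i[which.max(products$total_dup[i])], ]
  }
  ov_len <- function(a, b) {
    max(0L, min(a$t_end, b$t_end) - max(a$t_start, b$t_start))
  }
  pair_ov <- vapply(names(OVERLAP_PAIRS), function(nm) {
    a <- rep_of(OVERLAP_PAIRS[[nm]][1]); b <- rep_of(OVERLAP_PAIRS[[nm]][2])
    if (is.null(a) || is.null(b)) 0 else ov_len(a, b)
  }, numeric(1))
  totalOverlap <- 0; totalRel <- 0; avgOv <- 0
  sameShift <- 0; bothShift <- 0
  total_dup <- sum(products$total_dup)
  np <- nrow(products)
  if (np >= 2) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      o <- ov_len(products[i, ], products[j, ])
      if (o > 0) {
        d <- sort(products$total_dup[c(i, j)])
        totalOverlap <- totalOverlap + o
        totalRel <- totalRel + o * d[1] / d[2]
        avgOv <- avgOv + o * d[1] / total_dup
        if (products$arm[i] == products$arm[j]) {
          sameShift <- max(sameShift,
                           abs(products$modal_t5[i] - products$modal_t5[j]))
        }
      }
    }
  }
  # bothShift: deviation of the opposite-arm miR pair from the duplex register
  if (isTRUE(cand$dup_found)) {
    m5 <- products[products$label == "miR-5p", , drop = FALSE]
    m3 <- products[products$label == "miR-3p", , drop = FALSE]
    if (nrow(m5) && nrow(m3)) {
      star <- if (products$arm[products$is_major][1] == "5p") m3[1, ] else m5[1, ]
      bothShift <- max(abs(star$t_start - cand$star_t1),
                       abs(star$t_end - cand$star_t2))
    }
  }
  # sense vs antisense displacement
  regs <- rrs$regions
  anti <- regs[regs$chrom == cand$chrom & regs$strand != cand$strand &
               regs$start < cand$end & regs$end > cand$start, , drop = FALSE]
  tapd <- 0; disp <- numeric(0)
  if (nrow(anti)) {
    sense_regs <- regs[match(products$region_id, regs$region_id), ]
    for (i in seq_len(nrow(anti))) {
      for (k in seq_len(nrow(sense_regs))) {
        if (anti$start[i] < sense_regs$end[k] &&
            anti$end[i] > sense_regs$start[k]) {
          disp <- c(disp, abs(anti$modal_start[i] - sense_regs$modal_start[k]))
        }
      }
    }
    tapd <- sum(disp)
  }
  c(as.list(pair_ov),
    list(totalOverlap = totalOverlap, totalRelativeOverlapAmount = totalRel,
         averageOverlapAmount = avgOv, sameShift = sameShift,
         bothShift = bothShift, tapd = tapd,
         aapd = if (length(disp)) mean(disp) else 0))
}

#' Read-count and start-position variance features
#'
#' Per product: the population variance of dup-counts across distinct reads
#' (APV family) and the dup-weighted population variance of 5' start
#' positions (ARV family). APV/ARV are plain means over products; wAPV is
#' weighted by each product's read fraction and wARV by product length.
#'
#' @param products from \code{\link{name_products}}.
#' @param rrs \code{read_region_set}.
#' @return named list: APV, wAPV, ARV, wARV.
#' @export
variance_features <- function(products, rrs) {
  pv <- rv <- numeric(nrow(products))
  for (i in seq_len(nrow(products))) {
    rd <- region_reads(rrs, products$region_id[i])
    pv[i] <- pop_var(rd$dup_count)
    rv[i] <- pop_var(read_five_primes(rd), w = rd$dup_count)
  }
  wdup <- products$total_dup / sum(products$total_dup)
  len <- products$t_end - products$t_start
  wlen <- len / sum(len)
  list(APV = mean(pv), wAPV = sum(wdup * pv),
       ARV = mean(rv), wARV = sum(wlen * rv))
}

#' Count small-RNA loci neighbouring a candidate
#'
#' Number of read regions (any type, either strand) within \code{distance}
#' nt of the candidate span, excluding regions overlapping the candidate
#' itself. MicroRNA loci tend to cluster, so nearby loci are evidence in
#' favour of a candidate.
#'
#' @param cand candidate row.
#' @param rrs \code{read_region_set}.
#' @param distance neighbourhood radius (default 1000 nt, inclusive).
#' @return integer count.
#' @export
neighbor_count <- function(cand, rrs, distance = 1000L) {
  regs <- rrs$regions[rrs$regions$chrom == cand$chrom, , drop = FALSE]
  gap <- pmax(regs$start - cand$end, cand$start - regs$end)
  sum(gap > 0 & gap <= distance)
}

#' Hairpin-precursor feature matrix
#'
#' Computes the 71-feature vector for every folded candidate: fold energy
#' and structure anatomy, sequence composition of the precursor, ARPM
#' expression on both strands, product-distribution, overlap/shift and
#' variance features, the neighbour count, and the mean MPRF decision value
#' of the candidate's products. Candidates without a major-product duplex
#' get 0 for the dup* features.
#'
#' @param cands folded candidates (\code{\link{fold_candidates}}).
#' @param rrs \code{read_region_set}.
#' @param library \code{\link{sample_library}}.
#' @param mprf_scores data frame \code{region_id}, \code{mprf_score}.
#' @param params \code{\link{span_params}}.
#' @return data frame: \code{cand_id} plus the 71 features in manifest
#'   order. Product tables are attached as the \code{"products"} attribute
#'   (a list indexed by candidate).
#' @export
hairpin_feature_matrix <- function(cands, rrs, library, mprf_scores,
                                   params = span_params()) {
  feat_names <- hprf_feature_names()
  if (nrow(cands) == 0) {
    m <- as.data.frame(matrix(numeric(0), ncol = length(feat_names) + 1))
    names(m) <- c("cand_id", feat_names)
    attr(m, "products") <- list()
    return(m)
  }
  prods_list <- vector("list", nrow(cands))
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    mir <- c(cand$mir_t1, cand$mir_t2)
    anatomy <- parse_hairpin(cand$structure, mir)
    star <- if (isTRUE(cand$dup_found)) c(cand$star_t1, cand$star_t2) else NULL
    sf <- structural_features(anatomy, mir, star)
    prods <- name_products(cand, anatomy, rrs, params)
    prods_list[[i]] <<- prods
    dfeat <- distribution_features(prods, cand, rrs, library)
    ofeat <- overlap_shift_features(prods, cand, rrs)
    vfeat <- variance_features(prods, rrs)
    fdc <- if (isTRUE(cand$dup_found)) {
      dup <- data.frame(found = TRUE, structure = cand$dup_structure,
                        q_start = cand$dup_q1, q_end = cand$dup_q2,
                        t_start = cand$star_t1, t_end = cand$star_t2,
                        stringsAsFactors = FALSE)
      v <- duplex_paired_vector(dup, nchar(cand$seq), q_offset = cand$mir_t1)
      fold_duplex_agreement(cand$structure, v, c(0L, nchar(cand$seq)))
    } else 0
    sc <- mprf_scores$mprf_score[match(prods$region_id, mprf_scores$region_id)]
    rf_avg <- if (all(is.na(sc))) 0 else mean(sc, na.rm = TRUE)
    v <- c(list(mfe = cand$mfe, pbp = sf$pbp, urf = dfeat$urf,
                gcContent = gc_content(cand$seq),
                totalSenseRPM = dfeat$totalSenseRPM,
                loopSize = sf$loopSize, maxBulge = sf$maxBulge,
                tapd = ofeat$tapd, aapd = ofeat$aapd, ahc = dfeat$ahc,
                afh = dfeat$afh, sameShift = ofeat$sameShift,
                bothShift = ofeat$bothShift),
           as.list(dinucleotide_freqs(cand$seq)),
           list(maxInteriorLoop = sf$maxInteriorLoop,
                intLoopSideDiff = sf$intLoopSideDiff, OPA = dfeat$OPA,
                duplexEnergy = cand$dup_energy, foldDupCmp = fdc,
                dupPBP = sf$dupPBP, dupLoopLength = sf$dupLoopLength,
                APV = vfeat$APV, wAPV = vfeat$wAPV, ARV = vfeat$ARV,
                wARV = vfeat$wARV, mpLoopDistance = sf$mpLoopDistance,
                dupLoopDistance = sf$dupLoopDistance,
                totalOverlap = ofeat$totalOverlap,
                totalRelativeOverlapAmount = ofeat$totalRelativeOverlapAmount,
                averageOverlapAmount = ofeat$averageOverlapAmount,
                innerLoopGapCount = sf$innerLoopGapCount,
                totalAntisenseRPM = dfeat$totalAntisenseRPM,
                maxUnboundOverhang = sf$maxUnboundOverhang,
                numOffshoots = sf$numOffshoots, dupSize = sf$dupSize,
                neighborCount = neighbor_count(cand, rrs),
                RFProductAvg = rf_avg),
           dfeat[paste0("prodFrac_", gsub("-", "", PRODUCT_CLASSES))],
           ofeat[names(OVERLAP_PAIRS)])
    unlist(v)
  })
  m <- as.data.frame(do.call(rbind, rows))
  names(m) <- feat_names
  stopifnot(ncol(m) == 71)
  out <- cbind(cand_id = cands$cand_id, m)
  attr(out, "products") <- prods_list
  out
}

#' Resolve overlapping scored hairpins
#'
#' Greedy by descending HPRF score: a candidate is kept iff it overlaps no
#' already-kept candidate on the same strand. Ties break to lower genomic
#' start, then duplex-focused origin.
#'
#' @param cands candidates with an \code{hprf_score} column.
#' @return the kept subset, pairwise non-overlapping per strand.
#' @export
resolve_overlapping_hairpins <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  stopifnot(!is.null(cands$hprf_score))
  ord <- order(-cands$hprf_score, cands$start,
               cands$origin != "duplex_focused", cands$cand_id)
  cands <- cands[ord, , drop = FALSE]
  kept <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    prior <- which(kept)
    clash <- any(cands$chrom[prior] == cands$chrom[i] &
                 cands$strand[prior] == cands$strand[i] &
                 cands$start[prior] < cands$end[i] &
                 cands$end[prior] > cands$start[i])
    kept[i] <- !clash
  }
  out <- cands[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
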