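# Dot-bracket anatomy: loop decomposition of secondary structures into
# hairpin loops, bulges, interior loops, multiloop runs and exterior bases,
# and the per-feature geometry used by the hairpin-precursor classifier.
# Intervals at the API boundary are 0-based half-open; internal work is
# 1-based inclusive on the pair table.

#' Pair table of a dot-bracket structure
#'
#' @param structure balanced dot-bracket string.
#' @return integer vector pt with pt[i] = j if (i,j) paired, 0 if unpaired
#'   (1-based).
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket structure")
  pt
}

# direct child pairs of pair (i,j): list of c(k,l)
direct_children <- function(pt, i, j) {
  kids <- list()
  k <- i + 1L
  while (k < j) {
    if (pt[k] > k) {
      kids[[length(kids) + 1L]] <- c(k, pt[k])
      k <- pt[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  kids
}

# loop decomposition: classify every position exactly once
decompose_structure <- function(structure) {
  pt <- pair_table(structure)
  n <- length(pt)
  cls <- rep("exterior", n)
  cls[pt > 0] <- "paired"
  hairpins <- list(); bulges <- list(); interiors <- list()
  pairs <- which(pt > seq_len(n))
  for (i in pairs) {
    j <- pt[i]
    kids <- direct_children(pt, i, j)
    if (length(kids) == 0) {
      if (j > i + 1) {
        cls[(i + 1):(j - 1)] <- "loop"
        hairpins[[length(hairpins) + 1L]] <- c(i, j, i + 1L, j - 1L)
      } else {
        hairpins[[length(hairpins) + 1L]] <- c(i, j, NA_integer_, NA_integer_)
      }
    } else if (length(kids) == 1) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      left <- if (k > i + 1) (i + 1):(k - 1) else integer(0)
      right <- if (j > l + 1) (l + 1):(j - 1) else integer(0)
      if (length(left) && length(right)) {
        cls[c(left, right)] <- "interior"
        interiors[[length(interiors) + 1L]] <-
          c(i, j, min(left), max(left), min(right), max(right))
      } else if (length(left)) {
        cls[left] <- "bulge"
        bulges[[length(bulges) + 1L]] <- c(i, j, min(left), max(left), 5L)
      } else if (length(right)) {
        cls[right] <- "bulge"
        bulges[[length(bulges) + 1L]] <- c(i, j, min(right), max(right), 3L)
      }
    } else {
      inner <- setdiff((i + 1):(j - 1), unlist(lapply(kids, function(kl)
        kl[1]:kl[2])))
      cls[inner] <- "loop"  # multiloop runs count as loop territory
    }
  }
  to_df <- function(lst, names) {
    if (length(lst) == 0) {
      return(stats::setNames(as.data.frame(matrix(integer(0), ncol =
        length(names))), names))
    }
    stats::setNames(as.data.frame(do.call(rbind, lst)), names)
  }
  list(pt = pt, n = n, class = cls,
       hairpins = to_df(hairpins, c("ci", "cj", "ls", "le")),
       bulges = to_df(bulges, c("ci", "cj", "s", "e", "side")),
       interiors = to_df(interiors, c("ci", "cj", "l1", "l2", "r1", "r2")))
}

# length of the stacked-helix run starting at pair (i,j), descending inward
helix_len <- function(pt, i, j) {
  len <- 1L
  while (i + 1 <= length(pt) && j - 1 >= 1 && pt[i + 1] == j - 1 &&
         j - 1 > i + 1) {
    i <- i + 1L; j <- j - 1L; len <- len + 1L
  }
  len
}

subtree_pairs <- function(pt, i, j) sum(pt[i:j] > seq(i, j))

#' Hairpin anatomy of a folded candidate
#'
#' Identifies the main stem and hairpin loop relative to an anchor (the
#' major-product span) and classifies every position of the structure as
#' paired, (hairpin/multiloop) loop, bulge, interior loop, or exterior.
#' The main stem is the stem whose closing pair most tightly encloses the
#' anchor; in multibranch folds the descent follows the child helix with the
#' longest stacked run (ties toward more enclosed pairs, then leftmost).
#' Hairpin loops other than the main loop that lie within the enclosing pair
#' of the main stem are counted as offshoots.
#'
#' @param structure dot-bracket string (or a row of \code{\link{rna_fold}}).
#' @param anchor 0-based half-open interval \code{c(start, end)} of the
#'   major product on the folded sequence.
#' @return object of class \code{hairpin_anatomy}: list with \code{class}
#'   (per-position classification), \code{main_loop} (0-based half-open or
#'   NULL), \code{no_hairpin} flag, \code{offshoots} (count),
#'   \code{offshoot_spans}, decomposition tables, and the pair table.
#' @export
parse_hairpin <- function(structure, anchor) {
  if (is.data.frame(structure)) structure <- structure$structure[1]
  d <- decompose_structure(structure)
  n <- d$n
  a1 <- anchor[1] + 1L; a2 <- anchor[2]
  stopifnot(a1 >= 1, a2 <= n, a1 <= a2)
  pairs <- which(d$pt > seq_len(n))
  enclosing <- pairs[pairs <= a1 & d$pt[pairs] >= a2]
  if (length(enclosing)) {
    top_i <- max(enclosing)           # innermost enclosing pair
  } else {
    # no pair encloses the whole anchor: take a stem touching the anchor
    touching <- pairs[(pairs >= a1 & pairs <= a2) |
                      (d$pt[pairs] >= a1 & d$pt[pairs] <= a2)]
    if (length(touching) == 0) {
      return(structure(list(class = d$class, main_loop = NULL,
                            no_hairpin = TRUE, offshoots = 0L,
                            offshoot_spans = list(), decomposition = d,
                            pt = d$pt, outer_pair = NULL,
                            inner_region = NULL),
                       class = "hairpin_anatomy"))
    }
    # prefer the stem whose span overlaps the anchor the most (robust when
    # the anchor runs past the last paired base), ties to the longer helix
    ov <- pmin(d$pt[touching], a2) - pmax(touching, a1) + 1L
    hl <- vapply(touching, function(k) helix_len(d$pt, k, d$pt[k]),
                 integer(1))
    top_i <- touching[order(-ov, -hl, touching)][1]
  }
  i <- top_i; j <- d$pt[top_i]
  outer <- c(i, j)
  inner <- NULL                        # interior of first multiloop or hairpin
  repeat {
    kids <- direct_children(d$pt, i, j)
    if (length(kids) == 0) {
      if (is.null(inner)) inner <- c(i, j)
      main_loop <- if (j > i + 1) c(i + 1L, j - 1L) else NULL
      break
    }
    if (length(kids) > 1 && is.null(inner)) inner <- c(i, j)
    score <- vapply(kids, function(kl) {
      helix_len(d$pt, kl[1], kl[2]) * 1e6 +
        subtree_pairs(d$pt, kl[1], kl[2])
    }, numeric(1))
    best <- kids[[which.max(score)]]
    i <- best[1]; j <- best[2]
  }
  # offshoots: hairpin loops within the outer pair other than the main loop
  hp <- d$hairpins
  off <- hp[hp$ci >= outer[1] & hp$cj <= outer[2], , drop = FALSE]
  if (!is.null(main_loop)) {
    off <- off[!(off$ls %in% main_loop[1] & off$le %in% main_loop[2]), ,
               drop = FALSE]
  }
  structure(list(
    class = d$class,
    main_loop = if (is.null(main_loop)) NULL
                else c(main_loop[1] - 1L, main_loop[2]),  # 0-based half-open
    no_hairpin = FALSE,
    offshoots = nrow(off),
    offshoot_spans = if (nrow(off)) lapply(seq_len(nrow(off)), function(k)
      c(off$ls[k] - 1L, off$le[k])) else list(),
    decomposition = d, pt = d$pt,
    outer_pair = outer, inner_region = inner),
    class = "hairpin_anatomy")
}

#' @export
print.hairpin_anatomy <- function(x, ...) {
  cat("hairpin_anatomy:", length(x$class), "nt;",
      if (x$no_hairpin) "no hairpin" else
        sprintf("main loop [%d,%d)", x$main_loop[1], x$main_loop[2]),
      ";", x$offshoots, "offshoot(s)\n")
  invisible(x)
}

interval_gap <- function(a, b) {
  # gap in nt between 0-based half-open intervals; 0 when overlapping/abutting
  max(0L, max(a[1], b[1]) - min(a[2], b[2]))
}

intersects <- function(s, e, span) s < span[2] + 1 && e >= span[1] + 1

#' Structural feature block for a hairpin candidate
#'
#' Computes the structure-derived features of the precursor classifier from
#' a parsed anatomy: hairpin loop size, largest bulge and interior loop in
#' the miR/miR* region, interior-loop side difference, the largest unpaired
#' overhang at either end of the miR, the count of >=3-nt unpaired runs in
#' the loop region (more than one indicates a multibranched loop), offshoot
#' hairpins, miR and miR* distances to the loop, base-pairing densities of
#' the miR and of the duplexed region, the longest unpaired run in the
#' duplexed region and its size.
#'
#' @param anatomy from \code{\link{parse_hairpin}}.
#' @param mir 0-based half-open interval of the major product on the fold.
#' @param star interval of the region duplexing the major product, or NULL
#'   when no duplex was found (the dup* features are then 0).
#' @return named list of 13 features.
#' @export
structural_features <- function(anatomy, mir, star = NULL) {
  d <- anatomy$decomposition
  paired <- d$pt > 0
  rg <- if (!is.null(star)) c(min(mir[1], star[1]), max(mir[2], star[2]))
        else mir
  rg1 <- c(rg[1] + 1L, rg[2])  # 1-based inclusive
  b <- d$bulges
  binr <- b[b$s <= rg1[2] & b$e >= rg1[1], , drop = FALSE]
  maxBulge <- if (nrow(binr)) max(binr$e - binr$s + 1L) else 0L
  it <- d$interiors
  iinr <- it[(it$l1 <= rg1[2] & it$l2 >= rg1[1]) |
             (it$r1 <= rg1[2] & it$r2 >= rg1[1]), , drop = FALSE]
  if (nrow(iinr)) {
    sizes <- (iinr$l2 - iinr$l1 + 1L) + (iinr$r2 - iinr$r1 + 1L)
    k <- which.max(sizes)
    maxInteriorLoop <- sizes[k]
    intLoopSideDiff <- abs((iinr$l2[k] - iinr$l1[k]) - (iinr$r2[k] - iinr$r1[k]))
  } else {
    maxInteriorLoop <- 0L
    intLoopSideDiff <- 0L
  }
  # unpaired run lengths inward from either end of the miR
  mpos <- (mir[1] + 1L):mir[2]
  run5 <- 0L
  for (p in mpos) { if (!paired[p]) run5 <- run5 + 1L else break }
  run3 <- 0L
  for (p in rev(mpos)) { if (!paired[p]) run3 <- run3 + 1L else break }
  maxUnboundOverhang <- max(run5, run3)
  # >=3-nt unpaired runs strictly inside the innermost pair of the main stem
  innerLoopGapCount <- 0L
  if (!is.null(anatomy$inner_region)) {
    ir <- anatomy$inner_region
    if (ir[2] > ir[1] + 1) {
      up <- !paired[(ir[1] + 1):(ir[2] - 1)]
      r <- rle(up)
      innerLoopGapCount <- sum(r$values & r$lengths >= 3)
    }
  }
  loop <- anatomy$main_loop
  loopSize <- if (is.null(loop)) 0L else loop[2] - loop[1]
  mpLoopDistance <- if (is.null(loop)) 0L else interval_gap(mir, loop)
  pbp_at <- function(span) {
    if (span[2] <= span[1]) return(0)
    mean(paired[(span[1] + 1L):span[2]])
  }
  if (!is.null(star)) {
    dupLoopDistance <- if (is.null(loop)) 0L else interval_gap(star, loop)
    dupPBP <- pbp_at(star)
    spos <- (star[1] + 1L):star[2]
    r <- rle(!paired[spos])
    dupLoopLength <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    dupSize <- star[2] - star[1]
  } else {
    dupLoopDistance <- 0L; dupPBP <- 0; dupLoopLength <- 0L; dupSize <- 0L
  }
  list(loopSize = loopSize,
       maxBulge = maxBulge,
       maxInteriorLoop = maxInteriorLoop,
       intLoopSideDiff = intLoopSideDiff,
       maxUnboundOverhang = maxUnboundOverhang,
       innerLoopGapCount = innerLoopGapCount,
       numOffshoots = anatomy$offshoots,
       mpLoopDistance = mpLoopDistance,
       dupLoopDistance = dupLoopDistance,
       pbp = pbp_at(mir),
       dupPBP = dupPBP,
       dupLoopLength = dupLoopLength,
       dupSize = dupSize,
       has_star = !is.null(star))
}

#' Map a duplex structure onto full-sequence pairing states
#'
#' Builds a logical paired/unpaired vector of length \code{n} from a duplex
#' hit: positions inside the query and target spans take their pairing state
#' from the duplex dot-bracket; everything else is unpaired.
#'
#' @param dup one row of \code{\link{rna_duplex}}.
#' @param n length of the full sequence.
#' @param q_offset,t_offset 0-based offsets of the query and target
#'   sequences within the full sequence.
#' @return logical vector of length n.
#' @export
duplex_paired_vector <- function(dup, n, q_offset = 0L, t_offset = 0L) {
  v <- rep(FALSE, n)
  if (!isTRUE(dup$found)) return(v)
  halves <- strsplit(dup$structure, "&", fixed = TRUE)[[1]]
  qch <- strsplit(halves[1], "")[[1]]
  tch <- strsplit(halves[2], "")[[1]]
  qpos <- q_offset + dup$q_start + seq_along(qch)   # 1-based on full seq
  tpos <- t_offset + dup$t_start + seq_along(tch)
  v[qpos[qch != "."]] <- TRUE
  v[tpos[tch != "."]] <- TRUE
  v
}

#' Agreement between fold and duplex pairing over a span
#'
#' Fraction of positions in \code{span} whose paired/unpaired state agrees
#' between the full-fold structure and the duplex-derived pairing vector.
#' An empty span returns 1 by convention.
#'
#' @param fold_structure dot-bracket of the full fold.
#' @param dup_paired logical pairing vector (see
#'   \code{\link{duplex_paired_vector}}).
#' @param span 0-based half-open interval.
#' @return fraction in [0, 1].
#' @export
fold_duplex_agreement <- function(fold_structure, dup_paired, span) {
  if (span[2] <= span[1]) return(1)
  paired <- pair_table(fold_structure) > 0
  idx <- (span[1] + 1L):span[2]
  mean(paired[idx] == dup_paired[idx])
}
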