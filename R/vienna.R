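# Contract around the ViennaRNA command-line engine (RNAfold / RNAduplex).
# All folding is at the engine's default temperature (37 C) and parameters;
# the engine version is recorded once per session and attached to outputs.

.vienna <- new.env(parent = emptyenv())

vienna_path <- function(tool) {
  key <- paste0("path_", tool)
  if (is.null(.vienna[[key]])) {
    p <- Sys.which(tool)
    if (!nzchar(p)) {
      stop("ViennaRNA program '", tool, "' not found on PATH; ",
           "install ViennaRNA to use secondary-structure features",
           call. = FALSE)
    }
    .vienna[[key]] <- unname(p)
  }
  .vienna[[key]]
}

#' Version string of the folding engine
#' @return e.g. "RNAfold 2.7.2"
#' @export
vienna_version <- function() {
  if (is.null(.vienna$version)) {
    out <- suppressWarnings(system2(vienna_path("RNAfold"), "--version",
                                    stdout = TRUE, stderr = TRUE))
    .vienna$version <- out[1]
  }
  .vienna$version
}

normalize_rna <- function(seq) gsub("T", "U", toupper(seq))

#' Minimum-free-energy fold of RNA sequences
#'
#' Delegates to RNAfold. Vectorized: all sequences are folded in one engine
#' invocation. T is mapped to U on input.
#'
#' @param seqs character vector of nucleotide sequences (ACGU/T), each of
#'   length >= 10.
#' @return data frame with columns \code{seq} (RNA alphabet),
#'   \code{structure} (dot-bracket) and \code{mfe} (kcal/mol), one row per
#'   input sequence, in input order.
#' @export
rna_fold <- function(seqs) {
  if (length(seqs) == 0) {
    return(data.frame(seq = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  seqs <- normalize_rna(seqs)
  if (any(nchar(seqs) < 10)) stop("sequences must be >= 10 nt for folding")
  out <- system2(vienna_path("RNAfold"), c("--noPS"),
                 input = seqs, stdout = TRUE)
  # two output lines per sequence: sequence, then "structure ( mfe)"
  stopifnot(length(out) == 2 * length(seqs))
  sline <- out[seq(2, length(out), by = 2)]
  structure_str <- sub(" .*$", "", sline)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", sline))
  data.frame(seq = seqs, structure = structure_str, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Optimal inter-molecular RNA duplex
#'
#' Delegates to RNAduplex. Vectorized over query/target pairs; one engine
#' invocation per call. Spans are returned 0-based half-open on each
#' sequence. When the engine reports no favourable duplex (energy >= 0 or an
#' empty hit), \code{found} is FALSE and the spans are empty.
#'
#' @param query,target character vectors of equal length (or one recycled
#'   scalar) of nucleotide sequences.
#' @return data frame: \code{structure} (dot-bracket with '&'),
#'   \code{q_start}, \code{q_end}, \code{t_start}, \code{t_end},
#'   \code{energy} (kcal/mol), \code{found}.
#' @export
rna_duplex <- function(query, target) {
  n <- max(length(query), length(target))
  query <- rep_len(normalize_rna(query), n)
  target <- rep_len(normalize_rna(target), n)
  if (n == 0) {
    return(data.frame(structure = character(), q_start = integer(),
                      q_end = integer(), t_start = integer(),
                      t_end = integer(), energy = numeric(),
                      found = logical(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(query)) || any(!nzchar(target))) {
    stop("empty sequence passed to rna_duplex")
  }
  input <- as.vector(rbind(query, target))
  out <- system2(vienna_path("RNAduplex"), character(0),
                 input = input, stdout = TRUE, stderr = FALSE)
  out <- out[nzchar(out)]
  stopifnot(length(out) == n)
  parse1 <- function(line) {
    # "((((&))))   2,5   :   1,4   ( -5.40)"
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    st <- parts[1]
    q <- as.integer(strsplit(parts[2], ",")[[1]])
    t <- as.integer(strsplit(parts[4], ",")[[1]])
    en <- as.numeric(gsub("[()]", "", paste(parts[-(1:4)], collapse = "")))
    found <- is.finite(en) && en < 0 && t[2] >= t[1] && t[1] >= 1
    if (!found) {
      return(data.frame(structure = "", q_start = 0L, q_end = 0L,
                        t_start = 0L, t_end = 0L, energy = 0,
                        found = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(structure = st, q_start = q[1] - 1L, q_end = q[2],
               t_start = t[1] - 1L, t_end = t[2], energy = en,
               found = TRUE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(out, parse1))
  rownames(res) <- NULL
  res
}
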