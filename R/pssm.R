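#' Tally per-position base counts from aligned sites
#'
#' @param sites a [binding_sites()] collection (or plain character vector of
#'   equal-length ACGT strings).
#' @return A 4 x L integer matrix of class `"cpx_counts"` with rows
#'   `A,C,G,T` and one column per site position; attribute `n_sites` holds
#'   the collection size. Each column sums to `n_sites`.
#' @examples
#' count_matrix(binding_sites(c("AC", "AG")))
#' @export
count_matrix <- function(sites) {
  if (!inherits(sites, "cpx_sites")) sites <- binding_sites(sites)
  n <- length(sites)
  L <- attr(sites, "site_length")
  chars <- matrix(unlist(strsplit(unclass(sites), ""), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4L)
  }, integer(4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(counts, n_sites = n, class = c("cpx_counts", "matrix", "array"))
}

#' Turn base counts into position probabilities with a pseudocount
#'
#' Each probability is `(count + beta) / (n_sites + 4 * beta)`: the
#' pseudocount `beta` is allocated uniformly to the four bases of a column
#' (the default, matching a plain additive-smoothing reading), or weighted
#' by the background composition when `allocation = "background"`, in which
#' case `p = (count + 4 * beta * q_b) / (n_sites + 4 * beta)`.
#'
#' @param counts a `"cpx_counts"` matrix from [count_matrix()].
#' @param pseudocount non-negative smoothing constant, default 0.5.
#' @param allocation `"uniform"` (default) or `"background"`.
#' @param background base frequencies used only for `"background"`
#'   allocation; see [uniform_background()].
#' @return A 4 x L numeric probability matrix of class `"cpx_pwm"`; columns
#'   sum to 1. Attribute `pseudocount` records `beta`.
#' @export
build_pwm <- function(counts, pseudocount = 0.5,
                      allocation = c("uniform", "background"),
                      background = uniform_background()) {
  allocation <- match.arg(allocation)
  if (!inherits(counts, "cpx_counts")) stop("counts must come from count_matrix()")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  n <- attr(counts, "n_sites")
  beta <- pseudocount
  add <- if (allocation == "uniform") rep(beta, 4L) else 4 * beta * background
  p <- (unclass(counts) + add) / (n + 4 * beta)
  structure(p, pseudocount = beta, allocation = allocation,
            class = c("cpx_pwm", "matrix", "array"))
}

#' Uniform and sequence-composition background models
#'
#' A background model is a named numeric vector of four base frequencies
#' (`A,C,G,T`) summing to 1. `uniform_background()` gives 0.25 each;
#' `genome_background()` estimates the composition of a supplied sequence
#' (non-ACGT letters ignored), averaging both strands so that the
#' background is strand-symmetric.
#'
#' @param genome a character string, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Named numeric vector of length 4.
#' @export
uniform_background <- function() {
  stats::setNames(rep(0.25, 4L), DNA_BASES)
}

#' @rdname uniform_background
#' @export
genome_background <- function(genome) {
  seqs <- as_dna_strings(genome)
  counts <- colSums(Biostrings::letterFrequency(seqs, DNA_BASES))
  # strand symmetry: average complementary bases
  counts <- (counts + counts[c("T", "G", "C", "A")]) / 2
  q <- counts / sum(counts)
  stats::setNames(as.numeric(q), DNA_BASES)
}

check_background <- function(q) {
  if (length(q) != 4L || any(q <= 0) || abs(sum(q) - 1) > 1e-9) {
    stop("background must be 4 positive frequencies summing to 1")
  }
  if (is.null(names(q))) names(q) <- DNA_BASES
  q[DNA_BASES]
}

#' Build a log-odds scoring matrix (PSSM) from a probability matrix
#'
#' Scores are in bits: `s(i, b) = log2(p(i, b) / q(b))`. A window's score is
#' the sum of the per-position scores of its bases, so the consensus string
#' attains the matrix's maximum achievable score.
#'
#' @param pwm a `"cpx_pwm"` probability matrix from [build_pwm()].
#' @param background base frequencies `q`; default uniform.
#' @return A 4 x L numeric matrix of class `"cpx_pssm"` with the background
#'   stored in attribute `background`.
#' @export
build_pssm <- function(pwm, background = uniform_background()) {
  if (!inherits(pwm, "cpx_pwm")) stop("pwm must come from build_pwm()")
  q <- check_background(background)
  if (any(unclass(pwm) <= 0)) {
    stop("probability matrix contains zero entries; ",
         "rebuild the PWM with a pseudocount > 0 before taking log-odds")
  }
  s <- log2(unclass(pwm) / q)
  structure(s, background = q, class = c("cpx_pssm", "matrix", "array"))
}

#' @export
print.cpx_pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d positions, bits; max score %.4f; consensus %s\n",
              ncol(x), max_score(x), consensus_from_scores(x)))
  print(round(unclass(x), 4L))
  invisible(x)
}

#' Maximum achievable score of a scoring matrix
#'
#' @param pssm a `"cpx_pssm"` matrix.
#' @return Sum of per-position column maxima, in bits.
#' @export
max_score <- function(pssm) {
  sum(apply(unclass(pssm), 2L, max))
}

consensus_from_scores <- function(m) {
  paste(DNA_BASES[apply(unclass(m), 2L, which.max)], collapse = "")
}

#' Consensus sequence of a probability matrix
#'
#' Per-column argmax base; ties resolved by the fixed base order
#' `A < C < G < T` (so `which.max` semantics).
#'
#' @param pwm a `"cpx_pwm"` (or `"cpx_pssm"`) matrix.
#' @return A single DNA string.
#' @export
consensus_sequence <- function(pwm) {
  consensus_from_scores(pwm)
}

#' Score one fixed-length window against a PSSM
#'
#' @param pssm a `"cpx_pssm"` matrix with L columns.
#' @param window a DNA string of length L over `A,C,G,T`. Windows containing
#'   `N` or other ambiguity codes are not scoreable and raise an error;
#'   genome-level scanning skips them instead (see [scan_genome()]).
#' @return The window score in bits: the sum of the L looked-up cells.
#' @export
score_window <- function(pssm, window) {
  if (!inherits(pssm, "cpx_pssm")) stop("pssm must come from build_pssm()")
  L <- ncol(pssm)
  window <- toupper(window)
  if (length(window) != 1L || nchar(window) != L) {
    stop(sprintf("window must be one string of length %d", L))
  }
  idx <- match(strsplit(window, "")[[1L]], DNA_BASES)
  if (anyNA(idx)) stop("window contains a non-ACGT character")
  sum(unclass(pssm)[cbind(idx, seq_len(L))])
}

#' Reverse-complement a scoring or probability matrix
#'
#' `m'[i, b] = m[L + 1 - i, complement(b)]`; scoring a window with the
#' reverse-complemented matrix equals scoring the window's reverse
#' complement with the original matrix.
#'
#' @param m a `"cpx_pssm"` or `"cpx_pwm"` matrix.
#' @return A matrix of the same class.
#' @export
reverse_complement_matrix <- function(m) {
  out <- unclass(m)[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  for (a in setdiff(names(attributes(m)), c("dim", "dimnames"))) {
    attr(out, a) <- attr(m, a)
  }
  out
}

#' Export / import a matrix as TSV with a JSON sidecar
#'
#' The TSV has a header row `pos A C G T` and one row per position;
#' `kind` says whether the values are probabilities or bits. The JSON
#' sidecar (`<path>.json`) records the pseudocount, background and
#' alphabet so a scoring matrix round-trips losslessly.
#'
#' @param m a `"cpx_pwm"` or `"cpx_pssm"` matrix.
#' @param path output TSV path.
#' @return `path`, invisibly (`write_matrix`); the reconstructed matrix
#'   (`read_matrix`).
#' @export
write_matrix <- function(m, path) {
  kind <- if (inherits(m, "cpx_pssm")) "bits" else "probability"
  df <- data.frame(pos = seq_len(ncol(m)), t(unclass(m)))
  colnames(df) <- c("pos", DNA_BASES)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(kind = kind, alphabet = DNA_BASES,
               pseudocount = attr(m, "pseudocount"),
               background = as.list(attr(m, "background")))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, DNA_BASES]))
  dimnames(m) <- list(DNA_BASES, NULL)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (identical(meta$kind, "bits")) {
    structure(m, background = unlist(meta$background),
              class = c("cpx_pssm", "matrix", "array"))
  } else {
    structure(m, pseudocount = meta$pseudocount,
              class = c("cpx_pwm", "matrix", "array"))
  }
}

#' One-call matrix build: sites to PSSM
#'
#' Convenience wrapper chaining [count_matrix()], [build_pwm()] and
#' [build_pssm()].
#'
#' @inheritParams count_matrix
#' @inheritParams build_pwm
#' @inheritParams build_pssm
#' @return A `"cpx_pssm"` matrix.
#' @export
sites_to_pssm <- function(sites, pseudocount = 0.5,
                          background = uniform_background(),
                          allocation = c("uniform", "background")) {
  allocation <- match.arg(allocation)
  build_pssm(build_pwm(count_matrix(sites), pseudocount = pseudocount,
                       allocation = allocation, background = background),
             background = background)
}
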