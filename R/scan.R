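#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# Normalise a genome argument (FASTA path, character sequence(s),
# DNAString or DNAStringSet) to a named DNAStringSet.
as_dna_strings <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    ss <- genome
  } else if (is(genome, "DNAString")) {
    ss <- Biostrings::DNAStringSet(genome)
  } else if (is.character(genome)) {
    if (length(genome) == 1L && file.exists(genome) &&
        !grepl("^[ACGTNacgtn]+$", genome)) {
      ss <- Biostrings::readDNAStringSet(genome)
    } else {
      ss <- Biostrings::DNAStringSet(toupper(genome))
    }
  } else {
    stop("unsupported genome input of class ", class(genome)[[1L]])
  }
  if (is.null(names(ss))) names(ss) <- paste0("contig", seq_along(ss))
  names(ss) <- sub("\\s.*$", "", names(ss))
  ss
}

# Integer codes 1..4 for A,C,G,T; NA for anything else (N etc.).
dna_codes <- function(seq_chr) {
  match(utf8ToInt(seq_chr), c(65L, 67L, 71L, 84L))
}

# Sliding-window scores of one coded sequence against a matrix; NA where the
# window covers any non-ACGT base.
slide_scores <- function(pssm, codes) {
  k <- ncol(pssm)
  n <- length(codes) - k + 1L
  if (n < 1L) stop("sequence shorter than the matrix length")
  m <- unclass(pssm)
  sc <- numeric(n)
  for (i in seq_len(k)) {
    sc <- sc + m[cbind(codes[i:(i + n - 1L)], i)]
  }
  sc
}

#' Enumerate the scores of every fixed-length genome window
#'
#' Scores all windows of `ncol(pssm)` bases on the requested strands.
#' Minus-strand windows are scored as their reverse complement
#' (equivalently, against the reverse-complemented matrix) and reported at
#' the forward-strand coordinate of the window. Windows containing any
#' non-ACGT base are skipped and counted.
#'
#' @param pssm a `"cpx_pssm"` scoring matrix.
#' @param genome FASTA path, character sequence(s), or
#'   [Biostrings::DNAStringSet].
#' @param strands subset of `c("+", "-")`.
#' @param circular scan across the origin of each contig (windows wrap).
#' @return A list: `windows` — data.frame with columns `contig`, `start0`
#'   (0-based forward-strand start), `strand`, `score`; `n_windows` — number
#'   of scoreable windows enumerated; `n_skipped` — windows skipped for
#'   ambiguity codes.
#' @export
window_scores <- function(pssm, genome, strands = c("+", "-"),
                          circular = FALSE) {
  if (!inherits(pssm, "cpx_pssm")) stop("pssm must come from build_pssm()")
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  ss <- as_dna_strings(genome)
  k <- ncol(pssm)
  rc <- reverse_complement_matrix(pssm)
  out <- vector("list", length(ss) * length(strands))
  n_skipped <- 0L
  ii <- 0L
  for (ci in seq_along(ss)) {
    seq_chr <- as.character(ss[[ci]])
    L <- nchar(seq_chr)
    if (circular) seq_chr <- paste0(seq_chr, substr(seq_chr, 1L, k - 1L))
    codes <- dna_codes(seq_chr)
    n_pos <- if (circular) L else L - k + 1L
    for (st in strands) {
      m <- if (st == "+") pssm else rc
      sc <- slide_scores(m, codes)[seq_len(n_pos)]
      keep <- !is.na(sc)
      n_skipped <- n_skipped + sum(!keep)
      ii <- ii + 1L
      out[[ii]] <- data.frame(contig = names(ss)[[ci]],
                              start0 = which(keep) - 1L,
                              strand = st,
                              score = sc[keep])
    }
  }
  windows <- do.call(rbind, out[seq_len(ii)])
  rownames(windows) <- NULL
  list(windows = windows, n_windows = nrow(windows), n_skipped = n_skipped)
}

#' Calibrate the adaptive score threshold
#'
#' The cutoff is the mean of the score population minus its standard
#' deviation. The SD uses the population divisor `n` (not `n - 1`): the
#' window population is fully enumerated, not sampled.
#'
#' @param scores numeric vector of at least 2 scores (NA not allowed).
#' @return A list with `mu`, `sigma` and `threshold = mu - sigma`, in bits.
#' @examples
#' calibrate_threshold(c(0, 2))  # mu 1, sigma 1, threshold 0
#' @export
calibrate_threshold <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L || anyNA(scores)) {
    stop("threshold calibration needs at least 2 finite scores")
  }
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  list(mu = mu, sigma = sigma, threshold = mu - sigma)
}

#' Filter scored windows into putative binding-site hits
#'
#' Retains exactly the windows whose score is strictly greater than the
#' threshold, sorted by (contig, start, strand), and attaches the site
#' sequence as read 5'->3' on its strand.
#'
#' @param windows the `windows` data.frame from [window_scores()].
#' @param threshold score cutoff in bits (strict `>`).
#' @param genome the scanned genome (needed to extract hit sequences).
#' @param motif_length window length in bp.
#' @return A [GenomicRanges::GRanges] of hits (1-based starts, as usual for
#'   `GRanges`) with metadata columns `score`, `site_length` and `sequence`.
#' @export
filter_hits <- function(windows, threshold, genome, motif_length) {
  ss <- as_dna_strings(genome)
  keep <- windows$score > threshold
  w <- windows[keep, , drop = FALSE]
  w <- w[order(w$contig, w$start0, w$strand), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(w)) w$contig else character(),
    ranges = IRanges::IRanges(start = w$start0 + 1L,
                              width = rep(motif_length, nrow(w))),
    strand = if (nrow(w)) w$strand else character()
  )
  seqs <- character(nrow(w))
  if (nrow(w)) {
    L <- stats::setNames(Biostrings::width(ss), names(ss))
    for (ct in unique(w$contig)) {
      sel <- w$contig == ct
      sub <- Biostrings::DNAStringSet(ss[[ct]],
                                      start = w$start0[sel] + 1L,
                                      width = motif_length)
      fw <- as.character(sub)
      mn <- w$strand[sel] == "-"
      fw[mn] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fw[mn])))
      seqs[sel] <- fw
    }
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score = w$score, site_length = rep(motif_length, nrow(w)),
    sequence = seqs)
  gr
}

#' Scan a genome with one scoring matrix and an adaptive threshold
#'
#' Runs [window_scores()], calibrates the cutoff with
#' [calibrate_threshold()] over the chosen score population, and keeps the
#' windows above it with [filter_hits()].
#'
#' @inheritParams window_scores
#' @param threshold_population `"genome"` (default) calibrates over all
#'   scoreable windows of the scan; `"training"` calibrates over the scores
#'   of the supplied training sites themselves (`training_sites`);
#'   `"manual"` uses `threshold` as given.
#' @param training_sites a [binding_sites()] collection, required for
#'   `threshold_population = "training"`.
#' @param threshold manual cutoff in bits for
#'   `threshold_population = "manual"`.
#' @return An object of class `"cpx_scan"`: list with `hits` (`GRanges`),
#'   `mu`, `sigma`, `threshold`, `n_windows`, `n_skipped`, `motif_length`,
#'   `strands`, `threshold_population`.
#' @export
scan_genome <- function(pssm, genome, strands = c("+", "-"),
                        circular = FALSE,
                        threshold_population = c("genome", "training",
                                                 "manual"),
                        training_sites = NULL, threshold = NULL) {
  threshold_population <- match.arg(threshold_population)
  ss <- as_dna_strings(genome)
  ws <- window_scores(pssm, ss, strands = strands, circular = circular)
  if (threshold_population == "genome") {
    cal <- calibrate_threshold(ws$windows$score)
  } else if (threshold_population == "training") {
    if (is.null(training_sites)) {
      stop("training-population calibration needs training_sites")
    }
    cal <- calibrate_threshold(
      vapply(as.character(training_sites), function(s) score_window(pssm, s),
             numeric(1L)))
  } else {
    if (!is.numeric(threshold)) stop("manual calibration needs a threshold")
    cal <- list(mu = NA_real_, sigma = NA_real_, threshold = threshold)
  }
  hits <- filter_hits(ws$windows, cal$threshold, ss, ncol(pssm))
  structure(list(hits = hits, mu = cal$mu, sigma = cal$sigma,
                 threshold = cal$threshold, n_windows = ws$n_windows,
                 n_skipped = ws$n_skipped, motif_length = ncol(pssm),
                 strands = strands,
                 threshold_population = threshold_population),
            class = "cpx_scan")
}

#' @export
print.cpx_scan <- function(x, ...) {
  cat(sprintf(
    "Genome scan (%d-bp matrix, strands %s):\n  %d windows scored (%d skipped), mu = %.4f, sigma = %.4f, threshold = %.4f\n  %d hits above threshold\n",
    x$motif_length, paste(x$strands, collapse = ""), x$n_windows,
    x$n_skipped, x$mu, x$sigma, x$threshold, length(x$hits)))
  invisible(x)
}

#' Paired 15-bp / 16-bp screen
#'
#' Runs the scan independently for the 15-bp matrix and the
#' spacer-expanded 16-bp matrix, each calibrated against its own score
#' population; hit lists are kept separate (overlapping 15/16-bp hits at a
#' locus are both reported).
#'
#' @param pssm15,pssm16 the two scoring matrices.
#' @inheritParams scan_genome
#' @param training_sites15,training_sites16 site collections for
#'   `threshold_population = "training"`.
#' @return A list with elements `len15` and `len16`, each a `"cpx_scan"`.
#' @export
scan_pair <- function(pssm15, pssm16, genome, strands = c("+", "-"),
                      circular = FALSE,
                      threshold_population = c("genome", "training",
                                               "manual"),
                      training_sites15 = NULL, training_sites16 = NULL,
                      threshold = NULL) {
  threshold_population <- match.arg(threshold_population)
  ss <- as_dna_strings(genome)
  list(
    len15 = scan_genome(pssm15, ss, strands = strands, circular = circular,
                        threshold_population = threshold_population,
                        training_sites = training_sites15,
                        threshold = threshold),
    len16 = scan_genome(pssm16, ss, strands = strands, circular = circular,
                        threshold_population = threshold_population,
                        training_sites = training_sites16,
                        threshold = threshold)
  )
}
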