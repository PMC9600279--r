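# Shared fixtures and independent oracles for the suite.

toy_sites <- function() {
  binding_sites(c("GTAAACTGACGTAAA",
                  "GTAAACCGCCGTAAA",
                  "GTATATTGACGTAAA",
                  "CTAAACTGACGTATA"))
}

random_genome <- function(n, seed, freqs = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Naive substring-extraction scanner: extracts every window, scores it by
# direct cell lookup (not via the streaming scanner), skips ambiguous ones.
oracle_window_scores <- function(pssm, seq_chr, strands = c("+", "-")) {
  k <- ncol(pssm)
  L <- nchar(seq_chr)
  m <- unclass(pssm)
  cell_sum <- function(w) {
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(m[cbind(idx, seq_len(k))])
  }
  out <- list()
  for (p in seq_len(L - k + 1)) {
    w <- substr(seq_chr, p, p + k - 1)
    for (st in strands) {
      sc <- cell_sum(if (st == "+") w else rc_chr(w))
      if (!is.na(sc)) {
        out[[length(out) + 1]] <- data.frame(start0 = p - 1, strand = st,
                                             score = sc)
      }
    }
  }
  do.call(rbind, out)
}

# Canonical multiset key for comparing scanner outputs.
score_key <- function(df) {
  sort(sprintf("%d:%s:%.9f", df$start0, df$strand, df$score))
}

truth_hits <- function(planted, scores = NULL) {
  tr <- planted$truth
  if (is.null(scores)) scores <- rev(seq_len(nrow(tr))) + 10
  GenomicRanges::GRanges(
    seqnames = tr$contig,
    ranges = IRanges::IRanges(start = tr$start0 + 1L, end = tr$end0),
    strand = tr$strand,
    score = scores, site_length = tr$length,
    sequence = rep("N/A", nrow(tr)))
}

planted_windows <- function(planted, ...) {
  promoter_windows(planted$genes,
                   contig_lengths = stats::setNames(
                     Biostrings::width(planted$genome),
                     names(planted$genome)), ...)
}
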