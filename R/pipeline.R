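#' Pipeline configuration
#'
#' Collects every tunable of the screen with its default: pseudocount 0.5,
#' uniform background, log base 2 scoring, both strands, genome-population
#' mean-minus-SD threshold, promoter window 700 bp upstream / 100 bp
#' downstream, cluster gap 50 bp, 2-fold regulation rule, and the
#' high-score review cutoff of 17.68 bits (every box scoring above it was
#' associated with a regulated gene).
#'
#' @param sites,genome,genes,folds input paths (or in-memory objects for
#'   all but `folds`): aligned 15-bp sites, genome FASTA, gene models
#'   (GFF3 or [gene_table()]), optional wide fold-change TSV.
#' @param pseudocount,allocation,background matrix-build settings; see
#'   [build_pwm()]. `background` is `"uniform"` or `"genome"`.
#' @param strands,circular,threshold_population,threshold scan settings;
#'   see [scan_genome()].
#' @param upstream,downstream,max_gap annotation settings.
#' @param fold_threshold regulation cutoff (default 2).
#' @param fold_groups named list of fold-table column groups (see
#'   [read_fold_table()]); only used when `folds` is given.
#' @param high_score hits scoring above this are flagged for priority
#'   review.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param seed integer seed echoed into outputs.
#' @return A list of class `"cpx_config"`.
#' @export
run_config <- function(sites = NULL, genome = NULL, genes = NULL,
                       folds = NULL,
                       pseudocount = 0.5,
                       allocation = "uniform",
                       background = "uniform",
                       strands = c("+", "-"),
                       circular = FALSE,
                       threshold_population = "genome",
                       threshold = NULL,
                       upstream = 700L, downstream = 100L,
                       max_gap = 50L,
                       fold_threshold = 2,
                       fold_groups = NULL,
                       high_score = 17.68,
                       outdir = NULL, seed = 1L) {
  cfg <- list(sites = sites, genome = genome, genes = genes, folds = folds,
              pseudocount = pseudocount, allocation = allocation,
              background = background, strands = strands,
              circular = circular,
              threshold_population = threshold_population,
              threshold = threshold,
              upstream = as.integer(upstream),
              downstream = as.integer(downstream),
              max_gap = as.integer(max_gap),
              fold_threshold = fold_threshold, fold_groups = fold_groups,
              high_score = high_score, outdir = outdir,
              seed = as.integer(seed))
  stopifnot(cfg$pseudocount >= 0, all(cfg$strands %in% c("+", "-")),
            cfg$fold_threshold > 1)
  class(cfg) <- "cpx_config"
  cfg
}

#' Serialize / parse a configuration
#'
#' Configurations round-trip through JSON: `write_config()` then
#' `read_config()` then `write_config()` is byte-identical.
#'
#' @param config a [run_config()] list.
#' @param path file path (`.json`).
#' @return `path` invisibly; `read_config()` returns the config.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1L))])
}

# --- track writers -----------------------------------------------------

write_bed6 <- function(df, path) {
  df <- df[order(df$contig, df$start0, df$strand), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED score column: bits scaled by 50 and clamped into the 0-1000 integer
# range the format allows (lossless scores live in the TSV next to it).
bed_score <- function(bits) {
  as.integer(round(pmax(0, pmin(1000, bits * 50))))
}

hits_to_df <- function(hits) {
  data.frame(contig = as.character(GenomicRanges::seqnames(hits)),
             start0 = GenomicRanges::start(hits) - 1L,
             end0 = GenomicRanges::end(hits),
             strand = as.character(GenomicRanges::strand(hits)),
             length = hits$site_length,
             score_bits = hits$score,
             sequence = hits$sequence)
}

#' Write scan hits as BED6 and lossless TSV
#'
#' The BED name field carries the matrix-length tag (`len15`/`len16`); the
#' BED score is the bit score scaled by 50 and clamped to 0-1000. The TSV
#' keeps full precision (columns `contig`, `start0`, `end0`, `strand`,
#' `length`, `score_bits`, `sequence`; coordinates 0-based half-open).
#'
#' @param hits a `GRanges` of hits.
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @param tag name tag for the BED name column.
#' @return Paths invisibly.
#' @export
write_hits <- function(hits, prefix, tag = "hit") {
  df <- hits_to_df(hits)
  bed <- data.frame(contig = df$contig, start0 = df$start0, end0 = df$end0,
                    name = rep(tag, nrow(df)),
                    score = bed_score(df$score_bits), strand = df$strand)
  write_bed6(bed, paste0(prefix, ".bed"))
  tsv <- df[order(df$contig, df$start0, df$strand), , drop = FALSE]
  utils::write.table(tsv, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = paste0(prefix, ".bed"), tsv = paste0(prefix, ".tsv")))
}

#' Re-import hit intervals from a BED6 file
#'
#' @param path BED6 path.
#' @return A `GRanges` with the BED name in `name` and the (scaled) score
#'   in `score`.
#' @export
read_bed_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("contig", "start0", "end0", "name",
                                        "score", "strand"))
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = df$strand, name = df$name, score = df$score)
}

#' Export the track bundle of a finished screen
#'
#' One BED per matrix length, one BED of candidate best boxes (name
#' `gene|group`), and a candidates TSV (1-based inclusive coordinates,
#' stated in the header).
#'
#' @param scans a [scan_pair()] result.
#' @param candidates a [classify_candidates()] data.frame.
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
export_tracks <- function(scans, candidates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p15 <- write_hits(scans$len15$hits, file.path(dir, "hits_len15"), "len15")
  p16 <- write_hits(scans$len16$hits, file.path(dir, "hits_len16"), "len16")
  cb <- file.path(dir, "candidate_boxes.bed")
  bed <- data.frame(contig = candidates$contig,
                    start0 = candidates$best_start0,
                    end0 = candidates$best_end0,
                    name = paste0(candidates$gene_id, "|",
                                  candidates$group),
                    score = bed_score(candidates$best_score),
                    strand = candidates$best_strand)
  write_bed6(bed, cb)
  tsv <- file.path(dir, "candidates.tsv")
  hdr <- "# coordinates 1-based inclusive"
  writeLines(hdr, tsv)
  out <- candidates
  out$best_start1 <- out$best_start0 + 1L
  out$best_end1 <- out$best_end0
  out$best_start0 <- out$best_end0 <- NULL
  suppressWarnings(utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(c(p15, p16, boxes = cb, candidates = tsv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end screen
#'
#' Executes matrix build (15 bp and spacer-expanded 16 bp), the paired
#' genome scan with adaptive thresholding, promoter-window construction,
#' hit assignment, location-group classification and, when a fold-change
#' table is configured, regulation calling. When `config$outdir` is set,
#' writes the track bundle, a matrices export, and a JSON run summary.
#'
#' @param config a [run_config()].
#' @return A list of class `"cpx_run"`: `config`, `pssm15`, `pssm16`,
#'   `scans`, `windows`, `candidates`, `calls` (or `NULL`), `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cpx_config"))
  sites <- if (inherits(config$sites, "cpx_sites")) config$sites else
    read_binding_sites(config$sites)
  if (attr(sites, "site_length") != 15L) {
    stop("stage build-matrix: training sites must be 15 bp ",
         "(the 16-bp set is derived by spacer expansion)")
  }
  genome <- as_dna_strings(config$genome)
  genes <- if (is.data.frame(config$genes)) config$genes else
    read_genes(config$genes)
  bg <- if (identical(config$background, "genome")) {
    genome_background(genome)
  } else {
    uniform_background()
  }
  sites16 <- expand_spacer(sites)
  pssm15 <- sites_to_pssm(sites, pseudocount = config$pseudocount,
                          background = bg, allocation = config$allocation)
  pssm16 <- sites_to_pssm(sites16, pseudocount = config$pseudocount,
                          background = bg, allocation = config$allocation)
  scans <- scan_pair(pssm15, pssm16, genome, strands = config$strands,
                     circular = config$circular,
                     threshold_population = config$threshold_population,
                     training_sites15 = sites, training_sites16 = sites16,
                     threshold = config$threshold)
  contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  windows <- promoter_windows(genes, upstream = config$upstream,
                              downstream = config$downstream,
                              contig_lengths = contig_lengths)
  all_hits <- c(scans$len15$hits, scans$len16$hits)
  candidates <- classify_candidates(all_hits, windows, genes,
                                    max_gap = config$max_gap)
  calls <- NULL
  if (!is.null(config$folds)) {
    folds <- read_fold_table(config$folds, config$fold_groups)
    calls <- regulation_calls(folds, threshold = config$fold_threshold)
  }
  group_counts <- table(factor(candidates$group,
                               levels = c("A", "B", "C", "D")))
  summary <- list(
    n_sites = length(sites),
    len15 = scan_stats(scans$len15),
    len16 = scan_stats(scans$len16),
    n_candidates = nrow(candidates),
    candidates_per_group = as.list(group_counts),
    n_high_score = sum(all_hits$score > config$high_score),
    n_regulated_per_group = if (is.null(calls)) NULL else
      count_calls(calls),
    version = as.character(utils::packageVersion("cpxscreen")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  run <- structure(list(config = config, pssm15 = pssm15, pssm16 = pssm16,
                        scans = scans, windows = windows,
                        candidates = candidates, calls = calls,
                        summary = summary),
                   class = "cpx_run")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    export_tracks(scans, run$candidates, config$outdir)
    write_matrix(pssm15, file.path(config$outdir, "pssm15.tsv"))
    write_matrix(pssm16, file.path(config$outdir, "pssm16.tsv"))
    jsonlite::write_json(summary[names(summary) != "timestamp"],
                         file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (!is.null(calls)) {
      utils::write.table(calls, file.path(config$outdir, "calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  run
}

scan_stats <- function(scan) {
  list(n_windows = scan$n_windows, n_skipped = scan$n_skipped,
       mu = scan$mu, sigma = scan$sigma, threshold = scan$threshold,
       n_hits = length(scan$hits))
}

count_calls <- function(calls) {
  vcols <- grep("_verdict$", names(calls), value = TRUE)
  res <- lapply(vcols, function(cc) sum(calls[[cc]] != "insignificant"))
  names(res) <- sub("_verdict$", "", vcols)
  res$union <- sum(calls$regulated)
  res
}

#' @export
print.cpx_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("CpxR screen: %d training sites\n",
           "  15-bp scan: %d hits (threshold %.4f)\n",
           "  16-bp scan: %d hits (threshold %.4f)\n",
           "  %d candidate genes (A:%d B:%d C:%d D:%d), %d high-score hits\n"),
    s$n_sites, s$len15$n_hits, s$len15$threshold, s$len16$n_hits,
    s$len16$threshold, s$n_candidates,
    s$candidates_per_group$A, s$candidates_per_group$B,
    s$candidates_per_group$C, s$candidates_per_group$D, s$n_high_score))
  if (!is.null(s$n_regulated_per_group)) {
    cat("  regulated genes:",
        paste(names(s$n_regulated_per_group),
              unlist(s$n_regulated_per_group), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
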