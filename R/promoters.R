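#' Gene model table
#'
#' Genes are held in a plain data.frame with columns `gene_id`, `contig`,
#' `strand` (`+`/`-`) and the CDS interval `start0`/`end0` in 0-based
#' half-open forward-strand coordinates. The start codon's first base is
#' `start0` for a `+` gene and `end0 - 1` for a `-` gene.
#'
#' @param gene_id,contig,strand,start0,end0 vectors of equal length.
#' @return A validated gene data.frame.
#' @export
gene_table <- function(gene_id, contig, strand, start0, end0) {
  df <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   strand = as.character(strand),
                   start0 = as.integer(start0),
                   end0 = as.integer(end0))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$end0 <= df$start0) || any(df$start0 < 0L)) {
    stop("need 0 <= start0 < end0")
  }
  df
}

#' Read gene models from a GFF3 file
#'
#' Imports features with [rtracklayer::import()] and keeps `gene` records
#' (falling back to `CDS` when no `gene` features are present). The gene
#' identifier is taken from the first available of the `locus_tag`, `ID` or
#' `Name` attributes.
#'
#' @param path GFF3 file path.
#' @return A [gene_table()] data.frame.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  types <- as.character(gr$type)
  keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  id <- NULL
  for (col in c("locus_tag", "ID", "Name")) {
    if (col %in% colnames(mc) && !all(is.na(mc[[col]]))) {
      id <- as.character(mc[[col]])
      break
    }
  }
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  gene_table(gene_id = id,
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}

#' Build strand-aware promoter windows around start codons
#'
#' The screened region for each gene runs `upstream` bp upstream of the
#' start codon through `downstream` bp downstream of it (the start-codon
#' base counts as the first downstream base), oriented by gene strand. On
#' forward-strand coordinates (0-based half-open) a `+` gene with start
#' codon at `S` gets `[S - upstream, S + downstream)`; a `-` gene with
#' start codon at `S` gets the mirror image
#' `[S - downstream + 1, S + upstream + 1)`. Windows are clipped to the
#' contig and flagged when clipping shortened them.
#'
#' @param genes a [gene_table()] data.frame.
#' @param upstream,downstream non-negative extents in bp (defaults 700 and
#'   100).
#' @param contig_lengths optional named vector of contig lengths used to
#'   clip at the right edge.
#' @return A [GenomicRanges::GRanges] (1-based, as usual) with metadata
#'   columns `gene_id` and `clipped`.
#' @export
promoter_windows <- function(genes, upstream = 700L, downstream = 100L,
                             contig_lengths = NULL) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  plus <- genes$strand == "+"
  S <- ifelse(plus, genes$start0, genes$end0 - 1L)
  a <- ifelse(plus, S - upstream, S - downstream + 1L)
  b <- ifelse(plus, S + downstream, S + upstream + 1L)
  if (!is.null(contig_lengths)) {
    if (any(S < 0L) || any(S >= contig_lengths[genes$contig])) {
      stop("start codon outside contig")
    }
  }
  a_cl <- pmax(a, 0L)
  b_cl <- if (is.null(contig_lengths)) b else
    pmin(b, unname(contig_lengths[genes$contig]))
  if (any(b_cl <= a_cl)) stop("empty promoter window after clipping")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = a_cl + 1L, end = b_cl),
    strand = genes$strand,
    gene_id = genes$gene_id,
    clipped = (a_cl != a) | (b_cl != b))
  gr
}

#' Assign scan hits to promoter windows by full containment
#'
#' A hit is assigned to a gene when the hit interval lies fully inside the
#' gene's promoter window (partial overlaps are excluded so box counts are
#' unambiguous). Strand is ignored: a box on either strand can serve a
#' gene. One hit may be assigned to several genes — shared intergenic boxes
#' between divergent genes are the basis of the group-C layout.
#'
#' @param hits a `GRanges` of scan hits (e.g. from [scan_genome()]).
#' @param windows promoter windows from [promoter_windows()].
#' @return A data.frame with columns `gene_id` and `hit` (index into
#'   `hits`).
#' @export
assign_hits <- function(hits, windows) {
  ov <- GenomicRanges::findOverlaps(hits, windows, type = "within",
                                    ignore.strand = TRUE)
  data.frame(gene_id = windows$gene_id[S4Vectors::subjectHits(ov)],
             hit = S4Vectors::queryHits(ov))
}

#' Group genes into same-strand adjacency clusters
#'
#' An operon-style heuristic: maximal runs of consecutive genes on the same
#' contig and strand whose intergenic gaps are at most `max_gap` bp.
#' Singleton genes form one-gene clusters.
#'
#' @param genes a [gene_table()] data.frame.
#' @param max_gap maximum intergenic gap in bp (default 50).
#' @return `genes` with an added integer `cluster` column; cluster ids are
#'   assigned in genomic order.
#' @export
gene_clusters <- function(genes, max_gap = 50L) {
  ord <- order(genes$contig, genes$start0)
  g <- genes[ord, , drop = FALSE]
  n <- nrow(g)
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    new_run <- i == 1L ||
      g$contig[i] != g$contig[i - 1L] ||
      g$strand[i] != g$strand[i - 1L] ||
      (g$start0[i] - g$end0[i - 1L]) > max_gap
    if (new_run) cur <- cur + 1L
    cl[i] <- cur
  }
  g$cluster <- cl
  res <- genes
  res$cluster <- cl[match(genes$gene_id, g$gene_id)]
  res
}

# Collapse a set of hit intervals into distinct boxes: overlapping hits
# (e.g. nested 15/16-bp calls at one locus) count as one box, represented
# by the highest-scoring member (ties: leftmost, then longest).
collapse_boxes <- function(hits, idx) {
  sub <- hits[idx]
  red <- GenomicRanges::reduce(sub, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(sub, red, ignore.strand = TRUE)
  rep_idx <- integer(length(red))
  for (j in seq_along(red)) {
    members <- idx[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
    sc <- hits$score[members]
    st <- GenomicRanges::start(hits)[members]
    best <- members[order(-sc, st)][1L]
    rep_idx[j] <- best
  }
  rep_idx
}

#' Rank a gene's boxes by score
#'
#' Stable sort by score descending with ties broken by genomic coordinate
#' ascending; the first element is the gene's best box.
#'
#' @param hits a `GRanges` of boxes (with a `score` metadata column).
#' @return The same `GRanges`, reordered.
#' @export
rank_boxes <- function(hits) {
  hits[order(-hits$score, GenomicRanges::start(hits))]
}

#' Classify candidate genes into the four box-location groups
#'
#' Every gene with at least one assigned box receives exactly one group,
#' decided in priority order A > B > C > D:
#' \describe{
#'   \item{A}{the gene belongs to a multi-gene cluster and the distinct
#'     boxes assigned across the cluster's genes number at least 2
#'     (multiple boxes within a gene cluster);}
#'   \item{B}{the gene's own window holds at least 2 distinct boxes;}
#'   \item{C}{the gene's single box sits in the intergenic span shared with
#'     a divergently transcribed neighbour and inside both promoter
#'     windows;}
#'   \item{D}{otherwise (a single box in a single gene's window).}
#' }
#' Distinct boxes are non-overlapping intervals: overlapping 15- and 16-bp
#' hits at one locus collapse to one box, keeping the highest-scoring hit.
#'
#' @param hits `GRanges` of scan hits.
#' @param windows promoter windows from [promoter_windows()].
#' @param genes a [gene_table()] data.frame.
#' @param max_gap intergenic gap for [gene_clusters()].
#' @param assignments optionally precomputed [assign_hits()] output.
#' @return A data.frame with one row per candidate gene: `gene_id`,
#'   `group`, `n_boxes`, `contig`, best-box coordinates (`best_start0`,
#'   `best_end0`, 0-based half-open), `best_strand`, `best_score`,
#'   `best_sequence` and
#'   `shared_with` (partner gene for group C, else `NA`). The full ranked
#'   box list per gene is attached as attribute `boxes` (a named list of
#'   hit indices).
#' @export
classify_candidates <- function(hits, windows, genes, max_gap = 50L,
                                assignments = assign_hits(hits, windows)) {
  genes_cl <- gene_clusters(genes, max_gap = max_gap)
  cand <- unique(assignments$gene_id)
  cand <- cand[order(match(cand, genes$gene_id))]
  if (!length(cand)) {
    out <- data.frame(gene_id = character(), group = character(),
                      n_boxes = integer(), contig = character(),
                      best_start0 = integer(), best_end0 = integer(),
                      best_strand = character(), best_score = numeric(),
                      best_sequence = character(),
                      shared_with = character())
    attr(out, "boxes") <- list()
    return(out)
  }
  box_list <- stats::setNames(vector("list", length(cand)), cand)
  rows <- vector("list", length(cand))
  # distinct boxes per gene
  for (gi in seq_along(cand)) {
    g <- cand[[gi]]
    idx <- assignments$hit[assignments$gene_id == g]
    box_list[[g]] <- collapse_boxes(hits, idx)
  }
  # distinct boxes per cluster (union over member genes)
  cl_of <- stats::setNames(genes_cl$cluster, genes_cl$gene_id)
  cl_sizes <- table(genes_cl$cluster)
  cl_boxes <- new.env(parent = emptyenv())
  for (g in cand) {
    cl <- as.character(cl_of[[g]])
    cl_boxes[[cl]] <- union(if (is.null(cl_boxes[[cl]])) integer() else
      cl_boxes[[cl]], box_list[[g]])
  }
  for (gi in seq_along(cand)) {
    g <- cand[[gi]]
    boxes <- box_list[[g]]
    n_boxes <- length(boxes)
    cl <- as.character(cl_of[[g]])
    n_cluster_boxes <- length(collapse_boxes(hits, cl_boxes[[cl]]))
    multi_cluster <- cl_sizes[[cl]] >= 2L
    shared <- NA_character_
    if (multi_cluster && n_cluster_boxes >= 2L) {
      group <- "A"
    } else if (n_boxes >= 2L) {
      group <- "B"
    } else if (!is.na(p <- divergent_partner(g, boxes[[1L]], hits, windows,
                                             genes))) {
      group <- "C"
      shared <- p
    } else {
      group <- "D"
    }
    best_i <- boxes[order(-hits$score[boxes],
                          GenomicRanges::start(hits)[boxes])][1L]
    rows[[gi]] <- data.frame(
      gene_id = g, group = group, n_boxes = n_boxes,
      contig = as.character(GenomicRanges::seqnames(hits))[best_i],
      best_start0 = GenomicRanges::start(hits)[best_i] - 1L,
      best_end0 = GenomicRanges::end(hits)[best_i],
      best_strand = as.character(GenomicRanges::strand(hits))[best_i],
      best_score = hits$score[best_i],
      best_sequence = hits$sequence[best_i],
      shared_with = shared)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "boxes") <- box_list
  out
}

# Find a divergently transcribed partner sharing the given single box:
# opposite strand, overlapping promoter windows, the box inside both
# windows and inside the head-to-head intergenic span (the '-' gene lying
# left of the '+' gene). Returns the nearest partner's gene_id or NA.
divergent_partner <- function(gene_id, box_idx, hits, windows, genes) {
  g <- genes[genes$gene_id == gene_id, ]
  win_g <- windows[windows$gene_id == gene_id]
  box <- hits[box_idx]
  others <- genes[genes$gene_id != gene_id &
                  genes$contig == g$contig &
                  genes$strand != g$strand, , drop = FALSE]
  if (!nrow(others)) return(NA_character_)
  best <- NA_character_
  best_gap <- Inf
  for (i in seq_len(nrow(others))) {
    p <- others[i, ]
    left  <- if (g$strand == "-") g else p
    right <- if (g$strand == "-") p else g
    # head-to-head: '-' gene entirely left of '+' gene
    if (left$end0 > right$start0) next
    inter <- IRanges::IRanges(start = left$end0 + 1L, end = right$start0)
    if (IRanges::width(inter) < GenomicRanges::width(box)) next
    win_p <- windows[windows$gene_id == p$gene_id]
    ok <- length(GenomicRanges::findOverlaps(box, win_p, type = "within",
                                             ignore.strand = TRUE)) > 0L &&
      IRanges::start(box) >= IRanges::start(inter) &&
      IRanges::end(box) <= IRanges::end(inter) &&
      length(GenomicRanges::findOverlaps(win_g, win_p,
                                         ignore.strand = TRUE)) > 0L
    if (ok) {
      gap <- min(abs(p$start0 - g$end0), abs(g$start0 - p$end0))
      if (gap < best_gap) {
        best <- p$gene_id
        best_gap <- gap
      }
    }
  }
  best
}
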