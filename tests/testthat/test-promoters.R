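mk_hits <- function(start0, end0, strand = "+", score = NULL,
                    contig = "chr") {
  n <- length(start0)
  if (is.null(score)) score <- rep(1, n)
  GenomicRanges::GRanges(
    seqnames = rep(contig, n),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = rep(strand, length.out = n),
    score = score, site_length = end0 - start0,
    sequence = rep("N/A", n))
}

test_that("promoter windows span 700 up / 100 down around the start codon", {
  g <- gene_table("g1", "chr", "+", 1000L, 2000L)
  w <- promoter_windows(g)
  expect_identical(GenomicRanges::start(w), 301L)  # 0-based 300
  expect_identical(GenomicRanges::end(w), 1100L)   # half-open 1100
  expect_false(w$clipped)
  # minus-strand mirror image: start codon at end0 - 1
  gm <- gene_table("g2", "chr", "-", 200L, 1001L)  # start codon base 1000
  wm <- promoter_windows(gm)
  expect_identical(GenomicRanges::start(wm), 902L)  # 0-based 901
  expect_identical(GenomicRanges::end(wm), 1701L)
  expect_identical(GenomicRanges::width(wm), 800L)
  # clipping at the left contig edge
  gc <- gene_table("g3", "chr", "+", 50L, 500L)
  wc <- promoter_windows(gc)
  expect_identical(GenomicRanges::start(wc), 1L)
  expect_identical(GenomicRanges::end(wc), 150L)
  expect_true(wc$clipped)
  # clipping at the right contig edge needs contig lengths
  gr <- gene_table("g4", "chr", "-", 100L, 950L)
  wr <- promoter_windows(gr, contig_lengths = c(chr = 1000L))
  expect_identical(GenomicRanges::end(wr), 1000L)
  expect_true(wr$clipped)
  expect_error(promoter_windows(gene_table("g5", "chr", "+", 1500L, 1600L),
                                contig_lengths = c(chr = 1000L)),
               "outside contig")
})

test_that("window arithmetic is an involution under genome flipping", {
  L <- 10000L
  set.seed(60)
  n <- 20L
  starts <- sort(sample(800:9000, n))
  genes <- gene_table(paste0("g", 1:n), "chr",
                      sample(c("+", "-"), n, TRUE), starts, starts + 600L)
  w <- promoter_windows(genes, contig_lengths = c(chr = L))
  flipped <- gene_table(genes$gene_id, "chr",
                        ifelse(genes$strand == "+", "-", "+"),
                        L - genes$end0, L - genes$start0)
  wf <- promoter_windows(flipped, contig_lengths = c(chr = L))
  # flip the flipped windows back to forward coordinates
  back_start0 <- L - GenomicRanges::end(wf)
  back_end0 <- L - (GenomicRanges::start(wf) - 1L)
  expect_identical(back_start0, GenomicRanges::start(w) - 1L)
  expect_identical(back_end0, GenomicRanges::end(w))
})

test_that("hits attach to genes only by full containment", {
  genes <- gene_table("g1", "chr", "+", 1000L, 2000L)
  w <- promoter_windows(genes)  # [300, 1100)
  inside <- mk_hits(310L, 325L)
  straddle <- mk_hits(295L, 310L)
  expect_identical(nrow(assign_hits(inside, w)), 1L)
  expect_identical(nrow(assign_hits(straddle, w)), 0L)
})

test_that("a shared intergenic hit is assigned to both divergent genes", {
  genes <- gene_table(c("left", "right"), "chr", c("-", "+"),
                      c(300L, 1600L), c(1100L, 2500L))
  w <- promoter_windows(genes)
  shared <- mk_hits(1300L, 1315L)
  asg <- assign_hits(shared, w)
  expect_setequal(asg$gene_id, c("left", "right"))
})

test_that("containment assignment equals a brute-force double loop", {
  set.seed(61)
  n <- 60L
  starts <- sort(sample(800:49000, n))
  genes <- gene_table(paste0("g", 1:n), "chr",
                      sample(c("+", "-"), n, TRUE), starts, starts + 500L)
  w <- promoter_windows(genes, contig_lengths = c(chr = 50000L))
  hs <- sort(sample(0:49980, 200L))
  hits <- mk_hits(hs, hs + 15L, strand = sample(c("+", "-"), 200L, TRUE))
  got <- assign_hits(hits, w)
  key_got <- sort(paste(got$gene_id, got$hit))
  brute <- character()
  ws0 <- GenomicRanges::start(w) - 1L
  we0 <- GenomicRanges::end(w)
  for (i in seq_along(hits)) {
    for (j in seq_along(w)) {
      if (hs[i] >= ws0[j] && hs[i] + 15L <= we0[j]) {
        brute <- c(brute, paste(w$gene_id[j], i))
      }
    }
  }
  expect_identical(key_got, sort(brute))
})

test_that("gene clusters are same-strand runs with bounded gaps", {
  g <- gene_table(paste0("g", 1:3), "chr", "+",
                  c(100L, 1110L, 2130L), c(1100L, 2110L, 3000L))
  cl <- gene_clusters(g)  # gaps 10 and 20
  expect_identical(length(unique(cl$cluster)), 1L)
  g2 <- gene_table(c("a", "b"), "chr", "+", c(100L, 1600L),
                   c(1100L, 2000L))
  expect_identical(length(unique(gene_clusters(g2)$cluster)), 2L)
  g3 <- gene_table(c("a", "b", "c"), "chr", c("+", "-", "+"),
                   c(100L, 210L, 320L), c(200L, 310L, 420L))
  expect_identical(length(unique(gene_clusters(g3)$cluster)), 3L)
})

test_that("classification recovers the four engineered layouts", {
  pl <- plant_genome(motif_spec(identity = 1), seed = 3)
  hits <- truth_hits(pl)
  w <- planted_windows(pl)
  cand <- classify_candidates(hits, w, pl$genes)
  focal <- do.call(rbind, lapply(seq_len(nrow(pl$truth)), function(i) {
    data.frame(gene_id = strsplit(pl$truth$gene_id[i], ",")[[1]],
               class = pl$truth$class[i])
  }))
  focal <- unique(focal)
  got <- cand$group[match(focal$gene_id, cand$gene_id)]
  expect_identical(got, focal$class)
  # group multiplicity constraints
  expect_true(all(cand$n_boxes[cand$group %in% c("B")] >= 2))
  expect_true(all(cand$n_boxes[cand$group %in% c("C", "D")] == 1))
  # C genes cross-reference each other
  cpair <- cand[cand$group == "C", ]
  expect_identical(sort(cpair$gene_id), sort(cpair$shared_with))
  # every candidate has exactly one group
  expect_false(any(is.na(cand$group)))
  expect_identical(anyDuplicated(cand$gene_id), 0L)
})

test_that("overlapping 15/16-bp hits collapse to one distinct box", {
  genes <- gene_table("g1", "chr", "+", 1000L, 2000L)
  w <- promoter_windows(genes)
  hits <- c(mk_hits(400L, 415L, score = 5),
            mk_hits(400L, 416L, score = 7))
  cand <- classify_candidates(hits, w, genes)
  expect_identical(cand$n_boxes, 1L)
  expect_identical(cand$group, "D")
  expect_equal(cand$best_score, 7)  # highest-scoring member represents
})

test_that("box ranking is score-descending with coordinate tie-break", {
  hits <- c(mk_hits(100L, 115L, score = 12.3),
            mk_hits(400L, 415L, score = 17.1))
  r <- rank_boxes(hits)
  expect_equal(r$score[1], 17.1)
  tied <- c(mk_hits(400L, 415L, score = 3), mk_hits(100L, 115L, score = 3))
  expect_identical(GenomicRanges::start(rank_boxes(tied))[1], 101L)
  # operon-style pair: the higher-scoring upstream box ranks first
  cb <- c(mk_hits(200L, 215L, score = 18.2), mk_hits(600L, 615L, score = 14.0))
  expect_identical(GenomicRanges::start(rank_boxes(cb))[1], 201L)
})

test_that("a single box inside one window only is class D", {
  genes <- gene_table(c("g1", "g2"), "chr", c("+", "+"),
                      c(1000L, 9000L), c(2000L, 9900L))
  w <- promoter_windows(genes)
  cand <- classify_candidates(mk_hits(400L, 415L), w, genes)
  expect_identical(cand$group, "D")
  expect_true(is.na(cand$shared_with))
})

test_that("GFF3 gene models round-trip through the planted-genome writer", {
  pl <- plant_genome(motif_spec(identity = 1), n_decoys = 2, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_planted(pl, dir)
  genes <- read_genes(paths[["gff3"]])
  expect_identical(genes$gene_id, pl$genes$gene_id)
  expect_identical(genes$start0, pl$genes$start0)
  expect_identical(genes$end0, pl$genes$end0)
  expect_identical(genes$strand, pl$genes$strand)
})
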